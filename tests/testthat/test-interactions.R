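test_that("univariate slope on a balanced binary covariate equals the mean difference", {
  dat <- tibble::tibble(
    qtc = rep(c(400, 410), each = 50),
    flag = rep(c(0, 1), each = 50)
  )
  res <- suppressWarnings(univariate_model(dat, "flag")) # zero-residual fit
  expect_equal(res$slope, 10)
  expect_error(univariate_model(dplyr::mutate(dat, flag = 1), "flag"),
               "constant")
})

test_that("univariate fit matches the closed-form normal-equation slope", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(30:100, 1)
    x <- rnorm(n); y <- 400 + 3 * x + rnorm(n, 0, 5)
    res <- univariate_model(tibble::tibble(qtc = y, x = x), "x")
    slope_cf <- (sum(x * y) - n * mean(x) * mean(y)) /
      (sum(x^2) - n * mean(x)^2)
    expect_equal(res$slope, slope_cf, tolerance = 1e-10)
    o <- oracle_ols(cbind(1, x), y)
    expect_equal(res$se, o$se[2], tolerance = 1e-10)
    expect_equal(res$p, o$p[2], tolerance = 1e-10)
  }
})

test_that("a synthetic female-sex effect is recovered by the univariate model", {
  sim <- simulate_cohort(small_config(seed = 101, n_patients = 1500))
  kept <- filter_ecgs(compute_qtc(sim$ecgs))$kept
  dat <- dplyr::inner_join(kept, sim$patients, by = "patient_id",
                           suffix = c("", ".p"))
  dat$qtc <- dat$qtc_bazett_ms
  res <- univariate_model(dat, "female")
  expect_equal(res$slope, 7.20, tolerance = 2.5 * res$se / 7.20)
})

test_that("interaction d on a balanced saturated 2x2 design equals the cell-mean contrast", {
  cells <- tidyr::expand_grid(med = c(0, 1), cov = c(0, 1), i = 1:25)
  cells$qtc <- dplyr::case_when(
    cells$med == 0 & cells$cov == 0 ~ 400,
    cells$med == 1 & cells$cov == 0 ~ 405,
    cells$med == 0 & cells$cov == 1 ~ 410,
    cells$med == 1 & cells$cov == 1 ~ 425
  )
  res <- suppressWarnings(interaction_model(cells, "med", "cov", drug = "x"))
  expect_equal(res$d, (425 - 410) - (405 - 400), tolerance = 1e-12)
  expect_equal(res$a, 400, tolerance = 1e-12)
  expect_equal(res$b, 5, tolerance = 1e-12)
  expect_equal(res$c, 10, tolerance = 1e-12)
  expect_true(res$estimable)
})

test_that("interaction coefficients match an independent normal-equation solve", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(40:120, 1)
    med <- rbinom(n, 1, 0.5); cov <- rbinom(n, 1, 0.4)
    if (qr(cbind(1, med, cov, med * cov))$rank < 4) next
    y <- 400 + 4 * med + 6 * cov + 3 * med * cov + rnorm(n, 0, 8)
    dat <- tibble::tibble(qtc = y, med = med, cov = cov)
    res <- interaction_model(dat, "med", "cov")
    o <- oracle_ols(cbind(1, med, cov, med * cov), y)
    expect_equal(c(res$a, res$b, res$c, res$d), o$beta, tolerance = 1e-9)
    expect_equal(res$se_d, o$se[4], tolerance = 1e-9)
    expect_equal(res$p_d, o$p[4], tolerance = 1e-9)
  }
})

test_that("collinear designs are flagged inestimable, not fitted", {
  dat <- tibble::tibble(
    qtc = rnorm(40, 400), med = rep(c(0, 1), 20), cov = rep(c(0, 1), 20)
  )
  res <- interaction_model(dat, "med", "cov")
  expect_false(res$estimable)
  expect_equal(res$reason, "collinear_design")
})

test_that("bonferroni_flag thresholds at alpha over the family size and is monotone", {
  mk <- function(p) tibble::tibble(
    drug = "x", covariate = paste0("c", seq_along(p)),
    d = 1, se_d = 1, p_d = p, estimable = TRUE
  )
  res <- bonferroni_flag(mk(c(0.004, 0.006, rep(0.5, 8))), alpha = 0.05)
  expect_equal(res$m_tests, rep(10, 10))
  expect_equal(res$significant[1:2], c(TRUE, FALSE)) # 0.004 < 0.005 < 0.006
  expect_true(bonferroni_flag(mk(0.04), alpha = 0.05)$significant) # m = 1

  # monotone: lowering p never loses significance
  p <- runif(10, 0.001, 0.2)
  f1 <- bonferroni_flag(mk(p))$significant
  f2 <- bonferroni_flag(mk(p * 0.5))$significant
  expect_true(all(f2 >= f1))

  # inestimable cells do not inflate the family size
  part <- mk(c(0.009, 0.5))
  part$estimable[2] <- FALSE
  part$p_d[2] <- NA
  res2 <- bonferroni_flag(part, alpha = 0.05)
  expect_equal(res2$m_tests[1], 1)
  expect_true(res2$significant[1])
  expect_false(res2$significant[2])
})

test_that("heatmap_matrix holds d for significant cells and NA elsewhere", {
  res <- tibble::tibble(
    drug = rep(c("a", "b"), each = 2),
    covariate = rep(c("x", "y"), 2),
    d = c(10, 2, 3, 4),
    significant = c(TRUE, FALSE, FALSE, FALSE)
  )
  hm <- heatmap_matrix(res)
  expect_equal(dim(hm), c(2, 3))
  expect_equal(hm$x[hm$drug == "a"], 10)
  expect_true(is.na(hm$y[hm$drug == "a"]))
  expect_true(all(is.na(unlist(hm[hm$drug == "b", c("x", "y")]))))

  none <- dplyr::mutate(res, significant = FALSE)
  expect_true(all(is.na(unlist(heatmap_matrix(none)[, c("x", "y")]))))
})

test_that("stratified summaries match direct tallies and report empty strata", {
  exposure <- tibble::tibble(
    ecg_id = paste0("e", 1:8), patient_id = "p1", drug = "amiodarone",
    status = rep(c("on", "off_pre"), each = 4)
  )
  ecgs <- make_ecgs(8, qt_ms = seq(360, 430, by = 10))
  ecgs$ecg_id <- paste0("e", 1:8)
  ecgs <- compute_qtc(ecgs)
  ecgs$cad <- c(1, 1, 0, 0, 1, 0, 0, 0)
  out <- stratified_distribution(exposure, ecgs, "amiodarone", "cad")
  expect_equal(nrow(out), 4)
  expect_equal(sum(out$n), 8) # groups partition the cohort
  direct <- mean(ecgs$qtc_bazett_ms[1:2]) # on & cad rows e1, e2
  expect_equal(out$mean[out$level == 1 & out$status == "on"], direct)

  ecgs2 <- dplyr::mutate(ecgs, cad = 0)
  out2 <- stratified_distribution(exposure, ecgs2, "amiodarone", "cad")
  expect_equal(out2$n[out2$level == 1], c(0L, 0L))
  expect_true(all(is.na(out2$mean[out2$level == 1])))
})

test_that("interaction_screen recovers an injected drug-by-comorbidity interaction", {
  cfg <- small_config(
    seed = 77, n_patients = 2500,
    qtc_noise_sd_ms = 12,
    interaction_effects = tibble::tibble(
      drug = "amiodarone", covariate = "cad", d_ms = 12
    )
  )
  sim <- simulate_cohort(cfg)
  kept <- filter_ecgs(compute_qtc(sim$ecgs))$kept
  m <- exposure_matrix(kept, sim$prescriptions, "amiodarone")
  dat <- dplyr::inner_join(kept, sim$patients, by = "patient_id",
                           suffix = c("", ".p"))
  res <- interaction_screen(m, dat, "amiodarone")
  row <- res[res$covariate == "cad", ]
  expect_true(row$estimable)
  expect_equal(row$d, 12, tolerance = 3 * row$se_d / 12)
})
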