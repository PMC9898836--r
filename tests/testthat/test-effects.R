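test_that("mean_delta is the difference of group means and antisymmetric", {
  expect_equal(mean_delta(c(410, 420), c(400, 400)), 15)
  expect_equal(mean_delta(c(400, 410), c(410, 400)), 0)
  set.seed(8)
  on <- rnorm(40); off <- rnorm(25)
  expect_equal(mean_delta(on, off), -mean_delta(off, on))
  expect_error(mean_delta(numeric(0), off), "non-empty")
})

test_that("bootstrap CI is degenerate for constant inputs and reproducible under a fixed seed", {
  cfg <- bootstrap_config(n_replications = 500, seed = 42)
  ci <- bootstrap_ci(rep(410, 20), rep(400, 30), cfg)
  expect_equal(unname(ci["ci_low"]), 10)
  expect_equal(unname(ci["ci_high"]), 10)

  set.seed(1); on <- rnorm(80, 415, 20); off <- rnorm(90, 400, 20)
  ci1 <- bootstrap_ci(on, off, cfg)
  ci2 <- bootstrap_ci(on, off, cfg)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_ci(on, off, bootstrap_config(500, seed = 43))
  expect_false(identical(ci1, ci3))
})

test_that("bootstrap_ci leaves the caller's RNG stream untouched", {
  set.seed(123)
  expected <- runif(5)
  set.seed(123)
  invisible(bootstrap_ci(1:10, 1:10, bootstrap_config(50, seed = 7)))
  expect_identical(runif(5), expected)
})

test_that("the point estimate lies inside its percentile CI on random data", {
  set.seed(12)
  miss <- 0
  for (rep in 1:50) {
    on <- rnorm(sample(20:60, 1), 410, 15)
    off <- rnorm(sample(20:60, 1), 400, 15)
    ci <- bootstrap_ci(on, off, bootstrap_config(1000, seed = rep))
    d <- mean_delta(on, off)
    if (d < ci["ci_low"] || d > ci["ci_high"]) miss <- miss + 1
  }
  expect_lte(miss, 1) # flag-level: rare misses tolerated, frequent ones not
})

test_that("patient-level resampling works and falls back with one cluster", {
  set.seed(3)
  on <- rnorm(60, 412, 10); off <- rnorm(60, 400, 10)
  on_cl <- rep(1:12, each = 5); off_cl <- rep(1:20, each = 3)
  cfg <- bootstrap_config(400, seed = 5, resample_unit = "patient")
  ci <- bootstrap_ci(on, off, cfg, on_cl, off_cl)
  expect_true(ci["ci_low"] < ci["ci_high"])
  expect_true(ci["ci_low"] < 12 && ci["ci_high"] > 12)
  expect_warning(
    bootstrap_ci(on, off, cfg, rep(1, 60), off_cl),
    "falling back"
  )
})

test_that("estimation error shrinks with sample size (root-n recovery)", {
  # average |estimate - truth| at n and 16n; expect roughly a 4x drop,
  # tested with slack at a fixed seed
  set.seed(2024)
  theta <- 15
  err <- vapply(c(50, 800), function(n) {
    mean(vapply(1:40, function(i) {
      abs(mean_delta(rnorm(n, 400 + theta, 25), rnorm(n, 400, 25)) - theta)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(err[2], err[1] / 2)
})

test_that("build_cohort splits by status and flags empty sides", {
  exposure <- tibble::tibble(
    ecg_id = c("e1", "e2", "e3", "e4", "e5"),
    patient_id = "p1",
    drug = "amiodarone",
    status = c("on", "off_pre", "off_post", "indeterminate", "ineligible")
  )
  ecgs <- make_ecgs(5)
  ecgs$ecg_id <- paste0("e", 1:5)
  cohort <- build_cohort(exposure, ecgs, "amiodarone")
  expect_equal(cohort$on$ecg_id, "e1")
  expect_setequal(cohort$off$ecg_id, c("e2", "e3"))
  expect_true(cohort$reportable)

  all_on <- dplyr::mutate(exposure, status = "on")
  expect_false(build_cohort(all_on, ecgs, "amiodarone")$reportable)
})

test_that("screen_effects covers drugs x formulas with child seeds per pair", {
  sim <- simulate_cohort(small_config(seed = 21, n_patients = 400))
  kept <- filter_ecgs(compute_qtc(sim$ecgs))$kept
  drugs <- c("amiodarone", "lisinopril", "metformin")
  m <- exposure_matrix(kept, sim$prescriptions, drugs)
  cfg <- bootstrap_config(n_replications = 200, seed = 9)
  eff <- screen_effects(m, kept, drugs, cfg)
  expect_equal(nrow(eff), length(drugs) * 5)
  expect_setequal(unique(eff$formula), qtc_formula_names())
  expect_true(all(eff$ci_low_ms <= eff$ci_high_ms, na.rm = TRUE))
  expect_true(all(eff$n_on >= 1 & eff$n_off >= 1 | !eff$reportable))

  # determinism and drug-set insensitivity: dropping a drug leaves the
  # others' CIs untouched
  eff2 <- screen_effects(m, kept, drugs[-2], cfg)
  joined <- dplyr::inner_join(
    eff[eff$drug != "lisinopril", c("drug", "formula", "ci_low_ms")],
    eff2[, c("drug", "formula", "ci_low_ms")],
    by = c("drug", "formula")
  )
  expect_equal(joined$ci_low_ms.x, joined$ci_low_ms.y)
})

test_that("hr_sensitivity mirrors the QTc estimator on heart rate", {
  on <- make_ecgs(30, heart_rate_bpm = rep(80, 30))
  off <- make_ecgs(30, heart_rate_bpm = rep(72, 30))
  res <- hr_sensitivity(on, off, bootstrap_config(200, seed = 4))
  expect_equal(unname(res["delta"]), 8)
  expect_equal(unname(res["ci_low"]), 8) # constant groups: degenerate CI
})

test_that("consensus_top applies the at-least-3-of-5 rule with brute-force agreement", {
  # drug 'alpha' top under all formulas; 'beta' under exactly 2
  eff <- tidyr::expand_grid(
    drug = c("alpha", "beta", "gamma", "delta"),
    formula = qtc_formula_names()
  )
  eff$delta_ms <- dplyr::case_when(
    eff$drug == "alpha" ~ 20,
    eff$drug == "beta" & eff$formula %in% c("bazett", "hodges") ~ 15,
    TRUE ~ stats::runif(nrow(eff), 0, 5)
  )
  eff$reportable <- TRUE
  got <- consensus_top(eff, k = 1)
  expect_equal(got$drug, "alpha")
  expect_false("beta" %in% consensus_top(eff, k = 1)$drug)

  # randomized tables vs exhaustive rank intersection
  set.seed(55)
  for (rep in 1:10) {
    drugs <- paste0("d", 1:8)
    tab <- tidyr::expand_grid(drug = drugs, formula = qtc_formula_names())
    tab$delta_ms <- rnorm(nrow(tab))
    tab$reportable <- TRUE
    k <- sample(2:4, 1)
    brute <- Reduce(c, lapply(split(tab, tab$formula), function(s) {
      s$drug[order(-s$delta_ms, s$drug)][1:k]
    }))
    brute_sel <- sort(names(which(table(brute) >= 3)))
    expect_setequal(consensus_top(tab, k)$drug, brute_sel)
  }
})
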