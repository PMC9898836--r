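test_that("coverage intervals merge overlapping and abutting fills", {
  one <- coverage_intervals(make_fills(0, 30))
  expect_equal(one$start, day0)
  expect_equal(one$end, day0 + 30)

  merged <- coverage_intervals(make_fills(c(0, 20), c(30, 30)))
  expect_equal(nrow(merged), 1)
  expect_equal(as.numeric(merged$end - merged$start), 50)

  abutting <- coverage_intervals(make_fills(c(0, 30), c(30, 10)))
  expect_equal(nrow(abutting), 1)

  gapped <- coverage_intervals(make_fills(c(0, 100), c(30, 30)))
  expect_equal(nrow(gapped), 2)

  expect_equal(nrow(coverage_intervals(make_fills(integer(0), integer(0)))), 0)
})

test_that("merged day sets equal the brute-force union over random fills", {
  set.seed(201)
  for (rep in 1:20) {
    f <- random_fills(50)
    iv <- coverage_intervals(make_fills(f$fill_day, f$supply))
    days_pkg <- unlist(lapply(seq_len(nrow(iv)), function(i) {
      seq(as.numeric(iv$start[i] - day0), as.numeric(iv$end[i] - day0) - 1)
    }))
    days_truth <- sort(unique(unlist(mapply(
      function(d, s) seq(d, d + s - 1), f$fill_day, f$supply,
      SIMPLIFY = FALSE
    ))))
    expect_equal(sort(days_pkg), days_truth)
    # disjoint and sorted
    expect_true(all(diff(as.numeric(iv$start)) > 0))
    expect_true(all(as.numeric(iv$end - iv$start) > 0))
    if (nrow(iv) > 1) {
      expect_true(all(utils::head(iv$end, -1) < utils::tail(iv$start, -1)))
    }
  }
})

test_that("medication-list entries get the fallback duration", {
  fills <- make_fills(0, NA)
  fills$source <- "ehr_med_list"
  iv <- coverage_intervals(fills, ehr_list_days = 90)
  expect_equal(as.numeric(iv$end - iv$start), 90)
})

test_that("classify_exposure reproduces the canonical windows", {
  cfg <- exposure_config()
  iv <- coverage_intervals(make_fills(100, 30)) # covers day 100..129
  fills <- day0 + 100
  cls <- function(d) classify_exposure(day0 + d, iv, cfg, fills)
  expect_equal(cls(100), "on")            # fill date itself is covered
  expect_equal(cls(129), "on")
  expect_equal(cls(130), "indeterminate") # end is exclusive; washout window
  expect_equal(cls(130 + 50), "indeterminate") # 50 days post coverage
  expect_equal(cls(130 + 91), "off_post") # beyond washout, within eligibility
  expect_equal(cls(90), "off_pre")        # 10 days before earliest fill
  expect_equal(cls(100 - 400), "ineligible") # off_pre but no fill within 1 y
  expect_equal(cls(130 + 500), "ineligible") # off_post beyond eligibility
})

test_that("pre_only mode downgrades post-treatment ECGs to indeterminate", {
  cfg <- exposure_config(off_mode = "pre_only")
  iv <- coverage_intervals(make_fills(100, 30))
  expect_equal(classify_exposure(day0 + 260, iv, cfg, day0 + 100),
               "indeterminate")
  expect_equal(classify_exposure(day0 + 50, iv, cfg, day0 + 100), "off_pre")
})

test_that("washout anchored at the last fill shifts the post boundary", {
  cfg <- exposure_config(washout_anchor = "last_fill")
  iv <- coverage_intervals(make_fills(100, 30))
  # boundary becomes fill + washout = day 190 instead of day 220
  expect_equal(classify_exposure(day0 + 195, iv, cfg, day0 + 100), "off_post")
  expect_equal(
    classify_exposure(day0 + 195, iv, exposure_config(), day0 + 100),
    "indeterminate"
  )
})

test_that("zero washout and infinite eligibility reduce OFF to the coverage complement on single-interval histories", {
  cfg <- exposure_config(washout_days = 0, eligibility_days = Inf)
  iv <- coverage_intervals(make_fills(100, 30))
  days <- 0:400
  st <- classify_exposure(day0 + days, iv, cfg, day0 + 100)
  on_truth <- days >= 100 & days < 130
  expect_equal(st == "on", on_truth)
  expect_true(all(st[!on_truth] %in% c("off_pre", "off_post")))
})

test_that("classify_exposure matches the day-enumeration oracle on random histories", {
  set.seed(77)
  cfg_pool <- exposure_config()
  cfg_pre <- exposure_config(off_mode = "pre_only")
  for (rep in 1:300) {
    f <- random_fills(sample(1:6, 1))
    iv <- coverage_intervals(make_fills(f$fill_day, f$supply))
    d <- sample(-500:1200, 1)
    for (cfg in list(cfg_pool, cfg_pre)) {
      expect_equal(
        classify_exposure(day0 + d, iv, cfg, day0 + f$fill_day),
        oracle_classify(d, f$fill_day, f$supply,
                        washout = cfg$washout_days,
                        eligibility = cfg$eligibility_days,
                        off_mode = cfg$off_mode),
        label = sprintf("rep %d day %d mode %s", rep, d, cfg$off_mode)
      )
    }
  }
})

test_that("rank_medications selects top drugs, curated unions and exclusions", {
  rx <- tibble::tibble(drug = rep(c("a", "b", "c"), c(5, 3, 1)))
  expect_equal(rank_medications(rx, 2), c("a", "b"))
  expect_equal(rank_medications(rx, 2, cardiovascular_list = "c"),
               c("a", "b", "c"))
  expect_equal(rank_medications(rx, 2, exclusion_list = "a"), "b")
  expect_error(rank_medications(rx, 0), "top_n")

  # tie at the boundary: alphabetical selection, checked by brute force
  rx_tie <- tibble::tibble(drug = rep(c("zeta", "beta", "alpha"), c(4, 2, 2)))
  got <- rank_medications(rx_tie, 2)
  cnt <- table(rx_tie$drug)
  brute <- names(cnt)[order(-as.numeric(cnt), names(cnt))][1:2]
  expect_equal(got, sort(brute))
  expect_equal(got, c("alpha", "zeta"))
})

test_that("exposure_matrix agrees with per-pair classification and supports multi-drug ECGs", {
  fills <- dplyr::bind_rows(
    make_fills(c(0, 35), c(30, 30), drug = "druga"),
    make_fills(10, 60, drug = "drugb"),
    make_fills(0, 30, patient_id = "p0002", drug = "druga")
  )
  ecgs <- make_ecgs(3,
    patient_id = c("p0001", "p0001", "p0002"),
    date = day0 + c(15, 200, 400)
  )
  cfg <- exposure_config()
  m <- exposure_matrix(ecgs, fills, c("druga", "drugb"), cfg)
  # p0001's first ECG is inside both drugs' coverage
  both <- m[m$ecg_id == "e0001", ]
  expect_equal(sort(both$drug), c("druga", "drugb"))
  expect_true(all(both$status == "on"))
  # p0002 never filled drugb: no row
  expect_equal(nrow(m[m$patient_id == "p0002" & m$drug == "drugb", ]), 0)
  # row-level agreement with classify_exposure
  for (i in seq_len(nrow(m))) {
    pf <- fills[fills$patient_id == m$patient_id[i] &
                  fills$drug == m$drug[i], ]
    iv <- coverage_intervals(pf)
    expect_equal(
      m$status[i],
      classify_exposure(ecgs$date[match(m$ecg_id[i], ecgs$ecg_id)],
                        iv, cfg, pf$fill_date)
    )
  }
  expect_warning(exposure_matrix(ecgs, fills, c("druga", "ghost"), cfg),
                 "ghost")
})

test_that("statuses partition: exactly one status per pair, on/off disjoint", {
  sim <- simulate_cohort(small_config(seed = 3, n_patients = 120))
  m <- exposure_matrix(sim$ecgs, sim$prescriptions,
                       unique(sim$prescriptions$drug))
  expect_equal(anyDuplicated(m[, c("ecg_id", "drug")]), 0)
  expect_true(all(m$status %in% exposure_status_levels()))
})
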