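# Independent brute-force oracles. These deliberately share no code with
# the package: exposure is classified by enumerating covered days one by
# one, the ECG filter re-checks each criterion per record, and regressions
# are solved from the normal equations directly.

# day-by-day exposure classifier; dates as integer day numbers
oracle_classify <- function(ecg_day, fill_days, supplies,
                            washout = 90, eligibility = 365,
                            off_mode = "pooled") {
  covered <- sort(unique(unlist(mapply(
    function(f, s) seq(f, f + s - 1),
    fill_days, supplies, SIMPLIFY = FALSE
  ))))
  if (ecg_day %in% covered) return("on")
  status <- if (ecg_day < covered[1]) {
    "off_pre"
  } else if (ecg_day - covered[length(covered)] > washout) {
    "off_post"
  } else {
    "indeterminate"
  }
  if (status == "off_post" && off_mode == "pre_only") {
    status <- "indeterminate"
  }
  if (status %in% c("off_pre", "off_post") &&
      min(abs(fill_days - ecg_day)) > eligibility) {
    status <- "ineligible"
  }
  status
}

# per-record filter check; returns character vector of reasons (empty = keep)
oracle_filter_reasons <- function(rec, hr_min = 40, hr_max = 100,
                                  qrs_max = 120, qtc_min = 300,
                                  qtc_max = 700) {
  reasons <- character(0)
  hr <- rec$heart_rate_bpm; qt <- rec$qt_ms; qrs <- rec$qrs_ms
  malformed <- is.na(hr) || hr <= 0 || is.na(qt) || qt <= 0 ||
    is.na(qrs) || qrs <= 0 || is.na(rec$rhythm) || is.na(rec$setting)
  if (malformed) return("malformed")
  if (hr < hr_min || hr > hr_max) reasons <- c(reasons, "hr_out_of_range")
  if (qrs >= qrs_max) reasons <- c(reasons, "qrs_too_wide")
  qtc <- qt / sqrt(60 / hr)
  if (qtc < qtc_min || qtc > qtc_max) {
    reasons <- c(reasons, "qtc_out_of_range")
  }
  if (rec$rhythm != "sinus") reasons <- c(reasons, "non_sinus")
  if (rec$setting != "outpatient") reasons <- c(reasons, "inpatient")
  reasons
}

# OLS via the normal equations, with classical standard errors and
# two-sided t-test p-values
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(sigma2 * solve(XtX)))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(beta = as.numeric(beta), se = as.numeric(se), p = as.numeric(p))
}

# random prescription history for exposure fuzzing; returns day-number fills
random_fills <- function(n_fills, day0 = 0, horizon = 600,
                         supply_range = c(5, 60)) {
  tibble::tibble(
    fill_day = sort(sample(day0:horizon, n_fills, replace = TRUE)),
    supply = sample(supply_range[1]:supply_range[2], n_fills, replace = TRUE)
  )
}
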