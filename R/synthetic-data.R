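#' Configuration for the synthetic EHR cohort generator
#'
#' Builds the parameter set for [simulate_cohort()]. Defaults emulate a
#' large outpatient ECG cohort: demographic and comorbidity prevalences,
#' covariate effects on QTc, and the heart-rate distribution follow
#' typical values for an academic-center outpatient population (age mean
#' 59.8, SD 18.7 years; 53.5% female; 44.6% non-White; heart rate mean
#' 73.2, SD 12.6 bpm; hypertension 23.1%, coronary artery disease 10.9%,
#' heart failure 7.6%, diabetes 10.3%, chronic kidney disease 8.8%, liver
#' disease 1.5%, COPD 2.7%). The residual QTc noise SD (27.7 ms) is set
#' so the marginal Bazett QTc SD is about 29.4 ms once covariate-mix
#' variance is added, and the baseline (412 ms) puts the marginal mean
#' near 437 ms.
#'
#' True QTc for an ECG is
#' `baseline + sum(covariate effects) + sum(active drug effects and
#' interactions) + Gaussian noise`; the stored QT is back-computed by
#' inverting the Bazett formula (`QT = QTc * sqrt(RR)`) so the pipeline's
#' forward computation recovers the intended Bazett QTc exactly.
#'
#' @param n_patients Number of patients.
#' @param date_range Length-2 `Date` vector of the study window.
#' @param seed Integer seed; fully determines all output.
#' @param female_fraction,non_white_fraction Demographic prevalences.
#' @param age_mean,age_sd,age_range Age distribution (years), truncated.
#' @param comorbidity_prevalence Named vector of per-condition fractions.
#' @param covariate_effects_ms Named vector of additive QTc effects (ms);
#'   age effect is per decade.
#' @param baseline_qtc_ms Intercept of the true-QTc model.
#' @param qtc_noise_sd_ms Residual Gaussian noise SD (ms).
#' @param hr_mean_bpm,hr_sd_bpm,hr_range_bpm Heart-rate distribution
#'   (truncated normal).
#' @param qrs_mean_ms,qrs_sd_ms QRS distribution for clean records,
#'   truncated below 120 ms.
#' @param ecgs_per_patient_lambda ECGs per patient are
#'   `1 + Poisson(lambda)`.
#' @param contamination_fraction Fraction of ECGs given exactly one
#'   filter violation (non-sinus rhythm, inpatient setting, out-of-range
#'   heart rate, wide QRS, or out-of-range QTc), to exercise the filters.
#' @param drug_catalogue Tibble `drug`, `effect_ms`, `tdp_class`,
#'   `prevalence`; see [default_drug_catalogue()].
#' @param interaction_effects Tibble `drug`, `covariate`, `d_ms` of true
#'   medication-by-covariate interaction effects.
#' @param days_supply Days covered per pharmacy fill.
#' @param refill_mean Mean extra fills per treatment episode (Poisson).
#' @param gap_long_prob,gap_long_range Probability and day range of a
#'   long refill gap (creates indeterminate and post-treatment windows).
#' @param gap_short_mean Mean of the usual short refill gap (Poisson
#'   days).
#' @param ehr_list_fraction Fraction of prescription rows emitted as
#'   medication-list entries with missing days supply.
#' @param confounded_drug,confounding_strength Optional
#'   confounding-by-indication stressor: the named drug is prescribed
#'   preferentially to patients with high covariate-driven baseline QTc
#'   (log-odds shift per 10 ms of baseline above average).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_patients = 2000,
    date_range = as.Date(c("2008-09-30", "2019-12-31")),
    seed = 1,
    female_fraction = 0.535,
    non_white_fraction = 0.446,
    age_mean = 59.81, age_sd = 18.67, age_range = c(18, 100),
    comorbidity_prevalence = c(
      hypertension = 0.231, cad = 0.109, heart_failure = 0.076,
      diabetes = 0.103, ckd = 0.088, liver_disease = 0.015, copd = 0.027
    ),
    covariate_effects_ms = c(
      age_decades = 2.5, female = 7.20, non_white = 1.08,
      hypertension = 6.93, cad = 4.70, heart_failure = 17.1,
      diabetes = 8.57, ckd = 14.7, liver_disease = 16.4, copd = 6.89
    ),
    baseline_qtc_ms = 412,
    qtc_noise_sd_ms = 27.7,
    hr_mean_bpm = 73.20, hr_sd_bpm = 12.56, hr_range_bpm = c(40, 100),
    qrs_mean_ms = 88.14, qrs_sd_ms = 11.16,
    ecgs_per_patient_lambda = 0.95,
    contamination_fraction = 0.05,
    drug_catalogue = default_drug_catalogue(),
    interaction_effects = default_interaction_effects(),
    days_supply = 30,
    refill_mean = 3,
    gap_long_prob = 0.07, gap_long_range = c(100, 300),
    gap_short_mean = 5,
    ehr_list_fraction = 0.05,
    confounded_drug = NULL,
    confounding_strength = 0) {
  stopifnot(
    n_patients >= 0, length(date_range) == 2, date_range[1] < date_range[2],
    all(comorbidity_prevalence >= 0 & comorbidity_prevalence <= 1),
    female_fraction >= 0, female_fraction <= 1,
    non_white_fraction >= 0, non_white_fraction <= 1,
    contamination_fraction >= 0, contamination_fraction <= 1,
    qtc_noise_sd_ms >= 0, days_supply >= 1,
    all(drug_catalogue$prevalence >= 0 & drug_catalogue$prevalence <= 1)
  )
  structure(as.list(environment()), class = "generator_config")
}

#' Default synthetic drug catalogue
#'
#' A small catalogue of familiar drug names with plausible synthetic
#' additive QTc effects (ms) and TdP risk classes, spanning strong
#' prolongers, a shortener, and nulls. All values are generator inputs,
#' not clinical claims.
#'
#' @return Tibble `drug`, `effect_ms`, `tdp_class`, `prevalence`.
#' @export
default_drug_catalogue <- function() {
  tibble::tibble(
    drug = c("dofetilide", "amiodarone", "sotalol", "fluoxetine",
             "mirtazapine", "lisinopril", "metformin", "digoxin"),
    effect_ms = c(21.52, 14.96, 10.73, 4, 2, 0, 0, -21.02),
    tdp_class = c("known_risk", "known_risk", "known_risk",
                  "conditional_risk", "possible_risk", "unclassified",
                  "unclassified", "unclassified"),
    prevalence = c(0.015, 0.05, 0.03, 0.08, 0.05, 0.12, 0.10, 0.03)
  )
}

#' Default true interaction effects
#'
#' One synthetic medication-by-comorbidity interaction (amiodarone and
#' coronary artery disease) so the interaction screen has a recoverable
#' signal by default.
#'
#' @return Tibble `drug`, `covariate`, `d_ms`.
#' @export
default_interaction_effects <- function() {
  tibble::tibble(drug = "amiodarone", covariate = "cad", d_ms = 8)
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (n == 0) return(numeric(0))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

#' Generate the synthetic patient table
#'
#' Demographics and comorbidity flags are drawn independently at the
#' configured prevalences. Deterministic under the configuration seed.
#'
#' @param config A [generator_config()].
#' @return Tibble with `patient_id`, `age`, `age_decades`, `sex`, `race`,
#'   `female`, `non_white`, and one 0/1 column per comorbidity.
#' @export
generate_patients <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patients
  with_seed(child_seed(config$seed, "patients"), {
    out <- tibble::tibble(
      patient_id = sprintf("p%05d", seq_len(n)),
      age = round(rtruncnorm(n, config$age_mean, config$age_sd,
                             config$age_range[1], config$age_range[2]), 1),
      female = as.integer(stats::runif(n) < config$female_fraction),
      non_white = as.integer(stats::runif(n) < config$non_white_fraction)
    )
    out$age_decades <- out$age / 10
    out$sex <- ifelse(out$female == 1, "female", "male")
    out$race <- ifelse(out$non_white == 1, "non_white", "white")
    for (cm in names(config$comorbidity_prevalence)) {
      out[[cm]] <- as.integer(
        stats::runif(n) < config$comorbidity_prevalence[[cm]]
      )
    }
    out[, c("patient_id", "age", "age_decades", "sex", "race", "female",
            "non_white", names(config$comorbidity_prevalence))]
  })
}

# covariate-driven part of true QTc per patient (no baseline, no drugs)
covariate_qtc <- function(patients, config) {
  eff <- config$covariate_effects_ms
  contrib <- rep(0, nrow(patients))
  for (nm in names(eff)) {
    if (!nm %in% names(patients)) next
    contrib <- contrib + eff[[nm]] * as.numeric(patients[[nm]])
  }
  contrib
}

#' Generate synthetic prescription fills
#'
#' For each (patient, drug) pair a prescribing event occurs at the
#' catalogue prevalence; each event yields a treatment episode of one or
#' more fills with stochastic refill gaps. Occasional long gaps exceed
#' the washout so post-treatment ECGs exist. A configurable fraction of
#' rows are emitted as EHR medication-list entries with missing days
#' supply. With the confounding stressor enabled, the named drug's
#' prescribing odds increase with the patient's covariate-driven
#' baseline QTc.
#'
#' @param config A [generator_config()].
#' @param patients Output of [generate_patients()].
#' @return Tibble `patient_id`, `drug`, `fill_date`, `days_supply`,
#'   `source`.
#' @export
generate_prescriptions <- function(config, patients) {
  stopifnot(inherits(config, "generator_config"))
  cat <- config$drug_catalogue
  if (nrow(patients) == 0 || nrow(cat) == 0 || all(cat$prevalence == 0)) {
    empty <- tibble::tibble(patient_id = character(), drug = character(),
                            fill_date = as.Date(character()),
                            days_supply = integer(), source = character())
    return(empty)
  }
  base_qtc <- covariate_qtc(patients, config)
  base_centered <- base_qtc - mean(base_qtc)
  d0 <- as.numeric(config$date_range[1])
  d1 <- as.numeric(config$date_range[2])

  with_seed(child_seed(config$seed, "prescriptions"), {
    rows <- lapply(seq_len(nrow(cat)), function(j) {
      dg <- cat$drug[j]
      prev <- cat$prevalence[j]
      if (prev == 0) return(NULL)
      p <- rep(prev, nrow(patients))
      if (!is.null(config$confounded_drug) && dg == config$confounded_drug) {
        p <- stats::plogis(stats::qlogis(prev) +
                             config$confounding_strength * base_centered / 10)
      }
      takers <- which(stats::runif(nrow(patients)) < p)
      if (length(takers) == 0) return(NULL)
      dplyr::bind_rows(lapply(takers, function(i) {
        n_fills <- 1L + stats::rpois(1, config$refill_mean)
        start <- floor(stats::runif(1, d0, max(d0 + 1, d1 - 200)))
        dates <- numeric(n_fills)
        cur <- start
        for (k in seq_len(n_fills)) {
          dates[k] <- cur
          gap <- if (stats::runif(1) < config$gap_long_prob) {
            floor(stats::runif(1, config$gap_long_range[1],
                               config$gap_long_range[2] + 1))
          } else {
            stats::rpois(1, config$gap_short_mean)
          }
          cur <- cur + config$days_supply + gap
        }
        is_list <- stats::runif(n_fills) < config$ehr_list_fraction
        tibble::tibble(
          patient_id = patients$patient_id[i],
          drug = dg,
          fill_date = as.Date(dates, origin = "1970-01-01"),
          days_supply = ifelse(is_list, NA_integer_,
                               as.integer(config$days_supply)),
          source = ifelse(is_list, "ehr_med_list", "pharmacy_fill")
        )
      }))
    })
    out <- dplyr::bind_rows(rows)
    dplyr::arrange(out, .data$patient_id, .data$drug, .data$fill_date)
  })
}

# independent day-level enumeration classifier used for generator truth:
# walks the covered day set directly rather than interval arithmetic
truth_status_days <- function(day, covered_days, fill_days, washout,
                              eligibility, off_mode) {
  if (length(covered_days) == 0) return("ineligible")
  if (day %in% covered_days) return("on")
  status <- if (day < min(covered_days)) {
    "off_pre"
  } else if (day - max(covered_days) > washout) {
    "off_post"
  } else {
    "indeterminate"
  }
  if (status == "off_post" && off_mode == "pre_only") status <- "indeterminate"
  if (status %in% c("off_pre", "off_post") &&
      min(abs(fill_days - day)) > eligibility) {
    status <- "ineligible"
  }
  status
}

#' Generate synthetic ECGs and ground truth
#'
#' ECG dates are sampled before, during, and after each patient's
#' treatment episodes (plus background dates), so all exposure statuses
#' occur. True Bazett QTc is the configured baseline plus covariate
#' effects plus the effects (and interactions) of every drug actually
#' covered on the ECG date, plus Gaussian noise; heart rate is a
#' truncated normal and QT is back-computed as `QTc * sqrt(RR)`. Clean
#' records always pass the default filters; a `contamination_fraction`
#' of records receive exactly one filter violation.
#'
#' @param config A [generator_config()].
#' @param patients Output of [generate_patients()].
#' @param prescriptions Output of [generate_prescriptions()].
#' @param exposure_cfg The [exposure_config()] whose washout/eligibility
#'   rules define the exported true exposure statuses.
#' @return List with `ecgs` (pipeline input schema: `ecg_id`,
#'   `patient_id`, `date`, `rhythm`, `heart_rate_bpm`, `qrs_ms`, `qt_ms`,
#'   `setting`, `sex`) and `truth` (list of `ecg` — per-ECG true QTc and
#'   contamination flags; `exposure` — per-(ECG, drug) true status for
#'   every drug the patient was ever prescribed; `drugs` — the
#'   catalogue; `interactions`; `patients`).
#' @export
generate_ecgs <- function(config, patients, prescriptions,
                          exposure_cfg = exposure_config()) {
  stopifnot(inherits(config, "generator_config"))
  base_qtc <- config$baseline_qtc_ms + covariate_qtc(patients, config)
  cat <- config$drug_catalogue
  inter <- config$interaction_effects

  # per-patient, per-drug covered day sets and fill days
  rx_by_pd <- split(prescriptions,
                    list(prescriptions$patient_id, prescriptions$drug),
                    drop = TRUE)
  cover <- lapply(rx_by_pd, function(f) {
    iv <- coverage_intervals(f, ehr_list_days = exposure_cfg$ehr_list_days)
    list(days = unlist(lapply(seq_len(nrow(iv)), function(i) {
           seq(as.numeric(iv$start[i]), as.numeric(iv$end[i]) - 1)
         })),
         fills = as.numeric(as.Date(f$fill_date)))
  })

  d0 <- as.numeric(config$date_range[1])
  d1 <- as.numeric(config$date_range[2])

  with_seed(child_seed(config$seed, "ecgs"), {
    ecg_rows <- lapply(seq_len(nrow(patients)), function(i) {
      pid <- patients$patient_id[i]
      n_ecg <- 1L + stats::rpois(1, config$ecgs_per_patient_lambda)
      keys <- names(cover)[startsWith(names(cover), paste0(pid, "."))]
      dates <- vapply(seq_len(n_ecg), function(k) {
        if (length(keys) == 0 || stats::runif(1) < 0.1) {
          return(floor(stats::runif(1, d0, d1 + 1)))
        }
        cv <- cover[[sample(keys, 1)]]
        u <- stats::runif(1)
        if (u < 0.45) {
          cv$days[sample.int(length(cv$days), 1)]
        } else if (u < 0.75) {
          min(cv$days) - floor(stats::runif(1, 1, 366))
        } else {
          max(cv$days) + floor(stats::runif(1, exposure_cfg$washout_days + 1,
                                            366))
        }
      }, numeric(1))
      tibble::tibble(patient_id = pid, date_num = dates)
    })
    ecg <- dplyr::bind_rows(ecg_rows)
    n <- nrow(ecg)
    ecg$ecg_id <- sprintf("e%06d", seq_len(n))

    # drug effects active on each ECG date
    pat_idx <- match(ecg$patient_id, patients$patient_id)
    drug_eff <- rep(0, n)
    active_list <- vector("list", n)
    for (j in seq_len(n)) {
      pid <- ecg$patient_id[j]
      keys <- names(cover)[startsWith(names(cover), paste0(pid, "."))]
      act <- character(0)
      for (key in keys) {
        if (ecg$date_num[j] %in% cover[[key]]$days) {
          dg <- sub(paste0("^", pid, "\\."), "", key)
          act <- c(act, dg)
          drug_eff[j] <- drug_eff[j] + cat$effect_ms[match(dg, cat$drug)]
          if (nrow(inter) > 0) {
            hits <- inter[inter$drug == dg, , drop = FALSE]
            for (h in seq_len(nrow(hits))) {
              cvv <- as.numeric(patients[[hits$covariate[h]]][pat_idx[j]])
              drug_eff[j] <- drug_eff[j] + hits$d_ms[h] * cvv
            }
          }
        }
      }
      active_list[[j]] <- act
    }

    qtc_true <- base_qtc[pat_idx] + drug_eff +
      stats::rnorm(n, 0, config$qtc_noise_sd_ms)
    qtc_true <- pmin(pmax(qtc_true, 301), 699) # clean records must pass filters
    hr <- rtruncnorm(n, config$hr_mean_bpm, config$hr_sd_bpm,
                     config$hr_range_bpm[1], config$hr_range_bpm[2])
    qrs <- rtruncnorm(n, config$qrs_mean_ms, config$qrs_sd_ms, 50, 119.5)
    rhythm <- rep("sinus", n)
    setting <- rep("outpatient", n)

    contaminated <- stats::runif(n) < config$contamination_fraction
    ctype <- rep(NA_character_, n)
    if (any(contaminated)) {
      idx <- which(contaminated)
      ctype[idx] <- sample(c("non_sinus", "inpatient", "hr_out", "qrs_wide",
                             "qtc_out"), length(idx), replace = TRUE)
      rhythm[idx[ctype[idx] == "non_sinus"]] <- "afib"
      setting[idx[ctype[idx] == "inpatient"]] <- "inpatient"
      k <- idx[ctype[idx] == "hr_out"]
      hr[k] <- ifelse(stats::runif(length(k)) < 0.5,
                      stats::runif(length(k), 101, 140),
                      stats::runif(length(k), 25, 39))
      k <- idx[ctype[idx] == "qrs_wide"]
      qrs[k] <- stats::runif(length(k), 120, 180)
      k <- idx[ctype[idx] == "qtc_out"]
      qtc_true[k] <- ifelse(stats::runif(length(k)) < 0.5,
                            stats::runif(length(k), 705, 760),
                            stats::runif(length(k), 250, 295))
    }

    rr <- 60 / hr
    ecgs <- tibble::tibble(
      ecg_id = ecg$ecg_id,
      patient_id = ecg$patient_id,
      date = as.Date(ecg$date_num, origin = "1970-01-01"),
      rhythm = rhythm,
      heart_rate_bpm = round(hr, 1),
      qrs_ms = round(qrs, 1),
      qt_ms = qtc_true * sqrt(60 / round(hr, 1)),
      setting = setting,
      sex = patients$sex[pat_idx]
    )

    # true exposure status for every (ECG, ever-prescribed drug) pair,
    # via the day-enumeration classifier
    truth_rows <- lapply(seq_len(n), function(j) {
      pid <- ecg$patient_id[j]
      keys <- names(cover)[startsWith(names(cover), paste0(pid, "."))]
      if (length(keys) == 0) return(NULL)
      tibble::tibble(
        ecg_id = ecg$ecg_id[j],
        drug = sub(paste0("^", pid, "\\."), "", keys),
        status = vapply(keys, function(key) {
          truth_status_days(ecg$date_num[j], cover[[key]]$days,
                            cover[[key]]$fills,
                            exposure_cfg$washout_days,
                            exposure_cfg$eligibility_days,
                            exposure_cfg$off_mode)
        }, character(1), USE.NAMES = FALSE)
      )
    })
    truth_exposure <- dplyr::bind_rows(truth_rows)

    list(
      ecgs = ecgs,
      truth = list(
        ecg = tibble::tibble(
          ecg_id = ecg$ecg_id, patient_id = ecg$patient_id,
          qtc_true_ms = qtc_true, contaminated = contaminated,
          contamination_type = ctype,
          n_active_drugs = lengths(active_list)
        ),
        exposure = truth_exposure,
        drugs = cat,
        interactions = inter,
        patients = patients
      )
    )
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generate_patients()], [generate_prescriptions()] and
#' [generate_ecgs()] and assembles the four pipeline input tables plus
#' ground truth. Byte-identical output under a fixed configuration.
#'
#' @param config A [generator_config()].
#' @param exposure_cfg [exposure_config()] defining the truth statuses.
#' @return List `patients`, `prescriptions`, `ecgs`, `risk_classes`
#'   (tibble `drug`, `tdp_class`), `truth`.
#' @export
simulate_cohort <- function(config = generator_config(),
                            exposure_cfg = exposure_config()) {
  patients <- generate_patients(config)
  prescriptions <- generate_prescriptions(config, patients)
  gen <- generate_ecgs(config, patients, prescriptions, exposure_cfg)
  list(
    patients = patients,
    prescriptions = prescriptions,
    ecgs = gen$ecgs,
    risk_classes = config$drug_catalogue[, c("drug", "tdp_class")],
    truth = gen$truth
  )
}

#' Write a simulated cohort and its ground truth to disk
#'
#' Writes the four pipeline input tables and machine-readable truth
#' tables as headered CSV files.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of file paths.
#' @export
export_ground_truth <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    patients = file.path(dir, "patients.csv"),
    prescriptions = file.path(dir, "prescriptions.csv"),
    ecgs = file.path(dir, "ecgs.csv"),
    risk_classes = file.path(dir, "risk_classes.csv"),
    truth_ecg = file.path(dir, "truth_ecg.csv"),
    truth_exposure = file.path(dir, "truth_exposure.csv"),
    truth_drugs = file.path(dir, "truth_drugs.csv")
  )
  readr::write_csv(cohort$patients, paths["patients"])
  readr::write_csv(cohort$prescriptions, paths["prescriptions"])
  readr::write_csv(cohort$ecgs, paths["ecgs"])
  readr::write_csv(cohort$risk_classes, paths["risk_classes"])
  readr::write_csv(cohort$truth$ecg, paths["truth_ecg"])
  readr::write_csv(cohort$truth$exposure, paths["truth_exposure"])
  readr::write_csv(cohort$truth$drugs, paths["truth_drugs"])
  invisible(paths)
}
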