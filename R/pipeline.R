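#' Read the four pipeline input tables
#'
#' Thin readers over [readr::read_csv()] with explicit column types and
#' ISO-8601 date parsing.
#'
#' @param path Path to a headered CSV file.
#' @return A tibble in the corresponding input schema.
#' @name readers
NULL

#' @rdname readers
#' @export
read_ecgs <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    ecg_id = readr::col_character(), patient_id = readr::col_character(),
    date = readr::col_date(), rhythm = readr::col_character(),
    heart_rate_bpm = readr::col_double(), qrs_ms = readr::col_double(),
    qt_ms = readr::col_double(), setting = readr::col_character(),
    sex = readr::col_character(), .default = readr::col_guess()
  ))
}

#' @rdname readers
#' @export
read_prescriptions <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), drug = readr::col_character(),
    fill_date = readr::col_date(), days_supply = readr::col_double(),
    .default = readr::col_guess()
  ))
}

#' @rdname readers
#' @export
read_patients <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), .default = readr::col_guess()
  ))
}

#' @rdname readers
#' @export
read_risk_classes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    drug = readr::col_character(), tdp_class = readr::col_character()
  ))
}

#' Validate pipeline inputs
#'
#' Schema, date, and referential-integrity checks over the four input
#' tables. Hard errors (missing required columns, unparseable values)
#' are distinguished from warnings (orphan patient identifiers, unknown
#' risk classes).
#'
#' @param ecgs,prescriptions,patients,risk_classes Input tibbles (any may
#'   be `NULL` to skip its checks).
#' @return Tibble `level` (`"error"`/`"warning"`), `table`, `message`;
#'   zero rows when everything is clean.
#' @export
validate_inputs <- function(ecgs = NULL, prescriptions = NULL,
                            patients = NULL, risk_classes = NULL) {
  findings <- list()
  note <- function(level, table, message) {
    findings[[length(findings) + 1]] <<- tibble::tibble(
      level = level, table = table, message = message
    )
  }
  need_cols <- function(df, table, cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      note("error", table,
           paste0("missing column(s): ", paste(miss, collapse = ", ")))
    }
    length(miss) == 0
  }

  if (!is.null(ecgs)) {
    if (need_cols(ecgs, "ecgs",
                  c("ecg_id", "patient_id", "date", "rhythm",
                    "heart_rate_bpm", "qrs_ms", "qt_ms", "setting", "sex"))) {
      if (anyNA(as.Date(ecgs$date))) {
        note("error", "ecgs", "unparseable date values")
      }
      if (anyDuplicated(ecgs$ecg_id)) {
        note("error", "ecgs", "duplicate ecg_id values")
      }
      bad <- sum(!is.finite(ecgs$heart_rate_bpm) | ecgs$heart_rate_bpm <= 0 |
                   !is.finite(ecgs$qt_ms) | ecgs$qt_ms <= 0)
      if (bad > 0) {
        note("warning", "ecgs",
             paste0(bad, " record(s) with non-positive or missing ",
                    "heart rate or QT (will be excluded as malformed)"))
      }
    }
  }
  if (!is.null(prescriptions)) {
    if (need_cols(prescriptions, "prescriptions",
                  c("patient_id", "drug", "fill_date", "days_supply"))) {
      if (anyNA(as.Date(prescriptions$fill_date))) {
        note("error", "prescriptions", "unparseable fill_date values")
      }
      src <- if ("source" %in% names(prescriptions)) {
        prescriptions$source
      } else "pharmacy_fill"
      bad <- sum(is.na(prescriptions$days_supply) & src != "ehr_med_list")
      if (bad > 0) {
        note("error", "prescriptions",
             paste0(bad, " pharmacy fill(s) with missing days_supply"))
      }
      neg <- sum(!is.na(prescriptions$days_supply) &
                   prescriptions$days_supply < 1)
      if (neg > 0) {
        note("error", "prescriptions",
             paste0(neg, " fill(s) with days_supply < 1"))
      }
    }
  }
  if (!is.null(patients)) {
    need_cols(patients, "patients", "patient_id")
  }
  if (!is.null(risk_classes)) {
    if (need_cols(risk_classes, "risk_classes", c("drug", "tdp_class"))) {
      unknown <- setdiff(unique(risk_classes$tdp_class), tdp_class_levels())
      if (length(unknown) > 0) {
        note("warning", "risk_classes",
             paste0("unknown class label(s): ",
                    paste(unknown, collapse = ", ")))
      }
    }
  }
  if (!is.null(patients) && !is.null(ecgs) &&
      "patient_id" %in% names(patients) && "patient_id" %in% names(ecgs)) {
    orphans <- sum(!ecgs$patient_id %in% patients$patient_id)
    if (orphans > 0) {
      note("warning", "ecgs",
           paste0(orphans, " ECG(s) reference unknown patient_id"))
    }
  }
  if (!is.null(patients) && !is.null(prescriptions) &&
      "patient_id" %in% names(patients) &&
      "patient_id" %in% names(prescriptions)) {
    orphans <- sum(!prescriptions$patient_id %in% patients$patient_id)
    if (orphans > 0) {
      note("warning", "prescriptions",
           paste0(orphans, " fill(s) reference unknown patient_id"))
    }
  }
  if (length(findings) == 0) {
    return(tibble::tibble(level = character(), table = character(),
                          message = character()))
  }
  dplyr::bind_rows(findings)
}

#' Simulate a cohort and write it to disk
#'
#' @param out_dir Output directory.
#' @param config A [generator_config()].
#' @param exposure_cfg [exposure_config()] for the exported truth.
#' @return Invisibly, the cohort list from [simulate_cohort()].
#' @export
qt_simulate <- function(out_dir, config = generator_config(),
                        exposure_cfg = exposure_config()) {
  cohort <- simulate_cohort(config, exposure_cfg)
  export_ground_truth(cohort, out_dir)
  write_manifest(out_dir, stage = "simulate", seed = config$seed,
                 counts = c(patients = nrow(cohort$patients),
                            prescriptions = nrow(cohort$prescriptions),
                            ecgs = nrow(cohort$ecgs)))
  invisible(cohort)
}

#' Run the end-to-end medication screen
#'
#' Chains ECG quality control, exposure classification, bootstrap effect
#' estimation and risk-class summarisation: computes the five QTc
#' corrections, applies the inclusion filters, classifies every (ECG,
#' drug) pair, estimates per-drug per-formula mean QTc differences with
#' percentile bootstrap CIs, and summarises drug-level effects (primary
#' formula) by TdP risk class.
#'
#' @param ecgs,prescriptions,risk_classes Input tibbles.
#' @param drugs Drug set to screen; defaults to every drug in
#'   `prescriptions`.
#' @param criteria [filter_criteria()].
#' @param exp_config [exposure_config()].
#' @param boot_config [bootstrap_config()].
#' @param primary_formula Formula used for the class summary (default
#'   `"bazett"`).
#' @param out_dir Optional directory; when given, writes
#'   `ecgs_qtc.csv`, `exclusion_log.csv`, `exposure_matrix.csv`,
#'   `effects.csv`, `class_summary.csv` and a run manifest.
#' @return List `filtered` (from [filter_ecgs()]), `exposure`, `effects`
#'   (with `tdp_class` joined), `class_summary`, `ordering`.
#' @export
qt_screen <- function(ecgs, prescriptions, risk_classes = NULL,
                      drugs = NULL,
                      criteria = filter_criteria(),
                      exp_config = exposure_config(),
                      boot_config = bootstrap_config(),
                      primary_formula = "bazett",
                      out_dir = NULL) {
  ecgs <- compute_qtc(ecgs)
  filtered <- filter_ecgs(ecgs, criteria)
  if (is.null(drugs)) drugs <- sort(unique(prescriptions$drug))
  exposure <- exposure_matrix(filtered$kept, prescriptions, drugs, exp_config)
  effects <- screen_effects(exposure, filtered$kept, drugs, boot_config)

  if (is.null(risk_classes)) {
    risk_classes <- tibble::tibble(drug = character(), tdp_class = character())
  }
  effects <- dplyr::left_join(effects, risk_classes, by = "drug")
  effects$tdp_class[is.na(effects$tdp_class)] <- "unclassified"

  primary <- effects[effects$formula == primary_formula &
                       effects$reportable, , drop = FALSE]
  class_summary <- summarize_by_class(primary, risk_classes)
  ordering <- ordering_check(class_summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(filtered$kept, file.path(out_dir, "ecgs_qtc.csv"))
    readr::write_csv(filtered$exclusion_log,
                     file.path(out_dir, "exclusion_log.csv"))
    readr::write_csv(exposure, file.path(out_dir, "exposure_matrix.csv"))
    readr::write_csv(effects, file.path(out_dir, "effects.csv"))
    readr::write_csv(class_summary, file.path(out_dir, "class_summary.csv"))
    write_manifest(out_dir, stage = "screen", seed = boot_config$seed,
                   counts = c(ecgs_in = nrow(ecgs),
                              ecgs_kept = nrow(filtered$kept),
                              exposure_rows = nrow(exposure),
                              effect_rows = nrow(effects)))
  }
  list(filtered = filtered, exposure = exposure, effects = effects,
       class_summary = class_summary, ordering = ordering)
}

#' Run the interaction screen end to end
#'
#' Screens medication-by-covariate interactions for the consensus top
#' QTc-prolonging drugs (those in the top `k` under at least 3 of the 5
#' formulas) or for a user-supplied drug list, and assembles the
#' heat-map matrix of significant interaction coefficients.
#'
#' @param screen Output of [qt_screen()].
#' @param patients Patient table with covariate columns.
#' @param drugs Optional explicit drug list; default: consensus top.
#' @param k Top-rank cutoff for the consensus rule (default 10).
#' @param covariates Covariate column names (default
#'   `covariate_specs()$name`).
#' @param alpha Per-medication family-wise significance level.
#' @param formula QTc formula column to model (default `"bazett"`).
#' @param out_dir Optional directory for `interactions.csv` and
#'   `heatmap_matrix.csv`.
#' @return List `results` (long), `heatmap` (wide), `drugs`.
#' @export
qt_interact <- function(screen, patients, drugs = NULL, k = 10,
                        covariates = covariate_specs()$name,
                        alpha = 0.05, formula = "bazett", out_dir = NULL) {
  if (is.null(drugs)) {
    drugs <- consensus_top(screen$effects, k)$drug
  }
  ecgs_cov <- dplyr::inner_join(screen$filtered$kept, patients,
                                by = "patient_id",
                                suffix = c("", ".patient"))
  results <- interaction_screen(screen$exposure, ecgs_cov, drugs,
                                covariates = covariates,
                                formula = formula, alpha = alpha)
  hm <- if (nrow(results) > 0) {
    heatmap_matrix(results)
  } else {
    tibble::tibble(drug = character())
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(results, file.path(out_dir, "interactions.csv"))
    readr::write_csv(hm, file.path(out_dir, "heatmap_matrix.csv"))
  }
  list(results = results, heatmap = hm, drugs = drugs)
}

# machine-readable record of a run: stage, seed, row counts, and a hash
# of the counts so reruns can be compared cheaply
write_manifest <- function(out_dir, stage, seed, counts) {
  manifest <- list(
    stage = stage,
    seed = unname(seed),
    counts = as.list(counts),
    counts_hash = rlang::hash(counts)
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
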