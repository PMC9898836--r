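#' Bootstrap settings for effect estimation
#'
#' @param n_replications Number of bootstrap replications (default 1000).
#' @param seed Integer seed; one child seed per (drug, formula) is derived
#'   from it by hashing, so adding a drug to a screen never perturbs the
#'   confidence intervals of the others.
#' @param resample_unit `"ecg"` resamples individual ECGs (default);
#'   `"patient"` resamples whole patients, respecting within-patient
#'   correlation.
#' @param ci_level Confidence level for the percentile interval.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_replications = 1000, seed = 1,
                             resample_unit = c("ecg", "patient"),
                             ci_level = 0.95) {
  resample_unit <- match.arg(resample_unit)
  stopifnot(n_replications >= 1, ci_level > 0, ci_level < 1)
  structure(
    list(n_replications = as.integer(n_replications), seed = as.integer(seed),
         resample_unit = resample_unit, ci_level = ci_level),
    class = "bootstrap_config"
  )
}

#' Split a drug's exposure rows into on- and off-medication ECGs
#'
#' The on group is every ECG classified `on`; the off group is every ECG
#' classified `off_pre` or `off_post` (under a pre-only exposure
#' configuration `off_post` never occurs, so the off group is
#' pre-treatment only). Indeterminate and ineligible ECGs are used on
#' neither side.
#'
#' @param exposure Exposure matrix from [exposure_matrix()].
#' @param ecgs Filtered ECG table (the `kept` element of [filter_ecgs()]).
#' @param drug Drug name.
#' @return List with tibbles `on` and `off` (ECG rows joined to their
#'   exposure status) and logical `reportable` (both sides non-empty).
#' @export
build_cohort <- function(exposure, ecgs, drug) {
  rows <- exposure[exposure$drug == drug, , drop = FALSE]
  on_ids <- rows$ecg_id[rows$status == "on"]
  off_ids <- rows$ecg_id[rows$status %in% c("off_pre", "off_post")]
  on <- ecgs[as.character(ecgs$ecg_id) %in% on_ids, , drop = FALSE]
  off <- ecgs[as.character(ecgs$ecg_id) %in% off_ids, , drop = FALSE]
  list(on = tibble::as_tibble(on), off = tibble::as_tibble(off),
       reportable = nrow(on) >= 1 && nrow(off) >= 1)
}

#' Difference in group means
#'
#' @param on_values,off_values Numeric vectors (both non-empty).
#' @return `mean(on_values) - mean(off_values)`.
#' @export
mean_delta <- function(on_values, off_values) {
  if (length(on_values) == 0 || length(off_values) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  mean(on_values) - mean(off_values)
}

#' Percentile bootstrap CI for a difference in means
#'
#' Resamples the on and off groups independently with replacement,
#' recomputes the mean difference per replication, and returns the
#' percentile interval of the replicate distribution. With patient-level
#' resampling, whole clusters are drawn with replacement; if either side
#' has fewer than two clusters the function falls back to ECG-level
#' resampling with a warning. Output is fully determined by the inputs,
#' the seed, and the configuration; the caller's RNG state is untouched.
#'
#' @param on_values,off_values Numeric vectors (both non-empty).
#' @param config A [bootstrap_config()].
#' @param on_cluster,off_cluster Cluster (patient) identifiers parallel to
#'   the value vectors; required for `resample_unit = "patient"`.
#' @return Named numeric vector with elements `ci_low` and `ci_high`.
#' @export
bootstrap_ci <- function(on_values, off_values, config = bootstrap_config(),
                         on_cluster = NULL, off_cluster = NULL) {
  stopifnot(inherits(config, "bootstrap_config"))
  if (length(on_values) == 0 || length(off_values) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  unit <- config$resample_unit
  if (unit == "patient") {
    if (is.null(on_cluster) || is.null(off_cluster) ||
        length(unique(on_cluster)) < 2 || length(unique(off_cluster)) < 2) {
      warning("fewer than two clusters on one side; ",
              "falling back to ECG-level resampling", call. = FALSE)
      unit <- "ecg"
    }
  }
  B <- config$n_replications
  deltas <- with_seed(config$seed, {
    if (unit == "ecg") {
      resample_means(on_values, B) - resample_means(off_values, B)
    } else {
      on_groups <- split(on_values, on_cluster)
      off_groups <- split(off_values, off_cluster)
      vapply(seq_len(B), function(b) {
        on_b <- unlist(on_groups[sample.int(length(on_groups),
                                            replace = TRUE)],
                       use.names = FALSE)
        off_b <- unlist(off_groups[sample.int(length(off_groups),
                                              replace = TRUE)],
                        use.names = FALSE)
        mean(on_b) - mean(off_b)
      }, numeric(1))
    }
  })
  alpha <- 1 - config$ci_level
  ci <- stats::quantile(deltas, c(alpha / 2, 1 - alpha / 2),
                        names = FALSE, type = 7)
  c(ci_low = ci[1], ci_high = ci[2])
}

# column-means of B independent with-replacement resamples, chunked so the
# working matrix never exceeds ~2e7 cells
resample_means <- function(x, B) {
  n <- length(x)
  if (n == 1) return(rep(x, B))
  chunk <- max(1L, min(B, floor(2e7 / n)))
  out <- numeric(B)
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    m <- matrix(x[sample.int(n, n * b, replace = TRUE)], nrow = n)
    out[(done + 1L):(done + b)] <- colMeans(m)
    done <- done + b
  }
  out
}

#' Screen all drugs under all QTc formulas
#'
#' For every (drug, formula) pair, computes the mean QTc difference
#' between on- and off-medication ECGs with its percentile bootstrap CI,
#' plus a per-drug heart-rate difference (a sensitivity check that an
#' apparent QTc effect is not a residual heart-rate artefact). Drugs with
#' an empty on or off side are retained with `reportable = FALSE` and
#' missing estimates.
#'
#' @param exposure Exposure matrix from [exposure_matrix()].
#' @param ecgs Filtered ECG table with the five QTc columns.
#' @param drugs Character vector of drugs to screen; defaults to all drugs
#'   present in `exposure`.
#' @param config A [bootstrap_config()].
#' @param formulas Subset of [qtc_formula_names()].
#' @return Tibble with one row per (drug, formula): `drug`, `formula`,
#'   `n_on`, `n_off`, `mean_on_ms`, `mean_off_ms`, `delta_ms`,
#'   `ci_low_ms`, `ci_high_ms`, `hr_delta_bpm`, `hr_ci_low_bpm`,
#'   `hr_ci_high_bpm`, `reportable`; ordered by `delta_ms` descending
#'   within formula.
#' @export
screen_effects <- function(exposure, ecgs, drugs = NULL,
                           config = bootstrap_config(),
                           formulas = qtc_formula_names()) {
  stopifnot(all(formulas %in% qtc_formula_names()))
  if (is.null(drugs)) drugs <- sort(unique(exposure$drug))
  rows <- lapply(drugs, function(dg) {
    cohort <- build_cohort(exposure, ecgs, dg)
    hr <- if (cohort$reportable) {
      hr_sensitivity(cohort$on, cohort$off,
                     child_config(config, paste0(dg, "/hr")))
    } else {
      c(delta = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    }
    dplyr::bind_rows(lapply(formulas, function(f) {
      col <- paste0("qtc_", f, "_ms")
      base <- tibble::tibble(
        drug = dg, formula = f,
        n_on = nrow(cohort$on), n_off = nrow(cohort$off),
        mean_on_ms = NA_real_, mean_off_ms = NA_real_,
        delta_ms = NA_real_, ci_low_ms = NA_real_, ci_high_ms = NA_real_,
        hr_delta_bpm = unname(hr["delta"]),
        hr_ci_low_bpm = unname(hr["ci_low"]),
        hr_ci_high_bpm = unname(hr["ci_high"]),
        reportable = cohort$reportable
      )
      if (!cohort$reportable) return(base)
      on_v <- cohort$on[[col]]
      off_v <- cohort$off[[col]]
      ci <- bootstrap_ci(on_v, off_v, child_config(config, paste0(dg, "/", f)),
                         on_cluster = cohort$on$patient_id,
                         off_cluster = cohort$off$patient_id)
      dplyr::mutate(base,
        mean_on_ms = mean(on_v), mean_off_ms = mean(off_v),
        delta_ms = mean(on_v) - mean(off_v),
        ci_low_ms = unname(ci["ci_low"]), ci_high_ms = unname(ci["ci_high"])
      )
    }))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$formula, dplyr::desc(.data$delta_ms))
}

#' Heart-rate difference between on- and off-medication ECGs
#'
#' Same estimator as the QTc effect ([mean_delta()] + [bootstrap_ci()])
#' applied to heart rate. Minimal heart-rate differences support the
#' interpretation that an estimated QTc change reflects repolarisation,
#' not rate correction residue.
#'
#' @param on_ecgs,off_ecgs ECG tables with a `heart_rate_bpm` column.
#' @param config A [bootstrap_config()].
#' @return Named vector `delta`, `ci_low`, `ci_high` in bpm.
#' @export
hr_sensitivity <- function(on_ecgs, off_ecgs, config = bootstrap_config()) {
  d <- mean_delta(on_ecgs$heart_rate_bpm, off_ecgs$heart_rate_bpm)
  ci <- bootstrap_ci(on_ecgs$heart_rate_bpm, off_ecgs$heart_rate_bpm, config,
                     on_cluster = on_ecgs$patient_id,
                     off_cluster = off_ecgs$patient_id)
  c(delta = d, ci)
}

#' Cross-formula consensus ranking of QTc-prolonging drugs
#'
#' A drug qualifies when it appears among the top `k` drugs ranked by
#' estimated QTc prolongation under at least `min_formulas` of the
#' correction formulas present in the effects table. Rank ties are broken
#' alphabetically; qualifying drugs are ordered by mean rank across
#' formulas, then alphabetically.
#'
#' @param effects Output of [screen_effects()].
#' @param k Top-rank cutoff per formula.
#' @param min_formulas Minimum number of formulas in whose top `k` a drug
#'   must appear (default 3, the at-least-3-of-5 rule).
#' @return Tibble `drug`, `n_top_formulas`, `mean_rank`, restricted to
#'   qualifying drugs and ordered by consensus strength.
#' @export
consensus_top <- function(effects, k, min_formulas = 3) {
  stopifnot(k >= 1)
  rep_eff <- effects[effects$reportable & !is.na(effects$delta_ms), ,
                     drop = FALSE]
  ranked <- dplyr::mutate(
    dplyr::group_by(rep_eff, .data$formula),
    rank = order(order(-.data$delta_ms, .data$drug))
  )
  ranked <- dplyr::ungroup(ranked)
  per_drug <- dplyr::summarise(
    dplyr::group_by(ranked, .data$drug),
    n_top_formulas = sum(.data$rank <= k),
    mean_rank = mean(.data$rank),
    .groups = "drop"
  )
  out <- per_drug[per_drug$n_top_formulas >= min_formulas, , drop = FALSE]
  dplyr::arrange(out, .data$mean_rank, .data$drug)
}
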