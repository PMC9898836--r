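#' Exposure-classification settings
#'
#' Controls how ECG dates are classified against drug coverage windows.
#' An ECG is *on* a drug when its date falls inside a filled prescription's
#' coverage; it is *off* only before the first coverage or more than
#' `washout_days` after the last, and then only if the patient filled the
#' drug within `eligibility_days` of the ECG (so on- and off-drug ECGs are
#' drawn from the same prescribed population, limiting confounding by
#' indication). Everything else is indeterminate.
#'
#' @param washout_days Days after the end of coverage during which drug
#'   effect may persist; ECGs there are indeterminate (default 90).
#' @param eligibility_days Maximum days between the ECG and the nearest fill
#'   of the drug for an off-drug ECG to count (default 365).
#' @param off_mode `"pooled"` uses pre- and post-treatment ECGs as the off
#'   group; `"pre_only"` restricts to pre-treatment ECGs and treats
#'   post-treatment ones as indeterminate.
#' @param washout_anchor Where the post-treatment washout clock starts:
#'   `"coverage_end"` (default; when dispensed pills plausibly run out) or
#'   `"last_fill"` (the final fill date itself).
#' @param ehr_list_days Assumed coverage duration, in days, for medication
#'   -list entries that carry no days supply (default 90).
#' @return A list of class `exposure_config`.
#' @export
exposure_config <- function(washout_days = 90, eligibility_days = 365,
                            off_mode = c("pooled", "pre_only"),
                            washout_anchor = c("coverage_end", "last_fill"),
                            ehr_list_days = 90) {
  off_mode <- match.arg(off_mode)
  washout_anchor <- match.arg(washout_anchor)
  stopifnot(washout_days >= 0, eligibility_days >= washout_days,
            ehr_list_days >= 1)
  structure(
    list(washout_days = washout_days, eligibility_days = eligibility_days,
         off_mode = off_mode, washout_anchor = washout_anchor,
         ehr_list_days = ehr_list_days),
    class = "exposure_config"
  )
}

#' Exposure status levels
#'
#' @return Character vector of the five exposure statuses, in the order
#'   on, off_pre, off_post, indeterminate, ineligible.
#' @export
exposure_status_levels <- function() {
  c("on", "off_pre", "off_post", "indeterminate", "ineligible")
}

#' Merge prescription fills into coverage intervals
#'
#' Each fill covers the half-open day range
#' `[fill_date, fill_date + days_supply)`. Overlapping or abutting ranges
#' for the same patient and drug are merged (no stockpiling: overlapping
#' supplies do not extend coverage beyond the union of their day sets).
#' Medication-list entries with missing `days_supply` are assigned
#' `ehr_list_days` before merging.
#'
#' @param fills Data frame of fills for one patient and drug, with columns
#'   `fill_date` (`Date`) and `days_supply`; an optional `source` column is
#'   ignored beyond the missing-supply rule.
#' @param ehr_list_days Fallback duration for fills with missing supply.
#' @return Tibble with `start` (inclusive `Date`) and `end` (exclusive
#'   `Date`), sorted and disjoint. Zero rows for empty input.
#' @export
#' @examples
#' fills <- tibble::tibble(
#'   fill_date = as.Date("2015-01-01") + c(0, 20),
#'   days_supply = c(30, 30)
#' )
#' coverage_intervals(fills) # one merged interval of 50 days
coverage_intervals <- function(fills, ehr_list_days = 90) {
  if (is.null(fills) || nrow(fills) == 0) {
    return(tibble::tibble(start = as.Date(character()),
                          end = as.Date(character())))
  }
  fill_date <- as.Date(fills$fill_date)
  supply <- as.numeric(fills$days_supply)
  supply[is.na(supply)] <- ehr_list_days
  stopifnot(all(supply >= 1), !anyNA(fill_date))

  ord <- order(fill_date)
  start <- as.numeric(fill_date[ord])
  end <- start + supply[ord]

  # single pass merge of sorted half-open intervals (abutting merge too)
  ms <- me <- numeric(length(start))
  k <- 1L
  ms[1] <- start[1]; me[1] <- end[1]
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] <= me[k]) {
        me[k] <- max(me[k], end[i])
      } else {
        k <- k + 1L
        ms[k] <- start[i]; me[k] <- end[i]
      }
    }
  }
  tibble::tibble(
    start = as.Date(ms[seq_len(k)], origin = "1970-01-01"),
    end = as.Date(me[seq_len(k)], origin = "1970-01-01")
  )
}

#' Classify ECG dates against one drug's coverage
#'
#' Implements the on/off decision rule for a single patient-drug pair.
#' For each ECG date: `on` if it falls inside any coverage interval;
#' `off_pre` if it precedes the earliest coverage; `off_post` if it is at
#' least `washout_days` past the washout anchor; otherwise `indeterminate`
#' (gaps between refills and the post-coverage washout window). Off
#' statuses are downgraded to `ineligible` unless some fill of the drug
#' lies within `eligibility_days` of the ECG date. Under
#' `off_mode = "pre_only"`, `off_post` becomes `indeterminate`.
#'
#' @param ecg_date `Date` vector of ECG acquisition dates.
#' @param intervals Coverage intervals from [coverage_intervals()].
#' @param config An [exposure_config()].
#' @param fill_dates `Date` vector of the raw fill dates used for the
#'   eligibility check; defaults to the interval starts.
#' @return Character vector of statuses, one per `ecg_date` (see
#'   [exposure_status_levels()]).
#' @export
classify_exposure <- function(ecg_date, intervals, config = exposure_config(),
                              fill_dates = NULL) {
  stopifnot(inherits(config, "exposure_config"))
  d <- as.numeric(as.Date(ecg_date))
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep("ineligible", length(d)))
  }
  if (is.null(fill_dates)) fill_dates <- intervals$start
  fills <- as.numeric(as.Date(fill_dates))
  s <- as.numeric(as.Date(intervals$start))
  e <- as.numeric(as.Date(intervals$end))

  on <- vapply(d, function(x) any(s <= x & x < e), logical(1))
  post_base <- if (config$washout_anchor == "coverage_end") max(e) else max(fills)
  off_post <- !on & d >= post_base + config$washout_days
  off_pre <- !on & d < min(s)

  status <- rep("indeterminate", length(d))
  status[on] <- "on"
  status[off_pre] <- "off_pre"
  status[off_post & !off_pre] <- "off_post"

  if (config$off_mode == "pre_only") {
    status[status == "off_post"] <- "indeterminate"
  }

  is_off <- status %in% c("off_pre", "off_post")
  if (any(is_off)) {
    near_fill <- vapply(d[is_off], function(x) {
      min(abs(fills - x)) <= config$eligibility_days
    }, logical(1))
    status[which(is_off)[!near_fill]] <- "ineligible"
  }
  status
}

#' Select the study drug set
#'
#' Ranks drugs by fill count and returns the union of the `top_n` most
#' frequently filled drugs and a curated cardiovascular list, minus an
#' exclusion list (as-needed or non-systemic drugs). Ties at the rank
#' boundary are broken alphabetically.
#'
#' @param prescriptions Prescription table with a `drug` column.
#' @param top_n Number of top drugs by fill count to keep.
#' @param cardiovascular_list,exclusion_list Character vectors of drug names.
#' @return Sorted character vector of study drugs.
#' @export
rank_medications <- function(prescriptions, top_n,
                             cardiovascular_list = character(),
                             exclusion_list = character()) {
  if (!is.numeric(top_n) || length(top_n) != 1 || top_n < 1) {
    stop("`top_n` must be a single integer >= 1", call. = FALSE)
  }
  counts <- dplyr::count(prescriptions, .data$drug, name = "n_fills")
  counts <- dplyr::arrange(counts, dplyr::desc(.data$n_fills), .data$drug)
  top <- utils::head(counts$drug, top_n)
  sort(setdiff(union(top, cardiovascular_list), exclusion_list))
}

#' Build the (ECG, drug) exposure matrix
#'
#' Classifies every ECG of every patient ever prescribed each study drug.
#' Patients never prescribed a drug contribute no rows for it; a single
#' ECG may be `on` several drugs at once. Drugs in `drug_set` with no
#' prescriptions raise a warning and contribute zero rows.
#'
#' @param ecgs ECG table with `ecg_id`, `patient_id`, `date`.
#' @param prescriptions Prescription table with `patient_id`, `drug`,
#'   `fill_date`, `days_supply` (and optionally `source`).
#' @param drug_set Character vector of drugs to classify.
#' @param config An [exposure_config()].
#' @return Tibble with columns `ecg_id`, `patient_id`, `drug`, `status`.
#' @export
exposure_matrix <- function(ecgs, prescriptions, drug_set,
                            config = exposure_config()) {
  stopifnot(is.data.frame(ecgs), is.data.frame(prescriptions))
  ecgs <- dplyr::mutate(tibble::as_tibble(ecgs), date = as.Date(.data$date))
  prescriptions <- dplyr::mutate(
    tibble::as_tibble(prescriptions),
    fill_date = as.Date(.data$fill_date)
  )
  missing_drugs <- setdiff(drug_set, unique(prescriptions$drug))
  if (length(missing_drugs) > 0) {
    warning("no prescriptions for drug(s): ",
            paste(missing_drugs, collapse = ", "), call. = FALSE)
  }

  rows <- lapply(intersect(sort(drug_set), unique(prescriptions$drug)),
                 function(dg) {
    fills <- prescriptions[prescriptions$drug == dg, , drop = FALSE]
    by_patient <- split(fills, fills$patient_id)
    sub <- ecgs[ecgs$patient_id %in% names(by_patient), , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    parts <- lapply(split(sub, sub$patient_id), function(pe) {
      pf <- by_patient[[as.character(pe$patient_id[1])]]
      iv <- coverage_intervals(pf, ehr_list_days = config$ehr_list_days)
      tibble::tibble(
        ecg_id = as.character(pe$ecg_id),
        patient_id = as.character(pe$patient_id),
        drug = dg,
        status = classify_exposure(pe$date, iv, config,
                                   fill_dates = pf$fill_date)
      )
    })
    dplyr::bind_rows(parts)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(ecg_id = character(), patient_id = character(),
                          drug = character(), status = character())
  }
  dplyr::arrange(out, .data$drug, .data$patient_id, .data$ecg_id)
}
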