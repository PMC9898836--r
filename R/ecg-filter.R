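#' ECG inclusion criteria
#'
#' Constructs the quality-filter settings applied to ECG records before any
#' effect estimation. Defaults reproduce the standard screen: sinus rhythm,
#' outpatient setting, heart rate 40-100 bpm (inclusive), QRS < 120 ms
#' (strict), and Bazett QTc 300-700 ms (inclusive). QTc quantification is
#' unreliable at rate and interval extremes, which is what these bounds
#' guard against.
#'
#' @param hr_min_bpm,hr_max_bpm Inclusive heart-rate bounds in bpm.
#' @param qrs_max_ms Exclusive upper bound on QRS duration in ms.
#' @param qtc_min_ms,qtc_max_ms Inclusive bounds on the Bazett QTc in ms.
#' @param require_sinus Keep only records with rhythm `"sinus"`.
#' @param require_outpatient Keep only records with setting `"outpatient"`.
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(hr_min_bpm = 40, hr_max_bpm = 100,
                            qrs_max_ms = 120,
                            qtc_min_ms = 300, qtc_max_ms = 700,
                            require_sinus = TRUE,
                            require_outpatient = TRUE) {
  stopifnot(hr_min_bpm < hr_max_bpm, qtc_min_ms < qtc_max_ms, qrs_max_ms > 0)
  structure(
    list(
      hr_min_bpm = hr_min_bpm, hr_max_bpm = hr_max_bpm,
      qrs_max_ms = qrs_max_ms,
      qtc_min_ms = qtc_min_ms, qtc_max_ms = qtc_max_ms,
      require_sinus = isTRUE(require_sinus),
      require_outpatient = isTRUE(require_outpatient)
    ),
    class = "filter_criteria"
  )
}

#' Apply ECG inclusion filters
#'
#' Splits an ECG table into kept and excluded records and logs one reason
#' code per violated criterion. The QTc bound is evaluated on the Bazett
#' value only (the formula used for inclusion); the other corrections are
#' carried through unharmed. Records with unparseable or non-positive
#' heart rate, QT, or QRS are excluded with reason `"malformed"` — never
#' silently dropped. Filtering is idempotent: applying the same criteria to
#' the kept set removes nothing.
#'
#' Reason codes: `hr_out_of_range`, `qrs_too_wide`, `qtc_out_of_range`,
#' `non_sinus`, `inpatient`, `malformed`. A record violating several
#' criteria appears once per reason in the log.
#'
#' @param ecgs ECG table; if the QTc columns are absent, [compute_qtc()] is
#'   called first (requires `qt_ms`, `heart_rate_bpm`, `sex`).
#' @param criteria A [filter_criteria()] object.
#' @return A list with elements `kept` (tibble of passing records, QTc
#'   columns included) and `exclusion_log` (tibble with `ecg_id`, `reason`).
#' @export
#' @examples
#' ecgs <- tibble::tibble(
#'   ecg_id = c("a", "b"), patient_id = "p1",
#'   rhythm = "sinus", setting = "outpatient", sex = "female",
#'   heart_rate_bpm = c(75, 101), qrs_ms = 90, qt_ms = 380
#' )
#' filter_ecgs(ecgs)$exclusion_log
filter_ecgs <- function(ecgs, criteria = filter_criteria()) {
  stopifnot(is.data.frame(ecgs), inherits(criteria, "filter_criteria"))
  if (!"qtc_bazett_ms" %in% names(ecgs)) {
    ecgs <- compute_qtc(ecgs)
  }
  ecgs <- tibble::as_tibble(ecgs)
  n <- nrow(ecgs)
  if (n == 0) {
    return(list(
      kept = ecgs,
      exclusion_log = tibble::tibble(ecg_id = character(), reason = character())
    ))
  }

  hr <- suppressWarnings(as.numeric(ecgs$heart_rate_bpm))
  qt <- suppressWarnings(as.numeric(ecgs$qt_ms))
  qrs <- suppressWarnings(as.numeric(ecgs$qrs_ms))
  qtc <- ecgs$qtc_bazett_ms

  malformed <- !is.finite(hr) | hr <= 0 | !is.finite(qt) | qt <= 0 |
    !is.finite(qrs) | qrs <= 0 |
    is.na(ecgs$rhythm) | is.na(ecgs$setting)

  reasons <- list(
    malformed = malformed,
    hr_out_of_range = !malformed &
      (hr < criteria$hr_min_bpm | hr > criteria$hr_max_bpm),
    qrs_too_wide = !malformed & qrs >= criteria$qrs_max_ms,
    qtc_out_of_range = !malformed & is.finite(qtc) &
      (qtc < criteria$qtc_min_ms | qtc > criteria$qtc_max_ms),
    non_sinus = if (criteria$require_sinus) {
      !malformed & ecgs$rhythm != "sinus"
    } else rep(FALSE, n),
    inpatient = if (criteria$require_outpatient) {
      !malformed & ecgs$setting != "outpatient"
    } else rep(FALSE, n)
  )

  excluded <- Reduce(`|`, reasons)
  log <- dplyr::bind_rows(lapply(names(reasons), function(r) {
    idx <- which(reasons[[r]])
    tibble::tibble(ecg_id = as.character(ecgs$ecg_id[idx]), reason = r)
  }))
  log <- dplyr::arrange(log, .data$ecg_id, .data$reason)

  list(kept = ecgs[!excluded, , drop = FALSE], exclusion_log = log)
}
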