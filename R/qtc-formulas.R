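#' Heart-rate corrected QT interval (QTc) formulas
#'
#' The QT interval shortens as heart rate rises, so raw QT values are not
#' comparable across ECGs. These functions implement five published
#' corrections. All are vectorised over their arguments and use a common
#' unit convention: QT/QTc in milliseconds, the RR interval in seconds,
#' heart rate in beats per minute. Formula constants published on the
#' seconds scale are rescaled to milliseconds internally.
#'
#' * Bazett: `QTc = QT / sqrt(RR)`
#' * Fridericia: `QTc = QT / RR^(1/3)`
#' * Hodges: `QTc = QT + 1.75 * (HR - 60)`
#' * Framingham: `QTc = QT + 154 * (1 - RR)`
#' * Rautaharju: `QTc = QT + 18.5 * (RR - 1) + 6 * [sex == "male"]`
#'
#' At HR = 60 bpm (RR = 1 s) every correction returns QT unchanged, except
#' Rautaharju for males, which adds its fixed 6 ms sex term.
#'
#' @param qt_ms QT interval in milliseconds (> 0).
#' @param rr_s RR interval in seconds (> 0); see [rr_from_hr()].
#' @param heart_rate_bpm Heart rate in beats per minute (> 0).
#' @param sex Character vector; the value `"male"` (case-insensitive)
#'   activates the Rautaharju sex term, any other value does not.
#' @return Corrected QT in milliseconds.
#' @name qtc_formulas
#' @examples
#' qtc_bazett(400, 0.64)      # 500
#' qtc_fridericia(400, 0.512) # 500
#' qtc_hodges(400, 80)        # 435
#' qtc_framingham(400, 0.8)   # 430.8
#' qtc_rautaharju(400, 1, "male") # 406
NULL

#' Convert heart rate to RR interval
#'
#' @param heart_rate_bpm Heart rate in beats per minute (> 0).
#' @return RR interval in seconds, `60 / heart_rate_bpm`.
#' @export
#' @examples
#' rr_from_hr(75) # 0.8
rr_from_hr <- function(heart_rate_bpm) {
  check_positive(heart_rate_bpm, "heart_rate_bpm")
  60 / heart_rate_bpm
}

#' @rdname qtc_formulas
#' @export
qtc_bazett <- function(qt_ms, rr_s) {
  check_positive(qt_ms, "qt_ms")
  check_positive(rr_s, "rr_s")
  qt_ms / sqrt(rr_s)
}

#' @rdname qtc_formulas
#' @export
qtc_fridericia <- function(qt_ms, rr_s) {
  check_positive(qt_ms, "qt_ms")
  check_positive(rr_s, "rr_s")
  qt_ms / rr_s^(1 / 3)
}

#' @rdname qtc_formulas
#' @export
qtc_hodges <- function(qt_ms, heart_rate_bpm) {
  check_positive(qt_ms, "qt_ms")
  check_positive(heart_rate_bpm, "heart_rate_bpm")
  qt_ms + 1.75 * (heart_rate_bpm - 60)
}

#' @rdname qtc_formulas
#' @export
qtc_framingham <- function(qt_ms, rr_s) {
  check_positive(qt_ms, "qt_ms")
  check_positive(rr_s, "rr_s")
  qt_ms + 154 * (1 - rr_s)
}

#' @rdname qtc_formulas
#' @export
qtc_rautaharju <- function(qt_ms, rr_s, sex) {
  check_positive(qt_ms, "qt_ms")
  check_positive(rr_s, "rr_s")
  qt_ms + 18.5 * (rr_s - 1) + 6 * (tolower(as.character(sex)) == "male")
}

#' Compute all five QTc corrections for an ECG table
#'
#' Adds the RR interval and one QTc column per formula to a table of ECG
#' records. Rows with missing or non-positive `heart_rate_bpm` or `qt_ms`
#' get `NA` in every derived column rather than an error, so malformed
#' records survive to the filtering stage where they are logged.
#'
#' @param ecgs A data frame with columns `qt_ms`, `heart_rate_bpm` and `sex`.
#' @return The input with columns `rr_s`, `qtc_bazett_ms`,
#'   `qtc_fridericia_ms`, `qtc_hodges_ms`, `qtc_framingham_ms`,
#'   `qtc_rautaharju_ms` appended.
#' @export
#' @examples
#' compute_qtc(tibble::tibble(qt_ms = 400, heart_rate_bpm = 75, sex = "female"))
compute_qtc <- function(ecgs) {
  stopifnot(is.data.frame(ecgs))
  need <- c("qt_ms", "heart_rate_bpm", "sex")
  missing_cols <- setdiff(need, names(ecgs))
  if (length(missing_cols) > 0) {
    stop("`ecgs` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  hr <- suppressWarnings(as.numeric(ecgs$heart_rate_bpm))
  qt <- suppressWarnings(as.numeric(ecgs$qt_ms))
  ok <- is.finite(hr) & hr > 0 & is.finite(qt) & qt > 0
  rr <- ifelse(ok, 60 / hr, NA_real_)
  out <- dplyr::mutate(
    tibble::as_tibble(ecgs),
    rr_s = rr,
    qtc_bazett_ms = ifelse(ok, qt / sqrt(rr), NA_real_),
    qtc_fridericia_ms = ifelse(ok, qt / rr^(1 / 3), NA_real_),
    qtc_hodges_ms = ifelse(ok, qt + 1.75 * (hr - 60), NA_real_),
    qtc_framingham_ms = ifelse(ok, qt + 154 * (1 - rr), NA_real_),
    qtc_rautaharju_ms = ifelse(
      ok, qt + 18.5 * (rr - 1) + 6 * (tolower(as.character(.data$sex)) %in% "male"),
      NA_real_
    )
  )
  out
}

#' Names of the supported QTc formulas
#'
#' @return Character vector of formula identifiers in canonical order.
#' @export
qtc_formula_names <- function() {
  c("bazett", "fridericia", "hodges", "framingham", "rautaharju")
}

check_positive <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) {
    stop("`", name, "` must be finite and > 0", call. = FALSE)
  }
  invisible(x)
}
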