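#' Torsades-de-pointes risk classes
#'
#' Canonical class labels in decreasing expected-risk order, matching the
#' categories of curated TdP-risk databases: known risk, avoid in
#' congenital long-QT syndrome, conditional risk, possible risk, and
#' unclassified.
#'
#' @return Character vector of class labels in decreasing-risk order.
#' @export
tdp_class_levels <- function() {
  c("known_risk", "avoid_congenital_lqts", "conditional_risk",
    "possible_risk", "unclassified")
}

#' Per-class summaries of drug-level QTc effects
#'
#' Joins drug-level effect estimates (one delta per drug, typically under
#' the primary formula) to a drug-to-risk-class table and summarises each
#' class. Drugs absent from the class table are counted as
#' `unclassified`. Empty classes are reported with `n_drugs = 0` and
#' missing summaries.
#'
#' @param effects Tibble with one row per drug: columns `drug`,
#'   `delta_ms`.
#' @param classes Tibble with columns `drug`, `tdp_class`.
#' @return Tibble `tdp_class`, `n_drugs`, `mean_delta_ms`, `sd_delta_ms`,
#'   ordered by decreasing expected risk.
#' @export
summarize_by_class <- function(effects, classes) {
  stopifnot(all(c("drug", "delta_ms") %in% names(effects)),
            all(c("drug", "tdp_class") %in% names(classes)))
  joined <- dplyr::left_join(effects[, c("drug", "delta_ms")],
                             classes[, c("drug", "tdp_class")],
                             by = "drug")
  joined$tdp_class[is.na(joined$tdp_class)] <- "unclassified"
  got <- dplyr::summarise(
    dplyr::group_by(joined, .data$tdp_class),
    n_drugs = dplyr::n(),
    mean_delta_ms = mean(.data$delta_ms),
    sd_delta_ms = stats::sd(.data$delta_ms),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble::tibble(tdp_class = tdp_class_levels()),
                          got, by = "tdp_class")
  out$n_drugs[is.na(out$n_drugs)] <- 0L
  out
}

#' Check concordance of class means with the expected risk ordering
#'
#' The screen's qualitative validity check: mean estimated QTc
#' prolongation should not increase as the curated TdP risk class
#' decreases. Classes with no drugs are skipped.
#'
#' @param class_summaries Output of [summarize_by_class()].
#' @param expected_order Class labels in decreasing expected-risk order
#'   (default [tdp_class_levels()]).
#' @param strict Require strictly decreasing means (default `FALSE`:
#'   non-increasing).
#' @return List with `concordant` (logical) and `violations` (tibble of
#'   adjacent class pairs breaking the ordering, with their means).
#' @export
ordering_check <- function(class_summaries,
                           expected_order = tdp_class_levels(),
                           strict = FALSE) {
  present <- class_summaries[match(expected_order, class_summaries$tdp_class), ]
  present <- present[!is.na(present$tdp_class) & present$n_drugs > 0, ]
  v <- present$mean_delta_ms
  bad <- if (strict) which(diff(v) >= 0) else which(diff(v) > 0)
  violations <- tibble::tibble(
    higher_class = present$tdp_class[bad],
    lower_class = present$tdp_class[bad + 1],
    higher_mean = v[bad],
    lower_mean = v[bad + 1]
  )
  list(concordant = length(bad) == 0, violations = violations)
}
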