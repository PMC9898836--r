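#' Covariates screened for interaction with medication effects
#'
#' The default demographic and comorbidity covariates. Age enters the
#' models in decades (effects per 10 years); sex is coded as a female
#' indicator; race and ethnicity as a non-White indicator; comorbidities
#' as binary flags.
#'
#' @return Tibble with columns `name` (model column) and `kind`
#'   (`"age_decades"` or `"binary_flag"`).
#' @export
covariate_specs <- function() {
  tibble::tibble(
    name = c("age_decades", "female", "non_white", "hypertension", "cad",
             "heart_failure", "diabetes", "ckd", "liver_disease", "copd"),
    kind = c("age_decades", rep("binary_flag", 9))
  )
}

#' Univariate association of one covariate with QTc
#'
#' Ordinary least-squares regression of QTc on a single covariate. For a
#' binary covariate the slope equals the difference in group means; for
#' age in decades it is the QTc change per 10 years.
#'
#' @param data Data frame containing `qtc` and the covariate column.
#' @param covariate Name of the covariate column.
#' @param qtc_col Name of the response column (default `"qtc"`).
#' @return Tibble `covariate`, `slope`, `se`, `p`, `n`.
#' @export
univariate_model <- function(data, covariate, qtc_col = "qtc") {
  x <- data[[covariate]]
  y <- data[[qtc_col]]
  if (is.null(x)) stop("no column `", covariate, "`", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- y[keep]
  if (length(y) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("covariate `", covariate, "` is constant (singular design)",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  tibble::tibble(covariate = covariate, slope = cf["x", 1], se = cf["x", 2],
                 p = cf["x", 4], n = length(y))
}

#' Medication-by-covariate interaction model
#'
#' Fits the four-parameter linear model
#' `QTc = a + b*medication + c*covariate + d*medication*covariate`
#' by ordinary least squares, where `medication` is the on-drug indicator.
#' The interaction coefficient `d` measures how much the drug's QTc effect
#' differs across covariate levels (for a binary covariate, the
#' difference-in-differences of the four cell means). Standard error and
#' two-sided p-value for `d` come from the usual normal-theory t
#' statistic. Collinear designs (for example, every on-drug ECG sharing
#' one covariate level) are flagged inestimable rather than dropped
#' silently.
#'
#' @param data Data frame with the response, on-drug indicator and
#'   covariate columns.
#' @param on_col Name of the 0/1 (or logical) on-medication column.
#' @param covariate Name of the covariate column.
#' @param qtc_col Name of the response column (default `"qtc"`).
#' @param drug Drug label carried into the result.
#' @return Tibble `drug`, `covariate`, `a`, `b`, `c`, `d`, `se_d`, `p_d`,
#'   `n`, `estimable`, `reason` (NA when estimable).
#' @export
interaction_model <- function(data, on_col, covariate, qtc_col = "qtc",
                              drug = NA_character_) {
  med <- as.numeric(data[[on_col]])
  cov <- as.numeric(data[[covariate]])
  y <- data[[qtc_col]]
  keep <- !is.na(med) & !is.na(cov) & !is.na(y)
  med <- med[keep]; cov <- cov[keep]; y <- y[keep]

  base <- tibble::tibble(
    drug = drug, covariate = covariate,
    a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
    se_d = NA_real_, p_d = NA_real_, n = length(y),
    estimable = FALSE, reason = NA_character_
  )
  if (length(y) < 5) {
    base$reason <- "too_few_observations"
    return(base)
  }
  X <- cbind(1, med, cov, med * cov)
  if (qr(X)$rank < 4L) {
    base$reason <- "collinear_design"
    return(base)
  }
  fit <- stats::lm(y ~ med * cov)
  cf <- summary(fit)$coefficients
  dplyr::mutate(base,
    a = cf["(Intercept)", 1], b = cf["med", 1], c = cf["cov", 1],
    d = cf["med:cov", 1], se_d = cf["med:cov", 2], p_d = cf["med:cov", 4],
    estimable = TRUE, reason = NA_character_
  )
}

#' Run the interaction screen for a set of drugs
#'
#' Fits [interaction_model()] for every (drug, covariate) pair, using the
#' on/off cohorts from the exposure matrix, and applies the per-medication
#' Bonferroni rule via [bonferroni_flag()].
#'
#' @param exposure Exposure matrix from [exposure_matrix()].
#' @param ecgs Filtered ECG table joined to patient covariates; must
#'   contain the covariate columns and the chosen QTc column.
#' @param drugs Character vector of drugs to screen.
#' @param covariates Character vector of covariate column names (default
#'   `covariate_specs()$name`).
#' @param formula Which QTc formula's column to model (default
#'   `"bazett"`, the inclusion formula).
#' @param alpha Family-wise significance level per medication.
#' @return Long tibble of flagged [interaction_model()] results.
#' @export
interaction_screen <- function(exposure, ecgs, drugs,
                               covariates = covariate_specs()$name,
                               formula = "bazett", alpha = 0.05) {
  qtc_col <- paste0("qtc_", formula, "_ms")
  stopifnot(qtc_col %in% names(ecgs))
  rows <- lapply(drugs, function(dg) {
    cohort <- build_cohort(exposure, ecgs, dg)
    if (!cohort$reportable) return(NULL)
    dat <- dplyr::bind_rows(
      dplyr::mutate(cohort$on, .on = 1),
      dplyr::mutate(cohort$off, .on = 0)
    )
    res <- dplyr::bind_rows(lapply(covariates, function(cv) {
      interaction_model(dat, ".on", cv, qtc_col = qtc_col, drug = dg)
    }))
    bonferroni_flag(res, alpha = alpha)
  })
  dplyr::bind_rows(rows)
}

#' Per-medication Bonferroni correction
#'
#' Flags interaction results for one medication as significant when
#' `p_d < alpha / m`, where `m` is the number of estimable covariate
#' tests for that medication (inestimable cells do not inflate the
#' family size).
#'
#' @param results Interaction results for a single drug.
#' @param alpha Family-wise significance level (default 0.05).
#' @return `results` with columns `m_tests` and `significant` appended.
#' @export
bonferroni_flag <- function(results, alpha = 0.05) {
  m <- sum(results$estimable)
  dplyr::mutate(results,
    m_tests = m,
    significant = .data$estimable & !is.na(.data$p_d) &
      .data$p_d < alpha / max(m, 1)
  )
}

#' Heat-map matrix of significant interaction coefficients
#'
#' @param results Flagged interaction results across drugs.
#' @return Wide tibble, one row per drug, one column per covariate,
#'   holding `d` where significant and `NA` elsewhere (non-significant or
#'   inestimable).
#' @export
heatmap_matrix <- function(results) {
  cells <- dplyr::mutate(
    results,
    value = ifelse(.data$significant, .data$d, NA_real_)
  )
  tidyr::pivot_wider(
    cells[, c("drug", "covariate", "value")],
    names_from = "covariate", values_from = "value"
  )
}

#' Stratified QTc summaries for one drug and covariate
#'
#' Summarises the QTc distribution in the four groups defined by
#' on/off-medication status and a binary covariate — the data behind a
#' stratified distribution plot. Empty strata are reported with `n = 0`
#' and missing summaries.
#'
#' @param exposure Exposure matrix from [exposure_matrix()].
#' @param ecgs Filtered ECG table with covariates joined.
#' @param drug Drug name.
#' @param covariate Binary covariate column name.
#' @param formula QTc formula column to summarise (default `"bazett"`).
#' @return Tibble with one row per (covariate level, on/off) group:
#'   `n`, `mean`, `sd`, `q25`, `median`, `q75`.
#' @export
stratified_distribution <- function(exposure, ecgs, drug, covariate,
                                    formula = "bazett") {
  qtc_col <- paste0("qtc_", formula, "_ms")
  cohort <- build_cohort(exposure, ecgs, drug)
  dat <- dplyr::bind_rows(
    dplyr::mutate(cohort$on, status = "on"),
    dplyr::mutate(cohort$off, status = "off")
  )
  grid <- tidyr::expand_grid(level = c(0, 1), status = c("off", "on"))
  got <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(dat, level = as.numeric(.data[[covariate]])),
      .data$level, .data$status
    ),
    n = dplyr::n(),
    mean = mean(.data[[qtc_col]]),
    sd = stats::sd(.data[[qtc_col]]),
    q25 = stats::quantile(.data[[qtc_col]], 0.25, names = FALSE),
    median = stats::median(.data[[qtc_col]]),
    q75 = stats::quantile(.data[[qtc_col]], 0.75, names = FALSE),
    .groups = "drop"
  )
  out <- dplyr::left_join(grid, got, by = c("level", "status"))
  out$n[is.na(out$n)] <- 0L
  dplyr::mutate(out, drug = drug, covariate = covariate,
                .before = 1)
}
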