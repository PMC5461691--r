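#' Overmatching diagnostic: match factors regressed on the biomarker
#'
#' Overmatching arises when the match factors are themselves associated with
#' the exposure: matching then equalises the exposure within pairs, shrinks
#' the within-pair contrast, and biases the conditional estimate toward the
#' null. The diagnostic fits, in the controls only, an ordinary linear model
#' of the biomarker concentration on the six match factors and reports the
#' model R-squared — the fraction of biomarker variance the joint match-
#' factor distribution explains — decomposed into per-factor sequential
#' (Type I) partial R-squared components that sum exactly to the model
#' R-squared. A large R-squared warns that matching may have removed real
#' exposure signal; small per-factor components support the design.
#'
#' Sequential components depend on the order factors enter the model, which
#' is why `factor_order` is an explicit required argument; permuting it
#' redistributes the components but never changes their sum. A categorical
#' factor enters as its full indicator block and the block's sequential sum
#' of squares is attributed to the factor.
#'
#' @param controls Subject tibble; rows with `delirium_case == 1` are dropped
#'   unless `include_cases = TRUE` (exploration only — the diagnostic is
#'   defined on controls, whose biomarker is unaffected by the outcome).
#' @param factor_order Permutation of the six match-factor columns giving the
#'   sequential entry order.
#' @param time_points Time points to assess (default all three).
#' @param include_cases Keep cases in the regression sample (default FALSE).
#' @return An object of class `ncc_overmatch`: a per-time-point summary
#'   (`model_r2` as a fraction, `equivalent_r = sqrt(model_r2)`,
#'   `n_controls`) and a component table (`time_point`, `factor`,
#'   `partial_r2`).
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 2))
#' rep <- overmatch_assess(dplyr::filter(cohort, delirium_case == 0))
#' glance(rep)
#' @export
overmatch_assess <- function(controls,
                             factor_order = ncc_factor_cols(),
                             time_points = ncc_time_points(),
                             include_cases = FALSE) {
  if (!setequal(factor_order, ncc_factor_cols()) ||
      length(factor_order) != length(ncc_factor_cols()))
    abort(sprintf("`factor_order` must be a permutation of: %s",
                  paste(ncc_factor_cols(), collapse = ", ")))
  if (!include_cases && "delirium_case" %in% names(controls))
    controls <- dplyr::filter(controls, .data$delirium_case == 0)
  check_subject_cols(controls, factor_order, "controls")

  d <- controls
  d$surgery_type <- factor(d$surgery_type)
  d$gender <- factor(d$gender)

  one_tp <- function(tp) {
    col <- il6_col(tp)
    check_subject_cols(d, col, "controls")
    dd <- d[!is.na(d[[col]]), , drop = FALSE]
    fml <- as.formula(paste(col, "~", paste(factor_order, collapse = " + ")))
    fit <- lm(fml, data = dd)
    if (fit$df.residual <= 0 || anyNA(coef(fit)))
      abort(sprintf("rank-deficient overmatch model at %s: fewer observations than parameters", tp))
    sst <- sum((dd[[col]] - mean(dd[[col]]))^2)
    if (sst == 0)
      abort(sprintf("outcome variance is zero at %s: R-squared undefined", tp))
    aov_tab <- anova(fit)                      # sequential (Type I) SS
    terms <- rownames(aov_tab)
    terms <- terms[terms != "Residuals"]
    comp <- aov_tab[terms, "Sum Sq"] / sst
    model_r2 <- summary(fit)$r.squared
    list(summary = tibble::tibble(time_point = tp, model_r2 = model_r2,
                                  equivalent_r = sqrt(model_r2),
                                  n_controls = nrow(dd)),
         components = tibble::tibble(time_point = tp, factor = terms,
                                     partial_r2 = comp))
  }

  res <- purrr::map(toupper(time_points), one_tp)
  structure(list(summary = dplyr::bind_rows(purrr::map(res, "summary")),
                 components = dplyr::bind_rows(purrr::map(res, "components")),
                 factor_order = factor_order),
            class = "ncc_overmatch")
}

#' @export
print.ncc_overmatch <- function(x, ...) {
  cat("Overmatching diagnostic (controls-only linear model of the biomarker)\n")
  s <- dplyr::mutate(x$summary,
                     model_r2_pct = 100 * .data$model_r2,
                     equivalent_r = .data$equivalent_r)
  print(as.data.frame(s[, c("time_point", "model_r2_pct", "equivalent_r",
                            "n_controls")]), digits = 3, row.names = FALSE)
  cat("Sequential partial R-squared (%) in entry order:\n")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(x$components, partial_r2 = 100 * .data$partial_r2),
    names_from = "time_point", values_from = "partial_r2")
  print(as.data.frame(wide), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Convert a coefficient of determination to a correlation magnitude
#'
#' For a linear model, the multiple correlation between outcome and fitted
#' values is the square root of the model R-squared; this puts an R-squared
#' like 22.3% on the familiar correlation scale (~0.47).
#'
#' @param r2 R-squared value(s) as fractions in `[0, 1]`.
#' @return `sqrt(r2)`.
#' @examples
#' r_from_r2(0.2230)  # ~0.47
#' r_from_r2(0.0838)  # ~0.29
#' @export
r_from_r2 <- function(r2) {
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1))
    abort("`r2` must lie in [0, 1]")
  sqrt(r2)
}
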