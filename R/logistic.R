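#' Unconditional multivariable logistic regression on the full cohort
#'
#' The cohort-design counterpart of the matched conditional analysis: an
#' ordinary maximum-likelihood logistic regression of delirium status on the
#' biomarker plus the six match factors, fitted to every eligible subject
#' (no matching, no conditioning). Used together with [resample_biomarker()]
#' to ask whether the nested case-control design would have reached the same
#' answer as a full-cohort analysis.
#'
#' Categorical factors are reference-coded: surgery type against
#' `orthopedic`, gender against `male`; binary comorbidity/allele flags enter
#' as 0/1. Separation (some covariate pattern perfectly predicting the
#' outcome, recognisable as divergent coefficients with fitted probabilities
#' pinned at 0/1) raises an explicit error.
#'
#' @param cohort Subject tibble with `delirium_case`, the exposure column and
#'   the covariates.
#' @param time_point Time point selecting the exposure column, or `NULL`
#'   (with `exposure = NULL`) for a model without the biomarker.
#' @param exposure Optional exposure column name overriding `time_point`.
#' @param covariates Covariate columns; default the six match factors. May be
#'   `character(0)` for an exposure-only or intercept-only model.
#' @return An object of class `ncc_logistic` wrapping the fit: coefficient
#'   table (`tidy()`), log-likelihood, n, convergence flag.
#' @export
cohort_logistic_fit <- function(cohort, time_point = "POD2", exposure = NULL,
                                covariates = ncc_factor_cols()) {
  if (is.null(exposure) && !is.null(time_point)) exposure <- il6_col(time_point)
  terms <- c(exposure, covariates)
  check_subject_cols(cohort, c("delirium_case", terms), "cohort")
  if (any(is.na(cohort[, c("delirium_case", terms)])))
    abort("covariates must be complete for all subjects")

  d <- cohort
  if ("surgery_type" %in% terms)
    d$surgery_type <- stats::relevel(factor(d$surgery_type), ref = "orthopedic")
  if ("gender" %in% terms)
    d$gender <- stats::relevel(factor(d$gender), ref = "male")

  rhs <- if (length(terms) > 0) paste(terms, collapse = " + ") else "1"
  fit <- suppressWarnings(
    glm(as.formula(paste("delirium_case ~", rhs)), data = d,
        family = binomial()))

  est <- coef(fit)
  if (anyNA(est)) {
    warn(sprintf("dropping aliased (constant or collinear) covariate(s): %s",
                 paste(names(est)[is.na(est)], collapse = ", ")))
    est <- est[!is.na(est)]
  }

  # separation: fitted probabilities pinned at 0/1 together with a divergent
  # coefficient on the scale of its covariate's SD
  probs <- fit$fitted.values
  mm <- model.matrix(fit)[, names(est), drop = FALSE]
  covariate_sd <- apply(mm, 2, sd)
  scaled <- abs(est) * ifelse(covariate_sd > 0, covariate_sd, 1)
  scaled <- scaled[names(scaled) != "(Intercept)"]
  if (!fit$converged ||
      (any(probs < 1e-8 | probs > 1 - 1e-8) && any(scaled > 10))) {
    abort("separation detected in the unconditional logistic fit")
  }

  se <- sqrt(diag(vcov(fit)))[names(est)]
  z <- est / se
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * pnorm(-abs(z))),
    odds.ratio = exp(unname(est)),
    conf.low = exp(unname(est - qnorm(0.975) * se)),
    conf.high = exp(unname(est + qnorm(0.975) * se)))

  structure(list(coefficients = coefs,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n = nrow(d), converged = fit$converged,
                 exposure = exposure, fit = fit),
            class = "ncc_logistic")
}

#' @export
print.ncc_logistic <- function(x, ...) {
  cat(sprintf("Unconditional logistic fit (n = %d, logLik %.4f)\n",
              x$n, x$log_likelihood))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' Discordant-pair odds ratio for a binary exposure, both ways round
#'
#' With 1:1 matched pairs and a binary exposure, the conditional maximum-
#' likelihood odds ratio reduces to the ratio of the two discordant-pair
#' counts: pairs where only the case is exposed over pairs where only the
#' control is exposed. Swapping the roles of exposure and outcome (treating
#' exposure status as the "disease" and case/control membership as the
#' "exposure") gives the exposure odds ratio, which for a binary exposure
#' equals the disease odds ratio; both routes are computed and returned so
#' the identity can be checked directly.
#'
#' @inheritParams signed_rank_mpd
#' @return An object of class `ncc_discordant`: discordant counts
#'   `n_case_only`, `n_control_only`, `odds_ratio`, `odds_ratio_swapped`,
#'   and a `degenerate` flag when either discordant count is zero (the OR is
#'   then 0 or infinite).
#' @export
discordant_pair_or <- function(pairs, case_col = "case_value",
                               control_col = "control_value") {
  check_subject_cols(pairs, c(case_col, control_col), "pairs")
  cx <- pairs[[case_col]]; kx <- pairs[[control_col]]
  if (!all(c(cx, kx) %in% c(0, 1)))
    abort("discordant-pair odds ratio requires a binary (0/1) exposure")

  n10 <- sum(cx == 1 & kx == 0)   # case exposed, control unexposed
  n01 <- sum(cx == 0 & kx == 1)

  # swapped route: among exposure-discordant pairs, is the exposed member
  # the case? case-exposed over control-exposed — the Cornfield identity.
  exposed_is_case <- sum(cx == 1 & kx == 0)
  exposed_is_control <- sum(kx == 1 & cx == 0)

  structure(list(n_pairs = nrow(pairs),
                 n_case_only = n10, n_control_only = n01,
                 odds_ratio = n10 / n01,
                 odds_ratio_swapped = exposed_is_case / exposed_is_control,
                 degenerate = (n10 == 0 || n01 == 0)),
            class = "ncc_discordant")
}

#' @export
print.ncc_discordant <- function(x, ...) {
  cat("Discordant-pair odds ratio (binary exposure)\n")
  cat(sprintf("  case-only exposed: %d   control-only exposed: %d\n",
              x$n_case_only, x$n_control_only))
  cat(sprintf("  OR = %.4g (exposure-as-outcome OR = %.4g)%s\n",
              x$odds_ratio, x$odds_ratio_swapped,
              if (x$degenerate) "  [degenerate: a discordant count is zero]" else ""))
  invisible(x)
}
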