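#' Assemble matched sets for conditional analysis
#'
#' Joins a match result back to the subject table, producing one row per set
#' member (the case plus its matched controls) labelled by `set_id` (the
#' case's id). This is the long format [clr_fit()] and the trimmed refits
#' consume.
#'
#' @param match_result An `ncc_match` object.
#' @param cohort Subject tibble containing every matched id.
#' @return Tibble: `set_id`, then all subject columns.
#' @export
match_sets <- function(match_result, cohort) {
  stopifnot(inherits(match_result, "ncc_match"))
  check_subject_cols(cohort, "id", "cohort")
  pairs <- match_result$pairs
  members <- dplyr::bind_rows(
    tibble::tibble(set_id = unique(pairs$case_id), id = unique(pairs$case_id)),
    tibble::tibble(set_id = pairs$case_id, id = pairs$control_id))
  dplyr::inner_join(members,
                    dplyr::mutate(cohort, id = as.character(.data$id)),
                    by = "id")
}

#' Conditional logistic regression for matched sets with a single exposure
#'
#' Maximises the conditional likelihood
#' \deqn{\prod_s \frac{\exp(x_{case,s}\beta)}{\sum_{j \in s} \exp(x_{j,s}\beta)}}
#' over the scalar log odds ratio \eqn{\beta} by Newton-Raphson (start 0,
#' relative log-likelihood change < 1e-10 or gradient < 1e-8, at most 100
#' iterations). Conditioning on the sets eliminates all set-level nuisance
#' parameters, so the match factors never enter the model. Sets whose
#' exposure is constant across members carry no information and are dropped
#' (`n_informative_sets` records what remains). Exposures are centred within
#' set before optimisation, which leaves \eqn{\beta} unchanged (within-set
#' location invariance) but stabilises the exponentials.
#'
#' Inference is Wald on the log-odds scale: `se` from the observed
#' information, 95% CI `exp(beta +/- 1.96 se)`. Complete or quasi-complete
#' separation (the case holding the extreme exposure in every informative
#' set, giving a monotone likelihood) is detected by the estimate drifting
#' beyond any plausible scale and raised as an error rather than returned as
#' a silently huge coefficient.
#'
#' @param sets Long matched-set tibble from [match_sets()]: one case
#'   (`delirium_case == 1`) and at least one control per `set_id`.
#' @param time_point `"PREOP"`, `"PACU"` or `"POD2"`; picks the exposure
#'   column `il6_<time_point>` unless `exposure` names one directly.
#' @param exposure Optional exposure column name overriding `time_point`.
#' @return An object of class `ncc_clr`; see [tidy()]/[glance()] methods.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 5))
#' m <- optimal_match(dplyr::filter(cohort, delirium_case == 1),
#'                    dplyr::filter(cohort, delirium_case == 0))
#' fit <- clr_fit(match_sets(m, cohort), time_point = "POD2")
#' tidy(fit)
#' @export
clr_fit <- function(sets, time_point = "POD2", exposure = NULL) {
  exposure <- exposure %||% il6_col(time_point)
  check_subject_cols(sets, c("set_id", "delirium_case", exposure), "matched sets")
  if (any(is.na(sets[[exposure]])))
    abort(sprintf("exposure '%s' has missing values in the matched sets", exposure))

  by_set <- split(sets, sets$set_id)
  bad <- purrr::keep(by_set, ~ sum(.x$delirium_case == 1) != 1 || nrow(.x) < 2)
  if (length(bad) > 0)
    abort(sprintf("every set needs exactly one case and >= 1 controls; offending set(s): %s",
                  paste(head(names(bad), 5), collapse = ", ")))

  n_sets <- length(by_set)
  informative <- purrr::keep(by_set, ~ diff(range(.x[[exposure]])) > 0)
  n_inf <- length(informative)
  if (n_inf == 0)
    abort("conditional likelihood is flat: no informative sets (exposure constant within every set)")

  # centred exposure per set and the case's position
  xs <- purrr::map(informative, ~ .x[[exposure]] - mean(.x[[exposure]]))
  case_x <- unname(purrr::map2_dbl(xs, informative, ~ .x[.y$delirium_case == 1]))
  x_scale <- max(purrr::map_dbl(xs, ~ max(abs(.x))))

  # monotone likelihood: the case holds the (tied-or-strict) maximum or
  # minimum exposure in every informative set, so the MLE is infinite
  at_max <- purrr::map2_lgl(xs, case_x, ~ .y >= max(.x) - 1e-12)
  at_min <- purrr::map2_lgl(xs, case_x, ~ .y <= min(.x) + 1e-12)
  if (all(at_max) || all(at_min)) {
    abort(paste("separation detected in the conditional logistic fit:",
                "the likelihood is monotone in beta (the case holds the",
                "extreme exposure in every informative set)"))
  }

  loglik <- function(b) {
    sum(purrr::map2_dbl(xs, case_x, function(x, xc) {
      e <- x * b
      xc * b - (max(e) + log(sum(exp(e - max(e)))))
    }))
  }
  score_info <- function(b) {
    g <- 0; h <- 0
    for (i in seq_along(xs)) {
      x <- xs[[i]]
      w <- exp(x * b - max(x * b)); w <- w / sum(w)
      mu <- sum(w * x)
      g <- g + (case_x[i] - mu)
      h <- h + (sum(w * x^2) - mu^2)
    }
    list(g = g, h = h)
  }

  beta <- 0; ll <- loglik(0); converged <- FALSE; iter <- 0
  for (iter in seq_len(100)) {
    si <- score_info(beta)
    if (si$h <= 0) abort("conditional likelihood has no curvature at the current estimate")
    step <- si$g / si$h
    # halve overly large steps for stability
    while (abs(step) * x_scale > 5) step <- step / 2
    beta_new <- beta + step
    if (abs(beta_new) * x_scale > 500) {
      abort("conditional logistic estimate diverged (|beta| growing without bound)")
    }
    ll_new <- loglik(beta_new)
    if (is.finite(ll_new) && abs(ll_new - ll) <= 1e-10 * (abs(ll) + 1e-10)) {
      beta <- beta_new; ll <- ll_new; converged <- TRUE; break
    }
    beta <- beta_new; ll <- ll_new
    if (abs(si$g) < 1e-8) { converged <- TRUE; break }
  }
  si <- score_info(beta)
  if (abs(si$g) < 1e-6) converged <- TRUE
  se <- sqrt(1 / si$h)
  z <- beta / se
  ci <- beta + c(-1, 1) * qnorm(0.975) * se

  structure(list(beta = beta, se = se, wald_z = z,
                 p_value = 2 * pnorm(-abs(z)),
                 odds_ratio = exp(beta),
                 ci_lower = exp(ci[1]), ci_upper = exp(ci[2]),
                 log_likelihood = ll,
                 n_sets = n_sets, n_informative_sets = n_inf,
                 iterations = iter, converged = converged,
                 exposure = exposure, time_point = toupper(time_point)),
            class = "ncc_clr")
}

#' @export
print.ncc_clr <- function(x, ...) {
  cat(sprintf("Conditional logistic fit (%s, exposure %s)\n",
              x$time_point, x$exposure))
  cat(sprintf("  beta = %.4g (SE %.4g), z = %.3f, p = %.4g\n",
              x$beta, x$se, x$wald_z, x$p_value))
  cat(sprintf("  OR per unit = %.4g (95%% CI %.4g-%.4g)\n",
              x$odds_ratio, x$ci_lower, x$ci_upper))
  cat(sprintf("  sets: %d (%d informative), logLik %.4f, %s in %d iterations\n",
              x$n_sets, x$n_informative_sets, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  if (!is.null(x$trim)) {
    cat(sprintf("  trimmed at percentile %g (cutoff %.4g): %d set(s) removed\n",
                x$trim$percentile, x$trim$cutoff, x$trim$n_sets_removed))
  }
  invisible(x)
}

#' Sensitivity refit excluding sets with extreme exposures
#'
#' Computes the given percentile of the exposure pooled over all members of
#' all sets (cases and controls together), removes every set containing any
#' member strictly above that cutoff, and refits the conditional logistic
#' model. This probes whether a handful of very large biomarker values in the
#' right tail drive the association.
#'
#' @inheritParams clr_fit
#' @param percentile Percentile in (0, 100]; 100 removes nothing and returns
#'   the untrimmed fit.
#' @return An `ncc_clr` with an extra `trim` element recording the
#'   percentile, the cutoff on the exposure scale, and the sets removed.
#' @export
trim_refit <- function(sets, time_point = "POD2", exposure = NULL,
                       percentile = 90) {
  exposure <- exposure %||% il6_col(time_point)
  if (percentile <= 0 || percentile > 100)
    abort("`percentile` must lie in (0, 100]")
  check_subject_cols(sets, c("set_id", exposure), "matched sets")
  cutoff <- unname(quantile(sets[[exposure]], percentile / 100, na.rm = TRUE))
  drop_sets <- unique(sets$set_id[sets[[exposure]] > cutoff])
  kept <- dplyr::filter(sets, !.data$set_id %in% drop_sets)
  if (nrow(kept) == 0)
    abort("trimming removed every set; nothing left to fit")
  fit <- clr_fit(kept, time_point = time_point, exposure = exposure)
  fit$trim <- list(percentile = percentile, cutoff = cutoff,
                   n_sets_removed = length(drop_sets))
  fit
}
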