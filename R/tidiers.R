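#' Tidy and glance methods for nccdesign results
#'
#' broom-style accessors: `tidy()` returns the row-per-component view of a
#' result (pairs of a matching, coefficients of a fit, per-factor R-squared
#' components), `glance()` a one-row (or one-row-per-time-point) summary.
#'
#' @param x A result object from this package.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name ncc-tidiers
NULL

#' @rdname ncc-tidiers
#' @export
tidy.ncc_match <- function(x, ...) x$pairs

#' @rdname ncc-tidiers
#' @export
glance.ncc_match <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, ratio = x$criteria$ratio,
                 n_pairs = x$n_pairs, cases_matched = x$cases_matched,
                 mean_distance = x$mean_distance,
                 sum_distance = x$sum_distance,
                 n_unmatched_cases = length(x$unmatched_case_ids),
                 n_unmatched_controls = length(x$unmatched_control_ids))
}

#' @rdname ncc-tidiers
#' @export
tidy.ncc_clr <- function(x, ...) {
  tibble::tibble(term = x$exposure, estimate = x$beta, std.error = x$se,
                 statistic = x$wald_z, p.value = x$p_value,
                 odds.ratio = x$odds_ratio,
                 conf.low = x$ci_lower, conf.high = x$ci_upper)
}

#' @rdname ncc-tidiers
#' @export
glance.ncc_clr <- function(x, ...) {
  tibble::tibble(logLik = x$log_likelihood, n_sets = x$n_sets,
                 n_informative_sets = x$n_informative_sets,
                 iterations = x$iterations, converged = x$converged,
                 trim_percentile = if (is.null(x$trim)) NA_real_ else x$trim$percentile,
                 trim_cutoff = if (is.null(x$trim)) NA_real_ else x$trim$cutoff,
                 trim_sets_removed = if (is.null(x$trim)) NA_integer_ else x$trim$n_sets_removed)
}

#' @rdname ncc-tidiers
#' @export
tidy.ncc_paired <- function(x, ...) {
  tibble::tibble(estimate = x$mpd, statistic = x$statistic,
                 p.value = x$p_value, method = x$method,
                 n_pairs = x$n_pairs, n_nonzero = x$n_nonzero)
}

#' @rdname ncc-tidiers
#' @export
glance.ncc_paired <- function(x, ...) tidy.ncc_paired(x, ...)

#' @rdname ncc-tidiers
#' @export
tidy.ncc_logistic <- function(x, ...) x$coefficients

#' @rdname ncc-tidiers
#' @export
glance.ncc_logistic <- function(x, ...) {
  tibble::tibble(logLik = x$log_likelihood, n = x$n, converged = x$converged)
}

#' @rdname ncc-tidiers
#' @export
tidy.ncc_overmatch <- function(x, ...) x$components

#' @rdname ncc-tidiers
#' @export
glance.ncc_overmatch <- function(x, ...) x$summary

#' @rdname ncc-tidiers
#' @export
tidy.ncc_discordant <- function(x, ...) {
  tibble::tibble(odds.ratio = x$odds_ratio,
                 odds.ratio.swapped = x$odds_ratio_swapped,
                 n_case_only = x$n_case_only, n_control_only = x$n_control_only,
                 n_pairs = x$n_pairs, degenerate = x$degenerate)
}

#' @rdname ncc-tidiers
#' @export
glance.ncc_discordant <- function(x, ...) tidy.ncc_discordant(x, ...)
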