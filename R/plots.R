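#' Plot methods for nccdesign results
#'
#' `autoplot()` methods return ggplot objects: for a caliper sweep, match
#' yield (and mean distance) against caliper width by algorithm; for a match
#' result, the distribution of within-pair distances; for an overmatching
#' report, the per-factor sequential partial R-squared components stacked to
#' the model R-squared per time point.
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @name ncc-autoplot
NULL

#' @rdname ncc-autoplot
#' @export
autoplot.ncc_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$caliper, y = .data$n_pairs,
                                       colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$ratio),
                        labeller = ggplot2::labeller(
                          .default = function(k) paste0("1:", k))) +
    ggplot2::labs(x = "caliper width (applied to both continuous factors)",
                  y = "matched pairs", colour = "algorithm",
                  title = "Match yield across caliper widths") +
    ggplot2::theme_minimal()
}

#' @rdname ncc-autoplot
#' @export
autoplot.ncc_match <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey35", colour = "white") +
    ggplot2::labs(x = "within-pair distance", y = "pairs",
                  title = sprintf("Pair distances (%s, 1:%d)",
                                  object$algorithm, object$criteria$ratio)) +
    ggplot2::theme_minimal()
}

#' @rdname ncc-autoplot
#' @export
autoplot.ncc_overmatch <- function(object, ...) {
  comp <- dplyr::mutate(object$components,
                        factor = factor(.data$factor,
                                        levels = rev(object$factor_order)))
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$time_point,
                                     y = 100 * .data$partial_r2,
                                     fill = .data$factor)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "sequential partial R-squared (%)",
                  fill = "match factor",
                  title = "Overmatching diagnostic: variance of the biomarker\nexplained by the match factors (controls only)") +
    ggplot2::theme_minimal()
}
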