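#' Sweep the caliper width and compare matching algorithms
#'
#' Re-runs matching over a grid of caliper widths (the same width applied to
#' every calipered continuous factor), algorithms and control:case ratios, and
#' tabulates the match yield and quality of each configuration. Because the
#' feasible-edge set only grows with the caliper, the number of pairs is
#' non-decreasing in the caliper for a fixed algorithm and ratio; note the
#' optimal algorithm's total distance can exceed greedy's when it converts the
#' wider caliper into additional pairs.
#'
#' @inheritParams greedy_match
#' @param base_criteria Criteria supplying the exact factors and the names of
#'   the calipered factors; each sweep value replaces every caliper width.
#' @param caliper_values Positive widths, sorted ascending.
#' @param algorithms Subset of `c("greedy", "optimal")`.
#' @param ratios Integer vector of control:case ratios.
#' @return A tibble of class `ncc_sweep`: one row per
#'   (algorithm x ratio x caliper) with `n_pairs`, `cases_matched`,
#'   `cases_by_ratio` (e.g. `"7/6/1"` = 7 cases matched, 6 at 1:1, 1 at 1:2),
#'   `mean_distance`, `sum_distance`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_cases = 12, n_controls = 40, seed = 3))
#' caliper_sweep(dplyr::filter(cohort, delirium_case == 1),
#'               dplyr::filter(cohort, delirium_case == 0),
#'               caliper_values = c(1, 3, 5))
#' @export
caliper_sweep <- function(cases, controls, base_criteria = match_criteria(),
                          caliper_values = 1:5,
                          algorithms = c("greedy", "optimal"),
                          ratios = 1L) {
  if (any(caliper_values <= 0)) abort("`caliper_values` must be positive")
  if (is.unsorted(caliper_values)) abort("`caliper_values` must be sorted ascending")
  algorithms <- match.arg(algorithms, several.ok = TRUE)

  grid <- tidyr::expand_grid(algorithm = algorithms,
                             ratio = as.integer(ratios),
                             caliper = caliper_values)
  rows <- purrr::pmap(grid, function(algorithm, ratio, caliper) {
    crit <- base_criteria
    crit$caliper_factors[] <- caliper
    crit$ratio <- ratio
    fit <- if (algorithm == "greedy") greedy_match(cases, controls, crit)
           else optimal_match(cases, controls, crit)
    bk <- fit$ratio_breakdown
    tibble::tibble(
      algorithm = algorithm, ratio = ratio, caliper = caliper,
      n_pairs = fit$n_pairs,
      cases_matched = fit$cases_matched,
      cases_by_ratio = paste(c(fit$cases_matched, unname(bk)), collapse = "/"),
      mean_distance = fit$mean_distance,
      sum_distance = fit$sum_distance
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ncc_sweep", class(out))
  out
}

#' Covariate balance before and after matching
#'
#' Summarises the six match factors in four strata: all eligible cases and
#' controls (pre-match) and the matched cases and controls (post-match,
#' counting each subject once even under a 1:k design). Continuous factors
#' are reported as mean and SD, categorical factors as percentages. An empty
#' stratum yields `NA` cells rather than zeros.
#'
#' @inheritParams greedy_match
#' @param match_result An `ncc_match` from [greedy_match()] or
#'   [optimal_match()] computed on these subjects.
#' @return A tibble with one row per stratum.
#' @export
balance_table <- function(cases, controls, match_result) {
  stopifnot(inherits(match_result, "ncc_match"))
  summarise_stratum <- function(d, stratum) {
    if (nrow(d) == 0) {
      return(tibble::tibble(
        stratum = stratum, n = 0L,
        age_mean = NA_real_, age_sd = NA_real_,
        gcp_mean = NA_real_, gcp_sd = NA_real_,
        pct_female = NA_real_, pct_orthopedic = NA_real_,
        pct_vascular_comorbidity = NA_real_, pct_apoe_e4 = NA_real_))
    }
    tibble::tibble(
      stratum = stratum, n = nrow(d),
      age_mean = mean(d$age_years), age_sd = sd(d$age_years),
      gcp_mean = mean(d$gcp), gcp_sd = sd(d$gcp),
      pct_female = 100 * mean(d$gender == "female"),
      pct_orthopedic = 100 * mean(d$surgery_type == "orthopedic"),
      pct_vascular_comorbidity = 100 * mean(d$vascular_comorbidity == 1),
      pct_apoe_e4 = 100 * mean(d$apoe_e4 == 1))
  }
  post_cases <- dplyr::filter(cases, as.character(.data$id) %in%
                                unique(match_result$pairs$case_id))
  post_controls <- dplyr::filter(controls, as.character(.data$id) %in%
                                   unique(match_result$pairs$control_id))
  dplyr::bind_rows(
    summarise_stratum(cases, "pre_match_case"),
    summarise_stratum(controls, "pre_match_control"),
    summarise_stratum(post_cases, "post_match_case"),
    summarise_stratum(post_controls, "post_match_control")
  )
}
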