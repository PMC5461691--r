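#' Optimal matching: maximum pairs, then minimum total distance
#'
#' Solves the matching as a minimum-cost bipartite assignment problem with a
#' lexicographic objective: first maximise the number of case-control pairs
#' achievable under feasibility (every exact factor identical, every calipered
#' difference within its width), each control used at most once and each case
#' receiving at most `ratio` controls; then, among all matchings of that
#' cardinality, minimise the total distance. Unlike [greedy_match()], an
#' earlier pairing can be uncoupled and re-formed if that admits more pairs or
#' a smaller total distance, so the optimal algorithm never returns fewer
#' pairs than greedy and may return strictly more.
#'
#' The lexicographic objective is encoded by padding the assignment matrix
#' with dummy columns priced at a penalty exceeding any achievable total
#' distance, and solved with a shortest-augmenting-path assignment solver.
#'
#' @inheritParams greedy_match
#' @return An `ncc_match` object with elements `pairs` (tibble: `pair_id`,
#'   `case_id`, `control_id`, `distance`), `n_pairs`, `sum_distance`,
#'   `mean_distance`, `cases_matched`, `ratio_breakdown` (cases by number of
#'   controls received), `unmatched_case_ids`, `unmatched_control_ids`.
#'   Use [tidy()] for the pairs and [glance()] for the one-row summary.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_cases = 15, n_controls = 45, seed = 7))
#' cases <- dplyr::filter(cohort, delirium_case == 1)
#' controls <- dplyr::filter(cohort, delirium_case == 0)
#' m <- optimal_match(cases, controls, match_criteria())
#' glance(m)
#' @export
optimal_match <- function(cases, controls, criteria = match_criteria()) {
  cases <- filter_match_eligible(cases)
  controls <- filter_match_eligible(controls)
  if (nrow(cases) == 0 || nrow(controls) == 0)
    return(new_match_result(NULL, cases, controls, "optimal", criteria))

  d <- distance_matrix(cases, controls, criteria)
  if (all(is.infinite(d)))
    return(new_match_result(NULL, cases, controls, "optimal", criteria))

  k <- criteria$ratio
  nc <- nrow(cases); nk <- nrow(controls)
  n_rows <- nc * k
  # penalty dominating any achievable total distance; each feasible edge
  # distance <= sum of caliper widths
  width_sum <- sum(criteria$caliper_factors)
  penalty <- width_sum * min(n_rows, nk) + 1

  # rows: each case replicated k times (capacity k); dummy columns let any
  # row stay unmatched at cost `penalty`; infeasible edges cost 2*penalty so
  # they are never preferred to a dummy
  cost <- d[rep(seq_len(nc), each = k), , drop = FALSE]
  cost[is.infinite(cost)] <- 2 * penalty
  cost <- cbind(cost, matrix(penalty, nrow = n_rows, ncol = n_rows))

  assign <- lsap_solve(cost)
  row_case <- rep(seq_len(nc), each = k)
  real <- assign <= nk
  real[real] <- is.finite(d[cbind(row_case[real], assign[real])])

  pairs <- tibble::tibble(
    case_id = as.character(cases$id)[row_case[real]],
    control_id = as.character(controls$id)[assign[real]],
    distance = d[cbind(row_case[real], assign[real])]
  )
  new_match_result(pairs, cases, controls, "optimal", criteria)
}
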