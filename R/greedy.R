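#' Greedy nearest-available matching without replacement
#'
#' Processes cases sequentially (by default in the order they appear in
#' `cases`); each case takes the feasible, still-available control with the
#' smallest distance, which is then removed from the pool, and never revisits
#' a decision. With `ratio = k > 1` each case takes up to its k nearest
#' available controls in one pass. Ties among equidistant controls are broken
#' by the lexicographically smallest control id, so results are deterministic
#' for a given input order. The greedy strategy is locally optimal only: an
#' early pairing can block a later case entirely, which is exactly the
#' weakness that motivates [optimal_match()].
#'
#' @param cases,controls Data frames of subjects (one row each); must contain
#'   `id` and every criteria field. Rows with `hemolysis_ok` FALSE are
#'   excluded from matching.
#' @param criteria An [match_criteria()] object.
#' @param order `"input"` (default) processes cases in row order; the
#'   `"best_first"` variant repeatedly forms the globally closest remaining
#'   feasible pair instead. The sequential reading is the documented
#'   convention; best-first is exploratory.
#' @return An `ncc_match` object; see [optimal_match()] for the fields.
#' @seealso [optimal_match()], [caliper_sweep()], [balance_table()]
#' @export
greedy_match <- function(cases, controls, criteria = match_criteria(),
                         order = c("input", "best_first")) {
  order <- match.arg(order)
  cases <- filter_match_eligible(cases)
  controls <- filter_match_eligible(controls)
  if (nrow(cases) == 0 || nrow(controls) == 0)
    return(new_match_result(NULL, cases, controls, "greedy", criteria))

  d <- distance_matrix(cases, controls, criteria)
  control_ids <- as.character(controls$id)
  case_ids <- as.character(cases$id)
  available <- rep(TRUE, length(control_ids))
  pairs <- list()

  if (order == "input") {
    for (i in seq_along(case_ids)) {
      for (slot in seq_len(criteria$ratio)) {
        di <- d[i, ]
        di[!available] <- Inf
        if (all(is.infinite(di))) break
        # ties by smallest control id
        j <- which(di == min(di))
        j <- j[base::order(control_ids[j])][1]
        available[j] <- FALSE
        pairs[[length(pairs) + 1L]] <-
          tibble::tibble(case_id = case_ids[i], control_id = control_ids[j],
                         distance = unname(di[j]))
      }
    }
  } else {
    capacity <- rep(criteria$ratio, length(case_ids))
    w <- d
    repeat {
      w[, !available] <- Inf
      w[capacity == 0, ] <- Inf
      if (all(is.infinite(w))) break
      idx <- which(w == min(w), arr.ind = TRUE)
      idx <- idx[base::order(case_ids[idx[, 1]], control_ids[idx[, 2]]), ,
                 drop = FALSE]
      i <- idx[1, 1]; j <- idx[1, 2]
      capacity[i] <- capacity[i] - 1L
      available[j] <- FALSE
      pairs[[length(pairs) + 1L]] <-
        tibble::tibble(case_id = case_ids[i], control_id = control_ids[j],
                       distance = d[i, j])
    }
  }

  new_match_result(dplyr::bind_rows(pairs), cases, controls, "greedy", criteria)
}
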