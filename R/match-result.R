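# Shared constructor for the result of either matching algorithm.
new_match_result <- function(pairs, cases, controls, algorithm, criteria) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) > 0) {
    pairs <- dplyr::arrange(pairs, match(.data$case_id, as.character(cases$id)),
                            .data$distance) |>
      dplyr::mutate(pair_id = dplyr::row_number(), .before = 1)
  } else {
    pairs <- tibble::tibble(pair_id = integer(), case_id = character(),
                            control_id = character(), distance = numeric())
  }
  per_case <- table(pairs$case_id)
  breakdown <- if (length(per_case)) table(factor(as.integer(per_case),
                                                  levels = seq_len(criteria$ratio)))
               else table(factor(integer(), levels = seq_len(criteria$ratio)))
  structure(
    list(
      pairs = pairs,
      n_pairs = nrow(pairs),
      sum_distance = sum(pairs$distance),
      mean_distance = if (nrow(pairs) > 0) sum(pairs$distance) / nrow(pairs) else NA_real_,
      cases_matched = length(per_case),
      ratio_breakdown = setNames(as.integer(breakdown), names(breakdown)),
      unmatched_case_ids = setdiff(as.character(cases$id), pairs$case_id),
      unmatched_control_ids = setdiff(as.character(controls$id), pairs$control_id),
      algorithm = algorithm,
      criteria = criteria
    ),
    class = "ncc_match"
  )
}

#' @export
print.ncc_match <- function(x, ...) {
  cat(sprintf("Matched nested case-control set (%s algorithm, 1:%d)\n",
              x$algorithm, x$criteria$ratio))
  cat(sprintf("  pairs: %d   cases matched: %d   unmatched cases: %d\n",
              x$n_pairs, x$cases_matched, length(x$unmatched_case_ids)))
  if (x$n_pairs > 0) {
    cat(sprintf("  sum distance: %.4g   mean distance: %.4g\n",
                x$sum_distance, x$mean_distance))
    bk <- x$ratio_breakdown[x$ratio_breakdown > 0]
    if (length(bk))
      cat("  cases by controls received: ",
          paste(sprintf("%s control(s): %d", names(bk), bk), collapse = ", "), "\n")
  }
  invisible(x)
}
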