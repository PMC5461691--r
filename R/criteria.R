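#' Define matching criteria for a nested case-control design
#'
#' Matching requires identical values on every exact (categorical) factor and
#' an absolute difference no larger than the caliper on every continuous
#' factor. The pair distance is the sum of absolute differences over the
#' calipered factors; exact factors contribute zero by construction. Defaults
#' reproduce a six-factor design: exact match on gender, surgery type,
#' vascular comorbidity and APOE e4 carriage, with 5-unit calipers on age
#' (years) and general cognitive performance (GCP points).
#'
#' @param exact_factors Character vector of categorical column names that must
#'   match exactly.
#' @param caliper_factors Named numeric vector: names are continuous column
#'   names, values are caliper widths (> 0).
#' @param ratio Maximum number of controls per case (integer >= 1). A case
#'   counts as matched when it receives at least one control.
#' @return An object of class `ncc_criteria`.
#' @examples
#' match_criteria()
#' match_criteria(caliper_factors = c(age_years = 3, gcp = 3), ratio = 2)
#' @export
match_criteria <- function(exact_factors = c("gender", "surgery_type",
                                             "vascular_comorbidity", "apoe_e4"),
                           caliper_factors = c(age_years = 5, gcp = 5),
                           ratio = 1L) {
  if (length(caliper_factors) > 0) {
    if (is.null(names(caliper_factors)) || any(!nzchar(names(caliper_factors))))
      abort("`caliper_factors` must be a named numeric vector (name = column, value = width)")
    if (any(caliper_factors <= 0))
      abort("caliper widths must be > 0")
  }
  ratio <- as.integer(ratio)
  if (is.na(ratio) || ratio < 1L) abort("`ratio` must be an integer >= 1")
  structure(
    list(exact_factors = as.character(exact_factors),
         caliper_factors = caliper_factors,
         ratio = ratio),
    class = "ncc_criteria"
  )
}

#' @export
print.ncc_criteria <- function(x, ...) {
  cat("Match criteria\n")
  cat("  exact factors:  ", paste(x$exact_factors, collapse = ", "), "\n")
  cat("  calipers:       ",
      paste(sprintf("%s <= %g", names(x$caliper_factors), x$caliper_factors),
            collapse = ", "), "\n")
  cat("  controls:case:  ", x$ratio, ": 1\n", sep = "")
  invisible(x)
}

check_criteria_fields <- function(subject, criteria, label = "subject") {
  fields <- c(criteria$exact_factors, names(criteria$caliper_factors))
  for (f in fields) {
    if (!f %in% names(subject) || is.na(subject[[f]][1])) {
      id <- if ("id" %in% names(subject)) subject$id[1] else label
      abort(sprintf("subject '%s' is missing match field '%s'", id, f))
    }
  }
  invisible(TRUE)
}

#' Distance between one case and one control under matching criteria
#'
#' Returns the sum of absolute differences over the calipered continuous
#' factors, or `Inf` when the pair is infeasible: any exact factor differs, or
#' any calipered absolute difference exceeds its width. Caliper comparisons
#' are inclusive (a difference exactly equal to the width is allowed), with an
#' absolute floating-point tolerance of 1e-9.
#'
#' @param case,control Single-row data frames (one subject each).
#' @param criteria An [match_criteria()] object.
#' @return A non-negative number, or `Inf` for an infeasible pair.
#' @examples
#' a <- tibble::tibble(id = "c1", age_years = 74, gcp = 55, gender = "F",
#'                     surgery_type = "orthopedic", vascular_comorbidity = 0,
#'                     apoe_e4 = 0)
#' b <- dplyr::mutate(a, id = "k1", age_years = 77, gcp = 51)
#' pair_distance(a, b, match_criteria())  # 3 + 4 = 7
#' @export
pair_distance <- function(case, control, criteria = match_criteria()) {
  check_criteria_fields(case, criteria, "case")
  check_criteria_fields(control, criteria, "control")
  for (f in criteria$exact_factors) {
    if (case[[f]][1] != control[[f]][1]) return(Inf)
  }
  d <- 0
  for (f in names(criteria$caliper_factors)) {
    df <- abs(case[[f]][1] - control[[f]][1])
    if (df > criteria$caliper_factors[[f]] + 1e-9) return(Inf)
    d <- d + df
  }
  d
}

# Full cases x controls distance matrix (Inf = infeasible), vectorised.
distance_matrix <- function(cases, controls, criteria) {
  check_subject_cols(cases, c("id", criteria$exact_factors,
                              names(criteria$caliper_factors)), "cases")
  check_subject_cols(controls, c("id", criteria$exact_factors,
                                 names(criteria$caliper_factors)), "controls")
  nc <- nrow(cases); nk <- nrow(controls)
  if (nc == 0 || nk == 0)
    return(matrix(numeric(0), nrow = nc, ncol = nk))
  feasible <- matrix(TRUE, nc, nk)
  for (f in criteria$exact_factors) {
    feasible <- feasible & outer(as.character(cases[[f]]),
                                 as.character(controls[[f]]), "==")
  }
  d <- matrix(0, nc, nk)
  for (f in names(criteria$caliper_factors)) {
    diffs <- abs(outer(cases[[f]], controls[[f]], "-"))
    feasible <- feasible & (diffs <= criteria$caliper_factors[[f]] + 1e-9)
    d <- d + diffs
  }
  d[!feasible] <- Inf
  dimnames(d) <- list(as.character(cases$id), as.character(controls$id))
  d
}

# Drop subjects flagged as hemolysed before either pool enters matching.
filter_match_eligible <- function(subjects) {
  if ("hemolysis_ok" %in% names(subjects)) {
    subjects <- dplyr::filter(subjects, .data$hemolysis_ok %in% c(TRUE, 1))
  }
  subjects
}
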