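#' Round half away from zero
#'
#' Decimal rounding in which exact halves move away from zero (the convention
#' most statistical reports use for printed tables), unlike [base::round()]'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Numeric vector of the same length.
#' @examples
#' round_half_away(22.25, 1)  # 22.3
#' round(22.25, 1)            # 22.2 (banker's rounding)
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by an ulp-scale epsilon so values stored just under x.x5 still round up
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# match-factor columns shared by the generator, matcher and models
ncc_factor_cols <- function() {
  c("age_years", "gcp", "gender", "surgery_type",
    "vascular_comorbidity", "apoe_e4")
}

ncc_time_points <- function() c("PREOP", "PACU", "POD2")

il6_col <- function(time_point) {
  time_point <- match.arg(toupper(time_point), ncc_time_points())
  paste0("il6_", tolower(time_point))
}

check_subject_cols <- function(data, cols, what = "cohort") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# Deterministic per-stage seeds derived from one root seed: draw from a
# seeded stream so stages are independent but fully reproducible.
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
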