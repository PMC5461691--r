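#' Configuration for the synthetic surgical-cohort generator
#'
#' Builds the parameter set for [simulate_cohort()]. The defaults emulate an
#' older-adult elective-surgery cohort eligible for a matched nested
#' case-control study of an inflammatory biomarker (IL-6, pg/ml) and
#' postoperative delirium: 49 delirium cases and 143 controls whose six
#' match-factor marginals follow the study's pre-match distribution (cases:
#' age 77.2 +/- 4.9, GCP 54.2 +/- 5.9, 55% female, 86% orthopedic, 45%
#' vascular comorbidity, 18% APOE e4; controls: 76.3 +/- 4.8, 58.9 +/- 6.6,
#' 57%, 85%, 29%, 24%). Surgery-type mass outside orthopedic is split equally
#' between vascular and gastrointestinal.
#'
#' IL-6 is drawn log-normally per (time point x case status), parameterised by
#' target mean/SD on the pg/ml scale. The POD2 control stratum (mean 84.4, SD
#' 55) together with the default multiplicative case effect of 0.6 (cases
#' shifted x1.6) reproduces approximately the pooled matched-sample POD2
#' summary of mean ~110, SD ~80. PREOP and PACU strata have no case effect
#' and arbitrary but physiologically plausible defaults (PREOP mean 6, SD 5;
#' PACU mean 40, SD 30).
#'
#' @param n_cases,n_controls Subject counts (>= 0).
#' @param marginals Two-level list (`case`, `control`) of match-factor
#'   targets: `age_mean`, `age_sd`, `gcp_mean`, `gcp_sd`, `p_female`,
#'   `p_surgery` (named probabilities over orthopedic/vascular/
#'   gastrointestinal, summing to 1), `p_vascular`, `p_apoe`.
#' @param il6_model Per time point (`PREOP`, `PACU`, `POD2`), a list with
#'   `mean` and `sd` for the control stratum on the pg/ml scale.
#' @param pod2_effect Case shift at POD2; 0 means cases and controls share
#'   the POD2 distribution.
#' @param pod2_effect_type `"multiplicative"`: case mean = control mean x
#'   (1 + effect), coefficient of variation preserved; `"additive"`: case
#'   mean = control mean + effect, SD preserved.
#' @param age_gcp_cor Correlation between age and GCP within status group
#'   (default 0: factors independent, matching the marginal-only targets).
#' @param hemolysis_fail_rate Probability a subject's samples are too
#'   hemolysed for assay; flagged subjects keep their row but are excluded
#'   from match eligibility.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A validated list of class `ncc_config`.
#' @export
cohort_config <- function(n_cases = 49L, n_controls = 143L,
                          marginals = NULL, il6_model = NULL,
                          pod2_effect = 0.6,
                          pod2_effect_type = c("multiplicative", "additive"),
                          age_gcp_cor = 0,
                          hemolysis_fail_rate = 0,
                          seed = 1L) {
  pod2_effect_type <- match.arg(pod2_effect_type)
  default_marginals <- list(
    case = list(age_mean = 77.2, age_sd = 4.9, gcp_mean = 54.2, gcp_sd = 5.9,
                p_female = 0.55,
                p_surgery = c(orthopedic = 0.86, vascular = 0.07,
                              gastrointestinal = 0.07),
                p_vascular = 0.45, p_apoe = 0.18),
    control = list(age_mean = 76.3, age_sd = 4.8, gcp_mean = 58.9, gcp_sd = 6.6,
                   p_female = 0.57,
                   p_surgery = c(orthopedic = 0.85, vascular = 0.075,
                                 gastrointestinal = 0.075),
                   p_vascular = 0.29, p_apoe = 0.24))
  default_il6 <- list(PREOP = list(mean = 6, sd = 5),
                      PACU = list(mean = 40, sd = 30),
                      POD2 = list(mean = 84.4, sd = 55))
  marginals <- if (is.null(marginals)) default_marginals
               else list(case = modifyList(default_marginals$case, marginals$case %||% list()),
                         control = modifyList(default_marginals$control, marginals$control %||% list()))
  il6_model <- if (is.null(il6_model)) default_il6
               else modifyList(default_il6, il6_model)

  if (n_cases < 0 || n_controls < 0) abort("subject counts must be >= 0")
  for (g in c("case", "control")) {
    m <- marginals[[g]]
    probs <- c(m$p_female, m$p_vascular, m$p_apoe, m$p_surgery)
    if (any(probs < 0 | probs > 1)) abort("marginal probabilities must lie in [0, 1]")
    if (abs(sum(m$p_surgery) - 1) > 1e-8)
      abort("surgery-type probabilities must sum to 1")
    if (m$age_sd <= 0 || m$gcp_sd <= 0) abort("marginal SDs must be > 0")
  }
  for (tp in ncc_time_points()) {
    if (il6_model[[tp]]$mean <= 0 || il6_model[[tp]]$sd <= 0)
      abort("il6 model means and SDs must be > 0")
  }
  if (hemolysis_fail_rate < 0 || hemolysis_fail_rate > 1)
    abort("`hemolysis_fail_rate` must lie in [0, 1]")
  if (abs(age_gcp_cor) > 1) abort("`age_gcp_cor` must lie in [-1, 1]")
  if (pod2_effect_type == "multiplicative" && pod2_effect <= -1)
    abort("multiplicative `pod2_effect` must be > -1")

  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 marginals = marginals, il6_model = il6_model,
                 pod2_effect = pod2_effect,
                 pod2_effect_type = pod2_effect_type,
                 age_gcp_cor = age_gcp_cor,
                 hemolysis_fail_rate = hemolysis_fail_rate,
                 seed = as.integer(seed)),
            class = "ncc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log-normal location/scale from a target mean/SD on the natural scale
lognormal_params <- function(mean, sd) {
  sdlog2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# case-stratum target mean/SD at a time point after applying the POD2 effect
case_il6_target <- function(config, time_point) {
  base <- config$il6_model[[time_point]]
  if (time_point != "POD2" || config$pod2_effect == 0) return(base)
  if (config$pod2_effect_type == "multiplicative") {
    f <- 1 + config$pod2_effect
    list(mean = base$mean * f, sd = base$sd * f)
  } else {
    list(mean = base$mean + config$pod2_effect, sd = base$sd)
  }
}

#' Generate a synthetic cohort of surgical subjects
#'
#' Draws `n_cases + n_controls` subjects with the six match factors sampled
#' independently from the configured status-specific marginals (optionally
#' with an age-GCP correlation) and log-normal biomarker values per
#' (time point x status) stratum. Deterministic for a fixed config: the same
#' seed always reproduces the same cohort.
#'
#' @param config An [cohort_config()] object.
#' @return A tibble with one row per subject: `id`, `age_years`, `gcp`,
#'   `gender` (`"female"`/`"male"`), `surgery_type`, `vascular_comorbidity`
#'   (0/1), `apoe_e4` (0/1), `delirium_case` (0/1), `il6_preop`, `il6_pacu`,
#'   `il6_pod2` (pg/ml), `hemolysis_ok` (logical).
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 42))
#' dplyr::count(cohort, delirium_case)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "ncc_config"))
  set.seed(config$seed)

  draw_group <- function(n, status) {
    m <- config$marginals[[if (status == 1) "case" else "control"]]
    z1 <- rnorm(n); z2 <- rnorm(n)
    r <- config$age_gcp_cor
    age <- m$age_mean + m$age_sd * z1
    gcp <- m$gcp_mean + m$gcp_sd * (r * z1 + sqrt(1 - r^2) * z2)
    il6 <- lapply(ncc_time_points(), function(tp) {
      tgt <- if (status == 1) case_il6_target(config, tp) else config$il6_model[[tp]]
      p <- lognormal_params(tgt$mean, tgt$sd)
      rlnorm(n, p$meanlog, p$sdlog)
    })
    tibble::tibble(
      age_years = age, gcp = gcp,
      gender = c("male", "female")[rbinom(n, 1, m$p_female) + 1L],
      surgery_type = sample(names(m$p_surgery), n, replace = TRUE,
                            prob = m$p_surgery),
      vascular_comorbidity = rbinom(n, 1, m$p_vascular),
      apoe_e4 = rbinom(n, 1, m$p_apoe),
      delirium_case = status,
      il6_preop = il6[[1]], il6_pacu = il6[[2]], il6_pod2 = il6[[3]],
      hemolysis_ok = rbinom(n, 1, config$hemolysis_fail_rate) == 0
    )
  }

  cohort <- dplyr::bind_rows(draw_group(config$n_cases, 1L),
                             draw_group(config$n_controls, 0L))
  dplyr::mutate(cohort,
                id = sprintf("S%04d", dplyr::row_number()), .before = 1)
}

#' Build a biomarker pool from measured subjects
#'
#' Pivots the per-time-point biomarker columns of (typically) the matched
#' subjects into the long (time_point, status, value) pool that
#' [resample_biomarker()] samples from; missing values are dropped.
#'
#' @param subjects Subject tibble with `delirium_case` and the `il6_*` columns.
#' @return Tibble with columns `time_point`, `delirium_case`, `il6`.
#' @export
biomarker_pool <- function(subjects) {
  check_subject_cols(subjects, c("delirium_case", "il6_preop", "il6_pacu",
                                 "il6_pod2"), "subjects")
  tidyr::pivot_longer(subjects,
                      cols = c("il6_preop", "il6_pacu", "il6_pod2"),
                      names_to = "time_point", names_prefix = "il6_",
                      values_to = "il6") |>
    dplyr::mutate(time_point = toupper(.data$time_point)) |>
    dplyr::filter(!is.na(.data$il6)) |>
    dplyr::select("time_point", "delirium_case", "il6")
}

#' Assign biomarker values to a full cohort by stratified resampling
#'
#' Unrestricted random sampling (URS): every subject, at every time point,
#' receives a value drawn uniformly *with replacement* from the pool stratum
#' matching that subject's (time point, case status) — emulating the device
#' of extending a biomarker measured only on the matched subset to the whole
#' match-eligible cohort so an unconditional cohort analysis can be run. All
#' subjects are reassigned, including those whose biomarker was actually
#' measured, so every subject has the same probability of any pooled value.
#'
#' @param cohort Subject tibble (see [simulate_cohort()]).
#' @param pool Long pool from [biomarker_pool()].
#' @param seed Integer seed.
#' @return The cohort with `il6_preop`, `il6_pacu`, `il6_pod2` replaced by
#'   resampled values.
#' @export
resample_biomarker <- function(cohort, pool, seed = 1L) {
  check_subject_cols(cohort, "delirium_case", "cohort")
  check_subject_cols(pool, c("time_point", "delirium_case", "il6"), "pool")
  set.seed(as.integer(seed))
  out <- cohort
  for (tp in ncc_time_points()) {
    col <- il6_col(tp)
    for (status in unique(cohort$delirium_case)) {
      stratum <- pool$il6[pool$time_point == tp &
                            pool$delirium_case == status]
      idx <- which(cohort$delirium_case == status)
      if (length(idx) == 0) next
      if (length(stratum) == 0) {
        abort(sprintf(
          "biomarker pool has no values for stratum (time_point = %s, delirium_case = %s)",
          tp, status))
      }
      out[[col]][idx] <- stratum[sample.int(length(stratum), length(idx),
                                            replace = TRUE)]
    }
  }
  out
}

#' Read / write a cohort as delimited text
#'
#' Plain-CSV serialisation of the subject table (header row, one row per
#' subject, empty cell = missing biomarker value).
#'
#' @param path File path.
#' @param cohort Subject tibble.
#' @return `read_cohort()` returns the subject tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id = readr::col_character(),
                    gender = readr::col_character(),
                    surgery_type = readr::col_character(),
                    hemolysis_ok = readr::col_logical(),
                    .default = readr::col_double()))
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}
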