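# Minimal subject builder: one row per element of `age`, everything else
# constant unless overridden.
make_subjects <- function(id, age, gcp = 50, gender = "female",
                          surgery_type = "orthopedic",
                          vascular_comorbidity = 0, apoe_e4 = 0,
                          delirium_case = 0) {
  tibble::tibble(id = as.character(id), age_years = age, gcp = gcp,
                 gender = gender, surgery_type = surgery_type,
                 vascular_comorbidity = vascular_comorbidity,
                 apoe_e4 = apoe_e4, delirium_case = delirium_case)
}

# Random matching instance: two binary exact factors, two calipered
# continuous factors, sizes and spread chosen so instances mix feasible and
# infeasible edges.
random_instance <- function(n_cases, n_controls, caliper = 5) {
  draw <- function(n, prefix) {
    make_subjects(paste0(prefix, seq_len(n)),
                  age = runif(n, 70, 90),
                  gcp = runif(n, 40, 70),
                  gender = sample(c("female", "male"), n, replace = TRUE),
                  apoe_e4 = sample(0:1, n, replace = TRUE))
  }
  list(cases = draw(n_cases, "C"), controls = draw(n_controls, "K"),
       criteria = match_criteria(exact_factors = c("gender", "apoe_e4"),
                                 caliper_factors = c(age_years = caliper,
                                                     gcp = caliper)))
}

# 1:1 matched pairs generated from the conditional logistic model with a
# known log odds ratio: member exposures are drawn iid and the case label
# falls on member 1 with probability exp(x1 b) / (exp(x1 b) + exp(x2 b)).
simulate_clr_pairs <- function(n_pairs, beta) {
  x1 <- rnorm(n_pairs); x2 <- rnorm(n_pairs)
  p1 <- 1 / (1 + exp(-(x1 - x2) * beta))
  case_first <- runif(n_pairs) < p1
  tibble::tibble(
    set_id = rep(sprintf("P%03d", seq_len(n_pairs)), each = 2),
    delirium_case = as.integer(rbind(case_first, !case_first)),
    x = as.numeric(rbind(x1, x2)))
}
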