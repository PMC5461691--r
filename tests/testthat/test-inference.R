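# ---- conditional logistic regression -----------------------------------

binary_pair_sets <- function(n_case_only, n_control_only, n_concordant = 4) {
  n <- n_case_only + n_control_only + n_concordant
  case_x <- c(rep(1, n_case_only), rep(0, n_control_only), rep(1, n_concordant))
  ctrl_x <- c(rep(0, n_case_only), rep(1, n_control_only), rep(1, n_concordant))
  tibble::tibble(set_id = rep(sprintf("S%02d", 1:n), each = 2),
                 delirium_case = rep(c(1L, 0L), n),
                 x = as.numeric(rbind(case_x, ctrl_x)))
}

test_that("binary-exposure conditional MLE equals the discordant-count ratio", {
  sets <- binary_pair_sets(10, 5)
  fit <- clr_fit(sets, exposure = "x")
  expect_equal(fit$beta, log(2), tolerance = 1e-6)
  expect_equal(fit$odds_ratio, 2, tolerance = 1e-6)
  expect_equal(fit$n_sets, 19)
  expect_equal(fit$n_informative_sets, 15)  # concordant pairs carry nothing
  expect_true(fit$converged)

  # and the discordant-pair odds ratio agrees through both routes
  pairs <- tibble::tibble(case_value = c(rep(1, 10), rep(0, 5), rep(1, 4)),
                          control_value = c(rep(0, 10), rep(1, 5), rep(1, 4)))
  dor <- discordant_pair_or(pairs)
  expect_equal(dor$odds_ratio, 2)
  expect_equal(dor$odds_ratio_swapped, 2)
  expect_false(dor$degenerate)
  expect_equal(dor$odds_ratio, exp(fit$beta), tolerance = 1e-6)
})

test_that("balanced discordant counts give OR 1 and concordant-only data are degenerate", {
  even <- discordant_pair_or(tibble::tibble(case_value = c(rep(1, 7), rep(0, 7)),
                                            control_value = c(rep(0, 7), rep(1, 7))))
  expect_equal(even$odds_ratio, 1)
  conc <- discordant_pair_or(tibble::tibble(case_value = c(1, 0),
                                            control_value = c(1, 0)))
  expect_true(conc$degenerate)
  expect_error(discordant_pair_or(tibble::tibble(case_value = 0.5,
                                                 control_value = 0)), "binary")
})

test_that("a flat conditional likelihood (no informative sets) is an error", {
  sets <- tibble::tibble(set_id = rep(c("a", "b"), each = 2),
                         delirium_case = rep(c(1L, 0L), 2),
                         x = c(3, 3, 7, 7))
  expect_error(clr_fit(sets, exposure = "x"), "flat|informative")
})

test_that("malformed sets (no case, or case-only) are rejected", {
  sets <- tibble::tibble(set_id = c("a", "a", "b", "b"),
                         delirium_case = c(1L, 1L, 1L, 0L),
                         x = c(1, 2, 3, 4))
  expect_error(clr_fit(sets, exposure = "x"), "exactly one case")
})

test_that("1:1 conditional beta matches the intercept-free difference-logistic oracle", {
  set.seed(501)
  for (i in 1:5) {
    sets <- simulate_clr_pairs(40, beta = runif(1, -1, 1))
    fit <- clr_fit(sets, exposure = "x")
    expect_equal(fit$beta, difference_logistic_beta(sets), tolerance = 1e-6)
  }
})

test_that("conditional fit agrees with an established survival-model implementation", {
  skip_if_not_installed("survival")
  set.seed(502)
  # 1:2 sets exercise the general (non-pair) conditional likelihood
  sets <- dplyr::bind_rows(purrr::map(1:30, function(i) {
    tibble::tibble(set_id = sprintf("S%02d", i),
                   delirium_case = c(1L, 0L, 0L), x = rnorm(3))
  }))
  fit <- clr_fit(sets, exposure = "x")
  ref <- survival::coxph(survival::Surv(rep(1, nrow(sets)), delirium_case) ~
                           x + survival::strata(set_id),
                         data = sets, ties = "exact")
  expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-8)
})

test_that("adding a constant to every exposure leaves the conditional beta unchanged", {
  set.seed(503)
  sets <- simulate_clr_pairs(30, beta = 0.4)
  f1 <- clr_fit(sets, exposure = "x")
  f2 <- clr_fit(dplyr::mutate(sets, x = x + 1000), exposure = "x")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$se, f2$se, tolerance = 1e-8)
})

test_that("separation (case always extreme) raises an error, not a huge estimate", {
  sets <- tibble::tibble(set_id = rep(sprintf("S%d", 1:8), each = 2),
                         delirium_case = rep(c(1L, 0L), 8),
                         x = as.numeric(rbind(11:18, 1:8)))
  expect_error(clr_fit(sets, exposure = "x"), "separation")
})

# ---- median paired difference / signed-rank ----------------------------

test_that("signed-rank handles the symmetric, ordered, and all-equal textbook cases", {
  sym <- signed_rank_mpd(tibble::tibble(case_value = c(0, 2),
                                        control_value = c(1, 1)))
  expect_equal(sym$mpd, 0)
  expect_equal(sym$p_value, 1)

  inc <- signed_rank_mpd(tibble::tibble(case_value = c(1, 2, 3),
                                        control_value = 0))
  expect_equal(inc$mpd, 2)
  expect_equal(inc$p_value, 0.25)   # 2/8 sign assignments as extreme
  expect_equal(inc$method, "exact")

  all5 <- signed_rank_mpd(tibble::tibble(case_value = rep(5, 6),
                                         control_value = 0))
  expect_equal(all5$mpd, 5)
  expect_equal(all5$p_value, 2 / 2^6)
})

test_that("zeros are dropped and an all-zero set is degenerate with p = 1", {
  r <- signed_rank_mpd(tibble::tibble(case_value = c(1, 1, 3),
                                      control_value = c(1, 1, 1)))
  expect_equal(r$n_nonzero, 1)
  expect_equal(r$n_pairs, 3)
  expect_equal(r$mpd, 0)  # median of (0, 0, 2)

  z <- signed_rank_mpd(tibble::tibble(case_value = c(2, 2),
                                      control_value = c(2, 2)))
  expect_equal(z$method, "degenerate")
  expect_equal(z$p_value, 1)
  expect_equal(z$mpd, 0)
})

test_that("exact p matches full sign-assignment enumeration, ties included", {
  set.seed(504)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # many ties, no zeros
    r <- signed_rank_mpd(tibble::tibble(case_value = d, control_value = 0))
    expect_equal(r$p_value, enumerate_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("tie-free exact p agrees with the standard implementation", {
  set.seed(505)
  d <- rnorm(12)
  r <- signed_rank_mpd(tibble::tibble(case_value = d, control_value = 0))
  ref <- stats::wilcox.test(d, exact = TRUE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(r$statistic, unname(ref$statistic))
})

test_that("above the exact limit the tie-corrected normal approximation is used", {
  set.seed(506)
  d <- round(rnorm(40, 0.3), 1)
  d <- d[d != 0]
  r <- signed_rank_mpd(tibble::tibble(case_value = d, control_value = 0))
  expect_equal(r$method, "normal-approximation")
  ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = FALSE))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
})

# ---- trimming ----------------------------------------------------------

test_that("percentile 100 trims nothing; a unique maximum is removed at 90", {
  set.seed(507)
  sets <- simulate_clr_pairs(10, beta = 0.3)
  full <- clr_fit(sets, exposure = "x")
  t100 <- trim_refit(sets, exposure = "x", percentile = 100)
  expect_equal(t100$beta, full$beta)
  expect_equal(t100$trim$n_sets_removed, 0)

  sets$x[1] <- 50  # gross outlier in set P001
  t90 <- trim_refit(sets, exposure = "x", percentile = 90)
  expect_gte(t90$trim$n_sets_removed, 1)
  expect_lt(t90$n_sets, 10)
  expect_error(trim_refit(sets, exposure = "x", percentile = 101), "percentile")
})

test_that("trimming moves the estimate toward the truth when one outlier pair inflates it", {
  set.seed(508)
  beta_true <- 0.5
  wins <- purrr::map_lgl(1:200, function(i) {
    sets <- simulate_clr_pairs(40, beta = beta_true)
    # one gross outlier: a control exposure far beyond the rest drags the
    # estimate toward (and past) the null, since its likelihood term stays
    # ~linear in beta until the estimate chases it
    sets$x[sets$set_id == "P001" & sets$delirium_case == 0] <- 30
    full <- clr_fit(sets, exposure = "x")
    trim <- trim_refit(sets, exposure = "x", percentile = 95)
    abs(trim$beta - beta_true) <= abs(full$beta - beta_true)
  })
  expect_gte(mean(wins), 0.8)
})

# ---- unconditional cohort model ----------------------------------------

test_that("intercept-only fit recovers the closed-form log odds of caseness", {
  co <- tibble::tibble(delirium_case = rep(c(1L, 0L), c(49, 143)))
  fit <- cohort_logistic_fit(co, time_point = NULL, covariates = character(0))
  expect_equal(fit$coefficients$estimate[1], log(49 / 143), tolerance = 1e-8)
})

test_that("a constant exposure has a near-zero coefficient and full covariates fit cleanly", {
  co <- simulate_cohort(cohort_config(seed = 12))
  co$il6_pod2 <- 0
  expect_warning(cohort_logistic_fit(co, "POD2"), "aliased")

  co2 <- simulate_cohort(cohort_config(pod2_effect = 0, seed = 13))
  fit <- cohort_logistic_fit(co2, "POD2")
  row <- dplyr::filter(fit$coefficients, term == "il6_pod2")
  expect_lt(abs(row$statistic), 3)  # null covariate: |z| small
  expect_equal(nrow(fit$coefficients), 9)  # intercept + il6 + 6 factors (surgery = 2 dummies)
})

test_that("perfectly separated data raise an explicit separation error", {
  co <- tibble::tibble(delirium_case = rep(c(1L, 0L), each = 20),
                       il6_pod2 = c(rnorm(20, 100), rnorm(20, 0)))
  expect_error(cohort_logistic_fit(co, "POD2", covariates = character(0)),
               "separation")
})
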