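---
title: "Matched nested case-control studies: design, analysis, and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched nested case-control studies: design, analysis, and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(nccdesign)
library(dplyr)
```

## The setting

A prospective cohort has complete outcome data (postoperative delirium,
assessed in hospital) but the exposure of interest — an inflammatory
biomarker, interleukin-6 (IL-6, pg/ml), measured at up to three blood draws
(preoperative, post-anaesthesia care unit, postoperative day 2) — is
expensive to assay. A nested case-control (NCC) design measures it only in
the cases and a matched subset of controls. Done well, this loses little
efficiency relative to assaying the whole cohort; done carelessly, it can
introduce bias through the match algorithm, the analysis model, or
overmatching. This package implements each step of that workflow together
with the diagnostics that probe its weak points, and a synthetic cohort
generator so the whole chain can be exercised and tested without
subject-level data.

## Matching model

A control is *feasible* for a case when every exact factor (gender, surgery
type, vascular comorbidity, APOE ε4 carriage) is identical and every
calipered continuous factor (age in years, baseline general cognitive
performance (GCP) score) differs by at most its caliper width. The pair
distance is the sum of absolute calipered differences; exact factors
contribute zero by construction, so with two 5-unit calipers every feasible
pair has distance ≤ 10. Caliper comparisons are inclusive with an absolute
tolerance of 1e-9, so a difference of exactly 5.0 is feasible even after
floating-point noise.

`greedy_match()` processes cases sequentially in input order; each takes the
nearest available feasible control (ties broken by the lexicographically
smallest control id), which is then removed from the pool. The processing
order is a documented convention, not a claim about any particular software:
descriptions of greedy matching rarely state it, determinism requires one,
and order sensitivity is precisely the greedy weakness. A global best-first
variant (`order = "best_first"`) is exposed for exploration.

`optimal_match()` solves the lexicographic problem — maximum number of
pairs subject to feasibility, each control used at most once, each case
receiving at most `ratio` controls; then minimum total distance among
matchings of that cardinality. It is encoded as a linear sum assignment:
each case is replicated `ratio` times (variable 1:k matching, so a case
takes two controls when feasible and one otherwise), dummy columns allow a
row to stay unmatched at a penalty P chosen larger than any achievable total
distance (P = W·min(rows, controls) + 1 with W the sum of caliper widths),
and infeasible edges cost 2P so they are never preferred to a dummy. The
solver is a shortest-augmenting-path (Jonker–Volgenant style) algorithm in
C++, exact for this problem class; the test suite verifies it against full
enumeration on hundreds of small instances and against the greedy lower
bound on larger ones. Subjects whose samples are too hemolysed for reliable
assay (`hemolysis_ok = FALSE`) are removed from both pools before matching.

`caliper_sweep()` re-runs both algorithms across a caliper grid; because
widening a caliper only adds feasible edges, pair counts are non-decreasing
in the caliper, and the optimal algorithm's *total* distance can exceed
greedy's whenever it converts the wider caliper into extra pairs — yield
and per-pair quality trade off, which is the point of reporting both.
`balance_table()` summarises the six factors pre- and post-match.

## Two analytic strategies

With delirium as the outcome, `clr_fit()` maximises the conditional
likelihood

$$L(\beta)=\prod_s \frac{\exp(x_{\text{case},s}\,\beta)}
{\sum_{j\in s}\exp(x_{j,s}\,\beta)}$$

over the scalar log odds ratio per pg/ml. Conditioning on the matched sets
removes all set-level nuisance parameters, which is why the match factors
never appear in the model. Sets with constant exposure contribute a constant
factor and are dropped (reported as `n_sets - n_informative_sets`). The
maximiser is Newton–Raphson from β = 0 with step-halving, declaring
convergence when the relative log-likelihood change is below 1e-10 or the
gradient below 1e-8, capped at 100 iterations. Exposures are centred within
set first; this is exactly the within-set location invariance of the
conditional likelihood and keeps the exponentials bounded. Inference is Wald
on the log-odds scale (95% CI = exp(β ± 1.96·SE)); this is the package's
fixed convention, since printed intervals in reports are often not exactly
recoverable from a printed β and SE under any single rule. If the case holds
the extreme exposure in every informative set the likelihood is monotone and
the MLE infinite; `clr_fit()` detects this configuration up front and raises
a separation error rather than returning a silently enormous estimate.

With the biomarker as the outcome, `signed_rank_mpd()` reports the median
paired difference (MPD, pg/ml; median over *all* differences, zeros
included) and the Wilcoxon signed-rank test: zero differences dropped
(Wilcoxon's convention), mid-ranks for ties, exact tie-aware null
distribution (computed by convolution over half-ranks) when at most
`exact_limit = 25` nonzero differences remain, otherwise the normal
approximation with tie correction and no continuity correction. The two
strategies answer different questions — odds of disease per unit of
exposure versus the longitudinal exposure contrast between groups — and the
package keeps both first-class so their inferential agreement can be checked
on any dataset. For a binary exposure the two collapse:
`discordant_pair_or()` computes the discordant-count odds ratio both ways
round (disease-as-outcome and exposure-as-outcome) and the conditional MLE
equals that ratio, an identity the tests verify numerically.

`trim_refit()` probes sensitivity to the right tail: it computes a pooled
percentile of the exposure over all matched subjects (cases and controls
together — the cutoffs in such analyses are typically quoted for the
combined distribution), removes every set containing any member above it,
and refits.

## Cohort comparison by resampling

To ask whether the NCC design reaches the same answer as a full-cohort
analysis, `resample_biomarker()` assigns to *every* eligible subject, at
each time point, a value drawn uniformly with replacement (unrestricted
random sampling) from the measured pool of the matching (time point × case
status) stratum. The measured subjects are reassigned too, so every subject
has the same chance of any pooled value. `cohort_logistic_fit()` then fits
the unconditional multivariable logistic model of delirium on the biomarker
plus all six match factors (surgery type reference-coded against
orthopedic, gender against male, binaries 0/1). The resampling operation
accepts a seed and may be repeated; how many replicates to draw is the
caller's choice (with a small measured pool, replicates are highly
correlated, so a single draw is often deemed sufficient — but that is a
judgement, not a constraint of the implementation).

## Overmatching diagnostic

Matching on factors associated with the *exposure* compresses the
within-pair exposure contrast and biases the conditional estimate toward
the null. `overmatch_assess()` quantifies the risk: in the controls only
(their biomarker is unaffected by the outcome), an ordinary linear model of
the biomarker on the six match factors. The model R² measures how much
exposure variance the joint match-factor distribution explains;
`r_from_r2()` converts it to the correlation scale (r = √R²). The per-factor
"partial R²" components are sequential (Type I) sums of squares divided by
the total sum of squares, in a caller-specified entry order: this is the
decomposition under which the components sum *exactly* to the model R²
(an identity the tests check to machine precision), at the cost of
order-dependence — which is why `factor_order` is an explicit argument
rather than a hidden default. Categorical factors enter as indicator blocks
whose block SS is attributed to the factor. Permuting the order
redistributes components but never changes their sum.

## The synthetic cohort generator

`cohort_config()` defaults encode the study conditions the analyses assume:
49 delirium cases and 143 eligible controls; case marginals age 77.2 ± 4.9
years, GCP 54.2 ± 5.9, 55% female, 86% orthopedic, 45% vascular
comorbidity, 18% APOE ε4; control marginals 76.3 ± 4.8, 58.9 ± 6.6, 57%,
85%, 29%, 24%. Two generator choices are deliberately arbitrary and flagged
as such: the non-orthopedic surgery mass is split equally between vascular
and gastrointestinal (only the orthopedic percentage is commonly reported),
and the PREOP/PACU biomarker strata (mean 6 ± 5 and 40 ± 30 pg/ml) are
physiologically plausible placeholders with no case effect, since only the
POD2 distribution is pinned down. IL-6 is log-normal per
(time point × status) — right-skewed and strictly positive, as biomarker
concentrations are — with location/scale solved from the target mean/SD.
The POD2 control stratum (84.4 ± 55) with the default multiplicative case
effect of 0.6 (cases ×1.6) makes the pooled 39:39 matched sample
approximate the reference summary mean ≈ 110, SD ≈ 80 pg/ml.

What the generator does *not* emulate: within-subject longitudinal
correlation of the biomarker across time points; correlation among match
factors (independent by default, though an age–GCP correlation can be
supplied); assay measurement error; and truncation of age at the cohort's
eligibility threshold of 70 (a plain normal keeps the configured marginals
exact, which the marginal-recovery tests rely on). Consequently, passing
tests demonstrate correctness of the algorithms and estimators under the
stated statistical structure — not that any real cohort has that structure.
In particular, because the default generator draws the biomarker
independently of the match factors, its overmatching R² is small by
construction; a real cohort can show R² of 20% or more, and the diagnostic
exists precisely to measure that.

## Numerical and testing choices

* Determinism: every stochastic operation takes a seed; `run_pipeline()`
  derives one sub-seed per stage from a single root seed via a seeded
  integer draw, and stamps every output file with a manifest header.
* Degenerate inputs are contracts, not crashes: empty case/control pools
  give empty match results; an all-zero difference set gives MPD 0 with
  p = 1 flagged degenerate; empty post-match strata give `NA` balance
  cells; a constant covariate in the unconditional model is dropped with a
  warning; flat conditional likelihoods, separation, rank deficiency and
  zero outcome variance raise named errors.
* Reported decimals use round-half-away-from-zero (`round_half_away()`),
  the convention of printed statistical tables, rather than banker's
  rounding.
* Problem sizes in the test suite were chosen to make each property
  decisive at desk scale: exhaustive matching oracles on 500 instances up
  to 6×6, greedy-dominance fuzz on 1,000 instances up to 50×150, signed-rank
  enumeration up to n = 12, 500-replicate coverage studies at 39 pairs
  (matched) and n = 192 (cohort), and a null overmatching simulation at
  n = 10,000.
* The cohort-model recovery simulation runs at a moderate scaled effect
  (exposure N(100, 20), β = 0.015, ~26% case fraction). At strong scaled
  effects (β·SD(x) near 1) the logistic MLE's well-known O(1/n) small-sample
  bias is of the same order as the Monte-Carlo resolution of a 500-replicate
  mean, so an unbiasedness check there would measure that bias, not
  implementation correctness; confidence-interval coverage is asserted
  separately and holds in both regimes.

## A compact run

```{r example, eval = FALSE}
cohort   <- simulate_cohort(cohort_config(seed = 2025))
cases    <- filter(cohort, delirium_case == 1)
controls <- filter(cohort, delirium_case == 0)

m    <- optimal_match(cases, controls, match_criteria())
fit  <- clr_fit(match_sets(m, cohort), time_point = "POD2")
mpd  <- signed_rank_mpd(paired_values(m, cohort, "POD2"))
over <- overmatch_assess(controls)

glance(m); tidy(fit); tidy(mpd); glance(over)
autoplot(caliper_sweep(cases, controls, caliper_values = 1:5))
```

## Limitations

Conditional likelihoods are implemented for one case per set and a single
scalar exposure (the design under study); multi-case sets, robust/sandwich
variances and Firth-type separation corrections are out of scope —
separation is detected and reported, never silently corrected. The MPD
strategy treats pairs as independent, which a 1:k design violates when a
case contributes multiple pairs; the pairing helper documents this and the
conditional model is the appropriate tool there. Propensity-score matching
is intentionally absent: with four factors requiring exact agreement it
cannot guarantee feasibility, which is why algorithmic matching is used
instead.
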