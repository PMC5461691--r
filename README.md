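# nccdesign

Design and analysis of **matched nested case-control (NCC) studies**, built
around the setting in which an expensive exposure — an inflammatory biomarker
such as interleukin-6 (IL-6, pg/ml) — can only be assayed for a subset of a
prospective cohort. Cases (here: older surgical patients who develop
postoperative delirium) are matched to controls on potential confounders, and
the biomarker is measured only in the matched subset. The package is aimed at
biostatisticians and epidemiologists planning or analysing such designs, and
at methodologists who want to compare design choices on synthetic cohorts.

It covers the full workflow:

* **Matching.** Exact matching on categorical factors (gender, surgery type,
  vascular comorbidity, APOE ε4) combined with calipers on continuous factors
  (age, baseline general cognitive performance). Two algorithms:
  * *greedy* — each case takes the nearest available feasible control, never
    revisiting a decision;
  * *optimal* — a minimum-cost bipartite assignment with a lexicographic
    objective (maximum number of pairs, then minimum total distance), solved
    by a shortest-augmenting-path solver, so earlier pairings can be
    "uncoupled" when that admits more matches.
  Both support variable 1:k ratios, plus caliper-sweep and covariate-balance
  diagnostics.
* **Analysis.** The two rival strategies for a matched sample: conditional
  logistic regression of case status on the biomarker (odds ratio per pg/ml,
  eliminating set-level nuisance parameters by conditioning), and the median
  paired difference (MPD) tested with the Wilcoxon signed-rank test; plus
  percentile-trimmed sensitivity refits and the discordant-pair odds ratio
  identity for binary exposures.
* **Cohort comparison.** Unrestricted random sampling (URS, with replacement,
  stratified by time point × case status) extends the measured biomarker to
  the full eligible cohort so an unconditional multivariable logistic
  regression can be compared against the matched analysis.
* **Overmatching diagnostic.** A controls-only linear model of the biomarker
  on the six match factors; the model R² is decomposed into sequential
  (Type I) partial R² components that sum exactly to the model R², with the
  conversion r = √R² onto the correlation scale.
* **Synthetic cohorts.** A calibrated generator (49 cases / 143 controls by
  default, with the match-factor marginals and POD2 biomarker summary of an
  older-adult elective-surgery cohort) so every analysis is reproducible
  without subject-level data.

## The model in brief

For matched sets *s* with case exposure x<sub>case,s</sub>, the conditional
likelihood maximised by `clr_fit()` is

L(β) = ∏<sub>s</sub> exp(x<sub>case,s</sub> β) / Σ<sub>j∈s</sub> exp(x<sub>j,s</sub> β),

giving the log odds ratio β per pg/ml. The MPD strategy instead reports
median(x<sub>case</sub> − x<sub>control</sub>) with an exact tie-aware
signed-rank null for ≤ 25 nonzero differences. Matching feasibility requires
identical exact factors and |difference| ≤ caliper on each continuous factor;
the pair distance is the sum of absolute calipered differences.

## Worked example

```r
library(nccdesign)
library(dplyr)

cohort   <- simulate_cohort(cohort_config(seed = 2025))
cases    <- filter(cohort, delirium_case == 1)
controls <- filter(cohort, delirium_case == 0)

m <- optimal_match(cases, controls, match_criteria())
m
#> Matched nested case-control set (optimal algorithm, 1:1)
#>   pairs: 36   cases matched: 36   unmatched cases: 13
#>   sum distance: 134.1   mean distance: 3.726

glance(greedy_match(cases, controls, match_criteria()))
#> 1 greedy        1      33            33          3.34         110.
```

The optimal algorithm matches 36 of 49 cases where greedy stops at 33 — the
uncoupling advantage. The two analytic strategies on the matched sample:

```r
clr_fit(match_sets(m, cohort), time_point = "POD2")
#> Conditional logistic fit (POD2, exposure il6_pod2)
#>   beta = 0.01117 (SE 0.004779), z = 2.338, p = 0.01939
#>   OR per unit = 1.011 (95% CI 1.002-1.021)

signed_rank_mpd(paired_values(m, cohort, "POD2"))
#> Median paired difference (case - control), signed-rank test
#>   MPD = 28.25 over 36 pairs (36 nonzero differences)
#>   W+ = 499, two-sided p = 0.009108 (normal-approximation)
```

Both read the same way: on postoperative day 2 the biomarker is associated
with delirium — a ~1.1% increase in the odds per pg/ml, or a median
case-minus-control difference of ~28 pg/ml. The overmatching check on the
controls:

```r
overmatch_assess(controls)
#> Overmatching diagnostic (controls-only linear model of the biomarker)
#>  time_point model_r2_pct equivalent_r n_controls
#>       PREOP         3.66        0.191        143
#>        PACU         7.07        0.266        143
#>        POD2        10.65        0.326        143
```

Small per-factor components (see `tidy()` on the result) indicate matching
did not absorb much exposure variance. `run_pipeline()` executes the whole
workflow and writes every table with a seed-stamped manifest;
`inst/scripts/ncc` exposes the same steps as shell subcommands
(`simulate`, `match`, `sweep`, `analyze`, `cohort-analyze`, `overmatch`,
`report`).

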