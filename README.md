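# attritionr

Tools for analyzing **dropout attrition** in item-level survey response
data — participants who start a questionnaire but stop answering before the
end. Reporting a single completion rate hides where attrition happens,
whether the apparent cliffs are statistically real, and who drops out.
`attritionr` implements a three-stage framework for survey methodologists
and health-services researchers working with web-based instruments:

1. **Visualize** — per-item respondent/dropout bar charts (skip-aware
   stacked and group-stratified variants) and survival-type step curves,
   with a reproducible heuristic segmentation into Eysenbach's curiosity /
   attrition / stable-participation phases.
2. **Confirm** — for each pair of sequential items, a random-intercept
   logistic model
   `logit P(y_ik = 1 | u_i) = β₀ + β₁·1[k = 2] + u_i`, `u_i ~ N(0, σ_u²)`,
   fit by adaptive Gauss–Hermite quadrature. The subject-level random
   intercept accounts for the within-subject dependence that earlier
   attrition induces. Logit-scale estimates transform to a difference in
   response proportions `Δ = expit(β₀) − expit(β₀+β₁)` with a multivariate
   delta-method standard error and 95% CI.
3. **Identify factors** — chi-square/Fisher contingency tests of prior-item
   responses and subject attributes against next-item dropout;
   completer-vs-noncompleter outcome comparisons; and, on the discrete
   dropout times (completers censored after the final item), the log-rank
   test and Cox proportional-hazards regression (Efron ties,
   time-interaction PH check, screening-then-adjustment workflow).

A synthetic questionnaire-response generator with known ground truth —
discrete per-boundary dropout hazards, subject-level frailty on the logit
hazard, sporadic independent skips, group and covariate effects, a
completion-linked binary outcome — makes every stage testable without
access to study data. See `vignette source in vignettes/attrition-analysis.Rmd`
for the model details, tunable parameters, and limitations.

## Worked example

Simulate a realistic cohort — three cancer-screening cohorts of 638, 1249
and 468 starters answering 12 items, with hazards calibrated so the pooled
respondent curve falls from 100% to about 42% — then run all three stages:

```r
library(attritionr)

cfg <- sim_preset("paper_like", seed = 42)
sim <- simulate_survey(cfg)

at <- summarize_attrition(sim$responses)
estimate_phases(at)
#> Attrition phase segmentation (heuristic, threshold = 0.05 incremental dropout/item)
#>   curiosity plateau: items 1-2
#>   attrition phase:   items 3-4
#>   stable phase:      items 5+ at 48.0% participation

scan <- sequential_attrition_scan(sim$responses)
scan$table[1:6, c("pair", "p1", "p2", "diff", "se", "p_value", "significant")]
#>              pair    p1    p2     diff       se  p_value significant
#>  item_1 to item_2 1.000 0.975  0.02460 0.003240 7.77e-01       FALSE
#>  item_2 to item_3 1.000 0.980  0.02040 0.001160 1.31e-59        TRUE
#>  item_3 to item_4 0.999 0.857  0.14300 0.034100 5.92e-30        TRUE
#>  item_4 to item_5 0.914 0.593  0.32100 0.066700 9.21e-15        TRUE
#>  item_5 to item_6 0.586 0.857 -0.27100 0.059500 6.08e-09        TRUE
#>  item_6 to item_7 1.000 0.997  0.00283 0.000456 1.16e-16        TRUE
```

Reading the scan: `p1`/`p2` are subject-specific (random effect = 0)
response proportions; the big attrition cliffs land at items 3–5 and the
*negative* difference at the item 5 → 6 pair reflects the skip-induced rise
in respondents (some subjects skip item 5 and return at item 6) — a real
feature of skip-permitting surveys, not an error. The first pair, where
item 1 was answered by everyone, is quasi-separated: the fit is flagged and
its wide, unstable interval reported as-is. Significance tests are Wald
tests of the logit-scale item effect, so a pair can have a tiny absolute
difference yet a real, well-supported drop (items 6–7).

```r
sd <- build_survival_data(sim$responses, sim$covariates)
logrank_test(sd, "group")
#> Log-rank test on dropout times by 'group'
#>       group observed expected
#>      breast      406   340.29
#>  colorectal      704   719.78
#>    prostate      233   282.94
#>   chi-square = 26.7934, df = 2, p = 1.52e-06

completer_outcome_test(sim$responses, sim$covariates, "screened")
#> Contingency analysis (chi-square)
#>               outcome
#> completion     0             1
#>   completer    770 (76.09%)  242 (23.91%)
#>   noncompleter 1095 (81.53%) 248 (18.47%)
#>   X-squared = 10.3914, df = 1, p = 0.001266 (min expected 210.56)
```

The breast-cancer cohort drops out most (406 observed vs 340 expected
dropouts), the prostate cohort least — the group effects built into the
preset — and survey completers obtained their screening test more often
than noncompleters (23.9% vs 18.5%).

## Command line

The same pipeline is scriptable; the wrapper installs under
`system.file("cli", "attritionr", package = "attritionr")`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","attritionr",package="attritionr"))')
Rscript "$CLI" simulate --preset paper_like --seed 42 --out data/
Rscript "$CLI" report --preset paper_like --seed 42 --out report/
Rscript "$CLI" scan --input data/responses.csv --alpha 0.05 --out scan/
```

`report` runs visualize → confirm → identify in one pass, writing every
table as CSV, every figure with its coordinate table, and a machine-readable
run manifest (options, package version, input checksums). Errors exit
nonzero with a one-line class-tagged diagnostic on stderr.

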