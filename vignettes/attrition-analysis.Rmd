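---
title: "Analyzing dropout attrition in item-level survey data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing dropout attrition in item-level survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attritionr)
```

## The problem

Web-based surveys recruit cheaply and widely, but participants who *start* a
survey frequently stop answering partway through — **dropout attrition**, as
opposed to nonresponse attrition (never starting, which this package does not
address). Dropout is usually reported as a single completion rate, which hides
*where* it happens, *whether* the apparent cliffs are statistically real, and
*who* drops out. `attritionr` implements a three-stage workflow for item-level
response indicators:

1. **Visualize** — per-item respondent/dropout bar charts (skip-aware and
   group-stratified variants) and survival-type step curves;
2. **Confirm** — a random-intercept logistic model fit to each pair of
   sequential items, transformed to a difference in response proportions with
   a delta-method standard error;
3. **Identify factors** — contingency tests of responses and attributes
   against next-item dropout, plus log-rank and Cox proportional-hazards
   comparisons of whole attrition trajectories, treating completers as
   censored after the final item.

Because item-level survey datasets of this kind are rarely shareable, the
package ships a synthetic generator with known ground truth
(`simulate_survey()`); every stage is tested against it.

## Data model: answered, skipped, dropped

The input is a subjects × items binary matrix of answered indicators
(`response_matrix()`, loaded from wide or long delimited text by
`load_responses()`). Items are indexed by their position in the *analyzed*
sequence; conditional or branched items should be excluded by the caller
beforehand, with original question labels preserved as item labels. Subjects
who answered nothing never started and are excluded at load time with a
logged count.

Every not-answered cell is then classified (`classify_cells()`):

* `last_answered(i)` — position of subject *i*'s last answered item;
* `dropout_point(i) = last_answered(i) + 1` (exceeding the item count for
  completers);
* a not-answered cell *before* `last_answered` is a **skip** (the subject
  returned later); every cell at or after `dropout_point` is **dropped**.

A subject who answered earlier items but skipped the final one is
indistinguishable from a dropout at `last_answered + 1`. This trailing-skip
ambiguity is intrinsic to indicator-only data; rather than pretending it
away, `trailing_skip_misclassification_rate()` quantifies it under any
simulation configuration (at a constant 5% skip probability and 10% hazard it
stays well below the skip probability itself, and it grows monotonically
with the skip rate).

## Stage 1: summaries and phases

`summarize_attrition()` tabulates per item: respondents, skips, incremental
dropouts (subjects whose dropout point is that item) and cumulative dropouts,
as counts and percentages. The percentage denominator is the starter count
(so item 1 plots at ~100% and the three states sum to 100% at every item);
group-stratified tables use group-specific starter counts so unequal cohorts
are comparable. Percentages are reported to 2 decimals.

`estimate_phases()` segments the curve into the three phases of Eysenbach's
sigmoidal attrition pattern — curiosity plateau, attrition phase, stable
participation. The rule is deliberately simple and labeled a heuristic: the
attrition phase starts at the first item whose incremental dropout proportion
exceeds a threshold (default 0.05 of starters per item, chosen so that a
survey losing 5% of its audience at a single item counts as an attrition
point) and extends through the maximal run above threshold, tolerating
single-item gaps so one quiet item inside a cliff does not split the phase.
No formal changepoint inference is attempted; the threshold is a tunable
lens, not an estimator.

## Stage 2: the pairwise mixed model

For items $q$ and $q'$ in sequence, every starter contributes two binary
observations ($y_{i1}$ = answered $q$, $y_{i2}$ = answered $q'$) to

$$\operatorname{logit} P(y_{ik}=1 \mid u_i) = \beta_0 + \beta_1 \mathbf{1}[k=2] + u_i,
\qquad u_i \sim N(0, \sigma_u^2),$$

where the subject-level random intercept absorbs the strong within-subject
dependence that earlier attrition induces (a plain chi-square comparison of
the two proportions would ignore it). The likelihood is maximized by
adaptive Gauss–Hermite quadrature (default 25 nodes, mode-centered per
response pattern). Since the pair model has only four response patterns, the
likelihood collapses onto pattern counts, so a fit costs the same at
$n = 100$ as at $n = 100{,}000$ — which is what makes the replication studies
in the test suite affordable.

Estimates transform to the proportion scale as $p_1 = \text{expit}(\beta_0)$,
$p_2 = \text{expit}(\beta_0+\beta_1)$, with
$\widehat{\Delta} = p_1 - p_2$ and a multivariate delta-method standard
error using the gradient $(p_1(1-p_1) - p_2(1-p_2),\, -p_2(1-p_2))$
(`delta_method_difference()`). Numerical choices worth knowing:

* **Conditional vs marginal scale.** $p_1, p_2$ are subject-specific
  ($u = 0$) proportions — the direct transform of the fixed effects. When
  $\sigma_u$ is large these are more extreme than the raw marginal
  fractions; `marginal_pair_proportions()` provides the population-averaged
  alternative by integrating the expit over the fitted frailty.
* **P-values** are Wald tests of $\beta_1 = 0$ on the logit scale with a
  normal reference. Mixed-model software often uses $t$ references with
  estimated degrees of freedom, but DF methods differ between
  implementations; with thousands of subjects the distinction is immaterial
  and the normal reference is documented and deterministic.
* **Quasi-separation.** When an item was answered by everyone, the
  likelihood drifts along $\beta_0$; estimates are capped at ±15 on the logit
  scale (expit(15) ≈ 1 to 7 decimals), a `separation_warning` is set, and
  the resulting wide interval is reported as-is — deliberately *not* clipped
  to $[-1, 1]$, so an unstable first-item comparison is visibly unstable. A
  Firth-type Jeffreys penalty is available behind `firth = TRUE` for users
  who prefer interior estimates.
* **Boundary $\sigma_u$.** $\log\sigma_u$ is optimized within
  $[\log 10^{-4}, \log 25]$; estimates below $10^{-3}$ set a
  `sigma_boundary` flag. Covariances come from the observed information with
  eigenvalues floored at a relative $10^{-10}$, so flat directions yield
  huge-but-positive variances instead of failures.
* **Determinism.** Fixed starting values (marginal logits, $\sigma = 0.5$)
  and an L-BFGS-B tolerance of ~$10^{-9}$ relative log-likelihood.

`sequential_attrition_scan()` applies the fit to every adjacent pair, flags
$p < \alpha$ (no multiplicity adjustment by default, mirroring the
one-pair-at-a-time reporting convention of this literature; Bonferroni/Holm
behind a switch), and reports failed pairs with `converged = FALSE` instead
of aborting.

## Stage 3: factors

`response_vs_next_dropout()` cross-tabulates the response category given at
item $q$ against answering item $q'$, testing independence with Pearson's
chi-square (no continuity correction by default, appropriate to the
large-sample setting; Yates behind a flag) or Fisher's exact test whenever
any expected count falls below 5. "Dropout at the next question" is
operationalized as *not answering* $q'$ — skippers count as "No", exactly as
a respondent-count analysis would see them.
`completer_outcome_test()` runs the analogous 2×2 comparison of a binary
downstream outcome between completers and noncompleters.

`build_survival_data()` recodes classification into discrete survival form:
event = dropout at `time = dropout_point` (values 2…items), completers
censored at the final item. `logrank_test()` (with per-group product-limit
curves for plotting) and `cox_fit()` (Newton–Raphson on the partial
likelihood) are implemented in-package and verified, in the test suite,
against the `survival` package to $10^{-4}$ on twenty random datasets, plus
hand-worked toy values. Efron tie handling is the default because
item-indexed times make ties massive; Breslow exists for parity checks. The
proportional-hazards assumption is checked per covariate by a Wald test on a
`covariate × log(time)` interaction added one at a time (`ph_check`);
residual-based diagnostics are out of scope. `screen_then_adjust()` wraps
the conventional epidemiological sequence — bivariate screening at
$\alpha$, then a multivariate model with exposure × covariate interactions —
labeling significant interactions "effect modification" and significant main
effects "confounding candidates" (labels, not causal claims).

## The simulator and what it does (not) emulate

`simulation_config()` fixes: per-group sizes, item count, a per-boundary
dropout hazard vector $h_j$, a frailty SD on the logit hazard, per-item skip
probabilities, group/covariate logit-hazard shifts, and an optional
completion-linked binary outcome. Dropout is discrete (only at item
boundaries), skips are independent given activity, and the frailty enters
the continuation logit — the same place the pairwise model puts its random
intercept, so parameter-recovery tests are well posed. Each subject draws
from an own pseudorandom stream derived from the master seed: output is
bit-identical under a fixed seed and enlarging the sample never perturbs
existing subjects.

With all shifts zero the marginal respondent proportion at item $q$ is
$(1-s_q)\prod_{j<q}(1-h_j)$; `expected_attrition()` generalizes this closed
form to the full mixture (groups × categorical covariate combinations ×
Gauss–Hermite integration over the normal frailty-plus-numeric-covariate
shift), and the suite checks simulations against it within 3 binomial SE.

The `paper_like` preset encodes the study conditions the package is designed
around: 3 cohorts of 638/1249/468 (2355 starters), 12 analyzed items, and a
pooled respondent curve equal to
`paper_like_targets()` = (1.00, 0.97, 0.76, 0.56, 0.52, 0.54, …, 0.42) —
steep early attrition settling near 42%. Hazards are calibrated by
sequential root-finding so the *pooled marginal* curve (mixing groups,
frailty SD 1, covariate effects) hits those targets exactly; the single
non-monotone entry (0.52 → 0.54) forces a ~3.7% skip probability at item 5
via the smallest non-increasing survival envelope. Effect sizes the design
leaves open were chosen once as modest, realistic values and not revisited:
cohort shifts ±0.25 on the logit hazard (highest attrition in the smallest
cohort, lowest in the reference-population one), +0.15 for one gender, up to
+0.15 across recruitment phases, and screening-outcome rates of 22.37% /
17.42% for completers / noncompleters. The `cliff` preset (one group of
3000, 6 items, hazard 0.25 between items 2 and 3 against 0.01 elsewhere)
drives detection-power checks; `null` (two equal groups, constant hazard)
drives size checks.

What the generator does **not** emulate: informative skipping (skips are
independent of the frailty), non-monotone re-engagement beyond skips,
item-content effects, paradata/timing, or dependence between the outcome and
covariates given completion. Passing tests therefore demonstrate correctness
of the machinery under a clean, known mechanism — not that real surveys obey
that mechanism. One consequence is visible in the scan: simulated dropout
is almost perfectly monotone, so within-subject dependence is near-perfect
and the paired test flags even 1–2-point true drops at $n \approx 2355$;
real data with pervasive skipping yield noisier, less significant small
differences.

## Problem sizes used in the checks

The replication studies in the test suite use 1000 null replicates at
$n = 1000$ for type-I error (observed rate must lie in $[0.03, 0.07]$), 200
cliff replicates for detection power (≥ 95%), 60 + 60 replicates for
log-rank power/size, and single $n = 5000$–$10{,}000$ datasets for
parameter-recovery and closed-form calibration checks — sizes at which a
3-SE criterion is meaningful while the whole suite stays fast, thanks to the
pattern-collapsed likelihood.

## Known limitations

* The pairwise model analyzes two items at a time; a single whole-survey
  mixed model with structured dependence, and discrete-time survival
  regression, are out of scope.
* Phase segmentation is a visual heuristic made reproducible, not an
  inference procedure.
* The Cox model here has no time-varying covariates or frailty terms; the
  PH check is a time-interaction Wald test only.
* Counts behind published-style percentage-only tables cannot be recovered,
  so such tables can only be reproduced at the percentage level.
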