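---
title: "Methods: weighted survey aggregation and SMART multi-criteria evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted survey aggregation and SMART multi-criteria evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resilmcda)
```

# The problem

After the COVID-19 emergency, health-system planners faced a concrete
question: of several candidate strategies for making a national healthcare
system more resilient — rapid emergency-regime fixes, medium-term
reorganization, or long-term structural prioritization — which one should be
selected, given what frontline healthcare professionals experienced and
reported? `resilmcda` implements a two-stage answer:

1. **Stage 1 — survey aggregation.** Likert-scale questionnaire responses
   from healthcare professionals are aggregated into per-item summaries
   under *differentiated respondent weights*: answers from more qualified,
   more experienced and more pandemic-exposed respondents count for more.
   The summaries surface the salient risks and opportunities (staff
   overload, underfunding, access of vulnerable groups, telemedicine, legal
   gaps).
2. **Stage 2 — SMART evaluation.** The risks/opportunities are grouped into
   four criterion dimensions, weighted with the Simple Multi-Attribute
   Rating Technique, and three strategies are scored through a rank-based
   performance matrix and the linear additive utility
   $U_j = \sum_k w_k\, u_{jk}$. The maximizer is the recommended strategy.

Because the underlying questionnaire data are not publicly deposited, the
package ships a synthetic-survey generator that emulates the published
study conditions; stage 1 is therefore validated by structural properties
and planted-parameter recovery, while stage 2 — whose inputs are fully
published — is reproduced exactly.

# Stage 1: weighted aggregation

## Respondent weights

Three demographic/behavioral fields carry weight coefficients:

| field | categories (low to high) | coefficients |
|---|---|---|
| education level | health assistant … PhD/academic | 1, 1.5, 2, 2.5, 3, 3.5 |
| years in specialty | 0–4 … 20+ | 1, 1.5, 2, 2.5, 3 |
| pandemic role | not involved … COVID support hospital/ER/ambulance | 1, 1.5, 2, 2.5, 3 |

The source scheme assigns the three coefficients but never states how they
combine into one per-respondent weight. We default to the **arithmetic
mean**: it keeps the composite on the same 1–3.5 scale as its inputs, so no
respondent can outweigh another by more than a factor 3.5, whereas the
product scheme would allow a factor of 31.5. `product` and `sum` remain
available via `composite_weight(..., scheme =)`; all stage-1 statistics are
invariant to rescaling the composite weights, so `sum` and `mean` give
identical summaries and only `product` genuinely changes the aggregation.
Unmapped categories are a hard load error rather than a silent weight of 1,
which would quietly flatten the scheme.

## Item summaries

For item $q$ with responses $x_i$ and composite weights $w_i$ over the
non-missing respondents:

- weighted mean $\bar{x}_w = \sum w_i x_i / \sum w_i$ and *weighted index*
  $= \bar{x}_w / \text{scale}_{\max} \times 100$, a percentage that is
  comparable across items measured on 1–5 and 1–6 scales;
- *preferred response*: the scale point with the greatest total weight
  (weighted mode), with its weight share reported as a percentage;
- dispersion: weighted **population** standard deviation (denominator
  $\sum w_i$), chosen because it is exactly invariant to weight rescaling
  and equals the plain population SD of the replicated sample under integer
  weights — the property the test suite exploits;
- quartiles: **type-1** (left-continuous inverse CDF) weighted quantiles,
  which always return an observed scale point on a discrete scale — no
  interpolated values like 4.37 on a Likert item.

Missing answers are excluded item-wise (listwise per item), matching how
per-question nonresponse fractions are conventionally reported;
`n_responses + n_missing` always equals the respondent count. Modal ties
break toward the *lower* scale point and are flagged, so "strong agreement"
is never overstated by a tie-break; item-ranking ties break
lexicographically by item id and are flagged too.

The published study reports per-item "weight index values" around 15–16
whose defining formula is not stated and whose raw inputs are unavailable;
those printed values are treated as observations, not reproduction targets.
The index defined above is this package's own, fully specified statistic.
Stage 1 is therefore accepted by properties: invariance to respondent and
item permutation, invariance to positive rescaling of all weights,
agreement with the replicated-respondent oracle for integer weights
(respondent $i$ repeated $w_i$ times), and recovery of planted modal
responses on synthetic surveys.

## Criteria extraction

`extract_criteria()` makes the narrative link between the survey and the
decision model explicit and auditable: a configuration maps each decision
attribute to the survey items that evidence it, and the attribute's
salience is the mean weighted index of its source items. The packaged
mapping ties, for example, the staff-overload block to the
personnel-shortage attribute and the telemedicine items to the
alternative-solutions attribute.

# Stage 2: the SMART decision core

## Model

Four criterion dimensions carry weights normalized from SMART importance
scores in [10, 100] ($w_k = s_k / \sum s$); the packaged model uses scores
(70, 60, 40, 30), i.e. weights **(0.35, 0.30, 0.20, 0.15)** over budget
allocation, healthcare service planning, human-resource management and the
legal framework. Seven attributes nest in the dimensions (four under
service planning, one under each of the others). Three strategies — S1
emergency-regime prioritization, S2 medium-term solutions, S3 long-term
prioritization — assign each attribute an importance rank under a common
**rank budget of 14** per strategy, which forces prioritization instead of
rating everything maximal; the budget is validated with an error naming any
offending strategy.

Scoring is linear throughout: an attribute contributes
$\text{rank} \times w_k$, a dimension scores the sum of its attributes
($u_{jk}$), the performance total is $\sum_k u_{jk}$, and the utility is
$U_j = \sum_k w_k u_{jk}$. With the packaged configuration:

```{r}
res <- smart_evaluate(resilience_decision_model())
res
```

The totals (3.70, 3.80, 3.90) and utilities (1.04, 1.09, 1.14) match the
published decision analysis to the printed precision, and S3 — long-term
prioritization — is optimal.

Two reconciliations were needed in transcribing the published
configuration, both recorded in the packaged model file:

- the source tables label the two single-attribute dimensions with weights
  0.35 and 0.20 inconsistently (budget allocation vs human-resource
  management swap between tables). The model is keyed by the numeric weight
  vector in performance-matrix row order, which is consistent everywhere;
  both label variants are carried (`label` / `alt_label`). The ranks of the
  two dimensions are identical within each strategy, so the numbers are
  unaffected under either labeling.
- two printed per-cell values conflict with both $\text{rank} \times w_k$
  and their own printed column totals; the formula wins, which uniquely
  reproduces every printed total and utility.

A per-strategy "total ranking" column (strategy rank × a common 0.35
coefficient, giving 0.35/0.70/1.05) is computed by `rank_alternatives()`
and carried as metadata; it does not enter $U_j$.

Exact utility ties are broken toward the lowest strategy id with an
explicit tie flag; floating-point comparisons use an absolute tolerance of
$10^{-9}$ (u-values here are sums of at most seven products of small
rationals, so anything closer is a true tie up to representation).

## Sensitivity

The additive model's standard companion check asks how robust the
recommendation is to the elicited weights. `sensitivity_analysis()`
perturbs one dimension weight at a time by $\pm\delta$ over a grid,
renormalizes the remaining weights proportionally (preserving their
relative importance), **re-scores the model from its ranks** (dimension
scores themselves depend on $w_k$, so rescaling stored utilities would be
wrong), and reports the smallest $\delta$ per dimension that flips the
optimum. Perturbations that would push any weight out of $(0,1)$ are
skipped and noted. On the packaged model the recommendation flips when the
service-planning weight shifts by 0.05 (S1 leads that dimension), while no
feasible perturbation of the human-resources weight reverses it — useful
honesty about how much the elicited weights matter.

## Properties under test

Beyond the exact reproduction above, the decision core is tested against an
independent loop-based oracle (exhaustive over all rank assignments for
model shapes with at most eight rank cells, ranks in {1, 2, 3}, plus 2,000
fixed-seed draws from the 3-strategy × 4-attribute space, whose full
enumeration at 531,441 cases would buy no additional coverage per cost);
monotonicity (raising any rank strictly raises that strategy's utility and
never lowers its rank position); dominance; and the constant-shift identity
$U_j(u + c) = U_j(u) + c$ implied by $\sum_k w_k = 1$.

# The synthetic survey generator

The generator exists so the stage-1 machinery and the end-to-end pipeline
are testable against a known ground truth. It emulates the published study
conditions: **412 respondents**, demographic marginals from the published
participant table, and the published 8 + 9 + 5 question blocks (risk
factors for professional practice on 1–6 scales; patient-access items and
the solutions/feedback block on 1–5 scales) with the printed preferred
responses as planted modes.

Responses follow a **discretized Laplace kernel**:
$P(x) \propto \exp(-|x - \text{mode}| \cdot c)$ over the scale points. One
concentration parameter $c$ spans the observed regimes — $c \to \infty$
reproduces the near-degenerate patterns (interquartile range collapsed on
one point) seen on strongly agreed items, $c \to 0$ approaches uniform. The
default $c = 2$ puts roughly 74% of the mass on the planted mode of an
interior-mode 1–5 item, comparable to the stronger published agreement
shares, and recovers every planted mode with 412 respondents in ≥ 99% of
seeds. Missingness is independent per cell at a default 5%, within the
published per-question nonresponse range.

Default choices the published material does not pin down, made once:

- the participant table's profession counts sum to 416, not 412; the
  probabilities are renormalized;
- education is published in three coarse bands but the weighting scheme
  needs six levels: each band is split evenly over its levels
  (pre-university → the two assistant levels, university → residents,
  post-university → specialist/primary/PhD evenly);
- experience bands are not published; the default (0.08, 0.18, 0.28, 0.26,
  0.20) over 0–4 … 20+ years is a mid-career profile consistent with the
  reported age distribution (40.8 ± 8.4 years);
- demographic fields are sampled independently — only marginals are
  published, so no joint structure (e.g. education × experience
  correlation) is emulated.

What passing tests on these data do **not** show: anything about the real
response distributions beyond their modal structure (real Likert data are
often skewed or bimodal where the kernel is symmetric and unimodal), about
correlated missingness (real nonresponse concentrated in the telemedicine
block), or about joint demographic structure. The synthetic data validate
the *machinery* — weighting, aggregation, ranking, recovery — not the
published stage-1 point estimates, which are not reproducible without the
raw data.

# Pipeline, determinism and problem sizes

`run_pipeline()` orchestrates simulate → stage 1 → criteria → SMART →
sensitivity. Configuration validation is all-or-nothing before any
computation (dangling attribute→item references, unknown sections and bad
schemes abort with the faulty path named), and all computation completes
before any file is written, so a failing run leaves no partial outputs.
With a fixed seed the full run is byte-identical across repetitions; the
run manifest records the package version, seed and a config hash rather
than wall-clock time for exactly that reason. A stage-2-only mode
(`decision` section without `survey`) evaluates a decision model directly —
the mode in which the published configuration is exactly reproducible —
because the published stage-1 → stage-2 linkage is narrative rather than
algorithmic; the criteria mapping is what makes that linkage explicit.

Test problem sizes were chosen to exercise every property at desk scale:
property sweeps use matrices up to 6 × 4 with integer weights ≤ 3
(replication-oracle exhaustive over shapes), 1,000-model random sweeps for
monotonicity/dominance, 100 seeds of the full 412-respondent survey for
mode recovery, and a 10,000-respondent draw for the law-of-large-numbers
check against the kernel's analytic mean. The whole suite runs in a few
minutes on one core.

# Known limitations

- The composite-weight scheme is a package decision (the source is silent);
  stage-1 levels depend on it, though `mean` vs `sum` differ only by a
  constant factor and change nothing after normalization.
- Stage-1 printed index values of the source study are not reproducible by
  design (formula and raw data unavailable); only their structure is.
- Importance ranks are treated as interval-scaled scores, which the
  additive model requires; with ranks in {1, 2, 3} this is an assumption,
  not a property of the elicitation.
- Sensitivity is one-at-a-time; no Monte-Carlo uncertainty over criterion
  scores, and no alternative MCDA families (AHP, outranking, fuzzy
  extensions) are in scope.
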