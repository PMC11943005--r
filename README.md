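# resilmcda

Two-stage decision analysis for health-system resilience planning from
healthcare-professional surveys.

**Who it is for:** health decision scientists and planners who need to turn
frontline questionnaire evidence into a defensible, auditable choice among
candidate system-strengthening strategies — and anyone who wants a tested,
reusable implementation of weighted Likert aggregation plus SMART
multi-criteria evaluation.

**Stage 1 — weighted survey aggregation.** Respondents carry differentiated
weight coefficients for education level (1–3.5), specialty experience (1–3)
and pandemic role (1–3), combined (by default) as their arithmetic mean.
Each Likert item is summarized on the weighted empirical distribution: the
weighted mean and a percentage-scaled *weighted index*
(mean / scale-max × 100, comparable across 1–5 and 1–6 scales), the
weighted modal *preferred response* and its weight share, weighted
population SD, and type-1 weighted quartiles. Items are ranked and mapped
onto risk/opportunity criteria.

**Stage 2 — SMART.** Criterion dimensions K1–K4 get weights by normalizing
importance scores in [10, 100]: w_k = s_k / Σs. Each strategy S_j assigns
every attribute an importance rank under a fixed rank budget (14); an
attribute contributes rank × w_k, dimensions sum their attributes into the
performance matrix u_jk, and strategies are compared by the linear additive
utility

    U_j = Σ_k w_k · u_jk,

the maximizer being the recommended strategy. A one-at-a-time
weight-sensitivity analysis reports the smallest weight perturbation that
reverses the recommendation.

Because the underlying raw survey is not publicly deposited, the package
ships a synthetic-survey generator (412 respondents, published demographic
marginals, 8 + 9 + 5 Likert items with planted modal responses from a
discretized Laplace kernel) so the full pipeline is testable against a
known ground truth. See `vignettes/resilience-mcda-methods.Rmd` for the
model, the conventions and their rationale.

## Worked example

```r
library(resilmcda)

# Stage 2: evaluate the packaged resilience decision model
res <- smart_evaluate(resilience_decision_model())
res
#> <performance_matrix>
#>      K1  K2  K3   K4 total
#> S1 0.35 2.7 0.2 0.45   3.7
#> S2 0.70 2.4 0.4 0.30   3.8
#> S3 1.05 2.1 0.6 0.15   3.9
#> utilities U_j:
#>   S1   S2   S3
#> 1.04 1.09 1.14
#> ranking: S3 > S2 > S1
#> optimal alternative: S3
```

Reading: each row is a strategy (S1 emergency-regime, S2 medium-term, S3
long-term prioritization), each column a criterion dimension score u_jk
(budget allocation, service planning, human resources, legal framework at
weights 0.35/0.30/0.20/0.15). S3's utility 1.14 is the highest, so
long-term prioritization is the recommended strategy.

```r
# Stage 1 on a synthetic survey, with ground-truth audit
sim <- simulate_survey(default_survey_spec(), seed = 42)
summaries <- summarize_items(sim$responses)
recovery_check(default_survey_spec(), summaries)
#> <recovery_report> 22/22 planted modes recovered; index rank agreement 0.957

# Robustness of the recommendation to the elicited weights
sensitivity_analysis(resilience_decision_model())
#> <sensitivity_report> baseline optimal: S3
#> smallest weight perturbation causing a rank reversal:
#>   K1: 0.06
#>   K2: 0.05
#>   K3: none within grid
#>   K4: 0.1
#>  (400 infeasible perturbations skipped)

# Survey design arithmetic
cochran_sample_size(1.96, 0.5, 0.05)
#> [1] 384
```

## The analysis workflow

The `analysis/` scripts run the study end to end, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate_survey.R   # synthetic survey (seed 42)
Rscript analysis/02_stage1_aggregate.R  # item summaries, ranking, criteria
Rscript analysis/03_smart_decision.R    # performance matrix and utilities
Rscript analysis/04_sensitivity.R       # weight-sensitivity grid
```

Each step states what it found; all computation lives in the package, so
the scripts are thin narrative drivers. `run_pipeline()` does the same in
one call from a YAML configuration (`packaged_pipeline_config()`), with
all-or-nothing validation and byte-identical reruns under a fixed seed.

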