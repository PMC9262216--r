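# ccea

Conjunctive clause discovery and KNN validation for small,
feature-rich cohorts.

## What it does and for whom

Studies that combine behavioral assessments with FreeSurfer-style
regional brain measures typically have a few dozen subjects and
hundreds of heterogeneous features (volumes ~10⁴ mm³, areas ~10³ mm²,
thickness ~2–3 mm, mean curvature ~0.1–0.2, scores on 0–20 scales).
This package is for researchers who need to *select* candidate
biomarkers from such tables — including feature interactions that carry
no marginal signal — and then validate the selected sets with an
independent classifier.

The core object is a **conjunctive clause**: a logical AND of
feature–interval conditions,

    CC = (F_i ∈ [a_i, b_i]) ∧ (F_j ∈ [a_j, b_j]) ∧ …

A subject matches a clause when every condition holds (intervals closed
on both ends). A clause matching *n* of *N* subjects, *k* of them among
the *K* target-class subjects, is scored by the hypergeometric
probability mass function

    P(k | N, K, n) = C(K, k) · C(N−K, n−k) / C(N, n)

with fitness defined as −log₁₀ P — not a p-value, simply the
improbability of the observed class enrichment. An evolutionary
algorithm searches clauses whose interval bounds snap to observed
values, prunes any clause containing a feature that contributes no
fitness (per-feature *sensitivity* = fitness drop when the conjunct is
removed), and keeps per-order elite archives across independent runs.
Selected low-order models are then validated with k-nearest-neighbors
leave-one-out cross-validation and train/test classification, using
deterministic tie rules and training-only z-scoring.

An exhaustive search over the same clause space (orders ≤ 2, small
tables) serves as a provable optimality oracle, and a synthetic-cohort
generator plants ground-truth rules — optionally with *no* main effects
— so the whole pipeline is testable without any study's raw data.

## Worked example

Generate a 21-subject discovery cohort (7 ASD-labelled cases, 14 NT
controls) with one planted two-feature rule among 50 noise features,
run the full five-run search, and validate the selected features:

```r
library(ccea)

rule <- plantedRule(c("pf_a", "pf_b"), lower = c(4000, 1480),
                    upper = c(4600, 1700), targetClass = "ASD")
syn <- generateCohort(nTarget = 7, nOther = 14, rules = list(rule),
                      nNoiseFeatures = 50, seed = 424)
syn$table
#> FeatureTable: 21 subjects x 52 features
#>   outcome: ASD (target) n=7 | NT n=14
#>   feature kinds: behavioral=10, neuroanatomical=42

arch <- runCCEA(syn$table, config = cceaConfig(seed = 424))
arch
#> ClauseArchive: 250 clauses (max order 5)
#>   order 1: 50 clauses, best fitness 3.0743
#>   order 2: 50 clauses, best fitness 5.0655
#>   ...

best <- bestClause(arch, order = 2)
best$metrics
#> ClauseMetrics: n=7 matched (k=7 in class of 7; N=21)
#>   fitness=5.0655 (pmf=8.6e-06)  PPV=1.000  coverage=1.000
```

The best two-feature clause matches exactly the 7 target subjects:
fitness log₁₀ C(21,7) ≈ 5.0655 is the theoretical maximum on this
cohort, and its PPV and class coverage are both 100%. (On a plateau
like this several clauses tie at the maximum — the planted pair is
among them; the archive's deterministic tie-break picks the displayed
one.) Validating the union of the top second-order models with KNN:

```r
feats <- uniqueFeatureUnion(selectParsimonious(arch, order = 2, topM = 8))
res <- loocv(subsetFeatures(syn$table, feats), knnConfig(k = 3))
res$cm
#> ConfusionMatrix (positive = ASD): ACC 90.48%
#>          Predicted ASD Predicted NT
#> True ASD             7            0
#> True NT              2           12
```

i.e. 19 of 21 subjects are classified correctly under leave-one-out
cross-validation with k = 3.

The end-to-end study layout — fixed discovery cohort, parsimonious
model selection, feature unions, LOOCV and a balanced train/test split
— is driven by one configuration object (`pipelineConfig()` /
`runPipeline()`; a thin command-line wrapper lives in
`inst/scripts/ccea-pipeline.R`).

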