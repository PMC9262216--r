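---
title: "Conjunctive clause discovery and KNN validation in small cohorts"
author: "ccea package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conjunctive clause discovery and KNN validation in small cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccea)
```

## The problem this package addresses

Cohort studies in neurodevelopmental disorders routinely face tables
with a few dozen subjects and hundreds of measurements — behavioral
scores alongside FreeSurfer-style regional brain features (volumes in
mm³, surface areas in mm², cortical thickness in mm, mean curvature).
Classical per-feature statistics struggle here twice over: the multiple
testing burden is crushing, and genuinely interactive structure —
combinations of features that separate the groups while no single
feature does — is invisible to marginal tests.

This package implements a two-stage analysis for that setting:

1. **Feature selection** by a conjunctive clause evolutionary algorithm
   (CCEA).  A *conjunctive clause* is a logical AND of feature–interval
   conditions,
   $CC_k = (F_i \in a_i) \wedge (F_j \in a_j) \wedge \dots$,
   where $F_i$ is a feature and $a_i$ a closed numeric interval.  A
   subject *matches* the clause when every condition holds.  The number
   of conjuncts is the clause's *order*; lower order means a more
   parsimonious model.
2. **Validation** of the selected feature sets with a separate,
   deliberately simple classifier: k-nearest neighbors under
   leave-one-out cross-validation (LOOCV), plus train/test
   classification on a balanced split.

A synthetic-cohort generator with planted ground-truth rules makes both
stages testable end to end without access to any study's raw data.

## Clause fitness

A clause matching $n$ of $N$ subjects, $k$ of them among the $K$
target-class subjects, is scored by the hypergeometric probability mass
function

$$P(k \mid N, K, n) \;=\;
\frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}},$$

the probability of drawing that many target-class members by chance if
the clause picked $n$ subjects at random.  The package defines

$$\text{fitness} = -\log_{10} P(k \mid N, K, n)$$

and maximizes it, so that "highest fitness" coincides with
"least probable by chance".  This quantity is *not* a p-value and no
significance threshold is attached to it.  Two derived scores describe
a clause in clinical terms: the positive predictive value
$\text{PPV} = k/n$ and the class coverage $k/K$.  On a 21-subject
cohort with 7 target subjects the best attainable configuration is
$n = k = 7$, with fitness $\log_{10}\binom{21}{7} \approx 5.0655$ —
the package's tests verify by full enumeration that no other $(n, k)$
does better.

Two numerical conventions matter.  Intervals are closed on both ends.
And a clause matching nobody carries no information: its PMF is set to
1, its fitness to 0, and its PPV is flagged undefined rather than
silently zeroed.

### Direction

The hypergeometric improbability is two-sided: on the 21-subject
configuration a clause matching exactly the 14 *controls* ($n = 14$,
$k = 0$) has the same PMF, $1/\binom{21}{7}$, as one matching exactly
the 7 cases.  Since clauses are read as models of the target class
("a subject in these ranges is predicted to be a case"), the search —
the evolutionary algorithm, its bound refinement, and the exhaustive
oracle alike — assigns fitness 0 to any configuration whose PPV does
not exceed the class prior $K/N$.  `evaluateClause()` itself keeps the
plain $-\log_{10}$ PMF so that any clause, of either direction, can be
inspected.

### Per-feature sensitivity

To prevent overfitting by decorative conjuncts, each feature's
*sensitivity* is the clause fitness minus the fitness of the clause
with that conjunct removed — the fitness that feature contributes.  For
order-1 clauses the reduced clause matches everybody (fitness 0), so
sensitivity equals the clause's own fitness.  A clause enters the
archive only if every sensitivity is strictly above the configured
threshold (default 0); a conjunct spanning its feature's full observed
range has sensitivity exactly 0 and disqualifies its clause.

## The evolutionary search

The search mechanics are standard Michigan-style rule evolution;
correctness is anchored to an exhaustive oracle rather than to the
particular defaults, all of which are exposed in `cceaConfig()`:

* generational EA, population 200, 500 generations per run;
* 5 independent runs (run $r$ seeded with `seed` $+ r$), archives
  merged with de-duplication — multiple runs exist purely to search the
  fitness landscape more thoroughly;
* initialization with 1–3 random conjuncts; tournament selection
  (size 3); uniform per-feature conjunct exchange crossover
  (probability 0.5); exactly one mutation per offspring, chosen among
  add-conjunct (0.2), drop-conjunct (0.2), move-one-bound (0.4) and
  replace-feature (0.2); elitism of the single best individual;
* per-order elitist archives of 50 unique clauses, maximum order 5.

Candidate interval bounds **snap to observed feature values** of the
training table.  This keeps the search space finite and every reported
clause reproducible from the data; printed ranges like
$[3500, 4600]$ mm³ in source studies are understood as presentation
rounding of such data-anchored bounds.

Candidates offered to the archive are first polished by an exact
per-conjunct *bound refinement*: holding the other conjuncts fixed, a
conjunct's interval is replaced by the provably best pair of observed
values (computed with a cached interval-membership matrix), sweeping
until no conjunct improves.  This memetic step costs little and removes
the one failure mode observed in development — the EA finding the right
feature combination but stopping at slightly sub-optimal bounds.

`exhaustiveSearch()` enumerates *all* order-1 and order-2 clauses over
the same snapped candidate space and returns the provably optimal
fitness per order.  It refuses tables beyond 12 features or orders
beyond 2 (combinatorial guard).  The test suite asserts that the EA's
best order-≤2 fitness equals this optimum on batches of random tables —
the package's core correctness claim.

### Identifiability at maximum fitness

On cohorts as small as 21 subjects with dozens of candidate features,
*many* distinct order-2 clauses can reach the theoretical maximum
fitness: the optimum is a plateau, not a peak.  The archive therefore
breaks fitness ties deterministically (lower order first, then
lexicographic canonical form), and recovery of a planted rule should be
judged by "attains the optimum / appears among the maximally fit
clauses", not by the identity of the single top entry, which on such a
plateau is decided by the tie-break rather than by signal.  The
selection effect this reflects is real in null data too: the best of
thousands of scanned clauses beats the class prior even when no feature
carries signal — which is precisely why sensitivity pruning and the
preference for parsimony exist.

## Model selection and feature unions

`selectParsimonious()` picks the `topM` highest-fitness archived
clauses of one exact order — the analysis focuses on the lowest-order
models that explain the data, avoiding the overfitting that
higher-order clauses invite.  `uniqueFeatureUnion()` collects the
deduplicated union of their conjunct features (first-appearance order),
optionally appending extra features such as behavioral scores; these
unions are the feature sets handed to the classifier.

## KNN validation

`loocv()` runs one fold per subject; `trainTestClassify()` fits on a
balanced split and predicts the held-out remainder.  Choices the
underlying literature leaves open are fixed as follows:

* **Scaling.**  Features span five orders of magnitude (volumes
  $\sim 10^4$, curvatures $\sim 10^{-1}$), so Euclidean distance on raw
  values would be volume-dominated.  The default standardizes each
  feature by the *training* rows' mean and SD (re-fit inside every
  LOOCV fold; never from test rows); `scaling = "none"` is available
  for sensitivity analysis.  Constant training features get scale 1
  with a warning.
* **Ties.**  A plurality vote decides the label.  A tied vote (possible
  for even k) is resolved by the class of the single nearest neighbor
  among the tied classes; exact distance ties are resolved by training
  row order.  Both rules are deterministic, so every reported accuracy
  is exactly reproducible.
* **k** is a per-experiment configuration value; the package imposes no
  default grid.

When the validation cohort includes the subjects on which features were
selected (as the study design this mirrors does — the later-enrolled
holdout is *combined* with the discovery cohort for LOOCV), the
accuracy is knowingly optimistic; the pipeline documents the cohorts in
its provenance rather than pretending otherwise.

## The synthetic-cohort generator

`generateCohort()` emulates exactly the statistical structure the
analysis assumes: two classes with small, unbalanced counts (defaults
7 cases / 14 controls, the discovery-cohort shape); continuous features
on heterogeneous scales (per-measure Gaussians — volumes with locations
spread over 4,000–23,000 mm³ and 12% relative SD, areas 1,500–9,000
mm², thickness $\mathcal{N}(\cdot, 0.15)$ around 2.3–2.8 mm, mean
curvature $\mathcal{N}(\cdot, 0.02)$ around 0.12–0.2, behavioral
scores $\mathcal{N}(\cdot, 3)$ on a 0–20 scale); and planted
conjunctive rules.  Every target subject satisfies every planted rule;
each non-leaking control is forced to violate at least one conjunct, so
at most `floor(leakage × nOther)` controls match a rule.  The `leakage`
parameter exists because real cohorts yield imperfect lower-ranked
clauses, and tests need that regime.  Ground truth is returned beside
the table, never embedded in it.

`plantInteractionNoMainEffect()` builds the adversarial case the clause
search exists for: a two-feature rule that separates the classes
perfectly while *neither feature shifts in location between classes*.
The target class sits in a central rectangle; the controls are a
balanced mixture of two opposite off-axis clusters, one overlapping the
rule's interval on each axis, with the in-band cluster shifted so the
control-class mean equals the case-class mean *exactly* (to numerical
precision, every seed — the tests assert it at $10^{-9}$).  Each
single-feature projection of the rule then still covers all cases but
captures about half the controls, while the full conjunction captures
none.

What the generator does **not** emulate: inter-feature anatomical
correlation (real regional volumes co-vary strongly), non-Gaussian or
bounded score distributions, site or age effects, and missingness
(which the loader rejects by design — silently imputing a 28-subject
table would corrupt clause intervals).  Passing tests on synthetic
cohorts therefore demonstrate algorithmic correctness under the model's
assumptions, not clinical validity on real data.

## Determinism and numerical choices

All randomness flows from explicit integer seeds: the generators take a
`seed` argument and restore the caller's RNG state; the pipeline
derives per-stage seeds from one root seed via hashing; EA run $r$ uses
`seed + r`.  Identical configuration therefore yields byte-identical
archives and reports (timestamps aside), and the report's provenance
records a hash of the full configuration.  Fitness comparisons use a
$10^{-9}$ tolerance; the PMF is computed in log space via `lchoose` and
agrees with exact integer arithmetic to better than $10^{-12}$ across
the full support for $N \le 100$.  CSV round-trips format values with
10 significant digits, which is exact for every table this package
produces.

## Problem sizes in the test suite

The shipped tests run the study-scale cohort (21 subjects, 52 features,
5 default EA runs) once for the headline recovery check, and anchor the
oracle-equivalence and LOOCV-against-brute-force properties on batches
of 6–20 random tables with up to 20 and 40 subjects respectively —
sizes chosen so that the exhaustive and brute-force oracles remain
exact references while the whole suite completes in a few minutes.

## A worked example

```{r example, eval = FALSE}
rule <- plantedRule(c("pf_a", "pf_b"), lower = c(4000, 1480),
                    upper = c(4600, 1700), targetClass = "ASD")
syn <- generateCohort(nTarget = 7, nOther = 14, rules = list(rule),
                      nNoiseFeatures = 50, seed = 424)
arch <- runCCEA(syn$table, config = cceaConfig(seed = 424))
bestClause(arch, order = 2)

feats <- uniqueFeatureUnion(selectParsimonious(arch, order = 2, topM = 8))
loocv(subsetFeatures(syn$table, feats), knnConfig(k = 3))$metrics
```

## Known limitations

* The exhaustive oracle certifies optimality only up to order 2 and 12
  features; beyond that the EA's answer is a lower bound on the true
  optimum.
* Outcomes are strictly binary with a designated target class;
  multi-class extensions, overlapping-rule set covering, and
  significance thresholds on the PMF are out of scope.
* Reproducing published accuracies from a specific study requires that
  study's subject-level table; `reproduceStudyValidation()` runs the
  printed experiments when given such a file and reports
  "not-evaluable" otherwise.
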