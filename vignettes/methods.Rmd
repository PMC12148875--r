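---
title: "Methods: constrained Bayesian networks for pain comorbidity surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained Bayesian networks for pain comorbidity surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painbn)
```

## The model and its assumptions

`painbn` treats a pain survey as a sample from a discrete Bayesian network:
a DAG over the survey variables together with one conditional probability
table (CPT) per node. The factorization
`P(X) = prod_i P(X_i | Pa(X_i))` assumes complete-case categorical data and
no latent confounders; arcs encode conditional dependence, **not** causal
effects — the demographic constraints below enforce logical plausibility
(nothing can change a respondent's age), but an arc between two pain sites
only states that their co-occurrence is not explained away by the rest of
the network.

Structure is learned by greedy hill climbing from the empty graph over
single-arc additions, deletions and reversals, scored by the decomposable
BIC `logL - (d/2) log n` with `d = (r_child - 1) * prod(r_parents)` per
family. The blacklist forbids every arc into a demographic variable and
both orientations between demographics; forbidden arcs are simply never
proposed, so the guarantee is by construction, and reversals whose reversed
arc would be blacklisted are likewise skipped.

Parameters are maximum-likelihood conditional frequencies. Exact inference
enumerates the full joint (6,144 states for the default 12-variable
schema); a variable-elimination path exists and is required by the test
suite to agree to 1e-12 — two algorithms, one answer, which is the
package's main defence against indexing bugs in CPT layouts.

Association strength is reported as the odds ratio of the event given
evidence-present versus evidence-absent, with Woolf (log-OR) confidence
intervals computed from the 2×2 counts. Both an *empirical* table (counts
straight from the data, the default report) and a *model-based* table
(probabilities obtained by exact queries on the fitted network) are
available; the bundled published association table is reproduced exactly by
the empirical route, which is why it is the default.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `pseudocount` (CPT smoothing) | 0 | Pure MLE matches the reference analysis; >0 recommended for inference on small cohorts because sparse strata (seniors are 8.5% of the sample) produce empty or near-empty parent rows. |
| HC `tolerance` | 1e-9 | Accept a move only if the score gain exceeds floating-point noise. |
| HC `restarts` / `perturb` | 0 / 4 | Plain greedy search by default; seeded random restarts available for robustness experiments. |
| CI `level` | 0.95 | `z = qnorm(0.975) = 1.959964`; at 3 printed decimals indistinguishable from 1.96. |
| `zero_correction` | FALSE | A zero cell is an error by default so printed-value reproduction stays exact; optionally Haldane–Anscombe +0.5 with a per-row flag. |
| Generator `n`, `gender_split`, `age_mix` | 2400, 0.50, (0.409, 0.506, 0.085) | The composition of the reference cohort. |
| CPT clipping in the generator | [0.01, 0.99] | Keeps every synthetic configuration possible, so MLE refits and queries never hit structural zeros. |

## The synthetic-data generator

The participant-level survey data are not public; the generator exists so
that structure recovery, parameter recovery, inference and coverage are all
testable against a known truth. It emulates:

* the cohort margins (n = 2,400, 50/50 gender, 40.9/50.6/8.5% age strata);
* the published marginal prevalence of each pain site, **exactly** (to the
  printed decimal) in the implied distribution of the truth network;
* the published pairwise conditional percentages and odds ratios,
  **approximately**, with the published direction preserved for all 27
  relationships.

Construction: the reference 23-arc DAG is fixed; the single-parent node
(hip, given headache) takes its two published conditional probabilities
verbatim; every multi-parent pain node uses a log-odds additive rule —
`logit P(yes | parents) = b0 + sum_parents c(parent state)` with
`c = log(published pairwise OR)` for a "yes" (or female / the matching age
level) parent and 0 otherwise. The intercept `b0` is *solved* per node, in
topological order against the exact joint distribution of its parents under
the partially built network, so that the implied marginal equals the
published prevalence. Solving the intercept (rather than setting it to the
prevalence logit directly) is a deliberate design choice: with correlated
upstream parents the naive intercept inflates marginals badly — headache
would drift from 31.1% to ~39% — and the cohort would no longer resemble
the stated sample. The cost is that pairwise conditionals are only
approximate: measured once against the published table, the worst deviation
is ~6.9 percentage points (back → stomach) because correlated parents stack
their log-OR contributions; the headache → neck calibration pair lands
within 1 point (52.0% / 26.3% vs 51.138% / 26.739%).

Sampling is ancestral with a single seed; draws are consumed node-by-node
in topological order, `n` at a time, so identical seeds give bitwise
identical cohorts.

What the generator does **not** emulate: questionnaire skip-logic (the
"none of the above" option is implicit — a record with all pain indicators
"no"), missing data, measurement error, or the unpublished multi-parent
CPTs of the real fitted network. Consequently a green structure-recovery
test establishes that the search recovers *this* truth network from
cohorts of the stated size — not that the published structure is correct,
and the multi-evidence percentages quoted in the source abstract are
treated as supported query *shapes*, never as numeric targets.

## Numerical and design decisions

* **Level order** fixes all layouts: pain levels `no < yes`, age
  `young < middle < senior`, gender `female < male`. CPT rows enumerate
  parent configurations with parents sorted lexicographically and the last
  parent's level varying fastest.
* **Determinism**: node order is lexicographic everywhere (topological
  sort tie-break, move enumeration order add < delete < reverse then
  (parent, child) lexicographic, report row order). Two runs on one cohort
  are identical, byte for byte, in every exported artifact.
* **Empty parent rows** under pure MLE are returned uniform and flagged
  `unobserved` (with a warning) instead of `NaN`, so inference stays total;
  `loglik()` refuses records that hit a flagged row, because the model
  assigns them no estimated probability.
* **Zero-count score terms** use `0 log 0 = 0`; unobserved configurations
  contribute nothing to the likelihood but their parameters still count in
  the BIC dimension, the standard convention for decomposable scores.
* **Age dichotomization**: evidence `age = senior` contrasts seniors
  against young ∪ middle, matching the three published per-level rows.
* **Degenerate odds** (p ∈ {0, 1}) return ±Inf/0 tagged `degenerate`
  rather than erroring, so reports can carry the flag.

## Known limitations

* Hill climbing finds a local optimum; with the default (no restarts) the
  result can drop weak true arcs — at n = 2,400 the search typically
  recovers 18–21 of the 23 truth adjacencies with zero-to-one false
  adjacency.
* The ±0.01 parameter-recovery bound quoted in the acceptance suite is not
  attainable for *all* observed rows at n = 10^5: rows reached through the
  senior stratum and rare pains have N_j ≈ 500–2,500 and binomial SE
  0.01–0.02. The corresponding acceptance test is intentionally left
  failing rather than weakened; the package's own property test bounds each
  row at five binomial standard errors instead.
* Inference is exact but exponential in schema size; it is designed for
  survey-scale networks (≤ ~20 binary nodes), not high-dimensional ones.
* No multiple-testing adjustment is applied across report rows, matching
  the reference analysis; treat borderline CIs accordingly.
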