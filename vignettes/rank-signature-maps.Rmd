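---
title: "Rank-based signature maps: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based signature maps: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankmap)
library(dplyr)
```

## The problem and the idea

Circulating miRNA panels (plasma or serum, microarray or RT-qPCR) are
attractive biomarkers for minimally invasive diagnosis, but absolute
intensities from these platforms are notoriously sensitive to lab
protocol, calibration and batch. `rankmap` implements a classification
strategy that uses only the *ordering* of species within each profile,
never their absolute values: each sample gets its own rank-based
signature, all signatures are compared pairwise, and phenotype groups
emerge as communities of a similarity graph. Diagnosis of an unlabelled
sample is read off the map — which community it falls into, or what its
immediate neighbours are.

This is deliberately different from cohort-level marker lists: there is
no single discriminating gene list. The per-sample signature is the
identity of that sample's most extreme species, and the classifier is
the geometry of the whole cohort.

## The procedure

Given a probes-by-samples matrix of positive, linear-scale intensities:

1. **Missing-value filter.** Probes with any missing cell are dropped
   (`drop_incomplete_probes()`).
2. **Virtual control.** The per-probe arithmetic mean across *all*
   samples is the reference profile; dividing each profile by it
   (`differential_transform()`) re-expresses every value as deviation
   from the cohort norm. When a new test sample is diagnosed it is added
   to the cohort first and the virtual control is recomputed over all
   samples, the new one included. The transform divides by a per-probe
   constant, so within-probe sample orderings — and hence every test and
   every signature downstream — are what carry the information.
3. **Feature screen.** Each probe is tested control-vs-affected with a
   two-sided Mann-Whitney U test (`select_features()`); probes with
   p ≤ α are retained. The level is deliberately nonstringent
   (α = 0.1, no multiplicity correction): the screen is not inference,
   it only removes the mass of uninformative control probes that dilute
   signatures on dense arrays.
4. **Signature.** Within each sample the retained probes are ranked from
   highest to lowest differential value; the signature is the identity
   of the first `n1` and last `n2` probes (`extract_signatures()`).
5. **Distance.** The similarity of samples A and B averages four
   unweighted enrichment scores: A's top set against B's descending
   ranking, A's bottom set against B's ascending ranking (and the two
   with roles swapped). With m the set size and G the number of retained
   probes, walking the ranking adds 1/m on a hit and subtracts 1/(G−m)
   on a miss; the score is the running-sum excursion of largest
   magnitude, signed. The average s ∈ [−1, 1] becomes a distance
   d = (1 − s)/2 ∈ [0, 1] (`signature_distances()`).
6. **Map.** The K = ⌈N/100 · n(n−1)/2⌉ smallest pairwise distances
   become edges of an undirected graph whose nodes are the samples;
   edge weight is 1 − d (`build_map()`).
7. **Communities, labels, diagnosis.** Greedy modularity agglomeration
   partitions the map (`detect_communities()`); each community takes the
   majority phenotype of its labelled members (`label_clusters()`); each
   node is also diagnosed by the majority label of its immediate
   neighbours (`classify_majority()`), its own label never voting, which
   makes a single pass over the cohort a leave-one-out evaluation
   (`evaluate_diagnosis()`). An exact vote tie, or a node with no
   labelled neighbour, is an abstention and is scored as an error.

`fit_signature_map()` runs the whole chain and keeps every intermediate
result; `tidy()`, `glance()` and `autoplot()` summarise the fit.

## Parameters that matter

* `n1`, `n2` (probes, default 25/25): signature sizes. Robust over a
  broad range; they only need to capture each sample's reliably extreme
  species. On small panels keep `n1 + n2` well below the number of
  retained probes — a signature that saturates the ranking makes all
  samples look alike (see limitations).
* `alpha` (default 0.1): feature-screen level, inclusive (p ≤ α counts;
  `inclusive = FALSE` for strict). On null data the screen retains ≈ α
  of probes by construction.
* `exact` (default `"auto"`): Mann-Whitney p-values use the exact
  distribution when both groups have ≤ 12 samples and there are no
  ties, otherwise the normal approximation with tie and continuity
  corrections — deterministic at any cohort size.
* `n_pct` (percent, default 10): the map keeps the N% smallest
  distances. 10 is usually enough for a clear map; 20 suits small
  cohorts. An absolute distance cutoff is available via
  `mode = "absolute"`.
* `weighted` (default `FALSE`): neighbour votes may be weighted by
  inverse distance, floored at `eps = 1e-12`. Unweighted voting is
  invariant under any monotone rescaling of distances; weighted voting
  is not.
* The map-sharpening loop over (`n1`, `n2`, `n_pct`) is exposed as
  `scan_parameters()`, scored by weighted modularity; no automatic
  optimiser is claimed.

## Numerical choices

* Ranking ties are broken by probe ID, ascending; real-valued
  intensities make them rare but the rule keeps results
  platform-independent.
* The enrichment-score walk is computed in integer numerators over the
  common denominator m(G−m) — a hit steps +(G−m), a miss −m. Exact
  magnitude ties between the largest positive and negative excursion
  then resolve exactly (the positive value is returned), rather than by
  accumulated floating-point error.
* Edge selection keeps exactly K pairs; distance ties straddling the
  cutoff are resolved by lexicographic pair ID.
* The community step takes the cut of the greedy merge tree with
  maximal modularity, with ties (within 1e-10) resolved toward fewer
  communities; isolated nodes are singleton communities.
* Degenerate inputs fail loudly: non-positive or missing intensities at
  the transform, fewer retained probes than `n1 + n2`, a gene set that
  is empty or the whole ranking, cohorts without both phenotypes.

## The synthetic cohort generator

`synthetic_cohort()` provides seeded, fully reproducible two-group
cohorts so the pipeline is testable end to end without any download.
Per-probe baselines are drawn log-uniformly on [100, 5000] (typical
linear-scale summary intensities for bead arrays); a fraction
`frac_diff` of probes is perturbed in the affected group by `fold`
(half up, half down); every value is multiplied by lognormal(0, σ)
noise. Multiplicative noise is the natural companion of a ratio-based
transform — it is additive on the log scale and keeps values positive.
σ = 0.3 and fold = 4 are the defaults: a clearly detectable but not
caricatural effect (log-fold ≈ 1.4 against log-noise 0.3).

Two presets fix the shapes of the published study designs the method
targets: `"zhao"` (1134 probes, 20 + 20 samples, 5% of probes
perturbed — a genome-scale plasma panel) and `"bianchi"` (141 probes,
70 + 54 samples, 35% perturbed — a small serum panel pre-enriched for
informative species, so that the α = 0.1 screen retains roughly 50 of
141, the scale reported for such panels).

What the generator does *not* emulate: batch effects, probe-specific
noise, correlated miRNA modules, platform-specific intensity
distributions, or class imbalance beyond the preset group sizes.
Passing tests on synthetic cohorts therefore demonstrate the
*algorithmic* contract — rank invariance, metric properties, recovery
of a planted two-group structure — not clinical performance on real
serum or plasma data.

## Design choices where the design was open

* **Unweighted enrichment score.** A value-weighted score would
  reintroduce dependence on intensity calibration and contradict the
  rank-only robustness argument; the classic unweighted
  (Kolmogorov–Smirnov-style) statistic is used.
* **Bottom signature against the reversed ranking,** so concordant
  under-expression contributes positively, symmetrically with the top.
* **d = (1 − s)/2.** The simplest order-reversing affine map sending
  s = 1 to d = 0 and s = −1 to d = 1.
* **Screen after the transform.** Because the test is rank-based the
  order is immaterial (asserted by test); fixing it after the transform
  mirrors the two-step preprocessing description.
* **Community algorithm.** Greedy agglomerative modularity
  (Clauset–Newman–Moore, via igraph) on weights 1 − d: the method only
  requires *some* deterministic unsupervised partitioner, and this one
  is fast and reproducible.
* **Abstention** is recorded as its own outcome in the diagnosis table
  but scored as an error, keeping the headline accuracy conservative.

## Known limitations

* **In-sample screening is circular under the null.** The feature
  screen keeps exactly the probes that separate the two groups *in this
  dataset*. On data with no true effect it still keeps ≈ α of probes —
  the ones separating the groups by chance — and signatures built on
  them produce a genuinely group-assortative map, so leave-one-out
  accuracy on null data is far above chance. The tests demonstrate the
  mechanism: the same null cohort with the screen bypassed drops to
  chance level. For an unbiased error estimate the screen must be fit
  on samples independent of those being evaluated; the package runs the
  screen in-pipeline (matching the published protocol) and leaves
  cross-validated screening to the user.
* **Linear-scale input is the user's responsibility.** The virtual
  control divides by a mean; feeding log-scale data silently changes
  the model. No log detection is attempted.
* **Signature saturation on small panels.** When `n1 + n2` approaches
  the number of retained probes, every sample's signature covers nearly
  the whole panel and distances lose contrast; residual error persists
  even for strong effects.
* **Isolated nodes.** A sample whose distances all fall above the N%
  cutoff gets no edges, becomes a singleton community, and abstains
  under the neighbour vote. This is informative (an outlier), but it
  caps accuracy below 1 even on cleanly separated cohorts.
* Map rendering is delegated to external viewers through GraphML
  export (`export_graphml()`); the package computes no force-directed
  layout beyond the diagnostic `autoplot()`.

## Problem sizes used by the tests and the acceptance script

The property suite exhausts all rankings of up to 7 probes against all
gene-set sizes; the metric contract is checked on 200 random 10-sample
cohorts; end-to-end behaviour is checked on the two presets above plus
a 2000-probe null calibration. `scripts/acceptance.R` re-runs the two
presets, the null preset and the calibration from a single seed and
writes the resulting accuracies, selection counts and modularity as
JSON. These sizes were chosen to match the study designs the method was
demonstrated on while keeping a full run in the order of a minute.
```
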