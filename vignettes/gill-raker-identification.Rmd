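---
title: "Identifying traded mobulid gill rakers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying traded mobulid gill rakers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mobulidID` reimplements, as a tested pipeline, the two identification
channels used in market surveys of dried mobulid gill rakers: DNA
barcoding of the COI and NADH2 mitochondrial markers, and visual
classification of the dried plates. This vignette records the models, the
tunable parameters, and the design decisions taken where the published
account leaves the design open. It states no empirical result that the
package's tests and acceptance script do not themselves compute.

## The molecular channel

### Kimura 2-parameter distances

For two aligned sequences, sites where either carries `N` or a gap are
dropped (*pairwise deletion*; the standard barcoding convention — the
original analysis does not state its gap policy). Among the `n` retained
sites, `P` is the fraction of transitions (A–G, C–T) and `Q` the fraction
of transversions, and the distance is

    d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)   [substitutions/site].

When either log argument is non-positive the distance is *undefined by
saturation*; `k2p_distance()` raises an error rather than returning
infinity, `distance_matrix()` names the offending pair, and the bootstrap
discards (and counts) any replicate containing such a pair, warning when
more than 10% are lost. Inputs are assumed aligned and equal-length per
marker; multiple alignment is upstream of this package.

### Neighbor joining and bootstrap support

`neighbor_joining()` is the classic Saitou–Nei agglomeration on the
Q-criterion, with two pinned conventions the original (software-based)
analysis leaves unstated:

* **Ties** in the Q-criterion join the smallest pair in the current node
  ordering (input order, then creation order) — deterministic and
  order-reproducible.
* **Negative branch lengths** are clamped to zero with the deficit moved
  to the sibling branch (the Kuhner–Felsenstein convention); distance
  updates use the raw, unclamped values.

Two taxa yield a single evenly split edge; the general output is the usual
unrooted tree with a trifurcating root. On any additive matrix NJ must
recover the generating tree exactly — the test suite checks topology and
branch lengths against 50 random additive trees.

Support is the *bipartition frequency* over NJ trees rebuilt from
alignments resampled by columns with replacement (`replicates = 1000` by
default). Whether the original "99–100% supports" were bootstrap
percentages is not stated; bootstrap is assumed, being the default for the
cited tree method. The denominator is the number of retained (non-discarded)
replicates.

### Clusters, identity assignment, and the barcoding gap

`extract_clusters()` scans both sides of every internal bipartition (plus
the full leaf set, support 100 by convention) for maximal groups whose
contained references are single-species and whose edge support reaches
`min_support` (default 99, from the reported 99–100% range). Candidates
are accepted greedily, largest first, keeping disjoint groups; query
leaves outside every accepted group are `UNRESOLVED`. A support threshold
above 100 therefore unresolves everything, and a single-species tree
collapses to one cluster.

`assign_by_identity()` replaces the original web-based best-hit step with
local identity against a packaged reference panel: identity is matching
sites over comparable sites (same pairwise deletion as the distances), the
default acceptance threshold is 0.99 (the "99–100% identical" convention),
exact ties go to the earliest reference in panel order and are flagged.
Species calls of *Manta birostris* always carry a complex-level caveat
flag: *Ma. alfredi* is indistinguishable on both markers, so the call is
really "*Manta* complex".

`barcoding_gap()` reports the within- and between-species distance ranges
as percentages; a gap exists when the largest intra-specific distance sits
below the smallest inter-specific one, which is what licenses
threshold-based identification.

## The morphological channel

Each dried plate is coded as five filament-length measurements (two plate
edges, the midpoint, two in between; their mean is *the* filament length)
plus four categorical traits: arrangement (loose/general/tight), color
(light end / light base / whole light / whole dark), middle-lobe structure
(finger-like projections / veins / oval / cilia / none obvious) and
terminal-lobe shape (large and fused / oval / sharp apex).

### The three-step enforcement rule

1. Plates whose terminal lobes are not enlarged-and-fused are weeded out
   (`OTHER_MOBULA`).
2. Among fused plates, *variegated* gills go to `MOBULA_TARAPACANA`.
   "Variegated" is operationalized as `color == light_base` **and**
   `middle_lobe == cilia` — the species is described as dark with a light
   base and loupe-visible cilia, but no crisp rule is published; the
   predicate is a documented, configurable choice
   (`variegated_rule` argument).
3. Finger-like projections identify `MANTA`. Projections can be invisible
   on small or poorly preserved plates, so fused plates without them fall
   back to a *low-confidence* call instead of an abstention: `MANTA` when
   uniformly colored with no obvious middle-lobe structure, otherwise
   `MOBULA_TARAPACANA`. The pipeline thus always returns a class plus a
   confidence flag.

The `> 70 mm` size screen is a strict inequality ("longer than 70 mm").
The rule is total: all 180 trait combinations map to exactly one class
(enumerated in the tests).

### Naive Bayes on the published trait table

`trait_bayes_classify()` is a transparent probabilistic counterpart to
visual discrimination, parameterized directly by the published per-species
trait frequencies, length Normals and specimen counts. The posterior is
prior x categorical likelihoods x Gaussian length density. Zero published
frequencies are smoothed only in this classifier (never in the generator)
with pseudo-count `smoothing = 0.5` against the species prior count:
`p = (freq*n + s) / (n + s*K)`. With `smoothing = 0` the published
frequencies act verbatim, so a trait exclusive to one species (e.g.
finger-like projections) pins the posterior on it. Missing traits drop
their factor; an all-zero likelihood falls back to the prior with a
warning. Two published frequency columns do not total 100% (terminal lobes
of *Mo. kuhlii*, 92%, and *Mo. thurstoni*, 83%); all rows are renormalized
to sum to one at construction.

### The bagged-tree ensemble

No decision-tree package is assumed: `ensemble_classify()` implements the
standard forest recipe in Rcpp — 1000 trees by default, each grown to
purity on a bootstrap sample with `floor(sqrt(p))` randomly subsampled
columns per split, Gini impurity, one-hot encoded categorical traits plus
the mean filament length. Errors are out-of-bag. Vote ties and equal-gain
splits resolve to the first candidate in a fixed order, so reports are
deterministic per seed.

Two usefulness measures are reported, because they answer different
questions:

* `marginal_error` — the OOB error of a forest retrained on each feature
  *alone*. This is the per-characteristic error-rate concept behind the
  published trait-usefulness ordering, and it is what
  `variable_importance_check()` ranks on. For a single categorical trait
  this error is determined by the published marginal table itself, which
  is why the synthetic values land close to the published column.
* `importance` — classical OOB permutation importance (mean decrease in
  accuracy), permuting all dummy columns of a trait jointly. On the
  synthetic data this measure favors the terminal lobes, which guard the
  dominant *Mo. japanica* class; it is carried for reference.

## The synthetic survey generator

The generator emulates the published survey's *stated* statistical
structure, and provides ground truth for every other module:

* the species mix (103/25/27/12/21 specimens, 188 total);
* filament lengths: per-species Normals (means 36.0/20.4/51.4/25.5/62.6 mm)
  truncated at 2 mm, with five measured points jittered at 5% of the plate
  mean;
* traits drawn **independently per specimen** from the per-species
  frequency rows;
* prices: per-species Normals truncated at 10 US$/kg; the *Mo. kuhlii*
  standard deviation is unpublished (a single observation), default 10,
  configurable;
* sequences: one random ancestor per marker (COI 761 bp, NADH2 1033 bp);
  five species consensus sequences with substitutions at disjoint random
  sites (transition:transversion 2:1); per species, three reference
  haplotypes and per-specimen queries each within the intra-species
  divergence target (0.006) of the consensus; a 16% dropout fraction
  without sequences (the unidentified/collected ratio of the survey);
* survey cities drawn independently of species with fixed probabilities
  (majority Guangzhou). Published per-city price differences are *not*
  modeled; per-city means are reported descriptively only.

Root-to-consensus divergences form an arithmetic ladder chosen so that all
pairwise inter-species distances stay inside the configured 4–13% band
*and* every species keeps a consensus stem of at least ~2.5% — short stems
(few diagnostic sites) erode bootstrap support for the least divergent
species, which would contradict the stated 99–100% support regime.
Realized consensus distances are verified within 25% of target before the
panel is returned. Site evolution is independent-site substitution without
rate heterogeneity — sufficient for K2P-level testing, not for model-fit
studies.

**The key simplification is trait independence.** Only marginal trait
frequencies are published, so specimens are sampled with independent
traits given species. Consequences: single-feature (marginal) error rates
are faithfully reproduced, but joint-trait error rates are not — synthetic
*Ma. birostris* plates lacking finger-like projections (19%) become partly
confusable with other dark fused plates, inflating that species' ensemble
error relative to the published "<0.1%", while *Mo. japanica* (96% sharp
apex) comes out cleaner than its published 3.88%. A green classifier test
therefore establishes the *structure* (hardest and easiest classes, trait
usefulness ordering, error magnitudes) and not the exact published
per-species errors, which depend on unreleased specimen-level joint data.
The hardest-class result (*Mo. thurstoni*, almost always misread as
*Mo. kuhlii*) and the total error magnitude are robust across seeds.

Everything is reproducible: a config plus seed yields byte-identical
output; the bootstrap and the forest take explicit seeds.

## Numerical and policy choices, in brief

* Saturated distances: error, never infinity; bootstrap replicates
  containing one are discarded and counted.
* Identity/assignment and gap summaries use the same pairwise-deletion
  convention as the distances.
* Composition percentages print to 1 decimal (their sum may miss 100 by
  rounding; the invariant allows 0.2).
* The final pipeline call prefers the molecular channel; morphological
  fallbacks are always flagged low-confidence. When both markers are
  assigned and disagree, the COI call wins and the conflict is flagged.
* Unannotated trees (no bootstrap) pass the cluster support filter;
  support is then taken as 100.
* Web-based identification, multiple alignment, other substitution models,
  ANOVA/GLM/Tukey/MDS price statistics, and image analysis are out of
  scope; the pipeline exports tidy CSV/JSON so external tools can take
  over.

## Known limitations

* *Mo. kuhlii* vs *Mo. thurstoni* cannot be separated morphologically —
  by construction of the trait table, not by classifier weakness.
* *Manta* calls are complex-level (see the caveat flag).
* The generator does not model joint trait structure, geographic
  population structure, rate heterogeneity, or price–city–species
  interactions; conclusions drawn from synthetic data are limited
  accordingly (see above).
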