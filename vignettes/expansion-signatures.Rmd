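---
title: "Detecting range-expansion signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting range-expansion signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfline)
```

# The problem

An invading population spreading from a single introduction point leaves
a characteristic genetic footprint. Each colonisation step is a founder
event sampling only part of the source deme's alleles, so allelic
richness and expected heterozygosity decay with distance from the
origin; and because the wavefront repeatedly passes through small
numbers of founders, individual alleles can "surf" to high frequency far
from the origin without any selective advantage, producing frequency
clines along the expansion axis. `surfline` turns georeferenced
multiallelic genotypes into tests for exactly these signals, and ships a
simulator that generates data under the assumed demography so every test
can be calibrated and its power measured.

# The analysis model

## Spatial linearization

A continental invasion is effectively one-dimensional along its
corridor. Samples are projected onto a user-supplied polyline (GeoJSON
LineString) with a designated origin point. Projection drops a
perpendicular per segment in a local equirectangular frame and measures
the offset as the great-circle distance to the foot on a sphere of
radius 6371.0088 km; at continental scales this is accurate to well
under a kilometre, which is immaterial against group bins hundreds of km
wide. The signed path distance `s` is the along-path distance to the
foot minus that of the origin, so samples nearer the path's first vertex
than the origin get `s < 0`; by convention the path is digitised with
its "west" terminus first. Samples more than `maxOffsetKm` (default
150 km) from the path are excluded — far-off samples cannot be
attributed to a corridor position without arbitrary choices.

The occupied interval `[min s, max s]` is split into `nSegments`
(default 18) equal-width half-open bins, the last closed; a sample on an
interior boundary belongs to the right-hand bin. Groups below
`minGroupSize` (default 10) individuals are merged, smallest first, into
their smaller adjacent neighbour (ties toward the origin) until all
groups reach the floor or one remains. The merge direction is a genuine
design freedom: merging into the *smaller* neighbour equalises sizes
rather than letting one big group absorb everything, and the tie rule is
deterministic so runs reproduce exactly. Each group is summarised by the
median signed distance of its members (even counts: mean of the central
pair).

Directional subsets — needed because the two arms of an expansion may
differ — are `west` = groups with median `s ≤ 0` and `east` = median
`s ≥ 0`, with the group nearest the origin always in both. Including
the origin group in both arms anchors each gradient at its high-diversity
end; the alternative (assigning it to one side) discards information on
the other side for no benefit.

## Quality control

Continental data violate random mating globally, so Hardy–Weinberg and
linkage tests run inside 1° × 1° grid cells (floor of latitude and
longitude; half-open). Cells with fewer than 10 located, genotyped
individuals at a locus are not tested — exact tests below that size have
essentially no power. Hardy–Weinberg uses a Monte-Carlo exact test:
gene copies are pooled and re-paired at random (Levene's conditional
distribution), the observed table's conditional probability is compared
to the permuted ones, and `p = (1 + n_extreme)/(1 + n_reps)`, which can
never be exactly zero. Full enumeration is infeasible for multiallelic
tables, hence Monte-Carlo with a default of 9999 seeded replicates.
Linkage disequilibrium uses a permutation G-test on the joint genotype
contingency table of each locus pair (at least 5 doubly-called
individuals), permuting one locus across individuals. Null alleles are
flagged by the Brookfield estimator `r = (He − Ho)/(1 + He)`; negative
values (heterozygote excess) are reported as-is with a no-deficit flag.

Bonferroni families are all tests of one kind across cells (or pairs) at
family-wide α = .05. A locus is dropped when it rejects
Hardy–Weinberg, after correction, in more than half its testable cells,
or is in corrected-significant linkage in more than half its testable
pairs. The majority-of-cells rule is our choice — no published numeric
rule exists for combining per-cell verdicts — and both fractions are
config-exposed.

Missingness is a whole-genotype state: a half-called genotype (one
allele read) is demoted to missing with a warning, because the
individual-level filter (drop below 60% of loci called) and all
gene-copy counting are defined per locus, not per allele.

## Diversity statistics

Allele frequencies per (group, locus) use non-missing gene copies only;
the copy count is twice the called individuals. Expected
heterozygosity defaults to Nei's unbiased form
`(n/(n−1))(1 − Σp²)`. Allelic richness is rarefied:
`A_g = Σ_a [1 − C(N−N_a, g)/C(N, g)]` is the exact expectation of the
distinct-allele count in `g` copies drawn without replacement, computed
with log-binomials for stability. The rarefaction size is, per locus,
the smallest copy count over groups with data (floored at 2) — the
standard minimum-sample convention, config-exposed — so groups of 10 and
789 are compared on equal footing. Both the rarefied and the raw
allele-count variants (sum and median across loci) are reported, since
either may be plotted against distance.

Differentiation: Nei's `G_ST` uses unweighted group means for `H_S` and
the diversity of unweighted mean frequencies for `H_T`, multi-locus as
`(mean H_T − mean H_S)/mean H_T`; unweighted because group sizes span
two orders of magnitude and weighting would let the largest groups
dominate a statistic meant to describe spatial structure. Pairwise
FST is Weir–Cockerham θ as a multi-locus ratio of summed variance
components (alleles and loci pooled before the ratio), the estimator's
standard form; pairwise Nei GST is available as an alternative.

## Mantel cline tests

Group summary statistics and per-allele frequencies are tested for
association with path distance via Mantel tests between
absolute-difference matrices: `D_ij = |v_i − v_j|` for the statistic and
for the group median distances. Binning has already removed most of the
distance correlation among samples, and the Mantel permutation handles
the non-independence of matrix entries. With 7 or fewer groups all
`n!` label permutations are enumerated and the p-value is exact
(identity included, so `p > 0`); otherwise `nPerm` seeded samples give
the plus-one estimate. The default tail is one-sided "greater": a
monotone cline makes |Δfrequency| and |Δdistance| co-increase, so r > 0
regardless of whether the cline rises or falls. The direction of change
is reported separately as the sign of the correlation between the raw
values and the groups' *absolute* distance from the origin — a decline
away from the origin is `−` on both arms, which keeps "significant
decline" a single well-defined event. A two-sided tail is available.

For the allele scan, an allele is *insufficient* when present
(frequency > 0) in fewer than 3 groups of the directional subset, when
fewer than 3 groups have data at its locus, or when its frequency does
not vary; no published criterion exists, so the floor is exposed in
config. Bonferroni correction is per locus — threshold
`α / (alleles at that locus)` — reading the protocol's "α = .05 / number
of alleles / locus" as a per-locus family; a global family
(`α / total alleles examined`) is available by flag. The surfing
summary reports proportions on both the all-examined and the
examined-minus-insufficient denominators, because published tallies are
ambiguous between the two accountings; the internal consistency
`bonferroni ≤ raw ≤ examined − insufficient` is enforced and tested.

# The simulator

`simulateExpansion` runs a 1-D stepping-stone lattice: demes of carrying
capacity `N` diploids at fixed spacing, colonised outward from an origin
deme in one or both directions. Every `colonizationInterval` generations
(per direction) the wavefront deme founds the next empty deme with
`founderSize` diploids sampled with replacement; each generation, all
occupied demes exchange a fraction `migrationRate` of their gene pool
with each occupied neighbour (symmetric gamete-pool mixing — Wright–
Fisher-compatible and far cheaper than individual tracking), then
resample `2N` copies multinomially, then each copy mutates with
probability `mutationRate` by ±1 allele state, reflecting at the bounds
of a ladder sized to stay 3-digit GENEPOP-encodable. After both fronts
reach the ends, `stabilityGenerations` more generations run — the
post-expansion stability phase that makes detection non-trivial.

Defaults emulate the documented study conditions: an origin deme seeded
by 50 founders (within the "tens to low hundreds" historically
released), a distinct high-diversity source pool (symmetric Dirichlet
frequencies, concentration 0.7 over 12 alleles at 25 loci, giving
source-like heterozygosity near 0.8), ~100 km deme spacing, and a total
of roughly 40–70 generations (expansion plus 30 stability generations),
consistent with a ~150-year history at a 2–3-year generation time —
config-exposed, not asserted as biological truth. Samples get jittered
coordinates (uniform ± half a deme spacing along-path, ± 30 km
across-path) so the projection and offset-filter machinery is genuinely
exercised. `SimulationTruth` records colonisation generations, true
deme positions and source frequencies for recovery tests.

What the simulator does *not* emulate: two-dimensional habitat,
landscape heterogeneity, long-distance dispersal, selection, overlapping
generations, and genotyping artefacts other than what QC injects in test
fixtures. Passing recovery tests therefore demonstrates that the
statistics detect the serial-founder signal *when the assumed demography
holds*, not that real landscapes cannot produce confounded gradients.

Presets:

- `panmixia_null` — one deme, samples spread uniformly along the path:
  the negative control for calibration.
- `strong_founder_west` — 40 demes, 5 founders per step against
  capacity 100, migration 0.05, 25 loci, 30 stability generations:
  strong surfing and diversity erosion.
- `bidirectional_asymmetric` — interior origin, 30-deme west arm vs
  12-deme east arm, faster westward colonisation: the two-front
  invasion analog used by `scripts/acceptance.R`.
- `two_cluster_barrier` — migration suppressed across the lattice
  midpoint after colonisation passes: a desert-barrier analog that
  should appear as elevated cross-barrier FST.

# Numerical and degenerate-input choices

- Monte-Carlo and permutation p-values use the plus-one rule everywhere;
  p = 0 is impossible by construction.
- Rarefaction uses `lchoose` differences; `g` above the available copies
  masks the cell rather than extrapolating.
- Monomorphic loci: He = 0, richness 1, Hardy–Weinberg p = 1 (flagged),
  G = 0 for linkage.
- `G_ST` is masked when mean `H_T` = 0 (all groups fixed for one
  allele); group pairs with no co-typed polymorphic locus are masked in
  the FST matrix.
- Projection ties between equidistant segments resolve to the smaller
  along-path distance; all samples at one point collapse to a single
  degenerate group with a warning; merging that exhausts all groups
  returns one group with a warning.
- All randomness flows from explicit seeds; the pipeline derives one
  stream per stage from its master seed, and identical config + seed
  reproduce every output byte-for-byte (tested).

# Problem sizes used in the test-suite experiments

Calibration uses 200 single-deme replicates of 20 loci with 150 samples
in 10 segments and 199-permutation tests; recovery uses 50 replicates of
the `strong_founder_west` preset (40 demes × 10 samples, 25 loci)
against matched panmictic controls; barrier detection uses 40 replicates
of `two_cluster_barrier`. These sizes give the binomial envelopes quoted
in the tests while keeping a full run at desk scale.

# Known limitations

- The per-allele tests within a locus are not independent (frequencies
  sum to one), so family-wise error control by Bonferroni is
  conservative in principle but the effective number of tests is smaller
  than the count of alleles.
- The Mantel test on absolute-difference matrices detects monotone
  gradients; non-monotone structure (e.g. a diversity trough at a
  barrier) appears instead in the adjacent-pair differentiation series.
- Grid-cell QC assumes cells approximate random-mating units; strong
  within-cell structure can still inflate Hardy–Weinberg rejections.
- GENEPOP carries no coordinates; geography travels in a sidecar table,
  which must accompany the file.
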