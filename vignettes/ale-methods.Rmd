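---
title: "ALE meta-analysis and network overlap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ALE meta-analysis and network overlap: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aleoverlap)
```

This vignette documents the statistical model the package implements,
the parameters that matter and their defaults, the numerical choices
made where several implementations are defensible, and what the
synthetic-data tests do and do not establish about behaviour on real
data.

## The model

### Modelled activation maps

A reported focus is not a point measurement: its location carries
spatial uncertainty from template normalisation and from between-subject
anatomical variability. The revised ALE algorithm models a focus as a
3-D isotropic Gaussian probability mass. Both uncertainty components
were estimated empirically in the literature the algorithm derives from,
as mean Euclidean displacements (ED): 5.7 mm between templates and
11.6 mm between subjects. An ED converts to a Gaussian FWHM via
`ED / (2 sqrt(2/pi)) * sqrt(8 ln 2)`, and the per-experiment kernel
combines the two in quadrature with the subject term scaled by the
sample size:

FWHM(n)^2 = FWHM_template^2 + FWHM_subject^2 / n.

`kernel_sigma()` exposes this curve; `ale_kernel_constants()` holds the
two displacement constants so an alternative calibration can be swapped
in without code changes. At n = 10 the model gives FWHM close to 10 mm,
the figure usually quoted for typical experiments; as n grows the width
approaches the between-template floor (sigma about 3.57 mm).

Within one experiment, overlapping kernels combine by the voxelwise
**maximum**, the revised algorithm's non-additive rule: convergence
within a single experiment is not evidence of convergence across
experiments, so a focus listed twice contributes nothing extra. The
older probabilistic-union aggregation is available as
`compute_ma_map(..., aggregate = "union")` for comparison only.

Kernels are evaluated on the analysis grid as separable 1-D Gaussian
masses (density times voxel size) and truncated at 5 sigma, where the
omitted mass is below 1e-6 of the peak; beyond that radius
contributions are exactly zero, which also gives MA maps a finite
support and makes results bit-reproducible.

### ALE scores and the analytic null

Across experiments, MA values combine as a probabilistic union,
`ALE = 1 - prod(1 - MA_i)`: the probability that at least one experiment
truly activates the voxel, under independence. The null hypothesis of
spatial independence keeps each experiment's MA *value distribution*
(within the grey-matter mask) but forgets *where* the values sit; the
null ALE distribution is the union of one independent draw per
experiment. `build_null()` computes it by non-linear histogram
integration over a discretised score axis.

Two numerical paths produce that histogram:

* **Exact path** (small problems): while the joint support — the product
  of the experiments' distinct within-mask MA value counts — is at most
  `max_exact` (default 2e5), all value combinations are enumerated
  exactly and binned once at the end. This makes the toy-scale null
  *identical* to brute-force enumeration, which the test suite verifies
  bin for bin.
* **Binned path** (realistic problems): each experiment's values are
  floored onto the bin grid and combined sequentially through the union
  formula, flooring each intermediate score. Flooring only ever moves
  scores down, by less than one bin per combination step, so the
  survival function is correct to a few bin widths; with the default
  bin width of 1e-5 ALE units that slack is far below any threshold of
  interest.

The survival function uses right-open bins with scores floored down, so
a p-value is read as `P(null >= bin lower edge)`, the conservative
direction. P-values at ALE 0 are exactly 1; observed scores above the
null's top bin (possible only with inconsistent inputs) receive the
smallest positive tail mass with a warning.

### Cluster-level inference

The observed map is thresholded at a voxel-level cluster-forming
threshold (`voxel_alpha`, default 0.001), supra-threshold voxels are
grouped by 26-neighbour connectivity (6 and 18 are selectable; the
choice only matters for marginal, snake-like clusters), and components
below 100 mm^3 — 13 voxels at 2 mm — are dropped. Family-wise error over
clusters is controlled by a Monte Carlo null: each permutation relocates
every experiment's foci to uniformly random in-mask voxel centres
(preserving per-experiment focus and subject counts), recomputes the ALE
map, applies the same voxel threshold and volume floor, and records the
maximum surviving cluster size. Clusters at or above the
`1 - cluster_alpha` quantile of that distribution survive; a cluster
exactly at the critical size is retained.

One deliberate deviation from the most literal reading of
"re-run everything per permutation": the histogram null depends only on
the kernels and the mask — relocating foci leaves the within-mask MA
value distribution unchanged except for edge effects — so the
voxel-level critical ALE score is computed once from the observed
dataset and reused across permutations. This is the convention of the
field's reference implementations and cuts the Monte Carlo cost by an
order of magnitude; `fwe_max_cluster_null(..., recompute_null = TRUE)`
runs the literal variant, and the two agree on the toy problems in the
test suite.

The permutation count default is 1000 (the source analyses do not state
one); the packaged tests and the acceptance script use 100–200, which
is enough to place the empirical family-wise error rate inside a wide
Monte Carlo band (the suite checks [0.01, 0.12] at nominal 0.05 over 40
noise-only replicates).

### Conjunction, volume matching and region tables

Conjunction uses the minimum statistic under the conjunction null: a
voxel survives only if significant in every input network, and its value
is the minimum of the retained ALE scores. The same 100 mm^3 floor is
applied to conjunction clusters. Overlap percentages between two
networks are reported both from the raw intersection and from the
volume-filtered conjunction, since headline percentages in the
literature do not always say which is meant; the denominator is the
first network (conventionally the imagery-analogue one) and rounding is
half away from zero to one decimal, matching how such tables are
printed.

Volume matching reduces a larger network to a target voxel count by
raising its retention threshold. The sweep runs over the *exact sorted
distinct* retained values (plus the empty-network candidate) rather than
a fixed increment: this is deterministic, and it attains the optimum of
any fixed-step scheme. Ties in |count - target| resolve toward the
smaller volume — consistent with published matched volumes landing just
under their target. When all retained values are distinct (generic for
continuous ALE scores), the match is exact.

Region tables intersect each atlas template with the imagery-analogue
network (the percentage denominator), then with each comparison network.
Templates are user-supplied NIfTI masks; when their grid differs from
the analysis grid they are resampled by nearest neighbour only — label
volumes must never be interpolated — and in the orchestrated pipeline a
grid mismatch is an error unless resampling is explicitly enabled. The
DLPFC-style merged template is the voxelwise union of its parts
(`merge_templates()`). The percentage denominator is the region-by-
imagery volume: the published tables' own numbers (e.g. 640/649 = 98.6%)
fix that convention unambiguously even though the surrounding prose is
loose about it.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure of a paradigm
dataset: per experiment, a subject count drawn uniformly from a range
(default 8–25, bracketing the per-experiment averages of the real
datasets), each planted convergence locus reported with probability
`reporting_probability` (default 0.8) at the locus plus isotropic
Gaussian jitter (default 2 mm), and uniform noise foci at in-mask voxel
centres (default 5–15 per experiment). Noise placement on the discrete
voxel-centre set matches the relocation null exactly, which is what
makes the enumeration oracle and the calibration experiments clean.
Jittered ground-truth foci are snapped back to the nearest in-mask voxel
centre when they fall outside the mask.

`generate_paradigm_trio()` mirrors the three-dataset design: an imagery
locus set, a working-memory set sharing a configurable fraction of it
(default 0.6) and an execution set sharing another fraction (default
0.3), with experiment counts `c(execution = 7, imagery = 13,
working_memory = 20)`. These preserve the real datasets' ordering
(execution smallest, working memory largest) at a desk scale chosen so
a full three-network analysis with permutation inference runs in
seconds; the working-memory count is reduced below a strict 1/10
scaling of the real 492 because the sequential null integration grows
linearly in experiments and nothing in the directional-recovery
question needs the extra bulk. Planted loci are kept at least 14 mm
apart (configurable) so their clusters stay separable at kernel
bandwidths around 10 mm FWHM.

Default test masks are 30^3-voxel spheres at 2 mm. What passing these
desk-scale tests shows: the null is calibrated against its own
generative assumptions, the inference recovers planted convergence, and
the overlap machinery recovers a planted ordering of shared structure.
What they cannot show: behaviour under the spatial inhomogeneity of
real grey matter, anisotropic smoothness, correlated foci within
papers, or publication bias — none of which the generator models.

## Numerical choices and degenerate inputs

* Coordinates stay at full float precision; discretisation happens only
  at kernel evaluation (nearest voxel centre).
* The Talairach-to-MNI conversion uses the SPM-variant affine by
  default (the source literatures are SPM-era); the FSL and pooled
  variants are selectable, and the constants live in a plain-text data
  file. Foci already in MNI pass through a converter unchanged, with a
  warning rather than an error.
* `voxel_alpha = 1` and `cluster_alpha = 1` are honoured as degenerate
  thresholds (everything in-mask passes; no Monte Carlo is run),
  which the tests use to pin the deterministic parts of the pipeline.
* Foci outside the analysis mask are retained for kernel computation
  (their Gaussian mass may reach in-mask voxels); out-of-grid
  coordinates are flagged, never silently dropped.
* An empty thresholded network is a valid result: overlap percentages
  against it are NaN with a warning, and the pipeline skips volume
  matching rather than failing.
* Connected-component labelling, kernel placement and the histogram
  convolution are implemented in C++ (Rcpp); the R reference
  implementation of kernel placement and an igraph-based labelling
  oracle remain in the package/tests as independent cross-checks.

## Problem sizes in the shipped checks

The test suite and the acceptance script run, per invocation: 20
calibration replicates (12 experiments each), 10 recovery runs and 40
noise-only runs at 200 permutations, 20 trio runs at 100 permutations,
all on the 30^3 sphere. These sizes put the stochastic checks'
Monte Carlo error comfortably inside their acceptance bands while
keeping a full run in the minutes range on a single CPU.

## Known limitations

* The analytic null treats voxels as exchangeable within the mask;
  real ALE implementations share this assumption, but it means edge
  voxels (whose kernels are clipped by the mask) are very slightly
  conservative.
* Volume matching applies a single global threshold per network; it
  does not rebalance cluster-by-cluster, and the 100 mm^3 floor is not
  re-applied after matching (matched networks can in principle contain
  sub-floor fragments of formerly larger clusters).
* Anatomical labelling of peaks is out of scope; regions enter only as
  user-supplied template masks.
* The per-paradigm reference tables shipped with the package are
  printed summary numbers for checking derived arithmetic; recomputing
  the full published networks requires the deposited coordinate data,
  the exact grey-matter mask and full permutation budgets.
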