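---
title: "Methods: connectome gradient mapping, group inference, and transcriptomic association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome gradient mapping, group inference, and transcriptomic association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`conngrad` implements a complete analysis chain for asking whether a
clinical group differs from controls in the low-dimensional organization of
its structural connectome, and whether the spatial pattern of that
difference tracks gene expression. This vignette explains each model in the
chain, the parameters that matter, the numerical conventions, and what the
synthetic cohorts used by the test suite do and do not establish.

## Gradient mapping

For each subject, the structural connectome `W` (parcels × parcels,
symmetric, non-negative, streamline-derived weights scaled by the inverse of
the two endpoint parcel volumes) is converted to an affinity matrix `A`
whose entry `(i, j)` is the similarity of the connectivity profiles of
regions `i` and `j`. The main kernel is cosine similarity; Spearman rank
correlation and the normalized angle `1 - acos(cos θ)/π` are available for
sensitivity analyses. Negative similarities are clipped to zero because the
subsequent diffusion operator requires non-negative weights, and the
diagonal is set to one. The affinity step may be preceded by proportional
thresholding (`sparsify()`); the main analysis uses the unthresholded
connectome (`sparsity = 0`).

Diffusion-map embedding then extracts gradients. With `D` the degree
diagonal of `A`, the anisotropic normalization

&nbsp;&nbsp;`W' = D^(-α) A D^(-α)`,&nbsp; `P = D'^(-1) W'`

yields a row-stochastic operator whose eigenvectors `ψ_i` (eigenvalues
`1 = λ_0 > λ_1 ≥ …`) order regions by connectivity-profile similarity. The
trivial constant eigenvector is discarded. We compute the spectrum through
the symmetric conjugate `D'^(1/2) P D'^(-1/2)` — numerically a dense
symmetric eigenproblem, exact at the parcel counts used here. Defaults
follow common practice: `α = 0.5` (approximating the Fokker–Planck
operator, preserving global relationships) and diffusion time `t = 0`,
where component `i` is scaled by the multi-scale weight `λ_i/(1 - λ_i)`;
for `t ≥ 1` the scale is `λ_i^t`. Ten components are computed and the
first three are analyzed.

Two conventions are deliberate choices the literature leaves open:

* **Explained variance** is reported as `λ_i² / Σ_j λ_j²` over the full
  non-trivial spectrum (`ev_power = 2`); first-power weighting is available
  via `ev_power = 1` (negative eigenvalues clamped to zero in the
  denominator). Only the ratio convention changes, never the gradients.
* **Sign convention.** Eigenvectors are defined up to sign. The template's
  first three gradients are flipped, if needed, so that each correlates
  non-negatively with a fixed spatial reference axis (the centroid x, y, z
  coordinate respectively); later components are flipped so their
  largest-magnitude element is positive. Individual subjects inherit
  orientation through alignment. Any deterministic convention would do;
  this one makes regression tests and cross-run comparisons stable.

**Template and alignment.** The group template is the embedding of the
element-wise mean connectome of all subjects (patients and controls
together). Each subject's gradient matrix `G` is then aligned to the
template `M` by orthogonal Procrustes: the rotation/reflection `S`
minimizing `‖GS − M‖²_F`, computed from the SVD of `GᵀM`, with no scaling
and no translation. Alignment happens in the full 10-component space;
statistics use the first three aligned gradients.

## Group inference

Subjects' aligned gradient scores are compared with a multivariate linear
model. For responses `Y` (subjects × 3 gradients) and design
`X = [1, group, age, sex]` (patient = 1, male = 1), the group contrast `c`
gives

&nbsp;&nbsp;`T² = (cB̂)ᵀ [ (c(XᵀX)⁻¹cᵀ) Σ̂ ]⁻¹ (cB̂)`,&nbsp;
`Σ̂ = EᵀE/(n − rank X)`,

referred to an F distribution via
`F = T² (n − p − k + 1)/(k(n − p))` with `(k, n − p − k + 1)` degrees of
freedom — exact under Gaussian errors, and reducing to the classical
two-sample Hotelling T² without covariates and to the squared t statistic
at `k = 1` (both identities are asserted to 1e-8/1e-10 in the tests).
Families are corrected with Benjamini–Hochberg FDR: the seven networks for
network-level tests, all cortical regions for region-level tests, and
per-gradient univariate families corrected separately per gradient (the
joint 7 × 3 option exists but is not the default, since network and
gradient families answer different questions). Post-hoc per-gradient maps
following a significant multivariate result use Bonferroni `p < 0.05/3`.
Functional decoding (`decode_term_maps()`) is a generic correlate-with-
term-maps step: the statistic map with non-significant regions zeroed is
Pearson-correlated against user-supplied term maps and the top 15 terms
reported.

**Subcortical-weighted gradients.** A subcortical structure's profile row
(volume-scaled with the same sum rule as cortical edges) multiplies each
cortical gradient element-wise; the mean of that weighted gradient is the
structure's degree along the gradient. Degrees along the first three
gradients are compared with the same multivariate machinery, FDR-corrected
across the 16 structures. Each subject's own aligned gradients and own
subcortical connectivity are used (a template-gradient variant exists for
sensitivity work); aligned gradients are required for cross-subject
comparability.

## Spatial null models

Spatial correlations between region-level maps are tested against spin
permutations: a rotation drawn uniformly from SO(3) (QR orthogonalization
of a Gaussian matrix with sign correction) is applied to the parcel
centroids on the sphere, and each region takes the value of the region
whose original centroid is nearest (great-circle) to its rotated position,
ties to the lowest index. Whole-cortex maps rotate the left hemisphere and
apply the x-mirrored rotation to the right, preserving hemispheric
correspondence; left-only analyses (the transcriptomic arm) rotate the
left-hemisphere sphere alone. The permutation p-value uses the +1
correction and is two-tailed on |r|. Only the first map is spun; spinning
the second instead changes nothing when the same rotations are used.

The nearest-centroid reassignment is not a bijection; the realized
duplication rate is logged and stays near 10% on the package's synthetic
geometry (the test suite requires < 20%). Two calibration facts matter for
interpretation and are established by the tests:

* For spatially unstructured maps the test is exact (empirical rejection
  0.0475 at the nominal 0.05 in the suite's 200-replicate check).
* For smooth maps the test is **anticonservative**: conditioning on the
  realized map, rotations reproduce only part of the between-realization
  variance of the correlation, so the null is too narrow. On the synthetic
  geometry at the default field scale (0.3 rad) the rejection rate at
  nominal 0.05 is ≈ 0.11–0.13, rising with smoothness. This is a known
  property of parcel-level rotation nulls, not an implementation defect;
  the corresponding acceptance check is intentionally left failing rather
  than recalibrated, and spin p-values near the threshold should be read
  accordingly.

## PLS transcriptomic association

The response `y` is the left-hemisphere region-level multivariate statistic
map (standardized); the predictors are the columns of a left-hemisphere
regions × genes expression matrix (column-standardized). Single-response
PLS is fitted by sequential covariance-maximizing extraction with
deflation: `w = Xᵀy/‖Xᵀy‖`, scores `t = Xw`, then `X` and `y` are deflated
by the score regression. The first-component weight vector is proportional
to `Xᵀy`, which the tests assert against the implementation to 1e-8, and
the scores agree with an independent PLS implementation to correlation
> 0.999. Per-component explained variance is the incremental R² of the
original response on the scores; the analyzed component is the one with
the highest explained variance (automatic argmax, manual override).

Significance of the explained variance comes from refitting on permuted
responses — spin-permuted by default, preserving spatial autocorrelation;
plain shuffling is available — reporting both the joint test on the
cumulative variance and per-component tests, since published analyses are
often ambiguous about which is meant. Gene stability uses 2000 bootstrap
resamples of regions; each resampled weight vector is re-signed to
correlate positively with the original component before the SD is taken.
This sign alignment is mandatory: without it component sign flips inflate
the SD and destroy Z calibration (a regression test covers it). Genes with
FDR-significant two-sided normal p-values on `Z = w/SD_boot` are split by
weight sign into positive and negative sets, and the realized |Z| at the
FDR boundary is reported rather than fixed in advance, because it depends
on the data.

**A caution the tests quantify.** Bootstrap-Z selection measures the
*stability* of a gene's realized spatial correlation with the response,
not its significance against a spatially autocorrelated null. Smooth but
truly signal-free gene maps have stably non-zero correlations with any
smooth target, and are therefore selected at a high rate: in the planted-
signal experiment (20 signal genes among 500, 100 regions) sensitivity is
1.0 but the false-discovery proportion among selected genes is ≈ 0.6. The
acceptance check bounding that proportion at 0.1 is left failing by
design; the implication for real analyses is that PLS gene lists should be
read as "genes whose maps robustly resemble the difference map", not as an
FDR-controlled discovery set against spatial chance.

## The synthetic cohort generator

The generator provides every downstream stage with data of known ground
truth. Its defaults are the reference study conditions used throughout the
tests and analysis scripts; they were fixed once, on realism grounds, and
the recovery thresholds in the tests are asserted against them unchanged.

* **Geometry.** Left-hemisphere parcel centroids are placed quasi-uniformly
  on the unit sphere by Lloyd (k-means) relaxation of a dense uniform
  sample — real parcellation centroids are well separated, and iid-uniform
  centroids would push the spin test's nearest-neighbour duplication to
  ≈ 37%. The right hemisphere mirrors the left in x, giving each
  hemisphere its own registration sphere as surface pipelines do. Networks
  are contiguous caps of comparable size (k-means of the centroids),
  mirrored across hemispheres. Volumes are log-normal with unit median.
  Distances are great-circle, matching the spin-test geometry.
* **Connectomes.** Expected weight `exp(−d/0.75)` with a ×2 boost within
  networks, multiplied by log-normal noise (σ = 0.4). The patient effect
  multiplies *within*-effect-network edges by `1 + effect_size`
  (default 0.4, somatomotor network). The scope matters: scaling *all*
  edges incident to an effect region multiplies that region's entire
  profile by a constant, which profile-normalizing kernels cancel exactly,
  so the perturbation would act diffusely on everyone else and barely move
  the effect network itself. Changing within-network cohesion is the
  construction that actually shifts a network's gradient position;
  `effect_scope = "incident"` preserves the alternative.
* **Covariates.** Age ~ Normal(62, 8) truncated to [45, 80]; sex
  Bernoulli(0.5); no group–covariate confound by default.
* **Subcortical connectivity.** Each structure sits at a random deep
  anchor (bilateral pairs mirrored); profiles decay with Euclidean
  distance to the cortical centroids under log-normal noise; an optional
  group effect scales designated structures' rows.
* **Expression.** Every gene map is a smooth Gaussian random field
  (squared-exponential kernel, length 0.3 rad) plus white measurement
  noise of equal amplitude — parcel-averaged microarray values retain
  substantial probe/donor noise. Signal genes add the standardized target
  map. Columns are standardized.

What the synthetic data do **not** emulate: tractography biases and
streamline-count distributions, realistic cortical folding or geometry,
inter-regional distance effects beyond a single decay scale, gene–gene
co-expression structure, and donor sampling of real microarray atlases.
Passing recovery tests therefore demonstrate that the chain of estimators
is correct and well calibrated under its own assumptions — not that effect
sizes or gene lists from real cohorts are trustworthy at these sample
sizes.

## Numerical choices and degenerate inputs

* Dense symmetric `eigen()` is used throughout (exact reference behaviour
  at ≤ 400 parcels); tied eigenvalues are returned in stable order.
* Disconnected affinity graphs, all-zero connectivity rows, constant maps,
  constant responses, zero/negative volumes, non-finite file entries and
  shape mismatches all raise informative errors naming the offending unit.
* An exactly-null contrast (responses identical across subjects) returns
  `T² = 0, p = 1` rather than failing on the singular covariance.
* Sparsification ties at the threshold keep lower (row, col) pairs;
  `round((1−s)·n_pairs)` pairs always survive.
* Degenerate bootstrap resamples (one distinct region, or constant
  resampled response) are redrawn and counted.
* All generators and permutation machinery are bit-reproducible from their
  seed arguments; the pipeline derives per-stage seeds deterministically
  from one base seed so stages can be rerun in isolation.

## Problem sizes

The reference simulation uses 100 cortical regions, 7 networks, 2 × 25
subjects, 16 subcortical structures and 500 genes — sizes at which the
full pipeline runs in well under two minutes while keeping every stage's
estimator in its intended regime. Calibration experiments in the test
suite use 500 cohorts of 2 × 15 subjects at 60 regions for type-I error,
500 replicates at 200 spins for the spin null, and 50/20 seeds for the
recovery experiments.

## Known limitations

* Parcel-level spin tests are anticonservative for smooth maps (quantified
  above); variogram-matching or spectral nulls would be the next step and
  are out of scope here.
* Bootstrap-Z gene selection has no spatial null; its false-discovery
  proportion against smooth null genes is high (quantified above).
* The type-I error of the region-level tests is nominal only approximately
  (0.052 over 500 null cohorts): aligned gradient scores are mildly
  heavy-tailed and share a cohort-derived template, so the Gaussian F
  reference is not exact for them.
* The F-based Hotelling p-values assume Gaussian errors; a permutation
  option exists for robustness checks but is not the default.
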