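---
title: "MR radiomics for medulloblastoma subgroups: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR radiomics for medulloblastoma subgroups: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbRadiomics)
```

# Scope

`mbRadiomics` implements a complete MR radiomics analysis for pediatric
medulloblastoma cohorts with four molecular subgroups (WNT, SHH, Group 3,
Group 4): image harmonization, a 253-feature radiomics catalog, k-NN
imputation of modality-wise missing features, rank-based subgroup
comparison, Cox proportional-hazards prognostication, and a nested
leave-one-out SVM subtype classifier. Because clinical MRI of this kind is
rarely shareable, the package ships a synthetic multimodal cohort generator
whose statistical structure matches what the analysis assumes; every stage
is tested against it. Molecular subgroup labels are treated as given inputs
(their derivation from expression data is out of scope), as are the tumour
masks.

# The synthetic cohort generator

Each subject has up to five modalities (CET1, T1WI, T2WI, FLAIR, ADC). The
CET1 reference volume lives on a 0.75 x 0.75 x 3.0 mm grid (default
32 x 32 x 16 voxels); its tumour mask is a randomly perturbed ellipsoid,
constrained to a single 26-connected component strictly inside the grid with
50–5000 voxels. Tumour texture is a Gaussian random field: white noise
convolved with an isotropic Gaussian kernel whose standard deviation is the
subgroup's *correlation length* in millimetres (respecting the anisotropic
spacing), normalized to unit variance inside the mask, plus a subgroup
intensity shift and i.i.d. voxel noise. Correlation length is the single
texture knob: short correlation means neighbouring voxels are nearly
independent, driving up GLCM contrast and dissimilarity and driving down
IDN/IDMN; this direction is verified by test. Default correlation lengths
(1.2, 2.5, 4.5, 8 mm) and noise SD 0.25 were fixed once as plausible
within-tumour texture scales relative to the 0.75 mm in-plane voxel; the
response of texture features saturates once the correlation length exceeds
the tumour diameter, so benchmarks that need strong separation use lengths
inside the sensitive 0.4–8 mm band.

Non-CET1 modalities are deliberately generated on a coarser grid
(1.5 x 1.5 x 3 mm) and their content is shifted by a rigid world offset
(default +3.0, −1.5, 0 mm) that is *not* recorded in the NIfTI header, so
harmonization has genuine registration work to do. Each non-CET1 modality is
dropped independently with its configured probability (default 0.1,
emulating incomplete scan protocols); CET1 is never dropped.

Survival is exponential with rate
$\exp(\beta \cdot x) / \text{scale}$, administratively censored — the
simplest law satisfying proportional hazards exactly. The planted covariate
$x$ is a scalar texture summary of the subject's CET1 field (mean absolute
difference of x-neighbouring tumour voxels), so short-correlation tumours
can be made to carry higher hazard.

A second, feature-level generator (`simulateFeatureCohort()`) draws the
253-column feature table directly, with per-subgroup signature columns,
block missingness and feature-linked survival. The calibration suites (null
distributions at n = 400, 200-replicate uniformity checks, permutation
nulls) need sample sizes where voxel-level simulation adds nothing but
runtime; image-level structure is exercised wherever images are the point.

What the generator does *not* emulate: anatomy (no brain, no skull),
scanner-specific intensity non-uniformity or bias fields, nonrigid motion,
and realistic inter-feature correlation beyond what the shared texture field
induces. Passing tests therefore demonstrate correctness of the pipeline's
computations and calibration of its statistics under the stated model — not
clinical performance on real MRI.

# Harmonization

All volumes are resampled to 0.75 x 0.75 x 3.0 mm. The output grid keeps
the input origin and has `ceiling(extent / target)` voxels per axis
(documented extent convention; a 64 x 64 x 20 volume at 1.5 x 1.5 x 3 mm
becomes 128 x 128 x 20). Interpolation is trilinear for images and
nearest-neighbour for masks; sampling clamps at the border so a constant
volume stays exactly constant.

Non-CET1 modalities are registered to the resampled CET1 with a
six-parameter rigid transform maximizing mutual information on a 32 x 32
joint histogram, estimated over a regular ~8000-voxel subsample of the fixed
grid. The optimizer is a multi-start over coarse translations (±8 mm, 4 mm
steps) followed by Nelder-Mead refinement of all six parameters; the
identity transform is always a candidate, so the returned score never falls
below it. The planted generator offset is recovered within one voxel per
axis (tested). Rotation angles are parameterized about the fixed volume's
centre.

Intensity normalization fixes the "standardized ranges" requirement
concretely: within the tumour mask, voxels are z-scored by the region mean
and SD, clipped to ±3, and mapped affinely from [−3, 3] to [0, 1]; the
region mean lands at 0.5 and anything at or beyond ±3 SD saturates at 0/1.
Outside the region voxels are set to 0. A bounded range is required by the
equal-width discretization downstream; a zero-variance region is an error,
not a silent pass-through.

# The feature catalog

57 distinct features; 49 (16 first-order + 22 GLCM + 11 GLRLM) per modality
over five modalities, plus 8 shape features from the mask: 253 qualified
features per subject, with `NA` marking features of absent modalities.

First-order statistics use population moments (kurtosis non-excess) and a
32-bin equal-width histogram over the masked range for entropy/uniformity.
The 16-name list is the Aerts-style set plus the 10th/90th percentiles and
is configurable at the catalog level.

Texture features are computed on gray levels discretized into `Ng = 32`
equal-width bins over the masked intensity range (the minimum maps to
level 1, the maximum to level `Ng`, a constant region entirely to level 1).
GLCM and GLRLM pool counts across the 13 unique voxel-index offsets at
Chebyshev distance 1 *before* normalization — per-direction averaging was
rejected because thin masks can have directions with almost no pairs. Both
pair orders are counted, so the GLCM is symmetric by construction. All logs
are base 2 with 0·log 0 = 0. IDN/IDMN use `Ng` in their normalizing
denominators. Sum variance is centred on the sum average (the convention of
modern radiomics implementations; the classical text centres on sum
entropy). Run percentage divides the pooled run count by
(number of directions) x (mask voxels) so it stays in (0, 1]. Directions are
voxel-index offsets, not millimetre offsets, on the anisotropic grid;
features are invariant to 90° in-plane rotation on isotropic grids (tested)
but not on anisotropic ones.

Shape features derive volume from the voxel count times voxel volume and
surface area from a marching-tetrahedra iso-surface at level 0.5 of a mildly
smoothed (0.7 voxel sigma, capped by the mask's per-axis extent) binary
field: interpolating mesh vertices on the smoothed field removes the voxel
staircase bias that makes face-counting overestimate areas by ~50%. On a
digital ball of radius 10 the area is within ~1% of 4πr² and sphericity is
0.99. The smoothing slightly rounds sharp corners (a cube's area reads ~12%
low) and very thin slabs remain underestimated — a known limitation recorded
here; all shape features are exactly translation-invariant (the mask is
cropped to its bounding box with a fixed margin before meshing). The maximum
3D diameter is the largest pairwise world-space distance between surface
voxel centres.

# Missing features and imputation

Subjects missing a modality lack that modality's 49 features. k-NN
imputation (k = 3 by default, matching the smallest subgroup size of 7)
fills each missing cell with the unweighted mean of the k nearest subjects
observed at that column. Distance is Euclidean over the columns observed in
both subjects, each column z-scored by its observed mean/SD (unscaled
mixed-unit features would let high-magnitude features dominate), rescaled by
`sqrt(p / shared)` so subjects sharing few columns are not spuriously close.
Ties break by subject order; observed cells are never altered; a complete
table is returned unchanged. A column observed in fewer than k subjects is
an error naming the column. Distance weighting is available but off by
default (the unweighted mean is the plainest reading of k-NN imputation).

# Subgroup comparison

Per feature: Kruskal-Wallis omnibus (tie-corrected, delegated to
`stats::kruskal.test`) and Dunn's multiple-comparisons test at α = 0.05 —
pairwise z statistics from differences of mean pooled ranks with
tie-corrected variance, two-sided p-values Bonferroni-adjusted within the
feature's 6 pairs (raw p-values available by flag; whether the original
analysis adjusted is not stated, so both are exposed and the default is the
conservative one). "Discriminates k groups" is operationalized as the size
of the largest clique of mutually separated subgroups. No correction is
applied across the 253 features; both facts are recorded in the output
metadata. Note that with subgroup sizes around 7–12, rank statistics bound
the achievable pairwise z, so level-4 discriminability generally needs
larger groups — the planted-effect tests use 20 per subgroup.

# Survival prognostication

Cox fits go through `survival::coxph` with Efron tie handling (day-resolution
ties are expected). The stage screens all features univariately at α = 0.05
(Wald), refits the survivors jointly (ridge-stabilized with a flag if the
candidate set is collinear), designates the multivariate-significant feature
with the smallest p as the prognosticator, dichotomizes it at the third
quartile (linear-interpolation / R type-7 quantile; the high-risk group is
*strictly greater* than the threshold), and reports Kaplan-Meier medians
(earliest time with survival ≤ 0.5, `NA` when not reached), the log-rank
(Mantel-Cox) chi-square and p, and the HR with 95% CI from a one-covariate
Cox fit on group membership. Complete separation of the curves leaves the HR
unbounded; it is reported as `NA` rather than a fabricated number.

# Subtype classification

The classifier is a linear-kernel one-vs-rest soft-margin SVM over four
classes (per-class AUCs imply one-vs-rest; the kernel is configuration —
the cost grid is {0.01, 0.1, 1, 10, 100} by default). Feature selection is
one of: mRMR (MID difference variant, mutual information on 4
equal-frequency bins), sequential forward selection, or sequential backward
elimination, the latter two scored by explicit inner leave-one-out SVM
accuracy. SFS fills to the target size (so with m = all features it returns
a full ordering); SBE stops early only when every removal strictly hurts.
For the sequential algorithms a Kruskal-Wallis pre-filter (default top 30,
computed inside the decoding set) bounds the otherwise quadratic search.

Evaluation is nested leave-one-out: the outer loop holds out one subject;
standardization statistics, the pre-filter, feature selection and the cost
parameter (inner LOO) are all computed on the remaining decoding set only.
Outer predictions pool into overall accuracy and per-class one-vs-rest AUC
(rank/trapezoidal, ties counted half). Classes with a single member flag
their outer fold rather than silently dropping it. Everything is
deterministic for a fixed subject order — the inner CV is an explicit R
loop because libsvm's built-in cross-validation shuffles folds with an RNG
that cannot be seeded from R.

Subjects with missing modalities are handled upstream by imputation by
default; restricting the feature scope to one modality only requires
completeness within that scope, so a deliberately CET1-only cohort can be
classified without imputing the absent modalities.

One property of leave-one-out worth knowing when reading permutation nulls:
with balanced classes and label-independent features, LOO accuracy is
systematically *below* chance (holding out a subject makes its class the
minority of the decoding set, and a no-signal classifier drifts to the
majority). The leakage check therefore asserts that permuted-label accuracy
does not *exceed* chance plus binomial noise; information leaking into the
outer loop would push it above.

The model grid evaluates {five modalities + all} x {mrmr, sfs, sbe} and
reports the accuracy matrix, the winning cell and the winner's per-class
AUCs. With one-vs-rest linear classifiers, a single ordinal effect axis
(e.g. monotone correlation lengths) makes *middle* classes hard to separate
by construction; per-subgroup signatures (distinct feature blocks, or
several texture features with differently-shaped responses) are what the
classifier benchmarks rely on.

# Numerical choices and degenerate inputs

* Discretization: `Ng = 32` equal-width bins (configurable); constant
  region = level 1 everywhere; GLCM of a constant tumour is the point mass
  P(1,1) = 1 with entropy 0, energy 1, IDN = IDMN = 1.
* Registration: 32-bin joint histogram; −MI minimized by Nelder-Mead
  (parameter scaling 0.05 rad / 1 mm); degenerate (constant) images are an
  error.
* Cox: Newton iteration inside `coxph` (iter.max 50); non-convergence and
  monotone likelihood surface as errors with the covariates named.
* Ties: Dunn variance uses the standard `sum(t^3 - t)` correction; k-NN
  donor ties and selection-score ties break by index order; the rank AUC
  counts ties as 1/2.
* Quantiles are linear-interpolation (R type 7) everywhere.

# Problem sizes used by the shipped tests

The test and acceptance suites run the full image pipeline at 32 x 32 x 16
(and 24 x 24 x 12) grids with 8–56 subjects, the statistical calibrations at
n = 400 with 200 replicates, the power suites at n = 80–100 over 10–20
seeds, and the classifier benchmarks at 20–56 subjects. These sizes were
chosen so the whole suite is a desk-scale computation while every claim is
still measured, not asserted.

# Known limitations

* The surface mesh underestimates area for masks a single voxel thick along
  one axis, and shape features inherit the smoothing's corner rounding.
* MI registration is tested for the generator's translation-dominated
  offsets; large rotations would need a rotation multi-start.
* Mutual information estimates in mRMR use plug-in entropies on 4 bins and
  inherit their small-sample bias; this affects selection order among
  near-uninformative features only.
* The Dunn step's Bonferroni adjustment is within-feature; across-feature
  multiplicity is reported, not corrected.
* Clinical numbers from any particular patient cohort (AUCs, accuracies,
  survival medians, hazard ratios, Q3 thresholds) are properties of that
  cohort; the package reproduces the *procedure*, and its tests verify
  calibration and planted-effect recovery on synthetic data only.
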