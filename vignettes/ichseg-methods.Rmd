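---
title: "Methods: unsupervised haematoma and oedema segmentation from T2* GRE and FLAIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised haematoma and oedema segmentation from T2* GRE and FLAIR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous intracerebral haemorrhage (SICH) leaves a blood collection — the
haematoma — surrounded by a variable rim of perihaematomal oedema. Both
volumes are prognostic and both are wanted as trial outcome measures, but
manual delineation is slow enough that it is rarely done. In the acute and
early-subacute window the haematoma is strongly hypo-intense on T2*
gradient-recalled-echo (GRE) imaging while the oedema is hyper-intense on
FLAIR, with high contrast between the two. `ichseg` exploits this contrast
to segment both structures from co-registered T2* GRE and FLAIR volumes in a
training-free, fully unsupervised way: there is no model fitting beyond
robust statistics computed per case, so nothing is learned from, or biased
towards, any particular cohort.

The package assumes registration has already happened: all four inputs (T2*
GRE, FLAIR, an anatomical label map, and a small-vessel-disease probability
map) share one voxel grid. Grid mismatches are a fatal error, never silently
resampled.

## Anatomical masks

Five masks are derived from a MALP-EM-style parcellation of the subject's
anatomy (an integer label map; 0 = background, 18 = CSF):

* **whole-brain** — the intersection of the binarised label map with the
  nonzero supports of the T2* GRE and FLAIR images (each support first
  regularised by one iteration of *hole-filling-closing*, defined below),
  then eroded twice with the 3×3×3 kernel. The erosions pull the mask away
  from the skull and the brain surface, where both sequences misbehave.
* **susceptibility** — regions prone to susceptibility artefact on T2* GRE
  (skull base, cortical surface; 32 labels, shipped as
  `susceptibility_labels()`).
* **lesion** — subcortical territory where spontaneous haemorrhage is
  common (basal ganglia, thalamus, white matter; `lesion_labels()`).
* **ventricle** — the ventricular system (`ventricle_labels()`).
* **WM-GM** — the whole-brain mask minus CSF-labelled voxels and the
  ventricle mask. White and grey matter are iso-intense on both sequences,
  so any strong hypo- or hyper-intensity inside this mask is a lesion
  candidate.

Label sets are configuration, not code: a YAML file can override any of
them, which also lets reduced catalogues (such as the phantom's four-label
map) or maps carrying an extra lesion label flow through unchanged.
*Hole-filling-closing* with *n* iterations is *n* dilations with the full
3×3×3 (26-neighbour) box kernel, filling of interior cavities (background
regions with no 6-connected path to the grid border, in full 3-D), then *n*
erosions. The operator is kept extensive — the input is always a subset of
the output — including for shapes touching the grid border, by unioning the
result with the input.

## Robust outlier detection

Intensity thresholds are estimated per case with the univariate Minimum
Covariance Determinant (MCD) estimator on the intensities inside the brain
mask, independently for each sequence. With support fraction 0.6 the
estimator finds the 60% of voxels with minimal variance, so it resists up to
40% of outlying voxels — far more than any plausible lesion load. In one
dimension the minimal-variance h-subset is always a contiguous window of the
sorted sample, so `mcd_location_scale()` computes the estimator *exactly* by
a sliding window over the order statistics in O(n log n); no iterative
approximation is involved, and the unit tests confirm equality with
exhaustive subset search. The window's standard deviation is multiplied by
the asymptotic normal consistency factor for the support fraction
(`sqrt(alpha / pchisq(qchisq(alpha, 1), 3))`, about 2.159 at 0.6), making it
unbiased for the clean-tissue scale. Outliers are then declared by the
chi-squared rule at the 0.975 quantile: `T_low/T_high = mu ± 2.2414 sigma`.
Both the support fraction and the quantile are configurable
(`pipeline_params()`); above 2×10⁵ in-mask voxels the fit uses a seeded
uniform subsample of that size, which changes the estimate negligibly at
these sample sizes while bounding the sort cost.

A consequence worth stating: by construction about 1.2% of perfectly normal
tissue sits beyond each threshold, so the hypo/hyper maps always contain
scattered single-voxel speckles. Every downstream stage is designed to be
indifferent to them (component scoring, geodesic reachability, morphology).

## Haematoma segmentation

The T2* hypo-intensity map within WM-GM is split into 6-connected components
`C_i`. Blind acceptance of the largest would fail in two ways: susceptibility
artefacts create hypo-intense regions far from any haematoma, and blooming
makes the haematoma look larger than it is. Each component is therefore
scored by `w_i * S(C_i)` where

* `w_i = o_i^2 (l_i + 1) / (s_i + 1)` — `o_i` is the overlap with the FLAIR
  hyper-intensity map (oedema ringing is the haematoma's signature; a
  component with `o_i = 0` scores zero outright), `l_i` the overlap with
  the lesion mask (rewarding haemorrhage-prone territory), `s_i` the
  overlap with the susceptibility mask (penalising artefact territory);
* `S(x) = |x|^3 / |B(x)|^2` — the volume times the squared extent relative
  to the axis-aligned bounding box, a surrogate for solidity and roundness.
  A component filling its box scores its own volume; sparse or elongated
  shapes are penalised quadratically.

The winning component still carries the bloom, so its true extent is read
off FLAIR, where blooming is absent: voxels of the component with FLAIR
intensity strictly below a threshold `H` are kept. `H` is the mean FLAIR
intensity `mu` inside the component — unless heavy blooming has pulled in
enough normal tissue to make the distribution left-skewed (`mu` below the
median `nu`), in which case `H = mu + 6 (mu − nu)`, which sits `2k` standard
deviations below the mean with `k = 3 (mu − nu) / sigma` (Pearson's second
skewness coefficient). Mean, median and standard deviation use the
population convention; at component sizes of 10³–10⁶ voxels the distinction
from the sample convention is far below any threshold's sensitivity, and
fixing one convention keeps runs bit-reproducible.

Thresholding can leave thin accidental bridges between the haematoma and
unrelated structures. A *weak link* is a true voxel whose 26-neighbourhood
contains exactly two true voxels and those two are the opposite face
neighbours along one axis — a one-voxel axis-aligned tube interior.
Diagonal chains are deliberately not matched. All weak links are detected on
the input mask simultaneously and removed in one pass, so the result is
independent of traversal order, anti-extensive, and idempotent. Of the
remaining 26-connected components the one with maximal shape score `S` is
the haematoma candidate; 26-connectivity is the natural companion of a
removal rule defined over the 26-neighbourhood. Hole-filling-closing with 3
iterations then fills iso-intense cores (FLAIR-bright centres excluded by
`H`), and finally all ventricle-mask voxels are removed: intraventricular
blood is out of scope, and atlas ventricles are the one place where label
propagation errors would otherwise cause over-segmentation. Ties in either
argmax are broken by the deterministic component ordering (volume
descending, then lexicographically smallest voxel).

## Oedema segmentation

Oedema may extend anywhere in the brain, so the FLAIR hyper-intensity mask
for this stage uses the whole-brain mask and the scalar threshold
`base_T = T_high` from the FLAIR MCD fit. Two confounds remain:
leukoaraiosis (chronic small-vessel white-matter lesions) is also
FLAIR-hyper-intense, and unrelated bright structures may simply be far from
the haematoma. Both are handled by geography:

* `D` — the geodesic quasi-euclidean distance from the haematoma, computed
  by Dijkstra's algorithm over 26-neighbour steps with costs 1, √2, √3,
  constrained to the hyper-intensity mask. Hyper-intense voxels with no
  hyper-intense path back to the haematoma get `D = +Inf`. Distances are in
  voxel lengths by default (inputs are assumed resampled to an isotropic
  grid); a mm mode scales the step costs by the voxel spacing.
* `L = (1 + S)^2` — a weight in [1, 4] from the voxel-wise
  small-vessel-disease probability `S`, inflating the effective distance of
  probable leukoaraiosis.

The scalar threshold becomes the voxel-wise map
`T(x) = base_T (D L + lambda) / (2 lambda)`: half the scalar threshold on
the haematoma boundary, rising linearly and crossing `base_T` where
`D L = lambda`, infinite where `D` is. `lambda` (default 15) sets how fast
the evidence requirement grows with distance. The published rendering of
this formula is typographically ambiguous; the linear form above is the
reading consistent with the stated steepness role of `lambda`, the infinity
behaviour, and dimensional analysis. A squared alternative
(`base_T ((D L + lambda)/lambda)^2 / 2`, same boundary behaviour) is kept
behind `eq7_variant = "squared"` for cross-checking. Two monotonicity
properties follow directly from the linear form and are property-tested:
the pre-morphology oedema set grows (never shrinks) with `lambda`, and
never grows when the SVD map is raised voxel-wise.

Initial oedema is every brain-mask voxel with FLAIR intensity strictly above
`T(x)`; hole-filling-closing with a single iteration regularises it (only
one, because oedema surfaces are genuinely irregular and heavier closing
would fill real dents); haematoma voxels are removed so the two labels are
disjoint. Note that the division by 2 in the threshold map makes this stage
equivariant under positive *scaling* of the intensities but not under
intensity *offsets*; the haematoma stage is fully affine-equivariant.

## The phantom generator

Patient data cannot ship with the package, so validation rests on a
seedable synthetic generator, `generate_case()`. It emulates the features
the algorithm actually consumes: an ellipsoidal brain (label map, zero
padding outside), a haematoma that is T2*-hypo-intense with a configurable
susceptibility bloom margin and optional iso-intense core, FLAIR-hypo at its
true size, ringed by FLAIR-hyper oedema of configurable thickness; a
ventricle with CSF contrast and a thin CSF shell; optionally a decoy
hypo-intensity in susceptibility-labelled territory and leukoaraiosis
lesions with or without a thin hyper-intense tract connecting them to the
rim, mirrored in the SVD map.

Three generator choices deserve explanation:

* **Anatomical texture.** Tissue classes carry seeded Gaussian texture of
  sd 2 (about 2% of the tissue contrast) independent of the `noise_sd`
  parameter. Perfectly constant tissue would make any scale estimate
  degenerate (the MCD refuses constant windows), and real parenchyma is
  never constant; `noise_sd = 0` therefore means "no acquisition noise",
  not "no intensity variation". Intensity levels are arbitrary-unit, as MR
  intensities are; the defaults (background 100, T2* hypo 30, FLAIR
  haematoma 40, hyper 180) put the classes roughly 30 texture standard
  deviations apart, so the 0.975-quantile thresholds separate them cleanly
  up to noise around 10% of the contrast.
* **The decoy has no hyper-intensity by construction.** The decoy fixture
  exists to show that a larger, rounder hypo-intensity with no oedema ring
  is rejected through `o = 0`, so its FLAIR signal is set slightly below
  background (85), as in susceptibility-related signal loss — otherwise
  upper-tail texture speckles inside it would register a handful of
  overlap voxels.
* **Minimal label catalogue.** Mask construction only consumes set
  membership, so one representative label per needed region (16, 18, 23,
  10) stands in for the full 138-label parcellation.

What the phantom does *not* model: bias fields, motion, partial-volume
fading of oedema near CSF (the known failure mode of the method on real
data), anisotropic acquisition, and realistic lesion shapes. Passing the
phantom suite therefore demonstrates algorithmic correctness — each stage
does what it claims on inputs with the assumed contrast structure — not
clinical performance. The published evaluation of this class of method
against expert raters is the evidence for the latter, and those data are
not redistributable.

The shipped fixtures (`fixture_catalogue()`) cover the six designed
behaviours: clean recovery, iso-intense core filling, decoy rejection,
intraventricular exclusion, connected-vs-unreachable leukoaraiosis with SVD
weighting, and a wide-bloom case whose left-skewed FLAIR distribution forces
the corrected threshold branch.

## Numerical and reproducibility choices

* Component ordering is deterministic (volume descending, then
  lexicographically smallest voxel), so every argmax tie-break is
  reproducible.
* Strict inequalities are used exactly where the method statements say so
  (`< H`, `> base_T`, `> T(x)`); voxels exactly at a threshold are excluded.
* Erosion treats outside-grid as background; phantoms keep structures at
  least 4 voxels from the border so morphology never interacts with it.
* All randomness (MCD subsampling, phantom texture/noise) flows through
  explicit integer seeds; two runs with identical inputs, parameters and
  seeds produce bit-identical NIfTI outputs, which the test suite asserts
  byte-for-byte.
* Intensity volumes are written as float64 so write/read round trips are
  bit-exact; masks are uint8.
* Default problem sizes: unit and property tests run on 8³–24³ grids, the
  oracle comparisons on 12³–20³ grids (25 MCD samples with n ≤ 15 against
  exhaustive search in the unit suite and 200 in the validation suite; 6
  and 50 geodesic grids against Dijkstra), and end-to-end checks on 64³
  phantoms with one 128³ case — sizes at which the brute-force oracles
  remain exact yet every code path, including MCD subsampling, is
  exercised.

## Limitations

The method inherits the assumptions of its imaging window: outside roughly
day 1–6 after onset the T2*/FLAIR contrast regime changes and the intensity
model no longer holds. Haematomas whose oedema rim is absent score zero and
are reported as a distinct no-haematoma condition rather than guessed at.
Partial-volume attenuation of FLAIR near CSF can truncate oedema; the
dynamic threshold has no term for it. Registration quality is assumed, not
checked — a misaligned label map shifts every mask-derived count.
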