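# ichseg

Training-free, unsupervised segmentation of **haematoma** and
**perihaematomal oedema** from co-registered T2* gradient-recalled-echo
(GRE) and FLAIR MR volumes of acute/early-subacute spontaneous intracerebral
haemorrhage (SICH).

In the acute window the haematoma is hypo-intense on T2* GRE and the
surrounding oedema is hyper-intense on FLAIR. `ichseg` turns that contrast
into segmentations without any training data:

1. **Robust outlier maps.** Per case, a univariate Minimum Covariance
   Determinant (MCD) fit (support fraction 0.6, resisting 40% outliers)
   estimates the normal-tissue intensity location `mu` and scale `sigma` of
   each sequence inside the brain mask; hypo/hyper maps follow from the
   chi-squared cutoffs `mu ± sqrt(qchisq(0.975, 1)) * sigma`.
2. **Component selection.** Among the 6-connected T2* hypo components
   `C_i`, the haematoma maximises `w_i * S(C_i)` with context weight
   `w_i = o_i^2 (l_i + 1)/(s_i + 1)` (overlap with FLAIR hyper-intensity,
   lesion-prone and susceptibility-prone atlas regions) and shape score
   `S(x) = |x|^3 / |B(x)|^2`.
3. **FLAIR refinement.** Within the winner, voxels below the
   skewness-corrected threshold `H` (`H = mu`, or `mu + 6(mu - nu)` when the
   mean falls below the median) recover the haematoma's true, bloom-free
   extent; weak one-voxel bridges are cut, the roundest strongly-connected
   component is kept, closed (3 iterations), and ventricle voxels removed.
4. **Oedema by geodesic dynamic thresholding.** The scalar FLAIR threshold
   `T` becomes the voxel-wise map `T (D L + lambda) / (2 lambda)`, where `D`
   is the geodesic quasi-euclidean distance from the haematoma through the
   hyper-intensity mask (`+Inf` if unreachable) and `L = (1 + S)^2` weights
   a small-vessel-disease probability map so leukoaraiosis must clear a
   higher bar. `lambda = 15` by default.

Intended users: neuroimaging researchers who need reproducible haematoma and
oedema volumes (e.g. for trial outcome measures) from acute-phase MR, with
registration and atlas propagation done upstream by their usual tools.

A seedable phantom generator ships with the package, so the whole pipeline
is testable without patient data.

## Worked example

```r
library(ichseg)

case <- generate_case(phantom_spec())          # synthetic SICH case, seed 42
res  <- run_case(case$t2s, case$flair, case$labels, case$svd)
res
#> <ich_result> haematoma 1.04 mL (1039 voxels), oedema 2.38 mL (2379 voxels)
#>   FLAIR haemorrhage threshold H = 91.39 (mean branch); base_T = 104.9; lambda = 15

evaluate_segmentation(res, case$truth_haematoma, case$truth_oedema)
#> $dice_haematoma
#> [1] 1
#> $dice_oedema
#> [1] 0.9947179
#> $dice_combined
#> [1] 0.9963295
```

The printout says the 1 mm-isotropic phantom carries a 1.04 mL haematoma
and 2.38 mL of oedema; `H = 91.39` is the per-case FLAIR threshold that
separates blood from its oedema ring inside the selected component ("mean
branch" means the intensity distribution was not left-skewed, so no
correction was needed), and `base_T = 104.9` is the robust whole-brain
hyper-intensity threshold that seeds the oedema stage. Against the
generator's ground truth the haematoma is recovered exactly and the oedema
rim at Dice 0.9947. Every intermediate decision is kept in
`res$provenance` — the MCD fits, every candidate component's
`(volume, o, s, l, w, S)`, and the threshold record:

```r
res$provenance$candidates[1, c("volume", "o", "s", "l", "w")]
#>   volume   o s    l         w
#> 1   1642 603 0 1642 597409587
```

Real cases run the same way with NIfTI paths:

```r
res <- run_case("t2s.nii.gz", "flair.nii.gz", "labels.nii.gz", "svd.nii.gz",
                pipeline_params(lambda = 15), out_dir = "out/")
```

or from a shell via the thin wrapper `inst/cli/ichseg.R`
(`run`, `eval` and `phantom` subcommands; exit code 2 signals that no
haematoma was found).

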