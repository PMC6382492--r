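#' Pipeline parameters
#'
#' Collects every tunable of the segmentation pipeline with its default:
#' `lambda = 15` (dynamic-threshold steepness), MCD support fraction 0.6
#' (resisting 40% outliers), chi-squared cutoff quantile 0.975, the linear
#' threshold-map variant, the shipped atlas label sets and a fixed RNG seed
#' for the (rarely triggered) MCD subsampling step.
#'
#' @param lambda Positive steepness parameter of the dynamic threshold map.
#' @param mcd_support_fraction MCD support fraction in (0.5, 1].
#' @param mcd_cutoff_quantile Chi-squared quantile for outlier cutoffs.
#' @param mcd_subsample_size Maximum voxels used per MCD fit.
#' @param eq7_variant `"linear"` or `"squared"` threshold-map form.
#' @param label_config Label sets, see [read_label_config()].
#' @param rng_seed Integer seed.
#' @return A list of class `ich_params`.
#' @export
pipeline_params <- function(lambda = 15,
                            mcd_support_fraction = 0.6,
                            mcd_cutoff_quantile = 0.975,
                            mcd_subsample_size = 2e5,
                            eq7_variant = c("linear", "squared"),
                            label_config = read_label_config(),
                            rng_seed = 1234L) {
  eq7_variant <- match.arg(eq7_variant)
  stopifnot(lambda > 0, mcd_support_fraction > 0.5, mcd_support_fraction <= 1,
            mcd_cutoff_quantile > 0, mcd_cutoff_quantile < 1)
  structure(list(lambda = lambda,
                 mcd_support_fraction = mcd_support_fraction,
                 mcd_cutoff_quantile = mcd_cutoff_quantile,
                 mcd_subsample_size = mcd_subsample_size,
                 eq7_variant = eq7_variant,
                 label_config = label_config,
                 rng_seed = as.integer(rng_seed)),
            class = "ich_params")
}

as_label_array <- function(x) {
  if (inherits(x, "ich_volume")) x <- x$data
  stopifnot(is.array(x), length(dim(x)) == 3L)
  storage.mode(x) <- "integer"
  x
}

#' Run the full segmentation pipeline on one case
#'
#' Orchestrates mask construction, robust outlier estimation, haematoma
#' segmentation and oedema segmentation on four co-registered volumes
#' sharing one grid (registration is upstream of this tool; a grid mismatch
#' is fatal). Inputs may be NIfTI file paths or in-memory objects.
#'
#' @param t2s,flair T2* GRE and FLAIR volumes (`ich_volume` or path).
#' @param labels Anatomical label map (integer array, `ich_volume` or path).
#' @param svd SVD probability volume in \[0, 1\] (array, `ich_volume` or
#'   path).
#' @param params An [pipeline_params()] list.
#' @param out_dir Optional directory; when given, the haematoma and oedema
#'   masks are written as NIfTI uint8 plus a JSON provenance sidecar.
#' @return A list of class `ich_result`: `haematoma`, `oedema` (logical
#'   masks), `haematoma_volume_ml`, `oedema_volume_ml`, `bundle` (the mask
#'   bundle), and `provenance` (intermediate statistics: MCD fits, the
#'   haemorrhage threshold record, every scored hypo-intensity component,
#'   and all parameters).
#' @export
run_case <- function(t2s, flair, labels, svd, params = pipeline_params(),
                     out_dir = NULL) {
  if (is.character(t2s)) t2s <- read_volume(t2s)
  if (is.character(flair)) flair <- read_volume(flair)
  if (is.character(labels)) labels <- read_volume(labels)
  if (is.character(svd)) svd <- read_volume(svd)
  labels <- as_label_array(labels)
  if (inherits(svd, "ich_volume")) svd <- svd$data
  dims <- list(dim(t2s$data), dim(flair$data), dim(labels), dim(svd))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("input volumes do not share one grid; register and resample upstream")

  bundle <- build_mask_bundle(labels, t2s, flair, params$label_config)
  stats_t2s <- robust_stats(t2s, bundle$brain,
                            support_fraction = params$mcd_support_fraction,
                            cutoff_quantile = params$mcd_cutoff_quantile,
                            subsample_size = params$mcd_subsample_size,
                            seed = params$rng_seed)
  stats_flair <- robust_stats(flair, bundle$brain,
                              support_fraction = params$mcd_support_fraction,
                              cutoff_quantile = params$mcd_cutoff_quantile,
                              subsample_size = params$mcd_subsample_size,
                              seed = params$rng_seed)
  haem <- segment_haematoma(t2s, flair, bundle, stats_t2s, stats_flair)
  oede <- segment_oedema(flair, bundle$brain, haem$mask, stats_flair, svd,
                         lambda = params$lambda, variant = params$eq7_variant)

  voxel_ml <- prod(t2s$spacing) / 1000
  provenance <- list(
    params = list(lambda = params$lambda,
                  mcd_support_fraction = params$mcd_support_fraction,
                  mcd_cutoff_quantile = params$mcd_cutoff_quantile,
                  mcd_subsample_size = params$mcd_subsample_size,
                  eq7_variant = params$eq7_variant,
                  rng_seed = params$rng_seed),
    mcd_t2s = unclass(stats_t2s),
    mcd_flair = unclass(stats_flair),
    haem_threshold = unclass(haem$threshold),
    selected_component = as.list(haem$component),
    candidates = haem$candidates,
    base_T = oede$base_T
  )
  res <- structure(list(haematoma = haem$mask, oedema = oede$mask,
                        haematoma_volume_ml = round(sum(haem$mask) * voxel_ml, 2),
                        oedema_volume_ml = round(sum(oede$mask) * voxel_ml, 2),
                        bundle = bundle, haem_detail = haem, oedema_detail = oede,
                        spacing = t2s$spacing, provenance = provenance),
                   class = "ich_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mask(res$haematoma, file.path(out_dir, "haematoma.nii.gz"), t2s$spacing)
    write_mask(res$oedema, file.path(out_dir, "oedema.nii.gz"), t2s$spacing)
    prov <- provenance
    prov$candidates <- as.list(utils::head(provenance$candidates, 50))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}

#' @export
print.ich_result <- function(x, ...) {
  cat(sprintf("<ich_result> haematoma %.2f mL (%d voxels), oedema %.2f mL (%d voxels)\n",
              x$haematoma_volume_ml, sum(x$haematoma),
              x$oedema_volume_ml, sum(x$oedema)))
  cat(sprintf("  FLAIR haemorrhage threshold H = %.4g (%s branch); base_T = %.4g; lambda = %g\n",
              x$provenance$haem_threshold$H,
              if (x$provenance$haem_threshold$corrected) "skew-corrected" else "mean",
              x$provenance$base_T, x$provenance$params$lambda))
  invisible(x)
}

#' Evaluate a segmentation against reference masks
#'
#' Computes Dice overlap for the haematoma label, the oedema label and the
#' combined label (union of both in prediction vs union in reference).
#'
#' @param pred An `ich_result` (or a list with `haematoma` and `oedema`
#'   logical masks).
#' @param ref_haematoma,ref_oedema Reference logical masks.
#' @return A list with `dice_haematoma`, `dice_oedema`, `dice_combined`.
#' @export
evaluate_segmentation <- function(pred, ref_haematoma, ref_oedema) {
  ref_haematoma <- as_mask(ref_haematoma)
  ref_oedema <- as_mask(ref_oedema)
  list(dice_haematoma = dice_score(pred$haematoma, ref_haematoma),
       dice_oedema = dice_score(pred$oedema, ref_oedema),
       dice_combined = dice_score(pred$haematoma | pred$oedema,
                                  ref_haematoma | ref_oedema))
}
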