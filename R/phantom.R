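#' Specify a synthetic ICH phantom
#'
#' Defines a co-registered synthetic case: an ellipsoidal brain containing an
#' ellipsoidal haematoma with a surrounding oedema rim, a ventricle, and
#' optional confounds. The contrast regimes mimic acute/early-subacute
#' spontaneous ICH: the haematoma is hypo-intense on T2* GRE (optionally with
#' an iso-intense centre), blooms slightly beyond its true extent through
#' susceptibility effects, is hypo-intense at its true size on FLAIR, and is
#' ringed by FLAIR hyper-intense oedema. Optional extras: a decoy
#' hypo-intensity blob inside susceptibility-artefact territory (no adjacent
#' hyper-intensity) and leukoaraiosis lesions, FLAIR hyper-intense and
#' optionally connected to the rim by a thin hyper-intense tract, with an
#' accompanying SVD probability map.
#'
#' Tissue intensities carry a smooth deterministic Gaussian texture
#' (`texture_sd`, seeded) standing in for normal anatomical intensity
#' variation, so robust scale estimation is well-posed even on "noise-free"
#' cases; `noise_sd` adds further acquisition noise on top. MR intensities
#' are arbitrary-unit; the defaults put roughly 30 texture standard
#' deviations between tissue classes so outlier thresholds separate them
#' cleanly at noise levels up to about 10% of the contrast.
#'
#' @param grid_shape 3-vector of grid dimensions.
#' @param brain_centre,brain_radii Brain ellipsoid (voxel units); centre
#'   defaults to the grid centre.
#' @param haematoma_centre,haematoma_radii Haematoma ellipsoid.
#' @param iso_core_fraction Fraction of haematoma volume that is iso-intense
#'   on T2* GRE (0 = none).
#' @param oedema_rim_thickness Oedema rim thickness in voxels.
#' @param susceptibility_bloom Extra hypo-intense margin on T2* GRE in voxels.
#' @param ventricle_centre,ventricle_radii Ventricle ellipsoid.
#' @param decoy `NULL`, or `list(centre =, radius =)` for a spherical decoy
#'   hypo-intensity inside a susceptibility-labelled region. The decoy region
#'   is constructed with no adjacent or overlapping FLAIR hyper-intensity:
#'   its FLAIR signal sits slightly below background (`decoy_flair`), as in
#'   susceptibility-related signal loss, so its hyper-overlap count is zero
#'   by design.
#' @param leukoaraiosis List of lesions, each
#'   `list(centre =, radius =, connected =, svd_probability =)`.
#' @param intensity Named list of class mean intensities: `background`,
#'   `t2s_hypo`, `flair_haematoma`, `hyper`, `csf_t2s`, `csf_flair`.
#' @param texture_sd Gaussian anatomical texture sd (intensity units).
#' @param noise_sd Additional acquisition noise sd (0 = noise-free).
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A validated list of class `ich_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         brain_centre = NULL,
                         brain_radii = c(26, 26, 26),
                         haematoma_centre = c(38, 30, 32),
                         haematoma_radii = c(7, 6, 6),
                         iso_core_fraction = 0,
                         oedema_rim_thickness = 3,
                         susceptibility_bloom = 1,
                         ventricle_centre = c(24, 42, 32),
                         ventricle_radii = c(4, 5, 4),
                         decoy = NULL,
                         leukoaraiosis = list(),
                         intensity = list(background = 100, t2s_hypo = 30,
                                          flair_haematoma = 40, hyper = 180,
                                          csf_t2s = 110, csf_flair = 30,
                                          decoy_flair = 85),
                         texture_sd = 2,
                         noise_sd = 0,
                         seed = 42L) {
  if (is.null(brain_centre)) brain_centre <- (grid_shape + 1) / 2
  spec <- structure(as.list(environment()), class = "ich_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16),
              iso_core_fraction >= 0, iso_core_fraction < 1,
              oedema_rim_thickness >= 1, susceptibility_bloom >= 0,
              texture_sd > 0, noise_sd >= 0)
    if (!(intensity$t2s_hypo < intensity$background &&
          intensity$flair_haematoma < intensity$background &&
          intensity$background < intensity$hyper))
      stop("intensity ordering violated: need hypo < background < hyper")
    margin <- 4
    check_inside <- function(centre, extent, what) {
      if (any(centre - extent < margin) || any(centre + extent > grid_shape - margin + 1))
        stop(what, " closer than ", margin, " voxels to the grid border")
    }
    check_inside(brain_centre, brain_radii, "brain")
    outer <- max(oedema_rim_thickness, susceptibility_bloom)
    check_inside(haematoma_centre, haematoma_radii + outer, "haematoma")
    check_inside(ventricle_centre, ventricle_radii, "ventricle")
    if (!is.null(decoy)) check_inside(decoy$centre, decoy$radius, "decoy")
    for (lk in leukoaraiosis) check_inside(lk$centre, lk$radius, "leukoaraiosis lesion")
  })
  invisible(spec)
}

# Ellipsoid membership on the (X, Y, Z) coordinate grids.
ellipsoid <- function(X, Y, Z, centre, radii) {
  ((X - centre[1]) / radii[1])^2 + ((Y - centre[2]) / radii[2])^2 +
    ((Z - centre[3]) / radii[3])^2 <= 1
}

#' Generate a synthetic case from a phantom specification
#'
#' Produces the four co-registered input volumes (T2* GRE, FLAIR, label map,
#' SVD probability map) plus ground-truth haematoma and oedema masks.
#' Generation is bit-reproducible given the spec (including its seed). The
#' label map uses a minimal catalogue: 16 (cerebral white matter, in the
#' lesion set) for brain tissue, 23 (lateral ventricle), 18 (CSF) for a thin
#' shell around the ventricle, and 10 (cerebellum exterior, in the
#' susceptibility set) over the decoy region when present.
#'
#' @param spec An `ich_phantom_spec`.
#' @return A list of class `ich_phantom_case`: `t2s`, `flair`
#'   (`ich_volume`), `labels` (integer array), `svd` (double array),
#'   `truth_haematoma`, `truth_oedema` (logical arrays), and `spec`.
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "ich_phantom_spec"))
  validate_phantom_spec(spec)
  d <- as.integer(spec$grid_shape)
  zero <- array(0, dim = d)
  X <- slice.index(zero, 1); Y <- slice.index(zero, 2); Z <- slice.index(zero, 3)
  ell <- function(centre, radii) ellipsoid(X, Y, Z, centre, radii)

  brain <- ell(spec$brain_centre, spec$brain_radii)
  haem <- ell(spec$haematoma_centre, spec$haematoma_radii)
  rim <- ell(spec$haematoma_centre, spec$haematoma_radii + spec$oedema_rim_thickness) &
    !haem & brain
  bloom <- ell(spec$haematoma_centre, spec$haematoma_radii + spec$susceptibility_bloom)
  core <- if (spec$iso_core_fraction > 0)
    ell(spec$haematoma_centre, spec$haematoma_radii * spec$iso_core_fraction^(1 / 3))
  else zero > 1
  vent <- ell(spec$ventricle_centre, spec$ventricle_radii) & brain
  csf_shell <- dilate_mask(vent) & !vent & brain

  labels <- array(0L, dim = d)
  labels[brain] <- 16L
  labels[csf_shell] <- 18L
  labels[vent] <- 23L

  inten <- spec$intensity
  t2s <- zero; flair <- zero; svd <- zero
  t2s[brain] <- inten$background
  flair[brain] <- inten$background
  t2s[csf_shell | vent] <- inten$csf_t2s
  flair[csf_shell | vent] <- inten$csf_flair
  flair[rim] <- inten$hyper
  flair[haem & brain] <- inten$flair_haematoma
  t2s[bloom & brain] <- inten$t2s_hypo
  t2s[core & brain] <- inten$background

  if (!is.null(spec$decoy)) {
    dec <- ell(spec$decoy$centre, rep(spec$decoy$radius, 3)) & brain
    region <- ell(spec$decoy$centre, rep(spec$decoy$radius + 3, 3)) & brain & !vent & !csf_shell
    labels[region] <- 10L
    t2s[dec] <- inten$t2s_hypo
    flair[dec] <- inten$decoy_flair
  }

  for (lk in spec$leukoaraiosis) {
    blob <- ell(lk$centre, rep(lk$radius, 3)) & brain
    site <- blob
    if (isTRUE(lk$connected)) {
      tract <- tract_mask(d, spec$haematoma_centre, lk$centre) & brain & !haem
      site <- site | tract
    }
    flair[site] <- inten$hyper
    svd[site] <- pmax(svd[site], lk$svd_probability)
  }

  textured <- with_local_seed(spec$seed, {
    n <- length(t2s)
    t2s_t <- t2s + stats::rnorm(n, 0, spec$texture_sd) * (t2s > 0)
    flair_t <- flair + stats::rnorm(n, 0, spec$texture_sd) * (flair > 0)
    if (spec$noise_sd > 0) {
      t2s_t <- t2s_t + stats::rnorm(n, 0, spec$noise_sd) * (t2s > 0)
      flair_t <- flair_t + stats::rnorm(n, 0, spec$noise_sd) * (flair > 0)
    }
    list(t2s = t2s_t, flair = flair_t)
  })
  dim(textured$t2s) <- d; dim(textured$flair) <- d

  structure(list(
    t2s = intensity_volume(textured$t2s),
    flair = intensity_volume(textured$flair),
    labels = labels,
    svd = svd,
    truth_haematoma = haem & brain & !vent,
    truth_oedema = rim & !vent,
    spec = spec
  ), class = "ich_phantom_case")
}

# Voxels within one voxel of the line segment between two points.
tract_mask <- function(d, from, to) {
  m <- array(FALSE, dim = d)
  len <- sqrt(sum((to - from)^2))
  ts <- seq(0, 1, length.out = max(2, ceiling(4 * len)))
  for (t in ts) {
    p <- round(from + t * (to - from))
    lo <- pmax(p - 1, 1); hi <- pmin(p + 1, d)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  m
}

#' Catalogue of named phantom fixtures
#'
#' Named specifications exercising each behaviour the pipeline defends
#' against:
#' \describe{
#'   \item{clean}{default noise-free case: one hypo-intense haematoma ringed
#'     by hyper-intense oedema.}
#'   \item{iso_core}{haematoma with an iso-intense T2* centre (30% of its
#'     volume), testing that hole-filling-closing recovers the full lesion.}
#'   \item{susceptibility_decoy}{an additional, larger hypo-intensity blob
#'     inside a susceptibility-labelled region with no adjacent
#'     hyper-intensity; its context weight is zero so the true haematoma
#'     must still be selected.}
#'   \item{intraventricular}{haematoma extending into the ventricle; the
#'     final segmentation must contain no ventricle voxel.}
#'   \item{connected_leukoaraiosis}{one leukoaraiosis lesion joined to the
#'     oedema rim by a thin hyper-intense tract (high SVD probability) plus
#'     one unreachable distant lesion.}
#'   \item{negative_skew}{a wide susceptibility bloom over a thin rim makes
#'     the FLAIR intensity distribution of the selected component
#'     left-skewed (mean below median), forcing the skewness-corrected
#'     threshold branch.}
#' }
#'
#' @return A named list of `ich_phantom_spec` objects.
#' @export
fixture_catalogue <- function() {
  list(
    clean = phantom_spec(),
    iso_core = phantom_spec(iso_core_fraction = 0.3),
    susceptibility_decoy = phantom_spec(
      decoy = list(centre = c(26, 20, 24), radius = 7)),
    intraventricular = phantom_spec(
      ventricle_centre = c(38, 20, 32), ventricle_radii = c(4, 6, 4)),
    connected_leukoaraiosis = phantom_spec(
      leukoaraiosis = list(
        list(centre = c(38, 52, 32), radius = 3, connected = TRUE,
             svd_probability = 0.9),
        list(centre = c(20, 20, 32), radius = 3, connected = FALSE,
             svd_probability = 0.9))),
    negative_skew = phantom_spec(
      haematoma_radii = c(6, 6, 6), oedema_rim_thickness = 1,
      susceptibility_bloom = 4)
  )
}

#' Write a phantom case to NIfTI files
#'
#' Emits `t2s.nii.gz`, `flair.nii.gz`, `labels.nii.gz`, `svd.nii.gz`,
#' `truth_haematoma.nii.gz`, `truth_oedema.nii.gz` and a `spec.json` echo
#' into a directory.
#'
#' @param case An `ich_phantom_case`.
#' @param out_dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_case <- function(case, out_dir) {
  stopifnot(inherits(case, "ich_phantom_case"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_volume(case$t2s, p("t2s.nii.gz"))
  write_volume(case$flair, p("flair.nii.gz"))
  lab <- RNifti::asNifti(case$labels)
  RNifti::writeNifti(lab, p("labels.nii.gz"), datatype = "int16")
  write_volume(intensity_volume(case$svd), p("svd.nii.gz"))
  write_mask(case$truth_haematoma, p("truth_haematoma.nii.gz"))
  write_mask(case$truth_oedema, p("truth_oedema.nii.gz"))
  spec <- case$spec
  spec$grid_shape <- as.integer(spec$grid_shape)
  jsonlite::write_json(unclass(spec), p("spec.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}
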