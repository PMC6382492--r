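#' Geodesic quasi-euclidean distance from a seed set
#'
#' Shortest-path distance over 26-neighbour steps with costs 1, sqrt(2) and
#' sqrt(3) (scaled by voxel spacing in mm mode), computed by Dijkstra's
#' algorithm from the seed set, constrained to the traversable set
#' `domain | seed`. Non-traversable and unreachable voxels are assigned
#' `+Inf`: a hyper-intense region with no hyper-intense path back to the
#' haematoma can never be claimed as oedema.
#'
#' @param seed Logical mask of distance-zero voxels (non-empty).
#' @param domain Logical mask of traversable voxels.
#' @param spacing `NULL` for voxel-length units (the default; inputs are
#'   assumed resampled to an isotropic grid), or a 3-vector of voxel edge
#'   lengths for distances in mm.
#' @return A double array of distances (`+Inf` where unreachable).
#' @export
geodesic_distance <- function(seed, domain, spacing = NULL) {
  seed <- as_mask(seed); domain <- as_mask(domain)
  stopifnot(identical(dim(seed), dim(domain)))
  if (!any(seed)) stop("empty seed set")
  sp <- if (is.null(spacing)) c(1, 1, 1) else as.numeric(spacing)
  stopifnot(length(sp) == 3L, all(sp > 0))
  d <- dim(seed)
  array(cpp_geodesic(seed, domain, d, sp), dim = d)
}

#' Leukoaraiosis weight map
#'
#' `L = (1 + S)^2`, where `S` is the voxel-wise small-vessel-disease
#' probability in \[0, 1\]. The weight ranges over \[1, 4\] and inflates the
#' effective geodesic distance of probable chronic white-matter lesions so
#' the dynamic threshold excludes them. Out-of-range probabilities are
#' clipped with a warning.
#'
#' @param svd An `ich_volume` (or 3-D array) of SVD probabilities.
#' @return A double array in \[1, 4\].
#' @export
leukoaraiosis_weight <- function(svd) {
  if (inherits(svd, "ich_volume")) svd <- svd$data
  stopifnot(is.array(svd), length(dim(svd)) == 3L)
  if (any(svd < 0 | svd > 1)) {
    warning("SVD probabilities outside [0, 1] clipped")
    svd <- pmin(pmax(svd, 0), 1)
    dim(svd) <- dim(svd)
  }
  (1 + svd)^2
}

#' Voxel-wise dynamic hyper-intensity threshold map
#'
#' Converts the scalar FLAIR hyper-intensity threshold `base_T` into a
#' voxel-wise map that rises with the (leukoaraiosis-weighted) geodesic
#' distance from the haematoma. The default `"linear"` form is
#' `base_T * (D * L + lambda) / (2 * lambda)`: half the scalar threshold on
#' the haematoma itself (`D = 0`), crossing `base_T` where `D * L = lambda`,
#' and `+Inf` wherever `D` is infinite. `lambda` (default 15 in the
#' pipeline) controls the steepness of the rise around the haematoma. The
#' `"squared"` variant `base_T * ((D * L + lambda) / lambda)^2 / 2` is
#' provided as an alternative reading with identical boundary behaviour at
#' `D = 0` and `D = Inf`.
#'
#' @param base_T Scalar FLAIR threshold (from the robust fit).
#' @param D Distance array from [geodesic_distance()].
#' @param L Weight array from [leukoaraiosis_weight()].
#' @param lambda Positive steepness parameter.
#' @param variant `"linear"` (default) or `"squared"`.
#' @return A double array of thresholds (`+Inf` propagates from `D`).
#' @export
dynamic_threshold_map <- function(base_T, D, L, lambda,
                                  variant = c("linear", "squared")) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(lambda), length(lambda) == 1L)
  if (lambda <= 0) stop("'lambda' must be strictly positive")
  stopifnot(identical(dim(D), dim(L)))
  if (variant == "linear") base_T * (D * L + lambda) / (2 * lambda)
  else base_T * ((D * L + lambda) / lambda)^2 / 2
}

#' Segment perihaematomal oedema
#'
#' Oedema workflow, seeded by the final haematoma segmentation:
#' \enumerate{
#'   \item whole-brain FLAIR hyper-intensity mask: intensity strictly above
#'     the scalar threshold `base_T = stats_flair$T_high`, within the brain
#'     mask (oedema may occur anywhere in the brain, not only WM-GM);
#'   \item geodesic distance `D` from the haematoma through the
#'     hyper-intensity mask;
#'   \item leukoaraiosis weight `L` from the SVD probability map;
#'   \item dynamic threshold map from `base_T`, `D`, `L` and `lambda`;
#'   \item initial oedema: brain voxels with FLAIR intensity strictly above
#'     the threshold map;
#'   \item hole-filling-closing with one iteration (a single iteration only,
#'     as oedema boundaries are irregular and heavier closing would fill
#'     genuine surface dents);
#'   \item removal of haematoma voxels (the two labels are disjoint).
#' }
#'
#' @param flair An `ich_volume`.
#' @param brain Whole-brain logical mask.
#' @param haematoma Final haematoma logical mask (non-empty).
#' @param stats_flair `ich_robust_stats` FLAIR fit.
#' @param svd SVD probability volume (array or `ich_volume`).
#' @param lambda Positive steepness parameter, default 15.
#' @param variant Threshold-map variant, see [dynamic_threshold_map()].
#' @return A list of class `ich_oedema`: `mask`, `base_T`, `lambda`,
#'   `variant`, `distance` (the geodesic map), `initial` (pre-morphology
#'   oedema mask).
#' @export
segment_oedema <- function(flair, brain, haematoma, stats_flair, svd,
                           lambda = 15, variant = c("linear", "squared")) {
  variant <- match.arg(variant)
  brain <- as_mask(brain); haematoma <- as_mask(haematoma)
  stopifnot(inherits(flair, "ich_volume"),
            identical(dim(flair$data), dim(brain)),
            identical(dim(flair$data), dim(haematoma)))
  if (!any(haematoma)) stop("empty haematoma seed")
  base_T <- stats_flair$T_high
  hyper <- flair$data > base_T & brain
  D <- geodesic_distance(haematoma, hyper)
  L <- leukoaraiosis_weight(svd)
  tmap <- dynamic_threshold_map(base_T, D, L, lambda, variant)
  initial <- brain & flair$data > tmap
  mask <- hole_filling_closing(initial, 1) & !haematoma
  structure(list(mask = mask, base_T = base_T, lambda = lambda,
                 variant = variant, distance = D, initial = initial),
            class = "ich_oedema")
}
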