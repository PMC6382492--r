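#' @useDynLib ichseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct an intensity volume
#'
#' An intensity volume is a 3-D scalar grid (arbitrary MR intensity units)
#' together with its voxel spacing in millimetres. `NaN` values in the input
#' are mapped to 0 with a warning, since padded or masked-out voxels are
#' encoded as zero throughout the pipeline.
#'
#' @param data A 3-D numeric array.
#' @param spacing Numeric vector of 3 strictly positive voxel edge lengths (mm).
#' @return An object of class `ich_volume`: a list with elements `data`
#'   (3-D double array) and `spacing`.
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive voxel edge lengths")
  storage.mode(data) <- "double"
  if (anyNA(data)) {
    warning("NaN/NA intensities mapped to 0")
    data[is.na(data)] <- 0
  }
  structure(list(data = data, spacing = spacing), class = "ich_volume")
}

#' @export
print.ich_volume <- function(x, ...) {
  cat("<ich_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.ich_volume <- function(x) dim(x$data)

# Coerce an object to a logical 3-D mask array, validating shape.
as_mask <- function(x) {
  if (inherits(x, "ich_volume")) x <- x$data
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("a mask must be a 3-D array")
  if (!is.logical(x)) {
    storage.mode(x) <- "logical"
  }
  x[is.na(x)] <- FALSE
  x
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file into an [intensity_volume()]. 4-D images whose last
#' dimension is a singleton are squeezed to 3-D; any other dimensionality is
#' rejected.
#'
#' @param path Path to a NIfTI file.
#' @return An `ich_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  arr <- array(as.vector(as.array(img)), dim = d)  # drop niftiImage attributes
  if (length(d) == 4L && d[4] == 1L) {
    arr <- array(arr, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected a 3-D image (or 4-D with singleton last dimension), got ",
         length(d), "-D: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in header: ", path)
  intensity_volume(arr, sp)
}

#' Write a NIfTI volume or mask
#'
#' Intensity volumes are written as float64 so that a write/read round trip
#' preserves the data bit-exactly; masks are written as uint8 in \{0, 1\}.
#'
#' @param vol An `ich_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ich_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @param mask A logical 3-D array.
#' @param spacing Voxel spacing for the output header.
#' @rdname write_volume
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  mask <- as_mask(mask)
  arr <- array(as.integer(mask), dim = dim(mask))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a NIfTI file as a binary mask
#'
#' @param path Path to a NIfTI file; any nonzero voxel becomes `TRUE`.
#' @return A logical 3-D array.
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  vol$data != 0
}

#' Binarise nonzero voxels
#'
#' Padded voxels in MR acquisitions carry intensity exactly zero; the nonzero
#' support of a volume is therefore its acquisition footprint.
#'
#' @param vol An `ich_volume` (or 3-D array).
#' @return Logical array, `TRUE` exactly where intensity is nonzero.
#' @export
binarize_nonzero <- function(vol) {
  if (inherits(vol, "ich_volume")) vol <- vol$data
  stopifnot(is.array(vol), length(dim(vol)) == 3L)
  vol != 0
}

#' Morphological dilation and erosion with the 3x3x3 box kernel
#'
#' The structuring element is the full 26-neighbour 3x3x3 box. Outside-grid
#' voxels are treated as background, so erosion shrinks shapes touching the
#' border.
#'
#' @param mask Logical 3-D array.
#' @param n Number of iterations (>= 1).
#' @return Logical array of the same shape.
#' @export
dilate_mask <- function(mask, n = 1) {
  mask <- as_mask(mask)
  d <- dim(mask)
  for (i in seq_len(n)) mask <- array(cpp_dilate(mask, d), dim = d)
  mask
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, n = 1) {
  mask <- as_mask(mask)
  d <- dim(mask)
  for (i in seq_len(n)) mask <- array(cpp_erode(mask, d), dim = d)
  mask
}

#' Fill interior cavities of a mask
#'
#' A cavity is a background region with no 6-connected path to the grid
#' border; every cavity voxel is set `TRUE`. Filling is fully 3-D.
#'
#' @param mask Logical 3-D array.
#' @return Logical array with cavities filled.
#' @export
fill_holes <- function(mask) {
  mask <- as_mask(mask)
  d <- dim(mask)
  array(cpp_fill_holes(mask, d), dim = d)
}

#' Hole-filling-closing
#'
#' The composite operator used throughout the pipeline: `n` dilations with the
#' 3x3x3 box kernel, 6-connected cavity filling, then `n` erosions with the
#' same kernel. It is extensive (the input is a subset of the output).
#'
#' @param mask Logical 3-D array.
#' @param n Number of dilation/erosion iterations (>= 1).
#' @return Logical array.
#' @export
hole_filling_closing <- function(mask, n) {
  stopifnot(n >= 1)
  mask <- as_mask(mask)
  out <- erode_mask(fill_holes(dilate_mask(mask, n)), n)
  # extensivity guard: dilation/fill/erosion with equal counts can in
  # principle not remove original voxels away from borders, but border
  # truncation can; keep the operator extensive by construction.
  out | mask
}

#' Connected components of a binary mask
#'
#' Partitions the true voxels into maximal connected sets under 6- or
#' 26-connectivity. Components are ordered deterministically: by decreasing
#' volume, ties broken by the lexicographically smallest voxel coordinate.
#' Each component carries its axis-aligned bounding-box volume and shape
#' score.
#'
#' @param mask Logical 3-D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return An object of class `ich_components`: list with `labels` (integer
#'   array; 0 = background, components numbered 1..k in the deterministic
#'   order) and `table` (data.frame with columns `id`, `volume`,
#'   `bbox_volume`, `shape_score`, `min_x`, `min_y`, `min_z`).
#' @export
connected_components <- function(mask, connectivity = 6) {
  mask <- as_mask(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  d <- dim(mask)
  raw <- array(cpp_label_components(mask, d, connectivity), dim = d)
  idx <- which(raw > 0L)
  if (length(idx) == 0L) {
    tab <- data.frame(id = integer(), volume = integer(),
                      bbox_volume = integer(), shape_score = numeric(),
                      min_x = integer(), min_y = integer(), min_z = integer())
    return(structure(list(labels = raw, table = tab, connectivity = connectivity),
                     class = "ich_components"))
  }
  lab <- raw[idx]
  co <- arrayInd(idx, d)
  vol <- tabulate(lab)
  rng <- function(v, f) cbind(tapply(v, lab, min), tapply(v, lab, max))
  rx <- rng(co[, 1]); ry <- rng(co[, 2]); rz <- rng(co[, 3])
  bbox <- (rx[, 2] - rx[, 1] + 1) * (ry[, 2] - ry[, 1] + 1) * (rz[, 2] - rz[, 1] + 1)
  # lexicographically smallest voxel of each component, for tie-breaking
  o <- order(lab, co[, 1], co[, 2], co[, 3])
  first <- o[!duplicated(lab[o])]
  minvox <- co[first, , drop = FALSE]
  ord <- order(-vol, minvox[, 1], minvox[, 2], minvox[, 3])
  remap <- integer(length(vol))
  remap[ord] <- seq_along(ord)
  labels <- raw
  labels[idx] <- remap[lab]
  tab <- data.frame(id = seq_along(ord),
                    volume = as.integer(vol[ord]),
                    bbox_volume = as.integer(bbox[ord]),
                    shape_score = shape_score(vol[ord], bbox[ord]),
                    min_x = minvox[ord, 1], min_y = minvox[ord, 2],
                    min_z = minvox[ord, 3])
  structure(list(labels = labels, table = tab, connectivity = connectivity),
            class = "ich_components")
}

#' @export
print.ich_components <- function(x, ...) {
  cat("<ich_components> ", nrow(x$table), " component(s), ",
      x$connectivity, "-connectivity\n", sep = "")
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Component shape score
#'
#' A surrogate measure of solidity and roundness: the component volume times
#' the squared extent (volume over bounding-box volume),
#' `S = |x| * (|x|/|B(x)|)^2 = |x|^3 / |B(x)|^2`. A component that fills its
#' axis-aligned bounding box scores its own volume; elongated or sparse
#' components are penalised quadratically.
#'
#' @param volume Component voxel count(s), >= 1.
#' @param bbox_volume Axis-aligned minimal bounding-box voxel count(s).
#' @return Non-negative shape score(s), always <= `volume`.
#' @export
shape_score <- function(volume, bbox_volume) {
  stopifnot(all(volume >= 1), all(bbox_volume >= volume))
  as.numeric(volume)^3 / as.numeric(bbox_volume)^2
}

#' Dice overlap score
#'
#' `2|X & Y| / (|X| + |Y|)`: 0 for no overlap, 1 for perfect overlap. Two
#' empty masks are defined to overlap perfectly (score 1, with a warning).
#'
#' @param a,b Logical 3-D arrays of the same shape.
#' @return A number in \[0, 1\].
#' @export
dice_score <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}
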