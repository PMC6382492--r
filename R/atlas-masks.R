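#' Default MALP-EM label sets for the anatomical masks
#'
#' Label sets used to assemble the anatomical masks from a subject-space
#' MALP-EM-style parcellation (138 labels; 0 = unlabelled background,
#' 18 = CSF). `susceptibility_labels` lists regions prone to susceptibility
#' artefact in T2* GRE (skull-base and cortical-surface structures);
#' `lesion_labels` lists the subcortical regions where spontaneous
#' haemorrhages most commonly occur; `ventricle_labels` lists the ventricular
#' system.
#'
#' @return An integer vector of labels.
#' @export
susceptibility_labels <- function() {
  as.integer(c(10, 11, 45, 46, 59, 60, 61, 62, 63, 64, 65, 66, 67, 68,
               71, 72, 75, 76, 81, 82, 89, 90, 91, 92, 93, 94,
               111, 112, 119, 120, 133, 134))
}

#' @rdname susceptibility_labels
#' @export
lesion_labels <- function() {
  as.integer(c(3, 4, 7, 8, 9, 12, 13, 16, 17, 19, 20, 25, 26, 27, 28, 29, 30))
}

#' @rdname susceptibility_labels
#' @export
ventricle_labels <- function() {
  as.integer(c(1, 2, 21, 22, 23, 24))
}

#' Read a label-set configuration file
#'
#' A YAML file may override the default label sets with keys
#' `susceptibility_labels`, `lesion_labels`, `ventricle_labels` and
#' `csf_label`. Missing keys fall back to the shipped defaults, so a reduced
#' catalogue (e.g. for phantoms, or a map carrying an extra lesion label) can
#' be supplied without restating the full tables.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return A list with the four entries.
#' @export
read_label_config <- function(path = NULL) {
  cfg <- list(susceptibility_labels = susceptibility_labels(),
              lesion_labels = lesion_labels(),
              ventricle_labels = ventricle_labels(),
              csf_label = 18L)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (key in names(cfg))
      if (!is.null(user[[key]])) cfg[[key]] <- as.integer(user[[key]])
  }
  cfg
}

#' Build a mask from a set of atlas labels
#'
#' @param labels Integer 3-D array (subject-space label map).
#' @param label_set Non-empty integer vector of labels to include.
#' @return Logical array, `TRUE` where the label value is in `label_set`.
#' @export
build_region_mask <- function(labels, label_set) {
  if (inherits(labels, "ich_volume")) labels <- labels$data
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (length(label_set) == 0) stop("'label_set' must be non-empty")
  present <- label_set %in% labels
  if (!any(present))
    message("none of the requested labels occur in the map; empty mask")
  array(labels %in% label_set, dim = dim(labels))
}

#' Build the whole-brain mask
#'
#' Intersects three supports: (1) the binarised label map (any nonzero
#' label), (2) the nonzero support of the T2* GRE volume and (3) of the FLAIR
#' volume, the latter two each regularised by [hole_filling_closing()] with
#' one iteration so isolated zero-valued voxels inside the parenchyma are not
#' lost. The intersection is then eroded twice with the 3x3x3 kernel to pull
#' the mask away from the brain surface.
#'
#' @param labels Integer 3-D label array.
#' @param t2s,flair `ich_volume` objects on the same grid.
#' @return Logical array; an empty result is an error (no brain found).
#' @export
build_brain_mask <- function(labels, t2s, flair) {
  if (inherits(labels, "ich_volume")) labels <- labels$data
  stopifnot(identical(dim(labels), dim(t2s$data)),
            identical(dim(labels), dim(flair$data)))
  m_lab <- labels != 0
  m_t2s <- hole_filling_closing(binarize_nonzero(t2s), 1)
  m_fla <- hole_filling_closing(binarize_nonzero(flair), 1)
  brain <- erode_mask(m_lab & m_t2s & m_fla, 2)
  if (!any(brain)) stop("empty brain mask: label map and image supports do not intersect")
  brain
}

#' Build the white-and-grey-matter mask
#'
#' Removes from the whole-brain mask every voxel labelled CSF and every voxel
#' of the ventricle mask. White and grey matter are iso-intense in both T2*
#' GRE and FLAIR, so intensity outliers inside this mask are lesion
#' candidates.
#'
#' @param brain Whole-brain logical mask.
#' @param labels Integer 3-D label array.
#' @param ventricle Ventricle logical mask.
#' @param csf_label Integer CSF label (default 18).
#' @return Logical array.
#' @export
build_wm_gm_mask <- function(brain, labels, ventricle, csf_label = 18L) {
  if (inherits(labels, "ich_volume")) labels <- labels$data
  brain <- as_mask(brain); ventricle <- as_mask(ventricle)
  stopifnot(identical(dim(brain), dim(labels)),
            identical(dim(brain), dim(ventricle)))
  brain & labels != csf_label & !ventricle
}

#' Build the full anatomical mask bundle
#'
#' Convenience wrapper producing the five masks consumed by the segmentation
#' stages: whole-brain, susceptibility, lesion, ventricle and WM-GM.
#'
#' @param labels Integer 3-D label array.
#' @param t2s,flair `ich_volume` objects on the same grid.
#' @param config Label-set configuration as returned by [read_label_config()].
#' @return A list of class `ich_mask_bundle` with elements `brain`,
#'   `susceptibility`, `lesion`, `ventricle`, `wm_gm`.
#' @export
build_mask_bundle <- function(labels, t2s, flair, config = read_label_config()) {
  if (inherits(labels, "ich_volume")) labels <- labels$data
  brain <- build_brain_mask(labels, t2s, flair)
  ventricle <- build_region_mask(labels, config$ventricle_labels)
  bundle <- list(
    brain = brain,
    susceptibility = build_region_mask(labels, config$susceptibility_labels),
    lesion = build_region_mask(labels, config$lesion_labels),
    ventricle = ventricle,
    wm_gm = build_wm_gm_mask(brain, labels, ventricle, config$csf_label)
  )
  class(bundle) <- "ich_mask_bundle"
  bundle
}
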