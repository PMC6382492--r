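#' Context weight of a hypo-intensity component
#'
#' `w = o^2 * (l + 1) / (s + 1)`, where `o` is the number of component voxels
#' overlapping the FLAIR hyper-intensity map, `l` the overlap with the lesion
#' (likely-haemorrhage) mask and `s` the overlap with the susceptibility
#' mask. The weight favours components ringed by a large extent of
#' hyper-intensity (oedema) and sitting in subcortical haemorrhage-prone
#' regions, and penalises components arising in susceptibility-artefact
#' territory. A component with no adjacent hyper-intensity (`o = 0`) is
#' weighted zero outright.
#'
#' @param o,s,l Non-negative overlap counts (vectorised).
#' @return Non-negative weight(s).
#' @export
component_weight <- function(o, s, l) {
  stopifnot(all(o >= 0), all(s >= 0), all(l >= 0))
  as.numeric(o)^2 * (as.numeric(l) + 1) / (as.numeric(s) + 1)
}

#' Score components against the context masks
#'
#' Augments a [connected_components()] table with the overlap counts `o`
#' (hyper-intensity), `s` (susceptibility), `l` (lesion), the context weight
#' `w` and the selection score `w * S`.
#'
#' @param cc An `ich_components` object.
#' @param hyper,susceptibility,lesion Logical masks on the same grid.
#' @return The `ich_components` object with extended table.
#' @export
score_components <- function(cc, hyper, susceptibility, lesion) {
  stopifnot(inherits(cc, "ich_components"))
  k <- nrow(cc$table)
  count_in <- function(mask) {
    mask <- as_mask(mask)
    stopifnot(identical(dim(mask), dim(cc$labels)))
    v <- tabulate(cc$labels[mask], nbins = k)
    as.integer(v)
  }
  tab <- cc$table
  tab$o <- count_in(hyper)
  tab$s <- count_in(susceptibility)
  tab$l <- count_in(lesion)
  tab$w <- component_weight(tab$o, tab$s, tab$l)
  tab$score <- tab$w * tab$shape_score
  cc$table <- tab
  cc
}

#' Select the best T2* hypo-intensity component
#'
#' Returns the component maximising `w * S`. Since the component table is in
#' the deterministic order (volume-descending, then lexicographic smallest
#' voxel), ties resolve to the first-ordered component. If every score is
#' zero no component borders hyper-intensity and a no-haematoma error is
#' raised.
#'
#' @param cc An `ich_components` object scored by [score_components()].
#' @return The selected row of the component table.
#' @export
select_t2s_component <- function(cc) {
  stopifnot(inherits(cc, "ich_components"), "score" %in% names(cc$table))
  if (nrow(cc$table) == 0L) stop_no_haematoma("no hypo-intensity components")
  if (all(cc$table$score == 0))
    stop_no_haematoma("no hypo-intensity component borders FLAIR hyper-intensity")
  cc$table[which.max(cc$table$score), , drop = FALSE]
}

stop_no_haematoma <- function(msg) {
  stop(structure(class = c("ich_no_haematoma", "error", "condition"),
                 list(message = paste0("no haematoma found: ", msg),
                      call = sys.call(-1))))
}

#' Skewness-corrected FLAIR haemorrhage threshold
#'
#' Inside the selected T2* component the FLAIR intensities are mostly
#' haemorrhage (hypo/iso) with some brighter oedema voxels, so the mean `mu`
#' is a good upper threshold. When susceptibility blooming pulls in enough
#' normal tissue that the distribution becomes left-skewed (`mu < nu`, the
#' median), the threshold is corrected downwards to
#' `H = mu + 6 * (mu - nu)`, which sits `2k` standard deviations below the
#' mean, `k = 3 * (mu - nu) / sigma` being Pearson's second skewness
#' coefficient. Mean, median and standard deviation use the population
#' convention (divide by n).
#'
#' @param flair_values Numeric vector of FLAIR intensities (>= 1 value).
#' @return A list of class `ich_haem_threshold`: `mu`, `nu`, `sigma`, `k`,
#'   `H`, `corrected` (logical).
#' @export
haemorrhage_threshold <- function(flair_values) {
  x <- as.numeric(flair_values)
  stopifnot(length(x) >= 1)
  mu <- mean(x)
  nu <- stats::median(x)
  sigma <- sqrt(mean((x - mu)^2))
  k <- if (sigma > 0) 3 * (mu - nu) / sigma else 0
  corrected <- mu < nu
  H <- if (corrected) mu + 6 * (mu - nu) else mu
  structure(list(mu = mu, nu = nu, sigma = sigma, k = k, H = H,
                 corrected = corrected),
            class = "ich_haem_threshold")
}

#' @export
print.ich_haem_threshold <- function(x, ...) {
  cat(sprintf("<ich_haem_threshold> H=%.4g (mu=%.4g, nu=%.4g, sigma=%.4g, k=%.4g, %s branch)\n",
              x$H, x$mu, x$nu, x$sigma, x$k,
              if (x$corrected) "skew-corrected" else "mean"))
  invisible(x)
}

#' Remove weakly-linked voxels from a mask
#'
#' A true voxel is removed when its 26-neighbourhood forms a linear pattern:
#' exactly the two opposite face neighbours along one axis (x, y or z) are
#' true and the other 24 neighbours are false. Such voxels are one-voxel
#' bridges between otherwise separate blobs. All qualifying voxels are
#' detected on the input mask simultaneously and removed in a single pass,
#' so the result does not depend on any traversal order. The operation is
#' anti-extensive.
#'
#' @param mask Logical 3-D array.
#' @return Logical array with weak-link voxels set to `FALSE`.
#' @export
break_weak_links <- function(mask) {
  mask <- as_mask(mask)
  d <- dim(mask)
  weak <- array(cpp_weak_links(mask, d), dim = d)
  mask & !weak
}

#' Segment the haematoma
#'
#' Full haematoma workflow on co-registered T2* GRE and FLAIR volumes:
#' \enumerate{
#'   \item T2* hypo-intensity map `M_hypo` and FLAIR hyper-intensity map
#'     `M_hyper`, both restricted to the WM-GM mask;
#'   \item 6-connected components of `M_hypo`, scored by `w * S`;
#'   \item selection of the best T2* component;
#'   \item FLAIR haemorrhage threshold `H` from its FLAIR intensities;
#'   \item candidate map: component voxels with FLAIR intensity < `H`;
#'   \item weak-link removal;
#'   \item 26-connected components of the result, selecting the one with
#'     maximal shape score;
#'   \item hole-filling-closing with 3 iterations (fills iso-intense cores);
#'   \item removal of all ventricle-mask voxels.
#' }
#'
#' @param t2s,flair `ich_volume` objects on one grid.
#' @param bundle An `ich_mask_bundle`.
#' @param stats_t2s,stats_flair `ich_robust_stats` fits of the two volumes
#'   (fitted within the brain mask).
#' @return A list of class `ich_haematoma`: `mask` (final segmentation),
#'   `threshold` (the `ich_haem_threshold`), `component` (selected T2*
#'   component row), `candidates` (full scored component table), `m_hypo`,
#'   `m_hyper`.
#' @export
segment_haematoma <- function(t2s, flair, bundle, stats_t2s, stats_flair) {
  stopifnot(inherits(bundle, "ich_mask_bundle"),
            identical(dim(t2s$data), dim(flair$data)))
  m_hypo <- outlier_map(t2s, bundle$wm_gm, stats_t2s, "hypo")
  m_hyper <- outlier_map(flair, bundle$wm_gm, stats_flair, "hyper")
  if (!any(m_hypo)) stop_no_haematoma("no T2* hypo-intensity voxels in the WM-GM mask")

  cc <- connected_components(m_hypo, connectivity = 6)
  cc <- score_components(cc, m_hyper, bundle$susceptibility, bundle$lesion)
  best <- select_t2s_component(cc)
  comp_mask <- cc$labels == best$id

  thr <- haemorrhage_threshold(flair$data[comp_mask])
  candidate <- comp_mask & flair$data < thr$H
  if (!any(candidate))
    stop_no_haematoma("no component voxel lies below the FLAIR haemorrhage threshold")

  candidate <- break_weak_links(candidate)
  if (!any(candidate))
    stop_no_haematoma("candidate map vanished after weak-link removal")
  cc_flair <- connected_components(candidate, connectivity = 26)
  best_flair <- cc_flair$table[which.max(cc_flair$table$shape_score), , drop = FALSE]
  final <- cc_flair$labels == best_flair$id

  final <- hole_filling_closing(final, 3)
  final <- final & !bundle$ventricle

  structure(list(mask = final, threshold = thr, component = best,
                 flair_component = best_flair, candidates = cc$table,
                 m_hypo = m_hypo, m_hyper = m_hyper),
            class = "ich_haematoma")
}
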