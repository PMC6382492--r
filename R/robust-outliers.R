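#' Univariate Minimum Covariance Determinant location and scale
#'
#' Finds the subset of `h = ceiling(support_fraction * n)` observations with
#' minimal variance and returns its mean and standard deviation. In one
#' dimension the minimal-variance h-subset is always a contiguous window of
#' the sorted sample, so the estimator is computed exactly by a sliding
#' window over the order statistics (equivalent to exhaustive search over all
#' size-h subsets, at O(n log n) cost). Ties between windows are broken
#' towards the window starting at the smallest order statistic.
#'
#' The raw subset standard deviation systematically underestimates the scale
#' of the uncontaminated distribution; the returned `sigma` is corrected by
#' the asymptotic normal consistency factor for the achieved support fraction
#' `h/n`. With the default `support_fraction = 0.6` the estimator resists 40%
#' of arbitrarily placed outliers.
#'
#' @param x Numeric vector with at least 2 distinct finite values.
#' @param support_fraction Fraction of the sample the estimate must cover,
#'   in (0.5, 1]. Default 0.6.
#' @return A list: `mu`, `sigma` (consistency-corrected), `sigma_raw`
#'   (uncorrected sample sd of the optimal subset), `h`, `n`,
#'   `support_fraction`, `consistency` (the sd multiplier applied).
#' @export
mcd_location_scale <- function(x, support_fraction = 0.6) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L)
    stop("degenerate distribution: need at least 2 distinct sample values")
  if (support_fraction <= 0.5 || support_fraction > 1)
    stop("'support_fraction' must lie in (0.5, 1]")
  h <- as.integer(ceiling(support_fraction * n))
  h <- max(h, 2L)
  xs <- sort(x)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  starts <- seq_len(n - h + 1L)
  ends <- starts + h - 1L
  s1 <- cs[ends] - c(0, cs)[starts]
  s2 <- cs2[ends] - c(0, cs2)[starts]
  ss <- pmax(s2 - s1^2 / h, 0)  # h * population variance of each window
  best <- which.min(ss)         # which.min takes the first minimum: smallest start
  mu <- s1[best] / h
  sigma_raw <- sqrt(ss[best] / (h - 1L))
  if (sigma_raw == 0)
    stop("degenerate distribution: minimal-variance subset is constant")
  cf <- sqrt(mcd_consistency_factor(h / n))
  list(mu = mu, sigma = sigma_raw * cf, sigma_raw = sigma_raw,
       h = h, n = n, support_fraction = support_fraction, consistency = cf)
}

#' Asymptotic consistency factor for the univariate MCD variance
#'
#' The optimal h-subset of a normal sample asymptotically covers the central
#' `alpha = h/n` probability mass, whose variance is
#' `F_chi2(3)(q) / alpha` times the true variance, with
#' `q = qchisq(alpha, 1)`. The raw subset variance is therefore multiplied by
#' the reciprocal, `alpha / pchisq(qchisq(alpha, 1), 3)`, to be consistent at
#' the normal model.
#'
#' @param alpha Achieved support fraction in (0.5, 1].
#' @return The variance multiplier (> 1 for alpha < 1).
#' @export
mcd_consistency_factor <- function(alpha) {
  stopifnot(alpha > 0.5, alpha <= 1)
  if (alpha == 1) return(1)
  alpha / stats::pchisq(stats::qchisq(alpha, df = 1), df = 3)
}

#' Robust intensity statistics and outlier thresholds for a volume
#'
#' Fits the univariate MCD to the intensities of `vol` inside `roi` and
#' derives two-sided outlier thresholds by the chi-squared rule:
#' `T_low = mu - c * sigma`, `T_high = mu + c * sigma` with
#' `c = sqrt(qchisq(cutoff_quantile, 1))` (c = 2.2414 at the default 0.975
#' quantile). Above `subsample_size` in-mask voxels the fit uses a seeded
#' uniform random subsample (the thresholds still apply to every voxel).
#'
#' @param vol An `ich_volume`.
#' @param roi Logical mask selecting the fit region.
#' @param support_fraction MCD support fraction, default 0.6.
#' @param cutoff_quantile Chi-squared quantile for the outlier cutoff,
#'   default 0.975.
#' @param subsample_size Maximum number of voxels used for the fit,
#'   default 2e5.
#' @param seed Integer seed for the subsampling draw, default 1234.
#' @return A list of class `ich_robust_stats`: `mu`, `sigma`, `T_low`,
#'   `T_high`, `cutoff`, plus the fit metadata of [mcd_location_scale()] and
#'   `n_total`/`n_fit` voxel counts.
#' @export
robust_stats <- function(vol, roi, support_fraction = 0.6,
                         cutoff_quantile = 0.975,
                         subsample_size = 2e5, seed = 1234L) {
  stopifnot(inherits(vol, "ich_volume"))
  roi <- as_mask(roi)
  stopifnot(identical(dim(vol$data), dim(roi)))
  values <- vol$data[roi]
  n_total <- length(values)
  if (n_total > subsample_size) {
    values <- with_local_seed(seed, sample(values, subsample_size))
  }
  fit <- mcd_location_scale(values, support_fraction)
  cc <- sqrt(stats::qchisq(cutoff_quantile, df = 1))
  out <- c(fit, list(T_low = fit$mu - cc * fit$sigma,
                     T_high = fit$mu + cc * fit$sigma,
                     cutoff = cc, cutoff_quantile = cutoff_quantile,
                     n_total = n_total, n_fit = length(values)))
  class(out) <- "ich_robust_stats"
  out
}

#' @export
print.ich_robust_stats <- function(x, ...) {
  cat(sprintf("<ich_robust_stats> mu=%.4g sigma=%.4g  [T_low=%.4g, T_high=%.4g]  n=%d (fit on %d)\n",
              x$mu, x$sigma, x$T_low, x$T_high, x$n_total, x$n_fit))
  invisible(x)
}

#' Threshold a volume into an outlier map
#'
#' @param vol An `ich_volume`.
#' @param roi Logical mask restricting the output (voxels outside are never
#'   flagged).
#' @param stats An `ich_robust_stats` fit.
#' @param direction `"hypo"` flags intensities strictly below `T_low`,
#'   `"hyper"` strictly above `T_high`.
#' @return Logical array.
#' @export
outlier_map <- function(vol, roi, stats, direction = c("hypo", "hyper")) {
  direction <- match.arg(direction)
  stopifnot(inherits(vol, "ich_volume"), inherits(stats, "ich_robust_stats"))
  roi <- as_mask(roi)
  stopifnot(identical(dim(vol$data), dim(roi)))
  if (direction == "hypo") vol$data < stats$T_low & roi
  else vol$data > stats$T_high & roi
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
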