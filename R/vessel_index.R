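# Temporal signal-variance mapping and extraction of the leptomeningeal
# high-CV vessel compartment, yielding the collateral vessel index
# CVI = highCV affected volume (mm^3) / highCV unaffected volume (mm^3).

#' Per-voxel temporal mean and standard deviation
#'
#' Computes the temporal mean mu and standard deviation sigma of the DSC
#' signal for every brain voxel. sigma uses the population (1/N)
#' normalisation. Voxels outside the brain mask are set to 0.
#'
#' @param series a motion-corrected [perfusion_series()].
#' @param brain a [binary_mask()] on the same grid.
#' @return List with `sigma` and `mu` [scalar_map()]s (units `"a.u."`).
#' @export
temporal_stats <- function(series, brain) {
  stopifnot(inherits(series, "cvi_perfusion_series"),
            inherits(brain, "cvi_binary_mask"))
  stop_geometry_mismatch(series$geometry, brain$geometry, "series and brain mask")
  x <- series$data
  d <- dim(x)
  mu <- rowMeans(x, dims = 3)
  centred <- x - as.vector(mu)      # recycles mu across the 4th dimension
  sig <- sqrt(rowMeans(centred^2, dims = 3))
  mu[!brain$data] <- 0
  sig[!brain$data] <- 0
  list(sigma = scalar_map(sig, series$geometry, "a.u."),
       mu = scalar_map(mu, series$geometry, "a.u."))
}

#' Coefficient-of-variation map, CV = sigma / mu
#'
#' Dimensionless relative signal variance. Where mu is at or below a
#' machine-scale floor (1e-6 times the median positive mu) CV is set to 0,
#' so background voxels never enter the robust range.
#'
#' @param sigma,mu [scalar_map()]s from [temporal_stats()].
#' @return A dimensionless [scalar_map()].
#' @export
cv_map <- function(sigma, mu) {
  stopifnot(inherits(sigma, "cvi_scalar_map"), inherits(mu, "cvi_scalar_map"))
  stop_geometry_mismatch(sigma$geometry, mu$geometry, "sigma and mu")
  m <- mu$data
  pos <- m[is.finite(m) & m > 0]
  eps <- if (length(pos)) 1e-6 * median(pos) else 0
  cv <- array(0, dim = dim(m))
  ok <- is.finite(m) & m > eps
  cv[ok] <- sigma$data[ok] / m[ok]
  scalar_map(cv, mu$geometry, units = "dimensionless")
}

#' Robust intensity range of a map
#'
#' The 2nd and 98th percentiles (linear interpolation) of the strictly
#' positive in-mask values — the "robust range" convention used when
#' thresholding CV maps.
#'
#' @param map a [scalar_map()].
#' @param mask a [binary_mask()] restricting the computation.
#' @param probs the two percentile levels, defaults `c(0.02, 0.98)`.
#' @return Numeric `c(rmin, rmax)`.
#' @export
robust_range <- function(map, mask, probs = c(0.02, 0.98)) {
  stopifnot(inherits(map, "cvi_scalar_map"), inherits(mask, "cvi_binary_mask"))
  stop_geometry_mismatch(map$geometry, mask$geometry, "map and mask")
  v <- map$data[mask$data]
  v <- v[is.finite(v) & v > 0]
  if (length(v) < 100L) {
    stop(sprintf("robust range needs >= 100 positive in-mask voxels (got %d)",
                 length(v)), call. = FALSE)
  }
  unname(quantile(v, probs, type = 7))
}

#' Threshold a CV map at the upper half of its robust range
#'
#' Keeps voxels with CV at or above `rmin + 0.5 * (rmax - rmin)`, the
#' upper 50\% of the robust range of positive in-mask CV values — the
#' high-CV vessel compartment.
#'
#' @param cv CV [scalar_map()].
#' @param mask in-brain [binary_mask()].
#' @param probs robust-range percentiles, see [robust_range()].
#' @return A [binary_mask()] labelled `"highCV"`, with the threshold stored
#'   in attribute `"threshold"`.
#' @export
threshold_highcv <- function(cv, mask, probs = c(0.02, 0.98)) {
  rr <- robust_range(cv, mask, probs)
  thr <- rr[1] + 0.5 * (rr[2] - rr[1])
  keep <- mask$data & is.finite(cv$data) & cv$data >= thr
  dim(keep) <- cv$geometry$shape
  out <- binary_mask(keep, cv$geometry, label = "highCV")
  attr(out, "threshold") <- thr
  out
}

#' Time point of maximum contrast-induced signal decrease
#'
#' The 0-based volume index minimising the mean in-brain signal — the bolus
#' peak. Ties break to the earliest index.
#'
#' @param series a [perfusion_series()].
#' @param brain a [binary_mask()].
#' @return Integer 0-based volume index.
#' @export
bolus_peak_index <- function(series, brain) {
  stopifnot(inherits(series, "cvi_perfusion_series"),
            inherits(brain, "cvi_binary_mask"))
  stop_geometry_mismatch(series$geometry, brain$geometry, "series and brain mask")
  d <- dim(series$data)
  m <- matrix(series$data, prod(d[1:3]), d[4])
  ts <- colMeans(m[as.vector(brain$data), , drop = FALSE])
  which.min(ts) - 1L
}

#' Remove low-intensity voxels from the high-CV mask
#'
#' Voxels of outer CSF and cortex adjacent to pial vessels show high CV at
#' low overall signal. This step removes from the high-CV mask the given
#' fraction (default 5\%) of its voxels with the lowest signal intensity at
#' the bolus-peak volume. The threshold is the empirical fraction-quantile
#' (lower order statistic) of peak-volume signal over the high-CV voxels;
#' voxels strictly below it are removed, so equal-intensity ties survive
#' and the mask is unchanged in the `fraction -> 0` limit.
#'
#' @param highcv high-CV [binary_mask()].
#' @param series the [perfusion_series()].
#' @param t_star 0-based bolus peak index from [bolus_peak_index()].
#' @param fraction proportion to strip, in (0, 1); default 0.05.
#' @param reference optional [binary_mask()] over which the quantile is
#'   computed instead of the high-CV voxels themselves (e.g. the whole
#'   brain); the default, quantile over the high-CV set, follows from the
#'   strip being an operation on that set.
#' @return A [binary_mask()], always a subset of the input.
#' @export
strip_low_intensity <- function(highcv, series, t_star, fraction = 0.05,
                                reference = NULL) {
  stopifnot(inherits(highcv, "cvi_binary_mask"),
            inherits(series, "cvi_perfusion_series"))
  stop_geometry_mismatch(highcv$geometry, series$geometry, "mask and series")
  nt <- dim(series$data)[4]
  if (t_star < 0 || t_star >= nt) stop("t_star outside the series", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)", call. = FALSE)
  sel <- highcv$data
  if (!any(sel)) {
    warning("empty highCV mask; nothing to strip")
    return(highcv)
  }
  vol <- series$data[, , , t_star + 1L]
  vals <- vol[sel]
  qref <- if (is.null(reference)) vals else vol[reference$data]
  q <- sort(qref)[min(floor(fraction * length(qref)) + 1L, length(qref))]
  keep <- sel
  keep[sel] <- vals >= q
  dim(keep) <- highcv$geometry$shape
  binary_mask(keep, highcv$geometry, label = highcv$label)
}

#' Exclude ventricle voxels from a mask
#'
#' Removes residual inner CSF spaces and choroid plexus using a ventricle
#' mask: returns `highcv AND NOT ventricles`.
#'
#' @param highcv,ventricles [binary_mask()]s on the same grid.
#' @return A [binary_mask()].
#' @export
exclude_ventricles <- function(highcv, ventricles) {
  stopifnot(inherits(highcv, "cvi_binary_mask"),
            inherits(ventricles, "cvi_binary_mask"))
  stop_geometry_mismatch(highcv$geometry, ventricles$geometry,
                         "mask and ventricle mask")
  out <- highcv$data & !ventricles$data
  dim(out) <- highcv$geometry$shape
  binary_mask(out, highcv$geometry, label = highcv$label)
}

#' Leptomeningeal compartment mask from a vessel-density atlas
#'
#' Binarises a coregistered vessel-density atlas (density > 0) after
#' subtracting the venous sinuses and large cerebral veins. The spatial
#' extent of the leptomeningeal compartment (lateral and cranial convexity)
#' is delegated to the atlas's own support.
#'
#' @param atlas_density vessel-density [scalar_map()] in PWI space.
#' @param sinus_veins [binary_mask()] of sinuses and large veins.
#' @return A [binary_mask()] labelled `"leptomeningeal"`.
#' @export
leptomeningeal_mask <- function(atlas_density, sinus_veins) {
  stopifnot(inherits(atlas_density, "cvi_scalar_map"),
            inherits(sinus_veins, "cvi_binary_mask"))
  stop_geometry_mismatch(atlas_density$geometry, sinus_veins$geometry,
                         "atlas and sinus mask")
  out <- is.finite(atlas_density$data) & atlas_density$data > 0 &
    !sinus_veins$data
  dim(out) <- atlas_density$geometry$shape
  binary_mask(out, atlas_density$geometry, label = "leptomeningeal")
}

#' Collateral vessel index from the high-CV mask
#'
#' Intersects the cleaned high-CV mask with the hemisphere-split
#' leptomeningeal compartment and reports
#' `CVI = highCV affected volume (mm^3) / highCV unaffected volume (mm^3)`.
#'
#' @param highcv cleaned high-CV [binary_mask()].
#' @param lepto a [split_hemispheres()] result for the leptomeningeal mask.
#' @param geometry the shared [geometry()].
#' @param cv_map optional CV [scalar_map()] to carry in the result.
#' @param threshold_used optional CV threshold to record.
#' @param bolus_peak optional 0-based bolus peak index to record.
#' @return A `cvi_result` with fields `cvi`, `highcv_affected_mm3`,
#'   `highcv_unaffected_mm3`, `highcv_mask`, `cv_map`, `threshold_used`,
#'   `bolus_peak_index`.
#' @export
compute_cvi <- function(highcv, lepto, geometry, cv_map = NULL,
                        threshold_used = NA_real_, bolus_peak = NA_integer_) {
  stopifnot(inherits(highcv, "cvi_binary_mask"),
            inherits(lepto, "cvi_hemisphere_split"))
  stop_geometry_mismatch(highcv$geometry, lepto$affected$geometry,
                         "highCV and leptomeningeal masks")
  vv <- voxel_volume(geometry)
  aff <- sum(highcv$data & lepto$affected$data) * vv
  unaff <- sum(highcv$data & lepto$unaffected$data) * vv
  if (unaff <= 0) {
    stop("collateral index undefined: no high-CV voxels in the unaffected leptomeningeal compartment",
         call. = FALSE)
  }
  structure(
    list(cvi = aff / unaff,
         highcv_affected_mm3 = aff,
         highcv_unaffected_mm3 = unaff,
         highcv_mask = highcv,
         cv_map = cv_map,
         threshold_used = threshold_used,
         bolus_peak_index = bolus_peak),
    class = "cvi_result"
  )
}

#' @export
print.cvi_result <- function(x, ...) {
  cat(sprintf("Collateral vessel index (CVI): %.4f\n", x$cvi))
  cat(sprintf("  highCV affected:   %.1f mm^3\n", x$highcv_affected_mm3))
  cat(sprintf("  highCV unaffected: %.1f mm^3\n", x$highcv_unaffected_mm3))
  if (is.finite(x$threshold_used)) {
    cat(sprintf("  CV threshold: %.4f, bolus peak at volume %d\n",
                x$threshold_used, x$bolus_peak_index))
  }
  invisible(x)
}

#' Dichotomize a collateral index at a cutoff
#'
#' Collateral status is `"good_moderate"` when `cvi >= cutoff` and `"poor"`
#' otherwise; the shipped default cutoff 0.963 is the cohort median used for
#' dichotomization.
#'
#' @param cvi numeric collateral index.
#' @param cutoff decision cutoff, default 0.963.
#' @return `"good_moderate"` or `"poor"`.
#' @export
dichotomize_cvi <- function(cvi, cutoff = 0.963) {
  ifelse(cvi >= cutoff, "good_moderate", "poor")
}

#' Full high-CV extraction from a motion-corrected series
#'
#' Convenience wrapper chaining [temporal_stats()], [cv_map()],
#' [threshold_highcv()], [bolus_peak_index()], [strip_low_intensity()] and
#' [exclude_ventricles()].
#'
#' @param series motion-corrected [perfusion_series()].
#' @param brain,ventricles [binary_mask()]s.
#' @param strip_fraction low-intensity strip fraction, default 0.05.
#' @param probs robust-range percentiles.
#' @return List with `highcv`, `cv`, `sigma`, `mu`, `threshold`, `t_star`.
#' @export
extract_highcv <- function(series, brain, ventricles,
                           strip_fraction = 0.05, probs = c(0.02, 0.98)) {
  st <- temporal_stats(series, brain)
  cv <- cv_map(st$sigma, st$mu)
  hc <- threshold_highcv(cv, brain, probs)
  thr <- attr(hc, "threshold")
  t_star <- bolus_peak_index(series, brain)
  hc <- strip_low_intensity(hc, series, t_star, strip_fraction)
  hc <- exclude_ventricles(hc, ventricles)
  list(highcv = hc, cv = cv, sigma = st$sigma, mu = st$mu,
       threshold = thr, t_star = t_star)
}
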