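#' DSC perfusion time series
#'
#' The raw 4D T2*-weighted bolus-passage signal S(v, t): a (x, y, z, t)
#' array in arbitrary units, with its grid geometry and the repetition
#' time between volumes.
#'
#' @param data 4D numeric array (x, y, z, t), finite and >= 0.
#' @param geom a [geometry()] matching the first three dimensions.
#' @param tr repetition time in seconds, > 0.
#' @return A `cvi_perfusion_series` object.
#' @export
perfusion_series <- function(data, geom, tr) {
  stopifnot(inherits(geom, "cvi_geometry"))
  d <- dim(data)
  if (length(d) != 4L) stop("perfusion series must be 4D", call. = FALSE)
  if (!identical(as.integer(d[1:3]), geom$shape)) {
    stop("series shape does not match geometry", call. = FALSE)
  }
  if (d[4] < 3L) {
    stop("need at least 3 volumes to estimate temporal statistics", call. = FALSE)
  }
  tr <- as.numeric(tr)
  if (!is.finite(tr) || tr <= 0) stop("tr must be > 0 seconds", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)) || any(data < 0)) {
    stop("series data must be finite and >= 0", call. = FALSE)
  }
  structure(list(data = data, geometry = geom, tr = tr),
            class = "cvi_perfusion_series")
}

#' 3D scalar map (sigma, mu, CV, ADC, TTP, TTP-delay, ...)
#'
#' @param data 3D numeric array.
#' @param geom a [geometry()].
#' @param units free-text unit tag, e.g. `"a.u."`, `"s"`, `"mm2/s"`.
#' @return A `cvi_scalar_map` object.
#' @export
scalar_map <- function(data, geom, units = "a.u.") {
  stopifnot(inherits(geom, "cvi_geometry"))
  d <- dim(data)
  if (length(d) != 3L || !identical(as.integer(d), geom$shape)) {
    stop("map shape does not match geometry", call. = FALSE)
  }
  structure(list(data = data, geometry = geom, units = units),
            class = "cvi_scalar_map")
}

#' 3D binary mask (brain, ventricles, highCV, lesions, ...)
#'
#' @param data 3D logical array (numeric input is taken as != 0).
#' @param geom a [geometry()].
#' @param label free-text label.
#' @return A `cvi_binary_mask` object.
#' @export
binary_mask <- function(data, geom, label = "") {
  stopifnot(inherits(geom, "cvi_geometry"))
  d <- dim(data)
  if (length(d) != 3L || !identical(as.integer(d), geom$shape)) {
    stop("mask shape does not match geometry", call. = FALSE)
  }
  if (!is.logical(data)) {
    dd <- d
    data <- data != 0
    dim(data) <- dd
  }
  structure(list(data = data, geometry = geom, label = label),
            class = "cvi_binary_mask")
}

#' @export
print.cvi_perfusion_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<perfusion series %s voxels x %d volumes, TR %.3g s>\n",
              paste(d[1:3], collapse = "x"), d[4], x$tr))
  invisible(x)
}

#' @export
print.cvi_scalar_map <- function(x, ...) {
  v <- x$data[is.finite(x$data)]
  cat(sprintf("<scalar map %s [%s], range %.4g..%.4g>\n",
              paste(dim(x$data), collapse = "x"), x$units,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
print.cvi_binary_mask <- function(x, ...) {
  cat(sprintf("<binary mask %s '%s', %d voxels set (%.1f mm^3)>\n",
              paste(dim(x$data), collapse = "x"), x$label, sum(x$data),
              sum(x$data) * voxel_volume(x$geometry)))
  invisible(x)
}

#' Number of set voxels times voxel volume, in mm^3
#' @param mask a [binary_mask()].
#' @return scalar mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "cvi_binary_mask"))
  sum(mask$data) * voxel_volume(mask$geometry)
}
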