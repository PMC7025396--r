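#' Voxel grid geometry
#'
#' Describes the sampling grid shared by all volumes of a case: grid shape,
#' voxel size in mm, the voxel-to-world affine (NIfTI convention: 0-based
#' voxel indices to world mm, RAS orientation after loading), and which array
#' axis runs left-right (its midpoint defines the median plane used to split
#' hemispheres).
#'
#' @param shape integer(3), voxels per axis.
#' @param voxel_size numeric(3), voxel edge lengths in mm, all > 0.
#' @param affine 4x4 voxel-to-world transform in mm; defaults to a diagonal
#'   built from `voxel_size` centred on the grid.
#' @param left_right_axis which array axis (1..3) is left-right; with RAS
#'   internal ordering this is axis 1 and lower indices are the left side.
#' @return A `cvi_geometry` object.
#' @export
geometry <- function(shape, voxel_size, affine = NULL, left_right_axis = 1L) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(shape) == 3L, length(voxel_size) == 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("voxel sizes must all be positive", call. = FALSE)
  }
  if (any(shape < 1L)) stop("shape must be positive", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (shape - 1) / 2
  }
  affine <- matrix(as.numeric(affine), 4, 4)
  left_right_axis <- as.integer(left_right_axis)
  stopifnot(left_right_axis %in% 1:3)
  structure(
    list(shape = shape, voxel_size = voxel_size, affine = affine,
         left_right_axis = left_right_axis),
    class = "cvi_geometry"
  )
}

#' Voxel volume in mm^3
#' @param geom a [geometry()] object.
#' @return scalar mm^3.
#' @export
voxel_volume <- function(geom) {
  stopifnot(inherits(geom, "cvi_geometry"))
  prod(geom$voxel_size)
}

#' @export
print.cvi_geometry <- function(x, ...) {
  cat(sprintf("<geometry %s voxels, %s mm, voxel volume %.3f mm^3>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              voxel_volume(x)))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

stop_geometry_mismatch <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b)) {
    stop(sprintf("geometry mismatch between %s", what), call. = FALSE)
  }
  invisible(TRUE)
}
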