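# NIfTI-1 input/output.
#
# No NIfTI package ships with the supported toolchain, so the format is read
# and written directly. Coverage: single-file .nii / .nii.gz, NIfTI-1 headers,
# datatypes uint8/int8/int16/uint16/int32/uint32/float32/float64, both
# endiannesses, scl_slope/scl_inter scaling, sform (preferred) and qform
# affines. On load, volumes are reoriented to RAS voxel order using the
# affine, so "left" is always the low-index half of axis 1.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE),
  `768` = list(what = "integer", size = 4L, signed = FALSE)
)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_nifti_raw <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_bytes <- readBin(con, "raw", n = 348L)
  if (length(hdr_bytes) < 348L) stop("file too short to be NIfTI-1", call. = FALSE)
  rd <- function(what, n, size, at, endian, signed = TRUE) {
    readBin(hdr_bytes[(at + 1L):(at + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd("integer", 1L, 4L, 0L, endian) != 348L) {
    endian <- "big"
    if (rd("integer", 1L, 4L, 0L, endian) != 348L) {
      stop("not a NIfTI-1 file (sizeof_hdr != 348)", call. = FALSE)
    }
  }
  magic <- rawToChar(hdr_bytes[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("missing NIfTI magic string", call. = FALSE)
  dim_field <- rd("integer", 8L, 2L, 40L, endian)
  ndim <- dim_field[1]
  if (ndim < 3L || ndim > 4L) {
    stop(sprintf("unsupported image dimensionality %d", ndim), call. = FALSE)
  }
  shape <- dim_field[2:(1 + ndim)]
  datatype <- rd("integer", 1L, 2L, 70L, endian)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("unsupported NIfTI datatype %d", datatype), call. = FALSE)
  pixdim <- rd("double", 8L, 4L, 76L, endian)
  vox_offset <- rd("double", 1L, 4L, 108L, endian)
  scl_slope <- rd("double", 1L, 4L, 112L, endian)
  scl_inter <- rd("double", 1L, 4L, 116L, endian)
  qform_code <- rd("integer", 1L, 2L, 252L, endian)
  sform_code <- rd("integer", 1L, 2L, 254L, endian)
  quatern <- rd("double", 3L, 4L, 256L, endian)
  qoffset <- rd("double", 3L, 4L, 268L, endian)
  srow <- rbind(rd("double", 4L, 4L, 280L, endian),
                rd("double", 4L, 4L, 296L, endian),
                rd("double", 4L, 4L, 312L, endian))
  if (any(pixdim[2:4] <= 0) || any(!is.finite(pixdim[2:4]))) {
    stop("non-positive voxel sizes in NIfTI header", call. = FALSE)
  }
  con2 <- nifti_connection(path, "rb")
  on.exit(close(con2), add = TRUE)
  readBin(con2, "raw", n = as.integer(max(vox_offset, 348)))
  n_vox <- prod(shape)
  data <- readBin(con2, dt$what, n = n_vox, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(data) < n_vox) stop("truncated NIfTI data section", call. = FALSE)
  data <- as.numeric(data)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  dim(data) <- shape
  affine <- if (sform_code > 0L) {
    rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    qform_affine(quatern, qoffset, pixdim)
  } else {
    a <- diag(c(pixdim[2:4], 1))
    a
  }
  list(data = data, shape = shape, pixdim = pixdim, affine = affine, ndim = ndim)
}

qform_affine <- function(q, offset, pixdim) {
  b <- q[1]; c_ <- q[2]; d <- q[3]
  a2 <- 1 - b^2 - c_^2 - d^2
  a <- if (a2 < 1e-7) 0 else sqrt(a2)
  qfac <- if (pixdim[1] < 0) -1 else 1
  R <- matrix(c(
    a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),    2 * (b * d + a * c_),
    2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2,  2 * (c_ * d - a * b),
    2 * (b * d - a * c_),   2 * (c_ * d + a * b),    a^2 + d^2 - b^2 - c_^2
  ), 3, 3, byrow = TRUE)
  R <- R %*% diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
  rbind(cbind(R, offset), c(0, 0, 0, 1))
}

# Reorient an array (3D or 4D) to RAS voxel order using the affine: each
# voxel axis is assigned to its dominant world axis and flipped if needed.
# Exact for axis-aligned affines; nearest-axis approximation for oblique.
reorient_ras <- function(data, affine) {
  A <- affine[1:3, 1:3]
  dom <- apply(abs(A), 2, which.max)
  if (anyDuplicated(dom)) {
    # degenerate/oblique header; leave as stored
    return(list(data = data, affine = affine))
  }
  perm <- order(dom)               # new axis k comes from old axis perm[k]
  signs <- sign(A[cbind(dom, seq_len(3))])[perm]
  d <- dim(data)
  nd <- length(d)
  perm_full <- c(perm, if (nd == 4L) 4L)
  if (!identical(perm_full[1:3], 1:3) || any(signs < 0)) {
    data <- aperm(data, perm_full)
    idx <- lapply(seq_len(nd), function(i) seq_len(dim(data)[i]))
    for (k in 1:3) if (signs[k] < 0) idx[[k]] <- rev(idx[[k]])
    data <- do.call(`[`, c(list(data), idx, list(drop = FALSE)))
    # new affine: old voxel index = P %*% new index + offset
    n_new <- dim(data)[1:3]
    P <- matrix(0, 4, 4); P[4, 4] <- 1
    for (k in 1:3) {
      P[perm[k], k] <- signs[k]
      if (signs[k] < 0) P[perm[k], 4] <- n_new[k] - 1
    }
    affine <- affine %*% P
  }
  list(data = data, affine = affine)
}

#' Read a NIfTI volume
#'
#' Reads a 3D map or 4D perfusion series from a `.nii` / `.nii.gz` file,
#' reorients it to RAS voxel order, and carries the grid geometry from the
#' header (sform preferred over qform). For 4D reads the repetition time is
#' taken from `pixdim[4]` when positive, otherwise from the `tr` argument.
#'
#' @param path file path.
#' @param expected_dims 3 or 4.
#' @param tr fallback repetition time in seconds for 4D files whose header
#'   leaves `pixdim[4]` unset; if the header value disagrees with a supplied
#'   `tr` by more than 1\%, the supplied value wins with a warning.
#' @param units unit tag attached to 3D maps.
#' @return A [perfusion_series()] for `expected_dims = 4`, otherwise a
#'   [scalar_map()].
#' @export
read_volume <- function(path, expected_dims, tr = NULL, units = "a.u.") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  stopifnot(expected_dims %in% c(3L, 4L))
  raw <- read_nifti_raw(path)
  if (raw$ndim != expected_dims) {
    stop(sprintf("expected a %dD image but '%s' is %dD",
                 expected_dims, basename(path), raw$ndim), call. = FALSE)
  }
  ro <- reorient_ras(raw$data, raw$affine)
  vs <- sqrt(colSums(ro$affine[1:3, 1:3]^2))
  geom <- geometry(dim(ro$data)[1:3], vs, ro$affine, left_right_axis = 1L)
  if (expected_dims == 4L) {
    hdr_tr <- raw$pixdim[5]
    use_tr <- if (is.finite(hdr_tr) && hdr_tr > 0) hdr_tr else tr
    if (is.null(use_tr)) {
      stop("header has no repetition time (pixdim[4]); supply tr", call. = FALSE)
    }
    if (!is.null(tr) && is.finite(hdr_tr) && hdr_tr > 0 &&
        abs(hdr_tr - tr) > 0.01 * tr) {
      warning(sprintf("header TR %.4g s disagrees with configured %.4g s; using configured",
                      hdr_tr, tr))
      use_tr <- tr
    }
    perfusion_series(ro$data, geom, use_tr)
  } else {
    scalar_map(ro$data, geom, units = units)
  }
}

#' Read a NIfTI binary mask
#'
#' @param path file path to a 3D mask image (nonzero = set).
#' @param label mask label.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, label = basename(path)) {
  m <- read_volume(path, expected_dims = 3L)
  binary_mask(m$data != 0 & is.finite(m$data), m$geometry, label = label)
}

#' Write a volume as NIfTI-1
#'
#' Scalar maps and perfusion series are written as float32, binary masks as
#' 8-bit 0/1 images. The geometry's affine goes into the sform (and an
#' identical qform-free header); 4D series store the repetition time in
#' `pixdim[4]`. `.gz` paths are gzip-compressed.
#'
#' @param vol a [scalar_map()], [binary_mask()] or [perfusion_series()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "cvi_perfusion_series")) {
    data <- vol$data; datatype <- 16L; bitpix <- 32L; tr <- vol$tr
  } else if (inherits(vol, "cvi_binary_mask")) {
    data <- vol$data + 0L; dim(data) <- dim(vol$data)
    datatype <- 2L; bitpix <- 8L; tr <- 0
  } else if (inherits(vol, "cvi_scalar_map")) {
    data <- vol$data; datatype <- 16L; bitpix <- 32L; tr <- 0
  } else {
    stop("unsupported volume type", call. = FALSE)
  }
  geom <- vol$geometry
  d <- dim(data)
  ndim <- length(d)
  dim_field <- rep(1L, 8); dim_field[1] <- ndim; dim_field[2:(1 + ndim)] <- d
  pixdim <- rep(0, 8)
  pixdim[1] <- 1; pixdim[2:4] <- geom$voxel_size; pixdim[5] <- tr
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wb(348L, 4L)                               # sizeof_hdr
  writeBin(raw(36), con)                     # unused through dim_info
  wb(as.integer(dim_field), 2L)              # dim[8]
  writeBin(raw(14), con)                     # intent_p1..intent_code
  wb(as.integer(datatype), 2L)
  wb(as.integer(bitpix), 2L)
  wb(0L, 2L)                                 # slice_start
  wb(pixdim, 4L)
  wb(352, 4L)                                # vox_offset
  wb(1, 4L); wb(0, 4L)                       # scl_slope, scl_inter
  wb(0L, 2L); writeBin(raw(1), con); writeBin(raw(1), con)  # slice_end, slice_code, xyzt_units
  wb(0, 4L); wb(0, 4L); wb(0, 4L)            # cal_max, cal_min, slice_duration
  wb(0, 4L)                                  # toffset
  wb(0L, 4L); wb(0L, 4L)                     # glmax, glmin
  writeBin(raw(80 + 24), con)                # descrip, aux_file
  wb(0L, 2L); wb(1L, 2L)                     # qform_code = 0, sform_code = 1
  wb(rep(0, 6), 4L)                          # quatern b,c,d + qoffset x,y,z
  wb(as.numeric(t(geom$affine[1:3, ])), 4L)  # srow_x, srow_y, srow_z
  writeBin(raw(16), con)                     # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)
  writeBin(raw(4), con)                      # extension flag
  vals <- as.numeric(data)
  vals[is.na(vals)] <- NaN
  if (datatype == 2L) {
    writeBin(as.integer(vals), con, size = 1L, endian = "little")
  } else {
    # writeBin caps each call at moderate sizes; chunk large arrays
    step <- 2^22
    for (s in seq(1, length(vals), by = step)) {
      e <- min(s + step - 1, length(vals))
      writeBin(vals[s:e], con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}
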