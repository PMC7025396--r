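# Rigid (6-DOF) registration: motion correction of the DSC series against its
# temporal mean, and coregistration of ADC/DWI-derived maps into PWI space.
# The contract (mean-volume reference, multi-resolution similarity
# optimisation, trilinear resampling) matches the processing used clinically;
# no external registration toolkit is required.

#' Rigid world-space transform
#'
#' @param matrix 4x4 rigid transform in world mm, mapping moving-space world
#'   coordinates to fixed-space world coordinates.
#' @param cost_value final similarity value reached by the optimiser
#'   (higher = more similar), or `NA` for constructed transforms.
#' @return A `cvi_rigid_transform`.
#' @export
rigid_transform <- function(matrix, cost_value = NA_real_) {
  matrix <- base::matrix(as.numeric(matrix), 4, 4)
  R <- matrix[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) {
    stop("rotation block is not orthonormal", call. = FALSE)
  }
  if (abs(det(R) - 1) > 1e-6) {
    stop("rotation block must be a proper rotation (det = +1)", call. = FALSE)
  }
  if (any(abs(matrix[4, ] - c(0, 0, 0, 1)) > 1e-9)) {
    stop("last row must be (0, 0, 0, 1)", call. = FALSE)
  }
  structure(list(matrix = matrix, cost_value = cost_value),
            class = "cvi_rigid_transform")
}

#' @export
print.cvi_rigid_transform <- function(x, ...) {
  p <- transform_params(x)
  cat(sprintf("<rigid transform: t = (%.3f, %.3f, %.3f) mm, rot = (%.3f, %.3f, %.3f) deg>\n",
              p[1], p[2], p[3], p[4] * 180 / pi, p[5] * 180 / pi, p[6] * 180 / pi))
  invisible(x)
}

# p = (tx, ty, tz mm, rx, ry, rz rad); rotation about world point `center`
params_to_matrix <- function(p, center = c(0, 0, 0)) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  R <- Rz %*% Ry %*% Rx
  t <- center + p[1:3] - R %*% center
  rbind(cbind(R, t), c(0, 0, 0, 1))
}

# Decompose a rigid matrix back into (t, rx, ry, rz) about the world origin.
transform_params <- function(transform) {
  M <- transform$matrix
  R <- M[1:3, 1:3]
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2]); rz <- 0
  }
  c(M[1:3, 4], rx, ry, rz)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(transform) {
  rigid_transform(solve(transform$matrix), transform$cost_value)
}

#' Serialize / read a transform as a 4x4 row-major text matrix
#' @param transform a [rigid_transform()].
#' @param path text file path.
#' @return `write_transform` returns `path` invisibly; `read_transform` the
#'   transform.
#' @export
write_transform <- function(transform, path) {
  lines <- apply(transform$matrix, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = " ")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- matrix(scan(path, quiet = TRUE), 4, 4, byrow = TRUE)
  rigid_transform(m)
}

#' Resample a map through a rigid transform onto a target grid
#'
#' Scalar maps are resampled with trilinear interpolation (out-of-field =
#' `NaN`), binary masks with nearest-neighbour (out-of-field = 0, output
#' strictly 0/1).
#'
#' @param vol a [scalar_map()] or [binary_mask()].
#' @param transform a [rigid_transform()] mapping the volume's world space to
#'   the target world space.
#' @param target_geometry the output [geometry()].
#' @return The resampled object of the same type.
#' @export
apply_transform <- function(vol, transform, target_geometry) {
  stopifnot(inherits(transform, "cvi_rigid_transform"),
            inherits(target_geometry, "cvi_geometry"))
  is_mask <- inherits(vol, "cvi_binary_mask")
  if (!is_mask && !inherits(vol, "cvi_scalar_map")) {
    stop("apply_transform expects a scalar map or binary mask", call. = FALSE)
  }
  M <- solve(vol$geometry$affine) %*% solve(transform$matrix) %*%
    target_geometry$affine
  src <- if (is_mask) vol$data + 0 else vol$data
  dim(src) <- dim(vol$data)
  out <- resample_affine_cpp(src, dim(vol$data), M, target_geometry$shape,
                             mode = if (is_mask) 1L else 0L,
                             oob = if (is_mask) 0 else NaN)
  if (is_mask) {
    binary_mask(out > 0.5, target_geometry, label = vol$label)
  } else {
    scalar_map(out, target_geometry, units = vol$units)
  }
}

resample_volume <- function(data, src_geom, transform_matrix, dst_geom,
                            mode = 0L, oob = 0) {
  M <- solve(src_geom$affine) %*% solve(transform_matrix) %*% dst_geom$affine
  resample_affine_cpp(data, dim(data), M, dst_geom$shape, mode, oob)
}

# Mean-pool a 3D array by integer factor f (truncating ragged edges) and
# derive the matching coarse geometry.
downsample_level <- function(data, geom, f) {
  if (f == 1L) return(list(data = data, geom = geom))
  d <- dim(data)
  nd <- pmax(d %/% f, 1L)
  data <- data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f),
               drop = FALSE]
  dim(data) <- c(f, nd[1], f, nd[2], f, nd[3])
  data <- aperm(data, c(2, 4, 6, 1, 3, 5))
  data <- rowMeans(data, dims = 3)
  A <- geom$affine
  A2 <- A
  A2[1:3, 1:3] <- A[1:3, 1:3] * f
  A2[1:3, 4] <- A[1:3, 4] + A[1:3, 1:3] %*% rep((f - 1) / 2, 3)
  list(data = data, geom = geometry(nd, geom$voxel_size * f, A2,
                                    geom$left_right_axis))
}

# Correlation ratio of `moving` given `fixed` intensities (higher = better).
similarity_cr <- function(fixed, moving, nbins = 32L) {
  rng <- range(fixed)
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  b <- findInterval(fixed, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  n <- length(moving)
  tot_ss <- sum(moving^2) - sum(moving)^2 / n
  if (tot_ss <= 0) return(0)
  sums <- rowsum(cbind(moving, moving^2, 1), b)
  within <- sum(sums[, 2] - sums[, 1]^2 / sums[, 3])
  1 - within / tot_ss
}

# Normalised mutual information (Studholme), higher = better.
similarity_nmi <- function(fixed, moving, nbins = 32L) {
  bin <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(rep(1L, length(x)))
    findInterval(x, seq(rng[1], rng[2], length.out = nbins + 1L),
                 rightmost.closed = TRUE, all.inside = TRUE)
  }
  bf <- bin(fixed); bm <- bin(moving)
  joint <- tabulate(bf + nbins * (bm - 1L), nbins * nbins)
  p <- joint / sum(joint)
  px <- rowSums(matrix(p, nbins)); py <- colSums(matrix(p, nbins))
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hxy <- H(p)
  if (hxy == 0) return(1)
  (H(px) + H(py)) / hxy
}

register_cost_factory <- function(moving, mgeom, fixed, fgeom, metric, center) {
  fdim <- fgeom$shape
  Af <- fgeom$affine
  Am_inv <- solve(mgeom$affine)
  fvec <- as.vector(fixed)
  sim <- if (metric == "nmi") similarity_nmi else similarity_cr
  function(p) {
    T <- params_to_matrix(p, center)
    M <- Am_inv %*% solve(T) %*% Af
    s <- resample_affine_cpp(moving, dim(moving), M, fdim, 0L, NaN)
    ok <- !is.na(s)
    if (sum(ok) < 0.1 * length(fvec)) return(1e6)  # lost overlap
    -sim(fvec[ok], s[ok])
  }
}

world_center <- function(geom) {
  as.vector(geom$affine %*% c((geom$shape - 1) / 2, 1))[1:3]
}

fov_overlap_fraction <- function(mgeom, fgeom) {
  # fraction of fixed voxel centers (coarse grid) inside the moving FOV
  gr <- lapply(1:3, function(a) unique(round(seq(0, fgeom$shape[a] - 1,
                                                 length.out = 12))))
  pts <- as.matrix(expand.grid(gr[[1]], gr[[2]], gr[[3]]))
  w <- fgeom$affine %*% rbind(t(pts), 1)
  v <- solve(mgeom$affine) %*% w
  inside <- v[1, ] > -0.5 & v[1, ] < mgeom$shape[1] - 0.5 &
    v[2, ] > -0.5 & v[2, ] < mgeom$shape[2] - 0.5 &
    v[3, ] > -0.5 & v[3, ] < mgeom$shape[3] - 0.5
  mean(inside)
}

# Intensity-weighted centre of mass in world mm.
centre_of_mass <- function(data, geom) {
  d <- dim(data)
  w <- pmax(data, 0)
  tot <- sum(w)
  if (tot <= 0) return(world_center(geom))
  # axis-wise marginal sums
  mx <- apply(w, 1, sum); my <- apply(w, 2, sum); mz <- apply(w, 3, sum)
  v <- c(sum(mx * (seq_len(d[1]) - 1)),
         sum(my * (seq_len(d[2]) - 1)),
         sum(mz * (seq_len(d[3]) - 1))) / tot
  as.vector(geom$affine %*% c(v, 1))[1:3]
}

register_rigid <- function(moving, mgeom, fixed, fgeom,
                           metric = "cr", levels = c(2L, 1L),
                           maxit = c(150L, 75L), init = NULL) {
  center <- world_center(fgeom)
  if (is.null(init)) {
    # moving -> fixed translation seeding: align centres of mass, so the
    # optimiser starts near the optimum even for multi-voxel shifts
    init <- c(centre_of_mass(fixed, fgeom) - centre_of_mass(moving, mgeom),
              0, 0, 0)
  }
  p <- init
  value <- NA_real_
  for (li in seq_along(levels)) {
    f <- levels[li]
    mv <- downsample_level(moving, mgeom, f)
    fx <- downsample_level(fixed, fgeom, f)
    cost <- register_cost_factory(mv$data, mv$geom, fx$data, fx$geom,
                                  metric, center)
    res <- optim(p, cost, method = "Nelder-Mead",
                 control = list(
                   maxit = maxit[min(li, length(maxit))],
                   reltol = 1e-9,
                   parscale = c(1, 1, 1, 0.02, 0.02, 0.02)))
    p <- res$par
    value <- -res$value
  }
  rigid_transform(params_to_matrix(p, center), cost_value = value)
}

#' Rigid coregistration of two scalar maps
#'
#' Finds the 6-DOF transform mapping the moving map's world space onto the
#' fixed map's, maximising the configured similarity metric over a
#' multi-resolution schedule. Deterministic given identical inputs and
#' settings.
#'
#' @param moving,fixed [scalar_map()]s with overlapping fields of view.
#' @param metric `"cr"` (correlation ratio, default) or `"nmi"` (normalised
#'   mutual information).
#' @param levels integer downsampling factors, coarse to fine.
#' @return A [rigid_transform()]; apply with [apply_transform()].
#' @export
coregister <- function(moving, fixed, metric = c("cr", "nmi"),
                       levels = c(2L, 1L)) {
  stopifnot(inherits(moving, "cvi_scalar_map"),
            inherits(fixed, "cvi_scalar_map"))
  metric <- match.arg(metric)
  if (fov_overlap_fraction(moving$geometry, fixed$geometry) < 0.10) {
    stop("fields of view overlap by less than 10%; cannot register",
         call. = FALSE)
  }
  mdat <- moving$data; mdat[!is.finite(mdat)] <- 0
  fdat <- fixed$data; fdat[!is.finite(fdat)] <- 0
  register_rigid(mdat, moving$geometry, fdat, fixed$geometry,
                 metric = metric, levels = levels)
}

#' Motion-correct a DSC perfusion series
#'
#' Registers every volume rigidly (6 DOF) to the temporal mean volume and
#' resamples it back onto the series grid with trilinear interpolation
#' (out-of-field voxels set to 0).
#'
#' @param series a [perfusion_series()] with at least 3 volumes.
#' @param metric similarity metric, as in [coregister()].
#' @param levels multi-resolution factors, coarse to fine.
#' @return List with `series` (corrected [perfusion_series()]) and
#'   `transforms` (one [rigid_transform()] per volume).
#' @export
motion_correct <- function(series, metric = "cr", levels = c(2L, 1L)) {
  stopifnot(inherits(series, "cvi_perfusion_series"))
  geom <- series$geometry
  nt <- dim(series$data)[4]
  ref <- rowMeans(series$data, dims = 3)
  out <- series$data
  transforms <- vector("list", nt)
  for (t in seq_len(nt)) {
    vol <- series$data[, , , t]
    dim(vol) <- geom$shape
    tr_t <- tryCatch(
      register_rigid(vol, geom, ref, geom, metric = metric, levels = levels),
      error = function(e) {
        stop(sprintf("motion correction failed at volume %d: %s",
                     t - 1L, conditionMessage(e)), call. = FALSE)
      })
    transforms[[t]] <- tr_t
    corr <- resample_volume(vol, geom, tr_t$matrix, geom, mode = 0L, oob = 0)
    corr[corr < 0] <- 0
    out[, , , t] <- corr
  }
  list(series = perfusion_series(out, geom, series$tr),
       transforms = transforms)
}
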