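test_that("rigid transforms validate orthonormality and invert exactly", {
  p <- c(2, -1, 0.5, 0.03, -0.02, 0.05)
  M <- cvipwi:::params_to_matrix(p)
  tf <- rigid_transform(M)
  expect_equal(invert_transform(tf)$matrix %*% tf$matrix, diag(4),
               tolerance = 1e-12)
  bad <- M; bad[1, 1] <- 2
  expect_error(rigid_transform(bad), "orthonormal")
  refl <- diag(c(-1, 1, 1, 1))
  expect_error(rigid_transform(refl), "proper rotation")
})

test_that("transforms serialize as 4x4 row-major text and read back", {
  tf <- rigid_transform(cvipwi:::params_to_matrix(c(1, 2, 3, 0.1, 0, -0.1)))
  f <- withr::local_tempfile(fileext = ".mat")
  write_transform(tf, f)
  expect_equal(read_transform(f)$matrix, tf$matrix, tolerance = 1e-12)
})

test_that("apply_transform respects the identity and the mask contract", {
  g <- geometry(c(12L, 10L, 6L), c(2, 2, 4))
  set.seed(5)
  arr <- array(runif(12 * 10 * 6, 0, 10), c(12, 10, 6))
  m <- scalar_map(arr, g)
  idt <- rigid_transform(diag(4))
  out <- apply_transform(m, idt, g)
  expect_equal(out$data, arr, tolerance = 1e-12)

  mask <- binary_mask(arr > 5, g)
  tf <- rigid_transform(cvipwi:::params_to_matrix(c(1.3, -0.7, 2.1, 0.05, 0.02, -0.04)))
  mout <- apply_transform(mask, tf, g)
  expect_type(mout$data, "logical")   # strictly 0/1 under nearest-neighbour
})

test_that("integer-voxel translation of an interior mask preserves its count", {
  g <- geometry(c(16L, 16L, 8L), c(2, 2, 4))
  m <- array(FALSE, g$shape)
  m[6:10, 6:10, 3:5] <- TRUE
  mask <- binary_mask(m, g)
  shift <- diag(4); shift[1, 4] <- 2  # one voxel along x (2 mm)
  out <- apply_transform(mask, rigid_transform(shift), g)
  expect_equal(sum(out$data), sum(m))
  expect_true(all(which(out$data) != which(m)))
})

test_that("transforming forward then back recovers interior values", {
  g <- geometry(c(20L, 20L, 10L), c(2, 2, 4))
  # smooth phantom: 3D Gaussian blob
  co <- lapply(1:3, function(a) seq_len(g$shape[a]) - (g$shape[a] + 1) / 2)
  r2 <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2 * 2, `+`)
  arr <- exp(-r2 / 120)
  m <- scalar_map(arr, g)
  tf <- rigid_transform(cvipwi:::params_to_matrix(c(1.2, -0.8, 1.5, 0.04, -0.03, 0.05)))
  fwd <- apply_transform(m, tf, g)
  back <- apply_transform(fwd, invert_transform(tf), g)
  interior <- array(FALSE, g$shape)
  interior[5:16, 5:16, 4:7] <- TRUE
  ok <- interior & is.finite(back$data)
  expect_lt(max(abs(back$data[ok] - arr[ok])), 0.05 * diff(range(arr)))
})

test_that("coregistration recovers identity and a known 3 mm translation", {
  p <- build_phantom(tiny_spec(noise_sigma = 0))
  fixed <- scalar_map(rowMeans(p$series$data, dims = 3), p$series$geometry)
  self <- coregister(fixed, fixed)
  pr <- cvipwi:::transform_params(self)
  expect_lt(max(abs(pr[1:3])), 0.1)                 # mm
  expect_lt(max(abs(pr[4:6])) * 180 / pi, 0.1)      # degrees

  g2 <- fixed$geometry
  g2$affine[1, 4] <- g2$affine[1, 4] + 3
  moved <- scalar_map(fixed$data, g2)
  tf <- coregister(moved, fixed)
  expect_lt(abs(abs(cvipwi:::transform_params(tf)[1]) - 3), 0.5)
})

test_that("disjoint fields of view raise a registration error", {
  g1 <- geometry(c(10L, 10L, 5L), c(2, 2, 4))
  g2 <- geometry(c(10L, 10L, 5L), c(2, 2, 4))
  g2$affine[1:3, 4] <- g2$affine[1:3, 4] + c(500, 500, 500)
  a <- scalar_map(array(1, g1$shape), g1)
  b <- scalar_map(array(1, g2$shape), g2)
  expect_error(coregister(a, b), "overlap")
})

test_that("motion correction finds no motion in a motionless phantom", {
  p <- build_phantom(tiny_spec(noise_sigma = 0, n_volumes = 8L))
  mc <- motion_correct(p$series)
  pars <- t(sapply(mc$transforms, cvipwi:::transform_params))
  expect_lt(max(abs(pars[, 1:3])), 0.1)
  expect_lt(max(abs(pars[, 4:6])) * 180 / pi, 0.1)
})

test_that("motion correction recovers an applied 2-voxel shift and lowers sigma", {
  p <- build_phantom(tiny_spec(
    n_volumes = 10L,
    motion = list(list(volume = 4L, shift_voxels = c(2, 0, 0)))))
  mc <- motion_correct(p$series)
  rec <- cvipwi:::transform_params(mc$transforms[[5]])
  vx <- p$series$geometry$voxel_size[1]
  # content was shifted +2 voxels; the recovered moving->fixed translation
  # undoes it
  expect_lt(abs(rec[1] / vx - (-2)), 0.25)
  st_un <- temporal_stats(p$series, p$truth$brain)
  st_co <- temporal_stats(mc$series, p$truth$brain)
  expect_lt(mean(st_co$sigma$data[p$truth$brain$data]),
            mean(st_un$sigma$data[p$truth$brain$data]))
})

test_that("motion correction is idempotent within a quarter voxel", {
  p <- build_phantom(tiny_spec(
    n_volumes = 8L,
    motion = list(list(volume = 3L, shift_voxels = c(1.5, 0, 0)))))
  mc1 <- motion_correct(p$series)
  mc2 <- motion_correct(mc1$series)
  pars <- t(sapply(mc2$transforms, cvipwi:::transform_params))
  expect_lt(max(abs(pars[, 1:3])) / min(p$series$geometry$voxel_size), 0.25)
})
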