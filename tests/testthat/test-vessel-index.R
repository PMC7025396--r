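make_series <- function(arr, voxel_size = c(1, 1, 1), tr = 1.5) {
  g <- geometry(dim(arr)[1:3], voxel_size)
  perfusion_series(arr, g, tr)
}
all_mask <- function(geom) binary_mask(array(TRUE, geom$shape), geom)

test_that("temporal statistics use the population (1/N) normalisation", {
  arr <- array(100, c(2, 2, 1, 5))
  s <- make_series(arr)
  st <- temporal_stats(s, all_mask(s$geometry))
  expect_equal(unique(as.vector(st$mu$data)), 100)
  expect_equal(unique(as.vector(st$sigma$data)), 0)

  arr2 <- array(0, c(1, 1, 1, 4))
  arr2[1, 1, 1, ] <- c(10, 10, 4, 10)
  s2 <- make_series(arr2)
  st2 <- temporal_stats(s2, all_mask(s2$geometry))
  expect_equal(as.vector(st2$mu$data), 8.5)
  expect_equal(as.vector(st2$sigma$data), sqrt(6.75))
  cv <- cv_map(st2$sigma, st2$mu)
  expect_equal(as.vector(cv$data), sqrt(6.75) / 8.5, tolerance = 1e-12)
})

test_that("vectorized temporal stats match a per-voxel loop oracle", {
  set.seed(31)
  arr <- array(runif(4 * 4 * 2 * 10, 50, 150), c(4, 4, 2, 10))
  s <- make_series(arr)
  st <- temporal_stats(s, all_mask(s$geometry))
  for (i in 1:4) for (j in 1:4) for (k in 1:2) {
    x <- arr[i, j, k, ]
    mu <- sum(x) / length(x)
    sg <- sqrt(sum((x - mu)^2) / length(x))
    expect_lt(abs(st$mu$data[i, j, k] - mu), 1e-10)
    expect_lt(abs(st$sigma$data[i, j, k] - sg), 1e-10)
  }
})

test_that("masking zeroes stats outside the brain", {
  set.seed(1)
  arr <- array(runif(4 * 4 * 2 * 6, 10, 20), c(4, 4, 2, 6))
  s <- make_series(arr)
  m <- array(FALSE, c(4, 4, 2)); m[1:2, , ] <- TRUE
  st <- temporal_stats(s, binary_mask(m, s$geometry))
  expect_true(all(st$mu$data[!m] == 0))
  expect_true(all(st$mu$data[m] > 0))
})

test_that("CV guards division by zero and is scale invariant", {
  g <- geometry(c(3L, 1L, 1L), c(1, 1, 1))
  sg <- scalar_map(array(c(2, 3, 0), c(3, 1, 1)), g)
  mu <- scalar_map(array(c(4, 0, 0), c(3, 1, 1)), g)
  cv <- cv_map(sg, mu)
  expect_equal(as.vector(cv$data), c(0.5, 0, 0))

  set.seed(8)
  arr <- array(runif(4 * 4 * 2 * 8, 100, 300), c(4, 4, 2, 8))
  s1 <- make_series(arr); s7 <- make_series(arr * 7)
  m <- all_mask(s1$geometry)
  st1 <- temporal_stats(s1, m); st7 <- temporal_stats(s7, m)
  cv1 <- cv_map(st1$sigma, st1$mu); cv7 <- cv_map(st7$sigma, st7$mu)
  expect_lt(max(abs(cv1$data - cv7$data)), 1e-12)
})

test_that("robust range is the 2nd/98th percentile of positive in-mask values", {
  g <- geometry(c(10L, 10L, 1L), c(1, 1, 1))
  m <- scalar_map(array(1:100, g$shape), g)
  rr <- robust_range(m, all_mask(g))
  expect_equal(rr, c(2.98, 98.02), tolerance = 1e-12)

  const <- scalar_map(array(7, g$shape), g)
  expect_equal(robust_range(const, all_mask(g)), c(7, 7))

  # zero-valued voxels do not move the range
  g2 <- geometry(c(10L, 10L, 2L), c(1, 1, 1))
  padded <- scalar_map(array(c(1:100, rep(0, 100)), g2$shape), g2)
  expect_equal(robust_range(padded, all_mask(g2)), c(2.98, 98.02),
               tolerance = 1e-12)

  few <- scalar_map(array(c(1:50, rep(0, 150)), g2$shape), g2)
  expect_error(robust_range(few, all_mask(g2)), "100")
})

test_that("highCV threshold keeps the upper 50% of the robust range", {
  g <- geometry(c(10L, 10L, 1L), c(1, 1, 1))
  cv <- scalar_map(array(1:100, g$shape), g)
  hc <- threshold_highcv(cv, all_mask(g))
  expect_equal(attr(hc, "threshold"), 50.5, tolerance = 1e-12)
  expect_identical(sum(hc$data), sum((1:100) >= 50.5))

  const <- scalar_map(array(3, g$shape), g)
  hc2 <- threshold_highcv(const, all_mask(g))
  expect_true(all(hc2$data))   # rmin = rmax = c, inclusive comparison
})

test_that("the phantom's vessel compartment is exactly what survives thresholding", {
  p <- build_phantom(tiny_spec(noise_sigma = 0))
  st <- temporal_stats(p$series, p$truth$brain)
  cv <- cv_map(st$sigma, st$mu)
  hc <- threshold_highcv(cv, p$truth$brain)
  vessel_like <- p$truth$vessels$data | p$truth$sinus$data
  expect_identical(hc$data, vessel_like)
})

test_that("bolus peak index minimises the in-mask mean signal, earliest tie", {
  p <- build_phantom(tiny_spec(noise_sigma = 0))
  t_star <- bolus_peak_index(p$series, p$truth$brain)
  peak_s <- p$spec$bolus$t0 + p$spec$bolus$alpha * p$spec$bolus$beta
  expect_lte(abs(t_star - peak_s / p$spec$tr), 1)

  up <- array(rep(1:6, each = 8), c(2, 2, 2, 6))
  s_up <- make_series(up)
  expect_identical(bolus_peak_index(s_up, all_mask(s_up$geometry)), 0L)

  flat <- make_series(array(5, c(2, 2, 2, 6)))
  expect_identical(bolus_peak_index(flat, all_mask(flat$geometry)), 0L)
})

test_that("low-intensity strip removes exactly the lowest 5% (sort oracle)", {
  set.seed(44)
  arr <- array(0, c(10, 10, 1, 3))
  vals <- sample(1:1000, 100)
  arr[, , 1, 2] <- vals
  arr[, , 1, c(1, 3)] <- 500
  s <- make_series(arr)
  hc <- all_mask(s$geometry)
  out <- strip_low_intensity(hc, s, t_star = 1L, fraction = 0.05)
  expect_equal(sum(out$data), 95)
  removed <- arr[, , 1, 2][!out$data]
  expect_setequal(removed, sort(vals)[1:5])

  # fraction -> 0 keeps everything
  out0 <- strip_low_intensity(hc, s, 1L, fraction = 1e-9)
  expect_identical(out0$data, hc$data)

  # all-equal intensities: nothing strictly below the quantile
  flat <- make_series(array(5, c(4, 4, 1, 3)))
  hc2 <- all_mask(flat$geometry)
  expect_identical(strip_low_intensity(hc2, flat, 0L)$data, hc2$data)

  empty <- binary_mask(array(FALSE, s$geometry$shape), s$geometry)
  expect_warning(res <- strip_low_intensity(empty, s, 1L), "empty")
  expect_false(any(res$data))
})

test_that("ventricle exclusion removes exactly the overlap", {
  g <- geometry(c(6L, 6L, 2L), c(1, 1, 1))
  set.seed(9)
  a <- array(runif(72) > 0.5, g$shape)
  v <- array(runif(72) > 0.7, g$shape)
  out <- exclude_ventricles(binary_mask(a, g), binary_mask(v, g))
  expect_equal(sum(out$data), sum(a) - sum(a & v))
  none <- exclude_ventricles(binary_mask(a, g),
                             binary_mask(array(FALSE, g$shape), g))
  expect_identical(none$data, a)
  all_v <- exclude_ventricles(binary_mask(a, g), binary_mask(a, g))
  expect_false(any(all_v$data))
})

test_that("leptomeningeal mask is the atlas support minus the sinuses", {
  g <- geometry(c(6L, 6L, 2L), c(1, 1, 1))
  dens <- array(0, g$shape); dens[2:5, 2:5, ] <- runif(32)
  sinus <- array(FALSE, g$shape); sinus[3, 3, ] <- TRUE
  lm <- leptomeningeal_mask(scalar_map(dens, g), binary_mask(sinus, g))
  expect_identical(lm$data, dens > 0 & !sinus)
  zero <- leptomeningeal_mask(scalar_map(array(0, g$shape), g),
                              binary_mask(sinus, g))
  expect_false(any(zero$data))
})

test_that("CVI is the mm^3 ratio of affected to unaffected highCV volume", {
  g <- geometry(c(8L, 4L, 2L), c(1.8, 1.8, 5.2))
  hc <- array(FALSE, g$shape)
  hc[2:3, 2:3, ] <- TRUE    # 8 voxels left
  hc[6, 2:3, ] <- TRUE      # 4 voxels right
  lepto <- split_hemispheres(binary_mask(array(TRUE, g$shape), g), "left")
  res <- compute_cvi(binary_mask(hc, g), lepto, g)
  expect_equal(res$cvi, 2)
  expect_equal(res$highcv_affected_mm3, 8 * voxel_volume(g))
  expect_equal(res$highcv_unaffected_mm3, 4 * voxel_volume(g))
  expect_equal(res$cvi, res$highcv_affected_mm3 / res$highcv_unaffected_mm3)

  # undefined index is an error, not Inf
  hc[, , ] <- FALSE; hc[2, 2, 1] <- TRUE
  expect_error(compute_cvi(binary_mask(hc, g), lepto, g), "undefined")
})

test_that("the CVI cutoff 0.963 dichotomizes collateral status", {
  expect_identical(dichotomize_cvi(0.963), "good_moderate")
  expect_identical(dichotomize_cvi(1.2), "good_moderate")
  expect_identical(dichotomize_cvi(0.962), "poor")
})

test_that("each exclusion step only ever shrinks the highCV mask", {
  p <- build_phantom(tiny_spec(seed = 5L))
  st <- temporal_stats(p$series, p$truth$brain)
  cv <- cv_map(st$sigma, st$mu)
  hc0 <- threshold_highcv(cv, p$truth$brain)
  t_star <- bolus_peak_index(p$series, p$truth$brain)
  hc1 <- strip_low_intensity(hc0, p$series, t_star, 0.05)
  hc2 <- exclude_ventricles(hc1, p$truth$ventricles)
  expect_true(all(hc1$data <= hc0$data))
  expect_true(all(hc2$data <= hc1$data))
})

test_that("mirroring the case and swapping the affected anatomy inverts the CVI", {
  p <- build_phantom(tiny_spec(asymmetry_ratio = 0.5, seed = 13L))
  res <- phantom_cvi(p, "left")
  pm <- mirror_phantom(p)
  res_m <- phantom_cvi(pm, "left")
  expect_equal(res_m$cvi, 1 / res$cvi, tolerance = 0.02)
})
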