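pwi_geom <- function(shape = c(20L, 20L, 8L)) geometry(shape, c(1.8, 1.8, 5.2))
full_brain <- function(g) binary_mask(array(TRUE, g$shape), g)

test_that("connected-component cleaning removes specks and fills holes", {
  g <- pwi_geom()
  brain <- full_brain(g)
  m <- array(FALSE, g$shape)
  m[4:13, 4:13, 2:6] <- TRUE            # 500-voxel blob
  expect_identical(clean_lesion(binary_mask(m, g), brain)$data, m)

  speckled <- m
  speckled[16, 16, c(1, 3, 5)] <- TRUE
  speckled[18, 2, c(2, 4)] <- TRUE      # five specks well under 300 mm^3
  expect_identical(clean_lesion(binary_mask(speckled, g), brain)$data, m)

  holey <- m
  holey[8, 8, 4] <- FALSE               # fully enclosed cavity
  expect_identical(clean_lesion(binary_mask(holey, g), brain)$data, m)

  empty <- binary_mask(array(FALSE, g$shape), g)
  expect_false(any(clean_lesion(empty, brain)$data))

  # diagonal neighbours are one 26-connected component
  diag2 <- array(FALSE, g$shape)
  diag2[5:9, 5:9, 3:4] <- TRUE
  diag2[10:14, 10:14, 5:6] <- TRUE      # touches corner-to-corner
  labs <- cvipwi:::label_components(diag2, 26L)
  expect_equal(max(labs), 1L)
})

test_that("core segmentation applies 0 < ADC < 600e-6 mm^2/s then cleaning", {
  g <- pwi_geom()
  brain <- full_brain(g)
  healthy <- scalar_map(array(800e-6, g$shape), g, units = "mm2/s")
  expect_false(any(segment_core(healthy, brain)$data))

  adc <- array(800e-6, g$shape)
  adc[4:13, 4:13, 2:6] <- 450e-6
  adc[1, , ] <- 0                       # background excluded by the lower guard
  core <- segment_core(scalar_map(adc, g, "mm2/s"), brain)
  expect_equal(sum(core$data), 500)
  expect_equal(mask_volume_mm3(core), 500 * 1.8 * 1.8 * 5.2)

  # values in 1e-6 mm^2/s are auto-detected from the in-brain median
  core2 <- segment_core(scalar_map(adc * 1e6, g, "a.u."), brain)
  expect_identical(core2$data, core$data)

  weird <- scalar_map(array(42, g$shape), g, "a.u.")
  expect_error(segment_core(weird, brain), "units")
})

test_that("TTP is TR times the frame of the signal minimum", {
  g <- pwi_geom(c(4L, 4L, 2L))
  arr <- array(100, c(4, 4, 2, 20))
  arr[1, 1, 1, 15] <- 40               # minimum at 0-based frame 14
  s <- perfusion_series(arr, g, 1.5)
  ttp <- ttp_map(s, full_brain(g))
  expect_equal(ttp$data[1, 1, 1], 21.0)
  expect_equal(ttp$data[2, 2, 2], 0)   # flat voxel ties to frame 0
  outside <- binary_mask(array(FALSE, g$shape), g)
  expect_true(all(is.nan(ttp_map(s, outside)$data)))
})

test_that("phantom TTP reflects the affected-side bolus delay", {
  p <- build_phantom(tiny_spec(delay_affected = 6, seed = 2L))
  ttp <- ttp_map(p$series, p$truth$brain)
  sp <- split_hemispheres(p$truth$brain, "left")
  aff <- exclude_ventricles(sp$affected, p$truth$ventricles)
  unaff <- exclude_ventricles(sp$unaffected, p$truth$ventricles)
  d <- median(ttp$data[aff$data]) - median(ttp$data[unaff$data])
  expect_lt(abs(d - 6), p$series$tr / 2)
})

test_that("TTP-delay is referenced to the contralesional median", {
  g <- pwi_geom(c(10L, 10L, 4L))
  ttp <- array(30, g$shape)
  ttp[1:5, , ] <- 36                   # affected half delayed 6 s
  unaff <- array(FALSE, g$shape); unaff[6:10, , ] <- TRUE
  delay <- ttp_delay(scalar_map(ttp, g, "s"), binary_mask(unaff, g))
  expect_equal(attr(delay, "reference_median_s"), 30)
  expect_true(all(delay$data[1:5, , ] == 6))
  expect_true(all(delay$data[6:10, , ] == 0))

  # shifting every TTP by a constant changes nothing
  delay2 <- ttp_delay(scalar_map(ttp + 11.5, g, "s"), binary_mask(unaff, g))
  expect_equal(delay2$data, delay$data)

  expect_error(ttp_delay(scalar_map(ttp, g, "s"),
                         binary_mask(array(FALSE, g$shape), g)), "empty")
})

block_delay_case <- function() {
  # three 100-voxel blocks at delays 0 / 5 / 10 s
  g <- pwi_geom(c(18L, 10L, 6L))
  delay <- array(0, g$shape)
  delay[2:6, 3:6, 2:6] <- 0
  delay[8:12, 3:6, 2:6] <- 5
  delay[14:18, 3:6, 2:6] <- 10
  list(g = g, delay = scalar_map(delay, g, "s"),
       core = binary_mask(array(FALSE, g$shape), g),
       brain = full_brain(g))
}

test_that("block delays {0, 5, 10} give nested compartments and HIR 0.5", {
  cs <- block_delay_case()
  comp <- compartments(cs$delay, cs$core, cs$brain)
  vv <- voxel_volume(cs$g)
  expect_equal(comp$at_risk_mm3, 200 * vv)
  expect_equal(comp$severe_mm3, 100 * vv)
  expect_equal(comp$perfusion_lesion_mm3, 200 * vv)
  expect_equal(comp$hir, 0.5)
  expect_true(all(comp$severe$data <= comp$at_risk$data))
  expect_true(all(comp$at_risk$data <= comp$perfusion$data))
})

test_that("HIR hits its 0 and 1 edge cases", {
  g <- pwi_geom(c(10L, 10L, 6L))
  brain <- full_brain(g)
  core <- binary_mask(array(FALSE, g$shape), g)
  d <- array(0, g$shape); d[3:8, 3:8, 2:5] <- 5
  comp <- compartments(scalar_map(d, g, "s"), core, brain)
  expect_equal(comp$hir, 0)

  d2 <- array(10, g$shape)
  comp2 <- compartments(scalar_map(d2, g, "s"), core, brain)
  expect_equal(comp2$hir, 1)

  d3 <- array(0, g$shape)
  comp3 <- compartments(scalar_map(d3, g, "s"), core, brain)
  expect_true(is.na(comp3$hir))        # no tissue at risk: undefined
})

test_that("mismatch region subtracts the core from the perfusion lesion", {
  g <- pwi_geom(c(12L, 8L, 6L))
  d <- array(0, g$shape); d[2:11, 2:7, 2:5] <- 6
  core <- array(FALSE, g$shape); core[2:5, 2:7, 2:5] <- TRUE
  comp <- compartments(scalar_map(d, g, "s"), binary_mask(core, g),
                       full_brain(g))
  expect_equal(sum(comp$mismatch$data), sum(comp$perfusion$data) - sum(core))
})

test_that("mismatch ratios divide by the DWI lesion volume", {
  r <- mismatch_ratios(20000, 7000, 2000)
  expect_equal(r$entire, 10)
  expect_equal(r$at_risk, 3.5)
  expect_lte(r$at_risk, r$entire)
  expect_equal(mismatch_ratios(5000, 5000, 5000)$entire, 1)
  expect_warning(u <- mismatch_ratios(5000, 1000, 0), "undefined")
  expect_true(is.na(u$entire))
})

test_that("cortical and subcortical core volumes sum exactly", {
  g <- pwi_geom(c(12L, 12L, 6L))
  core <- array(FALSE, g$shape); core[3:8, 3:8, 2:4] <- TRUE
  cortex <- array(FALSE, g$shape); cortex[3:8, 3:5, 2:4] <- TRUE
  cv <- cortical_volume(binary_mask(core, g), binary_mask(cortex, g))
  expect_equal(cv$cortical_mm3 + cv$subcortical_mm3,
               sum(core) * voxel_volume(g))
  expect_equal(cv$cortical_mm3, sum(core & cortex) * voxel_volume(g))

  disjoint <- array(FALSE, g$shape); disjoint[10:11, 10:11, 5] <- TRUE
  expect_equal(cortical_volume(binary_mask(core, g),
                               binary_mask(disjoint, g))$cortical_mm3, 0)

  inside <- cortical_volume(binary_mask(core, g), binary_mask(core, g))
  expect_equal(inside$cortical_mm3, sum(core) * voxel_volume(g))
  expect_equal(inside$subcortical_mm3, 0)
})

test_that("compartment nesting holds for random delay fields", {
  set.seed(77)
  g <- pwi_geom(c(14L, 14L, 6L))
  brain <- full_brain(g)
  core <- binary_mask(array(FALSE, g$shape), g)
  for (rep in 1:3) {
    d <- array(pmax(0, rnorm(prod(g$shape), 4, 4)), g$shape)
    comp <- compartments(scalar_map(d, g, "s"), core, brain)
    expect_true(all(comp$severe$data <= comp$at_risk$data))
    expect_true(all(comp$at_risk$data <= comp$perfusion$data))
    expect_lte(comp$severe_mm3, comp$at_risk_mm3)
    expect_lte(comp$at_risk_mm3, comp$perfusion_lesion_mm3)
    if (comp$at_risk_mm3 > 0) {
      expect_gte(comp$hir, 0); expect_lte(comp$hir, 1)
    }
  }
})
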