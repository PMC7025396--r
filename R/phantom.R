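# Synthetic 4D DSC bolus-passage phantom with ground-truth compartments.
# Emulates a gradient-echo EPI perfusion acquisition (TR 1.5 s, 19 axial
# slices, ~67 volumes) over an ellipsoidal brain with CSF ventricles, a pial
# vessel shell with controllable inter-hemispheric asymmetry, a venous sinus
# strip, an optional low-ADC core block and optional per-volume rigid motion.

#' Peak-normalised gamma-variate bolus curve
#'
#' Standard model of the first-pass contrast-induced signal drop:
#' 0 for `t < t0`, and
#' `amplitude * ((t - t0) / (alpha * beta))^alpha * exp(alpha - (t - t0)/beta)`
#' for `t >= t0`. Normalised so the maximum equals `amplitude`, reached at
#' `t = t0 + alpha * beta`.
#'
#' @param t time in seconds (vectorised).
#' @param t0 bolus arrival time, s.
#' @param alpha dimensionless shape parameter, > 0.
#' @param beta time-scale parameter in s, > 0.
#' @param amplitude peak signal drop in a.u., >= 0.
#' @return Signal drop at `t`, a.u.
#' @export
gamma_variate <- function(t, t0, alpha, beta, amplitude) {
  if (!is.finite(alpha) || alpha <= 0 || !is.finite(beta) || beta <= 0) {
    stop("gamma-variate shape parameters alpha and beta must be > 0", call. = FALSE)
  }
  dt <- t - t0
  y <- numeric(length(t))
  up <- dt > 0
  y[up] <- amplitude * (dt[up] / (alpha * beta))^alpha * exp(alpha - dt[up] / beta)
  y
}

#' Phantom specification
#'
#' Defaults state the emulated acquisition: 64 x 64 x 19 voxels of
#' 1.8 x 1.8 x 5.2 mm (half-matrix version of a 128 x 128, 19-slice EPI
#' protocol with 4 mm slices + 1.2 mm gap), 67 volumes at TR = 1.5 s.
#' Vessels have a low baseline and a deep bolus drop (about half the
#' baseline), parenchyma a shallower drop (about 15\%), CSF none — so the
#' vessel compartment carries the highest temporal CV.
#'
#' @param shape,voxel_size,n_volumes,tr grid and timing.
#' @param baseline named list of per-compartment baseline signals (a.u.).
#' @param bolus list: `t0`, `alpha`, `beta` (gamma-variate timing; peak at
#'   `t0 + alpha*beta` = 30 s by default) and `amplitude` per compartment.
#' @param asymmetry_ratio affected / unaffected pial vessel volume ratio.
#' @param delay_affected bolus delay on the affected side, s.
#' @param noise_sigma Gaussian noise standard deviation, a.u.
#' @param motion `NULL`, or a list of `list(volume = <0-based index>,
#'   shift_voxels = c(dx, dy, dz))` rigid shifts.
#' @param core_size_voxels `NULL`, or integer(3): edge lengths of a low-ADC
#'   (450e-6 mm^2/s) core block placed in the affected hemisphere.
#' @param affected_side which side carries the asymmetry/delay/core.
#' @param seed RNG seed fixing the noise and motion realisation (truth masks
#'   do not depend on it).
#' @return A `cvi_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 19L),
                         voxel_size = c(1.8, 1.8, 5.2),
                         n_volumes = 67L, tr = 1.5,
                         baseline = list(vessel = 200, parenchyma = 300,
                                         csf = 400, background = 0),
                         bolus = list(t0 = 12, alpha = 3, beta = 6,
                                      amplitude = list(vessel = 100,
                                                       parenchyma = 45,
                                                       csf = 0)),
                         asymmetry_ratio = 1,
                         delay_affected = 0,
                         noise_sigma = 3,
                         motion = NULL,
                         core_size_voxels = NULL,
                         affected_side = "left",
                         seed = 42L) {
  amp <- unlist(bolus$amplitude)
  if (any(amp < 0)) stop("bolus amplitudes must be >= 0", call. = FALSE)
  if (bolus$amplitude$vessel <= bolus$amplitude$parenchyma) {
    stop("vessel bolus amplitude must exceed the parenchymal amplitude",
         call. = FALSE)
  }
  if (!is.finite(asymmetry_ratio) || asymmetry_ratio < 0) {
    stop("asymmetry_ratio must be >= 0", call. = FALSE)
  }
  stopifnot(affected_side %in% c("left", "right"), n_volumes >= 3L,
            tr > 0, noise_sigma >= 0)
  structure(
    list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
         n_volumes = as.integer(n_volumes), tr = tr, baseline = baseline,
         bolus = bolus, asymmetry_ratio = asymmetry_ratio,
         delay_affected = delay_affected, noise_sigma = noise_sigma,
         motion = motion, core_size_voxels = core_size_voxels,
         affected_side = affected_side, seed = as.integer(seed)),
    class = "cvi_phantom_spec"
  )
}

flag_voxels <- function(idx, d) {
  x <- array(FALSE, d)
  x[idx] <- TRUE
  x
}

# Deterministic subsample of `n` items down to `k`, independent of the
# caller's RNG state (truth masks must not vary with the noise seed).
fixed_subsample <- function(n, k) {
  if (k >= n) return(seq_len(n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(190831L)
  sort(sample.int(n, k))
}

#' Build a phantom case
#'
#' Constructs the 4D perfusion series, the ADC map and all ground-truth
#' compartment masks from a [phantom_spec()]. The anatomy is mirror-symmetric
#' about the median plane before the asymmetry subsetting, so a spec with
#' `asymmetry_ratio = 1`, no delay and no noise yields an exactly symmetric
#' case.
#'
#' @param spec a [phantom_spec()].
#' @return List with `series` ([perfusion_series()]), `adc` ([scalar_map()],
#'   mm^2/s), `truth` (masks: `brain`, `ventricles`, `vessels`,
#'   `vessels_affected`, `vessels_unaffected`, `atlas_density`, `sinus`,
#'   `cortex`, `core`, `delay_region`) and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "cvi_phantom_spec"))
  d <- spec$shape
  geom <- geometry(d, spec$voxel_size)
  # voxel-centred normalised ellipsoid radius; symmetric about the midplane
  cx <- (d + 1) / 2
  semi <- 0.44 * d
  xi <- (seq_len(d[1]) - cx[1]) / semi[1]
  yj <- (seq_len(d[2]) - cx[2]) / semi[2]
  zk <- (seq_len(d[3]) - cx[3]) / semi[3]
  r2 <- outer(outer(xi^2, yj^2, `+`), zk^2, `+`)
  brain <- r2 <= 1
  shell <- brain & r2 >= 0.90^2
  cortex <- brain & r2 >= 0.72^2 & r2 < 0.90^2
  # two periventricular CSF ellipsoids, mirror-symmetric
  vent <- array(FALSE, d)
  for (s in c(-1, 1)) {
    vx <- (seq_len(d[1]) - (cx[1] + s * 0.08 * d[1])) / (0.05 * d[1])
    vy <- (seq_len(d[2]) - cx[2]) / (0.14 * d[2])
    vz <- (seq_len(d[3]) - cx[3]) / (0.13 * d[3])
    vent <- vent | (outer(outer(vx^2, vy^2, `+`), vz^2, `+`) <= 1)
  }
  vent <- vent & brain & !shell
  # venous sinus: thin posterior midline strip of the shell
  xcol <- abs(seq_len(d[1]) - cx[1]) <= 1.5
  ypost <- (seq_len(d[2]) - cx[2]) / semi[2] > 0.55
  sinus <- shell & outer(outer(xcol, ypost, `&`), rep(TRUE, d[3]), `&`)
  # hemisphere index sets (median plane excluded for odd axis length)
  left_cols <- seq_len(d[1]) <= floor(d[1] / 2)
  right_cols <- seq_len(d[1]) > ceiling(d[1] / 2)
  side_arr <- function(cols) {
    outer(outer(cols, rep(TRUE, d[2]), `&`), rep(TRUE, d[3]), `&`)
  }
  left <- side_arr(left_cols); right <- side_arr(right_cols)
  if (spec$affected_side == "left") {
    aff_side <- left; unaff_side <- right
  } else {
    aff_side <- right; unaff_side <- left
  }
  pial <- shell & !sinus
  v_aff_full <- which(pial & aff_side)
  v_unaff_full <- which(pial & unaff_side)
  r <- spec$asymmetry_ratio
  if (r <= 1) {
    keep_aff <- v_aff_full[fixed_subsample(length(v_aff_full),
                                           round(r * length(v_unaff_full)))]
    keep_unaff <- v_unaff_full
  } else {
    keep_aff <- v_aff_full
    keep_unaff <- v_unaff_full[fixed_subsample(length(v_unaff_full),
                                               round(length(v_aff_full) / r))]
  }
  if (!length(keep_unaff)) {
    stop("phantom spec empties the unaffected vessel shell", call. = FALSE)
  }
  vessels <- array(FALSE, d)
  vessels[keep_aff] <- TRUE
  vessels[keep_unaff] <- TRUE
  vessels_sinus <- vessels | sinus          # sinus veins carry vessel kinetics
  parench <- brain & !vessels_sinus & !vent
  # core block in the affected hemisphere
  core <- array(FALSE, d)
  if (!is.null(spec$core_size_voxels)) {
    cs <- as.integer(spec$core_size_voxels)
    ctr <- round(cx)
    ctr[1] <- ctr[1] + (if (spec$affected_side == "left") -1L else 1L) *
      as.integer(round(0.1875 * d[1]))
    lo <- ctr - cs %/% 2
    hi <- lo + cs - 1L
    if (any(lo < 1L) || any(hi > d)) stop("core block outside the grid", call. = FALSE)
    core[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    core <- core & parench
    if (sum(core) < prod(cs)) {
      warning(sprintf("core block clipped to %d of %d voxels by the anatomy",
                      sum(core), prod(cs)))
    }
  }
  # signal model
  base_map <- array(spec$baseline$background, d)
  base_map[parench] <- spec$baseline$parenchyma
  base_map[vessels_sinus] <- spec$baseline$vessel
  base_map[vent] <- spec$baseline$csf
  amp_map <- array(0, d)
  amp_map[parench] <- spec$bolus$amplitude$parenchyma
  amp_map[vessels_sinus] <- spec$bolus$amplitude$vessel
  amp_map[vent] <- spec$bolus$amplitude$csf
  delay_region <- brain & aff_side & !vent
  amp_delayed <- amp_map * delay_region
  amp_prompt <- amp_map * !delay_region
  tt <- (seq_len(spec$n_volumes) - 1) * spec$tr
  g0 <- gamma_variate(tt, spec$bolus$t0, spec$bolus$alpha, spec$bolus$beta, 1)
  gd <- gamma_variate(tt, spec$bolus$t0 + spec$delay_affected,
                      spec$bolus$alpha, spec$bolus$beta, 1)
  shifts <- vector("list", spec$n_volumes)
  if (!is.null(spec$motion)) {
    for (mv in spec$motion) shifts[[mv$volume + 1L]] <- mv$shift_voxels
  }
  set.seed(spec$seed)
  S <- array(0, c(d, spec$n_volumes))
  for (t in seq_len(spec$n_volumes)) {
    vol <- base_map - amp_prompt * g0[t] - amp_delayed * gd[t]
    if (!is.null(shifts[[t]])) {
      Tm <- diag(4)
      Tm[1:3, 4] <- shifts[[t]] * spec$voxel_size
      vol <- resample_volume(vol, geom, Tm, geom, mode = 0L, oob = 0)
    }
    if (spec$noise_sigma > 0) {
      vol <- vol + rnorm(length(vol), 0, spec$noise_sigma)
    }
    S[, , , t] <- pmax(vol, 0)
  }
  adc <- array(0, d)
  adc[parench] <- 800e-6
  adc[vessels_sinus] <- 900e-6
  adc[vent] <- 3000e-6
  adc[core] <- 450e-6
  atlas <- array(0, d)
  atlas[shell] <- 1
  bm <- function(x, lab) binary_mask(x, geom, label = lab)
  list(
    series = perfusion_series(S, geom, spec$tr),
    adc = scalar_map(adc, geom, units = "mm2/s"),
    truth = list(
      brain = bm(brain, "brain"),
      ventricles = bm(vent, "ventricles"),
      vessels = bm(vessels, "pial_vessels"),
      vessels_affected = bm(flag_voxels(keep_aff, d), "pial_vessels_affected"),
      vessels_unaffected = bm(flag_voxels(keep_unaff, d),
                              "pial_vessels_unaffected"),
      atlas_density = scalar_map(atlas, geom, units = "density"),
      sinus = bm(sinus, "sinus_veins"),
      cortex = bm(cortex, "cortex"),
      core = bm(core, "true_core"),
      delay_region = bm(delay_region, "delay_region")
    ),
    spec = spec
  )
}

#' Named suite of phantom specifications
#'
#' The standard set of cases used by the tests and documentation: a
#' symmetric case (plus its noise-free variant), asymmetry ratios 0.25, 0.5
#' and 1.5, a 6 s delayed case, a severely delayed case (10.5 s, with a core
#' block), a 2-voxel motion case and a high-noise case.
#'
#' @param seed base RNG seed shared by the specs.
#' @return Named list of [phantom_spec()]s.
#' @export
default_suite <- function(seed = 42L) {
  list(
    symmetric = phantom_spec(seed = seed),
    symmetric_noise_free = phantom_spec(noise_sigma = 0, seed = seed),
    asymmetry_025 = phantom_spec(asymmetry_ratio = 0.25, seed = seed),
    asymmetry_05 = phantom_spec(asymmetry_ratio = 0.5, seed = seed),
    asymmetry_15 = phantom_spec(asymmetry_ratio = 1.5, seed = seed),
    delayed_6s = phantom_spec(asymmetry_ratio = 0.5, delay_affected = 6,
                              seed = seed),
    severe_delay = phantom_spec(asymmetry_ratio = 0.25, delay_affected = 10.5,
                                core_size_voxels = c(10L, 10L, 10L),
                                seed = seed),
    motion_2vox = phantom_spec(
      motion = list(list(volume = 33L, shift_voxels = c(2, 0, 0))),
      seed = seed),
    noisy = phantom_spec(noise_sigma = 10, seed = seed)
  )
}
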