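# Threshold-defined ischaemic core (ADC < 600e-6 mm^2/s), TTP-delay
# compartments relative to the contralesional median (tissue at risk >= 4.5 s,
# severe hypoperfusion >= 9.5 s), mismatch ratios, the hypoperfusion intensity
# ratio and cortical infarct volume.

#' Automatic lesion-mask correction
#'
#' Restricts a lesion mask to the brain, removes 26-connected components
#' smaller than `min_component_mm3`, and fills fully enclosed holes — the
#' automatic artifact correction applied after ADC/TTP thresholding.
#'
#' @param mask lesion [binary_mask()].
#' @param brain brain [binary_mask()].
#' @param min_component_mm3 smallest component kept, default 300 mm^3.
#' @return A cleaned [binary_mask()].
#' @export
clean_lesion <- function(mask, brain, min_component_mm3 = 300) {
  stopifnot(inherits(mask, "cvi_binary_mask"), inherits(brain, "cvi_binary_mask"))
  stop_geometry_mismatch(mask$geometry, brain$geometry, "mask and brain")
  m <- mask$data & brain$data
  if (!any(m)) return(binary_mask(m, mask$geometry, label = mask$label))
  vv <- voxel_volume(mask$geometry)
  labs <- label_components(m, connectivity = 26L)
  if (max(labs) > 0L) {
    sizes <- tabulate(labs[labs > 0L])
    keep <- which(sizes * vv >= min_component_mm3)
    m <- array(labs %in% keep, dim = dim(m))
  }
  if (any(m)) m <- fill_holes(m)
  binary_mask(m, mask$geometry, label = mask$label)
}

# ADC unit handling: both 1e-6 mm^2/s (values ~ hundreds) and mm^2/s
# (values ~ 1e-3) circulate. Returns the map converted to mm^2/s.
adc_in_mm2s <- function(adc, brain, units = NULL) {
  u <- if (!is.null(units)) units else adc$units
  med <- median(adc$data[brain$data & is.finite(adc$data) & adc$data > 0])
  if (is.null(u) || is.na(u) || u %in% c("", "a.u.")) {
    u <- if (is.finite(med) && med >= 100 && med <= 3000) {
      "1e-6 mm2/s"
    } else if (is.finite(med) && med >= 1e-4 && med <= 3e-3) {
      "mm2/s"
    } else {
      stop("cannot determine ADC units; declare them in the config (\"mm2/s\" or \"1e-6 mm2/s\")",
           call. = FALSE)
    }
  }
  data <- switch(u,
    "mm2/s" = adc$data,
    "1e-6 mm2/s" = adc$data * 1e-6,
    "10-6 mm2/s" = adc$data * 1e-6,
    stop(sprintf("unknown ADC unit tag '%s'", u), call. = FALSE))
  scalar_map(data, adc$geometry, units = "mm2/s")
}

#' Segment the ischaemic core from an ADC map
#'
#' Core = voxels with `0 < ADC < threshold` inside the brain, artifact-
#' corrected with [clean_lesion()]. The established upper threshold is
#' 600e-6 mm^2/s. ADC = 0 background voxels are excluded by the lower guard.
#'
#' @param adc ADC [scalar_map()] in PWI space; its `units` tag (or the
#'   `units` argument) declares the convention, auto-detected from the
#'   in-brain median when untagged.
#' @param brain brain [binary_mask()].
#' @param threshold upper ADC threshold in mm^2/s, default `600e-6`.
#' @param min_component_mm3 passed to [clean_lesion()].
#' @param units optional explicit unit tag overriding `adc$units`.
#' @return Core [binary_mask()].
#' @export
segment_core <- function(adc, brain, threshold = 600e-6,
                         min_component_mm3 = 300, units = NULL) {
  stopifnot(inherits(adc, "cvi_scalar_map"), inherits(brain, "cvi_binary_mask"))
  stop_geometry_mismatch(adc$geometry, brain$geometry, "ADC and brain")
  adc <- adc_in_mm2s(adc, brain, units)
  m <- is.finite(adc$data) & adc$data > 0 & adc$data < threshold & brain$data
  dim(m) <- adc$geometry$shape
  clean_lesion(binary_mask(m, adc$geometry, label = "ischaemic_core"),
               brain, min_component_mm3)
}

#' Non-deconvolved time-to-peak map
#'
#' Per-voxel TTP = TR times the 0-based index of the temporal signal minimum
#' (the contrast peak in T2*-weighted DSC), in seconds, at frame resolution.
#' Ties break to the earliest frame; voxels outside the brain are `NaN`.
#'
#' @param series motion-corrected [perfusion_series()].
#' @param brain brain [binary_mask()].
#' @return TTP [scalar_map()] (units `"s"`).
#' @export
ttp_map <- function(series, brain) {
  stopifnot(inherits(series, "cvi_perfusion_series"),
            inherits(brain, "cvi_binary_mask"))
  stop_geometry_mismatch(series$geometry, brain$geometry, "series and brain")
  d <- dim(series$data)
  m <- matrix(series$data, prod(d[1:3]), d[4])
  idx <- max.col(-m, ties.method = "first") - 1L
  ttp <- idx * series$tr
  ttp[!as.vector(brain$data)] <- NaN
  dim(ttp) <- d[1:3]
  scalar_map(ttp, series$geometry, units = "s")
}

#' TTP-delay map referenced to the contralesional median
#'
#' Delay = `max(0, TTP - median TTP over the unaffected-hemisphere brain
#' voxels)`. The perfusion lesion is the set of affected-hemisphere voxels
#' with delay > 0. Adding a constant to every TTP value leaves the delay
#' unchanged (median-referenced).
#'
#' @param ttp TTP [scalar_map()] in seconds.
#' @param brain_unaffected non-empty [binary_mask()] of unaffected-hemisphere
#'   brain voxels (ventricles are best excluded: CSF TTP is noise).
#' @return Delay [scalar_map()] (units `"s"`) with the reference median in
#'   attribute `"reference_median_s"`.
#' @export
ttp_delay <- function(ttp, brain_unaffected) {
  stopifnot(inherits(ttp, "cvi_scalar_map"),
            inherits(brain_unaffected, "cvi_binary_mask"))
  stop_geometry_mismatch(ttp$geometry, brain_unaffected$geometry,
                         "TTP and reference mask")
  ref_vals <- ttp$data[brain_unaffected$data]
  ref_vals <- ref_vals[is.finite(ref_vals)]
  if (!length(ref_vals)) {
    stop("empty contralesional reference mask", call. = FALSE)
  }
  ref <- median(ref_vals)
  delay <- pmax(0, ttp$data - ref)
  dim(delay) <- ttp$geometry$shape
  out <- scalar_map(delay, ttp$geometry, units = "s")
  attr(out, "reference_median_s") <- ref
  out
}

#' TTP-delay compartments, volumes and the hypoperfusion intensity ratio
#'
#' Segments the perfusion lesion (delay > 0), tissue at risk (delay >=
#' `at_risk` s) and severely hypoperfused tissue (delay >= `severe` s),
#' each artifact-corrected with [clean_lesion()] and intersected to enforce
#' `severe` inside `at_risk` inside the perfusion lesion. The ischaemic core
#' is subtracted from the perfusion lesion to give the mismatch region.
#' HIR = severe / at-risk volume (NA when there is no tissue at risk).
#'
#' @param delay TTP-delay [scalar_map()] from [ttp_delay()].
#' @param core ischaemic-core [binary_mask()].
#' @param brain brain [binary_mask()] used by the cleaning step.
#' @param region optional [binary_mask()] restricting the perfusion lesion
#'   (typically the affected-hemisphere brain without ventricles).
#' @param thresholds list with `at_risk` (4.5 s) and `severe` (9.5 s).
#' @param min_component_mm3 cleaning parameter, default 300.
#' @return List with masks (`perfusion`, `at_risk`, `severe`, `mismatch`)
#'   and volumes in mm^3 plus `hir`.
#' @export
compartments <- function(delay, core, brain, region = NULL,
                         thresholds = list(at_risk = 4.5, severe = 9.5),
                         min_component_mm3 = 300) {
  stopifnot(inherits(delay, "cvi_scalar_map"), inherits(core, "cvi_binary_mask"))
  stop_geometry_mismatch(delay$geometry, core$geometry, "delay and core")
  geom <- delay$geometry
  restrict <- if (is.null(region)) {
    array(TRUE, geom$shape)
  } else {
    stop_geometry_mismatch(geom, region$geometry, "delay and region")
    region$data
  }
  seg <- function(cut) {
    m <- is.finite(delay$data) & delay$data >= cut & restrict
    if (cut == 0) m <- m & delay$data > 0
    dim(m) <- geom$shape
    clean_lesion(binary_mask(m, geom), brain, min_component_mm3)$data
  }
  perf <- seg(0)
  at_risk <- seg(thresholds$at_risk) & perf
  severe <- seg(thresholds$severe) & at_risk
  mismatch <- perf & !core$data
  vv <- voxel_volume(geom)
  at_risk_mm3 <- sum(at_risk) * vv
  severe_mm3 <- sum(severe) * vv
  list(
    perfusion = binary_mask(perf, geom, "perfusion_lesion"),
    at_risk = binary_mask(at_risk, geom, "tissue_at_risk"),
    severe = binary_mask(severe, geom, "severe_hypoperfusion"),
    mismatch = binary_mask(mismatch, geom, "mismatch_region"),
    perfusion_lesion_mm3 = sum(perf) * vv,
    at_risk_mm3 = at_risk_mm3,
    severe_mm3 = severe_mm3,
    hir = if (at_risk_mm3 > 0) severe_mm3 / at_risk_mm3 else NA_real_
  )
}

#' PWI/DWI mismatch ratios
#'
#' `entire` = perfusion-lesion volume / acute DWI lesion volume;
#' `at_risk` = tissue-at-risk volume / acute DWI lesion volume.
#' Undefined (NA, with a warning) when the DWI lesion volume is zero.
#'
#' @param perfusion_lesion_mm3,at_risk_mm3 compartment volumes in mm^3.
#' @param dwi_lesion_mm3 acute DWI lesion volume in mm^3.
#' @return List with `entire` and `at_risk` ratios.
#' @export
mismatch_ratios <- function(perfusion_lesion_mm3, at_risk_mm3, dwi_lesion_mm3) {
  if (!is.finite(dwi_lesion_mm3) || dwi_lesion_mm3 <= 0) {
    warning("DWI lesion volume is zero; mismatch ratios undefined")
    return(list(entire = NA_real_, at_risk = NA_real_))
  }
  list(entire = perfusion_lesion_mm3 / dwi_lesion_mm3,
       at_risk = at_risk_mm3 / dwi_lesion_mm3)
}

#' Cortical and subcortical infarct volume
#'
#' Volume of the core inside a supplied cortex mask; the remainder is
#' subcortical. The two always sum to the total core volume.
#'
#' @param core core [binary_mask()].
#' @param cortex cortex [binary_mask()].
#' @return List with `cortical_mm3` and `subcortical_mm3`.
#' @export
cortical_volume <- function(core, cortex) {
  stopifnot(inherits(core, "cvi_binary_mask"), inherits(cortex, "cvi_binary_mask"))
  stop_geometry_mismatch(core$geometry, cortex$geometry, "core and cortex")
  vv <- voxel_volume(core$geometry)
  cort <- sum(core$data & cortex$data) * vv
  list(cortical_mm3 = cort,
       subcortical_mm3 = sum(core$data) * vv - cort)
}

#' Assemble a per-case lesion report
#'
#' @param core core [binary_mask()].
#' @param comp result of [compartments()].
#' @param ratios result of [mismatch_ratios()].
#' @param cortical result of [cortical_volume()], or `NULL`.
#' @param contralesional_median_ttp reference median TTP in seconds.
#' @return A `cvi_lesion_report`.
#' @export
lesion_report <- function(core, comp, ratios, cortical = NULL,
                          contralesional_median_ttp = NA_real_) {
  structure(
    list(core_mm3 = mask_volume_mm3(core),
         core_cortical_mm3 = if (!is.null(cortical)) cortical$cortical_mm3 else NA_real_,
         perfusion_lesion_mm3 = comp$perfusion_lesion_mm3,
         at_risk_mm3 = comp$at_risk_mm3,
         severe_mm3 = comp$severe_mm3,
         mismatch_entire = ratios$entire,
         mismatch_at_risk = ratios$at_risk,
         hir = comp$hir,
         contralesional_median_ttp = contralesional_median_ttp),
    class = "cvi_lesion_report"
  )
}

#' @export
print.cvi_lesion_report <- function(x, ...) {
  cat("Lesion report:\n")
  cat(sprintf("  ischaemic core:        %.1f mm^3 (cortical %.1f mm^3)\n",
              x$core_mm3, x$core_cortical_mm3))
  cat(sprintf("  perfusion lesion:      %.1f mm^3\n", x$perfusion_lesion_mm3))
  cat(sprintf("  tissue at risk >=4.5s: %.1f mm^3\n", x$at_risk_mm3))
  cat(sprintf("  severe delay >=9.5s:   %.1f mm^3\n", x$severe_mm3))
  cat(sprintf("  mismatch entire/at-risk: %.3f / %.3f\n",
              x$mismatch_entire, x$mismatch_at_risk))
  cat(sprintf("  HIR: %.3f, contralesional median TTP: %.2f s\n",
              x$hir, x$contralesional_median_ttp))
  invisible(x)
}

#' @export
as.data.frame.cvi_lesion_report <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}
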