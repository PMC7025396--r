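# Small fixtures shared across the suite. Everything is generated in code;
# the tiny phantom keeps unit tests fast while the default-size phantom is
# reserved for the acceptance checks.

tiny_spec <- function(...) {
  # 32 volumes (48 s) so that delayed boluses still peak inside the window
  args <- utils::modifyList(list(shape = c(32L, 32L, 10L), n_volumes = 32L),
                            list(...))
  do.call(phantom_spec, args)
}

# Run the high-CV extraction + CVI on a built phantom with default settings.
phantom_cvi <- function(p, affected_side = p$spec$affected_side) {
  hc <- extract_highcv(p$series, p$truth$brain, p$truth$ventricles)
  lepto <- leptomeningeal_mask(p$truth$atlas_density, p$truth$sinus)
  compute_cvi(hc$highcv, split_hemispheres(lepto, affected_side),
              p$series$geometry, cv_map = hc$cv,
              threshold_used = hc$threshold, bolus_peak = hc$t_star)
}

# Mirror a 3D or 4D array along axis 1 (the left-right axis).
mirror_x <- function(a) {
  idx <- c(list(rev(seq_len(dim(a)[1]))),
           lapply(dim(a)[-1], seq_len), list(drop = FALSE))
  do.call(`[`, c(list(a), idx))
}

mirror_phantom <- function(p) {
  g <- p$series$geometry
  p$series <- perfusion_series(mirror_x(p$series$data), g, p$series$tr)
  for (nm in names(p$truth)) {
    obj <- p$truth[[nm]]
    if (inherits(obj, "cvi_binary_mask")) {
      p$truth[[nm]] <- binary_mask(mirror_x(obj$data), g, obj$label)
    } else {
      p$truth[[nm]] <- scalar_map(mirror_x(obj$data), g, obj$units)
    }
  }
  p
}
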