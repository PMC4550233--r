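# Small in-code fixtures shared across test files.

# Stack built directly from matrices (bypasses the renderer).
make_stack <- function(frames, tags = rep("spinning_tirf", length(frames)),
                       labels = tags, exposure = 0.005,
                       camera = camera_model(frame_shape = dim(frames[[1]]),
                                             read_noise = 0)) {
  spintirf:::new_image_stack(
    frames = lapply(frames, function(m) matrix(as.integer(m), nrow(m),
                                               ncol(m))),
    mode_tags = tags, labels = labels,
    timestamps = (seq_along(frames) - 1) * exposure,
    exposure_time = exposure, camera = camera)
}

uniform_frame <- function(value, n = 8L) matrix(as.integer(value), n, n)

tiny_camera <- function(n = 32L, ...) {
  camera_model(frame_shape = c(n, n), ...)
}

# Noise-corrected spatial CV of a rendered film: spatial variance of the
# temporal mean, minus the shot/read contribution estimated from the
# per-pixel temporal variance.
spatial_cv_corrected <- function(stack) {
  arr <- simplify2array(stack$frames)
  mu <- apply(arr, c(1, 2), mean)
  v_t <- apply(arr, c(1, 2), stats::var)
  v_spatial <- stats::var(as.vector(mu)) - mean(v_t) / dim(arr)[3]
  sqrt(max(v_spatial, 0)) / mean(mu)
}

default_tirf_depth <- function(radius = 0.97, cfg = optical_config()) {
  r_mm <- radius * cfg$objective_focal_length * cfg$numerical_aperture
  penetration_depth(cfg$wavelength, bfp_radius_to_angle(r_mm, cfg), cfg)
}

# Full puff pipeline on a puff_depths scenario: render, de-interleave,
# delta-F/F0, linked 3x3 ROIs from ground-truth positions, event windows
# from ground-truth times.
run_puff_pipeline <- function(scenario, seed = 2L, n_azimuths = 90) {
  stk <- render_stack(scenario$specimen, scenario$schedule, scenario$cfg,
                      scenario$camera, seed = seed,
                      speckle = scenario$speckle, n_azimuths = n_azimuths)
  subs <- deinterleave(subtract_black(stk), 2)
  nb <- sum(subs$tirf$timestamps < 0.5)
  rt <- df_f0(subs$tirf, c(1, nb))
  rw <- df_f0(subs$wf, c(1, nb))
  ps <- scenario$specimen$puff_sites
  px <- scenario$camera$pixel_size
  rois <- lapply(seq_len(nrow(ps)), function(i) {
    roi_center(floor(ps$x[i] / px), floor(ps$y[i] / px), 3,
               label = as.character(i))
  })
  names(rois) <- as.character(seq_len(nrow(ps)))
  events <- purrr::map_dfr(seq_len(nrow(ps)), function(i) {
    tibble::tibble(site_id = i, t0 = ps$event_times[[i]] - 0.02,
                   t1 = ps$event_times[[i]] + 0.25)
  })
  d <- default_tirf_depth(scenario$schedule$presets$radius[1])
  list(analysis = analyze_puffs(rt, rw, rois, events, d = d),
       truth = ps, d = d, tirf_ratio = rt, wf_ratio = rw, rois = rois)
}
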