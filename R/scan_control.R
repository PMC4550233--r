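#' Define a galvanometer scan preset
#'
#' A scan preset describes one illumination setting of the dual-galvanometer
#' spot scanner: how fast the laser spot revolves around the objective back
#' focal plane (BFP), the scan radius (which sets the incidence angle and
#' hence the illumination mode), the shape corrections applied to the circle
#' (ellipticity, phase, centre offsets), and the laser line driven while the
#' preset is active.
#'
#' Drive amplitudes are normalized so that 1.0 corresponds to the full
#' objective aperture radius at the BFP; conversion to physical millimetres
#' is handled by the optical model (see [angle_to_bfp_radius()]).
#'
#' @param label Short name for the preset (used as the per-frame mode label
#'   prefix in interleaved schedules).
#' @param frequency Scan revolutions per second (Hz). Ignored for
#'   `mode_tag = "stationary_tirf"`, where the spot is parked at a fixed
#'   azimuth.
#' @param radius Drive amplitude, normalized units in `[0, 1]` of the full
#'   aperture radius.
#' @param ellipticity Ratio of the y to the x drive amplitude. 1 gives a
#'   circular scan.
#' @param phase_offset Degrees added to the y channel beyond the nominal 90
#'   degree quadrature, used to correct residual ellipse tilt.
#' @param x_shift,y_shift Scan centre offsets in the same normalized units.
#' @param laser_id Laser line identifier, e.g. `488` or `532` (nm).
#' @param laser_power Laser power as a fraction of full power, in `[0, 1]`.
#' @param laser_on Logical; whether the laser is gated on during this preset.
#' @param mode_tag One of `"spinning_tirf"`, `"stationary_tirf"`,
#'   `"widefield"`, `"skimming"`.
#'
#' @return A one-row tibble of class `scan_preset`.
#' @examples
#' tirf <- scan_preset("tirf", frequency = 200, radius = 0.97)
#' wf <- scan_preset("wf", radius = 0.1, mode_tag = "widefield")
#' @export
scan_preset <- function(label = "preset",
                        frequency = 200,
                        radius = 0.95,
                        ellipticity = 1,
                        phase_offset = 0,
                        x_shift = 0,
                        y_shift = 0,
                        laser_id = 488,
                        laser_power = 1,
                        laser_on = TRUE,
                        mode_tag = c("spinning_tirf", "stationary_tirf",
                                     "widefield", "skimming")) {
  mode_tag <- match.arg(mode_tag)
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(frequency) || frequency <= 0) {
    rlang::abort("`frequency` must be > 0 Hz.", class = "spintirf_preset_error")
  }
  if (radius < 0) {
    rlang::abort("`radius` must be >= 0.", class = "spintirf_preset_error")
  }
  if (ellipticity <= 0) {
    rlang::abort("`ellipticity` must be > 0.", class = "spintirf_preset_error")
  }
  if (laser_power < 0 || laser_power > 1) {
    rlang::abort("`laser_power` must lie in [0, 1].",
                 class = "spintirf_preset_error")
  }
  out <- tibble::tibble(
    label = label, frequency = frequency, radius = radius,
    ellipticity = ellipticity, phase_offset = phase_offset,
    x_shift = x_shift, y_shift = y_shift,
    laser_id = laser_id, laser_power = laser_power, laser_on = laser_on,
    mode_tag = mode_tag
  )
  class(out) <- c("scan_preset", class(out))
  out
}

full_scale <- 1.0  # normalized drive limit: the BFP aperture radius

#' Synthesize galvanometer drive waveforms for one scan period
#'
#' Builds the lookup table that drives the two scan mirrors: the x channel is
#' a sine and the y channel a cosine (90 degrees out of phase), so the spot
#' traces a circle at the back focal plane. The table covers exactly one
#' revolution and is intended to be replayed cyclically at the stated sample
#' rate.
#'
#' The trajectory is
#' \deqn{x(t) = x_0 + A \sin(2\pi f t)}
#' \deqn{y(t) = y_0 + e A \cos(2\pi f t + \phi)}
#' with amplitude \eqn{A} (`radius`), frequency \eqn{f}, ellipticity \eqn{e}
#' and extra y phase \eqn{\phi} (`phase_offset`). For a
#' `stationary_tirf` preset the spot is parked at azimuth 0, i.e. at
#' \eqn{(x_0 + A, y_0)}.
#'
#' @param preset A [scan_preset()] (one-row data frame).
#' @param sample_rate Samples per second for the lookup table. Must be at
#'   least 100 times the scan frequency.
#'
#' @return A tibble of class `waveform_table` with columns `t` (s), `x`, `y`
#'   (normalized drive), and `laser_ttl` (logical laser gate), one row per
#'   sample over one period. Attributes: `sample_rate`, `frequency`,
#'   `frame_trigger_indices` (sample indices, 1-based, at which a camera
#'   exposure trigger is emitted — the start of the period).
#' @examples
#' wt <- synthesize_waveforms(scan_preset(frequency = 200), sample_rate = 1e6)
#' nrow(wt)  # 5000 samples per revolution
#' @export
synthesize_waveforms <- function(preset, sample_rate = 1e6) {
  p <- as.list(preset[1, ])
  if (sample_rate / p$frequency < 100) {
    rlang::abort(
      sprintf("undersampled scan: sample_rate/frequency = %.1f < 100",
              sample_rate / p$frequency),
      class = "spintirf_undersampled_error")
  }
  n <- round(sample_rate / p$frequency)
  tt <- (seq_len(n) - 1) / sample_rate
  if (identical(p$mode_tag, "stationary_tirf")) {
    x <- rep(p$x_shift + p$radius, n)
    y <- rep(p$y_shift, n)
  } else {
    ph <- 2 * pi * p$frequency * tt
    x <- p$x_shift + p$radius * sin(ph)
    y <- p$y_shift + p$ellipticity * p$radius *
      cos(ph + p$phase_offset * pi / 180)
  }
  if (max(abs(x), abs(y)) > full_scale + 1e-12) {
    rlang::abort(
      "scan clipped: radius plus offsets exceeds the full-scale aperture",
      class = "spintirf_clipping_error")
  }
  out <- tibble::tibble(
    t = tt, x = x, y = y,
    laser_ttl = rep(isTRUE(p$laser_on) && p$laser_power > 0, n)
  )
  attr(out, "sample_rate") <- sample_rate
  attr(out, "frequency") <- p$frequency
  attr(out, "frame_trigger_indices") <- 1L
  class(out) <- c("waveform_table", class(out))
  out
}

#' Build a frame-by-frame interleave schedule
#'
#' Up to three scan presets can be interleaved frame by frame so that
#' successive camera exposures use different illumination settings
#' (e.g. alternating spinning-spot TIRF and pseudo-widefield), giving
#' near-simultaneous multi-modal recordings after de-interleaving.
#'
#' Each spinning frame must span an integer number of spot revolutions so
#' that the exposure averages over all 360 degrees of azimuthal incidence.
#' When `exposure_time * frequency` is not an integer, the number of
#' revolutions per frame is rounded to the nearest integer (at least 1) and
#' the preset frequency adjusted accordingly; the adjustment is recorded in
#' the returned object.
#'
#' @param presets A data frame of 1-3 preset rows (rows from
#'   [scan_preset()], e.g. combined with [dplyr::bind_rows()]).
#' @param exposure_time Camera exposure per frame, seconds.
#' @param n_frames Total number of frames in the acquisition.
#'
#' @return A list of class `interleave_schedule` with elements `presets`
#'   (tibble, with an added `adjusted_frequency` column and
#'   `revolutions_per_frame`), `exposure_time`, `n_frames`, and `frames`, a
#'   tibble with one row per frame: `frame` (1-based index), `preset_index`,
#'   `label`, `mode_tag`, `start_time` (s).
#' @examples
#' sched <- build_schedule(
#'   dplyr::bind_rows(scan_preset("T"), scan_preset("W", mode_tag = "widefield")),
#'   exposure_time = 0.005, n_frames = 6)
#' sched$frames$mode_tag
#' @export
build_schedule <- function(presets, exposure_time, n_frames) {
  presets <- tibble::as_tibble(presets)
  k <- nrow(presets)
  if (k < 1L || k > 3L) {
    rlang::abort("between 1 and 3 presets are required.",
                 class = "spintirf_schedule_error")
  }
  if (exposure_time <= 0) {
    rlang::abort("`exposure_time` must be > 0.",
                 class = "spintirf_schedule_error")
  }
  spins <- presets$mode_tag != "stationary_tirf"
  if (any(spins & exposure_time * presets$frequency < 0.5)) {
    rlang::abort(
      "exposure is shorter than half a revolution at the requested frequency; no integer revolution count >= 1 is reachable",
      class = "spintirf_schedule_error")
  }
  rev_per_frame <- pmax(1, round(exposure_time * presets$frequency))
  adj <- ifelse(spins, rev_per_frame / exposure_time, presets$frequency)
  presets$revolutions_per_frame <- ifelse(spins, rev_per_frame, NA_real_)
  presets$adjusted_frequency <- adj
  idx <- ((seq_len(n_frames) - 1L) %% k) + 1L
  frames <- tibble::tibble(
    frame = seq_len(n_frames),
    preset_index = idx,
    label = presets$label[idx],
    mode_tag = presets$mode_tag[idx],
    start_time = (seq_len(n_frames) - 1) * exposure_time
  )
  structure(
    list(presets = presets, exposure_time = exposure_time,
         n_frames = as.integer(n_frames), frames = frames),
    class = "interleave_schedule")
}

#' @export
print.interleave_schedule <- function(x, ...) {
  cat(sprintf("<interleave_schedule> %d frame(s) x %.3g ms, %d preset(s): %s\n",
              x$n_frames, 1e3 * x$exposure_time, nrow(x$presets),
              paste(x$presets$label, collapse = " | ")))
  invisible(x)
}

#' Camera trigger table for an interleave schedule
#'
#' One TTL camera trigger is emitted at the start of every frame; the camera
#' exposure therefore spans exactly the integer number of spot revolutions
#' scheduled for that frame.
#'
#' @param schedule An [build_schedule()] result.
#' @return A tibble with columns `frame`, `start_time` (s) and `label`.
#' @export
frame_triggers <- function(schedule) {
  stopifnot(inherits(schedule, "interleave_schedule"))
  dplyr::select(schedule$frames, "frame", "start_time", "label")
}
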