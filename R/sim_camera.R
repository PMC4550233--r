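#' EMCCD camera model
#'
#' Parameters of the electron-multiplying CCD used to render synthetic
#' frames: pixel geometry, electron-multiplying gain, Gaussian read noise,
#' black level (camera offset) and quantum efficiency.
#'
#' EM gain is applied either as stochastic gamma multiplication (the
#' physical model, excess noise factor close to sqrt(2)) or as plain mean
#' multiplication (`gain_model = "mean"`, useful for exact-value checks).
#'
#' @param pixel_size Specimen-referred pixel size, um.
#' @param frame_shape Frame dimensions `c(rows, cols)`, pixels.
#' @param em_gain Electron-multiplying gain (>= 1), counts per
#'   photoelectron.
#' @param read_noise Read noise RMS, counts.
#' @param black_level Camera offset added to every pixel, counts.
#' @param qe Quantum efficiency in `[0, 1]`.
#' @param gain_model `"gamma"` (stochastic) or `"mean"` (deterministic
#'   multiplication).
#' @return A list of class `camera_model`.
#' @export
camera_model <- function(pixel_size = 0.4, frame_shape = c(128L, 128L),
                         em_gain = 50, read_noise = 10, black_level = 100,
                         qe = 0.9, gain_model = c("gamma", "mean")) {
  gain_model <- match.arg(gain_model)
  stopifnot(pixel_size > 0, length(frame_shape) == 2, em_gain >= 1,
            read_noise >= 0, black_level >= 0, qe > 0, qe <= 1)
  structure(
    list(pixel_size = pixel_size, frame_shape = as.integer(frame_shape),
         em_gain = em_gain, read_noise = read_noise,
         black_level = black_level, qe = qe, gain_model = gain_model),
    class = "camera_model")
}

#' Synthetic specimen
#'
#' A specimen is a uniform fluorophore film at the coverslip (z = 0), plus
#' optional point-like beads, light-blocking occluders (stand-ins for
#' refractile cellular structures) and Ca2+ puff sites.
#'
#' Brightness values are photons per pixel per reference exposure
#' (`reference_exposure`, default 5 ms) under unit excitation; rendering at
#' other exposures scales photon counts proportionally.
#'
#' @param film_brightness Photons/pixel per reference exposure from the
#'   film at z = 0 under unit excitation.
#' @param cytosol_brightness Photons/pixel per reference exposure from
#'   indicator distributed uniformly through the cytosolic volume, quoted
#'   for full (widefield) excitation of the `cytosol_thickness`. Under an
#'   evanescent field only the thin near-membrane slice of this volume is
#'   excited, so the cytosol inflates the widefield baseline F0 far more
#'   than the TIRF baseline — the reason superficial events show larger
#'   delta-F/F0 in TIRF than in widefield.
#' @param cytosol_thickness Axial extent of the cytosolic volume, um.
#' @param beads `NULL` or data frame with columns `x`, `y` (um), `z` (nm),
#'   `brightness` (photons per reference exposure, deposited in the bead's
#'   pixel).
#' @param occluders `NULL` or data frame with columns `x`, `y` (um),
#'   `radius` (um), `attenuation` (0-1).
#' @param puff_sites `NULL` or a data frame as built by [puff_sites()].
#' @param reference_exposure Exposure, s, at which brightnesses are quoted.
#' @return A list of class `specimen`.
#' @export
specimen <- function(film_brightness = 100, cytosol_brightness = 0,
                     cytosol_thickness = 5, beads = NULL, occluders = NULL,
                     puff_sites = NULL, reference_exposure = 0.005) {
  stopifnot(film_brightness >= 0, cytosol_brightness >= 0,
            cytosol_thickness > 0, reference_exposure > 0)
  if (!is.null(beads)) {
    beads <- tibble::as_tibble(beads)
    stopifnot(all(c("x", "y", "z", "brightness") %in% names(beads)),
              all(beads$z >= 0), all(beads$brightness >= 0))
  }
  if (!is.null(occluders)) {
    occluders <- tibble::as_tibble(occluders)
    stopifnot(all(c("x", "y", "radius", "attenuation") %in% names(occluders)),
              all(occluders$attenuation >= 0), all(occluders$attenuation <= 1))
  }
  if (!is.null(puff_sites)) puff_sites <- tibble::as_tibble(puff_sites)
  structure(
    list(film_brightness = film_brightness,
         cytosol_brightness = cytosol_brightness,
         cytosol_thickness = cytosol_thickness, beads = beads,
         occluders = occluders, puff_sites = puff_sites,
         reference_exposure = reference_exposure),
    class = "specimen")
}

#' Define Ca2+ puff sites
#'
#' Each site is a fixed (x, y) location releasing Ca2+ at depth `z` below
#' the plasma membrane at the listed event times. An event's fluorescence
#' rises linearly over `rise_time` and then decays exponentially with
#' `decay_time`, consistent with puff durations of tens to hundreds of ms.
#' The site's signal has a 2-D Gaussian footprint of `spatial_sigma`.
#'
#' The widefield-visible amplitude of an event is its full `amplitude`;
#' under an evanescent field of depth d the visible amplitude is
#' `amplitude * exp(-z / d)` — the minimal model in which only the fraction
#' of released indicator near the membrane is excited.
#'
#' @param x,y Site positions, um.
#' @param z Release depths below the membrane, nm.
#' @param event_times List (one element per site) of event start times, s.
#' @param amplitude Peak added brightness, photons/pixel per reference
#'   exposure under unit excitation, at the footprint centre.
#' @param rise_time,decay_time Kinetic constants, ms (`rise_time <
#'   decay_time`).
#' @param spatial_sigma Gaussian footprint sigma, um.
#' @return A tibble with one row per site (`site_id`, positions, kinetics,
#'   list-column `event_times`).
#' @export
puff_sites <- function(x, y, z, event_times, amplitude = 200,
                       rise_time = 10, decay_time = 100,
                       spatial_sigma = 0.8) {
  stopifnot(length(x) == length(y), length(y) == length(z),
            all(rise_time < decay_time), all(z >= 0))
  if (!is.list(event_times)) event_times <- list(event_times)
  tibble::tibble(
    site_id = seq_along(x), x = x, y = y, z = z,
    event_times = event_times,
    amplitude = amplitude, rise_time = rise_time, decay_time = decay_time,
    spatial_sigma = spatial_sigma
  )
}

# Temporal envelope of a site's events at time t (scalar): linear rise over
# rise_time ms to 1, then exponential decay with decay_time ms; events sum.
puff_temporal <- function(t, event_times, rise_ms, decay_ms) {
  if (length(event_times) == 0) return(0)
  dt <- t - event_times
  rise <- rise_ms / 1000
  decay <- decay_ms / 1000
  w <- ifelse(dt < 0, 0,
              ifelse(dt < rise, dt / rise, exp(-(dt - rise) / decay)))
  sum(w)
}

#' Expected photon signal of a specimen under an excitation field
#'
#' The noise-free photon map (photons/pixel per reference exposure) at time
#' `t`: each specimen component contributes its brightness times the lateral
#' excitation at its position times the axial weight at its depth, and for
#' puffs a temporal envelope and Gaussian spatial footprint.
#'
#' @param spec A [specimen()].
#' @param field An `excitation_field` on the camera grid.
#' @param t Time, s (affects puff sites only).
#' @param camera The [camera_model()] defining the grid.
#' @return A matrix of expected photons/pixel per reference exposure.
#' @export
expected_signal <- function(spec, field, t = 0, camera = camera_model()) {
  grid <- field_grid(camera)
  base <- spec$film_brightness +
    spec$cytosol_brightness *
      axial_volume_fraction(field, spec$cytosol_thickness)
  sig <- base * field$lateral
  if (!is.null(spec$beads) && nrow(spec$beads) > 0) {
    for (i in seq_len(nrow(spec$beads))) {
      b <- spec$beads[i, ]
      jj <- pmin(pmax(floor(b$x / grid$pixel_size) + 1, 1), grid$nx)
      ii <- pmin(pmax(floor(b$y / grid$pixel_size) + 1, 1), grid$ny)
      sig[ii, jj] <- sig[ii, jj] +
        b$brightness * field$lateral[ii, jj] * axial_weight(field, b$z)
    }
  }
  ps <- spec$puff_sites
  if (!is.null(ps) && nrow(ps) > 0) {
    for (i in seq_len(nrow(ps))) {
      s <- ps[i, ]
      tf <- puff_temporal(t, s$event_times[[1]], s$rise_time, s$decay_time)
      if (tf <= 0) next
      foot <- exp(-((grid$x - s$x)^2 + (grid$y - s$y)^2) /
                    (2 * s$spatial_sigma^2))
      sig <- sig + s$amplitude * tf * axial_weight(field, s$z) *
        field$lateral * foot
    }
  }
  sig
}

# Deterministic per-frame seed derived from the run seed (kept < 2^31 so
# frame-level parallel rendering cannot change results).
frame_seed <- function(seed, frame) {
  as.integer((as.double(seed) * 48271 + frame * 16807) %% 2147483647)
}

#' Render an interleaved image stack
#'
#' Simulates the full acquisition: for every frame of the schedule the
#' excitation field of the frame's preset is applied to the specimen,
#' photons are drawn from a Poisson distribution at
#' `qe x expected signal x exposure`, multiplied by the EM register
#' (gamma-distributed gain, or plain mean gain), read noise and the black
#' level are added, and the result is quantized to 16-bit counts. Frames
#' carry the schedule's mode labels so the stack can be de-interleaved
#' downstream.
#'
#' @param spec A [specimen()].
#' @param schedule A [build_schedule()] result.
#' @param cfg An [optical_config()].
#' @param camera A [camera_model()].
#' @param seed Integer seed; the run is reproducible from (inputs, seed),
#'   each frame drawing from its own counter-derived substream.
#' @param speckle A [speckle_model()] for the lateral irregularities.
#' @param n_azimuths Azimuths averaged per spinning/skimming frame.
#' @return An `image_stack`: list with `frames` (list of integer matrices),
#'   `mode_tags`, `labels`, `timestamps` (s), `exposure_time`, `camera`,
#'   and `meta` (seed, fields used).
#' @export
render_stack <- function(spec, schedule, cfg = optical_config(),
                         camera = camera_model(), seed = 1L,
                         speckle = speckle_model(), n_azimuths = 360) {
  stopifnot(inherits(schedule, "interleave_schedule"))
  pr <- schedule$presets
  fields <- vector("list", nrow(pr))
  for (i in seq_len(nrow(pr))) {
    fields[[i]] <- mode_field(pr$mode_tag[i], scan_radius = pr$radius[i],
                              speckle = speckle, occluders = spec$occluders,
                              cfg = cfg, camera = camera,
                              n_azimuths = n_azimuths)
  }
  exc <- ifelse(pr$laser_on, pr$laser_power, 0)
  expos <- schedule$exposure_time / spec$reference_exposure
  nfr <- schedule$n_frames
  frames <- vector("list", nfr)
  npx <- prod(camera$frame_shape)
  saturated <- FALSE
  for (f in seq_len(nfr)) {
    pi_ <- schedule$frames$preset_index[f]
    mu <- camera$qe * exc[pi_] * expos *
      expected_signal(spec, fields[[pi_]], schedule$frames$start_time[f] +
                        schedule$exposure_time / 2, camera)
    set.seed(frame_seed(seed, f))
    e <- stats::rpois(npx, mu)
    if (camera$gain_model == "gamma") {
      counts <- numeric(npx)
      pos <- e > 0
      counts[pos] <- stats::rgamma(sum(pos), shape = e[pos],
                                   scale = camera$em_gain)
    } else {
      counts <- e * camera$em_gain
    }
    counts <- counts + stats::rnorm(npx, 0, camera$read_noise) +
      camera$black_level
    counts <- round(counts)
    counts[counts < 0] <- 0
    if (any(counts > 65535)) {
      saturated <- TRUE
      counts[counts > 65535] <- 65535
    }
    frames[[f]] <- matrix(as.integer(counts), camera$frame_shape[1],
                          camera$frame_shape[2])
  }
  if (saturated) {
    rlang::warn("counts exceeded the 16-bit range and were clipped",
                class = "spintirf_saturation_warning")
  }
  new_image_stack(frames,
                  mode_tags = schedule$frames$mode_tag,
                  labels = schedule$frames$label,
                  timestamps = schedule$frames$start_time,
                  exposure_time = schedule$exposure_time,
                  camera = camera,
                  meta = list(seed = as.integer(seed),
                              n_azimuths = n_azimuths))
}

new_image_stack <- function(frames, mode_tags, labels, timestamps,
                            exposure_time, camera, meta = list()) {
  stopifnot(length(frames) == length(mode_tags),
            length(frames) == length(timestamps))
  structure(
    list(frames = frames, mode_tags = mode_tags, labels = labels,
         timestamps = timestamps, exposure_time = exposure_time,
         camera = camera, meta = meta),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  dims <- if (length(x$frames)) dim(x$frames[[1]]) else c(0, 0)
  cat(sprintf("<image_stack> %d frame(s) of %dx%d px, %.3g ms exposure, modes: %s\n",
              length(x$frames), dims[1], dims[2], 1e3 * x$exposure_time,
              paste(unique(x$mode_tags), collapse = ", ")))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack An `image_stack` or `ratio_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) length(stack$frames)

#' Packaged simulation scenarios
#'
#' Deterministic generators of specimen + schedule pairs mirroring the
#' benchmark experiments the package is built around:
#' \describe{
#'   \item{film_beads}{uniform rhodamine film with a few surface-adherent
#'     fluorescent beads, imaged in spinning-spot TIRF — used for field
#'     uniformity and temporal stability measurements (600 frames at 5 ms
#'     by default).}
#'   \item{shadow_cells}{film plus refractile occluders, alternating
#'     stationary- and spinning-spot TIRF frames, to exercise shadow
#'     suppression.}
#'   \item{puff_depths}{Ca2+ puff sites at depths drawn uniformly from
#'     0-600 nm, each with at least 4 events, imaged in alternating
#'     TIRF/widefield 5 ms frames for depth analysis.}
#'   \item{triple_interleave}{three presets (488 nm spinning TIRF, 532 nm
#'     spinning TIRF, skimming plane) cycled frame by frame.}
#' }
#'
#' @param name Scenario name.
#' @param seed Integer seed; the same seed yields an identical scenario and,
#'   via [render_stack()], byte-identical stacks.
#' @param overrides Named list overriding scenario defaults. Common keys:
#'   `n_frames`, `exposure_time`, `film_brightness`; `puff_depths` also
#'   accepts `n_sites`, `n_events`, `depth_range` (nm), `amplitude`,
#'   `event_spacing` (s), `depths` (explicit site depths, nm).
#' @return A list with elements `specimen`, `schedule`, `cfg`, `camera`,
#'   `speckle`, and `name`.
#' @export
make_scenario <- function(name = c("film_beads", "shadow_cells",
                                   "puff_depths", "triple_interleave"),
                          seed = 1L, overrides = list()) {
  name <- match.arg(name)
  ov <- function(key, default) {
    if (!is.null(overrides[[key]])) overrides[[key]] else default
  }
  cfg <- optical_config()
  speckle <- speckle_model(contrast = ov("speckle_contrast", 0.3),
                           seed = seed)
  exposure <- ov("exposure_time", 0.005)
  film <- ov("film_brightness", 100)

  if (name == "film_beads") {
    camera <- camera_model(frame_shape = ov("frame_shape", c(128L, 128L)))
    w <- camera$frame_shape[2] * camera$pixel_size
    beads <- if (isTRUE(ov("beads", TRUE))) {
      withr::with_seed(seed, tibble::tibble(
        x = stats::runif(5, 0.15 * w, 0.85 * w),
        y = stats::runif(5, 0.15 * w, 0.85 * w),
        z = c(0, 0, 0, 200, 400),
        brightness = 500))
    } else NULL
    spec <- specimen(film_brightness = film, beads = beads)
    sched <- build_schedule(scan_preset("tirf", frequency = 200,
                                        radius = 0.97),
                            exposure_time = exposure,
                            n_frames = ov("n_frames", 600))
  } else if (name == "shadow_cells") {
    camera <- camera_model(frame_shape = ov("frame_shape", c(96L, 96L)))
    w <- camera$frame_shape[2] * camera$pixel_size
    occ <- tibble::tibble(
      x = c(0.35, 0.6, 0.5) * w, y = c(0.4, 0.65, 0.25) * w,
      radius = c(2, 1.5, 1), attenuation = c(0.6, 0.5, 0.4))
    spec <- specimen(film_brightness = film, occluders = occ)
    sched <- build_schedule(
      dplyr::bind_rows(
        scan_preset("stat", frequency = 200, radius = 0.97,
                    mode_tag = "stationary_tirf"),
        scan_preset("spin", frequency = 200, radius = 0.97)),
      exposure_time = exposure, n_frames = ov("n_frames", 20))
  } else if (name == "puff_depths") {
    camera <- camera_model(frame_shape = ov("frame_shape", c(96L, 96L)))
    w <- camera$frame_shape[2] * camera$pixel_size
    n_sites <- ov("n_sites", 8)
    n_events <- ov("n_events", 6)
    spacing <- ov("event_spacing", 0.25)
    depth_range <- ov("depth_range", c(0, 600))
    ncol_s <- ceiling(sqrt(n_sites))
    nrow_s <- ceiling(n_sites / ncol_s)
    gx <- ((seq_len(ncol_s) - 0.5) / ncol_s) * 0.8 * w + 0.1 * w
    gy <- ((seq_len(nrow_s) - 0.5) / nrow_s) * 0.8 * w + 0.1 * w
    pos <- expand.grid(x = gx, y = gy)[seq_len(n_sites), ]
    st <- withr::with_seed(seed, list(
      z = ov("depths",
             stats::runif(n_sites, depth_range[1], depth_range[2])),
      jit = stats::runif(n_sites, 0, 0.02)))
    baseline <- ov("baseline_time", 0.5)
    times <- lapply(seq_len(n_sites), function(i) {
      baseline + (seq_len(n_events) - 1) * spacing + st$jit[i]
    })
    ps <- puff_sites(pos$x, pos$y, st$z, times,
                     amplitude = ov("amplitude", 200))
    spec <- specimen(film_brightness = film,
                     cytosol_brightness = ov("cytosol_brightness", 300),
                     puff_sites = ps)
    duration <- baseline + n_events * spacing + 0.3
    # scan radius just above the TIR threshold: deep-penetration TIRF
    # (d ~ 220 nm) commensurate with the 0-600 nm depth range probed
    sched <- build_schedule(
      dplyr::bind_rows(
        scan_preset("tirf", frequency = 200, radius = ov("tirf_radius", 0.925)),
        scan_preset("wf", radius = 0.1, mode_tag = "widefield")),
      exposure_time = exposure,
      n_frames = ov("n_frames", 2 * ceiling(duration / (2 * exposure))))
  } else { # triple_interleave
    camera <- camera_model(frame_shape = ov("frame_shape", c(64L, 64L)))
    w <- camera$frame_shape[2] * camera$pixel_size
    beads <- withr::with_seed(seed, tibble::tibble(
      x = stats::runif(4, 0.2 * w, 0.8 * w),
      y = stats::runif(4, 0.2 * w, 0.8 * w),
      z = c(0, 100, 400, 800), brightness = 500))
    spec <- specimen(film_brightness = film, beads = beads)
    sched <- build_schedule(
      dplyr::bind_rows(
        scan_preset("tirf488", frequency = 200, radius = 0.97,
                    laser_id = 488),
        scan_preset("tirf532", frequency = 200, radius = 0.97,
                    laser_id = 532),
        scan_preset("skim", frequency = 200, radius = 0.9,
                    mode_tag = "skimming")),
      exposure_time = exposure, n_frames = ov("n_frames", 9))
  }
  list(specimen = spec, schedule = sched, cfg = cfg, camera = camera,
       speckle = speckle, name = name)
}
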