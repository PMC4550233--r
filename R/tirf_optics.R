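#' Optical configuration of the TIRF illuminator
#'
#' Holds the physical constants of the through-the-objective TIRF geometry:
#' laser wavelength, refractive indices either side of the coverslip
#' interface, objective numerical aperture and focal length, plus the
#' phenomenological parameters of the illumination model (beam envelope,
#' shadow recovery length, widefield cell thickness, skimming-plane
#' effective depth).
#'
#' @param wavelength Excitation wavelength, nm.
#' @param n_glass Refractive index of the coverslip/immersion side
#'   (\eqn{n_1}).
#' @param n_water Refractive index of the aqueous side (\eqn{n_2}).
#' @param numerical_aperture Objective NA; must not exceed `n_glass`.
#' @param objective_focal_length Objective focal length, mm (3.0 mm for a
#'   60x objective with a 180 mm tube lens).
#' @param beam_waist Gaussian beam envelope 1/e^2 intensity radius at the
#'   specimen, um. `Inf` (the default) models a well-expanded beam that is
#'   flat over the imaged field.
#' @param shadow_length Recovery length of occluder shadows, um: the
#'   attenuation behind an occluder decays as `exp(-s / shadow_length)` with
#'   downstream distance `s`.
#' @param shadow_spread Half-angle, degrees, by which a shadow wedge widens
#'   with downstream distance.
#' @param cell_thickness Axial extent, um, excited uniformly in
#'   pseudo-widefield mode.
#' @param skimming_depth Effective exponential depth, nm, of skimming-plane
#'   illumination (scan radius just below the TIR threshold).
#'
#' @return A list of class `optical_config`.
#' @export
optical_config <- function(wavelength = 488,
                           n_glass = 1.515,
                           n_water = 1.33,
                           numerical_aperture = 1.45,
                           objective_focal_length = 3.0,
                           beam_waist = Inf,
                           shadow_length = 5,
                           shadow_spread = 5,
                           cell_thickness = 5,
                           skimming_depth = 1000) {
  if (n_water >= n_glass) {
    rlang::abort("total internal reflection requires n_water < n_glass",
                 class = "spintirf_no_tir_error")
  }
  if (numerical_aperture > n_glass) {
    rlang::abort("`numerical_aperture` cannot exceed `n_glass`",
                 class = "spintirf_optics_error")
  }
  stopifnot(wavelength > 0, objective_focal_length > 0)
  structure(
    list(wavelength = wavelength, n_glass = n_glass, n_water = n_water,
         numerical_aperture = numerical_aperture,
         objective_focal_length = objective_focal_length,
         beam_waist = beam_waist, shadow_length = shadow_length,
         shadow_spread = shadow_spread, cell_thickness = cell_thickness,
         skimming_depth = skimming_depth),
    class = "optical_config")
}

#' Critical angle for total internal reflection
#'
#' \eqn{\theta_c = \arcsin(n_2 / n_1)}: the minimum incidence angle at the
#' glass-water interface beyond which all light is totally internally
#' reflected and only an evanescent field enters the aqueous phase.
#'
#' @param n_glass,n_water Refractive indices (\eqn{n_1 > n_2}).
#' @return Critical angle in degrees.
#' @examples
#' critical_angle(1.515, 1.33)  # about 61.4 degrees
#' @export
critical_angle <- function(n_glass = 1.515, n_water = 1.33) {
  if (n_water > n_glass || n_water <= 0) {
    rlang::abort("no TIR: requires 0 < n_water <= n_glass",
                 class = "spintirf_no_tir_error")
  }
  asin(n_water / n_glass) * 180 / pi
}

#' Map back-focal-plane radius to incidence angle (and back)
#'
#' The objective obeys the Abbe sine condition, so a focused spot at radial
#' position `r` in the back focal plane emerges at incidence angle
#' \eqn{\theta = \arcsin(r / (f\, n_1))}. The usable aperture ends at
#' `r = f * NA`.
#'
#' @param r Radial position of the laser spot at the BFP, mm.
#' @param cfg An [optical_config()].
#' @return Incidence angle in degrees (`bfp_radius_to_angle`) or BFP radius
#'   in mm (`angle_to_bfp_radius`).
#' @examples
#' cfg <- optical_config()
#' bfp_radius_to_angle(3.99, cfg)   # TIR onset: the critical angle
#' angle_to_bfp_radius(61.39, cfg)
#' @export
bfp_radius_to_angle <- function(r, cfg = optical_config()) {
  r_max <- cfg$objective_focal_length * cfg$numerical_aperture
  if (any(r < 0) || any(r > r_max + 1e-9)) {
    rlang::abort(
      sprintf("BFP radius outside the aperture: r must lie in [0, %.3f] mm",
              r_max),
      class = "spintirf_aperture_error")
  }
  asin(r / (cfg$objective_focal_length * cfg$n_glass)) * 180 / pi
}

#' @rdname bfp_radius_to_angle
#' @param theta Incidence angle, degrees.
#' @export
angle_to_bfp_radius <- function(theta, cfg = optical_config()) {
  r <- cfg$objective_focal_length * cfg$n_glass * sin(theta * pi / 180)
  r_max <- cfg$objective_focal_length * cfg$numerical_aperture
  if (any(r > r_max + 1e-9)) {
    rlang::abort("angle maps outside the objective aperture",
                 class = "spintirf_aperture_error")
  }
  r
}

#' Evanescent-field penetration depth
#'
#' Above the critical angle the excitation intensity decays as
#' \eqn{\exp(-z/d)} with distance \eqn{z} from the interface, where
#' \deqn{d = \frac{\lambda}{4\pi\sqrt{n_1^2 \sin^2\theta - n_2^2}}.}
#' At the maximal angle of an NA 1.45 objective with 488 nm light the depth
#' is about 67 nm, i.e. excitation is confined to a sheet of the order of
#' 100 nm above the coverslip.
#'
#' @param wavelength Wavelength, nm.
#' @param theta Incidence angle, degrees; must exceed the critical angle.
#' @param cfg An [optical_config()] supplying the refractive indices.
#' @return Penetration depth \eqn{d}, nm.
#' @examples
#' cfg <- optical_config()
#' theta_max <- asin(cfg$numerical_aperture / cfg$n_glass) * 180 / pi
#' penetration_depth(488, theta_max, cfg)
#' @export
penetration_depth <- function(wavelength, theta, cfg = optical_config()) {
  thc <- critical_angle(cfg$n_glass, cfg$n_water)
  if (any(theta <= thc)) {
    rlang::abort(
      sprintf("subcritical angle: theta must exceed the critical angle (%.2f deg)",
              thc),
      class = "spintirf_subcritical_error")
  }
  s2 <- (cfg$n_glass * sin(theta * pi / 180))^2 - cfg$n_water^2
  wavelength / (4 * pi * sqrt(s2))
}

#' Phenomenological laser speckle model
#'
#' Coherent laser excitation introduced from a single azimuth produces
#' interference fringes whose orientation is locked to the illumination
#' direction. The model represents them as a sum of `n_components` cosine
#' fringes with randomized spatial period, small orientation jitter about
#' the azimuth, and random phases, with overall modulation depth `contrast`.
#'
#' @param n_components Number of interfering fringe terms (>= 1).
#' @param contrast Modulation depth in `[0, 1]`; 0 disables speckle.
#' @param fringe_period Nominal fringe period, um.
#' @param seed RNG seed for the fringe parameters; the same seed yields the
#'   same fringe family at every azimuth, so azimuthal averages are
#'   deterministic.
#' @return A list of class `speckle_model`.
#' @export
speckle_model <- function(n_components = 8, contrast = 0.3,
                          fringe_period = 1.5, seed = 1L) {
  stopifnot(n_components >= 1, contrast >= 0, contrast <= 1,
            fringe_period > 0)
  pars <- withr::with_seed(as.integer(seed), list(
    d_angle = stats::runif(n_components, -15, 15),       # deg about azimuth
    period = fringe_period * stats::runif(n_components, 0.7, 1.3),
    phase = stats::runif(n_components, 0, 2 * pi)
  ))
  structure(
    list(n_components = as.integer(n_components), contrast = contrast,
         fringe_period = fringe_period, seed = as.integer(seed),
         components = pars),
    class = "speckle_model")
}

#' Pixel-centred field grid
#'
#' Coordinates of pixel centres on the camera grid, in um, with the origin
#' at the corner of the field: pixel (row i, col j), 0-based, has centre
#' `((j + 0.5) * pixel_size, (i + 0.5) * pixel_size)`.
#'
#' @param camera A [camera_model()].
#' @return List with matrices `x`, `y` (um) and scalars `nx`, `ny`,
#'   `pixel_size`.
#' @keywords internal
field_grid <- function(camera) {
  ny <- camera$frame_shape[1]
  nx <- camera$frame_shape[2]
  xs <- (seq_len(nx) - 0.5) * camera$pixel_size
  ys <- (seq_len(ny) - 0.5) * camera$pixel_size
  list(x = matrix(xs, ny, nx, byrow = TRUE),
       y = matrix(ys, ny, nx),
       nx = nx, ny = ny, pixel_size = camera$pixel_size)
}

# Gaussian beam intensity envelope centred on the field (flat when waist Inf)
beam_envelope <- function(grid, cfg) {
  if (!is.finite(cfg$beam_waist)) {
    return(matrix(1, grid$ny, grid$nx))
  }
  cx <- grid$nx * grid$pixel_size / 2
  cy <- grid$ny * grid$pixel_size / 2
  exp(-2 * ((grid$x - cx)^2 + (grid$y - cy)^2) / cfg$beam_waist^2)
}

# Multiplicative shadow mask for occluders illuminated from `azimuth`.
# Light propagates toward +azimuth: each occluder disk attenuates by its
# `attenuation`, and casts a downstream wedge whose attenuation recovers
# exponentially over cfg$shadow_length um.
shadow_mask <- function(grid, occluders, azimuth, cfg) {
  mask <- matrix(1, grid$ny, grid$nx)
  if (is.null(occluders) || nrow(occluders) == 0) return(mask)
  a <- azimuth * pi / 180
  ux <- cos(a); uy <- sin(a)
  tanw <- tan(cfg$shadow_spread * pi / 180)
  for (i in seq_len(nrow(occluders))) {
    oc <- occluders[i, ]
    dx <- grid$x - oc$x
    dy <- grid$y - oc$y
    s <- dx * ux + dy * uy                 # downstream distance
    p <- abs(-dx * uy + dy * ux)           # perpendicular offset
    inside <- (dx^2 + dy^2) <= oc$radius^2
    wedge <- (s > 0) & (p <= oc$radius + s * tanw) & !inside
    att <- matrix(1, grid$ny, grid$nx)
    att[inside] <- 1 - oc$attenuation
    att[wedge] <- 1 - oc$attenuation * exp(-s[wedge] / cfg$shadow_length)
    mask <- mask * att
  }
  mask
}

#' Excitation field for a single (stationary) illumination azimuth
#'
#' The lateral excitation map produced when the laser spot is held at one
#' azimuthal position on the BFP circle: a Gaussian beam envelope modulated
#' by azimuth-locked interference fringes and by shadows cast downstream of
#' any occluders. The map is normalized to mean 1 so that switching
#' illumination geometry never changes the total expected signal from a
#' uniform specimen at the interface.
#'
#' @param azimuth Illumination azimuth, degrees (0 propagates toward +x).
#' @param speckle A [speckle_model()].
#' @param occluders `NULL` or a data frame with columns `x`, `y` (um),
#'   `radius` (um), `attenuation` (0-1).
#' @param cfg An [optical_config()].
#' @param camera A [camera_model()] defining the pixel grid.
#' @return A matrix (rows = camera rows) with mean 1.
#' @export
single_azimuth_field <- function(azimuth, speckle = speckle_model(),
                                 occluders = NULL,
                                 cfg = optical_config(),
                                 camera = camera_model()) {
  grid <- field_grid(camera)
  env <- beam_envelope(grid, cfg)
  fringes <- matrix(0, grid$ny, grid$nx)
  if (speckle$contrast > 0) {
    comp <- speckle$components
    for (i in seq_len(speckle$n_components)) {
      th <- (azimuth + comp$d_angle[i]) * pi / 180
      arg <- 2 * pi * (grid$x * cos(th) + grid$y * sin(th)) / comp$period[i] +
        comp$phase[i]
      fringes <- fringes + cos(arg)
    }
    fringes <- fringes / speckle$n_components
  }
  f <- env * (1 + speckle$contrast * fringes) *
    shadow_mask(grid, occluders, azimuth, cfg)
  f / mean(f)
}

#' Azimuthally averaged (spinning-spot) excitation field
#'
#' The lateral field seen by a camera exposure spanning a whole revolution
#' of the spot: the mean of [single_azimuth_field()] over `n_azimuths`
#' equally spaced illumination directions. Fringes and shadows point in a
#' different direction at every azimuth, so they average toward a uniform
#' field as `n_azimuths` grows.
#'
#' @inheritParams single_azimuth_field
#' @param n_azimuths Number of equally spaced azimuths averaged (>= 1).
#' @param scan_radius Normalized scan radius (fraction of the aperture
#'   radius) used to derive the evanescent depth of the axial model.
#' @return An `excitation_field`: list with `lateral` (mean-1 matrix),
#'   `axial` (model descriptor), `mode_tag`, `azimuths`, `pixel_size`.
#' @export
spinning_field <- function(n_azimuths = 360, speckle = speckle_model(),
                           occluders = NULL, cfg = optical_config(),
                           camera = camera_model(), scan_radius = 1) {
  stopifnot(n_azimuths >= 1)
  az <- (seq_len(n_azimuths) - 1) * 360 / n_azimuths
  lat <- matrix(0, camera$frame_shape[1], camera$frame_shape[2])
  for (a in az) {
    lat <- lat + single_azimuth_field(a, speckle, occluders, cfg, camera)
  }
  lat <- lat / n_azimuths
  d <- tirf_depth_from_scan_radius(scan_radius, cfg)
  new_excitation_field(lat, list(model = "evanescent", d = d),
                       "spinning_tirf", az, camera$pixel_size)
}

new_excitation_field <- function(lateral, axial, mode_tag, azimuths,
                                 pixel_size) {
  lateral <- lateral / mean(lateral)
  structure(
    list(lateral = lateral, axial = axial, mode_tag = mode_tag,
         azimuths = azimuths, pixel_size = pixel_size),
    class = "excitation_field")
}

#' @export
print.excitation_field <- function(x, ...) {
  ax <- switch(x$axial$model,
               evanescent = sprintf("evanescent, d = %.1f nm", x$axial$d),
               uniform = sprintf("uniform over %.1f um", x$axial$thickness),
               skimming = sprintf("skimming, d_eff = %.0f nm", x$axial$d))
  cat(sprintf("<excitation_field> %s, %dx%d px, %d azimuth(s), axial: %s\n",
              x$mode_tag, nrow(x$lateral), ncol(x$lateral),
              length(x$azimuths), ax))
  invisible(x)
}

# Evanescent depth for a spot at normalized scan radius (1 = aperture edge)
tirf_depth_from_scan_radius <- function(scan_radius, cfg) {
  r_mm <- scan_radius * cfg$objective_focal_length * cfg$numerical_aperture
  r_crit <- cfg$objective_focal_length * cfg$n_water
  if (r_mm <= r_crit * (1 + 1e-12)) {
    rlang::abort(
      sprintf("subcritical scan radius: TIRF needs r > %.3f (normalized %.3f)",
              r_crit, r_crit / (cfg$objective_focal_length *
                                  cfg$numerical_aperture)),
      class = "spintirf_subcritical_error")
  }
  theta <- bfp_radius_to_angle(r_mm, cfg)
  penetration_depth(cfg$wavelength, theta, cfg)
}

#' Axial excitation weight of a field at depth z
#'
#' @param field An `excitation_field`.
#' @param z Depth above the coverslip, nm (vectorized).
#' @return Relative excitation weight at each depth (1 at the interface).
#' @export
axial_weight <- function(field, z) {
  ax <- field$axial
  switch(ax$model,
         evanescent = exp(-z / ax$d),
         skimming = exp(-z / ax$d),
         uniform = as.numeric(z <= ax$thickness * 1000),
         rlang::abort("unknown axial model"))
}

#' Fraction of a uniform axial volume excited by a field
#'
#' The mean axial excitation weight over a slab of fluorophore extending
#' from the coverslip to `thickness` um: 1 for widefield (the whole slab is
#' excited), about `d / thickness` for an evanescent or skimming field.
#' Used to weight volume-distributed (cytosolic) indicator against
#' membrane-proximal components.
#'
#' @param field An `excitation_field`.
#' @param thickness Slab thickness, um.
#' @return Scalar in `(0, 1]`.
#' @export
axial_volume_fraction <- function(field, thickness) {
  ax <- field$axial
  l_nm <- thickness * 1000
  switch(ax$model,
         evanescent = ,
         skimming = ax$d / l_nm * (1 - exp(-l_nm / ax$d)),
         uniform = min(ax$thickness * 1000, l_nm) / l_nm,
         rlang::abort("unknown axial model"))
}

#' Excitation field for a named illumination mode
#'
#' Dispatches to the lateral + axial model of each of the four modes:
#' \describe{
#'   \item{spinning_tirf}{azimuthal average over `n_azimuths`; evanescent
#'     axial decay with depth set by the scan radius.}
#'   \item{stationary_tirf}{single azimuth (conventional TIRF); same axial
#'     model, but fringes and shadows survive in the lateral map.}
#'   \item{widefield}{small-radius scan giving near-axial epifluorescence:
#'     smooth lateral envelope, uniform axial excitation through the cell
#'     thickness.}
#'   \item{skimming}{scan radius just below the TIR threshold; azimuthally
#'     averaged lateral map with an effective exponential depth of order
#'     1 um.}
#' }
#'
#' @inheritParams spinning_field
#' @param mode_tag One of `"spinning_tirf"`, `"stationary_tirf"`,
#'   `"widefield"`, `"skimming"`.
#' @param azimuth Azimuth used for `stationary_tirf`, degrees.
#' @return An `excitation_field`.
#' @export
mode_field <- function(mode_tag, scan_radius = 1,
                       speckle = speckle_model(), occluders = NULL,
                       cfg = optical_config(), camera = camera_model(),
                       n_azimuths = 360, azimuth = 0) {
  switch(
    mode_tag,
    spinning_tirf = spinning_field(n_azimuths, speckle, occluders, cfg,
                                   camera, scan_radius),
    stationary_tirf = {
      d <- tirf_depth_from_scan_radius(scan_radius, cfg)
      lat <- single_azimuth_field(azimuth, speckle, occluders, cfg, camera)
      new_excitation_field(lat, list(model = "evanescent", d = d),
                           "stationary_tirf", azimuth, camera$pixel_size)
    },
    widefield = {
      grid <- field_grid(camera)
      lat <- beam_envelope(grid, cfg)
      new_excitation_field(lat,
                           list(model = "uniform",
                                thickness = cfg$cell_thickness),
                           "widefield", numeric(0), camera$pixel_size)
    },
    skimming = {
      az <- (seq_len(n_azimuths) - 1) * 360 / n_azimuths
      lat <- matrix(0, camera$frame_shape[1], camera$frame_shape[2])
      for (a in az) {
        lat <- lat + single_azimuth_field(a, speckle, occluders, cfg, camera)
      }
      new_excitation_field(lat / n_azimuths,
                           list(model = "skimming", d = cfg$skimming_depth),
                           "skimming", az, camera$pixel_size)
    },
    rlang::abort(sprintf("unknown mode_tag '%s'", mode_tag))
  )
}
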