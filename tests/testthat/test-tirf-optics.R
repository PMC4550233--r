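test_that("critical angle follows arcsin(n2/n1)", {
  expect_equal(critical_angle(1.515, 1.33), 61.39, tolerance = 1e-4)
  expect_equal(critical_angle(1.4, 1.4), 90)
  expect_error(critical_angle(1.515, 1.6), class = "spintirf_no_tir_error")
})

test_that("BFP radius maps to incidence angle by the sine condition", {
  cfg <- optical_config()
  # TIR onset: r = f * n_water -> exactly the critical angle
  expect_equal(bfp_radius_to_angle(3.0 * 1.33, cfg),
               critical_angle(1.515, 1.33), tolerance = 1e-9)
  # aperture edge: r = f * NA -> arcsin(NA / n1)
  expect_equal(bfp_radius_to_angle(3.0 * 1.45, cfg), 73.15,
               tolerance = 1e-3)
  expect_equal(bfp_radius_to_angle(0, cfg), 0)
  expect_error(bfp_radius_to_angle(4.5, cfg),
               class = "spintirf_aperture_error")
  # inverse consistency over the whole aperture
  r <- seq(0, 3.0 * 1.45, length.out = 50)
  expect_equal(angle_to_bfp_radius(bfp_radius_to_angle(r, cfg), cfg), r,
               tolerance = 1e-9)
})

test_that("TIRF annulus endpoints match the closed forms", {
  cfg <- optical_config()
  r_lo <- cfg$objective_focal_length * cfg$n_water
  r_hi <- cfg$objective_focal_length * cfg$numerical_aperture
  expect_equal(r_lo, 3.99)
  expect_equal(r_hi, 4.35)
  expect_error(spintirf:::tirf_depth_from_scan_radius(r_lo / r_hi, cfg),
               class = "spintirf_subcritical_error")
  expect_gt(spintirf:::tirf_depth_from_scan_radius(1, cfg), 0)
})

test_that("penetration depth follows the evanescent decay formula", {
  cfg <- optical_config()
  expect_equal(penetration_depth(488, 73.15569, cfg), 67.24,
               tolerance = 1e-3)
  thc <- critical_angle(1.515, 1.33)
  expect_gt(penetration_depth(488, thc + 1e-6, cfg), 1e4)  # pole at theta_c
  expect_gt(penetration_depth(488, 70, cfg),
            penetration_depth(488, 73, cfg))  # decreasing in theta
  expect_error(penetration_depth(488, thc, cfg),
               class = "spintirf_subcritical_error")
})

test_that("zero-contrast single-azimuth field is the flat beam envelope", {
  cam <- tiny_camera()
  f <- single_azimuth_field(0, speckle_model(contrast = 0), NULL,
                            optical_config(), cam)
  expect_equal(max(f) - min(f), 0, tolerance = 1e-12)
  expect_equal(mean(f), 1, tolerance = 1e-12)
  # with a finite beam waist the centre linescan is symmetric about its peak
  cfg_w <- optical_config(beam_waist = 10)
  fw <- single_azimuth_field(0, speckle_model(contrast = 0), NULL, cfg_w,
                             cam)
  prof <- linescan(fw)$value
  expect_equal(prof, rev(prof), tolerance = 1e-9)
})

test_that("occluders cast shadows away from the illumination azimuth", {
  cam <- tiny_camera()
  w <- 32 * cam$pixel_size
  occ <- tibble::tibble(x = w / 2, y = w / 2, radius = 1,
                        attenuation = 0.8)
  f0 <- single_azimuth_field(0, speckle_model(contrast = 0), occ,
                             optical_config(), cam)
  f180 <- single_azimuth_field(180, speckle_model(contrast = 0), occ,
                               optical_config(), cam)
  grid <- spintirf:::field_grid(cam)
  band <- abs(grid$y - w / 2) < 0.8
  down <- band & grid$x > w / 2 + 1.2
  up <- band & grid$x < w / 2 - 1.2
  expect_lt(mean(f0[down]), mean(f0[up]))         # shadow on the +x side
  expect_lt(mean(f180[up]), mean(f180[down]))     # mirrored at 180 degrees
  expect_equal(mean(f0[down]) / mean(f0[up]),
               mean(f180[up]) / mean(f180[down]), tolerance = 1e-6)
})

test_that("speckle contrast raises the field's coefficient of variation", {
  cam <- tiny_camera()
  cv <- function(c) {
    f <- single_azimuth_field(0, speckle_model(contrast = c, seed = 5),
                              NULL, optical_config(), cam)
    stats::sd(f) / mean(f)
  }
  expect_gt(cv(0.5), cv(0.1))
})

test_that("spinning field equals the brute-force azimuth average", {
  cam <- tiny_camera()
  sp <- speckle_model(seed = 3)
  f1 <- spinning_field(1, sp, NULL, optical_config(), cam)
  expect_equal(f1$lateral,
               single_azimuth_field(0, sp, NULL, optical_config(), cam),
               tolerance = 1e-12)
  n <- 8
  brute <- Reduce(`+`, lapply((0:(n - 1)) * 360 / n, function(a) {
    single_azimuth_field(a, sp, NULL, optical_config(), cam)
  })) / n
  fn <- spinning_field(n, sp, NULL, optical_config(), cam)
  expect_equal(fn$lateral, brute, tolerance = 1e-12)
})

test_that("azimuthal averaging monotonically smooths fringes and shadows", {
  cam <- tiny_camera()
  sp <- speckle_model(seed = 7)
  w <- 32 * cam$pixel_size
  occ <- tibble::tibble(x = w / 2, y = w / 2, radius = 0.8,
                        attenuation = 0.5)
  cvs <- vapply(c(1, 4, 16, 64, 360), function(n) {
    f <- spinning_field(n, sp, occ, optical_config(), cam)
    stats::sd(f$lateral) / mean(f$lateral)
  }, numeric(1))
  expect_true(all(diff(cvs) < 0))
  expect_lt(cvs[5], cvs[1])
})

test_that("all mode fields are mean-normalized with the stated axial models", {
  cam <- tiny_camera()
  for (m in c("spinning_tirf", "stationary_tirf", "widefield", "skimming")) {
    f <- mode_field(m, scan_radius = 1, camera = cam, n_azimuths = 16)
    expect_equal(mean(f$lateral), 1, tolerance = 1e-6)
    expect_true(all(f$lateral >= 0))
  }
  wf <- mode_field("widefield", camera = cam)
  expect_equal(axial_weight(wf, 0), axial_weight(wf, 2000))  # uniform slab
  sp <- mode_field("spinning_tirf", scan_radius = 1, camera = cam,
                   n_azimuths = 4)
  expect_equal(axial_weight(sp, sp$axial$d), exp(-1))
  sk <- mode_field("skimming", camera = cam, n_azimuths = 4)
  z <- 500
  expect_gt(axial_weight(sk, z), axial_weight(sp, z))
  expect_lt(axial_weight(sk, z), axial_weight(wf, z))
  expect_error(mode_field("spinning_tirf", scan_radius = 0.5, camera = cam),
               class = "spintirf_subcritical_error")
})

test_that("axial volume fraction integrates the decay over the slab", {
  cam <- tiny_camera()
  sp <- mode_field("spinning_tirf", scan_radius = 1, camera = cam,
                   n_azimuths = 1)
  d <- sp$axial$d
  expect_equal(axial_volume_fraction(sp, 5), d / 5000 * (1 - exp(-5000 / d)))
  wf <- mode_field("widefield", camera = cam)
  expect_equal(axial_volume_fraction(wf, 5), 1)
})
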