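flat_speckle <- speckle_model(contrast = 0)

test_that("expected signal composes film, beads and axial weights", {
  cam <- tiny_camera()
  f <- mode_field("spinning_tirf", scan_radius = 1, speckle = flat_speckle,
                  camera = cam, n_azimuths = 1)
  empty <- specimen(film_brightness = 0)
  expect_true(all(expected_signal(empty, f, 0, cam) == 0))
  d <- f$axial$d
  px <- cam$pixel_size
  two_beads <- specimen(film_brightness = 0, beads = tibble::tibble(
    x = c(3, 9), y = c(3, 9), z = c(0, d), brightness = 100))
  sig <- expected_signal(two_beads, f, 0, cam)
  v <- sort(sig[sig > 0], decreasing = TRUE)
  expect_equal(v[1] / v[2], exp(1), tolerance = 1e-9)
  # mean-1 lateral maps: film gives identical total signal in any mode
  film <- specimen(film_brightness = 50)
  wf <- mode_field("widefield", speckle = flat_speckle, camera = cam)
  expect_equal(sum(expected_signal(film, f, 0, cam)),
               sum(expected_signal(film, wf, 0, cam)), tolerance = 1e-9)
})

test_that("cytosolic indicator loads widefield baseline more than TIRF", {
  cam <- tiny_camera()
  cyto <- specimen(film_brightness = 0, cytosol_brightness = 100)
  tf <- mode_field("spinning_tirf", scan_radius = 0.925,
                   speckle = flat_speckle, camera = cam, n_azimuths = 1)
  wf <- mode_field("widefield", camera = cam)
  expect_equal(mean(expected_signal(cyto, wf, 0, cam)), 100,
               tolerance = 1e-9)
  expect_lt(mean(expected_signal(cyto, tf, 0, cam)), 10)
})

test_that("puff kinetics rise linearly then decay exponentially", {
  tempo <- function(t) spintirf:::puff_temporal(t, 1, 10, 100)
  expect_equal(tempo(0.999), 0)
  expect_equal(tempo(1.005), 0.5)
  expect_equal(tempo(1.010), 1)
  expect_equal(tempo(1.110), exp(-1))
  # overlapping events from the same site sum
  expect_equal(spintirf:::puff_temporal(1.01, c(1, 1), 10, 100), 2)
})

test_that("noise-free render of an empty specimen is the black level", {
  cam <- tiny_camera(16, read_noise = 0)
  sched <- build_schedule(scan_preset(radius = 0.97), 0.005, 2)
  stk <- render_stack(specimen(film_brightness = 0), sched,
                      camera = cam, speckle = flat_speckle, n_azimuths = 4)
  expect_true(all(vapply(stk$frames, function(f) all(f == 100L),
                         logical(1))))
})

test_that("rendering is byte-identical for the same seed", {
  sc <- make_scenario("film_beads", seed = 4,
                      overrides = list(n_frames = 3,
                                       frame_shape = c(32L, 32L)))
  r1 <- render_stack(sc$specimen, sc$schedule, sc$cfg, sc$camera, seed = 4,
                     speckle = sc$speckle, n_azimuths = 8)
  r2 <- render_stack(sc$specimen, sc$schedule, sc$cfg, sc$camera, seed = 4,
                     speckle = sc$speckle, n_azimuths = 8)
  expect_identical(r1$frames, r2$frames)
  r3 <- render_stack(sc$specimen, sc$schedule, sc$cfg, sc$camera, seed = 5,
                     speckle = sc$speckle, n_azimuths = 8)
  expect_false(identical(r1$frames, r3$frames))
})

test_that("photon counts scale linearly with exposure time", {
  cam <- tiny_camera(24, gain_model = "mean", read_noise = 0)
  spec <- specimen(film_brightness = 100)
  mean_counts <- function(expos) {
    sched <- build_schedule(scan_preset(radius = 0.97), expos, 30)
    stk <- subtract_black(render_stack(spec, sched, camera = cam, seed = 11,
                                       speckle = flat_speckle,
                                       n_azimuths = 1))
    mean(unlist(stk$frames))
  }
  m1 <- mean_counts(0.005)
  m2 <- mean_counts(0.010)
  # Poisson relative error at 24x24x30 x ~100 photons is ~ 0.08%
  expect_equal(m2 / m1, 2, tolerance = 0.01)
})

test_that("EM register noise matches gamma-gain theory", {
  cam <- tiny_camera(16, em_gain = 40, read_noise = 5)
  spec <- specimen(film_brightness = 100)
  sched <- build_schedule(scan_preset(radius = 0.97), 0.005, 600)
  stk <- subtract_black(render_stack(spec, sched, camera = cam, seed = 8,
                                     speckle = flat_speckle,
                                     n_azimuths = 1))
  arr <- simplify2array(stk$frames)
  v_over_m <- mean(apply(arr, c(1, 2), stats::var)) / mean(arr)
  mu_e <- 100 * cam$qe
  theory <- 2 * cam$em_gain + cam$read_noise^2 / (mu_e * cam$em_gain)
  expect_equal(v_over_m, theory, tolerance = 0.2)
})

test_that("overflowing counts saturate at 16 bits with a warning", {
  cam <- tiny_camera(8, em_gain = 1000, read_noise = 0)
  sched <- build_schedule(scan_preset(radius = 0.97), 0.005, 1)
  expect_warning(
    stk <- render_stack(specimen(film_brightness = 500), sched,
                        camera = cam, speckle = flat_speckle,
                        n_azimuths = 1),
    class = "spintirf_saturation_warning")
  expect_equal(max(stk$frames[[1]]), 65535L)
})

test_that("scenarios are deterministic and correctly structured", {
  expect_error(make_scenario("no_such_scenario"))
  a <- make_scenario("puff_depths", seed = 9)
  b <- make_scenario("puff_depths", seed = 9)
  expect_identical(a$specimen, b$specimen)
  ps <- a$specimen$puff_sites
  expect_true(all(lengths(ps$event_times) >= 4))
  expect_true(all(ps$z >= 0 & ps$z <= 600))
  tri <- make_scenario("triple_interleave", seed = 1,
                       overrides = list(n_frames = 7))
  expect_equal(tri$schedule$frames$label,
               rep(c("tirf488", "tirf532", "skim"), 3)[1:7])
  sh <- make_scenario("shadow_cells", seed = 1)
  expect_setequal(unique(sh$schedule$frames$mode_tag),
                  c("stationary_tirf", "spinning_tirf"))
})
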