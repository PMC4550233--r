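#' Load a run configuration
#'
#' Runs are described by a flat YAML document with up to seven blocks —
#' `optical`, `camera`, `speckle`, `scenario`, `processing`, `analysis` —
#' plus top-level `seed` and `out_dir`. Every field is optional; omitted
#' fields take the package defaults (the defaults of [optical_config()],
#' [camera_model()], [speckle_model()] and so on). Unknown blocks or fields
#' are rejected, with the offending field path in the error message.
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with elements `optical`
#'   (`optical_config`), `camera` (`camera_model`), `speckle`
#'   (`speckle_model`), `scenario` (list: `name`, `overrides`),
#'   `processing` (list: `black_level`, `baseline_range`, `f0_floor`,
#'   `deinterleave`), `analysis` (list: `lo`, `hi`, `min_events`, `k`,
#'   `noise_floor`), `seed`, `out_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("config file not found: %s", path),
                 class = "spintirf_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  run_config(raw)
}

#' @rdname load_config
#' @param x A named list (parsed YAML) to validate and fill with defaults.
#' @export
run_config <- function(x = list()) {
  known <- c("optical", "camera", "speckle", "scenario", "processing",
             "analysis", "seed", "out_dir")
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    rlang::abort(sprintf("unknown config field(s): %s",
                         paste(bad, collapse = ", ")),
                 class = "spintirf_config_error")
  }
  take <- function(block, builder) {
    vals <- x[[block]]
    if (is.null(vals)) vals <- list()
    extra <- setdiff(names(vals), names(formals(builder)))
    if (length(extra)) {
      rlang::abort(sprintf("unknown config field(s): %s",
                           paste0(block, ".", extra, collapse = ", ")),
                   class = "spintirf_config_error")
    }
    do.call(builder, vals)
  }
  proc_defaults <- list(black_level = NULL, baseline_range = NULL,
                        f0_floor = 1, deinterleave = 2L)
  ana_defaults <- list(lo = 0.9, hi = 1.1, min_events = 4L, k = 1,
                       noise_floor = 0.05)
  fill <- function(block, defaults) {
    vals <- x[[block]]
    if (is.null(vals)) vals <- list()
    extra <- setdiff(names(vals), names(defaults))
    if (length(extra)) {
      rlang::abort(sprintf("unknown config field(s): %s",
                           paste0(block, ".", extra, collapse = ", ")),
                   class = "spintirf_config_error")
    }
    utils::modifyList(defaults, vals)
  }
  scen <- x$scenario
  if (is.null(scen)) scen <- list()
  extra <- setdiff(names(scen), c("name", "overrides"))
  if (length(extra)) {
    rlang::abort(sprintf("unknown config field(s): %s",
                         paste0("scenario.", extra, collapse = ", ")),
                 class = "spintirf_config_error")
  }
  structure(
    list(optical = take("optical", optical_config),
         camera = take("camera", camera_model),
         speckle = take("speckle", speckle_model),
         scenario = list(name = scen$name %||% "film_beads",
                         overrides = scen$overrides %||% list()),
         processing = fill("processing", proc_defaults),
         analysis = fill("analysis", ana_defaults),
         seed = as.integer(x$seed %||% 1L),
         out_dir = x$out_dir %||% "."),
    class = "run_config")
}

#' Write a resolved run configuration
#'
#' Serializes the fully resolved configuration (defaults filled in) back to
#' YAML, so every output directory carries the exact settings that produced
#' it. `load_config(write_config(cfg, path))` round-trips.
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(
    optical = unclass(config$optical),
    camera = unclass(config$camera),
    speckle = unclass(config$speckle)[c("n_components", "contrast",
                                        "fringe_period", "seed")],
    scenario = config$scenario,
    processing = config$processing,
    analysis = config$analysis,
    seed = config$seed,
    out_dir = config$out_dir
  )
  out$optical$beam_waist <- if (is.finite(out$optical$beam_waist)) {
    out$optical$beam_waist
  } else ".inf"
  out$processing <- out$processing[!vapply(out$processing, is.null,
                                           logical(1))]
  if (length(out$scenario$overrides) == 0) out$scenario$overrides <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-run a headline benchmark end to end
#'
#' Recomputes one of the package's headline quantities from scratch and
#' compares it with its expected value:
#' \describe{
#'   \item{t1}{the scan frequency at which exactly one spot revolution fits
#'     a 5 ms camera exposure (expected 200 Hz), via the schedule logic.}
#'   \item{t2}{the evanescent penetration depth at the maximal incidence
#'     angle of an NA 1.45 objective at 488 nm (expected below the 100 nm
#'     sheet-thickness scale).}
#'   \item{t3}{the maximum percent deviation of the frame-mean intensity of
#'     a central 100x100 px region across 600 simulated 5 ms spinning-spot
#'     frames of a uniform film (expected within 1 percent).}
#'   \item{t4}{the number of 5 ms frames spanning a 3 s stability
#'     recording (expected 600).}
#' }
#'
#' @param target_id One of `"t1"`, `"t2"`, `"t3"`, `"t4"`.
#' @param seed Seed for the stochastic benchmark (`t3`).
#' @param quiet Suppress the printed report.
#' @return A one-row tibble: `target`, `value`, `expected`, `cmp`, `pass`.
#' @export
reproduce <- function(target_id, seed = 1L, quiet = FALSE) {
  res <- switch(
    target_id,
    t1 = {
      sched <- build_schedule(scan_preset(frequency = 200, radius = 0.97),
                              exposure_time = 0.005, n_frames = 1)
      tibble::tibble(target = "t1",
                     value = sched$presets$adjusted_frequency[1],
                     expected = 200, cmp = "eq")
    },
    t2 = {
      cfg <- optical_config()
      theta <- bfp_radius_to_angle(
        cfg$objective_focal_length * cfg$numerical_aperture, cfg)
      tibble::tibble(target = "t2",
                     value = penetration_depth(cfg$wavelength, theta, cfg),
                     expected = 100, cmp = "le")
    },
    t3 = {
      sc <- make_scenario("film_beads", seed = seed,
                          overrides = list(beads = FALSE, n_frames = 600))
      stk <- render_stack(sc$specimen, sc$schedule, sc$cfg, sc$camera,
                          seed = seed, speckle = sc$speckle)
      st <- stability_trace(subtract_black(stk), region_size = 100)
      tibble::tibble(target = "t3", value = st$max_deviation_pct,
                     expected = 1, cmp = "le")
    },
    t4 = {
      sched <- build_schedule(scan_preset(frequency = 200, radius = 0.97),
                              exposure_time = 0.005,
                              n_frames = round(3 / 0.005))
      trig <- frame_triggers(sched)
      tibble::tibble(target = "t4",
                     value = sum(trig$start_time < 3),
                     expected = 600, cmp = "eq")
    },
    rlang::abort(sprintf("unknown target '%s'", target_id),
                 class = "spintirf_target_error")
  )
  res$pass <- if (res$cmp == "le") res$value <= res$expected else
    isTRUE(all.equal(res$value, res$expected, tolerance = 1e-9))
  if (!quiet) {
    cat(sprintf("%s: computed %.4g, expected %s %.4g -> %s\n",
                res$target, res$value,
                if (res$cmp == "le") "<=" else "==",
                res$expected, if (res$pass) "PASS" else "FAIL"))
  }
  invisible(res)
}
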