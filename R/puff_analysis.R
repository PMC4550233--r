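#' Peak amplitude of an event within a trace window
#'
#' Amplitude is the maximum trace value inside the event window minus a
#' baseline offset, taken by default as the median of the trace outside all
#' supplied event windows (robust to the events themselves).
#'
#' @param trace A trace tibble from [roi_trace()] (columns `time`,
#'   `value`).
#' @param window Event time window `c(t0, t1)`, seconds.
#' @param all_windows Optional list of every event window in the trace,
#'   excluded from the baseline; defaults to `list(window)`.
#' @return Amplitude in the trace's units (counts or delta-F/F0).
#' @export
measure_amplitude <- function(trace, window, all_windows = list(window)) {
  stopifnot(length(window) == 2, window[2] > window[1])
  inside <- trace$time >= window[1] & trace$time <= window[2]
  if (!any(inside)) {
    rlang::abort("event window contains no trace samples",
                 class = "spintirf_window_error")
  }
  outside <- rep(TRUE, nrow(trace))
  for (w in all_windows) {
    outside <- outside & !(trace$time >= w[1] & trace$time <= w[2])
  }
  baseline <- if (any(outside)) stats::median(trace$value[outside]) else 0
  max(trace$value[inside]) - baseline
}

#' Per-event TIRF/widefield amplitude ratios
#'
#' For each event window, measures the delta-F/F0 amplitude on the TIRF
#' trace and on the widefield trace (from linked ROIs over the same site on
#' the two de-interleaved stacks) and forms the ratio
#' `amplitude_tirf / amplitude_wf`. A ratio above 1 means the event gave a
#' larger signal in TIRF than in widefield — a superficial event; deep
#' events are attenuated in the evanescent field and give ratios below 1.
#' Events whose widefield amplitude falls below `noise_floor` are excluded
#' (ratio undefined) and flagged.
#'
#' @param tirf_trace,wf_trace Trace tibbles (delta-F/F0) from linked ROIs.
#' @param events A data frame with columns `t0`, `t1` (window, s) and
#'   optionally `site_id` (default 1).
#' @param noise_floor Minimum widefield amplitude for a ratio to be formed.
#' @return A tibble of events: `site_id`, `event`, `t0`, `t1`,
#'   `amplitude_tirf`, `amplitude_wf`, `ratio`, `included`.
#' @export
event_ratios <- function(tirf_trace, wf_trace, events, noise_floor = 0.05) {
  events <- tibble::as_tibble(events)
  if (!"site_id" %in% names(events)) events$site_id <- 1L
  if (abs(nrow(tirf_trace) - nrow(wf_trace)) > 1) {
    rlang::abort("TIRF and WF traces differ by more than one frame",
                 class = "spintirf_trace_mismatch_error")
  }
  wins <- purrr::map2(events$t0, events$t1, c)
  out <- purrr::pmap_dfr(
    list(events$site_id, seq_len(nrow(events)), events$t0, events$t1),
    function(sid, i, t0, t1) {
      at <- measure_amplitude(tirf_trace, c(t0, t1), wins)
      aw <- measure_amplitude(wf_trace, c(t0, t1), wins)
      ok <- aw > noise_floor
      tibble::tibble(site_id = sid, event = i, t0 = t0, t1 = t1,
                     amplitude_tirf = at, amplitude_wf = aw,
                     ratio = if (ok) at / aw else NA_real_,
                     included = ok)
    })
  n_excl <- sum(!out$included)
  if (n_excl > 0) {
    rlang::inform(sprintf(
      "%d event(s) excluded: widefield amplitude below the noise floor (%.3g)",
      n_excl, noise_floor))
  }
  out
}

#' Per-site summary and depth classification
#'
#' Aggregates event ratios by site and classifies each site with at least
#' `min_events` events by its mean TIRF/WF ratio: `superficial` above `hi`,
#' `deep` below `lo`, `intermediate` otherwise. Sites with fewer events are
#' dropped, mirroring the >= 4 puffs-per-site inclusion rule.
#'
#' @param events An event tibble from [event_ratios()].
#' @param min_events Minimum events per site for classification.
#' @param lo,hi Classification thresholds on the site mean ratio.
#' @return A tibble with `site_id`, `n_events`, `mean_ratio`, `sd_ratio`,
#'   `class`.
#' @export
summarize_sites <- function(events, min_events = 4L, lo = 0.9, hi = 1.1) {
  events |>
    dplyr::filter(.data$included) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(n_events = dplyr::n(),
                     mean_ratio = mean(.data$ratio),
                     sd_ratio = stats::sd(.data$ratio),
                     .groups = "drop") |>
    dplyr::filter(.data$n_events >= min_events) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$mean_ratio > hi ~ "superficial",
      .data$mean_ratio < lo ~ "deep",
      TRUE ~ "intermediate"))
}

#' Histogram of TIRF/WF amplitude ratios
#'
#' Bins event ratios and reports the fraction of events with ratio above 1
#' (events brighter in TIRF than widefield).
#'
#' @param events An event tibble from [event_ratios()] (or any data frame
#'   with a `ratio` column).
#' @param bin_edges Breaks for the histogram.
#' @return A list with `counts` (tibble: `bin_lo`, `bin_hi`, `count`),
#'   `n_events`, and `fraction_gt_1`.
#' @export
ratio_histogram <- function(events, bin_edges = seq(0, 3, by = 0.2)) {
  r <- events$ratio[!is.na(events$ratio)]
  if (length(r) < 1) {
    rlang::abort("no events with defined ratios",
                 class = "spintirf_histogram_error")
  }
  edges <- bin_edges
  if (min(r) < edges[1]) edges <- c(min(r), edges)
  if (max(r) > edges[length(edges)]) edges <- c(edges, max(r))
  h <- hist(r, breaks = edges, plot = FALSE)
  list(counts = tibble::tibble(bin_lo = utils::head(h$breaks, -1),
                               bin_hi = h$breaks[-1],
                               count = h$counts),
       n_events = length(r),
       fraction_gt_1 = mean(r > 1))
}

#' Estimate event depth from a TIRF/WF amplitude ratio
#'
#' Inverts the forward model `ratio(z) = k * exp(-z / d)`, where `d` is the
#' evanescent penetration depth of the TIRF preset and `k` the calibration
#' ratio for an event at the interface (z = 0): `z = d * log(k / ratio)`,
#' clipped at zero. Ratios above `k` (superficial events plus noise) clip
#' to z = 0 with a warning. The widefield amplitude is treated as
#' depth-independent over the cell thickness — the model's main
#' simplification.
#'
#' @param ratio TIRF/WF amplitude ratio(s), > 0.
#' @param d Evanescent penetration depth, nm (e.g. from
#'   [penetration_depth()]).
#' @param k Calibration ratio at z = 0 (default 1: identical delta-F/F0
#'   normalization in both modes).
#' @return Estimated depth(s), nm.
#' @export
estimate_depth <- function(ratio, d, k = 1) {
  stopifnot(all(ratio > 0, na.rm = TRUE), all(d > 0), all(k > 0))
  if (any(ratio > k, na.rm = TRUE)) {
    rlang::warn("ratio(s) above the z = 0 calibration were clipped to depth 0",
                class = "spintirf_depth_clip_warning")
  }
  pmax(0, d * log(k / ratio))
}

#' Calibration ratio k from resting baselines
#'
#' The forward model for event ratios is `ratio(z) = k * exp(-z / d)` with
#' `k = F0_WF / F0_TIRF` at the site: cytosolic indicator inflates the
#' widefield resting fluorescence relative to TIRF, so an event at the
#' interface (z = 0) shows a delta-F/F0 ratio of exactly that baseline
#' ratio. `k` is therefore measurable directly from the two resting maps.
#'
#' @param tirf_ratio,wf_ratio `ratio_stack`s of the de-interleaved TIRF and
#'   widefield recordings (their `f0` maps are used).
#' @param roi A [roi_rect()] over the site.
#' @return The scalar calibration ratio.
#' @export
estimate_calibration <- function(tirf_ratio, wf_ratio, roi) {
  rows <- seq(roi$y0 + 1L, roi$y1)
  cols <- seq(roi$x0 + 1L, roi$x1)
  mean(wf_ratio$f0[rows, cols]) / mean(tirf_ratio$f0[rows, cols])
}

#' Simple threshold-crossing event detector
#'
#' Convenience helper (not part of the canonical analysis, where event
#' windows come from ground truth or the user): marks events where the
#' trace exceeds `threshold` for at least `min_frames` consecutive frames,
#' and pads each window by `pad` seconds.
#'
#' @param trace A trace tibble.
#' @param threshold Detection level in trace units.
#' @param min_frames Minimum consecutive supra-threshold frames.
#' @param pad Window padding, s.
#' @return A tibble with columns `t0`, `t1`.
#' @export
detect_events <- function(trace, threshold, min_frames = 2L, pad = 0.02) {
  above <- trace$value > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_frames
  tibble::tibble(t0 = trace$time[starts[keep]] - pad,
                 t1 = trace$time[ends[keep]] + pad)
}

#' End-to-end puff analysis of an interleaved TIRF/WF ratio recording
#'
#' Convenience wrapper tying the pipeline together for one or more sites:
#' extracts linked-ROI traces from the TIRF and widefield ratio stacks,
#' measures per-event amplitudes in both modes, forms TIRF/WF ratios,
#' summarizes and classifies sites, and estimates depths from site mean
#' ratios.
#'
#' @param tirf_ratio,wf_ratio `ratio_stack`s from the de-interleaved TIRF
#'   and widefield substacks.
#' @param rois Named list of [roi_rect()]s, one per site; names (or list
#'   index) become `site_id`s.
#' @param events Data frame with `site_id` matching the ROI names/indices
#'   and `t0`, `t1` windows (s).
#' @param d Evanescent penetration depth of the TIRF preset, nm.
#' @param k Calibration ratio at z = 0, or `NULL` (the default) to estimate
#'   it per site from the resting baselines via [estimate_calibration()].
#' @param min_events,lo,hi Site summary parameters (see
#'   [summarize_sites()]).
#' @param noise_floor Widefield amplitude floor for ratio inclusion.
#' @return An object of class `puff_analysis`: list with `events` (per
#'   event), `sites` (per site, with calibration `k` and `depth_nm`
#'   estimates), `histogram`, and the analysis parameters.
#' @export
analyze_puffs <- function(tirf_ratio, wf_ratio, rois, events, d,
                          k = NULL, min_events = 4L, lo = 0.9, hi = 1.1,
                          noise_floor = 0.05) {
  events <- tibble::as_tibble(events)
  if (is.null(names(rois))) names(rois) <- seq_along(rois)
  parts <- purrr::imap(rois, function(roi, sid) {
    site_events <- dplyr::filter(events, .data$site_id == sid |
                                   as.character(.data$site_id) == sid)
    if (nrow(site_events) == 0) return(NULL)
    tt <- roi_trace(tirf_ratio, roi)
    tw <- roi_trace(wf_ratio, roi)
    ev <- event_ratios(tt, tw, site_events, noise_floor = noise_floor)
    k_site <- if (is.null(k)) {
      estimate_calibration(tirf_ratio, wf_ratio, roi)
    } else k
    list(events = ev,
         cal = tibble::tibble(site_id = ev$site_id[1], k = k_site))
  })
  parts <- purrr::compact(parts)
  ev_all <- purrr::map_dfr(parts, "events")
  cal <- purrr::map_dfr(parts, "cal")
  sites <- summarize_sites(ev_all, min_events = min_events, lo = lo, hi = hi)
  sites <- dplyr::left_join(sites, cal, by = "site_id")
  sites$depth_nm <- suppressWarnings(
    estimate_depth(pmin(sites$mean_ratio, sites$k), d, sites$k))
  structure(
    list(events = ev_all, sites = sites,
         histogram = ratio_histogram(ev_all),
         params = list(d = d, k = k, min_events = min_events,
                       lo = lo, hi = hi, noise_floor = noise_floor)),
    class = "puff_analysis")
}

#' @export
print.puff_analysis <- function(x, ...) {
  cat(sprintf(
    "<puff_analysis> %d event(s) at %d site(s); fraction of ratios > 1: %.2f\n",
    sum(x$events$included), nrow(x$sites), x$histogram$fraction_gt_1))
  if (nrow(x$sites)) print(x$sites)
  invisible(x)
}
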