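#' Subtract the camera black level
#'
#' Removes the constant camera offset from every frame, flooring at zero.
#' The applied level is recorded in the stack metadata.
#'
#' @param stack An `image_stack`.
#' @param level Offset to subtract, counts (>= 0). Defaults to the stack's
#'   camera black level.
#' @return An `image_stack` with offset-corrected frames.
#' @export
subtract_black <- function(stack, level = stack$camera$black_level) {
  stopifnot(inherits(stack, "image_stack"), level >= 0)
  stack$frames <- lapply(stack$frames, function(fr) {
    fr <- fr - as.integer(round(level))
    fr[fr < 0L] <- 0L
    fr
  })
  stack$meta$black_subtracted <- level
  stack
}

#' De-interleave a stack into per-mode substacks
#'
#' Splits an interleaved acquisition (presets cycled ABCABC...) into `k`
#' substacks, substack j taking frames j, j+k, j+2k, ... with mode tags and
#' timestamps carried along. This is the step that turns an alternating
#' TIRF/widefield recording into two near-simultaneous single-mode movies.
#'
#' @param stack An `image_stack`.
#' @param k Interleave factor, 1 (identity), 2 or 3.
#' @return A named list of `k` `image_stack`s (named by the first frame's
#'   label or mode tag).
#' @export
deinterleave <- function(stack, k = 2L) {
  stopifnot(inherits(stack, "image_stack"), k %in% 1:3,
            length(stack$frames) >= k)
  if (k == 1L) return(stats::setNames(list(stack), stack$labels[1]))
  tags <- stack$mode_tags
  labs <- if (!is.null(stack$labels)) stack$labels else tags
  idx0 <- seq_along(tags)
  if (!all(labs == labs[((idx0 - 1L) %% k) + 1L])) {
    rlang::abort(
      sprintf("frame labels are not consistent with a stride-%d interleave", k),
      class = "spintirf_tag_mismatch_error")
  }
  out <- lapply(seq_len(k), function(j) {
    sel <- seq(j, length(stack$frames), by = k)
    new_image_stack(stack$frames[sel], tags[sel], labs[sel],
                    stack$timestamps[sel], stack$exposure_time,
                    stack$camera,
                    c(stack$meta, list(deinterleave = list(k = k, phase = j))))
  })
  stats::setNames(out, labs[seq_len(k)])
}

#' Re-interleave de-interleaved substacks
#'
#' Inverse of [deinterleave()]: merges substacks back into a single stack
#' ordered by timestamp.
#'
#' @param stacks List of `image_stack`s with disjoint timestamps.
#' @return A single `image_stack`.
#' @export
interleave_stacks <- function(stacks) {
  frames <- unname(do.call(c, lapply(stacks, `[[`, "frames")))
  tags <- unname(do.call(c, lapply(stacks, `[[`, "mode_tags")))
  labs <- unname(do.call(c, lapply(stacks, `[[`, "labels")))
  ts <- unname(do.call(c, lapply(stacks, `[[`, "timestamps")))
  o <- order(ts)
  meta <- stacks[[1]]$meta
  meta$deinterleave <- NULL
  new_image_stack(frames[o], tags[o], labs[o], ts[o],
                  stacks[[1]]$exposure_time, stacks[[1]]$camera, meta)
}

#' Pseudo-ratio (delta-F/F0) normalization
#'
#' Converts a fluorescence stack into a stack of pixelwise
#' \eqn{\Delta F / F_0 = (F - F_0)/F_0}, where \eqn{F_0} is the per-pixel
#' mean over a range of resting frames acquired before stimulation. This
#' normalizes away static spatial variations in excitation and dye loading.
#' Pixels whose baseline falls below `f0_floor` counts are masked (`NA`)
#' rather than producing unbounded ratios.
#'
#' @param stack An `image_stack` (black-subtracted counts).
#' @param baseline_range Integer frame interval `c(first, last)` (1-based,
#'   inclusive) used for F0.
#' @param f0_floor Minimum baseline, counts, for a pixel's ratio to be
#'   defined.
#' @return A `ratio_stack`: list with `frames` (numeric matrices of
#'   delta-F/F0, `NA` where masked), `f0` (baseline map), `baseline_range`,
#'   `mask`, `timestamps`, `mode_tags`, `exposure_time`.
#' @export
df_f0 <- function(stack, baseline_range, f0_floor = 1) {
  stopifnot(inherits(stack, "image_stack"), length(baseline_range) == 2,
            baseline_range[1] >= 1,
            baseline_range[2] <= length(stack$frames),
            baseline_range[1] <= baseline_range[2])
  bsl <- stack$frames[seq(baseline_range[1], baseline_range[2])]
  f0 <- Reduce(`+`, bsl) / length(bsl)
  if (all(f0 <= 0)) {
    rlang::abort("all-zero baseline: F0 is zero everywhere",
                 class = "spintirf_empty_baseline_error")
  }
  mask <- f0 >= f0_floor
  f0m <- f0
  f0m[!mask] <- NA_real_
  frames <- lapply(stack$frames, function(fr) (fr - f0m) / f0m)
  structure(
    list(frames = frames, f0 = f0, baseline_range = baseline_range,
         mask = mask, timestamps = stack$timestamps,
         mode_tags = stack$mode_tags, labels = stack$labels,
         exposure_time = stack$exposure_time,
         meta = c(stack$meta, list(f0_floor = f0_floor))),
    class = "ratio_stack")
}

#' @export
print.ratio_stack <- function(x, ...) {
  cat(sprintf("<ratio_stack> %d frame(s), baseline frames %d-%d, %d masked px\n",
              length(x$frames), x$baseline_range[1], x$baseline_range[2],
              sum(!x$mask)))
  invisible(x)
}

#' Maximum-intensity projection
#'
#' Per-pixel maximum over a frame range; the standard way to reveal every
#' puff site active anywhere within a recording.
#'
#' @param stack An `image_stack` or `ratio_stack`.
#' @param frame_range `c(first, last)` (1-based, inclusive); default all
#'   frames.
#' @return A matrix.
#' @export
max_projection <- function(stack, frame_range = c(1L, length(stack$frames))) {
  sel <- seq(frame_range[1], frame_range[2])
  stopifnot(length(sel) >= 1, frame_range[2] <= length(stack$frames))
  Reduce(pmax, stack$frames[sel])
}

#' Rectangular region of interest
#'
#' ROIs use 0-based, half-open pixel intervals: `x0 <= col < x1`,
#' `y0 <= row < y1`. Linked ROIs (same `group`) placed on de-interleaved
#' substacks share identical pixel coordinates, mirroring paired-ROI
#' measurement of the same site in two modes.
#'
#' @param x0,y0,x1,y1 Pixel bounds (0-based, half-open).
#' @param label ROI name.
#' @param group Linked-group identifier.
#' @return A list of class `roi`.
#' @export
roi_rect <- function(x0, y0, x1, y1, label = "roi", group = label) {
  stopifnot(x1 > x0, y1 > y0, x0 >= 0, y0 >= 0)
  structure(list(label = label, x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1), group = group),
            class = "roi")
}

#' Square ROI centred on a pixel
#'
#' Convenience for the "3x3 pixel (~1 x 1 um)" measurement regions centred
#' on a puff site.
#'
#' @param cx,cy Centre pixel (0-based column, row).
#' @param size Side length, pixels (odd).
#' @inheritParams roi_rect
#' @return A [roi_rect()].
#' @export
roi_center <- function(cx, cy, size = 3, label = "roi", group = label) {
  h <- (size - 1) %/% 2
  roi_rect(cx - h, cy - h, cx + h + 1, cy + h + 1, label, group)
}

#' Mean-intensity trace within an ROI
#'
#' The average pixel value inside the ROI at every frame, with the frame
#' timestamps. On a `ratio_stack` masked pixels are excluded from the mean.
#'
#' @param stack An `image_stack` or `ratio_stack`.
#' @param roi A [roi_rect()].
#' @return A tibble with columns `frame`, `time` (s), `value`, `roi`,
#'   `mode_tag`.
#' @export
roi_trace <- function(stack, roi) {
  dims <- dim(stack$frames[[1]])
  if (roi$x1 > dims[2] || roi$y1 > dims[1]) {
    rlang::abort("ROI extends beyond the frame bounds",
                 class = "spintirf_roi_error")
  }
  rows <- seq(roi$y0 + 1L, roi$y1)
  cols <- seq(roi$x0 + 1L, roi$x1)
  vals <- vapply(stack$frames,
                 function(fr) mean(fr[rows, cols], na.rm = TRUE),
                 numeric(1))
  tibble::tibble(
    frame = seq_along(vals),
    time = stack$timestamps,
    value = vals,
    roi = roi$label,
    mode_tag = stack$mode_tags
  )
}

#' Intensity profile along a horizontal line
#'
#' Pixel values along one image row, as used to compare field uniformity of
#' stationary- versus spinning-spot excitation along a line through the
#' image centre.
#'
#' @param image A matrix.
#' @param row 1-based row index; default the centre row.
#' @return A tibble with columns `col` and `value`.
#' @export
linescan <- function(image, row = ceiling(nrow(image) / 2)) {
  stopifnot(row >= 1, row <= nrow(image))
  tibble::tibble(col = seq_len(ncol(image)), value = image[row, ])
}

#' Field-uniformity metrics
#'
#' Two complementary measures of lateral illumination uniformity:
#' the coefficient of variation over all pixels (`cv`, percent), and the
#' maximum symmetric percent difference between mean intensities of
#' adjacent square tiles (`adjacent_variation`, percent;
#' `100 * |m_i - m_j| / (m_i + m_j)` maximized over 4-neighbour tile
#' pairs). A checkerboard of tile means 70 and 130 scores an adjacent
#' variation of 30 percent — the scale on which stationary-spot TIRF fields
#' show variations of tens of percent between adjacent regions.
#'
#' @param image A matrix (any residual rows/cols beyond a whole number of
#'   tiles are discarded).
#' @param tile Tile side, pixels.
#' @return A one-row tibble with columns `cv` and `adjacent_variation`
#'   (both percent).
#' @export
uniformity_metrics <- function(image, tile = 8L) {
  m <- mean(image)
  if (m == 0) {
    rlang::abort("zero-mean image", class = "spintirf_metrics_error")
  }
  cv <- 100 * stats::sd(image) / m
  nty <- nrow(image) %/% tile
  ntx <- ncol(image) %/% tile
  stopifnot(nty >= 1, ntx >= 1)
  tm <- matrix(0, nty, ntx)
  for (i in seq_len(nty)) {
    for (j in seq_len(ntx)) {
      tm[i, j] <- mean(image[((i - 1) * tile + 1):(i * tile),
                             ((j - 1) * tile + 1):(j * tile)])
    }
  }
  adj <- 0
  if (ntx > 1) {
    a <- tm[, -1]; b <- tm[, -ntx]
    adj <- max(adj, 100 * abs(a - b) / (a + b))
  }
  if (nty > 1) {
    a <- tm[-1, ]; b <- tm[-nty, ]
    adj <- max(adj, 100 * abs(a - b) / (a + b))
  }
  tibble::tibble(cv = cv, adjacent_variation = adj)
}

#' Per-frame mean-intensity stability
#'
#' The frame-by-frame mean over a centred square region, plus the maximum
#' percent deviation from the grand mean — the temporal-stability figure of
#' merit for the excitation (measured over a wide region to average out
#' shot noise).
#'
#' @param stack An `image_stack` (typically black-subtracted).
#' @param region_size Side of the centred square region, pixels.
#' @return A list with `trace` (tibble: `frame`, `time`, `value`) and
#'   `max_deviation_pct` (100 * max|mean - grand mean| / grand mean).
#' @export
stability_trace <- function(stack, region_size = 100L) {
  dims <- dim(stack$frames[[1]])
  stopifnot(region_size <= min(dims))
  r0 <- (dims[1] - region_size) %/% 2
  c0 <- (dims[2] - region_size) %/% 2
  roi <- roi_rect(c0, r0, c0 + region_size, r0 + region_size,
                  label = "center")
  tr <- roi_trace(stack, roi)
  gm <- mean(tr$value)
  list(trace = tr[, c("frame", "time", "value")],
       max_deviation_pct = 100 * max(abs(tr$value - gm)) / gm)
}
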