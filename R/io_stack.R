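#' Write / read an image stack as multi-page TIFF plus sidecar
#'
#' Stacks are stored as 16-bit grayscale multi-page TIFF (one page per
#' frame) together with a JSON sidecar (`<path>.json`) holding the per-frame
#' mode tags and labels, timestamps, exposure, camera parameters and
#' provenance metadata, so that `read_stack(write_stack(x))` is lossless.
#'
#' A plain TIFF without a sidecar can still be loaded: the stack gets
#' unknown tags and a warning, and an interleave factor `k` supplied by the
#' caller assigns cyclic placeholder labels so the stack can be
#' de-interleaved.
#'
#' @param stack An `image_stack`.
#' @param path TIFF file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   `image_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(stack$frames, function(fr) fr / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(
    mode_tags = stack$mode_tags,
    labels = stack$labels,
    timestamps = stack$timestamps,
    exposure_time = stack$exposure_time,
    camera = unclass(stack$camera),
    meta = stack$meta
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_stack
#' @param k Interleave factor used to label frames when no sidecar is
#'   present.
#' @param exposure_time Exposure, s, used when no sidecar is present.
#' @export
read_stack <- function(path, k = NULL, exposure_time = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
  })
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    sc <- jsonlite::read_json(sp, simplifyVector = TRUE)
    cam <- do.call(camera_model, sc$camera[names(sc$camera) %in%
                                             names(formals(camera_model))])
    return(new_image_stack(frames, sc$mode_tags, sc$labels, sc$timestamps,
                           sc$exposure_time, cam, as.list(sc$meta)))
  }
  rlang::warn("no sidecar found: mode tags unknown",
              class = "spintirf_missing_sidecar_warning")
  n <- length(frames)
  if (is.null(exposure_time)) exposure_time <- NA_real_
  labs <- if (is.null(k)) rep("unknown", n) else {
    paste0("preset_", ((seq_len(n) - 1L) %% k) + 1L)
  }
  new_image_stack(frames, labs, labs,
                  (seq_len(n) - 1) * ifelse(is.na(exposure_time), 1,
                                            exposure_time),
                  exposure_time,
                  camera_model(frame_shape = dim(frames[[1]])),
                  list(sidecar = FALSE))
}

#' Export an excitation field as a single-page TIFF
#'
#' @param field An `excitation_field`.
#' @param path Output TIFF path; the map is scaled to its maximum.
#' @export
write_field <- function(field, path) {
  tiff::writeTIFF(field$lateral / max(field$lateral), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Export ROI traces as a tab-separated ASCII table
#'
#' One row per frame with the frame time and one column per ROI, matching
#' the spreadsheet-ready export of paired-ROI measurements.
#'
#' @param traces A trace tibble (rows from one or more [roi_trace()]
#'   calls combined with [dplyr::bind_rows()]).
#' @param path Output file.
#' @return The wide tibble written, invisibly.
#' @export
export_traces <- function(traces, path) {
  wide <- traces |>
    dplyr::select("time", "roi", "value") |>
    tidyr::pivot_wider(names_from = "roi", values_from = "value")
  utils::write.table(wide, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(wide)
}

#' Read / write ROI definition files
#'
#' A plain tab-separated table with columns `label`, `x0`, `y0`, `x1`,
#' `y1`, `group` (0-based, half-open pixel intervals).
#'
#' @param path File path.
#' @return `read_rois` returns a named list of [roi_rect()]s.
#' @export
read_rois <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x0", "y0", "x1", "y1") %in% names(df)))
  if (!"group" %in% names(df)) df$group <- df$label
  rois <- purrr::pmap(df, function(label, x0, y0, x1, y1, group, ...) {
    roi_rect(x0, y0, x1, y1, label = label, group = group)
  })
  stats::setNames(rois, df$label)
}

#' @rdname read_rois
#' @param rois A list of [roi_rect()]s.
#' @export
write_rois <- function(rois, path) {
  df <- purrr::map_dfr(rois, function(r) {
    tibble::tibble(label = r$label, x0 = r$x0, y0 = r$y0, x1 = r$x1,
                   y1 = r$y1, group = r$group)
  })
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
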