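#' Detection settings for centroid tracking
#'
#' @param threshold `"otsu"` for automatic thresholding of the background
#'   difference image, or a fixed numeric value on the 0-255 scale.
#' @param min_blob_area Minimum connected-component area in pixels.
#' @param opening_radius Radius (px) of the morphological opening applied to
#'   the thresholded difference; `0` disables it.
#' @param max_gap_s Detection gaps up to this duration are linearly
#'   interpolated; longer gaps are masked missing.
#' @return An object of class `detection_settings`.
#' @export
detection_settings <- function(threshold = "otsu", min_blob_area = 5,
                               opening_radius = 1, max_gap_s = 3) {
  if (!(identical(threshold, "otsu") ||
        (is.numeric(threshold) && length(threshold) == 1L)))
    stop_validation("threshold must be \"otsu\" or a single number")
  check_number(min_blob_area, "min_blob_area", lower = 1)
  check_number(opening_radius, "opening_radius", lower = 0)
  check_number(max_gap_s, "max_gap_s", lower = 0)
  structure(list(threshold = threshold, min_blob_area = min_blob_area,
                 opening_radius = opening_radius, max_gap_s = max_gap_s),
            class = "detection_settings")
}

#' Estimate the static background of a frame stack
#'
#' Pixel-wise temporal median. The chamber is static and the larva small, so
#' any pixel occupied by the larva less than half of the time recovers the
#' empty-chamber intensity.
#'
#' @param frames A `frame_stack` (list of matrices) with at least 3 frames.
#' @return A `background_model`: list with the background matrix and a
#'   method tag.
#' @export
estimate_background <- function(frames) {
  if (length(frames) < 3L)
    stop_validation("background estimation requires at least 3 frames")
  arr <- simplify2array(frames)
  bg <- apply(arr, c(1, 2), stats::median)
  structure(list(background = bg, method = "temporal_median"),
            class = "background_model")
}

# Label 4-connected foreground components and return per-component area,
# summed difference intensity, and intensity-weighted centroid.
component_stats <- function(mask, weights) {
  labels <- EBImage::bwlabel(mask)
  n <- max(labels)
  if (n == 0) return(NULL)
  idx <- which(labels > 0)
  lab <- labels[idx]
  w <- weights[idx]
  rows <- ((idx - 1) %% nrow(mask)) + 1
  cols <- ((idx - 1) %/% nrow(mask)) + 1
  area <- tabulate(lab, n)
  wsum <- vapply(seq_len(n), function(k) sum(w[lab == k]), numeric(1))
  rwc <- vapply(seq_len(n), function(k) {
    s <- lab == k
    c(sum(w[s] * rows[s]), sum(w[s] * cols[s])) / sum(w[s])
  }, numeric(2))
  data.frame(area = area, wsum = wsum, row = rwc[1, ], col = rwc[2, ],
             minrow = vapply(seq_len(n), function(k) min(rows[lab == k]), numeric(1)))
}

#' Detect the larval centroid in a single frame
#'
#' Absolute background difference, thresholded (Otsu by default), cleaned by
#' morphological opening, connected components labelled, and the
#' intensity-weighted centroid of the largest qualifying component returned.
#' Equal-area ties go to the component with larger summed intensity, then to
#' the one nearer the top of the frame.
#'
#' @param frame A matrix in `[0, 255]`.
#' @param background A `background_model` from [estimate_background()].
#' @param settings A [detection_settings()].
#' @return Named numeric `c(row, col)` in pixel coordinates, or `NULL` when
#'   no component of sufficient area exists.
#' @export
detect_centroid <- function(frame, background, settings = detection_settings()) {
  bg <- background$background
  if (!all(dim(frame) == dim(bg)))
    stop_validation("frame and background dimensions differ")
  d <- abs(frame - bg)
  if (max(d) <= 1e-9) return(NULL)  # frame equals background
  thr <- if (identical(settings$threshold, "otsu")) {
    255 * EBImage::otsu(EBImage::Image(d / 255), range = c(0, 1))
  } else {
    settings$threshold
  }
  mask <- d > thr
  if (!any(mask)) return(NULL)
  if (settings$opening_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(settings$opening_radius) + 1L,
                                shape = "disc")
    mask <- EBImage::opening(EBImage::Image(mask * 1), brush) > 0.5
  }
  if (!any(mask)) return(NULL)
  st <- component_stats(mask, d)
  st <- st[st$area >= settings$min_blob_area, , drop = FALSE]
  if (is.null(st) || nrow(st) == 0) return(NULL)
  st <- st[order(-st$area, -st$wsum, st$minrow), , drop = FALSE]
  c(row = st$row[1], col = st$col[1])
}

#' Track a frame stack into a trajectory
#'
#' Runs [detect_centroid()] on every frame, converts pixel coordinates to mm
#' via the calibrated geometry, linearly interpolates detection gaps up to
#' `max_gap_s`, and masks longer gaps as missing. Interpolated frames are
#' flagged in the `interpolated` attribute of the returned trajectory.
#'
#' @param frames A `frame_stack`; its `layout` attribute (from
#'   [render_frames()]) supplies the pixel calibration. For external stacks
#'   pass `layout` explicitly.
#' @param background A `background_model`; estimated from the stack when
#'   `NULL`.
#' @param settings A [detection_settings()].
#' @param geometry A [chamber_geometry()].
#' @param layout Optional pixel layout (`surface_row`, `centre_col`, `ppm`).
#' @param times Sample times (s); defaults to 1 Hz frame index.
#' @param trial_id Trial identifier.
#' @return A [trajectory()] with attribute `interpolated` (logical per frame).
#' @export
track_stack <- function(frames, background = NULL,
                        settings = detection_settings(),
                        geometry = chamber_geometry(), layout = NULL,
                        times = NULL, trial_id = "tracked") {
  layout <- layout %||% attr(frames, "layout")
  if (is.null(layout) || is.null(layout$ppm) || is.null(layout$surface_row))
    stop_config("uncalibrated geometry: supply a frame layout with px_per_mm and surface row")
  background <- background %||% estimate_background(frames)
  n <- length(frames)
  times <- times %||% (seq_len(n) - 1)
  row <- rep(NA_real_, n); col <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cen <- detect_centroid(frames[[i]], background, settings)
    if (!is.null(cen)) { row[i] <- cen["row"]; col[i] <- cen["col"] }
  }
  pos <- px_to_mm(row, col, layout)
  x <- pos$x; z <- pos$z
  detected <- !is.na(row)
  interpolated <- rep(FALSE, n)
  if (any(detected) && any(!detected)) {
    dt <- if (n > 1) stats::median(diff(times)) else 1
    gaps <- logical_runs(!detected)
    for (k in seq_len(nrow(gaps))) {
      s <- gaps$start[k]; e <- gaps$end[k]
      if (s > 1 && e < n && (times[e + 1] - times[s - 1] - dt) <= settings$max_gap_s) {
        idx <- s:e
        x[idx] <- stats::approx(times[c(s - 1, e + 1)], x[c(s - 1, e + 1)],
                                xout = times[idx])$y
        z[idx] <- stats::approx(times[c(s - 1, e + 1)], z[c(s - 1, e + 1)],
                                xout = times[idx])$y
        interpolated[idx] <- TRUE
      }
    }
  }
  missing <- is.na(z)
  traj <- trajectory(times, x, z, trial_id = trial_id, missing = missing,
                     geometry = geometry)
  attr(traj, "interpolated") <- interpolated
  traj
}
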