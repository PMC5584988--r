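#' Behavioral mode codes
#'
#' Single-character codes used in ethogram files: S (surfacing), G (digging),
#' V (diving), E (escaping), X (excluded).
#' @export
MODE_LEVELS <- c(SURFACING = "S", DIGGING = "G", DIVING = "V",
                 ESCAPING = "E", EXCLUDED = "X")

#' Kernel density estimate of pooled centroid depths
#'
#' Gaussian-kernel KDE on a uniform grid, used to derive the diving
#' threshold. The grid spans the data range extended by three bandwidths;
#' the sample mean depth is recorded alongside.
#'
#' @details The kernel sum is evaluated exactly at every grid point (not by
#'   binned approximation), so closed-form identities hold to floating-point
#'   accuracy and the trapezoidal integral over the grid equals 1 up to the
#'   kernel mass beyond the grid ends (< 1e-8 with the 6-bandwidth span).
#'
#' @param depths Pooled depth samples (mm), typically a whole cohort.
#' @param bandwidth `"auto"` for Silverman's rule, or a bandwidth in mm.
#' @param grid_step Grid spacing in mm (default 0.05).
#' @return A `density_estimate`: list with `z` (grid), `density`, `bandwidth`,
#'   `mean_depth`, `n`.
#' @export
depth_pdf <- function(depths, bandwidth = "auto", grid_step = 0.05) {
  depths <- depths[is.finite(depths)]
  if (length(depths) < 2L)
    stop_validation("depth density requires at least 2 finite samples")
  if (length(depths) < 100L)
    warning("fewer than 100 depth samples; density estimate may be unstable")
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(depths) else {
    check_number(bandwidth, "bandwidth", lower = 0, strict = TRUE)
    bandwidth
  }
  if (bw <= 0) stop_validation("bandwidth must be positive (constant sample?)")
  lo <- min(depths) - 6 * bw
  hi <- max(depths) + 6 * bw
  grid <- seq(lo, hi, by = grid_step)
  if (grid[length(grid)] < hi) grid <- c(grid, grid[length(grid)] + grid_step)
  # exact Gaussian kernel sum, chunked to bound memory
  f <- numeric(length(grid))
  chunk <- 2000L
  for (s in seq(1, length(depths), by = chunk)) {
    xi <- depths[s:min(length(depths), s + chunk - 1L)]
    f <- f + colSums(stats::dnorm(outer(xi, grid, "-"), sd = bw))
  }
  f <- f / length(depths)
  structure(list(z = grid, density = f, bandwidth = bw,
                 mean_depth = mean(depths), n = length(depths)),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("Depth density: n = %d, bandwidth = %.3f mm, grid %.2f..%.2f mm (step %.3g)\n",
              x$n, x$bandwidth, min(x$z), max(x$z), x$z[2] - x$z[1]))
  cat(sprintf("  mean depth = %.2f mm\n", x$mean_depth))
  invisible(x)
}

#' @export
plot.density_estimate <- function(x, ...) {
  graphics::plot(x$z, x$density, type = "l", xlab = "depth z (mm)",
                 ylab = "density (1/mm)", ...)
  graphics::abline(v = x$mean_depth, lty = 2)
  invisible(x)
}

#' Diving threshold from the depth density
#'
#' Scans the density grid downward (decreasing z) from the sample mean and
#' returns the first local minimum — the boundary between the digging bulk
#' of the distribution and the deep diving tail. A plateau is broken toward
#' the shallower (larger z) end.
#'
#' A candidate minimum only qualifies when at least a fraction
#' `min_deep_mass` of the probability mass lies below it: a mode boundary
#' separates the digging bulk from a populated diving tail. Finite-sample
#' kernel estimates of even unimodal data develop tiny local minima between
#' sparse extreme samples, but the mass below such dips is negligible
#' (roughly the mass beyond 3 sd, about 0.1%), whereas diving occupies
#' percent-level time in real assays. If no qualifying minimum exists before
#' the deep end of the grid, a `digdive_no_minimum_error` is raised; callers
#' may then fall back to a configured default, but never silently.
#'
#' @param density A `density_estimate` from [depth_pdf()].
#' @param min_deep_mass Minimum probability mass below a qualifying minimum
#'   (default 0.01).
#' @return The threshold depth `z_diving` in mm (a grid point).
#' @export
dive_threshold <- function(density, min_deep_mass = 0.01) {
  stopifnot(inherits(density, "density_estimate"))
  z <- density$z; f <- density$density
  start <- max(which(z <= density$mean_depth))
  if (!is.finite(start) || start < 2)
    stop(errorCondition("no density grid below the sample mean",
                        class = c("digdive_no_minimum_error", "error")))
  step <- z[2] - z[1]
  # trapezoidal mass below (deeper than) each grid point
  mass_below <- (cumsum(f) - f / 2 - f[1] / 2) * step
  total <- mass_below[length(mass_below)]
  for (i in seq(start, 2)) {
    # local minimum: strict drop from the shallow side, non-strict on the
    # deep side (a flat valley resolves to its shallow edge)
    if (i + 1 <= length(f) && f[i] < f[i + 1] && f[i] <= f[i - 1] &&
        mass_below[i] >= min_deep_mass * total)
      return(z[i])
  }
  stop(errorCondition(
    "no qualifying local minimum of the depth density below the mean",
    class = c("digdive_no_minimum_error", "error")))
}

#' Classify per-frame behavioral modes
#'
#' Applies the depth thresholds frame by frame: `z > air_top` escaping,
#' `0 < z <= air_top` surfacing (with `z_digging = 0`), `z_diving < z <= 0`
#' digging, `z <= z_diving` diving. Missing frames inherit the previous
#' label; a missing lead-in is labelled surfacing (larvae are introduced at
#' the surface).
#'
#' @param traj A [trajectory()].
#' @param thresholds A [behavior_thresholds()].
#' @param geometry A [chamber_geometry()].
#' @return A `mode_track`: list with `trial_id`, `times`, `labels`
#'   (character), `escaped`, `inactive_from` (frame index or `NA`).
#' @export
classify_modes <- function(traj, thresholds, geometry = chamber_geometry()) {
  stopifnot(inherits(traj, "trajectory"), inherits(thresholds, "behavior_thresholds"))
  z <- traj$z
  lab <- ifelse(z > geometry$air_top_z, "ESCAPING",
                ifelse(z > thresholds$z_digging, "SURFACING",
                       ifelse(z > thresholds$z_diving, "DIGGING", "DIVING")))
  lab[traj$missing] <- NA_character_
  if (is.na(lab[1])) lab[1] <- "SURFACING"
  for (i in seq_along(lab)[-1]) if (is.na(lab[i])) lab[i] <- lab[i - 1]
  structure(list(trial_id = traj$trial_id, times = traj$times, labels = lab,
                 escaped = FALSE, inactive_from = NA_integer_),
            class = "mode_track")
}

#' @export
print.mode_track <- function(x, ...) {
  tab <- table(factor(x$labels, levels = names(MODE_LEVELS)))
  cat(sprintf("Mode track '%s': %d frames\n", x$trial_id, length(x$labels)))
  print(tab)
  if (x$escaped) cat("  escaped trial\n")
  if (!is.na(x$inactive_from))
    cat(sprintf("  inactive from frame %d\n", x$inactive_from))
  invisible(x)
}

#' Flag escaped trials
#'
#' A trial counts as escaped once its centroid has stayed out of the arena
#' (ESCAPING) for a contiguous run longer than `min_out_duration`. Frames
#' from the start of the first such run onward are relabelled EXCLUDED so
#' they do not enter time-fraction denominators; the trial keeps its escaped
#' flag.
#'
#' @param modetrack A `mode_track` from [classify_modes()].
#' @param min_out_duration Minimum contiguous out-of-arena duration (s).
#' @return The updated `mode_track`.
#' @export
flag_escape <- function(modetrack, min_out_duration = 30) {
  stopifnot(inherits(modetrack, "mode_track"))
  dt <- if (length(modetrack$times) > 1) stats::median(diff(modetrack$times)) else 1
  runs <- logical_runs(modetrack$labels == "ESCAPING")
  if (nrow(runs)) {
    durs <- (runs$end - runs$start + 1) * dt
    hit <- which(durs > min_out_duration)
    if (length(hit)) {
      first <- runs$start[hit[1]]
      modetrack$escaped <- TRUE
      modetrack$labels[first:length(modetrack$labels)] <- "EXCLUDED"
    }
  }
  modetrack
}

#' Flag terminally inactive (drowned) trials
#'
#' Drowned larvae freeze in place below the surface. A trial is flagged when,
#' while submerged (`z <= 0`), the total centroid displacement within every
#' rolling window of `window_s` seconds stays below `eps_mm` through to the
#' end of the trial. Frames from the onset of terminal immobility are
#' relabelled EXCLUDED and `inactive_from` records the onset frame; such
#' trials are excluded from cohort statistics.
#'
#' @param traj The [trajectory()] the track was classified from.
#' @param modetrack A `mode_track`.
#' @param eps_mm Displacement tolerance within one window (mm).
#' @param window_s Rolling window length (s).
#' @return The updated `mode_track`.
#' @export
flag_inactive <- function(traj, modetrack, eps_mm = 0.2, window_s = 120) {
  stopifnot(inherits(traj, "trajectory"), inherits(modetrack, "mode_track"))
  n <- length(traj$times)
  if (n < 3) return(modetrack)
  dt <- sample_interval(traj)
  w <- max(1L, as.integer(round(window_s / dt)))
  step <- sqrt(diff(traj$x)^2 + diff(traj$z)^2)  # NA across missing frames
  step[is.na(step)] <- Inf                        # gaps never count as still
  # displacement accumulated over the window starting at each frame
  csum <- c(0, cumsum(step))
  wsum <- vapply(seq_len(n), function(i) {
    j <- min(n, i + w - 1L)
    csum[j] - csum[i - 1L + 1L] + 0  # sum of steps i..j-1 (truncated at end)
  }, numeric(1))
  still <- wsum < eps_mm
  submerged <- !is.na(traj$z) & traj$z <= 0
  ok <- still & submerged
  # onset: earliest frame from which stillness persists to trial end
  suffix_ok <- rev(cumprod(rev(ok))) > 0
  if (suffix_ok[n] && any(suffix_ok)) {
    onset <- which(suffix_ok)[1]
    # require at least one full window of terminal stillness
    if ((n - onset + 1) * dt >= window_s) {
      modetrack$inactive_from <- onset
      modetrack$labels[onset:n] <- "EXCLUDED"
    }
  }
  modetrack
}

#' Estimate the diving threshold for a cohort
#'
#' Pools depths across trials (optionally restricted to submerged samples),
#' fits [depth_pdf()] and locates the threshold with [dive_threshold()].
#'
#' @param trajectories List of [trajectory()] objects.
#' @param bandwidth,grid_step Passed to [depth_pdf()].
#' @param submerged_only Pool only samples with `z <= air_top` (default pools
#'   all samples including the air chamber).
#' @param geometry A [chamber_geometry()].
#' @return A [behavior_thresholds()] with attribute `density`.
#' @export
cohort_thresholds <- function(trajectories, bandwidth = "auto",
                              grid_step = 0.05, submerged_only = FALSE,
                              geometry = chamber_geometry()) {
  depths <- unlist(lapply(trajectories, function(tr) tr$z[!tr$missing]))
  if (submerged_only) depths <- depths[depths <= geometry$air_top_z]
  dens <- depth_pdf(depths, bandwidth = bandwidth, grid_step = grid_step)
  thr <- behavior_thresholds(z_diving = dive_threshold(dens))
  attr(thr, "density") <- dens
  thr
}
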