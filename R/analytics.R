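#' Extract dive events from a classified trial
#'
#' A dive event is a maximal contiguous run of DIVING frames. Duration is
#' computed from timestamps: the event ends at the first non-diving sample
#' (or, for a trial-final dive, one sampling interval after the last frame).
#' Maximum depth is the most negative `z` within the run. Mean speed averages
#' the per-frame centroid path increment `sqrt(dx^2 + dz^2) / dt` over the
#' run; `speed = "vertical"` uses `|dz| / dt` instead.
#'
#' @param modetrack A `mode_track`.
#' @param traj The matching [trajectory()].
#' @param speed `"path"` (default) or `"vertical"`.
#' @return A data frame with columns `trial_id`, `start_s`, `end_s`,
#'   `duration_s`, `max_depth_mm`, `mean_speed_mm_per_s` (one row per event;
#'   zero rows when the trial contains no dive).
#' @export
extract_dives <- function(modetrack, traj, speed = c("path", "vertical")) {
  stopifnot(inherits(modetrack, "mode_track"), inherits(traj, "trajectory"))
  speed <- match.arg(speed)
  if (length(modetrack$labels) != length(traj$times))
    stop_validation("mode track and trajectory lengths differ")
  dt <- sample_interval(traj)
  runs <- logical_runs(modetrack$labels == "DIVING")
  empty <- data.frame(trial_id = character(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      max_depth_mm = numeric(0),
                      mean_speed_mm_per_s = numeric(0))
  if (nrow(runs) == 0) return(empty)
  n <- length(traj$times)
  out <- lapply(seq_len(nrow(runs)), function(k) {
    i <- runs$start[k]; j <- runs$end[k]
    start_s <- traj$times[i]
    end_s <- if (j < n) traj$times[j + 1] else traj$times[j] + dt
    idx <- i:j
    spd <- NA_real_
    if (j > i) {
      dz <- diff(traj$z[idx]); dx <- diff(traj$x[idx])
      dtt <- diff(traj$times[idx])
      inc <- if (speed == "path") sqrt(dx^2 + dz^2) else abs(dz)
      spd <- mean(inc / dtt, na.rm = TRUE)
    }
    data.frame(trial_id = traj$trial_id, start_s = start_s, end_s = end_s,
               duration_s = end_s - start_s,
               max_depth_mm = min(traj$z[idx], na.rm = TRUE),
               mean_speed_mm_per_s = spd)
  })
  do.call(rbind, out)
}

#' Per-mode time fractions of a trial
#'
#' Percentage of non-EXCLUDED frames carrying each behavioral label. The
#' four percentages sum to 100.
#'
#' @param modetrack A `mode_track`.
#' @return Named numeric vector over `SURFACING`, `DIGGING`, `DIVING`,
#'   `ESCAPING` (percent).
#' @export
mode_time_fractions <- function(modetrack) {
  stopifnot(inherits(modetrack, "mode_track"))
  lab <- modetrack$labels
  active <- lab != "EXCLUDED"
  if (!any(active))
    stop_validation("all frames are excluded; no time fractions defined")
  modes <- setdiff(names(MODE_LEVELS), "EXCLUDED")
  counts <- vapply(modes, function(m) sum(lab[active] == m), numeric(1))
  100 * counts / sum(counts)
}

#' Sliding-window mode probability across a cohort
#'
#' For each time point, the fraction of active (non-EXCLUDED) trials in the
#' given mode, smoothed with a centred moving average of `window_s` seconds
#' truncated at the trial edges. The number of active trials entering each
#' point is recorded.
#'
#' @param modetracks List of `mode_track`s on a common time base.
#' @param mode One of `SURFACING`, `DIGGING`, `DIVING`, `ESCAPING`.
#' @param window_s Smoothing window (s), default 60 (1 min).
#' @return A data frame `time_s`, `probability`, `n_trials`.
#' @export
sliding_mode_probability <- function(modetracks, mode = "DIVING",
                                     window_s = 60) {
  if (length(modetracks) < 1L) stop_validation("empty cohort")
  mode <- match.arg(mode, setdiff(names(MODE_LEVELS), "EXCLUDED"))
  check_number(window_s, "window_s", lower = 0, strict = TRUE)
  times <- modetracks[[1]]$times
  n <- length(times)
  if (!all(vapply(modetracks, function(m) length(m$labels) == n, logical(1))))
    stop_validation("mode tracks must share a common time base")
  ind <- vapply(modetracks, function(m) as.numeric(m$labels == mode), numeric(n))
  act <- vapply(modetracks, function(m) as.numeric(m$labels != "EXCLUDED"), numeric(n))
  if (is.null(dim(ind))) { ind <- matrix(ind, nrow = n); act <- matrix(act, nrow = n) }
  n_active <- rowSums(act)
  p_raw <- ifelse(n_active > 0, rowSums(ind) / n_active, NA_real_)
  dt <- if (n > 1) stats::median(diff(times)) else 1
  half <- floor(window_s / dt / 2)
  smooth <- vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    mean(p_raw[idx], na.rm = TRUE)
  }, numeric(1))
  smooth[is.nan(smooth)] <- NA_real_  # no active trial anywhere in the window
  data.frame(time_s = times, probability = smooth, n_trials = n_active)
}

#' Dive durations paired with the following surface interval
#'
#' For each dive that is followed by another dive within the trial, pairs the
#' dive duration with the time spent surfacing or digging before the next
#' dive. The final dive of a trial has a censored interval and is dropped.
#'
#' @param modetrack A `mode_track`.
#' @return A data frame `dive_duration_s`, `surface_s` (possibly zero rows).
#' @export
post_dive_intervals <- function(modetrack) {
  stopifnot(inherits(modetrack, "mode_track"))
  lab <- modetrack$labels
  dt <- if (length(modetrack$times) > 1) stats::median(diff(modetrack$times)) else 1
  runs <- logical_runs(lab == "DIVING")
  if (nrow(runs) < 2) {
    return(data.frame(dive_duration_s = numeric(0), surface_s = numeric(0)))
  }
  out <- lapply(seq_len(nrow(runs) - 1), function(k) {
    dur <- (runs$end[k] - runs$start[k] + 1) * dt
    between <- lab[(runs$end[k] + 1):(runs$start[k + 1] - 1)]
    data.frame(dive_duration_s = dur,
               surface_s = sum(between %in% c("SURFACING", "DIGGING")) * dt)
  })
  do.call(rbind, out)
}

#' Rank correlation of paired dive statistics
#'
#' Spearman (default) or Pearson correlation with a two-sided p-value, as
#' used for dive duration versus maximum depth and versus the following
#' surface interval.
#'
#' @param x,y Paired numeric vectors (or a two-column data frame as `x`).
#' @param method `"spearman"` or `"pearson"`.
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
correlate_pairs <- function(x, y = NULL, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.null(y)) { y <- x[[2]]; x <- x[[1]] }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_validation("correlation requires at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_validation("correlation undefined for constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method)
}

#' Empirical cumulative distribution function
#'
#' Right-continuous ECDF of dive depths or durations, returned as its sorted
#' support and cumulative fractions (final value 1).
#'
#' @param values Numeric vector (>= 1 value).
#' @return A data frame `value`, `cum_fraction`.
#' @export
dive_ecdf <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1) stop_validation("ECDF requires at least one value")
  support <- sort(unique(values))
  data.frame(value = support,
             cum_fraction = stats::ecdf(values)(support))
}

#' Per-trial and cohort summary
#'
#' One row per non-excluded trial (trials flagged terminally inactive are
#' dropped): mode time percentages, number of dives, mean and median dive
#' duration, deepest dive, mean dive speed, escaped flag. Cohort aggregates
#' (mean and sd of dive counts, pooled dive statistics) are attached as
#' attribute `aggregates`.
#'
#' @param modetracks List of `mode_track`s.
#' @param trajectories Matching list of [trajectory()] objects.
#' @return A data frame of trial summaries with attribute `aggregates`.
#' @export
cohort_summary <- function(modetracks, trajectories) {
  if (length(modetracks) < 1L) stop_validation("empty cohort")
  if (length(modetracks) != length(trajectories))
    stop_validation("modetracks and trajectories differ in length")
  keep <- vapply(modetracks, function(m) is.na(m$inactive_from), logical(1))
  if (!any(keep)) stop_validation("all trials are excluded as inactive")
  rows <- lapply(which(keep), function(i) {
    mt <- modetracks[[i]]; tr <- trajectories[[i]]
    fr <- mode_time_fractions(mt)
    ev <- extract_dives(mt, tr)
    data.frame(trial_id = mt$trial_id,
               pct_surfacing = fr[["SURFACING"]], pct_digging = fr[["DIGGING"]],
               pct_diving = fr[["DIVING"]], pct_escaping = fr[["ESCAPING"]],
               n_dives = nrow(ev),
               mean_dive_duration_s = if (nrow(ev)) mean(ev$duration_s) else NA_real_,
               median_dive_duration_s = if (nrow(ev)) stats::median(ev$duration_s) else NA_real_,
               max_dive_depth_mm = if (nrow(ev)) min(ev$max_depth_mm) else NA_real_,
               mean_dive_speed_mm_per_s = if (nrow(ev))
                 mean(ev$mean_speed_mm_per_s, na.rm = TRUE) else NA_real_,
               escaped = mt$escaped)
  })
  tab <- do.call(rbind, rows)
  all_events <- do.call(rbind, lapply(which(keep), function(i)
    extract_dives(modetracks[[i]], trajectories[[i]])))
  attr(tab, "aggregates") <- list(
    n_trials = nrow(tab),
    n_excluded = sum(!keep),
    dives_mean = mean(tab$n_dives), dives_sd = stats::sd(tab$n_dives),
    dive_duration_mean_s = if (nrow(all_events)) mean(all_events$duration_s) else NA_real_,
    dive_duration_median_s = if (nrow(all_events)) stats::median(all_events$duration_s) else NA_real_,
    max_depth_mean_mm = if (nrow(all_events)) mean(all_events$max_depth_mm) else NA_real_,
    pct_escaped = 100 * mean(tab$escaped)
  )
  tab
}
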