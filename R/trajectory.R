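#' Centroid trajectory of a single trial
#'
#' Per-second centroid positions of one larva. `x` is the horizontal offset
#' from the chamber midline and `z` the signed depth relative to the gel
#' surface (negative below). Tracking gaps are carried in an explicit
#' `missing` mask; masked frames hold `NA` coordinates.
#'
#' @param times Sample times in seconds, strictly increasing (nominally 1 Hz).
#' @param x,z Coordinates in mm (same length as `times`).
#' @param trial_id Identifier of the trial.
#' @param missing Logical mask of untracked frames.
#' @param geometry A [chamber_geometry()] used to validate the depth range.
#' @return An object of class `trajectory`: a list with elements `trial_id`,
#'   `times`, `x`, `z`, `missing`.
#' @export
trajectory <- function(times, x, z, trial_id = "trial",
                       missing = rep(FALSE, length(times)),
                       geometry = chamber_geometry()) {
  if (length(times) != length(x) || length(times) != length(z) ||
      length(times) != length(missing))
    stop_validation("times, x, z and missing must have equal length")
  if (length(times) < 1L) stop_validation("trajectory must contain at least one sample")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop_validation("times must be finite and strictly increasing")
  missing <- as.logical(missing)
  if (any(is.na(missing))) stop_validation("missing mask must be TRUE/FALSE")
  obs <- !missing
  if (any(!is.finite(z[obs])) || any(!is.finite(x[obs])))
    stop_validation("observed coordinates must be finite")
  lo <- geometry$gel_bottom_z - 1
  hi <- geometry$air_top_z + 5  # escapes may exceed the air chamber top
  if (any(z[obs] < lo | z[obs] > hi))
    stop_validation("z outside plausible chamber range [", lo, ", ", hi, "] mm")
  x[missing] <- NA_real_
  z[missing] <- NA_real_
  structure(list(trial_id = as.character(trial_id), times = as.numeric(times),
                 x = as.numeric(x), z = as.numeric(z), missing = missing),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  dt <- if (length(x$times) > 1) stats::median(diff(x$times)) else NA_real_
  cat(sprintf("Trajectory '%s': %d samples, dt = %g s, %d missing\n",
              x$trial_id, length(x$times), dt, sum(x$missing)))
  zr <- range(x$z, na.rm = TRUE)
  cat(sprintf("  depth range: [%.2f, %.2f] mm\n", zr[1], zr[2]))
  invisible(x)
}

# Median sampling interval; 1 for single-sample trajectories.
sample_interval <- function(traj) {
  if (length(traj$times) < 2L) return(1)
  stats::median(diff(traj$times))
}

#' Read a trajectory from CSV
#'
#' Expects a header `time_s,x_mm,z_mm`. Empty coordinate fields are read as
#' missing (masked) samples. Non-monotone time stamps are rejected.
#'
#' @param path Path to a CSV file.
#' @param geometry A [chamber_geometry()].
#' @param trial_id Trial identifier; defaults to the file name.
#' @return A [trajectory()].
#' @examples
#' csv <- system.file("extdata", "example_trajectory.csv", package = "digdive")
#' read_trajectory(csv)
#' @export
read_trajectory <- function(path, geometry = chamber_geometry(),
                            trial_id = NULL) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "x_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop_format("trajectory CSV must have header columns ", paste(need, collapse = ","))
  for (col in need) {
    if (!is.numeric(df[[col]]) && !all(is.na(df[[col]])))
      stop_format("non-numeric values in column ", col)
  }
  if (any(is.na(df$time_s))) stop_format("time_s must not contain missing values")
  miss <- is.na(df$x_mm) | is.na(df$z_mm)
  trajectory(df$time_s, df$x_mm, df$z_mm,
             trial_id = trial_id %||% tools::file_path_sans_ext(basename(path)),
             missing = miss, geometry = geometry)
}

#' Write a trajectory to CSV
#'
#' Inverse of [read_trajectory()]: coordinates are written with enough digits
#' that a read/write round trip preserves positions to better than 1e-9 mm.
#' Masked samples are written with empty coordinate fields.
#'
#' @param traj A [trajectory()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.15g", v))
  lines <- c("time_s,x_mm,z_mm",
             paste(fmt(traj$times), fmt(traj$x), fmt(traj$z), sep = ","))
  writeLines(lines, path)
  invisible(path)
}
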