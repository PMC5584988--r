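# Shared fixtures, built in code at test time.

# Mode track from a compact label string, e.g. "GVVVG" at 1 Hz.
make_modetrack <- function(codes, trial_id = "fix", dt = 1) {
  code_to_mode <- stats::setNames(names(MODE_LEVELS), MODE_LEVELS)
  labels <- unname(code_to_mode[strsplit(codes, "")[[1]]])
  stopifnot(!any(is.na(labels)))
  structure(list(trial_id = trial_id,
                 times = (seq_along(labels) - 1) * dt,
                 labels = labels, escaped = FALSE,
                 inactive_from = NA_integer_),
            class = "mode_track")
}

# Trajectory whose z is consistent with a label string (one depth per mode).
make_traj_for_labels <- function(codes, dt = 1,
                                 depths = c(S = 0.5, G = -2, V = -6, E = 2.5)) {
  ch <- strsplit(codes, "")[[1]]
  z <- unname(depths[ch])
  n <- length(z)
  trajectory((seq_len(n) - 1) * dt, rep(0, n), z, trial_id = "fix")
}

# Empty-chamber reference background rendered with the same canvas as the
# larva frames (the standard pre-trial reference acquisition).
reference_background <- function(geometry = chamber_geometry(),
                                 rp = render_params(), n_frames = 5,
                                 noise_sd = rp$noise_sd) {
  empty <- trajectory(0, NA, NA, missing = TRUE, trial_id = "empty",
                      geometry = geometry)
  rp_ref <- rp
  rp_ref$noise_sd <- noise_sd
  frames <- do.call(c, lapply(seq_len(max(n_frames, 3)), function(i)
    unclass(render_frames(empty, geometry, rp_ref))))
  estimate_background(structure(frames, class = "frame_stack",
                                layout = attr(render_frames(empty, geometry, rp_ref),
                                              "layout")))
}

# All permutations of 1..n (for exact permutation oracles at tiny n).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i)
    lapply(all_permutations(n - 1), function(p) c(i, p + (p >= i)))))
}

# Interior runs of a logical vector (truncated boundary runs dropped).
interior_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & starts > 1 & ends < length(flag)
  data.frame(start = starts[keep], end = ends[keep])
}

# Brute-force run-length dive extraction used as an independent oracle.
rle_dive_oracle <- function(labels, times, z, dt = 1) {
  n <- length(labels)
  events <- list()
  i <- 1
  while (i <= n) {
    if (labels[i] == "DIVING") {
      j <- i
      while (j < n && labels[j + 1] == "DIVING") j <- j + 1
      end_s <- if (j < n) times[j + 1] else times[j] + dt
      events[[length(events) + 1]] <-
        c(start = times[i], end = end_s, max_depth = min(z[i:j]))
      i <- j + 1
    } else i <- i + 1
  }
  events
}
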