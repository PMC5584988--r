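#' Simulation parameters for the semi-Markov behavior model
#'
#' The simulator alternates surfacing and digging dwells with lognormal
#' durations, interrupted by dive excursions scheduled at a configurable
#' per-trial rate. A dive descends at constant speed `dive_speed` to a target
#' depth drawn from a truncated normal on `(gel_bottom, z_diving_preset]`,
#' then ascends at the same speed back to a digging level. Time spent apneic
#' (below `z_diving_preset`) beyond `aerobic_limit` exposes the larva to a
#' per-second drowning hazard; a drowned larva freezes in place for the rest
#' of the trial. Condition presets for the published experimental groups are
#' available through [preset_params()].
#'
#' @param dive_rate Expected number of dives per trial.
#' @param dive_count_sd Optional standard deviation of the per-trial dive
#'   count; when it exceeds the Poisson value the count is drawn from a
#'   matching negative binomial, otherwise from a Poisson.
#' @param dive_speed Descent/ascent speed of dives (mm/s).
#' @param dive_depth_mean,dive_depth_sd Target maximum dive depth distribution
#'   (mm, negative), truncated to `(gel_bottom, z_diving_preset]`.
#' @param z_diving_preset Species diving threshold used for ground-truth
#'   labels (mm, negative).
#' @param surf_dwell_meanlog,surf_dwell_sdlog Lognormal parameters of
#'   surfacing dwell durations (log-seconds).
#' @param dig_dwell_meanlog,dig_dwell_sdlog Lognormal parameters of digging
#'   dwell durations (log-seconds).
#' @param surf_level_mean,surf_level_sd Station-keeping height above the gel
#'   during surfacing (mm, truncated to `(0, air_top]`).
#' @param dig_level_mean,dig_level_sd Station-keeping depth during digging
#'   (mm, truncated to `(z_diving_preset, 0]`).
#' @param jitter_sd Per-frame positional jitter (mm) applied horizontally and,
#'   as within-band wobble, vertically during surfacing/digging.
#' @param aerobic_limit Apneic duration (s) beyond which drowning may occur.
#' @param drown_hazard Per-second drowning probability beyond the limit.
#' @param escape_rate Per-trial probability of an escape excursion above the
#'   air chamber.
#' @param trial_length Trial duration in seconds (default 900 = 15 min).
#' @param condition Free-text condition name.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(dive_rate = 4.1, dive_count_sd = NULL,
                       dive_speed = 0.7,
                       dive_depth_mean = -6, dive_depth_sd = 1.2,
                       z_diving_preset = -3.6,
                       surf_dwell_meanlog = log(25), surf_dwell_sdlog = 0.6,
                       dig_dwell_meanlog = log(110), dig_dwell_sdlog = 0.7,
                       surf_level_mean = 0.8, surf_level_sd = 0.5,
                       dig_level_mean = -2.9, dig_level_sd = 0.55,
                       jitter_sd = 0.12,
                       aerobic_limit = 180, drown_hazard = 0,
                       escape_rate = 0, trial_length = 900,
                       condition = "custom") {
  check_number(dive_rate, "dive_rate", lower = 0)
  check_number(dive_speed, "dive_speed", lower = 0, strict = TRUE)
  check_number(trial_length, "trial_length", lower = 0, strict = TRUE)
  check_number(aerobic_limit, "aerobic_limit", lower = 0)
  check_number(drown_hazard, "drown_hazard", lower = 0, upper = 1)
  check_number(escape_rate, "escape_rate", lower = 0, upper = 1)
  check_number(jitter_sd, "jitter_sd", lower = 0)
  if (dive_depth_mean >= z_diving_preset)
    stop_validation("dive_depth_mean must lie below z_diving_preset")
  structure(
    list(dive_rate = dive_rate, dive_count_sd = dive_count_sd,
         dive_speed = dive_speed,
         dive_depth_mean = dive_depth_mean, dive_depth_sd = dive_depth_sd,
         z_diving_preset = z_diving_preset,
         surf_dwell_meanlog = surf_dwell_meanlog,
         surf_dwell_sdlog = surf_dwell_sdlog,
         dig_dwell_meanlog = dig_dwell_meanlog,
         dig_dwell_sdlog = dig_dwell_sdlog,
         surf_level_mean = surf_level_mean, surf_level_sd = surf_level_sd,
         dig_level_mean = dig_level_mean, dig_level_sd = dig_level_sd,
         jitter_sd = jitter_sd, aerobic_limit = aerobic_limit,
         drown_hazard = drown_hazard, escape_rate = escape_rate,
         trial_length = trial_length, condition = condition),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("Simulation parameters ('%s')\n", x$condition))
  cat(sprintf("  dive rate %g/trial, speed %g mm/s, target depth %g +/- %g mm\n",
              x$dive_rate, x$dive_speed, x$dive_depth_mean, x$dive_depth_sd))
  cat(sprintf("  z_diving preset %g mm, aerobic limit %g s, drown hazard %g/s\n",
              x$z_diving_preset, x$aerobic_limit, x$drown_hazard))
  invisible(x)
}

# Preset table. Dive counts (mean +/- sd) are calibrated to the published
# cohort anchors; dwell levels and speeds reproduce the qualitative structure
# of each condition (mode balance, roughly tenfold longer dives in
# D. suzukii, drowning risk in very soft gels).
.preset_table <- function() {
  list(
    mel_0.4_noodor = sim_params(
      dive_rate = 4.1, dive_count_sd = 3.2, dive_speed = 0.7,
      dive_depth_mean = -6, dive_depth_sd = 1.2, z_diving_preset = -3.6,
      condition = "mel_0.4_noodor"),
    mel_0.4_odor = sim_params(
      dive_rate = 5.3, dive_count_sd = 2.5, dive_speed = 0.7,
      dive_depth_mean = -7.5, dive_depth_sd = 1.5, z_diving_preset = -3.6,
      dig_dwell_meanlog = log(100), condition = "mel_0.4_odor"),
    mel_blocked = sim_params(
      dive_rate = 0.3, dive_count_sd = 0.6, dive_speed = 0.7,
      dive_depth_mean = -5, dive_depth_sd = 1, z_diving_preset = -3.6,
      surf_dwell_meanlog = log(140), dig_dwell_meanlog = log(45),
      condition = "mel_blocked"),
    suzukii_0.4 = sim_params(
      dive_rate = 1.9, dive_count_sd = 1.5, dive_speed = 0.13,
      dive_depth_mean = -8.5, dive_depth_sd = 1.5, z_diving_preset = -3.4,
      dig_level_mean = -2.7, condition = "suzukii_0.4"),
    suzukii_blocked = sim_params(
      dive_rate = 1.0, dive_count_sd = 0.9, dive_speed = 0.13,
      dive_depth_mean = -7, dive_depth_sd = 1.5, z_diving_preset = -3.4,
      surf_dwell_meanlog = log(90), dig_level_mean = -2.7,
      condition = "suzukii_blocked"),
    mel_soft_0.05 = sim_params(
      dive_rate = 0.15, dive_speed = 0.5,
      dive_depth_mean = -9, dive_depth_sd = 1.5, z_diving_preset = -3.6,
      surf_dwell_meanlog = log(200), surf_dwell_sdlog = 0.5,
      dig_dwell_meanlog = log(25), surf_level_mean = 1.4,
      aerobic_limit = 120, drown_hazard = 0.02,
      condition = "mel_soft_0.05"),
    mel_hard_2.0 = sim_params(
      dive_rate = 0.2, dive_speed = 0.4,
      dive_depth_mean = -4.5, dive_depth_sd = 0.5, z_diving_preset = -3.6,
      surf_dwell_meanlog = log(240), dig_dwell_meanlog = log(40),
      dig_level_mean = -1.8, condition = "mel_hard_2.0")
  )
}

#' Condition presets for the simulator
#'
#' Returns calibrated [sim_params()] for one of the published experimental
#' groups. Cohort dive-count means target the reported anchors (for example
#' 4.1 dives/trial for wild-type D. melanogaster in 0.4% agarose and 1.9 for
#' D. suzukii).
#'
#' @param condition One of the names returned by [list_presets()].
#' @return A [sim_params()] object.
#' @examples
#' preset_params("mel_0.4_noodor")$dive_rate
#' @export
preset_params <- function(condition) {
  tab <- .preset_table()
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% names(tab))
    stop_config("unknown condition preset: ", paste(condition, collapse = ", "),
                "; available: ", paste(names(tab), collapse = ", "))
  tab[[condition]]
}

#' @rdname preset_params
#' @export
list_presets <- function() names(.preset_table())

# Draw the per-trial dive count: negative binomial when the configured sd
# implies overdispersion relative to Poisson, else Poisson.
draw_dive_count <- function(params) {
  mu <- params$dive_rate
  if (mu == 0) return(0L)
  sdv <- params$dive_count_sd
  if (!is.null(sdv) && sdv^2 > mu) {
    size <- mu^2 / (sdv^2 - mu)
    stats::rnbinom(1, size = size, mu = mu)
  } else {
    stats::rpois(1, mu)
  }
}

#' Simulate one dig-and-dive trial
#'
#' Generates a 1 Hz centroid trajectory of `trial_length` samples together
#' with ground-truth per-frame states and dive events. Deterministic for a
#' given seed. Horizontal position is frozen during dives so that, with zero
#' jitter, the configured dive speed is exactly recoverable from the
#' trajectory.
#'
#' @param params A [sim_params()].
#' @param geometry A [chamber_geometry()].
#' @param seed Integer seed.
#' @param trial_id Trial identifier.
#' @return A list with elements `trajectory` (a [trajectory()]) and `truth`
#'   (list: `state` per-frame labels, `dives` data frame with
#'   `start`/`end` frame indices and `max_depth_mm`, `drowned_at` seconds or
#'   `NA`, `escaped` logical).
#' @export
simulate_trial <- function(params, geometry = chamber_geometry(), seed = 1,
                           trial_id = paste0(params$condition, "_t", seed)) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(as.integer(seed %% 2147483647))
  n <- as.integer(round(params$trial_length))
  dt <- 1
  v <- params$dive_speed * dt
  zdiv <- params$z_diving_preset
  air <- geometry$air_top_z
  bottom <- geometry$gel_bottom_z

  # dive schedule: count from the configured rate, starts uniform in-trial
  n_dives <- draw_dive_count(params)
  dive_starts <- if (n_dives > 0) sort(ceiling(stats::runif(n_dives, 0, n - 5))) else integer(0)

  # optional escape excursion
  esc_start <- NA_integer_; esc_len <- 0L
  if (stats::runif(1) < params$escape_rate && n > 200) {
    esc_start <- as.integer(floor(stats::runif(1, 60, n - 120)))
    esc_len <- as.integer(round(stats::rlnorm(1, log(60), 0.3)))
    esc_level <- air + stats::runif(1, 0.3, 2.5)
  }

  z <- numeric(n); x <- numeric(n)
  phase <- "SURF"  # larvae are introduced at the surface
  level <- rtruncnorm(1, params$surf_level_mean, params$surf_level_sd, 0, air)
  dwell_left <- max(1, round(stats::rlnorm(1, params$surf_dwell_meanlog,
                                           params$surf_dwell_sdlog)))
  dive_queue <- dive_starts
  diving <- FALSE; dive_target <- NA_real_; dive_return <- NA_real_
  descending <- FALSE
  apnea <- 0L
  drowned_at <- NA_real_
  escaping_until <- -1L

  new_dwell <- function(phase) {
    if (phase == "SURF") {
      list(level = rtruncnorm(1, params$surf_level_mean, params$surf_level_sd, 0, air),
           left = max(1, round(stats::rlnorm(1, params$surf_dwell_meanlog,
                                             params$surf_dwell_sdlog))))
    } else {
      list(level = rtruncnorm(1, params$dig_level_mean, params$dig_level_sd, zdiv, 0),
           left = max(1, round(stats::rlnorm(1, params$dig_dwell_meanlog,
                                             params$dig_dwell_sdlog))))
    }
  }

  zprev <- level
  for (i in seq_len(n)) {
    if (!is.na(drowned_at)) {
      z[i] <- zprev; x[i] <- x[i - 1L]
      next
    }
    if (!diving && length(dive_queue) && i >= dive_queue[1]) {
      dive_queue <- dive_queue[-1]
      if (i > escaping_until) {
        # quantize the target onto the constant-speed stepping grid so the
        # turn lands exactly on a sample
        raw <- rtruncnorm(1, params$dive_depth_mean, params$dive_depth_sd,
                          bottom, zdiv)
        steps <- max(1, ceiling((zprev - raw) / v))
        dive_target <- zprev - steps * v
        if (dive_target <= bottom) dive_target <- zprev - v * floor((zprev - bottom - 1e-9) / v)
        dive_return <- rtruncnorm(1, params$dig_level_mean, params$dig_level_sd, zdiv, 0)
        diving <- TRUE; descending <- TRUE
      }
    }
    if (diving) {
      zi <- if (descending) zprev - v else zprev + v
      if (descending && zi <= dive_target + 1e-12) {
        zi <- dive_target; descending <- FALSE
      }
      if (!descending && zi >= dive_return) {
        zi <- dive_return
        diving <- FALSE
        phase <- "DIG"; level <- dive_return
        dw <- new_dwell("DIG"); dwell_left <- dw$left
      }
      z[i] <- zi
      x[i] <- if (i > 1) x[i - 1L] else 0
      if (zi <= zdiv) apnea <- apnea + 1L else apnea <- 0L
      if (apnea > params$aerobic_limit &&
          stats::runif(1) < params$drown_hazard) {
        drowned_at <- (i - 1) * dt
      }
      zprev <- z[i]
      next
    }
    apnea <- 0L
    if (!is.na(esc_start) && i >= esc_start && escaping_until < i &&
        i <= esc_start + 2L) {
      escaping_until <- min(n, esc_start + esc_len)
    }
    if (i <= escaping_until) {
      z[i] <- min(air + 4.5, esc_level + stats::rnorm(1, 0, 0.1))
      x[i] <- rtruncnorm(1, 0, params$jitter_sd,
                         -geometry$chamber_width / 2, geometry$chamber_width / 2)
      zprev <- z[i]
      next
    }
    if (dwell_left <= 0L) {
      phase <- if (phase == "SURF") "DIG" else "SURF"
      dw <- new_dwell(phase)
      level <- dw$level; dwell_left <- dw$left
    }
    band <- if (phase == "SURF") c(0, air) else c(zdiv, 0)
    z[i] <- rtruncnorm(1, level, max(params$jitter_sd, 1e-6), band[1], band[2])
    x[i] <- rtruncnorm(1, 0, max(params$jitter_sd, 1e-6),
                       -geometry$chamber_width / 2, geometry$chamber_width / 2)
    dwell_left <- dwell_left - 1L
    zprev <- z[i]
  }

  times <- (seq_len(n) - 1) * dt
  state <- ifelse(z > air, "ESCAPING",
                  ifelse(z > 0, "SURFACING",
                         ifelse(z > zdiv, "DIGGING", "DIVING")))
  runs <- logical_runs(state == "DIVING")
  dives <- data.frame(start = runs$start, end = runs$end,
                      max_depth_mm = vapply(seq_len(nrow(runs)), function(k)
                        min(z[runs$start[k]:runs$end[k]]), numeric(1)))
  traj <- trajectory(times, x, z, trial_id = trial_id, geometry = geometry)
  list(trajectory = traj,
       truth = list(state = state, dives = dives, drowned_at = drowned_at,
                    escaped = any(state == "ESCAPING")))
}

#' Simulate a cohort of trials
#'
#' Runs [simulate_trial()] `n_trials` times with per-trial seeds derived from
#' the root seed (`(seed * 48271 + i * 1009) mod (2^31 - 1) + 1`), so each
#' trial is reproducible independently of cohort order.
#'
#' @param params A [sim_params()].
#' @param n_trials Number of trials (>= 1).
#' @param geometry A [chamber_geometry()].
#' @param seed Root seed.
#' @return A list of [simulate_trial()] results.
#' @export
simulate_cohort <- function(params, n_trials, geometry = chamber_geometry(),
                            seed = 1) {
  if (!is.numeric(n_trials) || n_trials < 1)
    stop_validation("n_trials must be >= 1")
  lapply(seq_len(n_trials), function(i)
    simulate_trial(params, geometry, seed = derive_seed(seed, i),
                   trial_id = sprintf("%s_%03d", params$condition, i)))
}
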