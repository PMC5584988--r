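test_that("dive events match construction and the run-length oracle", {
  mt <- make_modetrack("GVVVG")
  z <- c(-2, -4, -6, -4, -2)
  tr <- trajectory(0:4, rep(0, 5), z, trial_id = "fix")
  ev <- extract_dives(mt, tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 3)
  expect_equal(ev$max_depth_mm, -6)

  expect_equal(nrow(extract_dives(make_modetrack("SGGS"),
                                  make_traj_for_labels("SGGS"))), 0)

  set.seed(51)
  for (i in 1:100) {
    codes <- paste(sample(c("S", "G", "V"), 60, replace = TRUE),
                   collapse = "")
    mt <- make_modetrack(codes)
    tr <- make_traj_for_labels(codes)
    ev <- extract_dives(mt, tr)
    oracle <- rle_dive_oracle(mt$labels, tr$times, tr$z)
    expect_equal(nrow(ev), length(oracle))
    if (length(oracle)) {
      om <- do.call(rbind, oracle)
      expect_equal(ev$start_s, unname(om[, "start"]))
      expect_equal(ev$end_s, unname(om[, "end"]))
      expect_equal(ev$max_depth_mm, unname(om[, "max_depth"]))
    }
    # total event duration equals total diving time, exactly
    expect_equal(sum(ev$duration_s), sum(mt$labels == "DIVING"))
  }
})

test_that("simulated dive speed is exactly the configured constant", {
  p <- sim_params(dive_rate = 5, jitter_sd = 0, dive_speed = 0.6)
  s <- simulate_trial(p, seed = 61)
  thr <- behavior_thresholds(p$z_diving_preset)
  mt <- classify_modes(s$trajectory, thr)
  ev <- extract_dives(mt, s$trajectory)
  spd <- ev$mean_speed_mm_per_s[!is.na(ev$mean_speed_mm_per_s)]
  expect_gt(length(spd), 0)
  expect_lt(max(abs(spd - 0.6)), 1e-6)
})

test_that("mode time fractions count frames and sum to 100", {
  mt <- make_modetrack(paste0(strrep("S", 450), strrep("G", 450)))
  fr <- mode_time_fractions(mt)
  expect_equal(unname(fr[c("SURFACING", "DIGGING", "DIVING", "ESCAPING")]),
               c(50, 50, 0, 0))
  expect_equal(unname(mode_time_fractions(make_modetrack("VVVV"))[["DIVING"]]), 100)
  expect_error(mode_time_fractions(make_modetrack("XXX")),
               class = "digdive_validation_error")
  set.seed(71)
  for (i in 1:20) {
    codes <- paste(sample(c("S", "G", "V", "E", "X"), 90, replace = TRUE),
                   collapse = "")
    if (!grepl("[SGVE]", codes)) next
    fr <- mode_time_fractions(make_modetrack(codes))
    expect_lt(abs(sum(fr) - 100), 1e-9)
    lab <- strsplit(codes, "")[[1]]
    act <- lab[lab != "X"]
    expect_equal(unname(fr[["DIVING"]]), 100 * sum(act == "V") / length(act))
  }
})

test_that("sliding mode probability equals brute-force windowed means", {
  all_dive <- replicate(3, make_modetrack(strrep("V", 50)), simplify = FALSE)
  pr <- sliding_mode_probability(all_dive, "DIVING", window_s = 60)
  expect_true(all(pr$probability == 1))
  expect_true(all(pr$n_trials == 3))

  half <- list(make_modetrack(strrep("V", 50)), make_modetrack(strrep("G", 50)))
  pr2 <- sliding_mode_probability(half, "DIVING", window_s = 60)
  expect_true(all(pr2$probability == 0.5))

  set.seed(81)
  tracks <- lapply(1:5, function(i)
    make_modetrack(paste(sample(c("S", "G", "V", "X"), 80, replace = TRUE),
                         collapse = "")))
  w <- 9
  pr3 <- sliding_mode_probability(tracks, "DIVING", window_s = w)
  ind <- sapply(tracks, function(m) as.numeric(m$labels == "DIVING"))
  act <- sapply(tracks, function(m) as.numeric(m$labels != "EXCLUDED"))
  raw <- ifelse(rowSums(act) > 0, rowSums(ind * act) / rowSums(act), NA)
  # note indicator counts a labelled frame only when the trial is active
  half_w <- floor(w / 2)
  oracle <- vapply(seq_len(80), function(i) {
    idx <- max(1, i - half_w):min(80, i + half_w)
    mean(raw[idx], na.rm = TRUE)
  }, numeric(1))
  oracle[is.nan(oracle)] <- NA_real_
  expect_equal(pr3$probability, oracle, tolerance = 1e-12)
  expect_true(all(pr3$probability >= 0 & pr3$probability <= 1, na.rm = TRUE))

  # window equal to the sampling interval leaves the series unsmoothed
  pr4 <- sliding_mode_probability(tracks, "DIVING", window_s = 1)
  expect_equal(pr4$probability, raw, tolerance = 1e-12)
  expect_error(sliding_mode_probability(list(), "DIVING"),
               class = "digdive_validation_error")
})

test_that("post-dive intervals pair dives with the following surface time", {
  mt <- make_modetrack(paste0(strrep("V", 10), strrep("G", 5), strrep("V", 3)))
  pairs <- post_dive_intervals(mt)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$dive_duration_s, 10)
  expect_equal(pairs$surface_s, 5)

  # a single dive ending the trial is censored
  expect_equal(nrow(post_dive_intervals(make_modetrack("GGVVV"))), 0)

  set.seed(91)
  for (i in 1:50) {
    codes <- paste(sample(c("S", "G", "V"), 50, replace = TRUE), collapse = "")
    got <- post_dive_intervals(make_modetrack(codes))
    lab <- strsplit(codes, "")[[1]]
    r <- rle(lab)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    vruns <- which(r$values == "V")
    oracle <- if (length(vruns) >= 2) {
      do.call(rbind, lapply(seq_len(length(vruns) - 1), function(k) {
        i1 <- vruns[k]; i2 <- vruns[k + 1]
        between <- lab[(ends[i1] + 1):(starts[i2] - 1)]
        data.frame(dive_duration_s = r$lengths[i1],
                   surface_s = sum(between %in% c("S", "G")))
      }))
    } else data.frame(dive_duration_s = numeric(0), surface_s = numeric(0))
    expect_equal(got$dive_duration_s, oracle$dive_duration_s)
    expect_equal(got$surface_s, oracle$surface_s)
  }
})

test_that("rank correlation matches exact permutation enumeration", {
  expect_equal(correlate_pairs(1:5, c(2, 4, 6, 9, 20))$rho, 1)
  expect_error(correlate_pairs(1:5, rep(3, 5)),
               class = "digdive_validation_error")
  expect_error(correlate_pairs(1:2, 2:1), class = "digdive_validation_error")

  set.seed(101)
  x <- rnorm(6); y <- rnorm(6)
  got <- correlate_pairs(x, y)
  # exact two-sided permutation p for Spearman's rho at n = 6
  rho_obs <- cor(rank(x), rank(y))
  perms <- t(sapply(all_permutations(6), identity))
  rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y)[p]))
  p_exact <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  expect_lt(abs(got$p_value - p_exact), 0.02)
})

test_that("the empirical CDF is right-continuous and ends at one", {
  e1 <- dive_ecdf(2)
  expect_equal(e1$cum_fraction, 1)
  e2 <- dive_ecdf(c(1, 2, 2, 4))
  expect_equal(e2$cum_fraction[e2$value == 2], 0.75)
  expect_error(dive_ecdf(numeric(0)), class = "digdive_validation_error")
  set.seed(111)
  for (i in 1:10) {
    e <- dive_ecdf(rnorm(20))
    expect_true(all(diff(e$cum_fraction) > 0))
    expect_equal(e$cum_fraction[nrow(e)], 1)
  }
})

test_that("cohort summaries recompute from per-trial rows", {
  co <- simulate_cohort(preset_params("mel_0.4_noodor"), 12, seed = 121)
  trajs <- lapply(co, `[[`, "trajectory")
  thr <- behavior_thresholds(-3.6)
  mts <- lapply(trajs, classify_modes, thresholds = thr)
  summ <- cohort_summary(mts, trajs)
  agg <- attr(summ, "aggregates")
  expect_equal(agg$dives_mean, mean(summ$n_dives))
  expect_equal(agg$dives_sd, sd(summ$n_dives))
  expect_equal(agg$n_trials, nrow(summ))
  # n_dives equals the number of extracted events, trial by trial
  for (i in seq_along(mts)) {
    expect_equal(summ$n_dives[i], nrow(extract_dives(mts[[i]], trajs[[i]])))
  }

  one <- make_modetrack(strrep("S", 30), "only")
  tr1 <- make_traj_for_labels(strrep("S", 30))
  s1 <- cohort_summary(list(one), list(tr1))
  expect_equal(s1$n_dives, 0)
  expect_equal(s1$pct_surfacing, 100)
})

test_that("preset cohorts land near their calibration anchors", {
  co <- simulate_cohort(preset_params("mel_0.4_noodor"), 200, seed = 131)
  counts <- vapply(co, function(s) nrow(s$truth$dives), numeric(1))
  expect_lt(abs(mean(counts) - 4.1) / 4.1, 0.2)
})
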