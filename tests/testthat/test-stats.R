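test_that("Lilliefors statistic agrees with the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(40 + i * 7, mean = i, sd = i)
    got <- lilliefors_test(x, n_mc = 400, seed = 10 + i)
    ref <- nortest::lillie.test(x)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_lt(abs(got$p_value - ref$p.value), 0.12)
  }
})

test_that("Lilliefors test is calibrated under the null and powered against uniform", {
  set.seed(2)
  rejections <- vapply(1:1000, function(i)
    lilliefors_test(rnorm(50), n_mc = 200, seed = i)$p_value < 0.05, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)

  hits <- vapply(1:60, function(i)
    lilliefors_test(rexp(100), n_mc = 200, seed = 2000 + i)$p_value < 0.05,
    logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(lilliefors_test(rep(1, 10)), class = "digdive_validation_error")
  expect_error(lilliefors_test(rnorm(3)), class = "digdive_validation_error")
})

test_that("rank-sum test reproduces exact enumeration and handles ties", {
  x <- c(1, 2, 3); y <- c(10, 11, 12)
  got <- rank_sum_test(x, y)
  expect_equal(got$p_value, 0.1)  # 2 / choose(6, 3)
  expect_match(got$test, "exact")

  same <- c(1.3, 2.7, 5.1, 5.1, 8)
  expect_equal(rank_sum_test(same, same)$p_value, 1)

  # exact and approximate branches agree for moderate n
  set.seed(3)
  diffs <- vapply(1:30, function(i) {
    x <- rnorm(6); y <- rnorm(6)
    exact <- rank_sum_test(x, y)$p_value
    approx <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                  correct = TRUE))$p.value
    abs(exact - approx)
  }, numeric(1))
  expect_lt(max(diffs), 0.05)
  expect_lt(mean(diffs), 0.02)

  expect_error(rank_sum_test(numeric(0), 1:3),
               class = "digdive_validation_error")
})

test_that("Kruskal-Wallis post hoc letters reflect the significance graph", {
  g <- list(a = c(1, 2, 3, 4), b = c(1.1, 2.1, 2.9, 4.2), c = c(0.9, 2, 3.3, 3.8))
  res <- kruskal_posthoc(g)
  expect_identical(unname(res$letters), c("a", "a", "a"))

  set.seed(4)
  far <- list(lo = rnorm(10), hi = rnorm(10, 10, 1))
  res2 <- kruskal_posthoc(far)
  expect_identical(unname(res2$letters), c("a", "b"))

  # p-values carry the Bonferroni factor, capped at one
  k <- 3
  raw <- rank_sum_test(g$a, g$b)$p_value
  expect_equal(res$pairwise["a", "b"], min(1, raw * k * (k - 1) / 2))

  expect_error(kruskal_posthoc(list(a = 1:3)), class = "digdive_validation_error")
  expect_error(kruskal_posthoc(list(a = 1:3, b = 2)),
               class = "digdive_validation_error")
})

test_that("compact letters equal maximal cliques of the non-significance graph", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    ns <- matrix(FALSE, k, k)
    ns[upper.tri(ns)] <- sample(c(TRUE, FALSE), k * (k - 1) / 2, replace = TRUE)
    ns <- ns | t(ns); diag(ns) <- TRUE
    dimnames(ns) <- list(letters[1:k], letters[1:k])
    got <- digdive:::compact_letters(ns)
    gr <- igraph::graph_from_adjacency_matrix(ns, mode = "undirected",
                                              diag = FALSE)
    cl <- igraph::max_cliques(gr)
    # two groups share a letter iff they are not significantly different
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      share <- any(strsplit(got[i], "")[[1]] %in% strsplit(got[j], "")[[1]])
      expect_identical(share, ns[i, j], info = paste(rep, i, j))
    }
    # number of distinct letters equals the number of maximal cliques
    expect_equal(length(unique(unlist(strsplit(got, "")))), length(cl))
  }
})

test_that("two-sample KS statistic equals the brute-force supremum", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  expect_equal(ks_two_sample(x, y)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(12, 0.5)
    got <- ks_two_sample(x, y)$statistic
    grid <- sort(c(x, y))
    d_oracle <- max(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
    expect_equal(got, d_oracle, tolerance = 1e-12)
  }
  expect_error(ks_two_sample(1, 1:5), class = "digdive_validation_error")
})

test_that("one-sample t-test matches the sign-flip oracle", {
  sym <- c(-2, -1, 0, 1, 2) + 5
  got <- one_sample_t(sym, mu0 = 5)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
  expect_equal(one_sample_t(c(1, 2, 3), 2)$statistic, 0)

  set.seed(7)
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  t_stat <- function(v) mean(v) / (sd(v) / sqrt(length(v)))
  diffs <- vapply(1:8, function(i) {
    x <- rnorm(10, 0.4)
    t_obs <- abs(t_stat(x))
    t_null <- apply(flips, 1, function(s) abs(t_stat(s * x)))
    abs(one_sample_t(x, 0)$p_value - mean(t_null >= t_obs - 1e-12))
  }, numeric(1))
  expect_lt(mean(diffs), 0.02)
  expect_error(one_sample_t(rep(2, 5), 1), class = "digdive_validation_error")
})

test_that("Cohen's d uses the pooled sd and is affine invariant", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(8)
  x <- rnorm(200, 0, 1); y <- rnorm(200, 1, 1)
  expect_lt(abs(cohens_d(x, y) - 1), 0.25)
  d0 <- cohens_d(x, y)
  expect_equal(cohens_d(3 * x - 7, 3 * y - 7), d0, tolerance = 1e-12)
  expect_equal(cohens_d(x, y, denominator = "control"),
               abs(mean(x) - mean(y)) / sd(y))
  expect_error(cohens_d(rep(1, 5), rep(1, 5)),
               class = "digdive_validation_error")
})

test_that("noncentral-t power matches the closed-form reference", {
  spec <- power_spec(mu = 0, sigma = 1, delta = 1)
  # null effect: power equals the test size
  null_spec <- power_spec(mu = 0, sigma = 1, delta = 1e-12)
  expect_equal(t_power(20, null_spec), 0.05, tolerance = 1e-6)
  # strictly increasing in n
  pw <- t_power(2:60, spec)
  expect_true(all(diff(pw) > 0))
  # independent reference: power.t.test
  for (n in c(5, 10, 30)) {
    ref <- stats::power.t.test(n = n, delta = 1, sd = 1, sig.level = 0.05,
                               type = "one.sample", strict = TRUE)$power
    expect_equal(t_power(n, spec), ref, tolerance = 1e-6)
  }
})

test_that("sample-size search reproduces the published planning values", {
  expect_equal(sample_size_t(power_spec(mu = 0.15, sigma = 0.1, delta = 0.05)), 34)
  expect_equal(sample_size_t(power_spec(mu = 0.5, sigma = 0.2, delta = 0.3)), 6)
  # bracketing: returned n is minimal
  for (d in c(0.3, 0.5, 1, 1.5)) {
    spec <- power_spec(mu = 0, sigma = 1, delta = d)
    n0 <- sample_size_t(spec)
    expect_gte(t_power(n0, spec), 0.8)
    if (n0 > 2) expect_lt(t_power(n0 - 1, spec), 0.8)
  }
  expect_error(sample_size_t(power_spec(mu = 0, sigma = 1, delta = 0)),
               class = "digdive_validation_error")
})

test_that("normality gate routes to the right branch", {
  set.seed(9)
  t_branch <- vapply(1:20, function(i) {
    r <- select_test(rnorm(50), rnorm(50, 0.3), n_mc = 300, seed = 40 + i)
    r$branch
  }, character(1))
  expect_gte(mean(t_branch == "t"), 0.9)

  skewed <- vapply(1:10, function(i) {
    r <- select_test(rexp(60)^2, rnorm(60), n_mc = 300, seed = 140 + i)
    r$branch
  }, character(1))
  expect_true(all(skewed == "rank-sum"))

  r <- select_test(rnorm(30), rexp(30)^2, n_mc = 200, seed = 3)
  expect_true(r$branch %in% c("t", "rank-sum"))
  expect_false(is.null(r$branch))
})

test_that("assay index formulas follow their definitions", {
  expect_equal(preference_index(10, 10, 20), 0)
  expect_equal(preference_index(20, 0, 20), 1)
  expect_equal(preference_index(12, 6, 20), 0.3)
  expect_error(preference_index(5, 5, 0), class = "digdive_validation_error")
  expect_error(preference_index(15, 10, 20), class = "digdive_validation_error")

  expect_equal(survival_ratio(8, 10), 0.8)
  expect_equal(survival_ratio(0, 10), 0)
  expect_equal(survival_ratio(10, 10), 1)
  expect_error(survival_ratio(11, 10), class = "digdive_validation_error")

  expect_equal(mhc_rate(30, 60), 30)
  expect_equal(mhc_rate(0, 60), 0)
  expect_equal(mhc_rate(15, 30), 30)
  expect_error(mhc_rate(10, 0), class = "digdive_validation_error")
})
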