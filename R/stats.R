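#' Lilliefors normality test with Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov distance between the empirical CDF of `x` and a normal
#' distribution with mean and sd estimated from `x`. Because the parameters
#' are estimated, the usual KS null does not apply; the p-value is calibrated
#' by Monte Carlo: Gaussian samples of the same size are drawn, parameters
#' re-estimated per replicate, and the null distribution of the statistic
#' accumulated.
#'
#' @param x Numeric sample (n >= 4, non-constant).
#' @param n_mc Number of Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo null.
#' @return List with `statistic` (D), `p_value`, `n`.
#' @export
lilliefors_test <- function(x, n_mc = 2000, seed = 1) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop_validation("Lilliefors test requires at least 4 observations")
  if (stats::sd(x) == 0) stop_validation("Lilliefors test undefined for constant sample")
  D <- lillie_stat(x)
  set.seed(as.integer(seed %% 2147483647))
  null_D <- vapply(seq_len(n_mc), function(i) lillie_stat(stats::rnorm(n)),
                   numeric(1))
  p <- (1 + sum(null_D >= D)) / (n_mc + 1)
  list(statistic = D, p_value = p, n = n)
}

# KS distance to Normal(mean(x), sd(x)); sup over both one-sided gaps at the
# order statistics.
lillie_stat <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact enumeration for small samples without ties (`n_x + n_y <= 12`),
#' otherwise the tie-corrected normal approximation (midranks, tie-corrected
#' variance, continuity correction).
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (U), `p_value`, `test`, `n`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 1 || length(y) < 1)
    stop_validation("rank-sum test requires non-empty samples")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       test = if (exact) "rank-sum (exact)" else "rank-sum (normal approx.)",
       n = c(n_x = length(x), n_y = length(y)))
}

#' Kruskal-Wallis test with Bonferroni-corrected pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis across groups, then all pairwise rank-sum
#' tests with p-values multiplied by the number of pairs (capped at 1), and a
#' compact letter display in which two groups share a letter iff their
#' corrected p-value is at least `alpha`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha Significance level for the letter display.
#' @return List with `kw_p`, `pairwise` (symmetric matrix of corrected
#'   p-values), `letters` (named character vector).
#' @export
kruskal_posthoc <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop_validation("kruskal_posthoc requires at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop_validation("each group must contain at least 2 observations")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  kw <- stats::kruskal.test(groups)
  n_pairs <- k * (k - 1) / 2
  pmat <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    p <- rank_sum_test(groups[[i]], groups[[j]])$p_value
    pmat[i, j] <- pmat[j, i] <- min(1, p * n_pairs)
  }
  letters <- compact_letters(pmat >= alpha)
  list(kw_p = kw$p.value, pairwise = pmat, letters = letters)
}

# Compact letter display: letters correspond to the maximal cliques of the
# "not significantly different" graph (Bron-Kerbosch enumeration); each group
# receives one letter per maximal clique containing it, so two groups share a
# letter iff they are not significantly different.
compact_letters <- function(ns_matrix) {
  k <- nrow(ns_matrix)
  diag(ns_matrix) <- TRUE
  cliques <- list()
  bron_kerbosch <- function(r, p, x) {
    if (!length(p) && !length(x)) {
      cliques[[length(cliques) + 1]] <<- sort(r)
      return(invisible())
    }
    for (v in p) {
      nb <- setdiff(which(ns_matrix[v, ]), v)
      bron_kerbosch(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bron_kerbosch(integer(0), seq_len(k), integer(0))
  cliques <- cliques[order(vapply(cliques, min, numeric(1)),
                           vapply(cliques, paste, character(1), collapse = ","))]
  out <- character(k)
  for (ci in seq_along(cliques))
    for (g in cliques[[ci]]) out[g] <- paste0(out[g], letters[ci])
  names(out) <- rownames(ns_matrix)
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return List with `statistic` (D), `p_value`, `n`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop_validation("KS test requires at least 2 observations per sample")
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n = c(n_x = length(x), n_y = length(y)))
}

#' Two-sided one-sample Student t-test
#'
#' @param x Numeric sample (n >= 2, non-constant).
#' @param mu0 Null mean.
#' @return List with `statistic` (t), `p_value`, `n`, `mean`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop_validation("t-test requires at least 2 observations")
  if (stats::sd(x) == 0) stop_validation("t-test undefined for constant sample")
  tt <- stats::t.test(x, mu = mu0)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       n = length(x), mean = mean(x))
}

#' Cohen's d effect size
#'
#' Absolute difference between group means divided by the standard deviation.
#' The pooled standard deviation is the default denominator; `"control"`
#' uses the sd of `y` alone.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param denominator `"pooled"` or `"control"`.
#' @return Cohen's d (non-negative scalar).
#' @export
cohens_d <- function(x, y, denominator = c("pooled", "control")) {
  denominator <- match.arg(denominator)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop_validation("cohens_d requires at least 2 observations per sample")
  s <- if (denominator == "pooled") {
    sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
           (length(x) + length(y) - 2))
  } else {
    stats::sd(y)
  }
  if (s == 0) stop_validation("zero standard deviation; effect size undefined")
  abs(mean(x) - mean(y)) / s
}

#' Power specification for one-sample t sample-size planning
#'
#' @param mu Suspected baseline mean.
#' @param sigma Suspected standard deviation (> 0).
#' @param delta Difference to detect (non-zero).
#' @param power Target power (default 0.8).
#' @param alpha Significance level (default 0.05).
#' @param sides 1 or 2 (default two-sided).
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(mu, sigma, delta, power = 0.8, alpha = 0.05, sides = 2) {
  check_number(sigma, "sigma", lower = 0, strict = TRUE)
  check_number(power, "power", lower = 0, upper = 1, strict = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  if (!sides %in% c(1, 2)) stop_validation("sides must be 1 or 2")
  check_number(mu, "mu")
  check_number(delta, "delta")
  structure(list(mu = mu, sigma = sigma, delta = delta, power = power,
                 alpha = alpha, sides = sides),
            class = "power_spec")
}

#' Power of the one-sample t-test
#'
#' Computed from the noncentral t distribution with `df = n - 1` and
#' noncentrality `d * sqrt(n)` where `d = |delta| / sigma`.
#'
#' @param n Sample size (>= 2).
#' @param spec A [power_spec()].
#' @return Power in (0, 1).
#' @export
t_power <- function(n, spec) {
  stopifnot(inherits(spec, "power_spec"))
  if (!is.numeric(n) || any(n < 2)) stop_validation("n must be >= 2")
  d <- abs(spec$delta) / spec$sigma
  df <- n - 1
  ncp <- d * sqrt(n)
  if (spec$sides == 2) {
    tc <- stats::qt(1 - spec$alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - spec$alpha, df)
    1 - stats::pt(tc, df, ncp)
  }
}

#' Minimal sample size reaching the target power
#'
#' Smallest integer `n >= 2` whose one-sample t power meets the target;
#' the planning rule behind cohort sizes such as n = 34 for
#' (mu = 0.15, sigma = 0.1, delta = 0.05) and n = 6 for
#' (mu = 0.5, sigma = 0.2, delta = 0.3).
#'
#' @param spec A [power_spec()].
#' @param n_max Search bound.
#' @return Integer sample size.
#' @export
sample_size_t <- function(spec, n_max = 1e6) {
  stopifnot(inherits(spec, "power_spec"))
  if (spec$delta == 0)
    stop_validation("delta = 0: target power unreachable")
  n <- 2L
  while (t_power(n, spec) < spec$power) {
    n <- n + 1L
    if (n > n_max) stop_validation("sample size search exceeded n_max")
  }
  n
}

#' Normality-gated two-sample comparison
#'
#' Applies the Lilliefors test to each sample; when both pass at
#' `alpha_normality` a two-sided two-sample Student t-test is used, otherwise
#' the rank-sum test. The result records which branch ran, with Cohen's d
#' attached on the parametric branch.
#'
#' @param x,y Numeric samples.
#' @param alpha_normality Normality gate level.
#' @param n_mc,seed Monte-Carlo settings for the normality test.
#' @return List with `branch` (`"t"` or `"rank-sum"`), `statistic`,
#'   `p_value`, `normality_p`, and `effect_size_d` (parametric branch only).
#' @export
select_test <- function(x, y, alpha_normality = 0.05, n_mc = 1000, seed = 1) {
  px <- lilliefors_test(x, n_mc = n_mc, seed = seed)$p_value
  py <- lilliefors_test(y, n_mc = n_mc, seed = seed + 1)$p_value
  if (px >= alpha_normality && py >= alpha_normality) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    list(branch = "t", statistic = unname(tt$statistic), p_value = tt$p.value,
         normality_p = c(x = px, y = py), effect_size_d = cohens_d(x, y))
  } else {
    rs <- rank_sum_test(x, y)
    list(branch = "rank-sum", statistic = rs$statistic, p_value = rs$p_value,
         normality_p = c(x = px, y = py), effect_size_d = NA_real_)
  }
}

#' Two-choice preference index
#'
#' `PI = (nA - nB) / n_total`, in `[-1, 1]`.
#'
#' @param nA,nB Larvae counted on each condition.
#' @param n_total Total number of larvae (>= nA + nB).
#' @return Preference index.
#' @export
preference_index <- function(nA, nB, n_total) {
  for (v in c(nA, nB, n_total)) check_number(v, "count", lower = 0)
  if (n_total == 0) stop_validation("n_total must be positive")
  if (nA + nB > n_total) stop_validation("nA + nB cannot exceed n_total")
  (nA - nB) / n_total
}

#' Survival ratio
#'
#' Number of larvae that developed into adult flies divided by the total
#' number of larvae.
#'
#' @param n_adults Larvae that eclosed as adults.
#' @param n_larvae Total larvae (>= 1).
#' @return Ratio in `[0, 1]`.
#' @export
survival_ratio <- function(n_adults, n_larvae) {
  check_number(n_adults, "n_adults", lower = 0)
  check_number(n_larvae, "n_larvae", lower = 1)
  if (n_adults > n_larvae) stop_validation("n_adults cannot exceed n_larvae")
  n_adults / n_larvae
}

#' Mouth-hook contraction rate
#'
#' Contractions counted over a continuous observation window, expressed per
#' minute.
#'
#' @param count Number of contractions (>= 0).
#' @param window_s Observation window (s, > 0).
#' @return Contractions per minute.
#' @export
mhc_rate <- function(count, window_s = 60) {
  check_number(count, "count", lower = 0)
  if (!is.numeric(window_s) || length(window_s) != 1 || window_s <= 0)
    stop_validation("window_s must be positive")
  count * 60 / window_s
}
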