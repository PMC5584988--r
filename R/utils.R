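# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("digdive_validation_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("digdive_format_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("digdive_config_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(name, " must be a single finite number")
  if (strict) {
    if (x <= lower || x >= upper)
      stop_validation(name, " must be in the open interval (", lower, ", ", upper, ")")
  } else if (x < lower || x > upper) {
    stop_validation(name, " must be in [", lower, ", ", upper, "]")
  }
  invisible(x)
}

# Deterministic per-trial seed derived from a root seed so that cohort
# members are independent of simulation order. Kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  seed <- as.double(seed)
  ((seed * 48271 + index * 1009) %% 2147483647) + 1
}

# Draws from a normal distribution truncated to (lower, upper] by
# rejection; truncation regions used here retain ample mass.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Maximal runs of a logical vector: data.frame(start, end) of indices.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
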