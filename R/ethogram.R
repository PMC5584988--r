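#' Write an ethogram TSV
#'
#' One row per trial, one column per frame, single-character mode codes
#' (S surfacing, G digging, V diving, E escaping, X excluded). Rows are
#' ordered by ascending total diving time, matching the published raster
#' displays.
#'
#' @param modetracks Non-empty list of `mode_track`s.
#' @param path Output TSV path.
#' @return `path`, invisibly; the row order (indices into `modetracks`) is
#'   attached as attribute `order`.
#' @export
write_ethogram <- function(modetracks, path) {
  if (!is.list(modetracks) || length(modetracks) < 1L)
    stop_validation("write_ethogram requires a non-empty list of mode tracks")
  dive_time <- vapply(modetracks, function(m) {
    dt <- if (length(m$times) > 1) stats::median(diff(m$times)) else 1
    sum(m$labels == "DIVING") * dt
  }, numeric(1))
  ord <- order(dive_time)
  lines <- vapply(ord, function(i) {
    codes <- MODE_LEVELS[modetracks[[i]]$labels]
    paste(c(modetracks[[i]]$trial_id, codes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(structure(path, order = ord))
}

#' Read an ethogram TSV back into label matrices
#'
#' @param path Path written by [write_ethogram()].
#' @return A list with `trial_id` and a character matrix of mode labels
#'   (rows = trials).
#' @export
read_ethogram <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  code_to_mode <- stats::setNames(names(MODE_LEVELS), MODE_LEVELS)
  labs <- t(vapply(parts, function(p) code_to_mode[p[-1]],
                   character(length(parts[[1]]) - 1)))
  rownames(labs) <- ids
  list(trial_id = ids, labels = labs)
}

#' Plot an ethogram raster
#'
#' @param modetracks List of `mode_track`s.
#' @param sort_by_dive_time Order rows by ascending total diving time.
#' @param ... Passed to [graphics::image()].
#' @export
plot_ethogram <- function(modetracks, sort_by_dive_time = TRUE, ...) {
  stopifnot(length(modetracks) >= 1)
  dive_time <- vapply(modetracks, function(m) sum(m$labels == "DIVING"),
                      numeric(1))
  ord <- if (sort_by_dive_time) order(dive_time) else seq_along(modetracks)
  lv <- names(MODE_LEVELS)
  m <- vapply(modetracks[ord], function(mt) match(mt$labels, lv),
              numeric(length(modetracks[[1]]$labels)))
  cols <- c(SURFACING = "#d95f02", DIGGING = "#1b6ca8", DIVING = "#1b9e4b",
            ESCAPING = "#bdbdbd", EXCLUDED = "#f0f0f0")
  graphics::image(x = modetracks[[1]]$times, y = seq_along(ord), z = m,
                  col = cols, zlim = c(0.5, 5.5), xlab = "time (s)",
                  ylab = "trial (sorted by total dive time)", ...)
  invisible(ord)
}
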