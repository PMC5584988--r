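#' Rendering parameters for synthetic frames
#'
#' Controls the synthetic camera: image size via the chamber geometry and
#' `px_per_mm`, the larva drawn as a filled ellipse, 8-bit foreground and
#' background intensities, chamber walls at a distinct intensity, and
#' additive Gaussian noise clipped to `[0, 255]`.
#'
#' @param larva_semi_x,larva_semi_z Ellipse semi-axes in mm (horizontal,
#'   vertical).
#' @param fg,bg,wall Intensities in `[0, 255]` for the larva, the chamber
#'   interior, and the walls.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param margin_mm Rendered margin around the chamber (mm).
#' @return An object of class `render_params`.
#' @export
render_params <- function(larva_semi_x = 0.5, larva_semi_z = 0.9,
                          fg = 210, bg = 30, wall = 90, noise_sd = 0,
                          margin_mm = 1) {
  for (v in c(fg, bg, wall)) check_number(v, "intensity", lower = 0, upper = 255)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(larva_semi_x, "larva_semi_x", lower = 0, strict = TRUE)
  check_number(larva_semi_z, "larva_semi_z", lower = 0, strict = TRUE)
  structure(list(larva_semi_x = larva_semi_x, larva_semi_z = larva_semi_z,
                 fg = fg, bg = bg, wall = wall, noise_sd = noise_sd,
                 margin_mm = margin_mm),
            class = "render_params")
}

# Mapping between chamber coordinates (mm) and pixel space. Row 1 is the top
# of the image; z decreases with increasing row index.
frame_layout <- function(geometry, rp) {
  ppm <- geometry$px_per_mm
  height_mm <- (geometry$air_top_z - geometry$gel_bottom_z) + 2 * rp$margin_mm
  width_mm <- geometry$chamber_width + 2 * rp$margin_mm
  nrow <- as.integer(ceiling(height_mm * ppm))
  ncol <- as.integer(ceiling(width_mm * ppm))
  # pixel-centre of (x = 0, z = 0): surface_row rows from the top margin
  surface_row <- (geometry$air_top_z + rp$margin_mm) * ppm + 0.5
  centre_col <- (geometry$chamber_width / 2 + rp$margin_mm) * ppm + 0.5
  list(nrow = nrow, ncol = ncol, surface_row = surface_row,
       centre_col = centre_col, ppm = ppm)
}

mm_to_px <- function(x, z, layout) {
  list(row = layout$surface_row - z * layout$ppm,
       col = layout$centre_col + x * layout$ppm)
}

px_to_mm <- function(row, col, layout) {
  list(x = (col - layout$centre_col) / layout$ppm,
       z = (layout$surface_row - row) / layout$ppm)
}

# Static chamber background: interior at bg intensity, walls at wall
# intensity outside the chamber outline.
chamber_canvas <- function(geometry, rp, layout) {
  img <- matrix(rp$wall, layout$nrow, layout$ncol)
  rows <- matrix(seq_len(layout$nrow), layout$nrow, layout$ncol)
  cols <- matrix(seq_len(layout$ncol), layout$nrow, layout$ncol, byrow = TRUE)
  pos <- px_to_mm(rows, cols, layout)
  inside <- pos$x >= -geometry$chamber_width / 2 &
    pos$x <= geometry$chamber_width / 2 &
    pos$z >= geometry$gel_bottom_z & pos$z <= geometry$air_top_z
  img[inside] <- rp$bg
  img
}

#' Render a trajectory as a synthetic 8-bit frame stack
#'
#' Draws one grayscale frame per trajectory sample: the chamber canvas with
#' the larva as a filled ellipse centred at the mapped `(x, z)` position,
#' plus optional Gaussian noise clipped to `[0, 255]`. Masked (missing)
#' samples yield a larva-free frame.
#'
#' @param traj A [trajectory()].
#' @param geometry A [chamber_geometry()].
#' @param rp A [render_params()].
#' @return A list of integer matrices in `[0, 255]` (class `frame_stack`),
#'   with the layout stored in attribute `layout`.
#' @export
render_frames <- function(traj, geometry = chamber_geometry(),
                          rp = render_params()) {
  stopifnot(inherits(traj, "trajectory"))
  layout <- frame_layout(geometry, rp)
  canvas <- chamber_canvas(geometry, rp, layout)
  obs <- !traj$missing
  if (any(obs)) {
    p <- mm_to_px(traj$x[obs], traj$z[obs], layout)
    bad <- p$row < 1 | p$row > layout$nrow | p$col < 1 | p$col > layout$ncol
    if (any(bad))
      stop_validation("trajectory positions map outside the rendered frame")
  }
  a_px <- rp$larva_semi_x * layout$ppm
  b_px <- rp$larva_semi_z * layout$ppm
  rows <- matrix(seq_len(layout$nrow), layout$nrow, layout$ncol)
  cols <- matrix(seq_len(layout$ncol), layout$nrow, layout$ncol, byrow = TRUE)
  frames <- vector("list", length(traj$times))
  for (i in seq_along(frames)) {
    img <- canvas
    if (!traj$missing[i]) {
      c0 <- mm_to_px(traj$x[i], traj$z[i], layout)
      inside <- ((cols - c0$col) / a_px)^2 + ((rows - c0$row) / b_px)^2 <= 1
      img[inside] <- rp$fg
    }
    if (rp$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, rp$noise_sd)
      img <- pmin(pmax(img, 0), 255)
    }
    frames[[i]] <- matrix(as.numeric(img), layout$nrow, layout$ncol)
  }
  structure(frames, class = "frame_stack", layout = layout)
}

#' Write/read a frame stack
#'
#' `write_frames()` stores a stack as a multi-page TIFF (`.tif`/`.tiff`) or
#' as numbered 8-bit PNG files in a directory; `read_frames()` inverts it.
#'
#' @param frames A `frame_stack` (list of matrices in `[0, 255]`).
#' @param path Output `.tif` file or directory (PNG sequence).
#' @return `path` (write) or a `frame_stack` (read).
#' @export
write_frames <- function(frames, path) {
  imgs <- lapply(frames, function(m) m / 255)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(imgs))
      png::writePNG(imgs[[i]], file.path(path, sprintf("frame_%05d.png", i)))
  }
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    imgs <- lapply(files, png::readPNG)
  } else {
    imgs <- tiff::readTIFF(path, all = TRUE)
  }
  frames <- lapply(imgs, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m * 255
  })
  structure(frames, class = "frame_stack")
}
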