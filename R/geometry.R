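#' Chamber geometry of the dig-and-dive assay
#'
#' Describes the spatial frame of one assay chamber. The datum (`z = 0`) sits
#' at the gel surface; depths below the surface are negative, positions in the
#' air chamber above it are positive. Defaults follow a chamber with a 12 mm
#' agarose column, 3 mm wide, topped by a 2 mm air chamber.
#'
#' @param gel_bottom_z Depth of the bottom of the gel column (mm, negative).
#' @param air_top_z Top of the air chamber above the gel (mm, positive).
#' @param chamber_width Width of the gel column (mm).
#' @param px_per_mm Calibration used by the renderer and tracker (pixels per mm).
#' @return An object of class `chamber_geometry`.
#' @examples
#' geom <- chamber_geometry()
#' geom$air_top_z
#' @export
chamber_geometry <- function(gel_bottom_z = -12, air_top_z = 2,
                             chamber_width = 3, px_per_mm = 8) {
  check_number(gel_bottom_z, "gel_bottom_z", upper = 0, strict = TRUE)
  check_number(air_top_z, "air_top_z", lower = 0, strict = TRUE)
  check_number(chamber_width, "chamber_width", lower = 0, strict = TRUE)
  check_number(px_per_mm, "px_per_mm", lower = 0, strict = TRUE)
  structure(
    list(gel_surface_z = 0, gel_bottom_z = gel_bottom_z, air_top_z = air_top_z,
         chamber_width = chamber_width, px_per_mm = px_per_mm),
    class = "chamber_geometry"
  )
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat("Chamber geometry (z = 0 at gel surface, positive up)\n")
  cat(sprintf("  gel: %g to 0 mm, width %g mm; air chamber: 0 to +%g mm\n",
              x$gel_bottom_z, x$chamber_width, x$air_top_z))
  cat(sprintf("  calibration: %g px/mm\n", x$px_per_mm))
  invisible(x)
}

#' Depth thresholds separating behavioral modes
#'
#' The digging boundary is fixed at the gel surface (`z_digging = 0`); the
#' diving boundary `z_diving` is the first local minimum of the smoothed depth
#' density below its mean (see [dive_threshold()]). Frames with
#' `z <= z_diving` are diving, `z_diving < z <= z_digging` digging, and
#' `z > z_digging` surfacing (escaping above the air chamber).
#'
#' @param z_diving Diving threshold (mm, negative).
#' @param z_digging Digging threshold (mm); the gel surface by convention.
#' @return An object of class `behavior_thresholds`.
#' @export
behavior_thresholds <- function(z_diving, z_digging = 0) {
  check_number(z_diving, "z_diving")
  check_number(z_digging, "z_digging")
  if (z_diving >= z_digging)
    stop_validation("z_diving must lie below z_digging")
  structure(list(z_digging = z_digging, z_diving = z_diving),
            class = "behavior_thresholds")
}

#' @export
print.behavior_thresholds <- function(x, ...) {
  cat(sprintf("Behavior thresholds: z_digging = %g mm, z_diving = %g mm\n",
              x$z_digging, x$z_diving))
  invisible(x)
}
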