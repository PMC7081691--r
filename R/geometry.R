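#' Physical pixel geometry of an en face scan
#'
#' Converts the scan protocol (field width in mm, raster size in pixels) into
#' the physical pixel pitch and pixel area used for all deficit-area and
#' region computations. The standard macular protocol is a 6 mm x 6 mm field
#' sampled at 500 x 500, giving a 12 um pitch and 144 um^2 pixels.
#'
#' @param field_width Scan field width in mm (side of the square field).
#' @param grid_size Number of pixels per image side.
#' @return An object of class `pixel_geometry`: a list with `pixel_pitch`
#'   (um per pixel side), `pixel_area` (um^2), `field_width` (mm) and
#'   `grid_size` (pixels).
#' @examples
#' pixel_geometry(6, 500)   # 12 um pitch, 144 um^2 per pixel
#' @export
pixel_geometry <- function(field_width, grid_size) {
  assert_scalar_num(field_width, "field_width", lower = 0, strict = TRUE)
  if (!is.numeric(grid_size) || length(grid_size) != 1L || grid_size < 1 ||
      grid_size != round(grid_size)) {
    stop_ccfd("`grid_size` must be a positive whole number of pixels",
              "ccfd_invalid_argument")
  }
  pitch <- 1000 * field_width / grid_size
  structure(list(pixel_pitch = pitch,
                 pixel_area  = pitch^2,
                 field_width = field_width,
                 grid_size   = as.integer(grid_size)),
            class = "pixel_geometry")
}

#' @export
print.pixel_geometry <- function(x, ...) {
  cat(sprintf("pixel geometry: %g mm field, %d px/side -> %.4g um pitch, %.4g um^2/px\n",
              x$field_width, x$grid_size, x$pixel_pitch, x$pixel_area))
  invisible(x)
}
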