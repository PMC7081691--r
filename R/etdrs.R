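#' Build ETDRS-ring analysis regions on the image grid
#'
#' Constructs the four analysis regions used for topographic flow-deficit
#' statistics, derived from the ETDRS grid rings centred on the fovea:
#' Inner (disc of radius 0.5 mm), Middle (0.5-1.5 mm annulus), Outer
#' (1.5-3 mm annulus) and Full-Field. Pixel membership is decided by the
#' distance of the pixel centre, `((j - 0.5) * pitch, (i - 0.5) * pitch)` mm
#' from the top-left origin, using half-open radial bins `[0, 0.5)`,
#' `[0.5, 1.5)`, `[1.5, 3)`. Full-Field is by default the whole square
#' frame, corners included; set `full_field = "circle"` to restrict it to
#' the 3 mm disc.
#'
#' @param grid_size Pixels per image side.
#' @param field_width Field width in mm (default 6).
#' @param center Fovea position in mm from the top-left origin as `c(x, y)`;
#'   default is the geometric frame centre (fovea-centred scan).
#' @param radii The three ring radii in mm, default `c(0.5, 1.5, 3)`.
#' @param full_field `"frame"` (default, whole image) or `"circle"`
#'   (pixels within the outermost radius only).
#' @return Object of class `region_masks`: logical matrices `inner`,
#'   `middle`, `outer`, `full`, plus `center`, `radii`, `geometry`,
#'   `pixel_counts` and `areas_mm2`.
#' @examples
#' rg <- region_masks(500, 6)
#' rg$pixel_counts   # inner count ~ pi * 0.5^2 / (0.012^2)
#' @export
region_masks <- function(grid_size, field_width = 6, center = NULL,
                         radii = c(0.5, 1.5, 3),
                         full_field = c("frame", "circle")) {
  full_field <- match.arg(full_field)
  geometry <- pixel_geometry(field_width, grid_size)
  stopifnot(length(radii) == 3, all(diff(radii) > 0), radii[1] > 0)
  center <- center %||% rep(field_width / 2, 2)
  if (length(center) != 2 || !is.numeric(center)) {
    stop_ccfd("`center` must be c(x, y) in mm", "ccfd_invalid_argument")
  }
  if (any(center - radii[3] < -1e-9) ||
      any(center + radii[3] > field_width + 1e-9)) {
    stop_ccfd(sprintf(
      "the %g mm circle around center (%.3g, %.3g) is clipped by the %g mm frame",
      radii[3], center[1], center[2], field_width), "ccfd_region_clipped")
  }
  pitch_mm <- field_width / grid_size
  cy <- (seq_len(grid_size) - 0.5) * pitch_mm   # row centres (y)
  cx <- (seq_len(grid_size) - 0.5) * pitch_mm   # col centres (x)
  d2 <- outer((cy - center[2])^2, (cx - center[1])^2, `+`)
  r2 <- radii^2
  inner  <- d2 < r2[1]
  middle <- d2 >= r2[1] & d2 < r2[2]
  outerm <- d2 >= r2[2] & d2 < r2[3]
  full <- if (full_field == "frame") {
    matrix(TRUE, grid_size, grid_size)
  } else {
    d2 < r2[3]
  }
  counts <- c(inner = sum(inner), middle = sum(middle),
              outer = sum(outerm), full = sum(full))
  structure(list(inner = inner, middle = middle, outer = outerm, full = full,
                 center = center, radii = radii, geometry = geometry,
                 full_field = full_field,
                 pixel_counts = counts,
                 areas_mm2 = counts * pitch_mm^2),
            class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf("ETDRS regions on %d px / %g mm grid, center (%.3g, %.3g) mm\n",
              x$geometry$grid_size, x$geometry$field_width,
              x$center[1], x$center[2]))
  print(data.frame(region = names(x$pixel_counts),
                   pixels = as.integer(x$pixel_counts),
                   area_mm2 = round(x$areas_mm2, 4), row.names = NULL))
  invisible(x)
}

#' Regional flow-deficit percentage
#'
#' For each region, FD % = 100 * (deficit pixels in region) / (pixels in
#' region). The mask should normally be the globally area-filtered deficit
#' mask; a component straddling a ring boundary contributes its pixels to
#' every region it overlaps.
#'
#' @param mask A `deficit_mask` or logical matrix (TRUE = deficit).
#' @param regions A [region_masks()] of the same grid size.
#' @return Named numeric vector `fd_inner`, `fd_middle`, `fd_outer`,
#'   `fd_full`, each on \[0, 100\].
#' @export
fd_percentage <- function(mask, regions) {
  stopifnot(inherits(regions, "region_masks"))
  m <- if (inherits(mask, "deficit_mask")) mask$mask else mask
  stopifnot(is.matrix(m), is.logical(m))
  if (!all(dim(m) == regions$geometry$grid_size)) {
    stop_ccfd("mask and regions have different grid sizes",
              "ccfd_shape_mismatch")
  }
  out <- vapply(c("inner", "middle", "outer", "full"), function(rg) {
    100 * sum(m & regions[[rg]]) / regions$pixel_counts[[rg]]
  }, numeric(1))
  names(out) <- paste0("fd_", c("inner", "middle", "outer", "full"))
  out
}
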