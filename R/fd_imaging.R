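#' Binarize an angiogram into a flow-deficit mask
#'
#' Applies the fixed global threshold used for choriocapillaris slabs:
#' a pixel is a flow deficit iff its value is strictly below `threshold`
#' (a pixel exactly at the threshold counts as flow). No area filtering is
#' applied here; see [filter_by_area()].
#'
#' @param image A [angiogram()] object.
#' @param threshold Global threshold on (0, 1); default 0.2, the fixed value
#'   conventionally used for en face choriocapillaris OCTA slabs.
#' @return Object of class `deficit_mask`: list with `mask` (logical matrix,
#'   `TRUE` = deficit), `threshold`, `min_area` (`NULL` until filtered) and
#'   `geometry`.
#' @examples
#' img <- angiogram(matrix(c(0.1, 0.2, 0.3, 0.5), 2, 2))
#' binarize(img)$mask   # only the 0.1 pixel is a deficit
#' @export
binarize <- function(image, threshold = 0.2) {
  stopifnot(inherits(image, "cc_angiogram"))
  assert_scalar_num(threshold, "threshold", lower = 0, upper = 1, strict = TRUE)
  structure(list(mask      = image$values < threshold,
                 threshold = threshold,
                 min_area  = NULL,
                 geometry  = image$geometry),
            class = "deficit_mask")
}

#' @export
print.deficit_mask <- function(x, ...) {
  cat(sprintf("deficit mask: %d x %d px, %d deficit px (%.3f%%), threshold %g%s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), x$threshold,
              if (is.null(x$min_area)) ", unfiltered"
              else sprintf(", min area %g um^2", x$min_area)))
  invisible(x)
}

# neighbour offsets (row, col) for the two standard pixel connectivities
conn_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    list(c(1L, 0L), c(0L, 1L))
  } else if (connectivity == 8L) {
    list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  } else {
    stop_ccfd("`connectivity` must be 4 or 8", "ccfd_invalid_argument")
  }
}

#' Label connected flow-deficit components
#'
#' Standard connected-component labeling of the deficit mask, with per
#' component pixel counts and physical areas (`pixel_count * pixel_area`).
#' Components are relabeled 1, 2, ... in raster (column-major) order of
#' their first pixel, so labeling is deterministic.
#'
#' @param mask A `deficit_mask` (filtered or not) or a logical matrix.
#' @param connectivity 4 or 8 (default 8: diagonal neighbours touch).
#' @param geometry A [pixel_geometry()]; defaults to the mask's own.
#' @return Object of class `component_set`: list with `labels` (integer
#'   matrix, 0 = flow), `components` (data.frame: `label`, `pixel_count`,
#'   `area_um2`), `connectivity`, `geometry`, and the originating
#'   `threshold` if known.
#' @export
label_components <- function(mask, connectivity = 8, geometry = NULL) {
  if (inherits(mask, "deficit_mask")) {
    geometry <- geometry %||% mask$geometry
    threshold <- mask$threshold
    m <- mask$mask
  } else {
    m <- mask
    threshold <- NULL
  }
  stopifnot(is.matrix(m), is.logical(m))
  if (is.null(geometry)) {
    stop_ccfd("`geometry` is required when labeling a bare matrix",
              "ccfd_invalid_argument")
  }
  connectivity <- as.integer(connectivity)
  offs <- conn_offsets(connectivity)

  nr <- nrow(m); nc <- ncol(m)
  idx <- which(m)                       # linear (column-major) indices
  labels <- matrix(0L, nr, nc)
  comp <- data.frame(label = integer(), pixel_count = integer(),
                     area_um2 = numeric())
  if (length(idx)) {
    vid <- integer(nr * nc)             # pixel -> vertex id lookup
    vid[idx] <- seq_along(idx)
    r <- ((idx - 1L) %% nr) + 1L
    cl <- ((idx - 1L) %/% nr) + 1L
    from <- integer(0); to <- integer(0)
    for (off in offs) {
      dr <- off[1]; dc <- off[2]
      ok <- r + dr >= 1L & r + dr <= nr & cl + dc >= 1L & cl + dc <= nc
      nb <- idx[ok] + dr + dc * nr
      hit <- m[nb]
      from <- c(from, vid[idx[ok][hit]])
      to <- c(to, vid[nb[hit]])
    }
    g <- igraph::make_graph(rbind(from, to), n = length(idx),
                            directed = FALSE)
    memb <- igraph::components(g)$membership
    # deterministic labels: order components by their first pixel in raster order
    first <- vapply(split(seq_along(idx), memb), min, integer(1))
    relab <- integer(length(first))
    relab[order(first)] <- seq_along(first)
    lab <- relab[memb]
    labels[idx] <- lab
    counts <- tabulate(lab)
    comp <- data.frame(label = seq_along(counts),
                       pixel_count = counts,
                       area_um2 = counts * geometry$pixel_area)
  }
  structure(list(labels = labels, components = comp,
                 connectivity = connectivity, geometry = geometry,
                 threshold = threshold),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component set: %d components, %d deficit px, %d-connectivity\n",
              nrow(x$components), sum(x$labels > 0L), x$connectivity))
  invisible(x)
}

#' Remove flow deficits smaller than a physical area
#'
#' Drops every component whose area is strictly below `min_area` (um^2); a
#' component exactly at `min_area` is retained. With the default 500 um^2
#' cutoff and 12 um pixels, components of 1-3 pixels (144-432 um^2) are
#' removed and 4-pixel components (576 um^2) survive. This is the noise
#' filter applied once, globally, before any regional statistic.
#'
#' @param components A [label_components()] result.
#' @param min_area Minimum retained component area in um^2 (default 500).
#' @return A `deficit_mask` whose `mask` keeps only the retained components;
#'   its `min_area` field records the filter and `components` the surviving
#'   component table.
#' @export
filter_by_area <- function(components, min_area = 500) {
  stopifnot(inherits(components, "component_set"))
  assert_scalar_num(min_area, "min_area", lower = 0)
  keep <- components$components$area_um2 >= min_area
  keep_labels <- components$components$label[keep]
  mask <- matrix(components$labels %in% keep_labels,
                 nrow(components$labels), ncol(components$labels))
  structure(list(mask = mask,
                 threshold = components$threshold,
                 min_area = min_area,
                 connectivity = components$connectivity,
                 components = components$components[keep, , drop = FALSE],
                 geometry = components$geometry),
            class = "deficit_mask")
}

#' Threshold, label and noise-filter an angiogram in one call
#'
#' Convenience wrapper running [binarize()], [label_components()] and
#' [filter_by_area()] with the standard parameters.
#'
#' @inheritParams binarize
#' @inheritParams label_components
#' @inheritParams filter_by_area
#' @return The filtered `deficit_mask` (see [filter_by_area()]).
#' @export
flow_deficit_map <- function(image, threshold = 0.2, min_area = 500,
                             connectivity = 8) {
  filter_by_area(label_components(binarize(image, threshold),
                                  connectivity = connectivity),
                 min_area = min_area)
}

#' Write a deficit mask as a PNG plus a JSON provenance sidecar
#'
#' The mask is stored as an 8-bit PNG (0 = flow, 255 = deficit) and the
#' processing provenance (threshold, area filter, connectivity, geometry)
#' as `<path>.json`.
#'
#' @param mask A `deficit_mask`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_deficit_mask <- function(mask, path) {
  stopifnot(inherits(mask, "deficit_mask"))
  png::writePNG(mask$mask * 1, target = path)
  prov <- list(threshold = mask$threshold,
               min_area_um2 = mask$min_area,
               connectivity = mask$connectivity,
               field_width_mm = mask$geometry$field_width,
               grid_size = mask$geometry$grid_size,
               pixel_pitch_um = mask$geometry$pixel_pitch,
               n_deficit_px = sum(mask$mask))
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
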