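#' Specify a synthetic angiogram with exactly known ground truth
#'
#' Describes a synthetic en face angiogram whose thresholded deficit map is
#' known exactly by construction: deficit pixels take values inside
#' `deficit_band` (strictly below the threshold) and all other pixels take
#' values inside `background_band` (strictly above it), with a guard gap
#' around the threshold so that no rounding can move a pixel across it.
#'
#' @param grid_size Pixels per side (default 500).
#' @param field_width Field width in mm (default 6).
#' @param threshold Binarisation threshold the image is built around
#'   (default 0.2).
#' @param n_components Number of deficit components to place.
#' @param component_sizes Either an integer vector of exact per-component
#'   pixel counts (length `n_components`, placed in order) or a named list
#'   describing a distribution over pixel counts:
#'   `list(family = "poisson", lambda =, min =)`,
#'   `list(family = "geometric", prob =, min =)`, or
#'   `list(family = "uniform", min =, max =)`.
#' @param deficit_band Value interval for deficit pixels; must sit strictly
#'   below `threshold`.
#' @param background_band Value interval for background pixels; must sit
#'   strictly above `threshold`.
#' @param connectivity Pixel connectivity (4 or 8) used both to grow the
#'   components and to label them downstream, so truth components and
#'   detected components correspond one-to-one.
#' @param max_tries Placement retries per component before giving up.
#' @param seed Optional integer seed making generation deterministic.
#' @return Object of class `angiogram_spec`.
#' @export
angiogram_spec <- function(grid_size = 500, field_width = 6, threshold = 0.2,
                           n_components = 150,
                           component_sizes = list(family = "poisson",
                                                  lambda = 4, min = 1),
                           deficit_band = c(0, 0.15),
                           background_band = c(0.3, 1),
                           connectivity = 8, max_tries = 200, seed = NULL) {
  assert_scalar_num(threshold, "threshold", lower = 0, upper = 1, strict = TRUE)
  if (!is.numeric(n_components) || n_components < 0 ||
      n_components != round(n_components)) {
    stop_ccfd("`n_components` must be a non-negative whole number",
              "ccfd_invalid_argument")
  }
  stopifnot(length(deficit_band) == 2, length(background_band) == 2)
  if (deficit_band[1] < 0 || deficit_band[2] >= threshold ||
      deficit_band[1] > deficit_band[2]) {
    stop_ccfd("`deficit_band` must be an interval inside [0, threshold)",
              "ccfd_invalid_argument")
  }
  if (background_band[1] <= threshold || background_band[2] > 1 ||
      background_band[1] > background_band[2]) {
    stop_ccfd("`background_band` must be an interval inside (threshold, 1]",
              "ccfd_invalid_argument")
  }
  if (is.numeric(component_sizes)) {
    if (length(component_sizes) != n_components) {
      stop_ccfd("explicit `component_sizes` must have length `n_components`",
                "ccfd_invalid_argument")
    }
    if (any(component_sizes < 1 | component_sizes != round(component_sizes))) {
      stop_ccfd("component sizes must be positive whole pixel counts",
                "ccfd_invalid_argument")
    }
  }
  structure(list(grid_size = as.integer(grid_size),
                 field_width = field_width, threshold = threshold,
                 n_components = as.integer(n_components),
                 component_sizes = component_sizes,
                 deficit_band = deficit_band,
                 background_band = background_band,
                 connectivity = as.integer(connectivity),
                 max_tries = as.integer(max_tries), seed = seed),
            class = "angiogram_spec")
}

sample_component_sizes <- function(spec) {
  cs <- spec$component_sizes
  n <- spec$n_components
  if (is.numeric(cs)) return(as.integer(cs))
  switch(cs$family,
    poisson   = pmax(cs$min %||% 1L, stats::rpois(n, cs$lambda)),
    geometric = (cs$min %||% 1L) + stats::rgeom(n, cs$prob),
    uniform   = sample(seq.int(cs$min, cs$max), n, replace = TRUE),
    stop_ccfd(sprintf("unknown component size family '%s'", cs$family),
              "ccfd_invalid_argument"))
}

# grow one connected blob of `size` pixels by randomised accretion starting
# at linear index `start`; `free` marks admissible pixels. Returns linear
# indices or NULL if the blob gets stuck before reaching `size`.
grow_blob <- function(start, size, free, nr, nc, offs) {
  cur <- start
  frontier <- integer(0)
  add_neighbours <- function(px, frontier) {
    r <- ((px - 1L) %% nr) + 1L
    cl <- ((px - 1L) %/% nr) + 1L
    for (off in offs) {
      rr <- r + off[1]; cc <- cl + off[2]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- px[ok] + off[1] + off[2] * nr
      frontier <- c(frontier, nb[free[nb]])
    }
    frontier
  }
  frontier <- add_neighbours(start, frontier)
  while (length(cur) < size) {
    frontier <- setdiff(unique(frontier), cur)
    if (!length(frontier)) return(NULL)
    nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    cur <- c(cur, nxt)
    frontier <- add_neighbours(nxt, frontier)
  }
  cur
}

#' Generate a synthetic angiogram and its exact ground truth
#'
#' Places `n_components` connected deficit blobs (grown by randomised
#' accretion under the spec's connectivity) at random positions such that
#' no two components touch, even diagonally; fills deficit pixels from
#' `deficit_band` and all others from `background_band`. Binarising the
#' image at the spec threshold therefore recovers the ground-truth deficit
#' map exactly, pixel for pixel, and labeling recovers the placed
#' components one-to-one.
#'
#' @param spec An [angiogram_spec()].
#' @param seed Seed overriding `spec$seed`.
#' @return Object of class `synthetic_angiogram`: list with `image`
#'   (a `cc_angiogram`) and `truth`, itself a list with `mask` (logical
#'   matrix), `labels`, `components` (label, pixel_count, area_um2) and
#'   `regional_fd` (named FD % vector, present when the 3 mm circle fits in
#'   the field, otherwise `NULL`).
#' @export
generate_angiogram <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "angiogram_spec"))
  with_seed(seed, {
    n <- spec$grid_size
    offs <- conn_offsets(spec$connectivity)
    offs <- c(offs, lapply(offs, function(o) -o)) # growth needs both directions
    sizes <- sample_component_sizes(spec)
    labels <- matrix(0L, n, n)
    free <- matrix(TRUE, n, n)  # not yet part of, or adjacent to, a component
    for (k in seq_len(spec$n_components)) {
      placed <- FALSE
      for (try in seq_len(spec$max_tries)) {
        open <- which(free)
        if (!length(open)) break
        start <- if (length(open) == 1L) open else sample(open, 1L)
        px <- grow_blob(start, sizes[k], free, n, n, offs)
        if (!is.null(px)) {
          labels[px] <- k
          # block the blob and its full 8-neighbourhood so components can
          # never merge under either labeling connectivity
          r <- ((px - 1L) %% n) + 1L
          cl <- ((px - 1L) %/% n) + 1L
          for (dr in -1:1) for (dc in -1:1) {
            rr <- r + dr; cc <- cl + dc
            ok <- rr >= 1L & rr <= n & cc >= 1L & cc <= n
            free[px[ok] + dr + dc * n] <- FALSE
          }
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop_ccfd(sprintf(
          "could not place component %d (%d px) after %d tries: spec too dense",
          k, sizes[k], spec$max_tries), "ccfd_generation_error")
      }
    }
    vals <- matrix(stats::runif(n * n, spec$background_band[1],
                                spec$background_band[2]), n, n)
    didx <- which(labels > 0L)
    vals[didx] <- stats::runif(length(didx), spec$deficit_band[1],
                               spec$deficit_band[2])
    image <- angiogram(vals, field_width = spec$field_width)
    counts <- if (spec$n_components) tabulate(labels[didx]) else integer(0)
    comps <- data.frame(label = seq_along(counts), pixel_count = counts,
                        area_um2 = counts * image$geometry$pixel_area)
    regional <- NULL
    if (spec$field_width / 2 >= 3) {
      regional <- fd_percentage(labels > 0L,
                                region_masks(n, spec$field_width))
    }
    structure(list(image = image,
                   truth = list(mask = labels > 0L, labels = labels,
                                components = comps, regional_fd = regional),
                   spec = spec),
              class = "synthetic_angiogram")
  })
}

#' Write a synthetic angiogram and its ground truth to disk
#'
#' The image goes to an 8-bit PNG; the ground truth (component pixel lists
#' as linear indices, component table, regional truth FD %) to a JSON
#' sidecar `<path>.truth.json`.
#'
#' @param x A [generate_angiogram()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_synthetic_angiogram <- function(x, path) {
  stopifnot(inherits(x, "synthetic_angiogram"))
  write_angiogram(x$image, path)
  truth <- list(
    components = lapply(seq_len(nrow(x$truth$components)), function(k) {
      list(label = k, pixels = which(x$truth$labels == k))
    }),
    component_table = x$truth$components,
    regional_fd = as.list(x$truth$regional_fd),
    threshold = x$spec$threshold,
    grid_size = x$spec$grid_size,
    field_width = x$spec$field_width)
  jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
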