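# Independent brute-force oracles, deliberately naive implementations.

# stack-based flood fill labeling, independent of the package's graph-based
# labeler
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      px <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (off in offs) {
        r <- px[1] + off[1]; cc <- px[2] + off[2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- cur
          stack[[length(stack) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# per-pixel distance enumeration of the ring regions, plain double loop
brute_region_counts <- function(grid_size, field_width, center = NULL,
                                radii = c(0.5, 1.5, 3)) {
  pitch <- field_width / grid_size
  center <- if (is.null(center)) rep(field_width / 2, 2) else center
  counts <- c(inner = 0L, middle = 0L, outer = 0L, within3 = 0L)
  for (i in seq_len(grid_size)) {
    y <- (i - 0.5) * pitch
    for (j in seq_len(grid_size)) {
      x <- (j - 0.5) * pitch
      d <- sqrt((x - center[1])^2 + (y - center[2])^2)
      if (d < radii[1]) counts["inner"] <- counts["inner"] + 1L
      else if (d < radii[2]) counts["middle"] <- counts["middle"] + 1L
      else if (d < radii[3]) counts["outer"] <- counts["outer"] + 1L
      if (d < radii[3]) counts["within3"] <- counts["within3"] + 1L
    }
  }
  counts
}

# brute-force area filter: enumerate flood-fill components and keep pixels
# of components with >= min_area
brute_area_filter <- function(mask, pixel_area, min_area, connectivity = 8) {
  lab <- flood_fill_label(mask, connectivity)
  keep <- which(tabulate(lab) * pixel_area >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# small deterministic random logical matrix
random_mask <- function(nr, nc, density, seed) {
  set.seed(seed)
  matrix(runif(nr * nc) < density, nr, nc)
}

# shared heavy simulation for the acceptance suite (computed at most once)
acceptance_recovery <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- recovery_experiment(cohort_config(), n_reps = 500,
                                    seed = 20260923)
    }
    cache
  }
})
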