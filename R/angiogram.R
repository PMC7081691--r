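#' Construct an en face angiogram object
#'
#' Wraps a square matrix of flow-signal values on \[0, 1\] together with its
#' physical geometry. Rows index the vertical (y) direction, columns the
#' horizontal (x) direction; the physical origin is the top-left corner of
#' the field, and the centre of pixel `(i, j)` sits at
#' `((j - 0.5) * pitch, (i - 0.5) * pitch)` mm.
#'
#' @param values Square numeric matrix with entries in \[0, 1\].
#' @param field_width Physical field width in mm (default 6, the standard
#'   macular protocol).
#' @return Object of class `cc_angiogram`: list with `values` and `geometry`
#'   (a [pixel_geometry()]).
#' @export
angiogram <- function(values, field_width = 6) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_ccfd("`values` must be a numeric matrix", "ccfd_invalid_argument")
  }
  if (nrow(values) != ncol(values)) {
    stop_ccfd("angiogram must be square (equal rows and columns)",
              "ccfd_invalid_argument")
  }
  if (anyNA(values) || min(values) < 0 || max(values) > 1) {
    stop_ccfd("angiogram values must lie in [0, 1] with no missing entries",
              "ccfd_invalid_argument")
  }
  structure(list(values = values,
                 geometry = pixel_geometry(field_width, nrow(values))),
            class = "cc_angiogram")
}

#' @export
print.cc_angiogram <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("en face angiogram: %d x %d px, %g mm field (%.4g um pitch), values [%.3f, %.3f]\n",
              g$grid_size, g$grid_size, g$field_width, g$pixel_pitch,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read an en face angiogram from a grayscale image file
#'
#' Reads an 8- or 16-bit grayscale PNG (or TIFF, if the tiff package is
#' available). Integer sample values are mapped onto \[0, 1\] by the reader
#' (division by the dtype maximum); multi-channel images are collapsed by
#' channel averaging, dropping any alpha channel.
#'
#' @param path Path to a PNG or TIFF file.
#' @inheritParams angiogram
#' @return A `cc_angiogram`.
#' @export
read_angiogram <- function(path, field_width = 6) {
  ext <- tolower(tools::file_ext(path))
  v <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop_ccfd("reading TIFF requires the 'tiff' package", "ccfd_io_error")
      }
      tiff::readTIFF(path)
    },
    stop_ccfd(sprintf("unsupported image extension '%s' (use png/tiff)", ext),
              "ccfd_io_error")
  )
  if (length(dim(v)) == 3L) {
    nch <- dim(v)[3]
    if (nch %in% c(2L, 4L)) nch <- nch - 1L # drop alpha
    v <- apply(v[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  angiogram(v, field_width = field_width)
}

#' Write an angiogram as an 8-bit grayscale PNG
#'
#' Values v are stored as `round(255 * v)`; the quantisation error is below
#' half a grey level, so images generated with a guard gap around the
#' binarisation threshold round-trip to the same deficit mask.
#'
#' @param image A `cc_angiogram`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_angiogram <- function(image, path) {
  stopifnot(inherits(image, "cc_angiogram"))
  png::writePNG(image$values, target = path)
  invisible(path)
}
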