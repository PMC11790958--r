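#' Disc median filter
#'
#' Replaces each pixel by the median over a disc (Euclidean ball, boundary
#' ties included) of the given radius.  Image borders are handled by
#' mirror reflection.  Radius 0 returns the input unchanged.
#'
#' @param frame 2-D numeric intensity matrix.
#' @param radius disc radius in pixels (default 2, the standard smoothing
#'   radius for tether snapshots and kymograph input).
#' @return filtered matrix of the same shape.
#' @export
median_filter_frame <- function(frame, radius = 2) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (radius < 0) stop_loopx("radius must be >= 0", "loopx_bad_config")
  if (radius == 0) return(frame)
  .disc_median_cpp(frame, as.integer(radius))
}

#' White top-hat background subtraction
#'
#' Subtracts the morphological opening (grayscale erosion followed by
#' dilation) with a disc structuring element from the image, removing
#' background structure wider than the disc while preserving narrow bright
#' features.  The result is everywhere `>= 0` and `<= frame`.
#'
#' @param frame 2-D numeric intensity matrix.
#' @param radius disc radius in pixels (default 10, matched to tether
#'   snapshot background scales).
#' @return background-subtracted matrix.
#' @export
tophat_subtract <- function(frame, radius = 10) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (radius < 1) stop_loopx("radius must be >= 1", "loopx_bad_config")
  opened <- .disc_dilate_cpp(.disc_erode_cpp(frame, as.integer(radius)),
                             as.integer(radius))
  frame - opened
}

#' Build a kymograph from a tether image series
#'
#' Each kymograph column is one frame; the column is the row-wise sum of
#' the `2 * band_half_width + 1` pixel band centred on the DNA axis (11
#' pixels at the default half-width of 5).  By default the builder is a
#' pure band summation of the frames it is given; per-frame filtering
#' (`median_radius`, `tophat_radius`) and constant-background removal
#' (`background = "offband"`) are opted into by the quantification
#' pipeline.  Off-band background removal estimates the per-pixel
#' background of each frame as the median intensity of the columns
#' outside the summation band (which carry no tether signal), subtracts
#' it from the band sum and clamps each column at zero, so that intensity
#' ratios downstream are not diluted by camera background.
#'
#' @param series an `image_series` (see [simulate_tether_movie()] or
#'   [read_movie_tiff()]).
#' @param axis_col pixel column of the DNA axis; `NULL` picks the column
#'   with maximal total intensity.
#' @param band_half_width half-width of the summation band (default 5,
#'   i.e. an 11-pixel band).
#' @param median_radius disc median filter radius applied to each frame
#'   before summation (0 = frames used as given).
#' @param tophat_radius if non-`NULL`, apply white top-hat background
#'   subtraction after the median filter (display use).
#' @param background `"none"` (default) or `"offband"`.
#' @return a `kymograph`: list with `matrix` (position rows x time
#'   columns), `frame_interval`, `axis_col`, `band_half_width`.
#' @export
build_kymograph <- function(series, axis_col = NULL, band_half_width = 5,
                            median_radius = 0, tophat_radius = NULL,
                            background = c("none", "offband")) {
  background <- match.arg(background)
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$frames)
  rows <- d[1]; cols <- d[2]; n <- d[3]
  if (is.null(axis_col)) {
    colsum <- apply(series$frames, 2, sum)
    axis_col <- which.max(colsum)
  }
  lo <- axis_col - band_half_width
  hi <- axis_col + band_half_width
  if (lo < 1 || hi > cols)
    stop_loopx(sprintf(
      "summation band [%d, %d] exceeds frame columns [1, %d]", lo, hi, cols),
      "loopx_band_out_of_frame")
  band_w <- 2L * band_half_width + 1L
  mat <- matrix(0, nrow = rows, ncol = n)
  for (i in seq_len(n)) {
    f <- series$frames[, , i]
    if (median_radius > 0) f <- median_filter_frame(f, median_radius)
    if (!is.null(tophat_radius)) f <- tophat_subtract(f, tophat_radius)
    col <- rowSums(f[, lo:hi, drop = FALSE])
    if (background == "offband") {
      off <- setdiff(seq_len(cols), lo:hi)
      if (length(off)) {
        bg <- median(f[, off])
        col <- pmax(col - band_w * bg, 0)
      }
    }
    mat[, i] <- col
  }
  structure(list(matrix = mat, frame_interval = series$frame_interval,
                 axis_col = as.integer(axis_col),
                 band_half_width = as.integer(band_half_width)),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf(
    "<kymograph> %d positions x %d frames (%gs/frame), axis col %d, band %d px\n",
    nrow(x$matrix), ncol(x$matrix), x$frame_interval, x$axis_col,
    2L * x$band_half_width + 1L))
  invisible(x)
}

#' Write a kymograph to CSV (positions x frames) or TIFF
#'
#' @param kymo a `kymograph`.
#' @param path output path; format chosen by extension (`.csv` or
#'   `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    write.csv(kymo$matrix, path, row.names = FALSE)
  } else {
    m <- kymo$matrix
    tiff::writeTIFF(pmin(pmax(round(m), 0), 65535) / 65535, path,
                    bits.per.sample = 16L)
  }
  invisible(path)
}
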