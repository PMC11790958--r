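#' Detect candidate loop peaks in every kymograph line
#'
#' Finds local intensity maxima in each time line (column) of the
#' kymograph and keeps those whose topographic prominence exceeds a
#' fraction of the line's total intensity.  Prominence is the peak height
#' minus the higher of the two interval minima separating the peak from
#' taller terrain (or the line end), which rejects shot-noise maxima on a
#' bright tether line.
#'
#' @param kymo a `kymograph`.
#' @param min_prominence prominence threshold as a fraction of the line
#'   total intensity (default 0.05).
#' @return list with one data frame per frame (`row`, `intensity`,
#'   `prominence`), possibly zero rows.
#' @export
detect_peaks_per_line <- function(kymo, min_prominence = 0.05) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$matrix
  lapply(seq_len(ncol(m)), function(j) {
    line_peaks(m[, j], min_prominence * sum(m[, j]))
  })
}

# local maxima of v with prominence above `thresh`
line_peaks <- function(v, thresh) {
  n <- length(v)
  empty <- data.frame(row = integer(0), intensity = numeric(0),
                      prominence = numeric(0))
  if (n < 3) return(empty)
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (!length(idx)) return(empty)
  prom <- vapply(idx, function(i) {
    h <- v[i]
    lmin <- h
    for (k in seq(i - 1L, 1L)) {
      if (v[k] > h) break
      lmin <- min(lmin, v[k])
    }
    rmin <- h
    if (i < n) for (k in seq(i + 1L, n)) {
      if (v[k] > h) break
      rmin <- min(rmin, v[k])
    }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= thresh & prom > 0
  data.frame(row = idx[keep], intensity = v[idx[keep]],
             prominence = prom[keep])
}

#' Select the most intense peak per line and link across frames
#'
#' Per frame the most intense candidate is taken as the loop centre; the
#' per-frame centres are then connected into tracks by nearest-neighbour
#' linking: a centre joins the open track if it lies within `search_range`
#' pixels of the track's last position and the temporal gap does not
#' exceed `memory` skipped frames; otherwise a new track starts.  Tracks
#' shorter than `min_track_length` frames are discarded — a quality filter
#' standing in for the manual supervision of loop tracks.
#'
#' @param peaks output of [detect_peaks_per_line()].
#' @param search_range maximum frame-to-frame displacement (pixels).
#' @param memory maximum number of consecutive missing frames bridged.
#' @param min_track_length minimum number of detected frames for a track
#'   to be kept.
#' @return a `peak_track`: data frame (`frame`, `row`, `intensity`) of the
#'   longest retained track (zero rows when the tether never shows an
#'   acceptable track), with all retained tracks in attribute `tracks`.
#' @export
select_and_link <- function(peaks, search_range = 10, memory = 3,
                            min_track_length = 10) {
  sel <- do.call(rbind, lapply(seq_along(peaks), function(i) {
    p <- peaks[[i]]
    if (!nrow(p)) return(NULL)
    b <- p[which.max(p$intensity), , drop = FALSE]
    data.frame(frame = i, row = b$row, intensity = b$intensity)
  }))
  tracks <- list()
  if (!is.null(sel) && nrow(sel)) {
    cur <- sel[1, , drop = FALSE]
    for (i in seq_len(nrow(sel))[-1]) {
      last <- cur[nrow(cur), ]
      gap <- sel$frame[i] - last$frame
      if (gap <= memory + 1L && abs(sel$row[i] - last$row) <= search_range) {
        cur <- rbind(cur, sel[i, ])
      } else {
        tracks[[length(tracks) + 1L]] <- cur
        cur <- sel[i, , drop = FALSE]
      }
    }
    tracks[[length(tracks) + 1L]] <- cur
  }
  tracks <- Filter(function(t) nrow(t) >= min_track_length, tracks)
  best <- if (length(tracks)) {
    lens <- vapply(tracks, nrow, integer(1))
    tracks[[which.max(lens)]]
  } else data.frame(frame = integer(0), row = integer(0),
                    intensity = numeric(0))
  rownames(best) <- NULL
  structure(best, tracks = tracks, search_range = search_range,
            memory = memory, min_track_length = min_track_length,
            class = c("peak_track", "data.frame"))
}

#' Has a tether at least one accepted loop track?
#'
#' @param track a `peak_track`.
#' @return logical.
#' @export
has_loop_track <- function(track) {
  length(attr(track, "tracks", exact = TRUE)) > 0
}

#' Partition each tracked kymograph line into Up / Loop / Down
#'
#' The Loop region is the window of `2 * loop_halfwidth + 1` rows (9 at
#' the default) centred on the tracked peak, truncated at the kymograph
#' edges; Up is every row above the window and Down every row below.
#' Frames whose window is truncated are flagged `edge` — loop sizes cannot
#' be determined when the loop forms at the top or bottom of the
#' kymograph, and such frames are excluded from rate fitting downstream.
#'
#' @param kymo a `kymograph`.
#' @param track a `peak_track` from [select_and_link()].
#' @param loop_halfwidth half-width of the Loop window in rows (default 4).
#' @return a `region_partition` data frame (`frame`, `center_row`, `lo`,
#'   `hi`, `edge`), with the kymograph row count in attribute `n_rows`.
#' @export
partition_lines <- function(kymo, track, loop_halfwidth = 4) {
  stopifnot(inherits(kymo, "kymograph"), inherits(track, "peak_track"))
  n_rows <- nrow(kymo$matrix)
  if (nrow(track) && (any(track$row < 1) || any(track$row > n_rows)))
    stop_loopx("track rows outside the kymograph", "loopx_bad_track")
  lo <- pmax(track$row - loop_halfwidth, 1L)
  hi <- pmin(track$row + loop_halfwidth, n_rows)
  edge <- (track$row - loop_halfwidth < 1L) |
    (track$row + loop_halfwidth > n_rows)
  part <- data.frame(frame = track$frame, center_row = track$row,
                     lo = lo, hi = hi, edge = edge)
  structure(part, n_rows = n_rows, loop_halfwidth = loop_halfwidth,
            class = c("region_partition", "data.frame"))
}

#' Convert region intensity fractions to DNA amounts
#'
#' For every partitioned frame, the DNA in each region is the region's
#' share of the line's total fluorescence intensity multiplied by the
#' substrate size: `region_kbp = total_dna * I_region / I_line`.  The
#' three amounts therefore sum to `total_dna` exactly on every valid
#' frame.  Frames with non-positive line totals are marked invalid.
#'
#' @param kymo a `kymograph`.
#' @param partition a `region_partition` from [partition_lines()].
#' @param total_dna substrate size in kbp (48.5 for lambda DNA).
#' @return a `dna_partition_series` data frame (`frame`, `time_s`,
#'   `up_kbp`, `loop_kbp`, `down_kbp`, `valid`, `edge`).
#' @export
estimate_dna_amounts <- function(kymo, partition, total_dna = 48.5) {
  stopifnot(inherits(kymo, "kymograph"),
            inherits(partition, "region_partition"))
  m <- kymo$matrix
  n_rows <- nrow(m)
  res <- lapply(seq_len(nrow(partition)), function(i) {
    p <- partition[i, ]
    line <- m[, p$frame]
    tot <- sum(line)
    loop_i <- sum(line[p$lo:p$hi])
    up_i <- if (p$lo > 1) sum(line[1:(p$lo - 1L)]) else 0
    down_i <- if (p$hi < n_rows) sum(line[(p$hi + 1L):n_rows]) else 0
    if (!is.finite(tot) || tot <= 0)
      return(data.frame(frame = p$frame, up_kbp = NA_real_,
                        loop_kbp = NA_real_, down_kbp = NA_real_,
                        valid = FALSE, edge = p$edge))
    data.frame(frame = p$frame, up_kbp = total_dna * up_i / tot,
               loop_kbp = total_dna * loop_i / tot,
               down_kbp = total_dna * down_i / tot,
               valid = TRUE, edge = p$edge)
  })
  out <- do.call(rbind, res)
  out$time_s <- out$frame * kymo$frame_interval
  out <- out[, c("frame", "time_s", "up_kbp", "loop_kbp", "down_kbp",
                 "valid", "edge")]
  structure(out, total_dna = total_dna,
            class = c("dna_partition_series", "data.frame"))
}

#' Full per-tether quantification: kymograph to DNA partition
#'
#' Convenience wrapper chaining [build_kymograph()],
#' [detect_peaks_per_line()], [select_and_link()], [partition_lines()] and
#' [estimate_dna_amounts()] with shared defaults.
#'
#' @param series an `image_series`.
#' @param params list of stage parameters (see [pipeline_config()]).
#' @return list with `kymo`, `track`, `looped` (logical), and `dna`
#'   (`NULL` when no track was accepted).
#' @export
quantify_tether <- function(series, params = pipeline_config()) {
  kymo <- build_kymograph(series, axis_col = params$axis_col,
                          band_half_width = params$band_half_width,
                          median_radius = params$median_radius,
                          tophat_radius = params$quantify_tophat_radius,
                          background = params$kymo_background)
  peaks <- detect_peaks_per_line(kymo, min_prominence = params$min_prominence)
  track <- select_and_link(peaks, search_range = params$search_range,
                           memory = params$link_memory,
                           min_track_length = params$min_track_length)
  dna <- NULL
  if (nrow(track)) {
    part <- partition_lines(kymo, track,
                            loop_halfwidth = params$loop_halfwidth)
    dna <- estimate_dna_amounts(kymo, part, total_dna = params$total_dna)
  }
  list(kymo = kymo, track = track, looped = has_loop_track(track),
       dna = dna)
}
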