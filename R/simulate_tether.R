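#' Describe a single loop-extrusion event on a simulated tether
#'
#' A loop event starts at `t_start`, grows at a constant `rate` until it
#' reaches `max_loop` kbp, and then either plateaus or, if `slippage` is
#' given, shrinks back at that rate.  One tether carries at most one loop at
#' a time (the tracker follows a single punctum), so events on the same
#' tether must not overlap in time.
#'
#' @param t_start start time of the event (s).
#' @param rate extrusion rate (kbp/s), non-negative.
#' @param anchor_pos fractional position of the loop anchor along the
#'   tether, 0 = top attachment, 1 = bottom attachment.
#' @param max_loop plateau loop size (kbp); must stay below the substrate
#'   total.
#' @param slippage optional shrink rate (kbp/s) applied after the plateau.
#' @return an object of class `loop_event`.
#' @export
loop_event <- function(t_start, rate, anchor_pos = 0.5, max_loop = 20,
                       slippage = NULL) {
  stopifnot(is.numeric(t_start), length(t_start) == 1L, t_start >= 0,
            is.numeric(rate), length(rate) == 1L,
            is.numeric(anchor_pos), anchor_pos > 0, anchor_pos < 1,
            is.numeric(max_loop), max_loop > 0)
  if (rate < 0) stop_loopx("loop event rate must be >= 0", "loopx_bad_config")
  if (!is.null(slippage) && slippage < 0)
    stop_loopx("slippage must be >= 0", "loopx_bad_config")
  structure(list(t_start = t_start, rate = rate, anchor_pos = anchor_pos,
                 max_loop = max_loop, slippage = slippage),
            class = "loop_event")
}

# loop size (kbp) of one event at times t (vectorised)
event_loop_kbp <- function(ev, t) {
  grown <- pmax(0, (t - ev$t_start) * ev$rate)
  l <- pmin(grown, ev$max_loop)
  if (!is.null(ev$slippage) && ev$rate > 0) {
    t_plateau <- ev$t_start + ev$max_loop / ev$rate
    l <- ifelse(t > t_plateau,
                pmax(0, ev$max_loop - ev$slippage * (t - t_plateau)), l)
  }
  l
}

# active time interval of an event (loop size > 0)
event_interval <- function(ev) {
  if (ev$rate == 0) return(c(ev$t_start, ev$t_start))
  end <- Inf
  if (!is.null(ev$slippage) && ev$slippage > 0)
    end <- ev$t_start + ev$max_loop / ev$rate + ev$max_loop / ev$slippage
  c(ev$t_start, end)
}

#' Configuration for a synthetic tether movie
#'
#' Defines the acquisition geometry and photophysics of a simulated
#' doubly-tethered lambda-DNA molecule imaged as a vertical fluorescent
#' line.  Defaults give a 48.5 kbp substrate on a 100-pixel tether at
#' 1 s/frame; calibration (pixel size, frame interval) is always injected
#' explicitly, never assumed, because all downstream quantities are in kbp
#' and seconds.
#'
#' @param n_frames number of frames (>= 1); frame `i` is timestamped
#'   `i * frame_interval` seconds.
#' @param frame_interval seconds per frame.
#' @param tether_length_px vertical extent of the DNA line in pixels.
#' @param frame_shape `(rows, cols)` of each frame; defaults leave a margin
#'   around the tether wide enough that the PSF blur stays in-frame.
#' @param axis_col pixel column of the DNA axis (default: centre column).
#' @param tether_top first tether row (default: vertically centred).
#' @param total_dna substrate size in kbp (lambda DNA, 48.5).
#' @param loop_events list of [loop_event()] objects; must not overlap in
#'   time and must never exceed `total_dna`.
#' @param psf_sigma effective Gaussian spot sigma in pixels.  This is the
#'   width of the rendered line and punctum, i.e. the optical PSF
#'   convolved with the transverse thermal fluctuation of the slack
#'   tether and the physical extent of the loop condensate over one
#'   exposure, not the bare diffraction limit.
#' @param background_mean background level (counts/pixel) added before
#'   noise.
#' @param noise_model list with elements `poisson` (logical, shot noise on
#'   photon counts) and `gaussian_sd` (read noise in counts; 0 disables).
#' @param photons_per_kbp mean photon count emitted per kbp of DNA per
#'   frame; sets the SNR.
#' @param seed integer seed; identical config + seed reproduces the movie
#'   bit for bit.
#' @return an object of class `tether_sim_config`.
#' @export
tether_sim_config <- function(n_frames = 40, frame_interval = 1,
                              tether_length_px = 100,
                              frame_shape = NULL, axis_col = NULL,
                              tether_top = NULL, total_dna = 48.5,
                              loop_events = list(), psf_sigma = 1.8,
                              background_mean = 5,
                              noise_model = list(poisson = TRUE,
                                                 gaussian_sd = 2),
                              photons_per_kbp = 200, seed = 1L) {
  if (n_frames < 1) stop_loopx("n_frames must be >= 1", "loopx_bad_config")
  if (total_dna <= 0) stop_loopx("total_dna must be > 0", "loopx_bad_config")
  if (frame_interval <= 0)
    stop_loopx("frame_interval must be > 0", "loopx_bad_config")
  margin <- max(10L, as.integer(ceiling(6 * psf_sigma) + 2L))
  if (is.null(frame_shape))
    frame_shape <- c(tether_length_px + 2L * margin, 2L * margin + 1L)
  if (is.null(axis_col)) axis_col <- (frame_shape[2] + 1L) %/% 2L
  if (is.null(tether_top))
    tether_top <- (frame_shape[1] - tether_length_px) %/% 2L + 1L
  cfg <- structure(list(
    n_frames = as.integer(n_frames), frame_interval = frame_interval,
    tether_length_px = as.integer(tether_length_px),
    frame_shape = as.integer(frame_shape), axis_col = as.integer(axis_col),
    tether_top = as.integer(tether_top), total_dna = total_dna,
    loop_events = loop_events, psf_sigma = psf_sigma,
    background_mean = background_mean, noise_model = noise_model,
    photons_per_kbp = photons_per_kbp, seed = seed),
    class = "tether_sim_config")
  validate_tether_config(cfg)
  cfg
}

validate_tether_config <- function(cfg) {
  rows <- cfg$frame_shape[1]; cols <- cfg$frame_shape[2]
  bottom <- cfg$tether_top + cfg$tether_length_px - 1L
  if (cfg$tether_top < 1L || bottom > rows)
    stop_loopx("tether does not fit inside frame_shape", "loopx_bad_config")
  if (cfg$axis_col < 1L || cfg$axis_col > cols)
    stop_loopx("axis_col outside frame", "loopx_bad_config")
  t_end <- cfg$n_frames * cfg$frame_interval
  evs <- cfg$loop_events
  for (ev in evs) {
    if (!inherits(ev, "loop_event"))
      stop_loopx("loop_events must be loop_event objects", "loopx_bad_config")
    if (ev$t_start > t_end)
      stop_loopx("loop event starts after the acquisition ends",
                 "loopx_bad_config")
    if (ev$max_loop > cfg$total_dna)
      stop_loopx("loop DNA would exceed the substrate total",
                 "loopx_bad_config")
  }
  if (length(evs) > 1L) {
    iv <- t(vapply(evs, event_interval, numeric(2)))
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (any(iv[-nrow(iv), 2] > iv[-1, 1]))
      stop_loopx(
        "loop events overlap in time; the single-loop model allows one loop at a time",
        "loopx_bad_config")
  }
  invisible(cfg)
}

# normalised, symmetric 1-D Gaussian kernel (sums to 1)
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- ceiling(6 * sigma)
  g <- dnorm(seq(-h, h), sd = sigma)
  g / sum(g)
}

# place kernel `g` (odd length) centred at `center` on a zero vector of
# length n, scaled by `mass`; out-of-range kernel mass is dropped
place_kernel <- function(n, center, g, mass) {
  out <- numeric(n)
  h <- (length(g) - 1L) %/% 2L
  idx <- (center - h):(center + h)
  keep <- idx >= 1L & idx <= n
  out[idx[keep]] <- g[keep] * mass
  out
}

#' Simulate a tether movie with ground truth
#'
#' Renders each frame as a Gaussian-blurred vertical line whose local
#' intensity is proportional to local DNA density.  An active loop event
#' appears as a punctum at the anchor row carrying an intensity fraction
#' exactly equal to its DNA fraction; the visible non-looped DNA segments
#' above and below keep their linear density and shorten proportionally
#' toward the loop as DNA is reeled in (the slack, no-flow imaging
#' condition used for rate measurement), so total pre-noise frame
#' intensity is invariant over time.  Shot and read noise are applied
#' last.
#'
#' @param config a [tether_sim_config()].
#' @return a list with `series` (an `image_series`: frames
#'   `rows x cols x n_frames`, plus frame interval) and `truth` (a
#'   `ground_truth` data frame of per-frame `up_kbp`, `loop_kbp`,
#'   `down_kbp`, `loop_center_row`, with the pre-noise line and punctum
#'   photon stacks attached as attributes `clean_line` and
#'   `clean_punctum`, and `has_loop` as an attribute).
#' @export
simulate_tether_movie <- function(config) {
  stopifnot(inherits(config, "tether_sim_config"))
  validate_tether_config(config)
  rows <- config$frame_shape[1]; cols <- config$frame_shape[2]
  n <- config$n_frames
  L <- config$tether_length_px
  top <- config$tether_top; bottom <- top + L - 1L
  times <- seq_len(n) * config$frame_interval
  g <- gauss_kernel(config$psf_sigma)
  hprof <- place_kernel(cols, config$axis_col, g, 1)

  loop_kbp <- numeric(n); up_kbp <- numeric(n); down_kbp <- numeric(n)
  center_row <- rep(NA_integer_, n)
  anchor_frac <- rep(NA_real_, n)
  for (ev in config$loop_events) {
    l <- event_loop_kbp(ev, times)
    act <- l > 0
    loop_kbp[act] <- l[act]
    anchor_frac[act] <- ev$anchor_pos
  }
  up_kbp <- ifelse(is.na(anchor_frac), 0,
                   anchor_frac * (config$total_dna - loop_kbp))
  down_kbp <- ifelse(is.na(anchor_frac), 0,
                     (1 - anchor_frac) * (config$total_dna - loop_kbp))
  # frames with no active loop: whole substrate is "up+down" along the line;
  # report it split at the midpoint for bookkeeping (loop_kbp = 0 there)
  noloop <- is.na(anchor_frac)
  up_kbp[noloop] <- config$total_dna / 2
  down_kbp[noloop] <- config$total_dna / 2

  frames <- array(0, dim = c(rows, cols, n))
  clean_line <- array(0, dim = c(rows, cols, n))
  clean_punctum <- array(0, dim = c(rows, cols, n))
  ppk <- config$photons_per_kbp

  dens <- config$total_dna / L  # kbp per row at the resting extension
  for (i in seq_len(n)) {
    rowmass <- numeric(rows)
    if (noloop[i]) {
      rowmass[top:bottom] <- dens
      punct_mass <- 0
    } else {
      # Slack-tether rendering: non-looped DNA keeps its linear density and
      # the visible up/down segments shorten toward the loop as DNA is
      # reeled in, so the punctum window carries (essentially) loop
      # intensity only -- the assumption the intensity-ratio conversion
      # relies on.  Segments stay anchored at the fixed attachment rows.
      a <- anchor_frac[i]
      anchor <- top + as.integer(round(a * (L - 1L)))
      center_row[i] <- anchor
      rowmass <- rowmass + segment_mass(rows, top, +1L, up_kbp[i], dens)
      rowmass <- rowmass + segment_mass(rows, bottom, -1L, down_kbp[i], dens)
      punct_mass <- loop_kbp[i]
    }
    vline <- place_blur(rowmass, g)
    line_img <- outer(vline, hprof) * ppk
    clean_line[, , i] <- line_img
    if (punct_mass > 0) {
      vp <- place_kernel(rows, center_row[i], g, punct_mass)
      punct_img <- outer(vp, hprof) * ppk
      clean_punctum[, , i] <- punct_img
    }
  }
  clean <- clean_line + clean_punctum

  noisy <- with_seed(config$seed, {
    lambda <- clean + config$background_mean
    out <- lambda
    nm <- config$noise_model
    if (isTRUE(nm$poisson))
      out <- array(rpois(length(lambda), lambda), dim = dim(lambda))
    gsd <- nm$gaussian_sd %||% 0
    if (gsd > 0)
      out <- out + array(rnorm(length(out), sd = gsd), dim = dim(out))
    pmax(out, 0)
  })

  series <- structure(list(frames = noisy,
                           frame_interval = config$frame_interval,
                           roi_origin = c(1L, 1L)),
                      class = "image_series")
  truth <- data.frame(frame = seq_len(n), time_s = times,
                      up_kbp = up_kbp, loop_kbp = loop_kbp,
                      down_kbp = down_kbp, loop_center_row = center_row)
  attr(truth, "has_loop") <- any(loop_kbp > 0)
  attr(truth, "clean_line") <- clean_line
  attr(truth, "clean_punctum") <- clean_punctum
  attr(truth, "config") <- config
  class(truth) <- c("ground_truth", "data.frame")
  list(series = series, truth = truth)
}

# constant-density DNA segment of `kbp` starting at `from` and extending in
# direction `dir` (+1 down, -1 up); the last, partial row carries the
# remainder so the total mass is exact
segment_mass <- function(n_rows, from, dir, kbp, dens) {
  out <- numeric(n_rows)
  if (kbp <= 0) return(out)
  len <- kbp / dens
  full <- floor(len)
  rowseq <- from + dir * seq_len(full + 1L) - dir
  rowseq <- rowseq[rowseq >= 1L & rowseq <= n_rows]
  vals <- c(rep(dens, full), dens * (len - full))[seq_along(rowseq)]
  out[rowseq] <- vals
  out
}

# blur a row-mass vector with a symmetric kernel g (mass-conserving while
# the support of m stays >= half-kernel away from both ends)
place_blur <- function(m, g) {
  if (length(g) == 1L) return(m)
  h <- (length(g) - 1L) %/% 2L
  padded <- c(numeric(h), m, numeric(h))
  out <- stats::filter(padded, g, method = "convolution", sides = 2)
  as.numeric(out[(h + 1L):(h + length(m))])
}

#' @export
print.tether_sim_config <- function(x, ...) {
  cat(sprintf(
    "<tether_sim_config> %d frames @ %gs, tether %d px, %g kbp, %d loop event(s), seed %s\n",
    x$n_frames, x$frame_interval, x$tether_length_px, x$total_dna,
    length(x$loop_events), format(x$seed)))
  invisible(x)
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_series> %d frames of %d x %d px, %gs/frame\n",
              d[3], d[1], d[2], x$frame_interval))
  invisible(x)
}

#' Write / read a movie as multi-page 16-bit TIFF
#'
#' Counts are stored as 16-bit unsigned samples (clamped at 65535); reading
#' restores counts on the original scale.
#'
#' @param series an `image_series`.
#' @param path output TIFF path.
#' @return `write_movie_tiff` returns `path` invisibly; `read_movie_tiff`
#'   returns an `image_series`.
#' @export
write_movie_tiff <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  n <- dim(series$frames)[3]
  pages <- lapply(seq_len(n), function(i) {
    m <- series$frames[, , i]
    pmin(pmax(round(m), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param frame_interval seconds per frame to attach on read.
#' @export
read_movie_tiff <- function(path, frame_interval = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]] * 65535
  structure(list(frames = frames, frame_interval = frame_interval,
                 roi_origin = c(1L, 1L)), class = "image_series")
}
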