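# Shared fixtures and independent oracles (kept deliberately naive).

# wrap a bare matrix as a kymograph object
make_kymo <- function(m, frame_interval = 1, axis_col = 1L,
                      band_half_width = 0L) {
  structure(list(matrix = m, frame_interval = frame_interval,
                 axis_col = as.integer(axis_col),
                 band_half_width = as.integer(band_half_width)),
            class = "kymograph")
}

# wrap a frame stack as an image series
make_series <- function(frames, frame_interval = 1) {
  structure(list(frames = frames, frame_interval = frame_interval,
                 roi_origin = c(1L, 1L)), class = "image_series")
}

# 12-point log-spaced titration, 0.1-100 uM
titration_concs <- function() 10^seq(log10(0.1), log10(100), length.out = 12)

# disc offsets (Euclidean ball, ties included) for brute-force morphology
disc_offsets_r <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2, ]
}

# brute-force grayscale erosion/dilation with domain-clipped neighbourhood
brute_morph <- function(m, radius, fun) {
  off <- disc_offsets_r(radius)
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- i + off$dr; jj <- j + off$dc
    ok <- ii >= 1 & ii <= nrow(m) & jj >= 1 & jj <= ncol(m)
    out[i, j] <- fun(m[cbind(ii[ok], jj[ok])])
  }
  out
}

brute_tophat <- function(m, radius) {
  m - brute_morph(brute_morph(m, radius, min), radius, max)
}

# interior-pixel disc median by direct enumeration (no border handling)
brute_disc_median_interior <- function(m, radius) {
  off <- disc_offsets_r(radius)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in (1 + radius):(nrow(m) - radius))
    for (j in (1 + radius):(ncol(m) - radius))
      out[i, j] <- median(m[cbind(i + off$dr, j + off$dc)])
  out
}

# independent equilibrium solver for probe binding: solves the mass-action
# quadratic for bound probe B in (C - B)(P - B) = Kd * B by bisection
solve_bound_probe <- function(C, P, kd) {
  vapply(C, function(cc) {
    if (cc == 0) return(0)
    f <- function(B) (cc - B) * (P - B) - kd * B
    uniroot(f, c(0, min(cc, P)), tol = 1e-14)$root
  }, numeric(1))
}

# default simulated looping event for pipeline-level tests
std_loop_event <- function(rate = 1, t_start = 5, anchor = 0.5,
                           max_loop = 30) {
  loop_event(t_start = t_start, rate = rate, anchor_pos = anchor,
             max_loop = max_loop)
}

# simulate + quantify one tether; returns list(q, truth)
sim_and_quantify <- function(seed, events = list(std_loop_event()),
                             n_frames = 45, params = pipeline_config(), ...) {
  cfg <- tether_sim_config(n_frames = n_frames, loop_events = events,
                           seed = seed, ...)
  sim <- simulate_tether_movie(cfg)
  list(q = quantify_tether(sim$series, params), truth = sim$truth)
}

# simulate one experiment of n tethers, k of them with a loop event, and
# return the pipeline's per-tether looped calls
detect_experiment <- function(n, k, seed_base) {
  vapply(seq_len(n), function(i) {
    evs <- if (i <= k) list(std_loop_event()) else list()
    cfg <- tether_sim_config(n_frames = 45, loop_events = evs,
                             seed = seed_base + i)
    quantify_tether(simulate_tether_movie(cfg)$series)$looped
  }, logical(1))
}
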