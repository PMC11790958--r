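#' Build a loop growth curve with a Savitzky-Golay smoothed companion
#'
#' Takes the valid, non-edge frames of a DNA partition series and attaches
#' a Savitzky-Golay smoothed copy of `loop_kbp` (order 2, 50-point window
#' by default).  Smoothing is used only to locate the monotone fit window
#' and for display; rate fits always use the raw values.  An even
#' requested window is rounded down to the nearest odd value, and a window
#' longer than the series is shrunk to the largest odd length that fits
#' (with a warning).
#'
#' @param dna a `dna_partition_series`, or a data frame with `time_s` and
#'   `loop_kbp`.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param sg_window requested window size in points.
#' @return a `loop_growth_curve` data frame (`time_s`, `loop_kbp`,
#'   `smoothed_kbp`).
#' @export
loop_growth_curve <- function(dna, sg_order = 2, sg_window = 50) {
  d <- as.data.frame(dna)
  if (!is.null(d$valid)) d <- d[d$valid, , drop = FALSE]
  if (!is.null(d$edge)) d <- d[!d$edge, , drop = FALSE]
  if (!nrow(d))
    stop_loopx("no valid frames to build a growth curve", "loopx_no_curve")
  d <- d[order(d$time_s), , drop = FALSE]
  if (any(diff(d$time_s) <= 0))
    stop_loopx("time must be strictly increasing", "loopx_bad_curve")
  n <- nrow(d)
  w <- min(sg_window, n)
  if (w %% 2 == 0) w <- w - 1L
  if (w < sg_window && sg_window <= n)
    w <- sg_window - 1L  # even request rounded down
  if (sg_window > n)
    warning(sprintf(
      "Savitzky-Golay window %d longer than series (%d points); using %d",
      sg_window, n, w))
  smoothed <- if (w >= sg_order + 2 && w >= 3)
    signal::sgolayfilt(d$loop_kbp, p = sg_order, n = w)
  else d$loop_kbp
  out <- data.frame(time_s = d$time_s, loop_kbp = d$loop_kbp,
                    smoothed_kbp = smoothed)
  structure(out, sg_order = sg_order, sg_window = w,
            class = c("loop_growth_curve", "data.frame"))
}

#' Choose the linear fit window on a loop growth curve
#'
#' Returns the earliest window of `window_s` seconds, starting at or after
#' loop initiation (the first point of the curve with positive loop
#' size), within which
#' the smoothed curve is non-decreasing up to a noise tolerance
#' (individual smoothed decrements of at most `drop_tol` kbp are allowed).
#' Events with no monotone window are excluded from rate analysis.
#'
#' @param curve a [loop_growth_curve()].
#' @param window_s window length in seconds (default 5).
#' @param drop_tol largest tolerated smoothed decrement (kbp).
#' @return numeric `c(t0, t0 + window_s)`.
#' @export
choose_fit_window <- function(curve, window_s = 5, drop_tol = 0.5) {
  stopifnot(inherits(curve, "loop_growth_curve"))
  tt <- curve$time_s; s <- curve$smoothed_kbp
  pos <- which(curve$loop_kbp > 0)
  if (!length(pos))
    stop_loopx("no loop initiation detected", "loopx_no_monotone_window")
  # initiation = the point growth begins: the last zero before the curve
  # turns positive (or the first point of an already-positive curve)
  t_init <- tt[max(pos[1] - 1L, 1L)]
  starts <- tt[tt >= t_init & tt <= max(tt) - window_s]
  for (t0 in starts) {
    in_win <- tt >= t0 & tt <= t0 + window_s
    if (sum(in_win) < 3) next
    incr <- diff(s[in_win])
    grows <- s[in_win][sum(in_win)] - s[in_win][1] > 1e-6
    if (all(incr >= -drop_tol) && grows) return(c(t0, t0 + window_s))
  }
  stop_loopx(
    sprintf("no monotone %gs window found; event excluded from rate analysis",
            window_s), "loopx_no_monotone_window")
}

#' Fit the loop-extrusion rate over a time window
#'
#' Ordinary least squares of the raw (unsmoothed) loop size against time,
#' `loop_kbp = k * t + c`, over the chosen window.  `k` is the extrusion
#' rate in kbp/s.
#'
#' @param curve a [loop_growth_curve()].
#' @param window numeric `c(t0, t1)` from [choose_fit_window()].
#' @return a `rate_estimate`: list with `k` (kbp/s), `c` (kbp),
#'   `window`, `r_squared`, `n_points`.
#' @export
fit_rate <- function(curve, window) {
  stopifnot(inherits(curve, "loop_growth_curve"), length(window) == 2)
  sel <- curve$time_s >= window[1] & curve$time_s <= window[2]
  if (sum(sel) < 3)
    stop_loopx("fewer than 3 raw points in the fit window",
               "loopx_too_few_points")
  d <- curve[sel, ]
  fit <- lm(loop_kbp ~ time_s, data = d)
  ssr <- sum(residuals(fit)^2)
  ssy <- sum((d$loop_kbp - mean(d$loop_kbp))^2)
  structure(list(k = unname(coef(fit)[2]), c = unname(coef(fit)[1]),
                 window = window,
                 r_squared = if (ssy > 0) 1 - ssr / ssy else 1,
                 n_points = sum(sel)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> k = %.3f kbp/s (c = %.2f kbp, r2 = %.3f, %d pts in [%g, %g] s)\n",
    x$k, x$c, x$r_squared, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' Rate estimation for one quantified tether
#'
#' Builds the growth curve, picks the monotone window and fits the rate;
#' when the event is excluded (no monotone window, too few points) a
#' `loop_rate_excluded` record carrying the reason is returned instead.
#'
#' @param dna a `dna_partition_series`.
#' @param params a [pipeline_config()] list.
#' @return a `rate_estimate`, or a `loop_rate_excluded` list with
#'   element `reason`.
#' @export
estimate_loop_rate <- function(dna, params = pipeline_config()) {
  tryCatch({
    curve <- loop_growth_curve(dna, sg_order = params$sg_order,
                               sg_window = params$sg_window)
    w <- choose_fit_window(curve, window_s = params$fit_window_s,
                           drop_tol = params$monotone_drop_tol)
    fit_rate(curve, w)
  }, loopx_error = function(e)
    structure(list(reason = conditionMessage(e)),
              class = "loop_rate_excluded"))
}

#' Summarise looping activity of one experiment
#'
#' The fraction of looped DNA is the number of double-tethered DNA
#' molecules showing at least one loop event during the acquisition,
#' divided by the number of molecules analysed.
#'
#' @param tether_results logical vector, one element per tether
#'   (`TRUE` = at least one accepted loop track).
#' @param experiment_id label.
#' @param acquisition_span acquisition time in seconds (default 1000,
#'   including the initial flow phase).
#' @return a `looping_summary` list.
#' @export
fraction_looped <- function(tether_results, experiment_id = "exp",
                            acquisition_span = 1000) {
  if (!length(tether_results))
    stop_loopx("no tethers supplied", "loopx_empty_group")
  stopifnot(is.logical(tether_results))
  n <- length(tether_results); k <- sum(tether_results)
  structure(list(experiment_id = experiment_id, n_tethers = n,
                 n_looped = k, fraction_looped = k / n,
                 acquisition_span = acquisition_span),
            class = "looping_summary")
}

#' @export
print.looping_summary <- function(x, ...) {
  cat(sprintf("<looping_summary> %s: %d/%d tethers looped (%.1f%%) in %gs\n",
              x$experiment_id, x$n_looped, x$n_tethers,
              100 * x$fraction_looped, x$acquisition_span))
  invisible(x)
}

#' Two-sample Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' The statistic is the rank sum of the first sample (mid-ranks under
#' ties).  When the combined sample size is at most `exact_max_n` the
#' two-sided p-value is computed by full enumeration of all assignments of
#' the observed (possibly tied) ranks, `p = min(1, 2 * min(P(W <= w),
#' P(W >= w)))`; otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max_n largest combined n for exact enumeration.
#' @return list with `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
ranksum_test <- function(x, y, exact_max_n = 10) {
  if (!length(x) || !length(y))
    stop_loopx("both groups must be non-empty", "loopx_empty_group")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (N <= exact_max_n) {
    sums <- combn(N, n1, FUN = function(i) sum(r[i]))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(sums <= w + eps), mean(sums >= w - eps)))
    method <- "exact enumeration"
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = w, p_value = p, method = method)
}

#' Compare per-experiment looped fractions between conditions
#'
#' Applies the non-parametric Wilcoxon rank-sum test ([ranksum_test()]),
#' appropriate for the small number of independent experiments per
#' condition.  With more than two groups all pairwise comparisons are
#' returned.
#'
#' @param groups list of two or more numeric vectors of per-experiment
#'   fractions.
#' @return for two groups, the [ranksum_test()] result; otherwise a data
#'   frame of pairwise results.
#' @export
compare_fractions <- function(groups) {
  check_groups(groups, min_groups = 2, min_size = 1)
  if (length(groups) == 2)
    return(ranksum_test(groups[[1]], groups[[2]]))
  pairwise_table(groups, function(a, b) ranksum_test(a, b))
}

#' Welch's unequal-variance t-test between rate groups
#'
#' Unpaired, two-tailed t-test with the Welch-Satterthwaite degrees of
#' freedom.  Groups in which every observation is identical (zero variance
#' in both samples) are rejected with an explicit error rather than
#' silently inflating the variance.
#'
#' @param groups list of two or more numeric vectors (each of length >= 2).
#' @return for two groups, a list with `statistic`, `df`, `p_value`;
#'   otherwise a data frame of pairwise results.
#' @export
compare_rates <- function(groups) {
  check_groups(groups, min_groups = 2, min_size = 2)
  if (length(groups) == 2)
    return(welch_t(groups[[1]], groups[[2]]))
  pairwise_table(groups, welch_t)
}

welch_t <- function(x, y) {
  if (var(x) == 0 && var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(statistic = 0, df = length(x) + length(y) - 2,
                  p_value = 1))
    stop_loopx(
      "both groups have zero variance; Welch's t is undefined for degenerate input",
      "loopx_degenerate_groups")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

check_groups <- function(groups, min_groups, min_size) {
  if (!is.list(groups) || length(groups) < min_groups)
    stop_loopx(sprintf("need at least %d groups", min_groups),
               "loopx_empty_group")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < min_size))
    stop_loopx(sprintf("every group needs >= %d observations", min_size),
               "loopx_empty_group")
  invisible(TRUE)
}

pairwise_table <- function(groups, f) {
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  idx <- combn(length(groups), 2)
  do.call(rbind, lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    r <- f(groups[[i]], groups[[j]])
    data.frame(group1 = nm[i], group2 = nm[j],
               statistic = r$statistic, p_value = r$p_value)
  }))
}
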