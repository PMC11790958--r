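#' Estimate an ATPase rate from a phosphate time course
#'
#' Ordinary least squares slope of phosphate signal against time over a
#' steady-state window.  By default the window is found automatically:
#' the sampling noise is first estimated robustly from second differences
#' of the trace, and the longest contiguous window (earliest on ties, at
#' least `min_points` samples) whose linear-fit RMSE stays within
#' `tol_sd` times that noise level is used.  This excludes an initial lag
#' phase, because windows straddling the lag kink have residuals far
#' above the noise floor.  If no window is acceptably linear the full
#' trace is fitted and the result flagged.  The slope is reported both as
#' uM phosphate/min and normalised by the enzyme concentration (ATP per
#' enzyme per minute).
#'
#' @param trace a `phosphate_trace` (see [simulate_atpase_trace()] or
#'   [read_atpase_csv()]).
#' @param window optional fixed window `c(t0, t1)` in seconds, overriding
#'   the automatic search.
#' @param tol_sd linearity tolerance: largest accepted ratio of fit RMSE
#'   to the estimated sampling noise.
#' @param min_points minimum samples per window (>= 5).
#' @return an `atpase_rate`: list with `rate_uM_min`,
#'   `rate_per_enzyme_min`, `slope_se`, `window` (s), `r_squared`,
#'   `n_points`, `linearity_ok`.
#' @export
estimate_rate <- function(trace, window = NULL, tol_sd = 1.5,
                          min_points = 5) {
  d <- as.data.frame(trace)
  stopifnot(all(c("time_s", "signal_uM") %in% names(d)))
  if (any(diff(d$time_s) <= 0))
    stop_loopx("time must be strictly increasing", "loopx_bad_curve")
  enzyme <- attr(trace, "enzyme_conc_nM", exact = TRUE) %||% NA_real_
  t_min <- d$time_s / 60
  n <- nrow(d)
  if (!is.null(window)) {
    sel <- d$time_s >= window[1] & d$time_s <= window[2]
    if (sum(sel) < min_points)
      stop_loopx("fewer than min_points samples in the fixed window",
                 "loopx_too_few_points")
    best <- range(which(sel))
    ok <- TRUE
    r2b <- window_r2(t_min, d$signal_uM, best[1], best[2])
  } else {
    if (n < min_points)
      stop_loopx("trace too short", "loopx_too_few_points")
    # robust per-sample noise from second differences (kink-insensitive)
    d2 <- diff(d$signal_uM, differences = 2)
    sigma <- stats::mad(d2) / sqrt(6)
    rmse_max <- max(tol_sd * sigma, 1e-12)
    best <- NULL; ok <- FALSE
    for (len in seq(n, min_points)) {
      for (s in seq_len(n - len + 1L)) {
        if (window_rmse(t_min, d$signal_uM, s, s + len - 1L) <= rmse_max) {
          best <- c(s, s + len - 1L)
          break
        }
      }
      if (!is.null(best)) { ok <- TRUE; break }
    }
    if (is.null(best)) best <- c(1L, n)  # no linear window: flagged
    r2b <- window_r2(t_min, d$signal_uM, best[1], best[2])
  }
  idx <- best[1]:best[2]
  fit <- lm(d$signal_uM[idx] ~ t_min[idx])
  slope <- unname(coef(fit)[2])
  # noiseless traces fit exactly; the "essentially perfect fit" caveat of
  # summary.lm is expected there and the SE is legitimately ~0
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[2, 2]),
                 error = function(e) NA_real_)
  structure(list(
    rate_uM_min = slope,
    rate_per_enzyme_min = if (is.finite(enzyme)) slope * 1000 / enzyme
                          else NA_real_,
    slope_se = se,
    window = d$time_s[best], r_squared = r2b, n_points = length(idx),
    linearity_ok = ok), class = "atpase_rate")
}

# RMSE of the linear fit of y ~ t over samples s..e
window_rmse <- function(t, y, s, e) {
  fit <- lsfit(t[s:e], y[s:e])
  sqrt(mean(fit$residuals^2))
}

# r^2 of signal ~ time over samples s..e; flat (zero-variance) signal on
# any window is perfectly explained by a zero slope
window_r2 <- function(t, y, s, e) {
  yy <- y[s:e]; tt <- t[s:e]
  ssy <- sum((yy - mean(yy))^2)
  if (ssy == 0) return(1)
  fit <- lsfit(tt, yy)
  1 - sum(fit$residuals^2) / ssy
}

#' @export
print.atpase_rate <- function(x, ...) {
  cat(sprintf(
    "<atpase_rate> %.3g uM/min (%.3g ATP enzyme^-1 min^-1), r2 = %.4f over [%g, %g] s%s\n",
    x$rate_uM_min, x$rate_per_enzyme_min, x$r_squared,
    x$window[1], x$window[2],
    if (x$linearity_ok) "" else " [linearity flag]"))
  invisible(x)
}

#' DNA fold-stimulation of the ATPase rate
#'
#' Divides the ATPase rate at each DNA concentration by the rate without
#' DNA.  Relative uncertainties of numerator and baseline are propagated
#' in quadrature.
#'
#' @param rates_by_dna data frame with columns `dna_conc`, `rate` and
#'   optionally `se`; must contain a `dna_conc == 0` baseline with a
#'   positive rate.
#' @return a `fold_stimulation_curve` data frame (`dna_conc`, `fold`,
#'   `fold_se`).
#' @export
fold_stimulation <- function(rates_by_dna) {
  d <- as.data.frame(rates_by_dna)
  stopifnot(all(c("dna_conc", "rate") %in% names(d)))
  base <- d[d$dna_conc == 0, , drop = FALSE]
  if (nrow(base) != 1 || !is.finite(base$rate) || base$rate <= 0)
    stop_loopx("need exactly one dna_conc = 0 baseline with rate > 0",
               "loopx_missing_baseline")
  if (is.null(d$se)) d$se <- NA_real_
  fold <- d$rate / base$rate
  rel <- sqrt((d$se / d$rate)^2 + (base$se / base$rate)^2)
  fold_se <- abs(fold) * rel
  fold_se[d$dna_conc == 0] <- 0  # baseline fold is 1 by construction
  fold[d$dna_conc == 0] <- 1
  out <- data.frame(dna_conc = d$dna_conc, fold = fold, fold_se = fold_se)
  out <- out[order(out$dna_conc), ]
  rownames(out) <- NULL
  structure(out, class = c("fold_stimulation_curve", "data.frame"))
}

#' Compare ATPase rates between conditions
#'
#' Welch's unpaired two-tailed t-test, shared with the loop-extrusion
#' rate comparison ([compare_rates()]).
#'
#' @inheritParams compare_rates
#' @return see [compare_rates()].
#' @export
compare_conditions <- function(groups) compare_rates(groups)

#' Read an ATPase trace CSV
#'
#' Columns `time_s`, `signal_uM` (or raw `signal` plus a linear
#' `calibration` factor in uM per signal unit), and optional metadata
#' columns `enzyme_nM`, `dna_nM`, `condition` (constant per file).
#'
#' @param path CSV path.
#' @param calibration linear absorbance-to-phosphate factor applied to a
#'   `signal` column when `signal_uM` is absent.
#' @return a `phosphate_trace` data frame.
#' @export
read_atpase_csv <- function(path, calibration = 1) {
  d <- read.csv(path)
  if (!"signal_uM" %in% names(d)) {
    stopifnot("signal" %in% names(d))
    d$signal_uM <- d$signal * calibration
  }
  out <- data.frame(time_s = d$time_s, signal_uM = d$signal_uM)
  attr(out, "enzyme_conc_nM") <- if ("enzyme_nM" %in% names(d))
    d$enzyme_nM[1] else NA_real_
  attr(out, "dna_conc_nM") <- if ("dna_nM" %in% names(d)) d$dna_nM[1] else 0
  attr(out, "condition") <- if ("condition" %in% names(d))
    as.character(d$condition[1]) else "unknown"
  class(out) <- c("phosphate_trace", "data.frame")
  out
}
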