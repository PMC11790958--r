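#' Exact ligand-depletion fluorescence-polarisation binding model
#'
#' Closed-form mass-action solution for the polarisation change when a
#' fixed concentration of labelled probe peptide is titrated with
#' receptor, valid when the probe concentration is not negligible
#' relative to Kd (so the free receptor concentration is depleted by
#' binding):
#'
#' \deqn{FP = \frac{FP_{max}}{2[Pep]}\left(([C]+[Pep]+K_d) -
#'   \sqrt{([C]+[Pep]+K_d)^2 - 4[C][Pep]}\right)}
#'
#' The term under the square root can round off to a tiny negative value
#' near saturation; it is clamped at zero.
#'
#' @param c receptor concentration(s), uM (>= 0; vectorised).
#' @param pep probe concentration, uM (> 0).
#' @param kd equilibrium dissociation constant, uM (> 0).
#' @param fp_max polarisation change at saturation, mP.
#' @return polarisation change(s) in mP.
#' @export
fp_model <- function(c, pep, kd, fp_max) {
  if (length(pep) != 1 || pep <= 0)
    stop_loopx("probe concentration must be a single value > 0",
               "loopx_bad_model_input")
  if (kd <= 0)
    stop_loopx("kd must be > 0", "loopx_bad_model_input")
  if (any(c < 0))
    stop_loopx("receptor concentrations must be >= 0",
               "loopx_bad_model_input")
  s <- c + pep + kd
  disc <- pmax(s^2 - 4 * c * pep, 0)
  (fp_max / (2 * pep)) * (s - sqrt(disc))
}

#' Fit Kd and FPmax to a titration
#'
#' Nonlinear least squares of [fp_model()] over `(kd, fp_max)`.  By
#' default the fit runs on per-concentration replicate means with
#' inverse-variance weights from the replicate SDs; when replicate SDs
#' are unavailable or degenerate (fewer than 2 replicates, or a
#' near-zero SD at any concentration) the fit falls back to unweighted
#' means.  Starting values are `kd0` = the mid-titration concentration
#' and `fp_max0` = the largest observed mean, with `kd` bounded in
#' `[1e-4, 1e4]` uM.
#'
#' @param data a `titration_data` (from [simulate_fp_plate()] or
#'   [read_fp_csv()]), or a data frame with columns `receptor_conc_uM`
#'   and `fp_mP` plus attribute `probe_conc_uM`.
#' @param probe_conc probe concentration (uM); defaults to the
#'   `probe_conc_uM` attribute of `data`.
#' @param weighted use inverse-variance weights (default `TRUE`).
#' @return a `binding_fit`: list with `kd`, `fp_max`, `kd_se`,
#'   `fp_max_se`, `converged`, `residuals`, `data` (the per-concentration
#'   means), `message`.
#' @export
fit_kd <- function(data, probe_conc = NULL, weighted = TRUE) {
  d <- as.data.frame(data)
  probe_conc <- probe_conc %||% attr(data, "probe_conc_uM", exact = TRUE)
  if (is.null(probe_conc))
    stop_loopx("probe concentration not supplied", "loopx_bad_model_input")
  stopifnot(all(c("receptor_conc_uM", "fp_mP") %in% names(d)))
  if (!all(is.finite(d$fp_mP)))
    stop_loopx("non-finite FP readings", "loopx_bad_model_input")
  agg <- aggregate(fp_mP ~ receptor_conc_uM, data = d,
                   FUN = function(v) c(m = mean(v), s = sd(v), n = length(v)))
  means <- data.frame(receptor_conc_uM = agg$receptor_conc_uM,
                      fp_mean = agg$fp_mP[, "m"],
                      fp_sd = agg$fp_mP[, "s"],
                      n = agg$fp_mP[, "n"])
  if (length(unique(means$receptor_conc_uM)) < 4)
    stop_loopx("need at least 4 distinct receptor concentrations",
               "loopx_bad_model_input")
  w <- rep(1, nrow(means))
  if (weighted && all(means$n >= 2) && all(is.finite(means$fp_sd)) &&
      all(means$fp_sd > 1e-8)) {
    w <- 1 / means$fp_sd^2
    w <- w / mean(w)
  }
  pos <- means$receptor_conc_uM[means$receptor_conc_uM > 0]
  kd0 <- exp(mean(log(range(pos))))
  fp0 <- max(means$fp_mean)
  if (!is.finite(fp0) || fp0 <= 0) fp0 <- 1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fp_mean ~ fp_model(receptor_conc_uM, probe_conc, kd, fp_max),
      data = means, start = list(kd = kd0, fp_max = fp0),
      weights = w, lower = c(1e-4, 1e-8), upper = c(1e4, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(kd = NA_real_, fp_max = NA_real_,
                          kd_se = NA_real_, fp_max_se = NA_real_,
                          converged = FALSE, residuals = NULL,
                          data = means,
                          message = conditionMessage(fit)),
                     class = "binding_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  structure(list(kd = unname(cf["kd"]), fp_max = unname(cf["fp_max"]),
                 kd_se = unname(se[1]), fp_max_se = unname(se[2]),
                 converged = fit$convInfo$isConv %||% TRUE,
                 residuals = residuals(fit), data = means,
                 message = "converged"),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (is.na(x$kd)) {
    cat("<binding_fit> fit failed:", x$message, "\n")
  } else {
    cat(sprintf("<binding_fit> Kd = %.3g +/- %.2g uM, FPmax = %.3g +/- %.2g mP%s\n",
                x$kd, x$kd_se, x$fp_max, x$fp_max_se,
                if (isTRUE(x$converged)) "" else " (NOT converged)"))
  }
  invisible(x)
}

#' Analyse an FP competition experiment
#'
#' Subtracts matched background readings from each condition, reports the
#' background-subtracted mean and SD per condition and all pairwise
#' unpaired two-tailed t-test p-values between conditions.
#'
#' @param conditions named list of numeric mP reading vectors, one per
#'   condition (e.g. probe+receptor, plus competitor, etc.).
#' @param backgrounds named list of matched background readings; either
#'   one vector per condition (same names) or a single vector recycled
#'   for all conditions.  Each background vector must have as many
#'   readings as its condition, or length 1.
#' @return a `competition_result` data frame (`condition`, `mean_mP`,
#'   `sd_mP`, `n`) with the pairwise test table in attribute `tests`.
#' @export
analyze_competition <- function(conditions, backgrounds) {
  stopifnot(is.list(conditions), length(conditions) >= 2)
  nm <- names(conditions)
  if (is.null(nm) || any(nm == ""))
    stop_loopx("conditions must be named", "loopx_bad_model_input")
  if (!is.list(backgrounds)) backgrounds <- setNames(
    rep(list(backgrounds), length(conditions)), nm)
  sub <- lapply(nm, function(k) {
    x <- conditions[[k]]
    b <- backgrounds[[k]]
    if (is.null(b))
      stop_loopx(sprintf("no background readings for condition '%s'", k),
                 "loopx_bad_model_input")
    if (!(length(b) %in% c(1L, length(x))))
      stop_loopx(sprintf(
        "background for '%s' has %d readings, condition has %d",
        k, length(b), length(x)), "loopx_mismatched_replicates")
    x - b
  })
  names(sub) <- nm
  if (any(vapply(sub, length, integer(1)) < 2))
    stop_loopx("each condition needs >= 2 readings for testing",
               "loopx_bad_model_input")
  res <- data.frame(condition = nm,
                    mean_mP = vapply(sub, mean, numeric(1)),
                    sd_mP = vapply(sub, sd, numeric(1)),
                    n = vapply(sub, length, integer(1)),
                    row.names = NULL)
  tests <- pairwise_table(sub, function(a, b) {
    ht <- t.test(a, b)
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  })
  structure(res, tests = tests,
            class = c("competition_result", "data.frame"))
}

#' Read / write FP plate CSV
#'
#' Long-format plate files with columns `condition`, `receptor_conc_uM`,
#' `replicate`, `fp_mP` (plus optional `read`).
#'
#' @param path CSV path.
#' @param probe_conc probe concentration (uM) to attach.
#' @return a `titration_data` data frame.
#' @export
read_fp_csv <- function(path, probe_conc) {
  d <- read.csv(path)
  stopifnot(all(c("receptor_conc_uM", "fp_mP") %in% names(d)))
  attr(d, "probe_conc_uM") <- probe_conc
  class(d) <- c("titration_data", "data.frame")
  d
}
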