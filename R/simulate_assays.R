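#' Simulate a fluorescence-polarisation titration plate
#'
#' Generates replicate mP readings from the exact ligand-depletion binding
#' model ([fp_model()]) with i.i.d. Gaussian replicate noise, emulating a
#' plate of technical replicates read on a polarisation plate reader.
#'
#' @param kd ground-truth dissociation constant (uM).
#' @param fp_max ground-truth polarisation change at saturation (mP).
#' @param probe_conc labelled-peptide (probe) concentration (uM), > 0.
#' @param receptor_concs titrated receptor concentrations (uM); may
#'   include 0.
#' @param noise_sd replicate noise SD (mP), >= 0.
#' @param n_replicates technical replicates per concentration.
#' @param seed integer seed.
#' @return a `titration_data` data frame with columns `receptor_conc_uM`,
#'   `replicate`, `fp_mP`; probe concentration and the generating
#'   parameters are attached as attributes.
#' @export
simulate_fp_plate <- function(kd, fp_max, probe_conc, receptor_concs,
                              noise_sd = 2, n_replicates = 3, seed = 1L) {
  stopifnot(kd > 0, fp_max > 0, probe_conc > 0, length(receptor_concs) >= 1,
            all(receptor_concs >= 0), n_replicates >= 1)
  if (noise_sd < 0) stop_loopx("noise_sd must be >= 0", "loopx_bad_config")
  mu <- fp_model(receptor_concs, probe_conc, kd, fp_max)
  d <- with_seed(seed, {
    data.frame(
      receptor_conc_uM = rep(receptor_concs, each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = length(receptor_concs)),
      fp_mP = rep(mu, each = n_replicates) +
        rnorm(length(receptor_concs) * n_replicates, sd = noise_sd))
  })
  attr(d, "probe_conc_uM") <- probe_conc
  attr(d, "truth") <- list(kd = kd, fp_max = fp_max, noise_sd = noise_sd)
  class(d) <- c("titration_data", "data.frame")
  d
}

#' Simulate a phosphate-sensor ATPase time course
#'
#' Expected signal is linear in time with slope `rate` (after an optional
#' lag), with i.i.d. Gaussian noise, emulating an absorbance-based
#' phosphate-release readout already converted to phosphate concentration.
#'
#' @param rate phosphate release rate (uM/min), >= 0.
#' @param enzyme_conc enzyme concentration (nM).
#' @param duration acquisition length (min), > 0.
#' @param sampling sampling interval (s).
#' @param noise_sd signal noise SD (uM).
#' @param lag_min initial lag (min) during which the signal stays at
#'   baseline, to exercise automatic window selection.
#' @param dna_conc DNA concentration (nM) carried as metadata.
#' @param condition label carried as metadata.
#' @param seed integer seed.
#' @return a `phosphate_trace` data frame with columns `time_s`,
#'   `signal_uM` and metadata attributes.
#' @export
simulate_atpase_trace <- function(rate, enzyme_conc = 50, duration = 20,
                                  sampling = 15, noise_sd = 0.05,
                                  lag_min = 0, dna_conc = 0,
                                  condition = "basal", seed = 1L) {
  if (rate < 0) stop_loopx("rate must be >= 0", "loopx_bad_config")
  if (duration <= 0) stop_loopx("duration must be > 0", "loopx_bad_config")
  stopifnot(enzyme_conc > 0, sampling > 0, noise_sd >= 0)
  time_s <- seq(0, duration * 60, by = sampling)
  t_min <- time_s / 60
  mu <- rate * pmax(0, t_min - lag_min)
  sig <- with_seed(seed, mu + rnorm(length(mu), sd = noise_sd))
  d <- data.frame(time_s = time_s, signal_uM = sig)
  attr(d, "enzyme_conc_nM") <- enzyme_conc
  attr(d, "dna_conc_nM") <- dna_conc
  attr(d, "condition") <- condition
  attr(d, "truth") <- list(rate = rate, noise_sd = noise_sd,
                           lag_min = lag_min)
  class(d) <- c("phosphate_trace", "data.frame")
  d
}
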