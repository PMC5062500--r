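# Parametric synthetic-dataset generators for fit validation.

#' Generate a synthetic conductance-voltage dataset
#'
#' Evaluates the Boltzmann activation curve
#' `G(V) = g_max / (1 + exp(-q_a (V - v_half) / kT))` at the requested
#' voltages and adds Gaussian noise, emulating a pooled normalized G-V
#' measurement.
#'
#' @param v_half Half-activation voltage, mV.
#' @param q_a Apparent gating charge, elementary charges.
#' @param g_max Maximal conductance (nS, or 1 for normalized data).
#' @param voltages Voltages at which to evaluate, mV.
#' @param noise_sd Gaussian noise standard deviation, same units as `G`.
#' @param seed Integer RNG seed; the output is seed-reproducible.
#' @param temperature Absolute temperature in kelvin.
#' @return Data frame with columns `voltage_mV`, `conductance`.
#' @examples
#' gv <- generate_gv_dataset(-63, 0.54, 1, seq(-200, 200, by = 20),
#'                           noise_sd = 0.03, seed = 1)
#' @export
generate_gv_dataset <- function(v_half, q_a, g_max, voltages,
                                noise_sd = 0, seed = 1,
                                temperature = .GK_TEMPERATURE_K) {
  stopifnot(length(voltages) >= 1, noise_sd >= 0)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  kT <- kT_mV(temperature)
  g <- g_max / (1 + exp(-q_a * (voltages - v_half) / kT))
  if (noise_sd > 0) g <- g + stats::rnorm(length(g), 0, noise_sd)
  data.frame(voltage_mV = voltages, conductance = g)
}

#' Generate a synthetic dose-response dataset
#'
#' Evaluates the Hill inhibition curve
#' `f(c) = c^n / (c^n + K_D^n)` at the requested concentrations, adds
#' Gaussian noise, and truncates to `[0, 1]`, emulating pooled
#' fraction-inhibited measurements with `reps` patches per concentration.
#'
#' @param k_d Apparent dissociation constant, uM.
#' @param n_hill Hill coefficient.
#' @param concentrations Inhibitor concentrations, uM.
#' @param reps Replicates (patches) per concentration.
#' @param noise_sd Gaussian noise standard deviation (fraction units).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `conc_uM`, `inhibited`.
#' @examples
#' dr <- generate_dose_response(2.2, 2, c(0.5, 1, 2, 5, 10, 20),
#'                              reps = 5, noise_sd = 0.05, seed = 1)
#' @export
generate_dose_response <- function(k_d, n_hill, concentrations, reps = 1,
                                   noise_sd = 0, seed = 1) {
  stopifnot(k_d > 0, n_hill > 0, reps >= 1, noise_sd >= 0)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  conc <- rep(concentrations, each = reps)
  f <- conc^n_hill / (conc^n_hill + k_d^n_hill)
  f[conc == 0] <- 0
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
  data.frame(conc_uM = conc, inhibited = pmin(1, pmax(0, f)))
}
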