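# Simulated replications of the study protocols: each function runs one
# seeded in-silico experiment end to end (simulate -> measure -> fit) and
# returns the recovered quantity. They are the building blocks of the
# package's validation experiments and of the acceptance script.

#' Washout-recovery experiment
#'
#' Emulates recovery from inhibition: a 1000-channel patch is
#' equilibrated with agonist plus inhibitor, the inhibitor is removed at
#' t = 0, and the recovering current (sampled at 20 Hz with additive
#' recording noise) is fitted with a single exponential.
#'
#' @param seed Integer RNG seed.
#' @param scheme A [gating_scheme()]; default [build_default_scheme()].
#' @param oa_uM Inhibitor concentration before washout, uM.
#' @param voltage_mV Holding potential during recovery, mV.
#' @param duration_s Recording length after washout, s.
#' @param noise_frac Recording noise as a fraction of the uninhibited
#'   steady-state current.
#' @return Fitted recovery time constant, s.
#' @export
sim_washout_tau <- function(seed, scheme = build_default_scheme(),
                            oa_uM = 5, voltage_mV = 40, duration_s = 150,
                            noise_frac = 0.02) {
  i_max <- macroscopic_steady_current(scheme, 1000, voltage_mV, 4, 0)
  pr <- protocol(data.frame(duration_s = duration_s,
                            voltage_mV = voltage_mV,
                            capsaicin_uM = 4, oa_uM = 0),
                 sampling_rate = 20, filter_cutoff = 10,
                 noise_sd = noise_frac * abs(i_max), seed = seed,
                 init = list(voltage = voltage_mV, capsaicin = 4,
                             oa = oa_uM))
  tr <- simulate_macroscopic(scheme, 1000, pr)
  tc <- data.frame(t = (seq_along(tr$samples) - 1) * tr$dt, y = tr$samples)
  unname(fit_single_exponential(tc)$params["tau"])
}

#' Closed-state inhibition-onset experiment
#'
#' Emulates the resting-state application protocol: patches are held
#' closed (no agonist, -60 mV) and exposed to the inhibitor for
#' increasing durations; after each exposure a saturating agonist test
#' pulse measures the remaining current. The fraction remaining versus
#' exposure time is fitted with a single exponential.
#'
#' @inheritParams sim_washout_tau
#' @param exposures_s Exposure durations, s.
#' @param test_voltage_mV Voltage of the agonist test pulse, mV.
#' @return Fitted onset time constant, s.
#' @export
sim_closed_onset_tau <- function(seed, scheme = build_default_scheme(),
                                 oa_uM = 5,
                                 exposures_s = seq(0, 15, by = 1.5),
                                 test_voltage_mV = 60,
                                 noise_frac = 0.02) {
  i_max <- macroscopic_steady_current(scheme, 1000, test_voltage_mV, 4, 0)
  cur <- vapply(seq_along(exposures_s), function(i) {
    T <- exposures_s[i]
    segs <- if (T > 0)
      data.frame(duration_s = c(T, 1),
                 voltage_mV = c(-60, test_voltage_mV),
                 capsaicin_uM = c(0, 4), oa_uM = c(oa_uM, 0))
    else
      data.frame(duration_s = 1, voltage_mV = test_voltage_mV,
                 capsaicin_uM = 4, oa_uM = 0)
    pr <- protocol(segs, sampling_rate = 200, filter_cutoff = 100,
                   noise_sd = noise_frac * abs(i_max),
                   seed = seed * 100 + i, init = "C")
    tr <- simulate_macroscopic(scheme, 1000, pr)
    mean(utils::tail(tr$samples, 100))  # last 0.5 s of the test pulse
  }, numeric(1))
  fr <- as.numeric(fraction_remaining(cur, cur[1]))
  unname(fit_single_exponential(data.frame(t = exposures_s,
                                           y = fr))$params["tau"])
}

#' Open-state inhibition-onset experiment
#'
#' Emulates co-application to open channels: a 1000-channel patch is held
#' at a depolarized potential with saturating agonist, the inhibitor is
#' co-applied at t = 0, and the decaying current is fitted with a single
#' exponential.
#'
#' @inheritParams sim_washout_tau
#' @param baseline_s Agonist-only baseline before co-application, s.
#' @param oa_s Co-application window used for the fit, s.
#' @return Fitted onset time constant, s.
#' @export
sim_open_onset_tau <- function(seed, scheme = build_default_scheme(),
                               oa_uM = 5, voltage_mV = 60,
                               baseline_s = 10, oa_s = 40,
                               noise_frac = 0.02) {
  i_max <- macroscopic_steady_current(scheme, 1000, voltage_mV, 4, 0)
  segs <- data.frame(duration_s = c(baseline_s, oa_s),
                     voltage_mV = voltage_mV,
                     capsaicin_uM = 4, oa_uM = c(0, oa_uM))
  pr <- protocol(segs, sampling_rate = 20, filter_cutoff = 10,
                 noise_sd = noise_frac * abs(i_max), seed = seed)
  tr <- simulate_macroscopic(scheme, 1000, pr)
  ts <- (seq_along(tr$samples) - 1) * tr$dt
  sel <- ts >= baseline_s
  tc <- data.frame(t = ts[sel] - baseline_s, y = tr$samples[sel])
  unname(fit_single_exponential(tc)$params["tau"])
}

#' Single-channel open-probability decline experiment
#'
#' Emulates the single-channel time course of inhibition: for each of
#' `n_patches` one-channel patches, 40 consecutive 1.2 s sweeps are
#' simulated at +120 mV with saturating agonist while the inhibitor is
#' present from t = 0 (the channel starts from the uninhibited stationary
#' state). Each patch is idealized by half-amplitude threshold crossing;
#' the per-sweep open probabilities of all patches are pooled into one
#' time course (replicate sweeps share their application time) and
#' fitted with a single exponential through [po_timecourse()]. Pooling
#' many simulated patches keeps the ensemble relaxation estimate stable;
#' a wet-lab study must make do with the few one-channel patches it
#' obtains, at the cost of estimator precision.
#'
#' @inheritParams sim_washout_tau
#' @param n_patches One-channel patches averaged per experiment.
#' @param n_sweeps Consecutive 1.2 s sweeps per patch.
#' @param voltage_mV Holding potential, mV.
#' @param noise_sd_pA Recording noise, pA.
#' @return Fitted time constant of the open-probability decline, s.
#' @export
sim_po_decline_tau <- function(seed, scheme = build_default_scheme(),
                               oa_uM = 5, n_patches = 48, n_sweeps = 40,
                               voltage_mV = 120, noise_sd_pA = 1) {
  sweep_s <- 1.2
  sweep_mid <- (seq_len(n_sweeps) - 1) * sweep_s + sweep_s / 2
  all_events <- list()
  all_times <- numeric(0)
  for (p in seq_len(n_patches)) {
    pr <- protocol(data.frame(duration_s = n_sweeps * sweep_s,
                              voltage_mV = voltage_mV,
                              capsaicin_uM = 4, oa_uM = oa_uM),
                   sampling_rate = 5000, filter_cutoff = 2000,
                   noise_sd = noise_sd_pA, seed = seed * 100 + p,
                   init = list(voltage = voltage_mV, capsaicin = 4, oa = 0))
    rec <- simulate_single_channel(scheme, pr)
    levels <- estimate_levels(rec$trace)
    sweeps <- chop_trace(rec$trace, sweep_s)
    evs <- lapply(sweeps, idealize_half_threshold, levels = levels)
    all_events <- c(all_events, evs)
    all_times <- c(all_times, sweep_mid)
  }
  ord <- order(all_times)
  ptc <- po_timecourse(all_events[ord], all_times[ord])
  unname(ptc$fit$params["tau"])
}

#' Steady-state ensemble current at a condition
#'
#' Convenience: `n x g_open x P_open x (V - E_rev)` from the stationary
#' distribution; used to scale recording noise and normalize simulated
#' inhibition experiments.
#'
#' @inheritParams stationary_distribution
#' @param n_channels Channel count.
#' @return Current in pA.
#' @export
macroscopic_steady_current <- function(scheme, n_channels, voltage,
                                       capsaicin, oa) {
  sd <- stationary_distribution(scheme, voltage, capsaicin, oa)
  if (is.na(sd$p_open)) stop("stationary distribution is not unique here")
  g <- sum(sd$pi * scheme$conductance)
  n_channels * g * (voltage - scheme$e_rev) / 1000
}

#' Dose-response parameter-recovery experiment
#'
#' Generates one noisy synthetic dose-response dataset at the study's
#' fitted Hill parameters (K_D = 2.2 uM, n = 2 by default; 5 replicates
#' at each of 6 concentrations spanning 0.5-20 uM, 5% Gaussian noise)
#' and refits it.
#'
#' @param seed Integer RNG seed.
#' @param k_d,n_hill True Hill parameters used to generate.
#' @param concentrations Tested concentrations, uM.
#' @param reps Replicates per concentration.
#' @param noise_sd Gaussian noise s.d. (fraction units).
#' @return Named vector with fitted `k_d` and `n_hill`.
#' @export
sim_dose_recovery <- function(seed, k_d = 2.2, n_hill = 2,
                              concentrations = c(0.5, 1, 2, 5, 10, 20),
                              reps = 5, noise_sd = 0.05) {
  dr <- generate_dose_response(k_d, n_hill, concentrations, reps = reps,
                               noise_sd = noise_sd, seed = seed)
  fit_hill(dr)$params
}

#' Conductance-voltage parameter-recovery experiment
#'
#' Generates one noisy synthetic normalized G-V dataset at the study's
#' no-inhibitor Boltzmann parameters (V_half = -63 mV, q_a = 0.54 e0 by
#' default; 21 voltages from -200 to +200 mV, 3% Gaussian noise) and
#' refits it.
#'
#' @param seed Integer RNG seed.
#' @param v_half,q_a,g_max True Boltzmann parameters used to generate.
#' @param voltages Test potentials, mV.
#' @param noise_sd Gaussian noise s.d. (conductance units).
#' @return Named vector with fitted `g_max`, `v_half`, `q_a`.
#' @export
sim_gv_recovery <- function(seed, v_half = -63, q_a = 0.54, g_max = 1,
                            voltages = seq(-200, 200, by = 20),
                            noise_sd = 0.03) {
  gv <- generate_gv_dataset(v_half, q_a, g_max, voltages,
                            noise_sd = noise_sd, seed = seed)
  fit_boltzmann(gv)$params
}
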