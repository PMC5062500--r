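# gatekin

Markov gating simulation and kinetic analysis of allosteric ion-channel
inhibition, built around a concrete biophysical case: the inhibition of
the capsaicin receptor TRPV1 by oleic acid (OA), a monounsaturated fatty
acid that stabilizes the channel's closed state. The package is aimed at
ion-channel biophysicists who want a tested, reproducible version of the
standard single-channel and macroscopic analysis chain — and a simulator
realistic enough to validate every stage of that chain without
laboratory data.

## What it does

**Simulation (synthetic data).** A continuous-time Markov scheme with
states C, O, C·OA and C·OA₂ (only O conducts, 90 pS) drives exact-jump
(Gillespie) single-channel trajectories and deterministic ensemble
currents under arbitrary voltage/agonist/inhibitor protocols. Traces are
converted to pA, low-pass filtered (Gaussian kernel at the stated −3 dB
cutoff) and given Gaussian recording noise; the true dwell sequence is
returned alongside every simulated trace as ground truth. The C⇌O
equilibrium follows a Boltzmann law

    K(V) = exp(q_a (V − V_1/2) / kT),   q_a = 0.54 e0,  V_1/2 = −63 mV

at saturating (4 μM) capsaicin; OA binds closed conformations and is
captured from the open state through an effective voltage-dependent
pathway. The three free association constants are not hand-tuned: they
are solved (deterministically) so that, at 5 μM OA, inhibition develops
with τ = 2.9 s from rest, the open-probability relaxation has τ = 6.2 s
at +120 mV and 7.7 s at +60 mV, and washout recovers with τ = 38.8 s
(per-site unbinding 1/38.8 s⁻¹).

**Analysis.**

* half-amplitude threshold idealization (`estimate_levels`,
  `idealize_half_threshold`), per-sweep open probability, multichannel
  patch detection;
* logarithmic (Sine–Sigworth) dwell-time histograms and weighted
  least-squares fits of two- or three-exponential mixtures, with an
  explicit component-count rule (`build_log_histogram`,
  `fit_exponential_mixture`, `select_component_count`);
* Boltzmann conductance–voltage fits `G(V) = G_max / (1 + exp(−q_a (V −
  V_1/2)/kT))`, Hill dose–response fits `f(c) = cⁿ/(cⁿ + K_Dⁿ)`,
  single-exponential inhibition/recovery time courses, Ohm's-law
  conductance and fraction-remaining normalization;
* closed-state stabilization energetics `ΔΔG = q_a · ΔV_1/2`
  (`closed_state_energy`);
* replicate-group statistics (mean ± s.e.m., Welch t-tests) and a
  config-driven, fully seeded `run_pipeline` with artifact persistence;
* one-command in-silico replications of the study protocols
  (`sim_washout_tau`, `sim_closed_onset_tau`, `sim_open_onset_tau`,
  `sim_po_decline_tau`, `sim_dose_recovery`, `sim_gv_recovery`).

## Worked example

Simulate eight 1.2 s single-channel sweeps at +120 mV with 4 μM
capsaicin while 5 μM OA is applied at t = 0, idealize them, and compute
per-sweep open probability:

```r
library(gatekin)
scheme <- build_default_scheme()

prot <- protocol(
  data.frame(duration_s = 9.6, voltage_mV = 120,
             capsaicin_uM = 4, oa_uM = 5),
  sampling_rate = 5000, filter_cutoff = 2000, noise_sd = 1, seed = 9,
  init = list(voltage = 120, capsaicin = 4, oa = 0))
rec    <- simulate_single_channel(scheme, prot)
levels <- estimate_levels(rec$trace)
levels
#> <amplitude_levels> baseline 0.2587 pA, open 10.82 pA, threshold 5.539 pA (sd 0.99)
po <- vapply(lapply(chop_trace(rec$trace, 1.2),
                    idealize_half_threshold, levels = levels),
             open_probability, numeric(1))
round(po, 3)
#> [1] 0.986 0.987 0.984 0.727 0.000 0.000 0.000 0.000
```

The channel gates with P_o ≈ 0.98 until OA captures it into a
long-lived closed state (sweep 4 onward). A single patch is an
all-or-nothing realization, so the ensemble relaxation is estimated by
pooling many simulated patches:

```r
sim_po_decline_tau(seed = 1)   # simulate -> idealize -> Po -> exp fit
#> [1] 6.334002                # ensemble decline, tau in seconds
```

Dose–response and energetics:

```r
dr <- generate_dose_response(k_d = 2.2, n_hill = 2,
                             concentrations = c(0.5, 1, 2, 5, 10, 20),
                             reps = 5, noise_sd = 0.05, seed = 1)
fit_hill(dr)
#> <hill_fit> converged; sse = 0.060762
#>                k_d  n_hill
#> estimate  2.148300 2.04110
#> std.error 0.068866 0.11558

100 * hill_inhibition(5, k_d = 2.2, n_hill = 2)  # % block at 5 uM
#> [1] 83.78016

closed_state_energy(q_a = 0.5, delta_v_half = 108) # kcal/mol
#> [1] 1.245289
```

A fitted K_D near 2.2 μM with a Hill coefficient near 2 recovers the
generating dose–response; evaluating that model at 5 μM predicts ~84%
block; and a 108 mV rightward G–V shift at constant gating charge 0.5 e0
corresponds to ~1.2 kcal/mol of closed-state stabilization.

## Layout

* `R/` — scheme construction and calibration, protocols and simulators,
  idealization, dwell-time analysis, curve fits, experiments, pipeline,
  I/O.
* `vignettes/gating-kinetics.Rmd` — the model, its assumptions,
  numerical choices, and what the simulations can and cannot validate.
* `inst/cli/gatekin.R` — command-line front end
  (`simulate`, `idealize`, `dwell`, `gv-fit`, `dose-fit`,
  `timecourse-fit`, `energy`, `run`).
* `tests/testthat/` — unit, property and end-to-end suites.
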