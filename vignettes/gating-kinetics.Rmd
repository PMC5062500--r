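---
title: "Gating kinetics of allosteric closed-state stabilization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gating kinetics of allosteric closed-state stabilization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatekin)
```

This vignette documents the science inside `gatekin`: the gating model
and the reasoning behind its calibration, the signal-analysis
conventions, the numerical choices in every fitter, and — just as
important — what the synthetic-data tests do and do not demonstrate
about real recordings.

## The physiological problem

TRPV1 is a polymodal cation channel of nociceptive neurons, opened by
capsaicin, heat, protons and lysophosphatidic acid. Oleic acid (OA)
inhibits it: applied to membrane patches it abolishes most of the
capsaicin-activated current, shifts voltage activation toward positive
potentials, and in single-channel records converts the high-open-probability
gating seen with capsaicin into long silent periods. The quantitative
signature of an allosteric closed-state stabilizer is exactly this
combination: a rightward shift of the conductance–voltage (G–V) curve at
roughly constant gating charge, inhibition that develops faster when the
channel is closed than when it is open, and a dose–response with
apparent cooperativity. `gatekin` packages the full analysis chain for
such data and a gating simulator that emulates the underlying
experiments.

## The gating scheme

The default scheme (`build_default_scheme()`) has four states:

```
        alpha(V, caps)
   C  <---------------->  O          (O conducts, 90 pS, E_rev = 0)
   |        beta(V)       |
   | k_on1·[OA]           | k_cap(V)·[OA]   (effective capture)
   |  k_off1 = 1/38.8     |
  C·OA  <-----------------+
   |  k_on2·[OA] / k_off2 = 0.5
  C·OA2
```

**Voltage and agonist dependence.** The activation charge is split
symmetrically between the opening and closing rates:
`alpha = a0 · f(caps) · exp(+q_a V / 2kT)`,
`beta = b0 · exp(−q_a V / 2kT)`, so the equilibrium constant follows the
Boltzmann law with `q_a = 0.54 e0` and half-activation at −63 mV at
saturating capsaicin. The overall speed is anchored by
`beta(+120 mV) = 10 s⁻¹`, i.e. mean open dwells of 100 ms and mean
(unliganded) closed dwells of ~2.1 ms at +120 mV — comfortably above the
0.4 ms dead time of a 5 kHz recording, because the package deliberately
omits missed-event correction (below). Capsaicin enters as a single
multiplicative factor `f(c) = (c/(c+0.2)) / (4/4.2)` on the opening
rate: 1 at the 4 μM reference concentration, 0 without agonist, with no
claim about the capsaicin dose–response itself. Temperature is fixed at
24 °C (`kT/e = 25.61 mV`).

**Inhibitor binding.** Two sequential OA bindings to closed
conformations give the non-conducting states C·OA and C·OA₂. The
washout bottleneck is the single slow departure `k_off1 = 1/38.8 s⁻¹`;
the doubly-occupied state redistributes quickly
(`k_off2 = 0.5 s⁻¹`). An effective capture transition `O → C·OA` with
rate `k_cap(V)·[OA] = k_cap0 · exp(q_cap V/kT) · [OA]` represents the
open channel's pathway into the inhibited states; mechanistically it
lumps closure-and-capture events too brief to resolve, and its small
voltage dependence (`q_cap ≈ 0.16 e0`) is what lets one scheme reproduce
the different open-state onset time constants observed at +60 and
+120 mV.

**Calibration.** Three constants are free and are fixed by observables
rather than chosen by hand (see `calibrate_default_scheme()`):

| constant | value | fixed by |
|---|---|---|
| `k_on1` | 0.0663 /μM/s | slow eigenvalue of the closed-side chain = 1/2.9 s⁻¹ at 5 μM (onset from rest) |
| `k_cap0` | 0.0129 /μM/s | fitted Po-relaxation τ = 6.2 s at +120 mV, 4 μM caps, 5 μM OA |
| `q_cap` | 0.163 e0 | fitted Po-relaxation τ = 7.7 s at +60 mV, same condition |

The solver is deterministic (a bracketed root search plus a damped
Newton iteration on analytic occupancy relaxations), so the constants
are reproducible to the printed precision; they are hardcoded in the
scheme and a test re-derives them.

**A constraint worth understanding.** For any Markov binding scheme
whose unbinding bottleneck is `1/38.8 s⁻¹`, an onset relaxation of
`1/2.9 s⁻¹` forces the equilibrium bound fraction at that concentration
to at least `1 − 2.9/38.8 ≈ 0.93`. Onset, washout and a ~84%
equilibrium block at 5 μM are therefore mutually incompatible — no rate
assignment satisfies all three. The default scheme is calibrated to the
kinetics, and its stationary resting-state block at 5 μM comes out at
~0.94. The equilibrium dose–response used for Hill-fit validation is
instead produced by the parametric generator
(`generate_dose_response`), which evaluates the Hill law directly; this
division of labour keeps each validated quantity attached to the stage
that actually measures it. A related consequence: with the second
binding step constrained this way, the scheme's own equilibrium
dose–response has a Hill slope near 1, so the two-site topology should
be read as kinetic structure, not as the source of the measured
cooperativity.

## The simulator

Single-channel records are exact-jump (Gillespie) trajectories — no
time discretization — so the true dwell sequence exists independently
of the sampled trace and is returned for oracle testing. The state path
is converted to current (conductance × driving force), low-pass
filtered, and given additive Gaussian noise. The filter is a Gaussian
FIR kernel with its −3 dB point at the protocol's cutoff: the standard
software emulation of a recording chain's Bessel response, and
well-behaved even at cutoffs near the Nyquist limit (at 2 kHz/5 kHz the
kernel is nearly the identity). Macroscopic currents switch
automatically between the sum of independent single-channel
trajectories (≤ 500 channels) and the deterministic occupancy solution
(matrix exponential per constant-condition segment) scaled by the
channel count — beyond a few hundred channels, channel noise is
negligible relative to fit tolerances, and the method used is recorded
in the trace metadata. Every simulation consumes exactly one integer
seed and is bit-for-bit reproducible.

What the generator emulates: stationary gating at fixed conditions,
solution-exchange protocols as piecewise-constant segments,
band-limited unitary current steps, additive Gaussian noise, sweeps of
the stated length (1.2 s at 5 kHz/2 kHz for single channels, step
protocols at 10 kHz/2 kHz for ensembles). What it does not emulate:
baseline drift and seal instability, capacitive transients, flicker
block and subconductance states, desensitization (absent under the
study's conditions), temperature and pH gating, and open-channel noise
in excess of the baseline. Passing the recovery tests therefore shows
that the analysis chain is correct and unbiased *for data of this
class*; robustness to drift or sub-states is out of scope by design.

## Idealization conventions

Levels come from the all-points histogram (bin width
`max(0.1 pA, 5% of span)`, 5-bin moving-average smoothing, modes
refined to the local sample mean). The baseline is the mode nearer
0 pA; the threshold sits midway between baseline and open level
(half-amplitude criterion); fewer than two modes, or modes closer than
three baseline standard deviations, yield an explicit "no openings"
result rather than an error. Classification is per sample, with ties at
the threshold assigned to closed — conservative toward the resting
state and deterministic. Dwells shorter than the dead time (default two
sampling intervals, ≈0.4 ms at 5 kHz) are merged into their
neighbours, shortest first. Missed-event (first-order dead-time)
correction is deliberately omitted: the default scheme's dwell scales
are chosen so that the bias is small, and simulations that probe the
pipeline keep dwell scales well above the dead time. Patches with a
sustained second conductance level (beyond 1.5× the unitary amplitude)
are flagged and excluded from kinetic analysis.

## Dwell-time analysis

Dwells are binned on a log₁₀ time axis (10 bins per decade by
default), where an exponential component appears as a peaked bump at
its time constant. The lower histogram edge never extends below the
dead time: dwells there are censored, and bins the model structurally
cannot populate would otherwise dominate the weighted fit. Mixtures of
two or three exponentials are fitted by least squares on the binned
counts — each bin's model value is the exact integral of the mixture
density over the bin — with weights `1/max(count, 1)`
(square-root-count weighting, the usual variance stabilization).
Initialization is a deterministic multi-start: time constants at
histogram mass percentiles plus two starts spread over the binned
range (so that rare, long components — precisely the ones an inhibitor
creates — are reachable), with per-component start amplitudes taken
from the histogram mass nearest each seed. Reported amplitudes are
fractional event weights within the binned range, so a degenerate
component pushed outside the data carries ~zero weight. Three
components are kept only when they improve the residual by more than
10% *and* all three time constants are mutually separated by at least
0.3 decades; otherwise two (the data rarely justify more, and the
selection rule plus both fits are always returned for audit).

## Curve fits

* **Boltzmann.** `G(V) = G_max/(1+exp(−q_a(V−V_1/2)/kT))` by
  Levenberg–Marquardt with `q_a > 0`, from a deterministic grid of
  starts (`V_1/2` at the voltage quartiles × two `q_a` seeds). Raw
  conductances are scaled to unit maximum for conditioning and the
  fitted `G_max` rescaled; monotonically decreasing data draw a warning
  but are still fitted.
* **Hill.** `f(c) = cⁿ/(cⁿ+K_Dⁿ)` on the inhibited fraction, same
  convergence contract, starts with `K_D` at the concentration
  quartiles × two Hill-coefficient seeds.
* **Single exponential.** Because amplitude and offset enter linearly,
  the fit profiles them out and optimizes the residual over τ alone
  (geometric grid across the observation window, then bracketed 1-D
  refinement). This is exact on noiseless data and — unlike
  general-purpose nonlinear solvers — does not collapse to degenerate
  time constants on step-like relaxations, which single-channel
  ensembles routinely produce. Replicate time points (pooled sweeps)
  are allowed; the relaxation direction is detected from the data trend
  and recorded.
* **Energetics.** `ΔΔG = q_a · ΔV_1/2`, converted at
  1 eV = 23.0609 kcal/mol; with `q_a = 0.5 e0` and a 108 mV shift this
  is 1.245 kcal/mol, positive meaning the closed state is favoured. The
  G–V shift is passed explicitly because published summaries sometimes
  quote a shift that differs from the difference of the quoted
  per-condition `V_1/2` values; the function takes no position on which
  to use.

## Validation experiments and problem sizes

The `sim_*` functions replicate the study's protocols end to end; the
acceptance script and the test suite run them at these sizes, chosen to
keep each quantity's Monte-Carlo error well inside its tolerance while
running on a laptop in seconds to tens of seconds:

* dose–response recovery: 100 seeded datasets, 6 concentrations
  (0.5–20 μM) × 5 replicates, 5% noise;
* G–V recovery: 200 seeded datasets, 21 voltages (−200…+200 mV), 3%
  noise;
* washout, closed-state onset, open-state onset: 20 seeded
  1000-channel experiments each, recording noise 2% of the uninhibited
  current;
* single-channel Po decline: 10 seeded experiments, each pooling 48
  one-channel patches × 40 sweeps of 1.2 s. A single patch is an
  all-or-nothing step (one capture silences it for ~39 s), so the
  pooled fit is what estimates the ensemble relaxation; 48 patches make
  the median-of-10 estimator stable. A wet-lab study averages the few
  patches it can obtain and pays for it in estimator variance.

The closed-state onset experiment reproduces the resting-state
protocol faithfully: patches are held without agonist, exposed for
0–15 s, and probed with a brief saturating test pulse; the fraction of
current remaining versus exposure time is fitted with a single
exponential.

## Degenerate inputs, tie-breaks, tolerances

Non-ergodic schemes at a given condition are flagged, with conditional
stationary distributions per closed communicating class (and a unique
overall distribution whenever only one closed class exists — e.g. the
inhibitor-bound states are transient at zero OA). Fit convergence uses
relative-SSE tolerances of 1e−10; non-convergence returns best-effort
parameters with `converged = FALSE` rather than an error. Traces
round-trip through CSV at full double precision; all RNG use is
confined to functions that take an explicit seed.

## Known limitations

The capture pathway `O → C·OA` is phenomenological and one-way
(microscopically irreversible), so the scheme is a driven approximation
near that edge rather than a thermodynamically complete cycle; it is
the minimal structure that reproduces the observed open-state onset
kinetics. The scheme cannot — provably, not merely in practice —
reproduce the printed equilibrium block, onset and washout
simultaneously (see the calibration section), and its own equilibrium
dose–response is less cooperative than the measured one. Missed-event
correction, subconductance analysis, burst analysis,
maximum-likelihood dwell fitting and hidden-Markov idealization are out
of scope; the log-histogram least-squares route was chosen to match the
analysis it emulates.
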