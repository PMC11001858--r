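---
title: "Outlet boundary conditions for Circle-of-Willis flow models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outlet boundary conditions for Circle-of-Willis flow models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cowbc)
```

## Scope and model

`cowbc` evaluates pressure-based outlet boundary conditions (BCs) for
transient models of the cerebral arterial circulation. The working objects
are time-resolved volumetric-flow (mL/min) and static gauge-pressure (mmHg)
waveforms at the four feeding vessels and six outflow vessels of the Circle
of Willis (CoW), sampled uniformly (1 kHz by default) over whole cardiac
cycles at a fixed pump frequency `f` (1 Hz by default, 40:60
systole:diastole).

The transient solver is a 0D lumped-parameter surrogate for a 3D CFD solve.
Each vessel segment of length `l` and diameter `d` in a fluid of viscosity
`mu` and density `rho` becomes a resistance `R = 128*mu*l/(pi*d^4)`
(Poiseuille) in series with an inertance `L = 4*rho*l/(pi*d^2)`, so the
segment law is `p_a - p_b = R*q + L*dq/dt`. Kirchhoff's current law at every
junction, imposed volumetric flows at the inlet nodes and imposed BC
pressures at the outlet nodes close the system. The inertial term is
discretised by backward Euler (unconditionally stable), giving one constant
sparse symmetric positive-definite nodal matrix that is Cholesky-factorised
once and reused for all time steps (default `dt` = 1 ms, 3 cycles, last
cycle evaluated). Mass conservation therefore holds to solver precision at
every step (residuals are recorded; they sit near 1e-15).

What a 0D surrogate can and cannot say: BC derivation, the explicit-Euler
Windkessel coupling, cycle bookkeeping and all metrics are identical in kind
to a 3D workflow, so BC-to-BC *orderings* (e.g. stationary BCs degrade
transient pressures; playback is the metric floor) transfer. Absolute
deviation magnitudes do not: a lumped Poiseuille network underestimates the
distributed and secondary losses of a 3D geometry (our synthetic network
drops ~1–2 mmHg from inlets to outlets versus ~16 mmHg in the emulated
experiment), and a rigid 0D network, like rigid-wall CFD, reproduces neither
the damped outlet-flow amplitudes nor the inlet-to-outlet time shift of a
compliant system. Reports are labelled "0D surrogate" accordingly.

## The five outlet BC sets

All five specs answer `bc_pressure(spec, outlet, t, Q)` in mmHg; only the
Windkessel is stateful.

**ZP.** One stationary gauge pressure for all outlets, the cycle average of
all recorded outlet pressures (87 mmHg for the calibrated default). It
discards the between-outlet pressure differences; because the posterior
outlet means of the reference lie *above* the common average, imposing the
average under-pressurises the posterior outlets and shifts flow from the
anterior to the posterior circulation. This directional effect is asserted
in the tests as a sign check only.

**SP.** `p = pbar_n + 1/2*c_n*rho*(Q/A)^2`, where `pbar_n` is the
cycle-averaged outlet pressure averaged over the left/right members of each
vessel class (ACA, MCA, PCA) and imposed symmetrically. The loss
coefficients `c_n` and outlet areas `A` are configuration inputs; the
shipped default `c_n = 1` per class is a placeholder (flagged by a message)
for values that would come from a tabulated source, and `A` defaults to the
lumen area of the terminal segment. At physiological outlet flows the
dynamic term is small (~1 mmHg), so SP behaves as a quasi-stationary BC.

**DEP.** Linear-interpolating periodic playback of each outlet's recorded
pressure. Since the solver imposes outlet pressures directly, DEP reproduces
them to machine precision and serves as the floor for the other BCs'
outlet-pressure deviations.

**WM.** Two-element Windkessel `C dp/dt = Q - p/R` per outlet, gauge
pressure against a zero venous datum (no venous pressure is available in
the recordings, so `R ~ pbar/Qbar` at cycle means). `R` per outlet comes
from the least-squares slope of `dp = R*Q` through the origin on the
instantaneous transient pairs, then left/right members of a class are
averaged. A compliant transient biases this naive instantaneous fit by a few
percent (the `C dQ/dt` term is ignored); the unbiased ratio-of-cycle-means
mode is also available (`method = "mean"`). Capacitances follow from
requiring `tau = R*C` uniform across outlets, anchored at the MCA
compliance `C_MCA`. `C_MCA` is a required physiological input; the
documented default 8e-11 m³/Pa (giving `tau` ≈ 0.33 s at the calibrated MCA
resistance) is a placeholder of the right order for cerebral outlets, not a
measured value. The state is advanced by explicit Euler in the solver's
time step, mirroring how such couplings are implemented in CFD codes;
`dt/tau` ≈ 0.003 here, far from the stability limit (warn at 0.5, error at
2). The state initialises at the cycle-averaged outlet pressure to suppress
the start-up transient.

**PM.** The phase-modulated cosine
`p(t) = pbar_n*(1 + PI_p/2*cos(2*pi*f*t + phi + beta*cos(2*pi*f*t + phi)))`.
Because the inner modulation vanishes where the outer cosine crosses zero,
the extrema of the modulated carrier remain exactly ±1: `PI_p` is exactly
the pulse-pressure-to-mean ratio for any `beta`, while `beta` skews the
waveform (fast systolic upstroke, slow diastolic decay). Fitting uses
bounded Levenberg–Marquardt least squares per outlet with four phase starts
over `[0, 2*pi)` (the objective is non-convex in `phi`) and `beta` bounded
to `[0, 2]`; the shared parameter set is the across-outlet median of each of
`PI_p`, `phi` (circular median: median of deviations from the circular
mean) and `beta`, with per-outlet mean levels retained (the reference
workflow reuses the SP side-averaged means).

## The synthetic generator

`generate_waveform_set(default_config())` emulates the statistical structure
of a calibrated benchtop CoW experiment so that every downstream stage is
testable without external data. Both flows and pressures use the PM family
per vessel — `Q(t) = Qbar*(1 + PI/2 * pm_cosine)` — rather than a piecewise
systole/diastole template: the family is closed under the PM fit (exact
parameter-recovery ground truth) and its `beta` skew reproduces the
qualitative arterial waveform shape. Defaults:

- per-vessel mean flows and PI targets equal to the published benchtop
  calibration table (inlet rows sum to 659.2 mL/min, outlet rows to
  661.0 mL/min — the printed rows themselves, whose printed total differs by
  0.9 mL/min from their sum);
- inlet mean pressures 102–105 mmHg and outlet means 85–89 mmHg chosen
  inside the reported ranges such that the outlet average is 87 mmHg, the
  mean-pressure decrease is 16.0% and the pulse-pressure decrease 10.0%,
  with posterior outlet pressures above anterior ones (the ordering that
  produces the ZP anterior-to-posterior flow shift);
- phases: no per-vessel phase values are published, so they are package
  choices fixed once — carotid and vertebral inlets offset by 0.35 rad,
  outlets delayed by ~0.5 rad relative to inlets (a compliant system's
  inlet-to-outlet time shift); `beta` = 0.6 shared;
- measurement noise: i.i.d. Gaussian with SD half the stated sensor
  uncertainties (0.25 mmHg, 2.5 mL/min), reading the "±" bounds
  conservatively as 2-sigma intervals; one integer seed governs all noise
  and is recorded in the output metadata.

Compliant versus rigid mode: the emulated experiment uses a compliant
phantom, whose instantaneous outlet-flow sum need not equal the inlet sum,
and whose per-vessel pulsatilities are the calibration targets — so the
default (`compliant = TRUE`) applies no renormalisation and reproduces the
configured PIs exactly. `compliant = FALSE` renormalises the outlet flows
per sample to match the instantaneous inlet sum, as a rigid conservative
system requires; this necessarily drags outlet pulsatility toward the
(higher) aggregate inlet pulsatility, which is why mass consistency and
PI fidelity are asserted on the respective modes and not jointly.

What the generator does *not* emulate: mechanistic wave propagation, heart
or arterial-tree dynamics, baroreflex variability, beat-to-beat period
jitter, or network-consistent pressures (its pressures and flows are
calibration targets, not solutions of the shipped network). Passing tests on
synthetic data therefore demonstrate correctness of the pipeline's
*operations*, not predictive fidelity for any real subject.

## Numerical choices

- **Units.** Clinical units (mmHg, mL/min) at every interface; coherent SI
  internally (1 mmHg = 133.322 Pa, 1 mL/min = 1/6e7 m³/s). All pressures are
  gauge. Incompressible flow makes volumetric and mass bookkeeping
  equivalent up to the constant density.
- **Filtering.** 6th-order Butterworth low-pass at 7 Hz (the reference
  post-processing), causal single pass by default, forward–backward
  (zero-phase) by flag. At a 7/500 normalised cutoff the digital
  coefficients are ill-conditioned, so DC gain and linearity hold to ~1e-6
  rather than machine precision; tests budget for that. Because recordings
  are whole cycles, an optional periodic extension tiles the signal before
  filtering, removing start-up transients for periodic inputs (phase lag
  does not affect amplitude metrics such as PI).
- **Cycle segmentation.** Fixed `1/f` windows anchored at the start of the
  recording, since the pump frequency is fixed and known; foot detection
  (minimum of the first cycle) is an optional anchor. Calibration-table
  statistics average all complete cycles; BC comparisons use the last cycle
  only. Both selectors are exposed, since published protocols mix the two
  conventions.
- **Extrema.** Per-cycle global max/min with first-occurrence tie-breaking.
- **RMSD alignment.** Simulated and reference last cycles are compared on
  the shared grid with no phase re-alignment: phase error is part of the
  deviation being measured.
- **Windkessel fit ambiguity.** Whether the reference `dp = R*Q` fit used
  instantaneous or cycle-mean pairs is not specified; both are implemented,
  instantaneous being the default.
- **Degenerate inputs.** Waveforms shorter than one period, zero-mean flows
  (PI undefined), zero normalizers, disconnected networks, non-covering BC
  specs and unstable `dt/tau` all fail loudly rather than silently.

## Problem sizes

The shipped configuration — 3 cycles at 1 kHz, 1 ms solver step, an 18-node
CoW graph — was chosen as the smallest faithful representation of the
emulated protocol: one evaluation of all five BC sets completes in a few
seconds, and the test suite exercises every module on those sizes.

## Known limitations

- The CoW geometry shipped with the package is synthetic
  (literature-typical adult dimensions), not patient- or cohort-derived;
  `c_n` and `C_MCA` defaults are placeholders, as flagged in their
  documentation.
- The 0D pressure drop between inlets and outlets is far smaller than in a
  3D geometry, so simulated inlet pressures sit near the imposed outlet
  levels; inlet-pressure NRMSD values mostly reflect the BC's transient
  shape, not geometric losses.
- Three-element Windkessel and structured-tree outlets, FSI/compliant walls,
  non-Newtonian rheology and 1D wave propagation are out of scope.
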