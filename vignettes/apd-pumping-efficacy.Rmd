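---
title: "From IKs conductance to pumping efficacy: the cardem model chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From IKs conductance to pumping efficacy: the cardem model chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cardem links four stages of cardiac electromechanics into one sweep: a
human ventricular myocyte model whose slow delayed rectifier (IKs)
conductance is scaled to shorten the action potential; a crossbridge model
that converts the resulting calcium transient into tension and ATP
consumption; a one-dimensional monodomain cable that measures conduction
velocity and wavelength; and a lumped elastance-Windkessel ventricle that
converts the tension waveform into pressure-volume hemodynamics.  This
vignette explains each model, its assumptions, the tunable parameters, the
numerical choices, and what the package's tests do and do not establish.

## Myocyte electrophysiology

The cell stage is the ten Tusscher-Panfilov (2006) human ventricular
model: 19 state variables (membrane potential, 13 Hodgkin-Huxley-type
gates plus a Ca-release adaptation variable, and Na+/K+/Ca2+
concentrations with a three-pool Ca2+ system — cytosol, dyadic subspace,
sarcoplasmic reticulum with rapid buffering).  The twelve membrane
currents sum to `I_ion`, and `dV_m/dt = -(I_ion + I_stim)/C_m`.  Three
transmural variants are provided: endocardial, mid-myocardial (M) and
epicardial, differing in the transient-outward conductance, the `s`-gate
kinetics, and the baseline IKs conductance.

The protocol dial is IKs:

    I_Ks = g_Ks_base * g_Ks_scale * x_s^2 * (V_m - E_Ks)

with `g_Ks_base = 0.392 * 1.3` mS/uF (endo/epi) and `0.098 * 1.3` mS/uF
(M); `g_Ks_scale` runs over {1, 2, 4, 6, 8, 10}.  The 1.3x factor is
applied uniformly to all three cell types; whether the M cell's base
conductance should also carry it is genuinely ambiguous, and we flag it as
the dominant structural uncertainty of the cell stage: with this choice
the endo and epi APD90 sweeps land within a few ms of published values at
the baseline (the endo cell at tenfold conductance sits ~1 ms outside the
+-10 ms band), while the M-cell sweep runs 20-30 ms long across all scales —
no published M-cell conductance value we are aware of closes that gap
without breaking the endo/epi agreement, so we report the M results as
produced rather than fitting an ad hoc conductance.  A useful structural
check: in the 2006 formulation the M and epi variants differ *only* in
their IKs conductance, so the M cell at four times its base conductance
(0.098 x 1.3 x 4 mS/uF) is exactly the epi baseline cell (0.392 x 1.3) —
the package reproduces this identity bit-for-bit.  Any APD90 table in
which those two conditions differ therefore reflects an M model that
departs from the 2006 variant beyond its conductance.

Pacing follows the fixed protocol: basic cycle length (BCL) 600 ms, a 1-ms
stimulus of -52 uA/uF (about twice diastolic threshold), 50 conditioning
beats, measurement on the last beat.  Fifty beats is a deliberate choice:
it is the conventional conditioning depth for this model family, and the
quantities of interest (APD90, Ca transient) are stable to < 1 ms per beat
by then.  True steady state of the slow Na+ balance takes hundreds of
beats and would shift APD90 down several ms; we verified that the reported
trends are unchanged.

APD90 is measured from the maximum upstroke velocity (dV/dt max, the
stimulus-artifact-free convention) to the first crossing of
`V_peak - 0.9 (V_peak - V_rest)`, with linear interpolation between
samples; `V_rest` is the potential immediately before the stimulus of the
measured beat, which stays well-defined under incomplete repolarization at
short cycle lengths.  On piecewise-linear templates the maximum slope is
degenerate, so the earliest interval within floating-point tolerance of
the maximum is used — this pins the upstroke mark at the onset of a linear
ramp.

### Numerics

The production integrator is fixed-step: Rush-Larsen exponential updates
for the 13 gate-like variables, forward Euler for the potential and
concentrations, and the analytic quadratic solution for the instantaneous
Ca2+ buffer equilibria, at `dt = 0.02` ms.  This is the standard scheme
for this model family; halving the step moves APD90 by ~0.1 ms (the test
suite asserts < 0.5 ms).  An independently written pure-R right-hand side
integrated by `deSolve::lsoda` at `rtol = 1e-6` is kept as a cross-check:
one paced beat from the same initial state agrees to < 1 mV in membrane
potential and < 5% in cytosolic Ca2+ pointwise outside the first 10 ms of
the beat.  (During the upstroke, dV/dt approaches 300 mV/ms, so a
microsecond-scale phase offset between two correct solutions appears as
several mV pointwise; the comparison window excludes that phase-dominated
interval.)  We use the two-route agreement in place of an external
reference trace; it exercises every current and flux expression through an
entirely different code path and integrator, but both routes share one
reading of the published equations, which a shared transcription error
would survive.

## Crossbridge mechanics

The myofilament stage is a Rice-style four-state scheme: nonpermissive
(`N_xb`) and permissive (`P_xb`) regulatory conformations, and two bound
myosin states — pre-rotation (`XB_PreR`) and post-rotation (`XB_PostR`).
Thin-filament regulation follows the steep power law

    N -> P:  K_np * TCa_Tot^7.5        P -> N:  K_pn * TCa_Tot^-7.5

where `TCa_Tot` is the troponin Ca2+ saturation (first-order binding,
kon = 40 /mM/ms, koff = 0.024 /ms, Kd = 0.6 uM).  The exponent 7.5 is the
scheme's stated cooperativity; the ratio `K_np/K_pn = 2^15` places the
permissive/nonpermissive equilibrium switch at `TCa_Tot = 0.5`, i.e. at a
cytosolic Ca2+ of the troponin Kd, and `K_np = 1.5`/ms sets a ~30 ms
activation timescale at systolic Ca2+.  Attachment/rotation/detachment
rates (`f_aapT = 0.5`, `g_aapT = 0.07`, `h_fT = 2`, `h_bT = 0.4`,
`g_xbT = 0.07` /ms) are adapted from the published Rice parameter set.
Active force is the strain-weighted bound fraction, normalized so a fully
permissive steady state bearing the power-stroke strain `x0 = 0.007` um
produces unit force.  ATP consumption is the flux through the
`g_xbT`-detachment step, `g_xbT * XB_PostR`, integrated per cycle.

This operating point makes the tension response to the EP-derived Ca2+
transients steeper than in a full spatial model: across the conductance
sweep peak tension falls ~100x where a 3-D ventricle would fall ~2x.  The
orderings the package asserts (tension and ATP strictly decreasing as APD
shortens) are insensitive to this; absolute tension drops are not
meaningful and are not asserted.  A lower troponin Kd flattens the
response but saturates normal-condition tension and breaks the strict
orderings downstream, so the a-priori value is kept.

Contraction modes: the pipeline default is isosarcometric (fixed sarcomere
length; tension development only), since 3-D strain is out of scope.
Isometric mode couples the sarcomere length SL to a series elastic element
`F_afterload = KSE (SL - SL_0)` through the momentum-like law

    dSL/dt = (Integral_Force + (SL_0 - SL) viscosity) / mass,

with `Integral_Force` the running time-integral of the net normalized
force.  Isotonic mode fixes the afterload after release.  The (SL,
Integral_Force) pair is a stiff damped oscillator — angular frequency
`sqrt(KSE/mass)` ~ 1000/ms at the default `mass = 5e-5` — so it is
advanced with the exact matrix exponential of the linearized affine
system, which is unconditionally stable and reproduces the
`sqrt(mass)` scaling of the inertial step-response time.  Sustained
unloaded shortening in isotonic mode saturates the physical sarcomere
bounds [1.4, 2.4] um (values are clipped with a warning) and the bound
strains are capped at +-0.05 um; isotonic simulations are provided for
protocol completeness, not used by the sweep.

Occupancies are advanced with an exact 4x4 matrix exponential at rates
frozen mid-step.  This is what makes the `TCa^-7.5` law tractable: at
diastolic Ca2+ the P -> N rate exceeds 1000/ms, which any explicit scheme
at practical steps would turn into overflow, while the matrix exponential
is exact at frozen rates and O(dt^2) in their variation.  It also makes
occupancy conservation a matrix property rather than an integration
property (drift < 1e-10 over 1e5 steps), and the frozen-rate solution is
testable against an independent matrix-exponential oracle to 1e-6.

## Tissue: the 1-D monodomain cable

Conduction is measured on a 2-cm homogeneous cable,
`dV/dt = -(I_ion + I_stim)/C_m + D d2V/dx2`, no-flux ends, with a
stimulated segment of 0.075 cm at one end.  This deliberately replaces a
3-D ventricular mesh with heterogeneous conductivities and a Purkinje
activation system; consequently only within-sweep comparisons (CV
invariance, wavelength ratios) are meaningful, not absolute wavelengths.

Numerics: operator splitting (compiled cell step for reaction, explicit
three-point Laplacian for diffusion with a CFL guard), `dx = 0.00625` cm,
`dt = 0.005` ms.  These are finer than the cell-stage defaults because
conduction velocity converges more slowly than APD: at `dx = 0.025`,
halving the spacing still moved CV by ~7%, while at the chosen resolution
halving `dx` moves CV by 0.9% (the suite asserts < 3%).  The diffusivity
is the cable's one calibration constant: `D = 1/(rho S C_m)` with
`rho = 0.852` kOhm cm, `S = 1400` /cm, chosen once so the normal-condition
planar CV is ~57 cm/s — the value implied by a 17-cm wavelength at an
APD90 of ~0.3 s — and exposed in the configuration.  Activation is
detected at -20 mV on the upstroke (interpolated); CV uses probes at 25%
and 75% of the cable; wavelength is `CV x APD90 / 1000` cm.  All cable
nodes start from the single-cell paced steady state, so three cable beats
suffice for a stable measurement.

## Pump surrogate

The hemodynamic stage is deliberately a surrogate: a time-varying
elastance ventricle `P_lv = (E_min + gain * tension(t)) (V - V0)` filling
from a constant venous pressure through a mitral resistance and ejecting
through an ideal valve into a 3-element Windkessel.  The circulation model
it stands in for is unpublished in the detail needed to reproduce it, so
the surrogate targets orderings and relative drops only.  Its single
documented calibration sets `gain = 2.6` mmHg/mL per unit tension, which
lands the normal-condition ejection fraction near 45%; all other elements
(`E_min = 0.13` mmHg/mL, `V0 = 5` mL, `P_ven = 10` mmHg, `R_mv = Z_c =
0.05`, `R_p = 1.2` mmHg s/mL, `C_art = 1.5` mL/mmHg) are conventional
lumped-circulation values.  The model is integrated at 0.25 ms until both
end-diastolic volume and beat-start arterial pressure are beat-to-beat
stable (< 0.5%), then one cycle is reported: EDV, ESV, stroke volume,
ejection fraction, stroke work (signed shoelace area of the PV loop, with
a Green's-theorem fallback for degenerate near-zero-excursion loops),
pulse pressure, and stroke work per unit ATP.

One known limitation is documented rather than patched: stroke work per
unit single-cell ATP is not monotone across the whole sweep.  The ATP
denominator falls ~50% over the first conductance step (the cooperative
tension drop), while a surrogate calibrated to a normal ejection fraction
of 45% drops stroke work only ~30% there — the Windkessel adapts its
pressure to cardiac output and the preload reserve buffers the stroke
volume.  We verified this across the surrogate's reasonable parameter
range (mitral resistance 0.005-0.05, gain 2.6-4.0): stroke volume,
ejection fraction, stroke work and pulse pressure are strictly decreasing
in every configuration; the efficiency ratio rises over the first steps in
all of them.  A spatially integrated ATP measure (unavailable at this
scale) would be needed to reproduce the monotone efficiency decline of a
full 3-D model.

## Synthetic inputs

`make_ap()` and `make_ca()` generate measurement-stage test inputs with
closed-form ground truth: a piecewise AP (linear upstroke, flat plateau,
exponential repolarization) whose exact APD90 is
`upstroke + plateau + tau ln 10`, and a rise-times-decay Ca2+ transient
`dia + amp (1 - e^{-t/tau_r}) e^{-t/tau_d}` (with `tau_r` solved so the
peak falls at the requested time) whose exact integral is returned with
the trace.  The templates are deliberately simple — no notch, no
spike-and-dome — because their job is to make the measurement operators
testable against exact values, not to mimic AP morphology; realism is the
ionic model's job.  Consequently, measurement tests passing on these
templates establish correctness of the measurement geometry, not
robustness to every pathological AP shape.

## The sweep and reproducibility

`run_sweep()` executes the whole protocol and returns an 18-row cell-level
table (APD90, Ca integral, peak tension, ATP per cycle) and a 6-row
tissue/pump table (cable APD90, CV, wavelength, SV, EF, stroke work, pulse
pressure, efficiency), optionally writing per-run trace CSVs, both
summary tables and a JSON manifest of every parameter.  Runs are
deterministic: fixed-step solvers, no random input, so re-running a config
reproduces the tables bit-identically.  Problem sizes throughout (50
conditioning beats, 2-cm cable, 3 cable beats, 6 myofilament beats, 60
pump beats maximum) are chosen so the full default sweep completes in a
few minutes on one CPU while keeping every reported quantity inside its
verified convergence regime.

Cell-level results worth restating as the package's own: endo and epi
APD90 land within a few ms of the published single-cell sweep at baseline
(279.8 and 282.0 ms vs 279 and 280 ms) and shorten monotonically to 134
and 142 ms at tenfold conductance; the M cell is the longest at every
scale, as it must be, but runs 20-30 ms above the published series (see
the cell-stage discussion above).  The per-cell-type correlation between
APD90 and the cycle integral of cytosolic Ca2+ exceeds r = 0.99.

## What the tests show, and what they do not

The suite establishes: internal consistency of the two EP code routes;
integrator convergence in dt (cell) and dx (cable); exactness of the
measurement operators on closed-form inputs; conservation and closed-form
equivalence of the crossbridge chain; strict orderings of every stage's
outputs across the conductance sweep; and the APD90 comparison against
the published single-cell table at +-10 ms / +-5%.  It does not establish
absolute accuracy of tension, wavelength or hemodynamics against tissue
or organ data — each of those passes through a stated desk-scale
substitution (isosarcometric mechanics, 1-D cable, surrogate pump) whose
absolute outputs are calibration-dependent by construction.
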