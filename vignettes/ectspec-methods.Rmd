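---
title: "Models and methods behind ectspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ectspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectspec)
```

# The measurement and its model

An electrochemical tunneling spectroscopy (ECTS) I–z record starts from a
feedback set point (0.4 nA by default), opens the loop, and logs the probe
current while the piezo retracts at constant electrode potentials. Four
instrument realities shape every curve and are all part of the package's
forward model:

* a **faradaic leakage floor**: a distance-independent background through
  the probe insulation, of order picoamps (default 2 pA);
* **amplifier saturation** at 10 nA, clipping any current above it;
* **per-point averaging**: each recorded point is the mean of several raw
  samples (20 per point for the standard 1024-point/15 nm retraction,
  35 per point for the 4096-point/100 nm approach geometry);
* **noise**: a multiplicative lognormal term (default sigma 0.15) for gain
  and junction fluctuations, plus additive Gaussian current noise (default
  0.5 pA) from the amplifier chain.

The ideal current is `I*(z) = I_leak + (I_set − I_leak)·exp(−B(z))` with
`B(z) = β z` for a constant decay factor. When an oscillating local barrier
is requested, the local log-slope is tied to the barrier profile through the
square-barrier relation, and `B(z)` is the cumulative integral of
`slope_from_barrier(Φ(z))` along the curve's own grid: this guarantees that
the *local* logarithmic derivative equals the slope implied by the barrier
at that position, so barrier-profile analysis of a synthetic curve recovers
the generative Φ(z) (a direct product `β_eff(z)·z` in the exponent would
not have that property — its derivative acquires a `z dβ/dz` term that
grows without bound).

Curve-to-curve β dispersion is modelled at the **curve level** (one
Gaussian draw per curve, truncated below at 0.05 nm⁻¹ to exclude
non-decaying junctions), not at the point level: ensemble histograms of
fitted β in this kind of experiment reflect junction-to-junction geometry
changes, while within-curve scatter is instrument noise. The truncation
makes the generative ensemble mean slightly exceed the nominal centre
(e.g. 0.54 rather than 0.50 nm⁻¹ at the gating resonance); tests compare
recovered means against the truncated-Normal closed form rather than the
nominal centre for exactly this reason.

## Condition presets

The shipped presets encode the experimental conditions the package models:
bare gold in 50 mM buffer (β = 9 ± 2 nm⁻¹), the cytochrome *c*₁ /
cytochrome *c* redox pair (1.5 ± 0.8 nm⁻¹), the pair inhibited by excess
wild-type cytochrome *c* (3 ± 1 nm⁻¹), non-specific self-transfer
(3 ± 1 nm⁻¹), and bare gold in pure water, which shares the protein-pair
centre but is more broadly distributed — the spread (sd 1.5 nm⁻¹) is a
package choice, as only the qualitative breadth is established. The default
leakage of 2 pA and the noise sigmas were fixed once so that the floor is
clearly visible in a semilog plot without dominating the fit window of any
preset.

The `oscillating_gold` preset deserves its own note. The barrier between
gold electrodes in electrolyte oscillates between about 0.5 and 1.2 eV with
a 0.35 nm period (one water diameter). At β ≈ 9 nm⁻¹ the current crosses a
2 pA floor after only ~0.5 nm — barely one period — so a profile long
enough for period detection requires a quieter probe. The preset therefore
uses a 1 fA leakage floor, multiplicative noise of 0.02, no additive noise,
and a 3 nm span at full 1024-point sampling, which leaves ≈ 4 periods above
the floor. This models a well-insulated probe rather than the routine
acquisition; it is the regime in which barrier oscillations are measurable
at all.

# Decay-factor estimation

Per curve, the estimator proceeds in three steps.

1. **Leakage**: median |I| over the final 10% of the span. If that median
   exceeds 10% of the set point the curve has not reached its asymptote;
   the estimate is then meaningless as a floor and the curve is flagged
   `leakage_dominated`. For such slow decays nothing is subtracted — every
   fittable current sits orders of magnitude above the true pA floor, so
   the uncorrected log-linear fit is accurate. This matters: the slowest
   curves are the scientifically interesting ones (transfer beyond 10 nm at
   the gating resonance), and discarding or over-correcting them biases
   ensemble means upward.
2. **Window**: the largest contiguous run with `3·leakage < I <
   0.9·saturation`, starting at the first unsaturated point. The two
   thresholds are package conventions: 3× keeps the log transform away
   from the floor's noise, 0.9× keeps it away from clipping. Fewer than 8
   surviving points raises `too_few_points`, which (like `saturated_start`)
   invalidates the fit; `leakage_dominated` and `dropped_points` are
   quality notes that leave β usable.
3. **Fit**: ordinary least squares of `ln(I − leakage)` on z. Because the
   tail median also contains whatever exponential signal remains at the end
   of travel, the estimator refines the floor a few times by subtracting
   the fitted exponential's own predicted tail and refitting; the loop
   stops at a 10⁻⁹ relative change. On noiseless single-exponential input
   this recovers the generative β to better than 10⁻⁶ relative at any β.
   A three-parameter nonlinear refit (`method = "nls"`) is exposed and
   agrees with the log-linear route within 5% on default synthetic data;
   the log-linear route is the default for robustness on short windows.

Ensembles are reported as the arithmetic mean ± SD of per-curve β over
usable fits, with a histogram anchored at zero (bin width 0.25 nm⁻¹ below a
mean of 5 nm⁻¹, 1 nm⁻¹ above — matching the resolution at which such
histograms are normally displayed). "Distributed around X ± Y" language for
such ensembles can denote either the moment estimates or a Gaussian fit to
the histogram; both are available (`gaussian = TRUE`), the moments are the
default.

# Local barrier profiles and periodicity

`barrier_profile()` applies a sliding least-squares slope of
`ln(I − leakage)` over windows of 0.15 nm (about 10 points of a standard
retraction), then maps slopes through `Φ = 0.00952 eV·nm²·(dlnI/dz)²`. The
prefactor is the vacuum square-barrier constant `ħ²/8mₑ` — the only physics
constant in the module. Published barrier analyses sometimes include an
instrument-specific prefactor or smoothing; absolute Φ values can therefore
differ from a particular instrument's convention by a constant factor,
while ratios, oscillation periods and the tunneling/non-tunneling
distinction do not. The 0.15 nm window resolves a 0.35 nm oscillation (it
stays under half a period) while attenuating its extremes slightly — a
sliding-window average of a cosine shrinks its amplitude by a known factor,
which is why profile minima/maxima of the oscillating preset read ~0.56 and
~1.14 eV rather than exactly 0.5 and 1.2.

Period detection linearly detrends the profile, computes the
autocorrelation (rescaled by `n/(n−lag)` to undo the triangular taper that
otherwise drags peaks toward shorter lags on short profiles), takes the
first local maximum between 0.1 and 1 nm, and refines the lag by three-point
parabolic interpolation. A peak below 0.2 autocorrelation is reported as
`aperiodic` rather than as a number: on profiles a few periods long,
anything weaker is indistinguishable from noise. Autocorrelation was
preferred over a periodogram because the usable profiles are short and
their grids only piecewise regular; the periodogram of the resampled
profile is trivially available as a cross-check.

# Electrochemical gating

A gating experiment shifts both electrode potentials together at constant
bias, so the gate axis is a linear map of (U_P, U_S). The quantitative
definition of the gate potential is an instrument-level convention, so the
mapping is injectable everywhere; the default is `Vg = −U_S`, which places
the observed resonance minimum at −0.25 V when the sample potential is at
0.25 V — between the midpoint potentials of cytochrome *c*₁ (0.28 V) and
cytochrome *c* (0.35 V vs SSC).

The generator's gate response is a Gaussian well,
`β(Vg) = β_off − (β_off − β_min)·exp(−(Vg−V0)²/2w²)`, with defaults
β_off = 3.5 nm⁻¹, β_min = 0.5 nm⁻¹, V0 = −0.25 V, w = 0.03 V. The well
shape is a package choice (the resonance is a phenomenological observation,
not a fitted rate law); the narrow width makes the off-resonance condition
at −0.15 V sit essentially at β_off, so the model's own on/off ratio is
3.49/0.5 ≈ 7. The per-gate spread defaults to 0.3 nm⁻¹, the dispersion
observed at the resonance.

Series aggregation excludes only fatally flagged fits and reports per-gate
n so the count is auditable. The minimum is located by an exact parabola
through the grid minimum and its two neighbours — appropriate for 0.05–0.1 V
gate grids; a strictly monotone series returns an edge-flagged argmin, and
a series whose total variation is below its median per-gate SD returns "no
minimum" rather than a spurious vertex. Two figure-of-merit helpers round
the module out: the two-exponential current ratio
`exp((β_off−β_on)·z)` (≈10 at 1 nm for 0.5 vs 2.8 nm⁻¹), and the absolute
energy scale `E(eV) = −e·U − 4.6` used to place Fermi and redox levels on
one diagram.

# Double-layer electrostatics

The screening argument needs three tools, in reduced units (potentials in
kT/e; 25.7 mV at 298 K):

* `debye_length()`: κ⁻¹ from the closed form, 0.304 nm/√c at 298 K /
  eps_r 78.5 — about 1 nm at 100 mM, 1.36 nm at 50 mM;
* `gouy_chapman_potential()`: the exact single-plane solution
  `ψ = 4 atanh(tanh(ψ₀/4) e^{−κz})`, which is also the solver's oracle;
* `solve_pb_gap()`: the nonlinear Poisson–Boltzmann equation
  `ψ'' = sinh ψ` between two walls at fixed potential, discretised with
  second-order finite differences and solved by damped Newton iteration
  with continuation in wall potential (robust to |ψ| = 20 kT/e), each step
  a tridiagonal (Thomas) solve.

Dirichlet walls were chosen over fixed charge because gap potentials are
naturally reported in kT/e contour values; a constant-charge mode would be
the natural extension. The 50 mM phosphate buffer is treated as an
effective 1:1 electrolyte — phosphate speciation shifts the effective ionic
strength but not the qualitative picture the module exists to express: in a
3 nm gap at 50 mM with ±1.1 kT/e walls the midgap potential stays above
0.3 kT/e and cations are depleted throughout, i.e. the confined gap remains
unscreened and an electric field spans it. The residual tolerance defaults
to 10⁻¹⁰ with a floor of `~8ε(1+|ψ_wall|)/h²` because on fine grids the
1/h² difference operator amplifies round-off; the floor stays orders of
magnitude below the discretisation error. Verified properties include the
superposition limit against the analytic single-plane solution (10⁻⁴ kT/e
at 20 Debye lengths), the linearised cosh profile at small potentials,
second-order grid convergence, and wall-charge/space-charge balance.

This 1-D module deliberately reproduces only the *qualitative*
depletion/extended-field behaviour of a protein–protein junction; it is not
a substitute for 3-D electrostatics of real protein geometries, and no
quantitative map value is asserted anywhere in the package.

# Problem sizes, determinism, and what the tests show

The test-suite and the acceptance script use the standard acquisition
geometries: 150-curve ensembles (1024 points, 20 samples per point) per
retraction condition, 9 gates × 80 curves for gating, 20 curves for the
periodicity analysis, and PB grids of 801–4001 points — all chosen as the
sizes at which the corresponding experimental statements are made, and all
running in seconds. Randomness flows from one master seed through a
deterministic child-seed stream (kept below 2³¹), so fixed seeds give
bit-identical ensembles and byte-identical pipeline reports.

Passing tests demonstrate that the estimators recover the generative model
of the forward simulator under realistic noise — they cannot certify
behaviour on phenomena the generator does not contain. Known omissions:
thermal drift and piezo creep, multi-exponential or plateau (contact)
regimes, blinking, the ionic-strength dependence of β, and any mechanistic
rate law connecting the gate response to redox chemistry. On real data the
fitting, windowing and flagging logic applies unchanged, but those effects
would surface as flagged fits, lowered r², or histogram structure the
Gaussian summary does not capture.
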