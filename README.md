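# ectspec

Analysis of electrochemical tunneling spectroscopy (ECTS) current–distance
data, for experiments probing long-distance electron transfer across aqueous
gaps — for example between immobilised redox partner proteins such as
cytochrome *c*₁ and cytochrome *c* held between the sample and probe
electrodes of an electrochemical STM.

In an I–z acquisition the feedback loop is opened at a set-point current
(0.4 nA here) and the probe current is recorded while the piezo retracts.
For a tunneling-dominated junction the current decays as

    I(z) = I_leak + I0 · exp(−β z)

where β (nm⁻¹) is the **distance decay factor** and I_leak is the
distance-independent faradaic leakage floor (pA scale). The local tunneling
barrier follows from the logarithmic slope via the square-barrier relation

    Φ_local = (ħ²/8mₑ) (d ln I / dz)²  ≈  0.00952 eV·nm² · (d ln I/dz)²

so β ≈ 9 nm⁻¹ (clean gold in buffer) corresponds to Φ ≈ 0.77 eV, while
β ≈ 1.5 nm⁻¹ (a protein pair bridging the gap) corresponds to ~21 meV —
far below any tunneling barrier, the signature of a different transport
regime. The package covers the full workflow around these quantities:

- **curve I/O** — a plain-text, metadata-headed TSV dialect ("ectsv") for
  curve ensembles with per-curve electrode potentials;
- **decay analysis** — per-curve β by leakage-corrected log-linear fitting
  with windowing, quality flags, ensemble histograms and mean ± SD;
- **barrier analysis** — sliding-window Φ_local(z) profiles and detection of
  spatial periodicity (water layering, 0.35 nm);
- **gating analysis** — β vs electrochemical gate potential at constant
  bias: resonance minimum, on/off ratio, absolute energy scale
  E(eV) = −e·U(V vs SSC) − 4.6;
- **synthetic data** — a forward model of the acquisition (set point,
  amplifier saturation, leakage, per-point sample averaging, multiplicative
  and additive noise, curve-to-curve β dispersion, oscillating barriers,
  gate-dependent β) with presets for the standard experimental conditions;
- **electrostatics** — Debye length, analytic Gouy–Chapman profiles, and a
  nonlinear 1-D Poisson–Boltzmann solver for a confined electrolyte gap
  with ion-concentration profiles and depletion summaries.

## Worked example

```r
library(ectspec)

## simulate a protein-pair retraction experiment (150 curves, 15 nm travel)
curves <- make_curve_set(ects_preset("pCc1_hCc"), n = 150, seed = 42)
fits   <- fit_decay_set(curves)
summarize_beta(fits)
#> <beta_summary> beta = 1.52 +/- 0.644 nm^-1 (n = 150, 0 flagged)

fits[[1]]
#> <decay_fit> beta = 0.663 nm^-1, I0 = 4.04e-10 A, leakage = 2e-12 A, r2 = 0.9991

## screening length of the 50 mM buffer and the barrier of the mean decay
debye_length(electrolyte_spec(c0 = 0.05))     # 1.36 nm
1000 * barrier_from_slope(1.5)                # 21.4 meV
```

The ensemble mean ± SD (1.52 ± 0.64 nm⁻¹) recovers the generative
distribution of the protein-pair preset; the first curve happens to draw a
low β, which is exactly the curve-to-curve dispersion the histograms
summarise. A full run — all condition presets, barrier periodicity, a
9-gate × 80-curve gating dataset and the screening numbers — is one call:

```r
report <- run_pipeline(run_config(out_dir = "out", seed = 1))
```

which writes `.ectsv` ensembles, per-curve fit tables, the gating series and
a machine-readable `report.json`.

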