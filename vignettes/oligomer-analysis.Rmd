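---
title: "Modelling homo-oligomerization from SEC-MALS and CD data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling homo-oligomerization from SEC-MALS and CD data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligofit)
```

This vignette documents the models implemented in `oligofit`, the
assumptions behind them, the tunable parameters that matter, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the package's tests do not themselves compute.

## The scientific problem

Many centriolar and cytoskeletal proteins self-associate through more than
one interface: a coiled coil that trimerizes weakly, a compact helical
domain that dimerizes tightly, and — when both are present in one chain —
a concentration-dependent ladder of higher-order species (dimers joining
to tetramers and hexamers). Two solution observables constrain such
systems well at desk scale:

* **SEC-MALS**: the weight-average molecular weight of the eluting peak as
  a function of on-column concentration, measured over a dilution series.
  The concentration at which the curve transitions from the smallest to
  the largest species is the practitioner's "apparent K_d".
* **CD thermal melts**: the 222 nm ellipticity versus temperature. Each
  independently folded helical domain contributes one cooperative
  two-state transition; mutations that disrupt one interface shift or
  abolish that domain's transition while leaving the other unchanged.

## Assembly schemes and their equilibria

A scheme is defined by a protomer mass (plus an optional fusion-tag mass),
a base unit, and ordered association steps with stepwise dissociation
constants (`build_scheme()`). Three presets cover the architectures above:
`scheme_monomer_trimer()`, `scheme_monomer_dimer_trimer()` and
`scheme_dimer_tetramer_hexamer()`.

Design choices made here, and why:

* **Stepwise constants, observable-level apparent K_d.** Experimental
  papers typically quote a single "apparent K_d" per construct, defined on
  the measured MW-vs-concentration curve rather than on any particular
  reaction step. We therefore parameterize schemes with stepwise constants
  (the quantity mass action needs) but report the model-free midpoint
  crossing as the headline `apparent_kd()`, with the
  second-derivative-in-log-c inflection estimator available as an option.
  The two estimators are *different summaries*: for monomer–trimer
  association the inflection of M_w against log10 c sits below the
  midpoint concentration. Both scale identically with the underlying
  constants, which is what matters for comparisons between constructs.
* **Concentration scale.** All totals are protomer-equivalent µM. The
  midpoint apparent K_d is likewise quoted on the protomer-equivalent
  scale; because it is defined on the observable, no oligomer-scale
  ambiguity arises.
* **Obligate dimer.** Dimerization through the compact interlocked domain
  survives dilution to tens of nM, orders of magnitude below the
  coiled-coil transition; modelling it as infinitely tight removes an
  unidentifiable parameter. A finite dimer step can still be expressed as
  a `monomer`-based scheme if needed.
* **Dimer as explicit intermediate.** Whether a trimerizing coiled coil
  passes through a populated dimer is usually not resolvable from M_w
  data alone; the direct monomer–trimer scheme is the default and the
  monomer–dimer–trimer scheme is provided for sensitivity analysis.
* **Root finding.** Protomer conservation is strictly increasing in the
  free base-unit concentration, so the solver brackets `[0, c_total/b]`,
  bisects, and polishes with Newton steps using the analytic derivative.
  No starting guess is needed and convergence is certain; the solver
  raises an internal error if mass conservation exceeds 1e-9 relative,
  which the test suite verifies never happens across random schemes.
* **Fit parameterization.** `fit_association()` optimizes log10 K within
  [1e-4, 1e4] µM (positivity by construction). Multi-step fits start from
  the template's constants — in practice equal stepwise constants, which
  matches the observation that assembly-ladder steps tend to have
  comparable affinities. Data that contain no association drive the
  constant to the upper bound; the fit then reports `converged = FALSE`
  rather than a spurious estimate. Bootstrap confidence intervals (default
  seed 1729, 200 replicates when requested) resample points with
  replacement because no analytic uncertainty is available for this
  two-stage summary.

## SEC-MALS trace processing

The processing chain is deliberately minimal and mirrors what instrument
software does, with three simplifications that are documented rather than
hidden:

* **Single lumped LS calibration constant** instead of the multi-angle
  Zimm formalism: for proteins of a few hundred kDa or less the angular
  dependence is negligible, and the lumped constant is what the synthetic
  generator uses, so round-trip consistency is exact by construction.
* **Fast exchange**: the MW observed at the peak apex is taken to reflect
  equilibrium at the apex concentration. Plotting MW against on-column
  concentration presumes the same thing; re-equilibration during
  on-column dilution is not modelled.
* **Apex, not window average**, is reported as the on-column
  concentration (`extract_injection_point()`), matching the convention of
  reporting one concentration per injection. The reported MW is the
  concentration-weighted mean over the half-height window, so in the
  middle of an association transition it sits slightly below the apex-
  concentration model MW — the window averages over slices at lower
  concentration. The round-trip tests therefore compare against the same
  windowed statistic computed from the forward model.
* **Baseline** is the median of the outer 5% of slices at each end:
  robust, parameter-free, and exact for flat baselines (constant offsets
  cancel to numerical precision).
* **Overload flag** by half-height asymmetry ratio (default 3): column
  overloading manifests as strong peak fronting/tailing. The flag retains
  the point but excludes it from fitting by default.

Tunables: `dn_dc` (ml/g, default 0.1850 — the standard value for proteins,
applied uniformly even to fusion-tagged constructs, whose true increment
differs by a few percent), `ls_calib` (instrument constant), and the
masking threshold (5% of apex concentration) below which LS/c ratios are
too noisy to report.

## CD processing and thermal unfolding

**Smoothing** is Savitzky–Golay (local least-squares polynomial, default
window 11, order 3), exact for polynomials up to the chosen order, with
truncated-window fits at the edges. **Mean-residue ellipticity** uses the
standard normalization θ/(10 · c_M · l · N). High-tension voltages above
800 V truncate the spectrum before any further processing, since the
detector is saturated there.

**Deconvolution** solves nonnegative least squares against idealized
helix/strand/coil basis spectra built from Gaussian bands at the canonical
positions (`cd_basis_spectra()`). Shipping synthetic basis spectra is a
deliberate choice: the experimental reference sets used by deconvolution
servers are not redistributable, and fraction estimates from any basis set
are semi-quantitative. The NNLS solution is found by exhaustive active-set
enumeration — exact for three components — and the fractions are
renormalized to sum to one.

**Melting fits** use one or two independent two-state van't Hoff
transitions with shared linear folded/unfolded baselines; fractional
amplitudes φ_j partition the total signal change. ΔCp is fixed at zero:
melts rarely constrain it, and the apparent T_m is insensitive to that
choice. Temperatures are Kelvin internally, Celsius at every interface.

The optimizer is the part that required care. The parameter scales span
four orders of magnitude and the (ΔH, φ) valley is narrow, so a plain
quasi-Newton fit from grid starts stalls. `fit_melting()` therefore:

1. standardizes the signal (baseline parameters become O(1));
2. runs **variable projection** over only (T_m, log ΔH): conditional on
   the transition shapes, the model is linear in the baseline/amplitude
   terms and is solved exactly at every step. The multistart sweep (T_m
   grid every 10 °C) runs on a reduced family with constant step
   amplitudes, because the full family with per-transition amplitude
   slopes is flexible enough that noise can displace its optimum;
3. polishes the few distinct candidate optima under the constrained
   model (L-BFGS-B then Nelder–Mead) and keeps the lowest RSS, ordering
   transitions so T_m1 < T_m2.

Noiseless synthetic curves are recovered to optimizer tolerance, which the
tests assert across random parameter draws. A transition is flagged
non-cooperative when its fitted amplitude is below 3× the residual noise
*or* below 1% of the signal span — the second clause catches the
degenerate case of a perfectly linear trace, where both amplitude and
noise are near zero. `delta_tm()` compares matched transitions between two
fits (e.g. wild type vs point mutant); `tm_from_derivative()` provides the
model-free derivative-extremum estimator for cross-checking.

## The synthetic-data generators

The generators state the experimental world the package expects:

* **Dilution series** (`simulate_binding_series()`): 1:1 steps from a top
  concentration, default 11 points — the design that spans the ~3 decades
  of concentration a trimerizing coiled coil needs (e.g. 152 µM down to
  0.148 µM). MW noise is multiplicative lognormal, default 3%: MALS noise
  grows with signal, and a few percent is typical for well-behaved peaks.
* **Chromatograms** (`simulate_chromatogram()`): Gaussian elution peak,
  per-slice composition from the equilibrium model at the slice
  concentration (the same fast-exchange assumption the processing makes),
  detector traces by the exact forward model of the processing equations,
  additive Gaussian detector noise (default 1% of apex) — detector noise
  does not scale with the analyte.
* **Melts and spectra**: exact forward models plus multiplicative noise
  (default 2% for melts, matching the scatter of a 1 °C/min ramp).
  The generative baselines used in tests — folded near −30000 deg cm²
  dmol⁻¹ with mild positive drift, unfolded near −5000 — are typical
  mean-residue values for a helical protein melting to a residual coil.
* **Native MS** (`predict_native_ms_peaks()`): forward m/z prediction
  only, m/z = (n·M + z·1.00728)/z. No adduct series or in-flight
  dissociation; observed intensities are instrument-dependent and out of
  scope.
* `secmals_design_table()` records the per-construct design parameters
  (monomer mass, column, concentration range) of the motivating study's
  fifteen dilution-series experiments, as fixture parameters for
  realistic simulations.

What a green test does **not** establish: the generators do not model
column band-broadening, inter-detector delay, re-equilibration during
elution, aggregation, scan-rate-dependent (kinetic) unfolding, or
three-state coupling between domains. Agreement on synthetic data
validates the estimators under the stated assumptions, not those
assumptions themselves.

## Determinism and reproducibility

Every stochastic generator takes an explicit seed and restores the
caller's RNG state afterwards; identical seeds give bit-identical output.
The pipeline runners (`run_secmals_pipeline()`, `run_melting_pipeline()`)
thread a single config seed through the bootstrap and write key-value
reports that are byte-identical across reruns.

## Known limitations

* The apparent K_d of multi-step ladders summarizes the whole curve; the
  individual stepwise constants are only weakly identified when the
  species masses are close, and the fit reports them at face value.
* The two-transition melting fit assumes thermodynamically independent,
  additive transitions; strongly coupled domains would need a three-state
  model, which is out of scope.
* Secondary-structure fractions depend on the basis set and should be
  read as relative composition, not absolute content.
* Transitions within ~10 °C of each other or of the temperature-range
  edge are recovered with visibly larger variance under noise — the upper
  baseline is then short, and the data constrain T_m weakly. This is a
  property of the experiment, not of the optimizer.
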