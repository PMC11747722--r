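---
title: "Models and methods behind lungbrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lungbrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungbrain)
```

# Scope

`lungbrain` re-implements, as a reusable pipeline, the computational chain
of a crossover animal experiment on lung–brain interactions: how PEEP and
body position affect intracranial pressure (ICP) and cerebrovascular
pressure reactivity. It has four cooperating stages — a synthetic
physiology generator, a waveform-to-trend processing stage, a
respiratory-mechanics stage, and the crossover statistical analysis — plus
CSV formats and an end-to-end driver. This vignette records the models,
the tunable parameters, and every numerical decision that was genuinely
open, so that a maintainer can tell design from accident.

# The synthetic physiology generator

## Why a generator

The animal recordings the analysis was designed for are available only on
request, so the package ships a generator whose outputs have *known ground
truth* and the statistical structure the analysis assumes. Every claim a
green test makes is therefore a claim about the pipeline's ability to
recover what the generator put in — not about animal physiology itself.

## Signal model

For each animal (time in seconds, per-animal parameters drawn once from
population distributions under a per-animal seed):

* **Arterial pressure.** `ABP(t) = MAP + s_A · zA(t) + respiratory +
  cardiac + noise`, where `zA` is a standardized slow vasogenic process:
  a sum of `n_slow_components` (default 6) sinusoids with random phases
  and frequencies drawn uniformly from 0.005–0.05 Hz, the band that
  pressure-reactivity monitoring is sensitive to. Default slow-wave SD
  `abp_slow_sd = 3` mmHg; within-animal slow-wave power is not reported
  for this preparation, so this magnitude is a free parameter chosen to
  give realistic index sampling noise, documented here and in
  `synth_config()`.
* **Intracranial pressure.**
  `ICP(t) = baseline + 5 mmHg · supine + slope · (PEEP − 5)/5 +
  s_I · (g · zA + sqrt(1 − g²) · zB) + pulse + respiratory + noise`,
  with `zB` an independent slow process. The coupling convention makes
  the *expected* PRx equal `coupling_g` in the noise-free limit, because
  the block-averaged slow components of ABP and ICP then correlate at
  exactly `g`. Intact autoregulation is `g ≤ 0`, impaired `g > 0`.
* **Pulse amplitude.** The ICP cardiac pulse has amplitude
  `AMP = a0 + a1 · max(meanICP − threshold, 0)` (defaults 1 mmHg,
  0.15 per mmHg, 15 mmHg). Below the threshold AMP is flat, so RAP sits
  near zero (preserved compensatory reserve); above it AMP rises linearly
  with ICP and RAP approaches one. This is the simplest model that
  reproduces the compensatory-reserve interpretation of RAP.
* **Position.** A +5 mmHg supine offset. In pigs the frontal ICP probe
  sits lower in the supine posture, so supine reads *higher* than prone —
  opposite to the human pattern. (The source experiment's baseline table
  and its discussion agree on this direction; one sentence in its results
  section states the opposite and is treated as a typo.)
* **PEEP response.** Each animal's slope (mmHg per 5 cmH2O) is
  `icp_peep_slope + Σ covariate_effects · (covariate − population mean) +
  N(0, icp_peep_slope_sd)`. The population default of 1.0 mmHg per
  5 cmH2O reproduces the reported pooled ΔICP of roughly 1/2/3 mmHg at
  PEEP 10/15/20. The covariate modifiers (baseline ICP +, CVP +,
  E_rs −, TPP_ei −, TPP_ee −) were set so that the *marginal* Pearson
  correlations of the exploratory screen land near the reported values
  (≈ +0.2 ICP, +0.3 CVP, −0.2 E_rs, −0.34 TPP_ei, −0.2 TPP_ee); they were
  fixed once against those published anchors, not against the package's
  own tests.
* **Ventilator.** A single-compartment model: volume-control square
  insufflation (I:E 1:2, 20% end-inspiratory pause), passive exponential
  expiration with time constant `R/E_rs`, `Paw = PEEP + E_rs·V + R·flow`,
  `Pes = Pes_ee(PEEP) + E_cw·V`, with end-expiratory esophageal pressure
  rising with PEEP by the chest-wall share `E_cw/E_rs`. Occlusion-hold
  values are generated from the same elastances, so
  `Paw_ei − PEEPtot = VT·E_rs` and `Pes_ei − Pes_ee = VT·E_cw` hold
  *exactly* when noise is off — the round-trip identity the mechanics
  tests exploit. Animal mass (23–28 kg) and respiratory rate (20–30/min)
  are drawn per animal per the experimental protocol; VT is 7.5 mL/kg.
* **Randomization.** The prone-first/supine-first sequence is a seeded
  lot draw per animal with no balancing constraint; skewed splits (the
  original study had 8/4) occur naturally.

## What the generator does not emulate

No Windkessel or heart–lung ODE dynamics, no baroreflex, no
thermodilution or blood-gas physics, no waveform morphology beyond
sinusoidal pulses, no slow drifts in gas exchange. Respiratory-rate and
cardiac-frequency are constant within an animal. Consequently a green
test establishes algorithmic correctness and statistical calibration of
the pipeline, not physiological realism of any individual waveform.

## The table-level generator

`simulate_study_table()` draws the per-period summary table directly
(same animal-level effect structure, period-level residual noise standing
in for within-period averaging error) without synthesizing waveforms. It
exists because the statistical calibration studies need hundreds of
replicate studies; at the waveform level those would take hours, at the
table level seconds. The waveform path remains the reference for
everything upstream of the study table, and the two paths share the same
per-animal truth draws.

# Trend processing

* **Coarse graining.** Non-overlapping 10-s block means (0.1 Hz). A block
  is valid only if at least 50% of its raw samples are finite; trailing
  partial blocks are dropped. For fully valid data the mean of block
  means equals the raw mean to 1e-9 relative — a conservation property
  under test.
* **Artifact thresholds.** ICP blocks outside [−10, 60] mmHg are
  rejected; CPP = ABP − ICP outside [0, 150] mmHg rejects the block too.
  The thresholds are applied to 10-s block values (they are listed with
  the downsampling step in the source methods); `process_recording()`
  additionally offers raw-sample-level masking. Block-level application
  means an artifact is detected at block resolution: a contamination
  covering a minority of a block survives if the block mean stays in
  range. The mask only ever shrinks.
* **AMP.** The extraction algorithm behind the original analysis software
  is not published. The default here is 2× the magnitude of the
  Hann-windowed single-frequency Fourier component of each 10-s ICP block
  at the fundamental cardiac frequency — a peak-to-peak-equivalent
  convention (a pure sinusoid of amplitude *a* gives AMP = 2a). The Hann
  window suppresses leakage from within-block drift (a 3 mmHg drift
  perturbs AMP by well under 0.1 mmHg). A per-beat median peak-to-peak
  alternative is available (`amp_method = "beat"`). The cardiac frequency
  is taken from configuration or detected as the largest ABP periodogram
  peak in 0.5–5 Hz.
* **Moving correlations.** PRx correlates 30 consecutive 10-s ABP and ICP
  averages in a trailing 5-min window updated every minute; RAP does the
  same for AMP and ICP. Windows end at update instants; the first index
  is emitted 300 s after the start. A window is invalid below 24/30 valid
  pairs (tolerates brief artifacts without biasing r) or at zero
  variance. `z = atanh(r)` with |r| clamped at 0.99 keeps z finite.
* **Period summaries.** Per-period means over valid entries only. PRx and
  RAP are averaged on the z scale; tables report both mean z and
  tanh(mean z). The published baseline table prints PRx on the r scale
  while stating that the Fisher transform preceded analysis; since the
  exact back-transformation is unstated, both scales are carried through
  and the back-transformed value is the default for reporting. Δ columns
  are taken against the PEEP-5 baseline of the same position block.

# Respiratory mechanics

All formulas are in the README. Numerical decisions:

* The printed chest-wall formula "Pes_ei − Pes_ee/VT" is evaluated as
  `(Pes_ei − Pes_ee)/VT`; units and the classic occlusion formula demand
  the parenthesis.
* Study tables carry VT in mL; formulas convert to litres. The factor
  0.098 converts L·cmH2O/min to J/min.
* Where the mechanical-power formula calls for `Paw_ee`, the measured
  total end-expiratory hold pressure (PEEPtot) is used when available,
  falling back to set PEEP.
* "Peak lung pressure" in the non-dependent power formula is read as
  `Ppeak_l`, the only defined lung peak pressure.
* The occlusion-test acceptance band [0.8, 1.2] is boundary-inclusive.
* Negative lung elastance (E_cw > E_rs) and negative power raise warnings
  rather than errors: they flag implausible inputs but are arithmetic
  outcomes the caller may want to inspect.

# Crossover statistics

* **Assumption tests.** The mixed model is
  `Δ ~ peep * sequence + period + (1|animal) + (1|animal:position)`.
  "Animal and position as random effects" is implemented as a random
  intercept for animal plus one for position-within-animal: position as a
  crossed random factor with two levels is not estimable, so the nested
  intercept is the faithful estimable version.
* **P-values without parametric-df machinery.** Only `lme4` is assumed.
  The carry-over term (sequence × PEEP, a within-block contrast with
  ample residual df) is tested by ML likelihood ratio. The sequence and
  period main effects are *between*-stratum contrasts where the 1-df LRT
  is measurably anticonservative at 12 animals (≈14% empirical type-I for
  sequence in null simulations); they are instead tested by Wald t from
  the REML fit with design-stratum df (sequence: n−2 between animals;
  period: n−1 between blocks within animals), which simulation shows is
  calibrated (3–5% at n = 12 over 200+ null replicates). The paired
  baseline-vs-washout t-test is exact.
* **Two-way ANOVA.** Implemented as a two-way repeated-measures ANOVA
  with animal as the blocking factor, each effect tested against its
  animal-interaction stratum. A fixed-effects two-way ANOVA is
  conservative here (≈1% type-I for the interaction) because change
  scores within a position block share the baseline period's noise; the
  repeated-measures form restores nominal calibration, which the original
  design requires for its interaction test to be meaningful.
* **Pooled repeated-measures one-way ANOVA.** Classical within-subject F
  with sphericity assumed and no Greenhouse–Geisser correction, matching
  the plain ANOVA reported. The repeated unit is the position block
  (animal × position); "pooling" prone and supine means both of an
  animal's blocks enter as subjects. Degenerate inputs (zero treatment
  SS) return F = 0, p = 1 instead of 0/0.
* **Baseline comparison.** Shapiro–Wilk per group at α = 0.05 routes to a
  Welch t-test (both groups normal) or Mann–Whitney; groups under n = 3
  (or constant) go straight to Mann–Whitney. Mean ± SD or median (IQR)
  reported accordingly.
* **Covariate screen.** For each baseline covariate: Pearson r between
  pooled per-period ΔICP and the covariate's same-block baseline value,
  alongside the slope and LRT p from `Δ ~ covariate + (1|animal)`. The
  published analysis prints both r and p without defining either's exact
  derivation, so both routes are reported. No multiplicity correction,
  matching the source. α = 0.05 throughout.

# Calibration and recovery studies in the test suite

* Type-I error of the carry-over, two-way interaction and
  repeated-measures tests is checked over 200 seeded null studies against
  the binomial 95% band around 5%.
* Noise-free elastance recovery is exact to machine precision by
  construction; PRx recovery is within ±0.1 of `coupling_g` for
  g ∈ {0, 0.3, 0.6, 0.9} using the animal-level mean of period z values
  (a single 5-min window has sampling SD ≈ 0.19 even for white noise, so
  period-level equality can only hold after averaging).
* The covariate sign-recovery study injects *isolated, power-adequate*
  effects (CVP +0.2, E_rs −0.08, others zero) rather than the
  paper-calibrated defaults: at the published effect sizes (|r| ≈ 0.2 at
  12 animals) the sign of a fitted slope is only ~80% stable — consistent
  with those effects being borderline-significant in the original
  analysis — so a ≥95% sign-recovery requirement is only meaningful for a
  clearly identified signal.

# Conventions and limitations

Time is elapsed seconds from recording start; period intervals are
half-open `[start, end)`. CSV files use comma separators and dot decimals
regardless of locale. CPP uses block ABP − block ICP with no
transducer-height correction (animals lie at zero inclination). The
pipeline is batch-oriented: no streaming, no other autoregulation indices
(Mx, ORx, TOx), no intra-breath resistance/elastance fitting, and no
claim of hemodynamic organ-model realism. The CLI surface of the original
plan is fulfilled by the exported functions plus `run_pipeline()`; no
shell executable is shipped.
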