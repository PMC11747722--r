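# lungbrain

Mechanical ventilation shapes the brain through the chest: positive
end-expiratory pressure (PEEP) and body position change intrathoracic
pressures, venous return and hence intracranial pressure (ICP), while the
cerebral vasculature tries to buffer these swings through autoregulation.
`lungbrain` implements, as a tested and reusable R pipeline, the
computational chain used to quantify these interactions in a porcine
crossover experiment: each animal undergoes a stepwise PEEP protocol
(5, 10, 15, 20, back to 5 cmH2O, 20 min per level) in both the prone and
supine position (order randomized), with continuous arterial, intracranial,
venous, airway and esophageal pressure recordings and per-period occlusion
holds.

Because such animal datasets are available only on request, the package
includes a seeded synthetic-physiology generator with known ground truth,
so every downstream stage — signal processing, respiratory mechanics, and
crossover statistics — is testable end to end without any download.

It is aimed at researchers in neurocritical-care monitoring and
ventilation physiology who want a transparent reference implementation of
these trend-based indices and of the crossover analysis around them.

## What it computes

**Trend pipeline** (from multichannel waveforms):

- 0.1 Hz coarse-graining: non-overlapping 10-s block averages per channel,
  with a validity mask (a block needs ≥ 50% finite raw samples).
- Automated artifact rejection at block level: ICP outside [−10, 60] mmHg,
  or cerebral perfusion pressure CPP = ABP − ICP outside [0, 150] mmHg.
- AMP, the intracranial pulse amplitude: 2× the spectral magnitude of the
  ICP block at the fundamental cardiac frequency (a per-beat peak-to-peak
  method is available as an alternative).
- PRx, the pressure reactivity index: Pearson correlation between 30
  consecutive 10-s averages of ABP and ICP in a 5-min moving window,
  updated every minute. Negative PRx ⇒ preserved cerebrovascular
  reactivity; positive ⇒ impaired.
- RAP, the compensatory reserve index: same moving correlation between AMP
  and mean ICP. Values near 1 ⇒ exhausted intracranial compliance.
- Fisher transform z = atanh(r) (with |r| clamped at 0.99) before any
  averaging; per-period summaries report both mean z and tanh(mean z),
  plus change-from-baseline columns against each block's PEEP-5 period.

**Respiratory mechanics** (from end-inspiratory/end-expiratory holds):

    E_rs = (Paw_ei − PEEPtot) / VT        E_cw = (Pes_ei − Pes_ee) / VT
    E_l  = E_rs − E_cw                    Ppeak_l = Ppeak_rs − Ppeak_cw
    TPP_ei = Paw_ei − Pes_ei              TPP_ee = PEEPtot − Pes_ee
    TPP_elast = Paw_ei × E_l / E_rs

    MP_rs      = 0.098 · VT · RR · (Ppeak_rs − (Paw_ei − Paw_ee)/2)
    MP_lDep    = 0.098 · VT · RR · (Ppeak_l − (TPP_ei − TPP_ee)/2)
    MP_lnonDep = 0.098 · VT · RR · (Ppeak_l − (TPP_elast − TPP_ee)/2)

with VT in litres, pressures in cmH2O and mechanical power in J/min, plus
the esophageal-catheter occlusion check (ΔPes/ΔPaw within [0.8, 1.2]).

**Crossover statistics** (on the per-period study table):

- assumption tests for the two-period crossover: carry-over, sequence and
  period effects from a linear mixed model with random intercepts for
  animal and position-within-animal, plus a paired t-test of baseline vs
  washout;
- prone-vs-supine baseline comparison (Shapiro–Wilk guided t-test or
  Mann–Whitney);
- two-way repeated-measures ANOVA of ΔICP on PEEP × position;
- repeated-measures one-way ANOVA of the pooled ΔICP across PEEP levels;
- an exploratory screen relating ΔICP to baseline covariates (baseline
  ICP, CVP, elastances, transpulmonary pressures, gas exchange, ...) via
  Pearson r and a random-intercept mixed model, without multiplicity
  correction.

## Worked example

```r
library(lungbrain)

cfg <- synth_config(n_animals = 6, period_minutes = 10,
                    washout_minutes = 10, seed = 42)
sim <- simulate_animal(cfg, 1)
sim$recording
#> Waveform recording: 330000 samples x 7 channels @ 50 Hz (110.0 min)
#>   channels: ABP, ICP, CVP, Paw, Pes, Flow, Volume
#>   11 annotated periods, 0 artifact intervals

res <- process_recording(sim$recording, f_cardiac = cfg$heart_rate / 60)
head(res$summary[, c("position", "peep", "period_label", "icp", "cpp",
                     "prx", "rap", "delta_icp")])
#>   position peep period_label  icp  cpp    prx    rap delta_icp
#> 1   supine    5     baseline 11.5 73.4 -0.381 -0.154   0.00000
#> 2   supine   10 intervention 12.1 72.9 -0.315 -0.128   0.54072
#> 3   supine   15 intervention 12.6 72.4 -0.155  0.291   1.06990
#> 4   supine   20 intervention 13.2 71.8 -0.403  0.373   1.63615
#> 5   supine    5       return 11.6 73.4 -0.268  0.212   0.00885
#> 6   supine    5      washout 11.5 73.5 -0.175  0.161  -0.02751
```

This animal's configured reactivity is `coupling_g = -0.3` (intact
autoregulation) and its PEEP slope is about 0.55 mmHg per 5 cmH2O: PRx
stays negative in every period while ICP climbs by ~0.5 mmHg per PEEP
step and returns to baseline at the final PEEP-5 period.

```r
compute_mechanics(sim$holds)[1:3, c("peep", "E_rs", "E_cw", "E_l",
                                    "TPP_ei", "TPP_ee", "MP_rs")]
#>   peep E_rs E_cw  E_l TPP_ei TPP_ee MP_rs
#> 1    5 52.7 21.3 31.4   9.38   3.09  7.55
#> 2   10 51.7 18.1 33.5  12.53   5.82 10.08
#> 3   15 50.8 23.8 27.0  14.82   9.41 12.89

out <- run_pipeline(cfg)
out$assumptions
#> Statistical report: crossover assumptions for delta_icp
#>   model: delta_icp ~ peep * sequence + period + (1|animal) + (1|animal:position)  [ML, LRT]
#>   p[carryover] = 0.219
#>   p[sequence] = 0.538
#>   p[period] = 0.943
#>   p[paired_baseline_washout] = 0.584
out$rm_anova
#> Statistical report: repeated-measures one-way ANOVA of delta_icp across PEEP (positions pooled)
#>   model: delta_icp ~ peep + Error(animal:position)
#>   p[peep] = 0.0154
```

The crossover assumptions hold (no carry-over, sequence or period effect),
so the pooled repeated-measures ANOVA is the valid test of the PEEP
effect — here significant even with only 6 simulated animals.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full default analysis from scratch with the given seed —
simulating the 12-animal study, running the trend pipeline on every
recording, deriving the mechanics and fitting the crossover models — and
logs the pooled ΔICP per PEEP level and the headline p-values before
writing the JSON result object.

## Package layout

- `R/synth-*.R` — synthetic physiology: configuration, waveform-level
  generator, table-level generator for calibration studies,
  artifact injection.
- `R/trend.R`, `R/indices.R`, `R/periods.R` — coarse graining, artifact
  rejection, AMP, moving correlations (PRx/RAP), period summaries.
- `R/mechanics.R` — elastances, transpulmonary pressures, mechanical
  power, occlusion validation.
- `R/stats-crossover.R` — crossover assumption tests, baseline
  comparisons, ANOVAs, covariate screen.
- `R/io.R` — CSV dialects for waveforms/trends/designs and the
  end-to-end `run_pipeline()` driver with its JSON manifest.
- `vignettes/lungbrain-methods.Rmd` — the model, its assumptions, and
  every numerical choice, with rationale.
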