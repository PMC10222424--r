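# uniecg

Feasibility analysis of **single-position ECG detection** — reading a
cardiac signal at one body-surface point with a charge-induction sensor,
no distant reference electrode — evaluated entirely on simulated data.
The package is aimed at biosignal and instrumentation researchers who want
a reproducible, desk-scale testbed for the question: *does a
single-electrode, wave-like surface trace still carry the beat-to-beat
rhythm information that a conventional two-electrode lead provides?*

It contains two instruments and the analysis pipeline that connects them:

1. **A 2-D monodomain FitzHugh–Nagumo heart–torso phantom.** Active tissue
   follows

   ```
   du1/dt = div(D grad u1) + u1 (u1 - theta)(alpha - u1) - u2
   du2/dt = eps (beta u1 - gamma u2 - delta)
   ```

   on a labelled grid with a full conduction system (sinoatrial node →
   atria → atrioventricular node → His bundle → bundle branches → Purkinje
   fibers → ventricles), passive volume conductors (torso, lungs, blood
   chambers), a non-conducting fibrous barrier bridged only by the AV
   node, and an optional electrode layer. One simulation yields both a
   conventional differential lead (quasi-static volume-conductor
   projection; shows P–QRS–T) and the single-position trace (diffused
   field at the electrode contact; a smooth wave per cycle).

2. **A synthetic measurement campaign.** Paired 5-minute recordings — a
   single-position-morphology experimental channel and a PQRST control
   channel driven by one RR-interval sequence — plus an 8-minute dynamic
   recording cycling through sitting / office work / turning / stepping
   noise presets (baseline drift, 50 Hz powerline, white noise at exact
   target SNR).

3. **The evaluation pipeline.** ECG filter chains (0.5 Hz or 0.25 Hz
   high-pass arm, 50/100 Hz notches, 100 Hz low-pass, zero-phase),
   Pan–Tompkins-style beat detection, instantaneous heart-rate graphs
   (`FHR = 60/(nT)`), Pearson correlation and extremum deviation between
   the two channels' heart-rate curves, beat-ensemble SNR estimation, and
   unrecognizable-signal screening.

## Worked example

```r
library(uniecg)

## forward-simulate the phantom: 3 cycles at 75 bpm on a 100x100 grid
cfg <- default_run_config()
cfg$phantom$rows <- cfg$phantom$cols <- 100
cfg$simulation$duration_s <- 2.4
sim <- run_simulation_experiment(cfg)
round(sim$recording$activation_times, 4)
#> sinoatrial_node              atria atrioventricular_node     his_bundle
#>          0.0170             0.0358                0.0414         0.0512
#> bundle_branches    purkinje_fibers            ventricles
#>          0.0727             0.0835                0.1077

## synthesize a 5-minute paired recording and run the evaluation
pair <- synthesize_static_pair(cfg, seed = 1)
rep  <- analyze_pair(pair$experimental, pair$control,
                     exp_spec = filter_chain_spec(0.5),
                     ctrl_spec = filter_chain_spec(0.5))
c(r = rep$pearson_r, dmax = rep$max_hr_deviation_bpm,
  dmin = rep$min_hr_deviation_bpm)
#>         r      dmax      dmin
#> 0.9973708 0.1538254 0.3529735
```

The activation times confirm the physiological conduction sequence
(sinoatrial node first, ventricles last, ~90 ms later). The heart-rate
curves of the two detection modes correlate at r = 0.997 with extremum
deviations well under 1 bpm: the wave-like single-position channel tracks
the rhythm of the conventional channel essentially beat for beat at a
sitting-posture 20 dB SNR.

## Analysis workflow

The study is organised as numbered drivers over the package functions:

| script | what it does |
|---|---|
| `analysis/01_simulate_phantom.R` | phantom run; writes both surface traces, activation times, figures |
| `analysis/02_synthesize_recordings.R` | static 5-min pair + dynamic 8-min posture recording as CSV |
| `analysis/03_static_correlation.R` | both filter arms; heart-rate correlation report (JSON) |
| `analysis/04_dynamic_postures.R` | per-posture SNR and unrecognizable fraction |

Outputs land under `results/`. Signals are exchanged as
`time_s,value` CSV; reports as JSON. The methods vignette
(`vignettes/single-position-ecg.Rmd`) documents the model, the generator
and every estimator choice.

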