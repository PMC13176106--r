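# ivsi — isovolumic relaxation strain imaging

`ivsi` extracts early markers of **active diastolic dysfunction** from
speckle-tracking echocardiography strain traces, for researchers running
murine pressure-overload (TAC) studies — or any longitudinal design where
relaxation fails before conventional indices (E/A, E/E′, EF) move.

Conventional diastolic indices pseudonormalize as the ventricle remodels.
The isovolumic relaxation time (IVRT) — aortic valve closure (AVC) to
mitral valve opening (MVO), ~15–25 ms in the mouse — is the one window in
which ventricular volume is fixed and deformation is governed purely by
active relaxation. `ivsi` windows smoothed strain-derived signals on the
IVRT and computes, per myocardial segment and signal, the maximal value,
minimal value, maximal acceleration and minimal acceleration (signed and
absolute). The headline metric is

> **|min accel of radial strain rate|** = |min over IVRT of d(SR_rad)/dt|,

which falls when active relaxation slows (longer relaxation constant τ):
for the package's smooth-onset exponential relaxation model the exact law
is |min accel| = 1.0346 · P·g / (w²τ)^(2/3), with P the peak strain, g the
segment gain and w the IVRT duration — strictly decreasing in τ.

The package contains:

* a data model and delimited-text I/O for traces, valve events, cohort
  tables and results (`strain_trace()`, `read_trace_table()`,
  `valve_events()`, `write_metrics_table()`);
* signal processing: order-2 low-pass Butterworth at 20 Hz (zero-phase or
  single-pass), second-order numerical differentiation, phase windowing,
  IVRT extraction (`butterworth_lowpass()`, `differentiate()`,
  `window_trace()`, `ivsi_extract()`);
* hemodynamics (dP/dt extrema, Weiss tau from log-linear pressure decay)
  and conventional ratios (Teichholz EF, FS, E/A, E/E′);
* statistics: Welch tests, `value ~ group + day + (1 | animal)` mixed
  models with Satterthwaite df (lme4/lmerTest), BH-FDR, ICC(A,1),
  Bland–Altman, exact noncentral-t power analysis;
* a parametric murine cardiac-cycle simulator (`simulate_cycle()`,
  `simulate_cohort()`) providing ground truth for every stage, and a
  `run_pipeline()` orchestrator with a checksummed manifest.

## Worked example

Simulate one noisy cardiac cycle of a healthy mouse (420 bpm, 1000 Hz,
τ = 8 ms), process it, and read off the headline metric:

```r
library(ivsi)

cyc <- simulate_cycle(cycle_params(tau_active = 8, noise_sd = 0.5, seed = 42),
                      directions = "radial")
cyc
#> <ivsi_cycle> 6 traces, 142 samples @ 1000 Hz; HR 420 bpm, IVRT 18.0 ms, tau 8.0 ms

m <- process_cycle(cyc$traces, cyc$events)   # 20 Hz zero-phase filter, SR derivation
m[m$kind == "strain_rate" & m$metric == "min_accel", ][1:7, ]
#>    direction   layer        kind segment_id    metric  value abs_value
#> 28    radial midwall strain_rate          1 min_accel -64972     64972
#> 32    radial midwall strain_rate          2 min_accel -61069     61069
#> 36    radial midwall strain_rate          3 min_accel -55844     55844
#> 40    radial midwall strain_rate          4 min_accel -49630     49630
#> 44    radial midwall strain_rate          5 min_accel -55656     55656
#> 48    radial midwall strain_rate          6 min_accel -59910     59910
#> 54    radial midwall strain_rate         NA min_accel -57847     57847

headline_metric(m)   # across-segment mean |min accel radial SR|, %/s^2
#> [1] 57846.81
```

Per-segment rows localise the deficit; the `segment_id = NA` row is the
across-segment mean. Doubling τ (the TAC phenotype) drops the same metric
to ~45,000 %/s² — a ~22 % reduction after 20 Hz smoothing, detectable at
n = 10/group from the first measured day:

```r
tac <- simulate_cycle(cycle_params(tau_active = 16, noise_sd = 0.5, seed = 43),
                      directions = "radial")
headline_metric(process_cycle(tac$traces, tac$events))
#> [1] 45032.63
```

A full cohort run — simulate 2×10 animals over days 1–14, extract the
metric panel, fit mixed models with FDR, and write `metrics.tsv`,
`stats.tsv`, `ground_truth.json` plus a checksummed `manifest.json`:

```r
res <- run_pipeline(pipeline_config(out_dir = "demo_run", seed = 1))
subset(res$stats, effect == "group" & metric == "radial_midwall_strain_rate_min_accel_abs")
```

A thin command-line front end with `simulate`, `process`, `stats` and
`run` subcommands ships in `inst/scripts/ivsi`.

## Scientific background

The methods vignette (`vignettes/ivsi-methods.Rmd`) documents the cycle
model and its closed forms, the filtering/differentiation/windowing
choices, what the simulator does and does not emulate, and the statistical
design (mixed-model structure, FDR family, ICC variant, power-analysis
conventions).
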