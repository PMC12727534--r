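# photoflux

Analysis of two-channel fibre-photometry recordings in R, with a seeded
cohort simulator for end-to-end validation.

Fibre photometry records bulk fluorescence of a genetically encoded
sensor (a dopamine sensor such as dLight, or GCaMP in AgRP hunger
neurons) through an implanted fibre. The 465 nm channel carries the
ligand-dependent signal; the 405 nm isosbestic channel carries the same
bleaching and motion artifacts but no signal. photoflux implements the
standard correction-and-summary chain on top of that design:

1. **Preprocessing** — crop the power-up start, centred moving-average
   smoothing, bin-mean downsampling to 50 Hz, ordinary-least-squares
   alignment of the reference to the signal, and
   `dF/F = (F465 − scaled F405) / (scaled F405)`.
2. **Peri-event analysis** — trial extraction around event timestamps,
   per-trial z-scoring against a pre-event baseline
   (`z = (x − μ_base)/σ_base`), within-animal averaging, window means,
   binned traces and trapezoidal AUC. Built-in protocol presets
   (`dlight_food`, `agrp_food`, `agrp_injection`, `agrp_hormone`) carry
   the windows and baselines for the standard paradigms.
3. **Statistics** — pooled/Welch t-tests, paired t, Wilcoxon rank-sum
   with exact enumeration at small n, balanced two-way ANOVA with
   uncorrected Fisher's LSD post hoc, all returned as broom-style tidy
   tibbles.
4. **Simulation** — a generative model of the measurement (event-locked
   double-exponential transients, multi-exponential bleaching, a motion
   artifact shared across channels, channel noise) with full ground
   truth, so every stage can be validated without any recorded data.
5. **Phenotype metrics** — HOMA-IR (insulin × glucose / 22.5), odour and
   diet preference indices, normalized latency to eat, and lean-mass
   corrected energy expenditure.

## Worked example

Simulate a two-group cohort in which the "exposed" group has a blunted
dopamine response (half the transient amplitude), then run the full
dopamine food-approach analysis:

```r
library(photoflux)

coh <- simulate_cohort(c(5, 5), c(control = 0.06, exposed = 0.03),
                       sim_config(), seed = 42)
an  <- analyze_cohort(coh, load_protocol("dlight_food"))
glance(an)
#> # A tibble: 1 × 4
#>   preset      n_animals n_excluded n_dropped_trials
#>   <chr>           <int>      <int>            <int>
#> 1 dlight_food        10          0                0

tidy(an)
#> # A tibble: 20 × 8
#>   animal_id   group_id n_valid_trials window win_start win_end window_mean   auc
#>   <chr>       <chr>             <int> <chr>      <dbl>   <dbl>       <dbl> <dbl>
#> 1 control_a01 control               5 [0,5]          0       5       8.88  44.4
#> 2 control_a01 control               5 [5,10]         5      10       1.00   4.99
#> # ...

group_stats(an, "window_mean")
#>   window statistic df      p.value    mean_1    mean_2
#> 1  [0,5] 125.48859  8 1.817984e-14 8.9058852 4.4578802
#> 2 [5,10]  24.12187  8 9.302030e-09 0.9841053 0.4867178
```

Each animal contributes one value per summary window (its trial-averaged
z-scored response); the `[0,5]` s window mean of ~8.9 baseline-SDs in
controls versus ~4.5 in the exposed group reflects the simulated 2:1
amplitude ratio, and the pooled t-test on the 5 + 5 per-animal values
detects it. `plot_group_windows(an)` draws the per-animal dots with group
mean ± s.e.m.; `autoplot()` methods exist for recordings, dF/F traces,
trial matrices and per-animal mean traces.

Individual stages are exposed (`preprocess()`, `extract_trials()`,
`zscore_trials()`, `average_trials()`, `window_mean()`, `bin_trace()`,
`trace_auc()`), as are the file formats (`read_recording()`,
`read_events()`, CSV/TSV with a JSON metadata sidecar) and a shell
pipeline (`inst/scripts/photoflux.R` with `simulate`, `analyze`,
`report` subcommands).

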