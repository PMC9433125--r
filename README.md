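# swdeeg

Time-frequency-spatial analysis of multichannel scalp EEG around absence
seizures, for clinical-neurophysiology researchers who want a tested,
reproducible pipeline from raw 16-channel 10-20 recordings (200 Hz,
average reference) to per-rhythm statistics.

Absence seizures produce high-amplitude ~3 Hz spike-and-wave discharges
(SWD). The package quantifies their temporal, spectral and spatial
evolution and contrasts three states — seizure-free background
(inter-ictal), the 30 s before onset (pre-ictal), and the seizure itself
(ictal):

* **Preprocessing** — zero-phase Butterworth band-pass (1-70 Hz,
  order 4 applied forward-backward) and 50 Hz notch; half-open 1-s
  epochs anchored at the annotated seizure onset; amplitude-based
  artifact rejection.
* **Spectral power** — Welch's averaged modified periodogram
  (1-s Hamming windows): for segment *i*,
  `I_i(w) = |sum_n x_i(n) w(n) e^{-jwn}|^2 / (U M)` with
  `U = mean(w^2)`, averaged over segments; per-rhythm log band power
  `P_i = log10( sum_{f in band i} PSD(f) )` for delta (1-4), theta
  (4-8), alpha (8-12), beta (12-30) and gamma (30-70 Hz).
* **Synchronization** — instantaneous Hilbert phase per channel;
  phase locking value `PLV = |sum_n e^{j dPhi(n)}| / N` for each of the
  120 channel pairs; binary networks at `PLV > 0.6`; mean-PLV time
  courses.
* **Topography** — exact radial-basis interpolation of per-channel
  power onto the head disc, and a diffusion-extent metric (channels
  above a power level) tracking the spatial spread of the discharge.
* **Group statistics** — tie-corrected Kruskal-Wallis omnibus and
  pairwise contrasts per rhythm, for band power and PLV.
* **Synthetic data** — a deterministic generator of SWD recordings
  (1/f background, posterior alpha, pre-ictal delta/theta elevation,
  frontal-dominant 3 Hz discharges with propagation lag and phase
  jitter) so the whole pipeline is testable without patient data.
* **Cohort metadata** — a bundled 33-patient clinical table with
  summary statistics (age, sex, seizure counts by induction mode,
  frontal-origin fraction).

All tabular results are tidy tibbles that chain with the pipe; fitted
tests support `tidy()`/`glance()`; result types have `autoplot()`/
`plot_*()` ggplot2 methods.

## Worked example

```r
library(swdeeg)
library(dplyr)

run <- run_analysis(sim_config(rng_seed = 1))
run
#> <swd_run>  100 epochs | 8000 band-power rows | 72000 PLV rows | stats: 40 comparisons

run$stats |> filter(contrast == "omnibus") |> select(feature, band, H, df, p)
#> # A tibble: 10 × 5
#>    feature    band       H    df         p
#>    <chr>      <chr>  <dbl> <int>     <dbl>
#>  1 band_power delta  427.      2 1.60e- 93
#>  2 band_power theta  457.      2 6.98e-100
#>  3 band_power alpha  363.      2 1.27e- 79
#>  4 band_power beta   387.      2 8.13e- 85
#>  5 band_power gamma  226.      2 7.38e- 50
#>  6 plv        delta 2639.      2 0
#>  7 plv        theta 2709.      2 0
#>  8 plv        alpha 1929.      2 0
#>  9 plv        beta  2371.      2 0
#> 10 plv        gamma   10.2     2 5.96e-  3

tc <- run$plv_timecourse
tc$t_rel[which.max(tc$plv_mean)]   # broadband synchronization peaks at
#> [1] 6                            # 6 s after onset (PLV_mean 0.918)
```

The omnibus H statistics say that every rhythm's power and phase
locking differ across the three states on this simulated seizure —
the ictal state dominating both — and the mean-PLV time course rises
after onset, peaks mid-seizure and falls, the pattern the diffusion
extent of the topographic maps mirrors. Per-band tables
(`run$band_power`, `run$plv`), time courses, topographic frames
(`topography_frames()`, `autoplot()`) and pairwise contrasts are all in
the returned object; `out_dir =` additionally writes CSV/JSON artifacts
and a run manifest.

The cohort surface:

```r
summarize_cohort(parse_cohort()) |> as.data.frame()
#>   n_patients mean_age   sd_age sd_mode n_female n_male total_seizures
#> 1         33 8.343939 2.167374  sample       23     10             67
#>   n_spontaneous_seizures n_hyperventilation_seizures n_spontaneous_patients
#> 1                     21                          46                     10
#>   n_frontal_origin_patients frontal_fraction
#> 1                        22        0.6666667
```

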