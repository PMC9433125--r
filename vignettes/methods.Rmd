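---
title: "Time-frequency-spatial analysis of spike-wave discharge EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency-spatial analysis of spike-wave discharge EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdeeg)
library(dplyr)
```

## The problem

Childhood absence epilepsy presents as brief generalized seizures whose
scalp EEG signature is a high-amplitude, bilateral ~3 Hz spike-and-wave
discharge (SWD). Clinically useful questions are quantitative: how does
spectral power distribute over rhythms and over the scalp as a seizure
starts, spreads and ends, how strongly do channels phase-lock to one
another, and do the 30 seconds *before* a seizure already differ from
seizure-free background? `swdeeg` implements that analysis chain for
16-channel 10-20 recordings sampled at 200 Hz under a monopolar average
reference: zero-phase filtering, 1-s epoching around annotated onsets,
Welch spectral power, per-rhythm log band power, Hilbert-phase
phase-locking values (PLV), thresholded synchronization networks, scalp
topography with a diffusion-extent metric, and Kruskal-Wallis
comparisons across inter-ictal, pre-ictal and ictal states.

Patient EEG of this kind is rarely shareable, so the package carries a
first-class synthetic generator whose output has the statistical
structure the analysis assumes. Every stage is tested against that
generator; what that does and does not establish about real data is
discussed at the end.

## Preprocessing

Raw signals are band-passed 1-70 Hz with a fourth-order Butterworth
design and notch-filtered at 50 Hz. Both filters are applied forward and
backward (`signal::filtfilt` with 1 s of reflect padding), which doubles
the effective order and cancels group delay. Zero-phase operation is not
cosmetic here: PLV is computed from instantaneous phases, and a causal
filter's frequency-dependent delay would masquerade as spurious phase
differences between narrowband components. The notch is an order-2
band-stop of half-width 0.5 Hz: measured on sinusoids, it attenuates
50 Hz by far more than 20 dB while passing 48 and 52 Hz at gain 0.994.

Epochs are half-open 1-s windows `[t, t+1)` anchored at the annotated
seizure onset, so the first ictal epoch starts exactly at onset
(`t_rel = 0`). The 30 windows immediately before onset are pre-ictal;
complete windows inside an annotated background interval are
inter-ictal; windows after offset are post-ictal; partial trailing
windows are dropped. When several seizures occur in one recording, a
pre-ictal window that overlaps an earlier seizure is excluded (with a
message), since consecutive absences can encroach on the 30-s pre-ictal
span; where labels compete, ictal outranks pre-ictal, which outranks
post-ictal and background, and overlapping lower-priority windows are
discarded so accepted epochs tile the recording without overlap.

Component-based artifact cleaning is out of scope; a configurable
absolute-amplitude criterion (default 200 uV after filtering) stands in
for it, and the generator produces clean data by default. In the
pipeline the criterion is applied to non-ictal epochs only:
spike-wave discharges legitimately reach several hundred microvolts,
and an amplitude rule that discarded them would delete the seizure it
is meant to protect.

## Spectral estimation

Power spectral density uses Welch's averaged modified periodogram. The
signal is cut into `L` segments of `M` samples, each segment is windowed
by `w(n)` and Fourier transformed, and the periodograms
`I_i = |X_i|^2 / (U M)` with `U = mean(w^2)` are averaged and scaled to
a one-sided density in uV^2/Hz. Within a 1-s epoch the default is a
single 1-s Hamming segment (`L = 1`), in which case the estimate equals
the single windowed periodogram exactly — the unit the rest of the
pipeline consumes. Longer windows can trade resolution for variance via
`seg_len_s` and `overlap`; a property test confirms the variance
reduction that segment averaging exists to provide.

Band power for each rhythm (delta 1-4, theta 4-8, alpha 8-12, beta
12-30, gamma 30-70 Hz) is the log of the summed density over the band's
bins. Numerical conventions, each recorded in the output metadata:

* **log base 10** — decibel-like scale; the choice affects only scale,
  and the identity `P(c x) = P(x) + 2 log10 c` pins the convention in
  tests.
* **half-open band edges** `[f_low, f_high)` — shared edges (4, 8, 12,
  30 Hz) are counted once, so the five bands partition 1-70 Hz.
* **epsilon floor** `1e-12` uV^2/Hz before the log keeps silent
  channels finite (-12 per unit bin sum) instead of `-Inf`.

## Phase synchronization

The instantaneous phase of each channel is the argument of its analytic
signal (frequency-domain Hilbert construction), after zero-phase
band-pass filtering when a specific rhythm is requested. For a channel
pair, `PLV = |mean(exp(i (phi1 - phi2)))|` over the `N = 200` samples of
a 1-s epoch: 1 for any constant lag, approaching 0 for independent
phases. Expected small-sample behaviour is part of the test suite: for
i.i.d. uniform phase differences `E[PLV] ~ sqrt(pi / 4N)` (about 0.063
at `N = 200`), and for Gaussian phase differences of variance `v` the
asymptotic PLV is `exp(-v/2)`.

Edge handling: the Hilbert transform is circular, so the pipeline
computes analytic phases over the *whole* preprocessed recording and
then cuts epochs, leaving no per-epoch transients; standalone use of
`instantaneous_phase()` flags 25 samples at each end as unreliable.
Flat (zero-variance) channels raise an error naming the channel rather
than propagating `NaN` phases.

Networks binarize the symmetric PLV matrix at a strict threshold
(`PLV > 0.6` by default, read as strong coupling); the diagonal is
forced to zero and edge count is antitone in the threshold. Whether PLV
observations enter the group statistics pooled per epoch-pair (default)
or averaged per epoch first is selectable, since pooling gives many more
but correlated observations.

## Topography and diffusion extent

Per-channel scalars (typically total log power) are interpolated over
the unit head disc from the standard 2-D polar projection of the 16
10-20 electrode sites. The interpolant is an exact radial-basis fit. The
package defaults to the first-order polyharmonic kernel `phi(r) = r`
with 24 virtual rim electrodes (inverse-distance averages of the three
nearest real sites): measured over random inputs, this keeps the frame
within about 3% of the electrode value range while remaining exact at
electrodes. The classical thin-plate kernel `r^2 log r` is available as
an option but rings badly between 16 sparse sites — worst-case
overshoots above 50% of the data range — which would paint spurious
extrema on the scalp map; this is why it is not the default. Frames
carry the dual colour-scale convention of 0-1000 for pre/post-ictal and
0-5000 for ictal maps, since discharge power dwarfs background power.

The diffusion extent of a frame is the count of channels whose value
exceeds a level — a deliberately simple proxy for spatial spread. The
pipeline's default level lies midway between the median and the maximum
per-channel total log power: below typical discharge power, above
background, so the count resolves the discharge recruiting and then
releasing channels. A level at the background median would saturate at
16 throughout the seizure and show no dynamics.

## Group statistics

Band powers and PLVs are compared across the three states per rhythm
with the Kruskal-Wallis rank test (`stats::kruskal.test`, which
implements the classical tie-corrected statistic; ties arise when PLVs
saturate at 1). The omnibus three-group test is reported alongside the
three pairwise contrasts; degrees of freedom are `k - 1`. p-values use
the chi-square upper tail. No multiple-testing correction is applied by
default, mirroring per-band reporting conventions in this literature; a
Bonferroni option exists. Monte-Carlo suites verify the test's size
(null rejection rate near 0.05) and power under a large ictal shift.

## The synthetic generator

`simulate_recording()` is the package's stand-in for patient data. Its
defaults are the study conditions the rest of the package is tested
under; they were chosen once, from the recording conventions and
qualitative descriptions the analysis targets, not tuned to any test:

* 200 Hz, 16 montage channels, 120 s per recording, one 10-s seizure at
  70 s (absence seizures run roughly 9-32 s), a 30-s annotated
  background interval at 5-35 s.
* **Background**: spectrally shaped 1/f noise (power slope about -1,
  the canonical broadband EEG spectrum), 20 uV RMS per channel,
  independent per channel except for a 10% common component so that
  background PLV is small but nonzero, as in real average-referenced
  EEG; a 10 uV, 10 Hz posterior alpha component with slowly drifting
  phase, weighted toward O1/O2.
* **Pre-ictal state**: delta- and theta-band background power is raised
  1.5x in the 30 s before onset. No quantitative pre-ictal effect size
  is established for this syndrome; 1.5x is an artifact parameter
  chosen so the elevation is detectable at the study's sample sizes
  without being trivially large.
* **Ictal discharge**: a periodic spike-and-wave template (fundamental
  3 Hz plus four decaying aligned harmonics, unit peak) at 300 uV peak,
  frontally weighted (gain 1.0 front to 0.6 occipital), with onset
  delays graded 0-80 ms front to back, a 2-s attack / 3-s decay
  trapezoidal envelope, and per-channel phase jitter of 0.2 rad
  resampled each second — constant within an epoch, so within-epoch PLV
  stays high while epochs vary. Because the five-harmonic template tops
  out at 15 Hz, a sharp Gaussian transient (120 uV, 6 ms SD) is added at
  each spike time; real spike components are broadband, and without
  this term ictal recordings would show no beta/gamma elevation at all.
* **Determinism**: every stream is seeded from the configuration, with
  per-channel, per-stage derived seeds, so recordings are bit-identical
  under a fixed config and adding a channel does not perturb the others.

What the generator emulates: state-dependent band power and phase
locking, frontal dominance, graded propagation, rise-and-fall discharge
evolution, 2-4 Hz spectral peaks. What it does not: real artifact
classes (blinks, EMG, electrode pops), biophysical discharge morphology
(it is a signal model, not a thalamocortical model), inter-patient
variability in topography, or medication and vigilance effects.
Passing recovery tests therefore shows the *pipeline* extracts the
structure it is supposed to extract, not that the effect sizes match
any patient population.

## Problem sizes and runtime choices

The bundled test and verification suites use 1-s epochs at 200 Hz,
recordings of 60-120 s, 30 epochs per non-ictal state, and 20-50
simulated recordings per recovery claim — enough for the Monte-Carlo
rates being checked (rejection rates with bands of a few percent) while
keeping a full run in the minutes range on a single core. Monte-Carlo
oracle tests use 200-2000 replicates as stated alongside each check.

## Known limitations

* The EDF writer/reader supports the subset of the format this package
  produces (uniform rate, 16-bit, 1-s records); annotations travel in a
  sidecar CSV, not an embedded annotation channel.
* Epoching assumes annotation times on the second grid of the onset;
  sub-second onset offsets shift the grid with the onset.
* PLV is undirected and amplitude-blind by design; no lagged or
  directed connectivity measures are provided.
* The cohort module reports the sample-SD convention because it
  reproduces the published age dispersion; the population convention is
  available and flagged in the output.

## A worked run

```{r run, eval = FALSE}
run <- run_analysis(sim_config(rng_seed = 1), out_dir = "results")
run$stats |> filter(contrast == "omnibus", feature == "band_power")
plot_timecourse(run$plv_timecourse)
plot_state_comparison(run$band_power)
```
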