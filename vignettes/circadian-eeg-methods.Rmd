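---
title: "Methods: circadian rhythm extraction and phase estimation from sleep EEG/EMG"
author: "circaeeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian rhythm extraction and phase estimation from sleep EEG/EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`circaeeg` analyses circadian structure in long-term (multi-day) rodent
EEG/EMG recordings that have already been scored into WAKE / NREM / REM
stages per 10-s epoch. The pipeline has four analysis layers:

1. **Staging refinement** — per-epoch EMG amplitude, an Otsu-threshold wake
   override, and hourly stage amounts with cosinor fits.
2. **Spectral reduction** — per-epoch EEG power spectra on a fixed
   0–16 Hz / 0.1 Hz grid, averaged per (hour, stage) into the central
   tensor of the analysis.
3. **Rhythm extraction** — for every stage and frequency, the relative
   amplitude and peak time of the 24-h component of hourly power.
4. **Phase estimation** — machine-learning regression of the hourly
   normalized spectral distribution onto the unit circle, decoding
   subjective circadian time, evaluated with a cosine accuracy statistic.

A synthetic cohort generator with fully known injected rhythms is a
first-class module: every downstream stage has a ground-truth recovery test
against it.

## Staging layer

**EMG amplitude.** The amplitude of epoch $k$ is
$\log_{10} \mathrm{sd}(\text{EMG samples of } k)$, with the population SD
(divide by $n$). A zero-variance epoch has no defined log-amplitude and is
flagged missing, never $-\infty$; missing epochs keep their scored label in
the override.

**Wake override.** Muscle tone makes the EMG amplitude distribution
bimodal: low in sleep, high in wakefulness. The threshold between the modes
is found by Otsu's method on a 256-bin equal-width histogram of all
amplitudes, and every epoch whose amplitude *strictly exceeds* the
threshold is relabelled WAKE regardless of its scored stage. The override
never creates sleep labels and is idempotent. Numerical detail: the
between-class variance is exactly flat across empty histogram regions, so
for well-separated modes the maximizing boundary is a whole plateau; we
report the mean of the maximizing boundaries (the mid-gap threshold), which
is the behaviour users of image-processing implementations expect, rather
than the arbitrary lowest edge of the plateau.

**Hourly amounts and cosinor.** Stage minutes are counted per half-open
hour bin $[h, h+1)$. The rhythm of each stage's hourly amount is fit by
least squares as $y = M + A\cos(2\pi (t-\phi)/P)$ with amplitude
constrained nonnegative and the period bounded (default 20–28 h, wide
enough for free-running periods in constant darkness). Fitting uses
Levenberg–Marquardt (`minpack.lm`); initialization takes $M$ at the mean,
$A$ at half the range, and $\phi$ from the closed-form first-harmonic
estimator at $P = 24$ h, which makes the noiseless fit exact and the noisy
fit reliably convergent. A constant series is reported as amplitude 0 with
an unidentifiable (NA) period and a `flat` flag rather than an error.

## Spectral layer

Each 10-s epoch at 128 Hz yields 1280 samples, whose discrete Fourier
transform natively resolves 0.1 Hz — every analysis bin from 0.0 to
16.0 Hz (161 bins, both endpoints) is an exact DFT bin, so a rectangular
window with no zero-padding or interpolation is used and only the epoch
mean is removed. Inputs whose sample count and rate do not make 0.1 Hz a
native bin are rejected instead of interpolated. The per-bin power
convention is $|Y_k|^2/n$ with interior bins doubled, so the full one-sided
spectrum sums to $n$ times the epoch variance (Parseval); since every
downstream quantity is a ratio, the convention cancels.

The central tensor averages per-epoch spectra within each (hour, stage)
cell. A cell where the stage never occurs is *masked*: it carries NA, is
excluded from all downstream sums with the effective series length reduced
accordingly, and is never imputed as zero — interpolation would fabricate
rhythm where none was observed.

## Rhythm extraction

For each stage and frequency, hourly power is normalized to relative
deviations $\mathrm{norm}_i = (\mathrm{hourly}_i - \mathrm{ave}) /
\mathrm{ave}$, where the average runs over non-missing hours (at least 24
required, one full cycle). The 24-h component is

$$\mathrm{COS} = \frac{2}{T'}\sum_i \mathrm{norm}_i \cos\!\frac{2\pi i\,\Delta t}{\tau},
  \qquad
  \mathrm{SIN} = \frac{2}{T'}\sum_i \mathrm{norm}_i \sin\!\frac{2\pi i\,\Delta t}{\tau},$$

with $\tau = 24$ h, $\Delta t = 1$ h, $i$ the 1-based hour index over the
whole concatenated recording (72 h for 3 days), and $T'$ the count of
non-missing hours. Amplitude and peak time follow as
$A = \sqrt{\mathrm{COS}^2 + \mathrm{SIN}^2}$ and
$t_p = \mathrm{arctan2}(\mathrm{SIN}, \mathrm{COS})\,/\,2\pi \cdot 24$,
wrapped into $[0, 24)$. Over complete 24-h-periodic data sampled at 72
hourly points the estimator is exact by discrete orthogonality.

Two conventions deserve note:

* **Hour-time assignment.** The value of hour bin $[i-1, i)$ is assigned
  time $i\,\Delta t$, exactly as the index in the sum implies. Because the
  epochs in that bin centre near $i - 0.5$, a rhythm injected with peak $p$
  is recovered with peak $\approx p + 0.5$ h; this half-hour binning offset
  is inherent to the convention, well inside the ±1 h recovery tolerances
  used throughout, and cancels in all group comparisons (both groups share
  it). A `time_assign = "center"` switch in `fourier_component()` is
  provided for sensitivity analysis.
* **Fixed 24-h period.** The first-harmonic extraction uses $\tau = 24$ h
  under both light–dark and constant-dark conditions, with hours labelled
  as projected ZT; free-running period estimation is the cosinor's job via
  its period bounds.

**Group comparison.** Peak times are circular quantities; young–old peak
comparisons use the Mardia–Watson–Wheeler uniform-scores test. Pooled
observations get circular midranks mapped to equally spaced angles
$\beta = 2\pi\,\mathrm{rank}/N$ and
$W = 2\sum_g (C_g^2 + S_g^2)/n_g$; both the asymptotic $\chi^2_2$ p-value
and a label-permutation p-value (9999 permutations by default) are
reported, since group sizes in this field are often below the asymptotic
regime. Amplitudes, being linear quantities, are compared by Welch t-tests
as a convenience.

## Phase estimation

Time of day is encoded on the unit circle,
$(x, y) = (\cos, \sin)(\mathrm{ZT}/24 \cdot 2\pi)$, and two independent
single-output regressors are trained, one for each component; the estimate
is decoded as $\mathrm{arctan2}(\hat y, \hat x)/2\pi \cdot 24$. The decoder
is scale free, so predictions are deliberately not renormalized onto the
circle. Features are hourly spectral *distributions* — each constituent
spectrum divided by its sum — in one of five modes: one stage's spectrum
(NREM, REM, WAKE), the pooled hourly spectrum, or the concatenation of all
three stage spectra. The 0 Hz bin is excluded (identically ~0 after epoch
mean removal, a degenerate column). Hours where a single-stage mode's stage
is absent are dropped; in the concatenated mode the missing constituent is
imputed with that mouse's time-averaged normalized spectrum and flagged —
imputation with a time-constant quantity cannot inject rhythm, and it keeps
sample counts comparable across modes.

The regressor bank uses the standard implementations with their defaults:
`lm`, ridge (`MASS::lm.ridge`, $\lambda = 1$), k-nearest neighbours
(`caret::knnreg`, $k = 5$), support-vector regression (`e1071::svm`,
radial kernel, $\varepsilon$-regression defaults), and random forest
(`ranger`, 500 trees, impurity importance, fixed seed). Evaluation is
leave-one-mouse-out: train on all other mice, predict every hour of the
held-out mouse, and score with the accuracy statistic
$\mathrm{mean}\,\cos\{(\text{estimated} - \mathrm{ZT})/24 \cdot 2\pi\}$,
which is 1 for perfect estimation, $-1$ in antiphase, and 0 for a constant
6-h error. Stochastic algorithms are repeated with seeds $0..4$ and
averaged; deterministic ones run once. Cross-cohort prediction applies a
model trained on one cohort (e.g. young, LD) to another and summarizes the
per-timepoint circular mean delay $\mathrm{ZT} - \text{estimated}$
(positive = the cohort's subjective time lags the clock). Random-forest
feature importances are reported per frequency bin separately for the
cosine regressor (morning/evening discrimination) and the sine regressor
(day/night discrimination), normalized to sum to 1, plus per-stage sums.

One numerical-hygiene detail: feature vectors are quantized to 12
significant digits. Averaging different numbers of epochs leaves
count-dependent floating-point residue at ~1e-16 relative, and scale-free
learners (forests, nearest neighbours) would treat that residue as a real
covariate; in degenerate rhythm-free data it is the *only* across-hour
variation and deterministically encodes the stage-occupancy rhythm, so an
estimator could appear to decode time from spectra that carry no spectral
rhythm at all. Twelve digits is far below any physiological signal and
removes the side channel.

Algorithm *ranking* on synthetic cohorts is reported, not asserted: which
regressor wins is a property of the data-generating process, and the
synthetic process is much cleaner than animal data.

## The synthetic cohort generator

The generator is the package's test bed and defines its study conditions.

**Hypnograms.** Stage sequences come from a time-inhomogeneous Markov
chain. For each ZT hour, the transition matrix is constructed to have the
target occupancy (the spec's hourly WAKE/NREM/REM probabilities) as its
stationary distribution, with persistence set by fixed mean bout durations
— WAKE 60 s, NREM 100 s, REM 30 s, chosen as realistic fragmentation
scales for mice; published work rarely reports bout statistics, so these
are stand-ins, not estimates. The construction is reversible
(symmetric probability flow); when an hour's occupancy makes the flow
infeasible (one stage's leave-rate exceeding the sum of the others'), the
minority-stage rates are scaled up, which preserves the stationary
occupancy exactly at the cost of shortening minority bouts during strongly
dominated hours. With 360 epochs per hour the chain mixes well within an
hour, so hourly occupancies match their targets to sampling error.

**EEG.** Each epoch is synthesized by inverse FFT of the one-sided target
spectrum: the stage's spectral template multiplied per frequency by
$1 + a\cos(2\pi(t - p)/24)$ at the epoch's ZT $t$, with independent uniform
random phases per epoch and frequency, zero DC (epochs are mean free,
matching the analysis's mean removal; templates are stored strictly
positive but the DC bin carries no signal power), and no power above
16 Hz. Because only phases are random, each epoch's periodogram equals the
modulated template *exactly*; hourly averages are nearly noise free and the
recovery tolerances can be tight. This is a deliberate idealisation — see
limitations.

**EMG.** Per-epoch white noise with SD drawn as
$10^{\mathcal N(\mu_s, \sigma_s)}$, stage-dependent: log10 mean 1.0 (WAKE),
0.30 (NREM), 0.25 (REM) with SDs 0.15/0.12/0.12, giving the strongly
bimodal amplitude distribution the override relies on (WAKE–NREM
separation ≈ 3.6 pooled SDs).

**Modulation defaults ("young").** Smooth Gaussian-in-frequency amplitude
profiles: NREM peaking at 4 Hz with $a = 0.3$ and peak time ZT18 (delta
power maximal in the dark period), REM at 7 Hz ($a = 0.2$, ZT20), WAKE at
8 Hz ($a = 0.15$, ZT6); each stage's peak time drifts slowly across
frequency (0.5–0.75 h/Hz). The drift is what makes the hourly spectral
shape an injective function of ZT: modulation at a single common phase
would leave morning and evening mirror-images indistinguishable, and no
phase estimator could beat that symmetry.

**Aging.** One parameter pair: an amplitude attenuation factor in $(0,1]$
and a phase delay in hours, applied to the modulation map ($a \to
\alpha a$, $p \to p + d$) and to the rhythmic part of the stage-occupancy
curves (deviation from the 24-h mean scaled by $\alpha$ and rotated by
$d$; the hourly triples keep summing to 1 because all three stages
transform identically). The "old" cohorts used in tests set
$\alpha = 0.5$, $d = 2$ h.

**Lighting.** `LD` vs `DD` is metadata only: the generator's rhythms are
clock driven by construction, so constant darkness produces the same
statistical structure with hours still labelled as projected ZT.

**Seeding.** One root seed per cohort; each mouse draws from seed streams
derived arithmetically from the root seed and the mouse index (separate
streams for hypnogram and signals), so any mouse can be regenerated alone,
reruns are bit identical, and a cohort's first $k$ mice are themselves a
reproducible $k$-mouse cohort.

### What the generator does and does not emulate

It emulates: 10-s epochs at 128 Hz over multi-day recordings;
stage-dependent spectral shape; frequency-resolved circadian modulation of
power; diurnal stage-amount rhythms with realistic bout-scale
fragmentation; bimodal EMG amplitudes; attenuated and delayed rhythms in
old animals. It does **not** emulate: waveform morphology (spindles, theta
bursts), cross-epoch signal continuity, periodogram sampling noise
(epoch spectra are exact by design), artifacts and electrode drift,
inter-individual spectral variability beyond the stochastic hypnogram,
homeostatic (process-S) dynamics of delta power, or light-masking effects
on behaviour. Passing recovery tests therefore demonstrates correctness of
the analysis chain, not expected performance on animal data — real
leave-one-out accuracies will be lower than the synthetic ones.

## Problem sizes and runtime choices

Tests and the analysis scripts use cohorts sized to exercise the method at
the scale it was designed for while staying desk-runnable: 3-day
recordings; 10 young mice for leave-one-out phase estimation with the
5-trial random-forest protocol; 5 mice per group for young/old recovery
comparisons; 5 mice with modulation removed for the null check
(single-trial — the null needs no trial averaging); 20 replicate
hypnograms for occupancy recovery; 100 random inputs for the Otsu oracle
scan; 9999 permutations for circular tests. Quick unit tests use 1-day,
1–3-mouse cohorts.

## Known limitations

* Hypnograms are taken as given (scoring itself, e.g. by a neural-network
  scorer, is upstream); the first epochs of a recording are assumed
  scored.
* The EMG override assumes a bimodal amplitude distribution; recordings
  dominated by one state can make the Otsu threshold meaningless.
* Rhythm extraction assumes a sinusoidal 24-h component; strongly
  non-sinusoidal rhythms load their power onto harmonics the single-component
  estimator ignores (by design — multi-harmonic fits are out of scope).
* Missing-hour handling is unbiased only under missingness unrelated to
  the rhythm phase; a stage systematically absent at one phase biases the
  estimate, which is why minimum-hour prerequisites are enforced.
* The EDF interchange format is not read or written; signals enter as
  sample matrices or CSV, hypnograms as CSV.
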