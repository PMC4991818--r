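---
title: "Amplitude and phase coupling analysis for ECoG BCI sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplitude and phase coupling analysis for ECoG BCI sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogcoupling)
```

## The problem

During use of an electrocorticographic (ECoG) brain-computer interface
(BCI), a single *controlling electrode* (CTL) drives the cursor through its
high-gamma (HG, 70-150 Hz) band power, but many cortical sites outside the
controlling area are task-active.  `ecogcoupling` implements two
complementary measures of how remote sites interact with CTL during the
task, together with the surrogate-data statistics needed to call an
interaction significant:

* **STWC** (short-time windowed covariance): a lag-resolved Pearson
  correlation between the HG amplitude envelopes of CTL and a remote
  electrode, capturing transient amplitude-amplitude co-activation that
  may occur at slightly different times at the two sites.
* **bPLV** (bi-phase locking value): a cross-frequency, phase-only
  measure.  With X = Y = CTL and Z the remote site,
  \[
  B_{XYZ}(t, f_1, f_2) = \Bigl|\tfrac{1}{N}\sum_{j=1}^{N}
  e^{\,i\,(\phi_X^j(t,f_1) + \phi_Y^j(t,f_2) + \phi_Z^j(t,f_1+f_2))}\Bigr|,
  \]
  which is 1 when the triple phase sum is constant across trials and falls
  to the Rayleigh level \(\sqrt{\pi}/(2\sqrt{N})\) for independent phases.
  Because the remote phase at \(f_1+f_2\) is predicted by the CTL phases
  (and not vice versa), the configuration is directional ("outgoing" from
  CTL).  Time-varying terms common to all trials cancel inside the
  modulus, so only the trial-to-trial phase relationship matters.

No public recordings exist for this paradigm, so the package ships a
synthetic session generator with *known injected coupling*; every analysis
stage is validated as a parameter-recovery problem on those sessions.

## The processing chain

1. **Conditioning** (`preprocess_envelope()`, `preprocess_broadband()`):
   common average reference over good channels, zero-phase 4th-order
   Butterworth notches at 60/120 Hz, then either the HG envelope path
   (band-pass, Hilbert magnitude, 47 ms FWHM Gaussian smoothing) or the
   broadband path for phases; both end with polyphase resampling to
   400 Hz.
2. **Realignment** (`detect_hg_onset()`, `realign_trials()`): per up-target
   trial, the CTL HG envelope is smoothed with a 470 ms FWHM (1 s wide)
   Gaussian; the baseline is the smoothed minimum in the first second of
   feedback, the maximum is searched up to (exclusive of) 2 s into
   feedback, and the onset is the first point crossing halfway between
   them.  Analyses run both cue-locked and response-locked.
3. **STWC** (`stwc_single_trial()`, `stwc_pair_map()`, `extract_peak()`):
   500 ms windows, lags to +/-300 ms (201 samples and 120 samples at
   400 Hz); peaks searched in the first second of feedback (cue-locked) or
   +/-500 ms around the HG onset (response-locked).
4. **bPLV** (`wavelet_phase()`, `bplv_map()`, `integrate_bplv()`): 7-cycle
   complex Morlet phases at 1 Hz resolution; grid f1 = 7-25 Hz by
   f2 = 70-100 Hz (19 x 31 = 589 pairs) on epochs from -3 s to +2.5 s at
   400 Hz (2200 samples); bPLV integrated from control onset to +1 s.
5. **Inference** (`stwc_null()`, `bplv_null()`): described below.
6. **Session-level comparisons**: pseudo-zscore normalization against the
   -3-0 s baseline and grand averages with a +/-1 SEM (84% CI) band;
   early-versus-late trial-half comparisons with an SNR control; per-region
   summaries; CTL-distance comparisons between the two interaction types.

`run_pipeline()` orchestrates all of it from a single `pipeline_config()`
and writes TSV tables, a JSON summary and a stage log; identical config
and seed reproduce the summary byte for byte.

## Surrogate statistics

**STWC.** Envelopes show a stereotyped rise on every trial, so trial
shuffling alone cannot build a null: shuffled trials still co-rise.  Each
surrogate iteration therefore permutes the remote channel's trial pairing
*and* phase-randomizes every trial segment of both channels.  Phase
randomization is applied to the smoothed envelope segments rather than the
raw broadband signal: the statistic is a function of the envelopes only,
and randomizing their spectral phases preserves each envelope's power
spectrum - hence its autocorrelation, including the event-scale smoothness
that makes the stereotyped response problematic - while destroying
cross-channel alignment.  Per iteration the in-window peak of each pair's
average map is taken; with the default `scope = "max"` the maximum across
pairs is retained (the max-statistic convention, giving exact family-wise
control), while `scope = "pooled"` pools every pair's peak.  Observed
peaks are significant when they exceed the empirical 95th percentile
strictly; p-values use the `(1 + k)/(1 + n)` convention and are never 0.

**bPLV.** Absolute phase has no trial-to-trial consistency, so trial
shuffling suffices: the target's trial order is circularly shifted by a
uniform nonzero offset.  Only N-1 distinct shifts exist, so each is
computed once and the configured number of resamples draws among them -
numerically identical to naive resampling at a fraction of the cost.  Per
resample only the maximum of the integrated (f1, f2) grid is kept, which
corrects over the 589 grid cells without an explicit Bonferroni there;
the pair-level p is then Bonferroni corrected by the number of channel
pairs examined.

A small-N caveat on the bPLV null: circular shifts admit only N-1 distinct
surrogates, so the achievable p-value floor is effectively 1/N however many
resamples are drawn.  With a Bonferroni-corrected threshold this means the
corrected test cannot hold its level below roughly 1/N; sessions of a few
dozen trials or more are needed before the corrected 5% level is
meaningful (the nominal-level simulations use 40-trial sessions).

**Behavioral chance.**  Chance performance is 0.5; its per-subject CI is
the 2.5/97.5 percentile band of 1000 bootstrap means of N Bernoulli(0.5)
draws, N the subject's trial count.

## The synthetic session generator

`simulate_session()` builds sessions with a four-phase trial structure
(rest 1 s, targeting 2 s, feedback 3 s, reward 1 s by default - the
targeting duration is exposed as a parameter because task variants differ
on it), 1/f^alpha background (frequency-domain synthesis with
Hermitian-symmetric random phases: exactly real output, controllable
slope), 60/120 Hz line components, Bernoulli trial outcomes, and a 10 mm
grid montage.

* **Amplitude coupling** (`amp_coupling_spec()`): during up-target
  feedback, both channels receive 70-150 Hz carriers whose envelopes share
  a slow stochastic modulator - a smooth onset ramp at a per-trial latency
  (uniform 0.3-1.0 s) times positive low-pass (< 8 Hz) noise at full
  weight.  The slow cutoff keeps the injected co-modulation slow relative
  to the 500 ms analysis window; the full-weight noise gives the envelope
  enough sub-second structure that the injected lag is identifiable to one
  sample.  The target's modulator is the source's delayed by `lag_ms`,
  mixed at fraction `strength` with an independent modulator.  Carrier
  scale defaults to 2.5 x the channel SD, a typical task-related HG
  excursion at an active ECoG site.  The true per-trial onset is defined
  by running the same onset-detection rule on the clean modulator, so
  detection recovery is well-posed by construction.
* **Phase coupling** (`phase_coupling_spec()`): per trial, uniform phases
  \(\psi_1, \psi_2\) are drawn; the source receives
  \(\cos(2\pi f_1 t + \psi_1) + \cos(2\pi f_2 t + \psi_2)\) and the target
  \(\cos(2\pi(f_1+f_2)t - (\psi_1+\psi_2) + \varepsilon)\),
  \(\varepsilon \sim N(0, \sigma^2)\), inside a window relative to feedback
  onset, with 25 ms cosine tapers.  The triple sum is then constant across
  trials up to \(\varepsilon\).  The default tone scale (4 x SD) is chosen
  so that, at the low-frequency end where the 1/f background is strongest,
  the residual circular SD of the triple sum stays below 0.1 rad - i.e.
  injected phases are essentially deterministic.  In sessions that combine
  both injection types a moderate tone (about 1.5 x SD) is the better
  choice: the f2 tone lies inside the HG detection band at CTL, and at 4 x
  SD it dominates the envelope and masks the HG onset.

### What the generator does and does not emulate

It reproduces the features the analyses are sensitive to: spectral slope,
line noise, phase-locked trial structure, variable response latency,
lagged envelope co-modulation, and quadratic phase coupling confined to a
window.  It does *not* emulate cursor kinematics, decoder dynamics,
epileptiform artifacts, non-stationary background, or genuine multi-source
volume conduction.  Passing recovery tests on these sessions demonstrates
that the estimators and their nulls behave as designed - not that real
recordings satisfy the generator's assumptions.

### The common average reference couples small montages

A practical finding worth stating explicitly: with K good channels, the
common average reference mixes \(-1/K\) of every channel into every other.
For small K this induces a broadband correlation of \(-1/(K-1)\) between
referenced channels - and a *positive* envelope correlation of roughly its
square - and it spreads any strong single-channel signal across the whole
montage at \(1/K\) amplitude.  On a 3-channel montage this alone produces
envelope correlations near 0.2 and a badly inflated STWC false-positive
rate; at 24 channels (real grids have 48-64) the effect is negligible and
the surrogate scheme holds its nominal 5% family-wise level.  Nominal-level
simulations in the test suite therefore reference over a 24-electrode
montage, and sessions with strong injected tones will show reference
leakage at uninjected electrodes - visible in end-to-end runs as secondary
interactions accompanying the injected pair.  This mirrors the
volume-conduction caveat that applies to amplitude measures on real data;
the bPLV, being nonlinear in the phases, does not inherit spurious
quadratic coupling from such linear mixing on uncoupled sessions.

## Numerical choices

* Zero-phase (forward-backward) filtering everywhere, so filter group
  delay cannot bias STWC lag estimates; the notch stop band is 4 Hz wide
  (order and centers are standard, the bandwidth is this package's
  choice).
* The polyphase resampler uses a Kaiser-windowed sinc
  (beta = 7.8562, 20 max(p,q) + 1 taps): passband error about 2e-5, alias
  rejection better than 80 dB, zero group delay.  The bundled `signal`
  resampler showed about 5% passband ripple, which would violate the
  amplitude-preservation contract of the conditioning chain.
* Envelopes are clipped at zero after resampling (anti-aliasing ringing
  can dip slightly negative; nonnegativity is part of the envelope
  contract).  Smoothing uses reflective padding to avoid edge droop on
  short trial epochs.
* The STWC kernel computes windowed correlations via mean-centered prefix
  sums in C++ and matches a naive double-loop implementation to 1e-10
  (asserted in the tests); zero-variance windows yield missing values,
  which averaging and peak extraction skip rather than zero-fill.
* Exact peak ties break toward the smallest absolute lag, then toward the
  negative (remote-leads) lag.
* If the onset half-level is crossed between samples, the earlier sample
  is reported ("the first point when crossed"); the 2 s search bound is
  exclusive.
* Morlet width is 7 cycles at every frequency: about 1 Hz spectral
  resolution at the low end of the f1 range while keeping the temporal
  spread under 1 s.  At the top of the grid the bandwidth is proportionally
  wider (sigma_f = f/7, about 11 Hz at 80 Hz), so a coherent coupling
  lights up a neighborhood of grid cells nearly equally: the location of a
  recovered interaction is meaningful to the wavelet bandwidth, not to the
  1 Hz grid step.
* Integration of bPLV uses the time *mean* over [0, 1) s - affine to the
  integral, identical ranking and inference, and the value stays in
  [0, 1].
* The full f2 grid to 100 Hz is computed (sum frequencies to 125 Hz,
  consistent with the 589-pair count); a narrower printed range of target
  frequencies in the methodological literature appears to be a typo and is
  not silently adopted.
* The STWC null's per-iteration statistic defaults to the maximum across
  channel pairs - the cited max-statistic convention with exact
  family-wise control; pooling each pair's peak into one distribution is
  available as `scope = "pooled"`.  Nulls are built per subject, since
  their scale depends on the montage and trial count.
* Lag-sign convention: x is always CTL; a peak at positive lag means the
  remote channel's matching activity occurs later (remote lags CTL).
* The SNR used in the early/late control is
  (mean feedback HG - mean rest HG) / SD of per-trial rest means, with a
  two-sample t-test on per-trial activations deciding exclusion; no
  standard formula exists for this step, so this definition is the
  package's own.
* Screening uses an unpaired two-sample t-test and Cohen's d for ranking;
  the final CTL choice among candidates remains with the user.

## Problem sizes used in the checks

The test suite and acceptance script work at desk scale, chosen once as
realistic small sessions: 12-32 trials per session, 8-24 electrode
montages, 100 surrogate iterations for STWC nulls, 2000 resamples for
bPLV nulls (the reference analysis uses 10000; with circular shifts only
N-1 distinct surrogates exist either way), 200 uncoupled replicates for
the family-wise level and 20 for bPLV specificity.  Lag recovery to
within one sample at 400 Hz is demonstrated with 32 up-target trials;
with a dozen trials the average map's peak can wander by one to two
samples, which is worth remembering when interpreting single-session lag
estimates on real data.

## Known limitations

* Artifact handling is a good-channel mask supplied by the user; no
  automatic artifact or inter-ictal detection is attempted.
* Only the "outgoing" bPLV configuration (X = Y = CTL) is implemented.
* The generator injects coupling additively on a stationary background;
  non-stationarity, adaptation across trials and genuine conduction
  geometry are out of scope.
* EDF support covers the common 16-bit, uniform-rate case.
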