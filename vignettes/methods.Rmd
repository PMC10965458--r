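---
title: "Methods: simulation, preprocessing and inference in thetapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, preprocessing and inference in thetapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`thetapt` implements an analysis path for developmental EEG studies of
visual perspective-taking: from continuous 128-channel recordings,
through an artifact-rejection cascade, to time-frequency power contrasts
between perspective-taking and control trials, tested point-wise with a
one-sample sign-flip permutation test under Benjamini-Hochberg FDR
correction, and related to behavioral accuracy by Pearson correlation.
Because suitable infant/child EEG datasets cannot ship with a package,
`thetapt` includes a first-class synthetic-cohort generator whose ground
truth makes every stage testable.

# The synthetic cohort

Each simulated participant is a continuous multichannel recording:

* **Background**: $1/f^{\chi}$ noise with $\chi = 1$ (configurable),
  15 µV RMS per channel, generated by spectral shaping of white noise.
  This is the minimal realistic EEG spectrum; it deliberately omits
  volume conduction, so channels are spatially independent except for
  injected components.
* **Ongoing alpha**: an 8.7 Hz oscillation (6 µV RMS) with per-channel
  random phase and a slow sinusoidal amplitude envelope. Child alpha at
  age four sits near 8-9 Hz, just above the 6.2-7.7 Hz band of interest,
  and provides realistic spectral overlap for the wavelet analysis.
* **Condition-locked effect**: on perspective-taking trials, a
  band-limited burst (superposition of random-phase sinusoids drawn in
  6.2-7.7 Hz, Hann-windowed over 1.368-1.466 s after the prompt offset)
  is added coherently to the right temporal-parietal cluster channels
  with a Gaussian spatial gain profile. The default burst RMS is 8 µV
  with a between-participant SD of 3 µV (truncated at zero) — roughly a
  doubling of in-band power at the effect channels, i.e. a clearly
  detectable group effect at $n = 46$. "Does Not See" trials receive an
  extra 30% amplitude (the mismatch boost), mirroring the expectation
  that mismatched perspectives drive the strongest response. The burst
  is noise-like rather than a pure sinusoid so its time-frequency
  leakage resembles real data.
* **Trial structure**: four trial types (Can See / Does Not See /
  Yellow / Not Yellow), 8 trials each by default (16 perspective-taking
  and 16 control trials), inter-trial interval 6 s — trial pacing is
  unspecified in live dyadic designs, and 6 s leaves room for a 2-s
  epoch plus 1 s padding on each side. Events mark the Prompt-2 offset
  as a 0-based sample index; epochs are half-open $[onset, onset+2)$ s
  plus padding.
* **Behavior**: per-condition latent percent-correct values are drawn
  with means/SDs matching the reported group behavior (perspective
  taking split into Can See 82.61/21.18 and Does Not See 76.26/25.77;
  control 88.40/17.41). Does-Not-See accuracy is coupled to the
  participant's effect amplitude with population correlation
  $r = 0.35$; per-trial correctness is Bernoulli in the latent
  accuracy, which attenuates observed correlations slightly at 8 trials
  per type.
* **Artifacts** (optional): blink-shaped 400-ms raised-cosine
  transients with frontal-dominant topography, channels replaced by
  high-variance noise, and 300-ms broadband 20-40 Hz muscle bursts,
  each logged in a ground-truth table.

What the generator does *not* emulate: biophysical head geometry and
volume conduction, realistic spatial covariance, non-stationary state
changes, or movement artifacts of live interaction. Passing tests on
synthetic cohorts therefore demonstrate correctness of the analysis
machinery and its statistical calibration, not robustness to every
feature of real infant EEG.

# Preprocessing cascade

The stage order is fixed and logged: band-pass filter, resample,
outer-ring removal, bad-channel detection, ICA cleanup, epoching,
ocular-threshold marking, spherical-spline interpolation with epoch
pruning, average reference. Key choices:

* **FIR filter** (0.3-50 Hz): Hamming windowed-sinc, zero phase by
  group-delay compensation. Transition width at the low edge is
  `min(max(0.25 * low, 2), low)` Hz (0.3 Hz at a 0.3 Hz edge) and
  analogously at the high edge, order `ceiling(3.3 / normalized
  transition)` — standard windowed-sinc practice; the realized order is
  logged. DC attenuation at a 0.3 Hz edge is necessarily finite
  (about -40 dB).
* **Resampling** to 500 Hz uses polyphase anti-aliased resampling
  (`signal::resample`); event indices rescale as
  `floor(s * p / q + 0.5)`.
* **Bad channels**: three per-channel features with robust z-scores
  (median/MAD, |z| > 3): variance, mean absolute correlation with the
  other channels (low values flag), and Hurst-exponent deviation. This
  is the channel stage of the published feature-threshold approach;
  epoch- and component-level stages of that suite are covered by the
  dedicated rules below.
* **Combined voltage/spectral epoch rule** (on a 1 Hz high-passed
  copy, 1-s epochs): a channel-epoch is artifacted if any sample
  exceeds ±1000 µV — the printed "mV" threshold is read as microvolts,
  since a genuine millivolt threshold would never trigger on scalp
  EEG — or if 20-40 Hz band power falls outside [-100, 30] dB, with dB
  defined as $10\log_{10}$ of mean band power in µV² (the reference is
  unstated in the source material, so it is fixed and documented here).
  Channels artifacted in strictly more than 20% of epochs are removed
  from copy and original.
* **ICA**: symmetric FastICA (logcosh contrast, PCA whitening, at most
  30 components, fixed seed). On data whose bulk is Gaussian the
  symmetric fixed point does not reach tolerance — Gaussian directions
  are unidentifiable — so after one fresh-start retry the final iterate
  is used with a warning, matching the behavior of reference
  implementations that return after `maxit`. Components are classified
  by deterministic rules replacing visual inspection: frontal-dominant
  topography (frontal/global mean |mixing| ratio > 2) with > 50% of
  source power below 3 Hz = blink; excess kurtosis > 10 = transient;
  > 60% of power above 20 Hz = muscle. Thresholds are configuration
  with these defaults.
* **Ocular rule**: epochs where any remaining channel of the printed
  frontal set exceeds ±250 µV get those frontal channels marked for
  interpolation. One listed channel (E17) also appears in the outer
  ring and is normally gone by this stage; the rule uses whichever
  listed channels remain and the cascade logs a skip if none do.
* **Interpolation/pruning**: flagged channels are replaced by
  spherical-spline interpolation; epochs with strictly more than 10%
  flagged channels are rejected, as are epochs with fewer than 4 clean
  channels.
* **Participant exclusion**: strictly fewer than 5 surviving trials in
  either pooled condition excludes the participant.

# CSD and time-frequency power

The current-source-density transform is the spherical-spline surface
Laplacian with the cited toolbox's published defaults (spline order
m = 4, regularization $10^{-5}$, 50 Legendre terms, unit head radius),
since no parameters are printed in the source material. The transform
maps a degree-$l$ spherical harmonic to approximately $-l(l+1)$ times
itself; tests verify < 10% RMS error at 96 electrodes against this
analytic oracle, reference-independence, and linearity.

Spectral power uses complex Morlet wavelets on a 3-30 Hz grid (0.5 Hz
default step) with cycles increasing linearly from 3 at 3 Hz to 8 at
30 Hz. Wavelets are gain-normalized so a matched sinusoid of amplitude
$A$ yields power $A^2$. Epoch padding must cover half of the longest
wavelet so edge effects never reach the 2-s window; the implementation
uses circular FFT convolution whose wrap-around is confined to the
padding, and inverts only the wavelet's spectral support (a
band-limited inverse DFT) for speed. The printed band edges (6.2-7.7,
8.2-9.3 Hz) are representable only approximately on a regular grid; the
0.5 Hz default is an explicit approximation, and the exact grid is
configurable. The test statistic uses raw (not dB) power: the bounded
normalized difference needs no baseline, which is the point of the
contrast; dB conversion is provided for reporting only.

# Inference

Per participant, cluster and contrast, the normalized difference
$D = (A - B)/(A + B)$ of trial-averaged, cluster-averaged power maps is
formed ($A + B = 0$ masked). $D$ is computed per participant and tested
across participants — the construction that makes the one-sample
sign-flip null exchangeable. The observed statistic is the
across-participant mean of $D$ at each time-frequency point in
3-20 Hz; the null negates each participant's whole map at random. The
two-sided p-value uses the +1-corrected estimator
$(1 + \#\{|\bar D^{perm}| \ge |\bar D^{obs}|\})/(1 + n_{perm})$
(default $n_{perm} = 5000$), or the exact $k/2^n$ when all $2^n$ sign
patterns are enumerated ($n \le 16$). FDR correction is
Benjamini-Hochberg per cluster map at $q = .05$ (the map-level level is
not printed in the source material; .05 matches its significance
language) and $q = .2$ across the six behavioral correlation outcomes,
as printed. The two-level repeated-measures ANOVA is computed through
the paired-t identity ($F = t^2$, df = (1, n-1)) — exact for two
levels. The per-participant neural scalar for correlations defaults to
the mean of $D$ over the FDR-significant region of the
perspective-taking contrast; a fixed a-priori band/window region is
available since the construction is not printed.

# Problem sizes of the simulation studies

Cohort-level studies (effect recovery at $n = 46$, type-I calibration
on amplitude-zero cohorts, coupling recovery at $n = 44$) run on a
reduced profile chosen as the package's own trade-off between fidelity
and turnaround: generation at 100 Hz restricted to the 25
analysis-cluster channels, direct epoching of valid trials (the
simulated data are artifact-free by construction, so the artifact
stages would be no-ops), no CSD (a surface Laplacian on a sparse
25-channel subset is not meaningful), a 1 Hz frequency grid over the
3-20 Hz test band (well below the wavelet's spectral bandwidth of
$\ge 1.5$ Hz in-band), 20-ms output steps and 1000 permutations.
Generator effect parameters — amplitude distribution, band, window,
cluster, trial counts, cohort size — are identical to the full-profile
defaults. The full cascade, CSD and the 0.5 Hz grid are exercised by
their own unit and oracle tests at small problem sizes.

# Numerical choices and degenerate inputs

* Robust z-scores use median/MAD; zero MAD yields zero scores (no
  flags) rather than division by zero.
* The boundary rules are strict as printed: exactly ±1000 µV, exactly
  20% artifacted epochs, exactly ±250 µV, exactly 10% interpolated
  channels, exactly 5 trials are all on the "kept" side.
* Zero-variance behavioral vectors raise errors naming the degenerate
  test instead of returning infinite statistics.
* Spherical-spline systems reject duplicate electrode positions; the
  interpolation falls back to epoch rejection when fewer than 4 clean
  channels remain.
* All randomness (cohort, participant, ICA initialization, permutation)
  derives from explicit integer seeds; identical configuration and seed
  reproduce bit-identical results.

# Known limitations

* The generator's spatial model is idealized; CSD and interpolation
  accuracy on real geodesic-net geometry may differ from the
  Fibonacci-sphere results reported by the tests.
* The deterministic ICA component classifier replaces human visual
  inspection; its thresholds are sensible defaults, not a validated
  classifier.
* EDF input is not supported; the canonical on-disk dialect is
  BrainVision (IEEE float32, multiplexed, microvolts) in a BIDS-style
  layout.
* The hardware-specific anti-aliasing time-offset correction of the
  acquisition system is a no-op on synthetic data and is logged as
  skipped.
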