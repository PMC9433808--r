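---
title: "EEG and fNIRS biomarkers of post-stroke balance: models, simulators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG and fNIRS biomarkers of post-stroke balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurobalance)
```

## The problem and the task

After a stroke, balance is assessed with the Berg Balance Scale (BBS,
0–56), a therapist-administered instrument. `neurobalance` implements an
objective complement: brain signals recorded during ankle dorsiflexion — a
motor task patients who cannot yet walk can still perform, engaging the
leg motor area under the Cz electrode — are reduced to two scalar
biomarkers, one electrophysiological (ERD) and one hemodynamic (HBO), and
combined with age in a small linear model of BBS.

The paradigm is a fixed trial clock (`trial_timing()`): 1 s preparation,
2.5 s dynamic dorsiflexion, 3 s static hold, 5 s rest — 11.5 s per trial,
with movement onset (end of preparation) as t = 0 for every epoch window.

## The ERD model

EEG at Cz is band-passed to 0.05–35 Hz (zero-phase), down-sampled to
256 Hz and epoched −1 to +5 s around onset. Each trial yields a
time–frequency amplitude estimate $F_k(f,t)$ and the event-related
spectral perturbation is the trial-averaged power

$$\mathrm{ERSP}(f,t) = \frac{1}{n}\sum_{k=1}^{n} |F_k(f,t)|^2 .$$

Normalization is *subtractive*: with $\mathrm{baseline}(f)$ the mean of
$\mathrm{ERSP}(f,t)$ over the −1…0 s bins,
$\mathrm{nERSP}(f,t) = \mathrm{ERSP}(f,t) - \mathrm{baseline}(f)$. This
makes the per-frequency baseline mean exactly zero — an identity the test
suite asserts on arbitrary grids — and keeps the ERD index in power units.
A dB-ratio mode exists behind a flag but is never the default, because the
subtraction form is what the downstream index is defined on.

The scalar **ERD index** is the arithmetic mean of the *strictly negative*
nERSP bins inside the 15–23 Hz × 0–1 s rectangle (beta-band suppression
right after movement onset). Positive bins are excluded, not zeroed; if the
rectangle contains no negative bin at all the index is defined as 0 with an
explicit `empty_flag`, so the feature never silently disappears from a
subject. An empty *rectangle* (band or window off the grid) is an error —
a different situation from "no desynchronization found".

**Spectral estimator.** The estimator behind $F_k$ is deliberately simple:
a short-time Fourier transform with a 0.5 s Hann window and a hop of 1/16
window, evaluated directly at the requested frequencies and scaled so a
unit sinusoid gives power ≈ 1. The direct evaluation means the frequency
grid is exactly the user's `freqs` vector (no FFT bin snapping), and the
implementation is transparently checkable against a brute-force windowed
DFT written from the definition — one of the acceptance checks, which
agrees to 1e-10 relative error. A Morlet-wavelet estimator
(`method = "morlet"`, 7 cycles) is available because time–frequency
smoothing is estimator-dependent and some users will prefer wavelet
conventions; the default stays STFT.

**Filtering.** All zero-phase filtering in the package cascades a
Butterworth high-pass and low-pass (each applied forward and backward over
a reflectively padded signal) instead of designing one band-pass
polynomial. At the extreme normalized edges this pipeline needs — 0.05 Hz
at 1024 Hz sampling, 0.01 Hz at 20 Hz — a single band-pass polynomial is
numerically fragile, while the cascade is stable and meets the stop-band
targets (DC leakage < 1 % in the EEG band, cardiac 1.1 Hz leakage < 0.1 %
in the hemoglobin band). Zero-phase application preserves ERD latency,
which the 0–1 s index window depends on. Reflective padding spans three
filter time constants of the low edge (capped at the signal length), which
is also why `bandpass_hemo()` refuses recordings shorter than three time
constants (300 s at 0.01 Hz): below that the transient owns the signal.

No automatic artifact rejection is applied anywhere: ocular/muscular
cleanup (ICA-based, by visual inspection) is an upstream manual step, and
`preprocess_eeg()` says so in a message rather than pretending otherwise.

## The phase synchronization model

Channels are band-passed to the band of interest (alpha, 8–13 Hz, by
default — configurable, since "alpha" conventions vary), the instantaneous
phase is taken from the analytic signal, and for a pair with phase
difference $\phi_{xy}(t)$

$$\mathrm{PSI} = \sqrt{\langle\cos\phi_{xy}\rangle^2 +
                       \langle\sin\phi_{xy}\rangle^2} \in [0,1],$$

the resultant length of the phase-difference distribution: 1 for perfect
synchronization, 0 for none. The square-root (resultant-length) form is
the only one bounded by 1, which fixes the convention. Phases within one
filter settling length (1.5 cycles of the band's low edge) of either end
are trimmed before averaging, because filter transients there corrupt the
phase. A constant (zero) channel has no defined phase and is rejected
rather than silently producing arbitrary angles.

The subject-level summary is the mean PSI over homologous left–right
pairs — by default C3–C4, CP3–CP4, FC3–FC4, the motor-relevant central,
centro-parietal and fronto-central homologues; the pair set is fully
configurable since no single convention exists. Pair validity is enforced
by the 10/20 odd/even rule (one odd = left, one even = right label), so
(Cz, Cz) is rejected as not inter-hemispheric. When the recording has
movement events, averaging runs over the pooled 0–5 s post-onset task
intervals — synchronization *during exercise* — otherwise over the whole
trimmed support. Group contrasts use Welch's t by default (unequal
variances are the norm in patient/control contrasts) with Mann–Whitney as
the distribution-free alternative.

## The hemodynamic model

HBO and HBR are band-passed to 0.01–0.2 Hz, epoched −2 to +10 s around
onset, and each trial/channel epoch has its −2…0 s baseline mean
subtracted. Total hemoglobin is materialized as HBT = HBO + HBR *after*
correction, so the identity holds element-wise by construction (and is
still asserted). Curves are averaged over trials, then over the eight
sensorimotor source–detector channels (S2-D4, S2-D2, S7-D2, S7-D4, S7-D7,
S7-D5, S5-D7, S5-D5); the two averaging orders coincide here because all
channels share the same trials — with unequal counts the per-channel
average would come first. A requested channel that is absent is an error
naming it: silently analysing a different cortical patch would corrupt the
feature without a trace.

Two scalar features are implemented: the **peak** of the averaged HBO
curve on 0–10 s, and its **signed trapezoidal area** against the
horizontal axis (an unsigned mode exists behind a flag; the signed
integral is the reproducible default since negative lobes are real
undershoot, not noise). The regression uses the peak by default — the
packaged cohort tabulates peaks — while the area remains available as the
alternative predictor.

## The balance regression

`fit_bbs_model()` fits, by ordinary least squares on the unstandardized
design (Constant, ERD, HBO, AGE, HBO²),

$$\mathrm{BBS} = \beta_0 + \beta_1\,\mathrm{ERD} + \beta_2\,\mathrm{HBO}
 + \beta_3\,\mathrm{AGE} + \beta_4\,\mathrm{HBO}^2 + e,$$

with 95 % CIs and two-sided p-values from the t distribution on
$n - k - 1$ degrees of freedom and
$R^2_{adj} = 1 - (1 - R^2)(n-1)/(n-k-1)$. Classical t-based inference is
the default because nothing in the model demands more, and with n = 8 any
resampling-based interval would be noisier than the analytic one.

`loo_cv()` refits on every size-$(n-1)$ subset and predicts the held-out
subject; with $n$ subjects this *is* n-fold cross-validation with
singleton test sets (the only such partition), summarized by the RMSE over
the $n$ held-out predictions. It is deterministic, invariant to row order,
and validated in the suite against the hat-matrix identity
$e_{(i)} = e_i / (1 - h_{ii})$.

On the packaged eight-patient cohort the fitted coefficients are
(30.6, −12.4, 37.3, −0.5, −10.6) with adjusted R² 0.840 and LOO RMSE 9.84
— the numbers the README's worked example prints and
`scripts/acceptance.R` recomputes.

## What the simulators emulate — and what they do not

The signal simulators generate data with the statistical structure the
analysis assumes, so that every stage can be tested against known ground
truth without recording hardware.

**EEG** (`simulate_eeg_trials`): 1/f-amplitude Gaussian background (the
standard spectral surrogate for resting EEG) plus a beta-band sinusoid
whose amplitude is multiplied by $1-\mathrm{erd\_depth}$ during the
dynamic phase and recovers linearly over the static hold and rest. The
generative amplitude factor is the oracle behind two properties: the ERD
index is strictly negative at positive depth, and non-increasing in depth
under matched seeds.

**Phase pair** (`simulate_phase_coupled_pair`): two unit cosines sharing a
carrier phase, with a phase difference that is Gaussian with sd σ per
sample, giving expected PSI $e^{-\sigma^2/2}$ (wrapped-Gaussian resultant
length). One design choice matters here: the jitter is generated as a
*band-limited* Gaussian process (≈2 Hz bandwidth, standardized to marginal
sd exactly σ) rather than i.i.d. per sample. Sample-wise white jitter is
spectrally flat, so a band-pass + Hilbert analysis would filter most of it
out and measure a PSI far above the law; slow jitter passes through the
analysis band and the measured PSI matches $e^{-\sigma^2/2}$ to < 0.01 at
10⁵ samples, which is the jitter-law acceptance check (tolerance 0.02 at
σ ∈ {0.2, 0.5, 1}). The band of analysis must contain the modulation
sidebands (Carson-rule width ≈ 2(σ+1)·bw around the carrier); the checks
use 2–18 Hz around a 10 Hz carrier.

**fNIRS** (`simulate_fnirs_session`): canonical double-gamma HRF (peaks at
6 s, undershoot at 16 s, ratio 1/6) convolved with a boxcar spanning
onset → onset + 5.5 s (the movement interval), peak-normalized per single
trial so `amplitude_hbo` is the clean single-response peak; plus cardiac
(1.1 Hz), respiratory (0.25 Hz) and Mayer-wave (0.1 Hz) sinusoids, linear
drift and white noise, all configurable through `fnirs_noise()`. HBR is
the −1/3-scaled mirror of the clean response with independent noise — a
conventional ratio, chosen once, not an empirical claim. Note that at the
11.5 s inter-trial interval successive responses overlap, so the
trial-averaged, baseline-corrected peak is substantially smaller than
`amplitude_hbo` (≈ 0.32× noiseless); features remain exactly
1-homogeneous in amplitude, which is the recovery property the suite
checks (R² > 0.999 across amplitudes). HBO values are treated as
micromolar-scale relative changes without claiming a calibration.

**Cohort** (`simulate_cohort`): AGE, ERD, HBO uniform on ranges bracketing
the example cohort (30–75 y, −2…−0.3, 0.1–3), BBS from the generating
model with Gaussian noise. BBS is clipped to the clinical 0–56 range only
on request, so noiseless recovery tests are exact; consequently the
feature-table validator enforces the clinical range only for data read
from files.

What the simulators do **not** reproduce: volume conduction and spatial
mixing (no head model), motion and ocular artifacts, non-stationary
background spectra, optode coupling changes, or the optics upstream of
hemoglobin concentrations (the modified Beer–Lambert step is outside the
pipeline). Passing tests therefore demonstrate that the *computations* are
correct and the *statistical machinery* behaves nominally — not that the
pipeline is robust to every artifact class real recordings contain.

## Numerical conventions and degenerate inputs

- t = 0 at movement onset; all epoch and analysis windows are half-open
  `[start, end)` on sample/bin centers; frequency bands are closed at both
  edges; 1-based sample indexing as native in R.
- Decimation requires an integer rate ratio; a non-integer ratio falls
  back to polyphase resampling with an explicit warning.
- Epochs that would cross a recording edge are dropped with a logged
  count, never silently and never fatally; a channel missing from a
  requested set, by contrast, is always an error naming it.
- Every simulator is a pure function of its arguments including `seed`
  (RNG state is restored afterwards), so identical configurations give
  byte-identical outputs.
- Problem sizes in the test suite are chosen to exercise each property at
  desk scale: 10⁵ samples for synchronization laws, 50 trials × 256 Hz for
  the ERD chain, 200 replicates × 200 subjects for interval coverage.

## Known limitations

- The regression inference is classical OLS; with eight subjects the CIs
  are wide and the model is descriptive, not a validated clinical
  predictor.
- EDF and SNIRF readers are not included; recordings enter as CSV matrices
  with YAML sidecars and BIDS-like events TSVs (the writers produce
  exactly this layout).
- The ERD index depends on the spectral estimator's smoothing; STFT and
  Morlet values differ in magnitude (both are exposed, only the default is
  tested against the brute-force oracle).
- Group-level synchronization differences require cohorts of real
  recordings; the package implements the comparison machinery and its
  statistical behavior, not any published group contrast.
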