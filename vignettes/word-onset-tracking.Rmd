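---
title: "Word-onset tracking in basal ganglia beta-band envelopes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Word-onset tracking in basal ganglia beta-band envelopes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betatrack)
```

## The scientific question and the model

During two-speaker ("cocktail party") listening, word onsets impose a
temporal structure on speech. `betatrack` asks whether the amplitude
envelope of beta-band (12–30 Hz) local field potentials (LFPs) recorded
from deep-brain-stimulation (DBS) electrode contacts in the basal ganglia
tracks that structure, using a forward (encoding) temporal response
function (TRF):

$$\hat{y}(t) \;=\; \sum_{f \in \{\text{att},\,\text{unatt}\}} \;
  \sum_{\ell = 0}^{L} w_f(\ell)\, s_f(t - \ell) \;+\; b,$$

where $s_f$ is a binary word-onset train for stream $f$ (ones at word
onsets, the first attended one being the target word), $y(t)$ is the
Hilbert envelope of the band-passed LFP, and the kernels $w_f(\ell)$ span
lags 0–700 ms. The kernels are estimated by ridge regression; model
performance is the Pearson correlation $r$ between predicted and actual
envelopes under five-fold cross-validation, averaged over folds.
Inference is non-parametric: a trial bootstrap describes the variability
of real tracking, and an interval-preserving shuffle of the onset trains
provides the null. A contact "tracks" word onsets if its observed mean
$r$ exceeds the null with empirical $p < 0.05$.

## The synthetic session generator

No recordings are distributed with this problem, so the package ships a
generator (`simulate_session()`) whose defaults *are* the study
conditions the analysis assumes: 96 trials, 2 kHz sampling, two
quadripolar electrodes (4 monopolar contacts per hemisphere), sentences
of 3.18 s preceded by a 1 s silent baseline and a 0.56 s speech lead
before the target word, word-onset intervals with mean 353 ms / SD
134 ms (attended-equivalent stream) and 411 ms / 137 ms (other stream),
and 81% behavioral accuracy.

The forward process is an explicit modeling assumption made for testing,
not a claim about the underlying physiology: a modulator
$m(t) = \big[m_0 + \sum_f (s_f * k_f)(t)\big]_+$ (resting level $m_0$,
ground-truth kernels $k_f$, half-wave rectification because an envelope
is nonnegative) multiplies a 20 Hz sinusoidal carrier — the center of the
12–30 Hz band, the simplest signal whose Hilbert envelope is the imposed
modulator — with a random phase per trial. Each monopolar contact
receives the clean signal scaled by a contact-specific gain
(1, 0.75, 0.55, 0.4 along the electrode, so adjacent-contact differences
retain signal) plus white Gaussian noise. Inter-onset intervals are
gamma-distributed, moment-matched to the requested mean/SD (positive
support, two free moments), truncated below at 50 ms by rejection to
avoid unphysically short words; with SD = 0 the train is exactly
regular, which the tests exploit. Correctness flags are i.i.d. Bernoulli;
the behavioral process itself is not modeled.

Defaults chosen where the conditions leave freedom, fixed once: resting
level 0.2, kernel bumps `gaussian_kernel(amp = 1, peak_s = 0.15,
sd_s = 0.05)` (attended) and `(0.6, 0.20, 0.06)` (unattended) — smooth,
nonnegative, inside the 0–700 ms lag span, with the attended response
stronger and earlier; noise SD 0.5 per contact, which puts single-contact
tracking clearly above the shuffle null at 96 trials without being
trivial; inter-trial gap 0.75 s. Both streams' trains start at the
target-word time (in the paradigm both speakers utter a name
simultaneously there).

What passing tests on these simulations do **not** show: real LFP noise
is not white (no 1/f background, no line interference beyond what the
recording chain removed), electrode contacts share volume-conducted
sources in ways a gain vector does not capture, the real neural forward
process is unknown and need not be multiplicative, and attention effects
are reduced to two fixed kernels. Recovery and calibration results here
validate the *pipeline*, not the biology.

## Preprocessing

Monopolar contacts are re-referenced to their longitudinal neighbors
(bipolar montages 0–1, 1–2, 2–3 per hemisphere; 3 channels per side),
epochs are cut at (−1.56, +3.18) s around the target-word onset so the
−1…0 s pre-audio baseline is contained, and trials are screened in the
order: artifact rejection, then correctness.

The classic automatic criterion — z-score the trials and reject at 6
SDs — is ambiguous on its own (a trial z-scored within itself always
has SD 1). We standardize each
channel by the mean and SD pooled over *all* trials and samples of that
channel and flag a trial when any sample reaches $|z| \ge 6$ on any
channel — this detects outlier trials relative to the session, which is
the point of automatic artifact rejection. Trials are flagged, never
deleted, and flags are monotone across stages. A trial-level SD
statistic would be a defensible alternative; the pooled-max reading is
our design choice.

Acquisition-chain filters (50 Hz notch, 0.5 Hz high-pass, anti-alias
low-pass) are treated as properties of the input data: the generator
produces band-limited signal plus white noise, so re-applying them would
be a no-op here.

## Spectral estimation

Time-frequency power uses multitaper estimation: 2 s windows, 4 Slepian
tapers (time–bandwidth 2.5, i.e. ±1.25 Hz concentration), squared
Fourier amplitudes averaged over tapers. The tapers come from the
standard symmetric tridiagonal eigenproblem; for windows longer than
1024 samples they are computed at 1024 and interpolated (the sequences
are smooth, so this is accurate) — in practice we decimate epochs to
200 Hz before time-frequency analysis. The window step defaults to
50 ms, configurable. Power is expressed as percent change from the
per-trial baseline mean (the −1…0 s pre-audio window), normalized per
trial *before* trial averaging. The pixelwise paired t-test mask
(uncorrected, $p < 0.05$) is attached for visualization only and carries
a `visualization_only` attribute; all inference in the package is
resampling-based.

For the TRF target we take the Hilbert-envelope reading: the signal is
band-passed 12–30 Hz with a 4th-order zero-phase Butterworth filter
(maximally flat in band),
the analytic signal magnitude is taken, and the envelope is low-passed
and decimated to `fs_env` = 100 Hz, so lag steps are 10 ms and the 0–700 ms
window has 71 steps per stream. TRF fitting windows stop 0.25 s before
the epoch edge to discard filter transients.

## TRF estimation and cross-validation

The lagged design matrix holds, per stream, one column per 10 ms lag;
ridge regression solves
$\min_w \|y - Xw\|^2 + \lambda \|w\|^2$ in closed form with an
unpenalized intercept via centering. The ridge parameter is fixed at
$\lambda = 1$ *on the standardized problem*
(predictors and response scaled to unit variance using training-fold
statistics), which makes the penalty scale-free and — crucially — keeps
the real and null branches of the inference strictly identical in code
path. Stimulus and response are per-trial mean-centered before fitting.

Folds partition *trials* (never time samples, which would leak across
the 700 ms lag window): the trial list is shuffled with a seeded RNG and
cut into five contiguous blocks. Per fold, the correlation is computed
between the concatenation of the held-out trials' predictions and
envelopes; the five correlations are averaged.

## Resampling inference

* **Bootstrap (100×)**: (stimulus, response) trial *pairs* are resampled
  with replacement — the only reading that both resamples with
  replacement and keeps each trial's onset order and intervals intact —
  and the 5-fold CV mean $r$ is recomputed per replicate.
* **Shuffle null (500×)**: per replicate, every trial's and stream's
  onset train is shuffled independently by permuting the inter-onset
  intervals (the multiset is preserved exactly) and redrawing the
  initial offset uniformly so the train still fits in the sentence;
  the neural data are untouched. Shuffling is independent per trial and
  per stream.
* **Empirical p**: one-sided with the add-one correction,
  $p = (1 + \#\{r_{\text{null}} \ge r_{\text{obs}}\}) / (1 + n_{\text{null}})$,
  so $p$ is never zero.

The observed statistic compared to the null is the **un-resampled 5-fold
CV mean $r$** (the bootstrap mean is reported alongside). We considered
using the bootstrap mean as the observed statistic, but resampling
trials with replacement can place copies of one trial in both training
and test folds, giving the bootstrap mean a positive leakage bias under
the null and making $p$ anti-conservative; the un-resampled statistic
keeps the calibration property (below) intact and is itself a mean
Pearson correlation across the five folds.

Contacts are counted at uncorrected $p < 0.05$, with percentages rounded
to the nearest integer percent (28/48 → 58%); a Benjamini–Hochberg
column is emitted for reference but not used for headline counts.
Per-stream variants rerun the identical machinery with a single-feature
stimulus matrix.

## Numerical choices and degenerate inputs

Zero-SD intervals give exact regular trains; zero-variance predictions
or responses yield $r = 0$ rather than `NA`; zero-variance design
columns get unit scale; a rank-deficient design with $\lambda = 0$
raises an error advising regularization; a single-onset train can only
have its offset redrawn (reported via a message); baseline power of zero
trips a division guard. All resampling accepts explicit seeds, and the
session-level driver derives per-contact child seeds as
`seed + 7919 * contact_index`, so adding contacts never perturbs earlier
contacts' draws.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run at sizes chosen to exercise the
properties at desk scale: kernel recovery uses the full 96-trial, 2 kHz
noiseless session (envelope at 100 Hz); null calibration uses 51
noise-only 20-trial sessions at 200 Hz (envelope at 50 Hz), 4
non-overlapping bipolar contacts each (so contacts share no monopolar
noise and the binomial reference for the 5% flag rate applies), with the
null reduced to 100 replicates; smaller property tests use 10–15 trial
sessions. The analysis drivers under `analysis/` run the full
100-bootstrap / 500-null inference on a default session.

## Known limitations

The generator's linear-multiplicative forward model makes kernel
recovery easier than reality; percentages of significant contacts
obtained on simulations are properties of the chosen SNR, not estimates
for any real cohort. The multitaper window step and the choice of the
Hilbert envelope (rather than a multitaper power time course) as the
TRF target are both configurable conventions. The t-test mask is
deliberately quarantined from inference.
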