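---
title: "Methods: simulated closed-loop alpha neurofeedback and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated closed-loop alpha neurofeedback and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`alphanft` models a one-day alpha-band neurofeedback (NFT) experiment and the
analysis pipeline used to evaluate it. A cohort of *virtual subjects* —
parametric EEG generators with a latent learning rule — replaces human
participants, so every analysis stage can be tested against known ground
truth. The protocol it simulates: eyes-closed/eyes-open resting baselines, a
motor-imagery (MI) session (3 runs, 12 trials per task per run: left hand,
right hand, idle), six 3-minute closed-loop NFT runs, then post baselines and
a second MI session.

## The online feedback quantity

The engine tracks the **alpha relative power** over 16 frontal electrodes,

$$\mathrm{ARP} = \frac{P_\alpha}{P_{total}},\qquad
\Delta \mathrm{ARP} = \frac{\mathrm{ARP}_{epoch} - \mathrm{ARP}_{baseline}}
                            {\mathrm{ARP}_{baseline}},$$

with the alpha band anchored at the individual alpha frequency (IAF),
$(\mathrm{IAF}-2, \mathrm{IAF}+2)$ Hz, and the total band $(1, 50)$ Hz.
$P$ is the integral of a multitaper (DPSS) power spectral density; the
online loop evaluates 1 s epochs every 100 ms. $\mathrm{ARP}_{baseline}$ is
frozen from the pre-session eyes-open baseline, estimated with the same
1 s windows so online and offline values are numerically comparable.

The feedback bar is $\mathrm{clip}(\Delta\mathrm{ARP}/2\theta,\,-1,1)$,
green when $\Delta\mathrm{ARP}>0$. A dynamic threshold $\theta$ starts at
10%, moves in strides of 1%, and never drops below 1%; a ring buffer holds
the last 100 deviations (~10 s). The reward (smiley) rule is stated in the
source protocol only as "most epochs within a few seconds": we fix it as
*at least 80% of the trailing 30 frames (3 s) above* $\theta$, after which
$\theta$ rises one stride and the evaluation window restarts; if a full
buffer elapses with fewer than 20% of frames above $\theta$, $\theta$ drops
one stride. Both fractions and window lengths are `nft_config()` fields.
Feedback pauses for 5 frames (0.5 s) when any vertical-EOG sample exceeds
100 µV in magnitude — the source protocol says only "paused briefly", so
the pause length is configuration, not a claim.

## Frequency bands and band power

Five IAF-anchored bands partition $(1, 50)$ Hz exactly: delta
$[1, \mathrm{IAF}-6)$, theta $[\mathrm{IAF}-6, \mathrm{IAF}-2)$, alpha
$[\mathrm{IAF}-2, \mathrm{IAF}+2)$, beta $[\mathrm{IAF}+2, 30)$, gamma
$[30, 50)$. Band power integrates the PSD with an endpoint-interpolated
trapezoid over the closed interval: adjacent bands share their interpolated
edge values, so the five band powers sum *exactly* to the total-band power
and relative powers sum exactly to 1 — a property the test suite asserts
for arbitrary spectra.

The IAF estimator averages 4 s multitaper windows over posterior channels,
flattens the spectrum by a robust log-log linear fit of the 1/f background
(fitted outside 7–13 Hz), and takes the largest flattened local maximum in
7–13 Hz exceeding the background by a configurable margin (default 1.5x),
with parabolic sub-bin interpolation. Without a qualifying peak it returns
10 Hz and a warning flag. The cited automated method in the source protocol
is not reproduced; this stand-in is deterministic and fully specified here.
Near-ties resolve to the stronger peak; exactly equal flattened peaks
resolve to the lower frequency (first maximum wins).

Tapers are Slepian sequences from the symmetric tridiagonal eigenproblem,
solved by Sturm bisection + inverse iteration in C++ so long windows do not
require a dense eigendecomposition. The taper count is `min(2NW - 1, 8)`:
beyond ~8 tapers variance reduction is marginal while cost grows linearly.

## Event-related desynchronization

For each MI trial the epoch $[-3, 4)$ s around task onset splits into a
pre-task stage $[-3, 0)$ and task stage $[0, 4)$. Stage powers in the
individual alpha band are averaged over a task label's trials (all runs
pooled), and

$$\mathrm{ERD} = \frac{P_{task} - P_{pretask}}{P_{pretask}}.$$

The ratio is taken on trial-averaged powers (not averaged per-trial
ratios), because the defining equation is stated on stage powers. Stage
power is the mean over the stage's non-overlapping 1 s multitaper windows —
the same estimator used everywhere else in the package; this keeps online
and offline numbers on one scale and is substantially cheaper than
whole-stage tapers.

## Motor-imagery decoding

Sessions are band-passed 8–30 Hz with a linear-phase windowed-sinc
(Hamming) FIR, transition 2 Hz. The forward-backward application required
for zero net phase is implemented as a single convolution with the kernel
autocorrelation, which is algebraically identical for a symmetric kernel.
Epochs $[0, 4)$ s are spatially filtered by one-versus-rest CSP
(trace-normalised covariances, 5% shrinkage toward the scaled identity, 4
filters per subproblem — 2 from each eigenvalue extreme), reduced to
log-variance features, standardised, and classified by an RBF-SVM
(soft-margin C = 1, kernel width from the median heuristic on training
features). Accuracy is the mean over stratified 10-fold cross-validation
folds; CSP, standardisation and the SVM are fitted strictly inside each
training fold. The SVM is an in-package SMO implementation (no SVM library
exists in the target environment); it reproduces scikit-learn's SVC
predictions on a frozen fixture in the test suite.

## Functional connectivity

Eyes-open baselines are cut into non-overlapping 5 s segments (a 1 min
baseline gives exactly 12) on the 48 lateral electrodes (56-channel scalp
set minus the 8 midline electrodes). Two measures:

* **PLI**: per segment, channels are band-limited and converted to analytic
  signals by a frequency-domain cosine-tapered band mask (an FIR with a 2 Hz
  transition would outlast a 5 s segment for the delta band, which is why
  the FIR + Hilbert route was rejected);
  $\mathrm{PLI}_{ij} = |\langle \mathrm{sign}\sin(\phi_i-\phi_j)\rangle_t|$,
  averaged over segments.
* **imCoh**: multitaper cross-spectra from the package's 1 s windows within
  each segment; $|\Im S_{ij}| / \sqrt{S_{ii} S_{jj}}$ per frequency bin,
  averaged over the band's bins, then over segments. The magnitude
  convention is used because signed per-segment averaging can cancel;
  the sign of the pre/post difference is reported separately by
  `edge_contrast()`.

Both measures are zero for zero-lag (volume-conducted) mixtures, which the
tests demonstrate with a shared-source surrogate. Pre/post contrasts are
edge-wise paired t-tests with an uncorrected p < 0.01 mask and a
Benjamini-Hochberg FDR mask per band/measure family.

## The virtual subject

A 2-D Gaussian-pattern linear forward model mixes six sources onto the
58-channel layout (56 scalp + HEOG/VEOG): occipital alpha, frontal alpha
(gain 0.7 relative to occipital), left/right sensorimotor mu at C3/C4,
a blink source above the eyes, and an optional 90°-lagged left-frontal /
right-parietal pair giving connectivity a recoverable ground-truth edge.
No volume-conduction head model is attempted — the mixing suffices for
topographies, lateralised ERD and sensor correlations. Oscillators run at
the subject's IAF with ±20% slow amplitude modulation and random-walk phase
jitter (0.05 rad/sample); background noise is per-channel 1/f (power slope
−1). All generator outputs are pure functions of (profile, arguments,
seed).

Key latent parameters, with defaults chosen once as plausible desk-scale
values: resting alpha source amplitude `a0` (cohort: Normal(20, 4) µV
truncated to [12, 30]), task-stage mu amplitude `a_task = ratio * a0`
(ratio Normal(0.82, 0.05), calibrated so pre-training three-class decoding
sits in the moderate ~45–60% regime the source protocol reports rather
than at ceiling, leaving room for training-driven gains), noise RMS
Normal(10, 2) µV, IAF Normal(10, 0.5) Hz truncated to [8, 12], blink rate
Uniform(5, 15)/min. Test fixtures that need a strong injected effect
(e.g. ERD depth recovery at ratio 0.6, ERD $\approx -0.64$) set the ratio
explicitly.

**Learning rule.** The source protocol gives no quantitative model of how
a human responds to feedback; the stand-in is the explicit ODE

$$\dot a = \eta\, r\,(a_{max} - a) - \lambda\,(a - a_0),$$

Euler-stepped per frame, where $r \in \{0,1\}$ is 1 when the bar is green.
(The reward driving learning is the continuous green bar, not the sparse
smiley, which serves as "emotional support" in the protocol.) Trainability
$\eta$ is a mixture: ~30% of subjects near zero — matching the commonly
reported fraction of NFT non-responders — and the rest Uniform(0.01, 0.05)
per second, with decay $\lambda \approx 0.01$/s and ceiling
$a_{max} = 2 a_0$. Its parameters are not claims about human learning.
Following the observation that post-training gains appear in pre-task/rest
alpha while task-stage power is unchanged, `a_task` is held fixed per
subject: only the resting amplitude is learned, so ERD (and decodability)
deepens as resting alpha grows. This single mechanism links the three
headline outcomes — frontal ΔARP, ERD deepening, and decoding-accuracy
gain — so a positive ΔARP–Δaccuracy correlation is the expected signature
of a trainable cohort, and an `eta = 0` cohort is the negative control.

What a green test does *not* establish: real EEG has non-Gaussian,
non-stationary sources, volume conduction, reference effects, movement and
muscle artifacts, and human learning is not a two-parameter ODE. The
simulation validates the *pipeline* (no leakage, correct formulas,
calibrated statistics, recoverable injected effects), not the
neuroscientific claims.

## Numerical and design choices

* Time intervals are half-open `[t0, t1)` in samples; events are
  `(onset, duration, label)` with 0-based sample onsets. This avoids
  double-counting boundary samples.
* Signals are µV end to end; EDF physical dimension `uV`. EDF files use 1 s
  records when the length divides evenly, otherwise one record spanning the
  recording (avoids padding that would break round-trip identity).
* The exact identity of the 16 frontal target electrodes and of the 4
  channels dropped from the original 60 is not published; the defaults
  (`default_frontal16_names()`, `default_scalp_names()`) preserve the
  counts and are overridable in `montage()`.
* `init_engine()` rejects a baseline whose frontal ARP is below
  `arp_min = 0.01` (e.g. a pure 40 Hz tone) as degenerate.
* An exactly zero ΔARP (possible only on constructed replays) renders a
  neutral bar; any nonzero deviation is green/red by sign.
* Whether folds should be pooled or averaged is unstated in the source
  protocol; we average fold accuracies. CSP filter counts per OVR problem
  are likewise unstated; 4 per problem, in config.
* imCoh per-bin-then-average (rather than band-averaged cross-spectra) was
  chosen and is configurable only in code; the difference is second order
  for the 4-bin alpha band.
* Desk-scale study defaults (4 trials/task/run, 60 s NFT runs) keep an
  18-subject study around ten minutes on one CPU; `paper_scale = TRUE`
  restores full protocol timing. Structural counts (108 trials, 12
  segments, 48 channels, 100-frame buffer) are always tested at full scale.

## Known limitations

* The EDF writer emits 16-bit EDF+C with a single annotation channel; no
  discontinuous (EDF+D) support.
* The IAF stand-in is not the published automated method it replaces.
* PLI/imCoh are sensor-space only; no source reconstruction, no
  graph-theoretic summaries.
* The SMO SVM is adequate for tens of features and ~100 trials, not a
  general-purpose SVM.
* Smiley/threshold-lowering internals of the original system are not
  publicly specified; ours are explicit configuration defaults, and
  quantities that depend on them (smiley counts, threshold trajectories)
  should be read as properties of this implementation.
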