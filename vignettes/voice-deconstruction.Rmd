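---
title: "Source-tract voice deconstruction and gender-dependent speaker verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-tract voice deconstruction and gender-dependent speaker verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sourcetract)
```

## The model

Voiced speech is modelled as a glottal excitation filtered by the vocal
tract and differentiated by lip radiation. The glottal source carries
phonatory, largely physiological information about a speaker (pitch,
spectral tilt, cycle-to-cycle perturbation), while the vocal tract
carries the phonetic content. `sourcetract` separates running speech into
a *glottal source estimate* (GSE) and a *vocal tract estimate* (VTE)
with a sample-adaptive lattice structure, derives cepstral features from
the raw speech and from both estimates, and evaluates whether the
source-side features improve text-independent speaker verification in a
GMM-UBM system — separately per gender, since male and female voices
differ both acoustically and physiologically.

The separation chain has three blocks, all sharing one exponential
forgetting factor $\lambda$:

1. **Radiation compensation.** A first-order adaptive lattice tracks the
   exponentially weighted lag-0/lag-1 autocorrelation of the input,
   $k(n) = r_1(n)/r_0(n)$. The radiation stage is modelled as a
   first-order zero $1 - z_0 B$; reading $k$ as the lag-1 moment of that
   MA(1) (with a locally flat source), $k = -z_0/(1+z_0^2)$. The exact
   inverse of this relation has unbounded sensitivity at the physical
   limit $z_0 \to 1$ ($\mathrm{d}z_0/\mathrm{d}k \to \infty$), so the
   saturating linear surrogate $z_0 \approx \min(1, -2k)$ is used; it is
   exact at $z_0 = 1$ and only over-integrates slightly for small zeros,
   which is harmless. The estimated zero is inverted with a leaky pole
   $\min(z_0, 0.997)$ followed by a DC blocker (pole 0.995). The
   radiation inverse is genuinely underdetermined by the block structure
   alone; this reading satisfies three independent checks — zeros map to
   zeros, first-differenced white noise is restored to a flat spectrum
   within 1 dB/octave over 100 Hz-4 kHz, and the adapted coefficient
   converges to the batch lag-1 autocorrelation ratio on stationary
   AR(1) inputs.

2. **Inverse filtering.** A $k$-order prediction-error lattice with
   Burg-type exponentially weighted error-product recursions: per stage,
   cross and half-sum-of-squares accumulators with forgetting $\lambda$,
   whose ratio is the reflection coefficient. This form keeps every
   reflection coefficient strictly inside $(-1, 1)$ by construction and
   converges to the batch Levinson-Durbin PARCORs on stationary inputs
   at $\lambda = 1$ (verified against an independent batch oracle at
   tolerance $10^{-2}$). The forgetting factor is the only adaptation
   knob, which is why a recursive least-squares-style rule was chosen
   over gradient adaptation. Adaptation is per sample over whole
   utterances: no pitch-synchronous framing is needed, which is the
   point of the method for dynamic sounds and running speech.

3. **Joint-process estimation.** The final-stage forward error (the
   residual, an estimate of the whitened excitation) is the reference
   input of a lattice-ladder joint-process estimator on the compensated
   speech $s_l(n)$: a second lattice (same order, same $\lambda$)
   orthogonalises the residual into backward prediction errors
   $b_0 \ldots b_k$, and ladder gains regress $s_l(n)$ on them. The
   joint-process estimate — the component of $s_l$ predictable from the
   excitation — is assigned to the **GSE**; the estimation error, which
   keeps the resonant tail of the tract response, is the **VTE**. The
   two branches sum to $s_l$ exactly by construction and are
   second-order decoupled. Which branch is "source" and which "tract" is
   checked spectrally on every utterance by
   `decon_assignment_check()`: the GSE must show a harmonic
   peak-and-trough comb at multiples of F0 (the glottal source spectrum
   is *not* flat), the VTE envelope must peak at the formants.

Two numerical details matter in block 3. First, the adaptive Burg
lattice orthogonalises only approximately, so a single diagonal ladder
pass leaves a small correlated remainder; the ladder therefore runs a
second refinement sweep that regresses the remaining error on the
backward errors again (`jpe_sweeps = 2`). Two sweeps reduce the residual
source-tract correlation severalfold; more sweeps start chasing
adaptation noise and are not used. Second, quality statistics exclude a
burn-in that scales with the model: each lattice stage needs roughly one
forgetting time-constant ($1/(1-\lambda)$ samples, 12.5 ms at
$\lambda = 0.995$ and 16 kHz) of settled input from the stage below, so
the default burn-in is $1.25\,k$ time-constants, at least 50 ms. All
recursion denominators carry a guard of $10^{-8}$ times the input power,
so no division by zero can occur; reflection coefficients remain bounded
regardless.

Four separation presets ship with the package (`decon_presets()`):
orders 10 (male) and 16 (female) with $\lambda = 0.995$ for a clean,
controlled-microphone scenario, and orders 24 (male) and 36 (female) for
a noisier mobile-channel scenario. The higher mobile orders let the
lattice absorb channel colouration along with the tract. Because the
method must be re-tuned per recording condition, `grid_search()`
exhaustively evaluates candidate (order, $\lambda$) and front-end/model
settings by development-set EER only — the evaluation split is never
touched during tuning.

## The synthetic corpus

The licensed corpora the method was developed on cannot be
redistributed, so `generate_corpus()` builds seeded synthetic
populations with the statistical structure the method assumes:

* **Glottal pulse train** (`lf_pulse_train()`): one two-phase flow-
  derivative pulse per period — a polynomial opening/closing phase
  $A(2s - 3s^2)$ over the open quotient with its negative closure spike,
  smoothed by an exponential return phase (a one-pole filter with time
  constant `rq` cycles). This realises the spectral tilt and harmonic
  richness of the classical four-parameter glottal-flow model without
  its transcendental shape equations. Cycle lengths are perturbed
  multiplicatively by jitter, pulse amplitudes by shimmer.
* **Vocal tract**: one conjugate pole pair per formant, radius
  $e^{-\pi B/f_s}$. Per-speaker formant centers are Gaussian
  perturbations (sd 5%) of a gender template, scaled by a tract-length
  factor $\sim N(1, 0.04)$ (centers scale inversely with tract length,
  which is what makes F3 a speaker cue). Male F0 means are drawn from
  $N(120, 10)$ Hz truncated to [90, 155], female from $N(210, 12)$
  truncated to [175, 255] — the two gender pitch priors, with disjoint
  supports so the no-cross-gender-trials protocol is well defined.
* **Radiation**: a first difference, giving the compensation stage a
  true inverse to find.
* **Utterance shape**: 150 ms leading/trailing silence (so the VAD has
  work to do), syllabic-rate amplitude modulation (2.5-5 Hz, depth
  0.25-0.5 — without it, frame energy is a degenerate near-constant
  feature on sustained synthetic phonation), optional white noise at a
  target SNR. Durations default to 4 s on average, matching the
  clean-scenario recordings the protocol emulates; the desk-scale test
  runs use 2.5 s to keep suites fast.

Everything is a pure function of (parameters, seed). What the generator
does **not** emulate: phonetic variety (no consonants, glides, or
coarticulation), session/channel variability beyond additive noise,
reverberation, and realistic prosody. Consequently, passing tests show
that the algorithmic chain is implemented correctly and that its
claimed properties (orthogonal decomposition, formant/harmonic recovery,
source features helping verification) hold under the model's own
assumptions — they do not certify error rates on real corpora, which
the protocol deliberately leaves out of scope.

## Front end

Per gender, the feature vector concatenates MFCC streams from the
denoised speech, the GSE and the VTE, plus optional extras (log frame
energy E, its slope dE, F0, F3):

* Framing 25 ms / 10 ms, Hamming window, FFT 512 at 16 kHz (field
  convention; the method itself does not constrain framing).
* MFCCs: triangular mel filters spanning 0 to Nyquist, floor $10^{-10}$
  before the log, orthonormal DCT-II, coefficient 0 excluded — energy
  is carried separately as E. Deltas are least-squares slopes over
  $\pm 2$ frames, applied to the speech stream only (the narrow reading
  of the scheme; GSE/VTE deltas are configurable but off in presets).
* Denoising: MMSE short-time spectral-amplitude gains with
  decision-directed a-priori SNR (smoothing 0.98, floor $-18$ dB), noise
  tracked from the quietest tenth of frames and smoothed across
  frequency (few quiet frames leave per-bin estimates noisy enough to
  destabilise the decision-directed loop).
* F0: cumulative-mean-normalised difference function with absolute
  threshold 0.1 and parabolic dip interpolation, searched in
  gender-dependent ranges (60-250 Hz male, 120-400 Hz female).
* F3: per voiced frame, an order-14 autocorrelation LPC fit; resonances
  are pole pairs with bandwidth under 400 Hz, F3 the third lowest, 0
  when fewer than three qualify. Unvoiced F0/F3 frames carry the last
  voiced value within a segment by default (`unvoiced_fill = "hold"`;
  `"zero"` is the alternative) — the estimation-gap problem has no
  principled answer, so the behaviour is a documented switch.
* Channel compensation, in order: cepstral mean subtraction, feature
  warping (rank mapped through the standard-normal quantile function
  over a 301-frame ≈ 3 s window), then RASTA band-pass filtering
  (5-tap ramp numerator, pole 0.94, warm-started in steady state so
  constant trajectories map exactly to zero). Compensation applies to
  cepstral slices only: E, F0 and F3 are physical quantities that rank
  warping would destroy.
* VAD: frames above an adaptive threshold — the 2nd-percentile
  log-energy (a robust noise-floor estimate) plus 6 dB — then
  morphology: islands shorter than 100 ms are dropped unless within
  100 ms of a longer segment, silences under 200 ms are bridged. A
  percentile this low is deliberate: utterances are mostly speech, so
  mid-range percentiles would land inside the speech cluster.

## Back end and evaluation

Gender-dependent diagonal-covariance GMMs: the UBM is trained by
k-means-initialised EM (10 k-means iterations, up to 50 EM iterations,
relative tolerance $10^{-5}$, variance floor $10^{-3}$ of the global
per-dimension variance; components emptied during EM are re-seeded from
the heaviest component and logged). Speaker models are MAP adaptations
of the means only, $\mu_k = (n_k E_k + \alpha m_k)/(n_k + \alpha)$;
weights and variances stay at the UBM values. Trial scores are
log-likelihood ratios, averaged per frame so scores are
duration-comparable (summing is a switch). Z-, T- and ZT-norm
standardise scores against impostor cohorts drawn from the background
split only — never from development or evaluation speakers; for ZT-norm
the cohort-model scores are themselves Z-normalised with
leave-own-utterances-out statistics.

Evaluation follows the operational definitions: a trial is accepted iff
its score is at or above the threshold; the development threshold is the
candidate minimising $|FAR - FRR|$ (ties to the lowest threshold), the
EER is the mean of FAR and FRR there (an interpolated EER is available
as an option but not the default), the evaluation HTER is the FAR/FRR
mean at that frozen threshold, and HEER is the mean of the two gender
EERs — well defined because no cross-gender trials exist. DET curves
are double-probit with rates clamped by half a trial weight. The
uncertainty of a detection cost is a two-layer bootstrap: speakers are
resampled with replacement, then each sampled speaker's trials, 2000
replicates, separately per class.

## Desk-scale study conditions

The test and acceptance runs use problem sizes a laptop handles in
minutes, chosen once: 8-10 speakers per gender, 10 utterances each,
2.5 s mean duration, 15 dB SNR for the verification experiments, 32
Gaussians, and 5 corpus seeds for the directional comparison of
speech+GSE features against speech-only MFCCs. The shipped presets carry
the full-scale model sizes (256-1024 Gaussians) and are accepted by the
code, but the package makes no claim that desk-scale error rates match
full-scale ones — only the directional claim is tested, and it holds:
adding glottal-source MFCCs does not hurt, and under noise consistently
helps, median over seeds, both genders.

## Known limitations

* The radiation-compensation inverse is one consistent reading of an
  underdetermined block; other leaky-integrator variants would also
  satisfy the stated checks.
* Source-tract decorrelation is enforced adaptively, not exactly: on
  sustained vowels the absolute correlation stays below 0.05 for all
  shipped presets, but it is a small bias, not zero, and grows if the
  lattice order badly under-models the spectrum.
* The VTE formant diagnostic reads peaks from a tilt-detrended smoothed
  Welch envelope; with very high F0 (sparse harmonic sampling) formant
  peaks can shift by a few percent.
* EM is deterministic given the seed but k-means initialisation can
  land in different local optima across seeds; UBMs are therefore
  always reported with their seed.
* The synthetic corpus has no phonetic content, so VTE-stream features
  are weaker cues here than on real speech; the shipped mobile-female
  preset includes a VTE stream for completeness, not because it helps
  on synthetic data.
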