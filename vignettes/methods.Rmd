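---
title: "Frequency-tagged ssVEP analysis of threat generalization under aversive contexts: models and methods"
author: "ssvepContext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ssvepContext methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepContext)
```

## The scientific problem

When a visual cue that predicts an aversive outcome (the CS+, a Gabor patch
at +45 deg) flickers at a fixed rate, visual cortex entrains to the flicker
and produces a steady-state visually evoked potential (ssVEP) that can be
read out in the EEG at the driving frequency (7.5 Hz here) and its
harmonics (15 Hz). Cues similar to the CS+ (orientations −45, +15 ... +75
deg) elicit graded responses — a generalization gradient — and placing the
cues in front of inherently aversive versus neutral background pictures
adds a contextual threat manipulation orthogonal to cue identity. The
package implements the complete measurement and inference chain for this
design: spectral signal-to-noise ratios of the entrained response,
repeated-measures inference with effect-size confidence intervals,
Bayes-factor comparison of pre-specified cue-tuning patterns, and the
power simulation used to fix the sample size. Because the pipeline must be
testable without any recordings, a first-class synthetic-data module
generates epoched EEG, pupil traces, trial schedules and rating tables
with the statistical structure the analysis assumes.

## The ssVEP signal model and SNR

The generator writes, per trial, a cue-locked signal

$$ s(t) = a_1 \cos(2\pi f_0 t + \phi_1) + a_2 \cos(2\pi\, 2 f_0 t + \phi_2), \qquad 0 \le t < 4\,\mathrm{s}, $$

with $f_0 = 7.5$ Hz. The fundamental amplitude carries the context effect,
$a_1 = a_{1,\mathrm{base}} + a_{1,\mathrm{ctx}}[\text{aversive}]$, and the
second-harmonic amplitude carries a Gaussian generalization gradient over
orientation distance from the CS+,
$a_2 = a_{2,\mathrm{base}} + a_{2,\mathrm{peak}} \exp(-\Delta\theta^2 / 2w^2)$.
This encodes as ground truth the frequency-segregated effect structure the
analysis is designed to detect: a context main effect at the fundamental
and a cue gradient at the harmonic. The signal is weighted across the
scalp by a von-Mises-like kernel centred on Oz (the paper-level fact being
only that the response is occipitally maximal; the kernel is a modelling
choice), superimposed on independent $1/f$ background noise per sensor and
trial, and scaled by a lognormal subject gain.

Analysis-side, condition averages are transformed to current source
density, Fourier-transformed on a 600–3900 ms window, and summarized as

$$ \mathrm{SNR}(f) = \frac{P(f)}{\tfrac{1}{6}\sum_{k \in \{\pm2,\pm3,\pm4\}} P(f + k\,\Delta f)}, $$

the power at the tagged bin over the mean of six neighbouring bins,
skipping the two immediate neighbours. SNR is pooled over Oz and seven
neighbouring electrodes (the EGI labels 70, 71, 72, 74, 75, 76, 82, 83 in
the 129-channel reference layout).

### Why the FFT window is cycle aligned

The nominal analysis window 600–3900 ms is 3300 ms long; at a 500 Hz
sampling rate this does not place 7.5 Hz on an exact DFT bin, and the
neighbour-bin SNR formula is only meaningful for an on-bin target. The
window is therefore truncated to the largest integer number of 7.5 Hz
cycles — 24 cycles, 3200 ms, bin width 0.3125 Hz — so that 7.5 Hz falls on
bin 24 and 15 Hz on bin 48 exactly. Power is normalized so a
unit-amplitude bin-aligned sinusoid yields 0.5 (mean-square convention),
and the per-bin powers satisfy Parseval's identity with the windowed,
mean-removed series; both properties are asserted in the tests. Whether
the original analysis zero-padded or tolerated off-bin leakage is not
recoverable; cycle alignment is this package's documented interpretation
and is configurable (`alignCyclesToHz`).

## Preprocessing choices

**Filtering.** The printed specification of the original tool ("45
dB/octave, 23rd-order Butterworth") is internally inconsistent — a
23rd-order Butterworth rolls off at 138 dB/octave. The package therefore
treats the order as a configuration parameter and defaults to a 4th-order
zero-phase (forward–backward) Butterworth at 40 Hz, whose squared response
attenuates a 2×-cutoff component by ≈ 48 dB, comfortably beyond the 40 dB
the quoted slope implies one octave up. Zero-phase application uses
reflection padding with stationary initial conditions, applied to all
trials and sensors at once (the per-series recursion is the pipeline's hot
loop and is vectorized across channels).

**Artifact screening.** The statistical screening computes, per trial and
sensor, the maximum absolute value, the standard deviation, and the
maximum of successive absolute differences. The original procedure's exact
distribution limits are not recoverable from the publication, so the
package uses a documented approximation: each statistic is robust-z-scored
(median/MAD) both across trials within sensor and across sensors within
trial, and a sensor-trial is flagged when any |z| exceeds 3 (configurable).
Because the three statistics are right-skewed, the clean-data flag rate
sits a little above the Gaussian envelope (≈ 4–5% of sensor-trials at
realistic sensor counts); flagged sensors are replaced by spherical-spline
interpolation (order m = 4, uniform statistical weighting exposed as a
hook), and a trial is rejected outright when more than 20 sensors are
contaminated. On the clean synthetic fixture the retained-trial fraction
exceeds 95%.

**Acquisition half split.** For learning dynamics the acquisition trials
are split by position into halves (first ⌈n/2⌉ trials → half 1), and a
participant is excluded from the Cue × Time analysis when any
orientation × half cell has zero retained trials.

## Current source density

The surface Laplacian uses the classical spherical-spline construction:
with $g(x) = \frac{1}{4\pi}\sum_{n\ge1} \frac{2n+1}{n^m (n+1)^m} P_n(x)$
and $h(x)$ the same series multiplied by $n(n+1)$, the spline coefficients
solve the bordered system $[G + \lambda I, \mathbf{1}; \mathbf{1}^\top, 0]$
and the CSD is their $H$-projection. Defaults: $m = 4$, 50 Legendre terms
(series standard), $\lambda = 0.2$ as recommended for dense-array
montages; only $\lambda$ is fixed by the study's printed settings, the
rest follow the spline literature. The operator is linear, maps constants
to numerical zero, and at $\lambda = 0$ reproduces the analytic
surface-Laplacian eigenvalue $n(n+1)$ on a degree-2 spherical harmonic to
under 1%; with the dense-array regularization the map is deliberately
smoothing and no longer eigen-exact. Legendre polynomials are evaluated by
the Bonnet recurrence, which (unlike some library routines) stays accurate
at $x \to 1$, i.e. on the matrix diagonal.

## Inference

**Repeated-measures ANOVA.** Fully within-subject one- or two-factor
designs are decomposed by orthonormal effect contrasts; each effect is
tested against its own subject-by-effect interaction. Sphericity is
corrected with Greenhouse–Geisser epsilon computed from the covariance of
the contrast scores (Huynh–Feldt behind a flag); the fractional degrees of
freedom the convention prints (e.g. F(4.09, 208.81) on a 7-df factor)
imply exactly this kind of correction, and GG is the field default.
Partial eta-squared is the sums-of-squares ratio, with a 95% CI from
inverting the noncentral-F distribution in its noncentrality parameter and
mapping $\lambda / (\lambda + df_1 + df_2 + 1)$.

**Paired contrasts.** Cohen's d uses the difference-score standardization
$d = t/\sqrt{n}$ — the only convention that reproduces every printed
(t, d) pair of the reporting style this package follows — with a 95% CI
from inverting the noncentral-t distribution and dividing by $\sqrt{n}$.

**JZS Bayes factors.** The cue-pattern models are the published weight
vectors over the seven orientations +15 ... +75 deg (the −45 deg cue is
outside the printed vectors and is excluded): sharpening
(+0.5, −1, −2, +5, −2, −1, +0.5) and generalization
(−3, +0.5, +1.5, +2, +1.5, +0.5, −3), entered as a regressor for Cue,
with Context coded ±0.5 (centred; the coding is immaterial for a balanced
design) and subject random intercepts. The default Zellner–Siow setup
places a Cauchy(0.5) prior on standardized fixed slopes, Cauchy(1) on the
random-intercept scale, and Jeffreys priors on the intercept and error
variance. Conditional on the two g parameters the marginal-likelihood
ratio has a closed form (computed via the Woodbury identity on the small
cross-product matrices); the g's are integrated out by adaptive quadrature
after a probit change of variables that maps the half-Cauchy mixing
densities exactly onto the unit square (relative tolerance 1e-6, failures
raise an error rather than falling back silently). Cue-pattern Bayes
factors are *transitive*: log BF(weights + context vs null) −
log BF(context vs null), so they isolate the cue pattern over and above
the context effect through the common null — the only reading under which
a cue model can be indifferent at a frequency that carries a strong
context effect. The context model is compared against the
random-intercept null directly.

**Power simulation.** The pre-registered calculation draws, per
replicate, n = 50 bivariate-normal pairs with means (0, d·SD), SD = 1.4
and correlation ρ = 0.80, tests the context effect with a paired t at
α = .05, and reports the significant fraction of 5000 replicates. d = 0.30
is interpreted as a raw-scale standardized mean difference (δ = d·SD) with
correlated measures, not a difference-score dz: only this reading yields
the documented ≥ 80% power (the dz reading gives ≈ 55%), and it matches
how d, SD and ρ are listed as separate quantities. The Monte-Carlo
fraction is checked against the closed-form noncentral-t power with
$d_z = d/\sqrt{2(1-\rho)}$.

## The synthetic cohort: defaults and what they emulate

Trial schedules reproduce the design exactly: 18 presentations per
orientation in acquisition; six aversive and six neutral blocks of 24 cues
(three per orientation per block) in the context phase, 4-s cues, ISIs
uniform on 2–3 s, first cue 5–7 s after block start (the source states
ranges, not distributions; uniform is the maximum-entropy default), CS+
reinforced on 100% of trials, and no more than three identical orientations
in a row — enforced by rejection-resampling of permutations with the scan
running across block boundaries, erroring after a bounded number of
attempts rather than relaxing the constraint. The implied block length
falls in the documented ≈ 160 s range.

Amplitude defaults come from a forward calculation rather than tuning: a
1 µV occipital amplitude over 1/f noise of 15 µV broadband SD yields
pooled evoked-power SNRs in the single-digit range at 18 trials per cell,
which is where occipital ssVEP SNRs on condition averages typically land.
Defaults `a1ContextOffset = 0.4`, `a2Base = 0.6`, `a2GradientPeak = 0.6`
(gradient width 20 deg) then produce moderate, realistic effects at the
full design size (n ≈ 50, 18 trials/cell). Between-subject variability is
a lognormal amplitude gain (SD 0.25 on the log scale); ssVEP phases are
fixed at 0 by default since the analysis is phase-blind (configurable);
the generator emits sinusoids at $f_0$ and $2f_0$ directly rather than
simulating square-wave retinal transduction, because the analysis touches
only those two bins.

What the generator does *not* emulate: spatially correlated noise (sensor
noise is independent), volume-conduction mixing of distinct sources,
non-stationary ssVEP build-up (the signal is stationary from cue onset, so
the 600 ms discard is exercised but not strictly necessary on synthetic
data), realistic blink/EMG artifact morphology beyond the injected spike/
drift/flatline primitives, and eye-movement-related pupil foreshortening.
Passing tests therefore demonstrate the correctness of the measurement and
inference chain under the assumed generative model, not robustness to
every pathology of real recordings.

## Problem sizes used in the shipped tests

The recovery test runs n = 20 subjects with 6 trials per cell on a
64-sensor net — a size chosen so the full chain (filtering, screening,
interpolation, CSD, FFT, SNR, ANOVA, Bayes factors) runs in a few minutes
while leaving the frequency-specific dissociation clearly detectable. At
this reduced size the *default* effect amplitudes are underpowered for the
context contrast (as a real n = 20 subset would be), so the recovery
fixture uses deliberately strong ground-truth effects
(`a1ContextOffset = 0.8`, `a2Base = 0.5`, `a2GradientPeak = 1.0`): a
recovery test must place known, recoverable signal in the data so that a
miss indicts the pipeline rather than the sample size. Oracle-equivalence
tests (SNR neighbour enumeration, dense-matrix CSD, sums-of-squares ANOVA,
grid-quadrature JZS) run on small fixtures at tight tolerances; schedule
invariants are property-checked over 1000 seeds.

## Known limitations

* The screening thresholds approximate an unpublished parameterization;
  they are configurable, and conclusions about rejection *rates* on real
  data should not be read off the synthetic fixture.
* The CSD at λ = 0.2 is a smoothing estimator; topographies are
  sharpened but amplitudes are not comparable across montage sizes.
* The JZS integrals use 1–2 dimensional quadrature with the random
  intercept integrated as a single g block; designs with richer random
  structure (random slopes) are out of scope.
* Epoch containers live in memory; very large cohorts should be processed
  per subject (as `runPipeline()` does) rather than held simultaneously.
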