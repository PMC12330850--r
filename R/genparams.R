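#' Generative parameters for the synthetic cohort
#'
#' Defaults encode the study conditions the pipeline is designed for: a
#' 7.5 Hz driving frequency whose fundamental amplitude carries an
#' aversive-context increment, a second harmonic carrying a Gaussian
#' generalization gradient peaked at the CS+ (+45 deg), an occipitally
#' peaked topography, 1/f background EEG noise at a realistic broadband
#' scale, lognormal between-subject amplitude variability, and rating and
#' pupil response models sharing the same orientation gradient. Amplitude
#' and noise defaults are set so that subject-level pooled SNRs on averaged
#' data fall in the single-digit range typical of occipital ssVEP
#' recordings (see the package vignette for the forward calculation).
#'
#' @param nSubjects cohort size.
#' @param f0Hz driving frequency (Hz).
#' @param a1Base fundamental ssVEP amplitude (uV) at Oz.
#' @param a1ContextOffset amplitude increment (uV) in the aversive context.
#' @param a2Base second-harmonic baseline amplitude (uV).
#' @param a2GradientPeak harmonic amplitude increment (uV) at the CS+.
#' @param a2GradientWidthDeg Gaussian tuning width (deg) of the gradient.
#' @param phase1,phase2 sinusoid phases (rad); power analyses are phase
#'   blind, fixed at 0 for reproducibility.
#' @param topoKappa concentration of the von-Mises-like occipital topography.
#' @param noiseExponent 1/f^a spectral slope of the background noise.
#' @param noiseScale broadband background-noise SD (uV).
#' @param subjectSd between-subject SD of the lognormal amplitude gain.
#' @param ratingFloor baseline US-expectancy (0-100).
#' @param ratingGradient rating increment at the CS+ (scaled by the
#'   orientation gradient elsewhere).
#' @param ratingContextOffset rating increment in the aversive context.
#' @param ratingSubjectSd SD of subject rating intercepts.
#' @param ratingNoiseSd within-cell rating noise SD.
#' @param pupilGainMm event-related dilation (mm) at the CS+.
#' @param pupilContextOffsetMm dilation increment (mm) in aversive context.
#' @param pupilNoiseSd within-trace pupil noise SD (mm).
#' @param blinkRateHz blink events per second (gaps become missing samples).
#' @param trialsPerCell cue presentations per orientation (x context) cell.
#' @param seed master seed for the generator.
#' @return a validated \linkS4class{GenParams}.
#' @export
genParams <- function(nSubjects = 52L, f0Hz = 7.5,
                      a1Base = 1.0, a1ContextOffset = 0.4,
                      a2Base = 0.6, a2GradientPeak = 0.6,
                      a2GradientWidthDeg = 20,
                      phase1 = 0, phase2 = 0, topoKappa = 10,
                      noiseExponent = 1.0, noiseScale = 15,
                      subjectSd = 0.25,
                      ratingFloor = 20, ratingGradient = 60,
                      ratingContextOffset = 5, ratingSubjectSd = 10,
                      ratingNoiseSd = 15,
                      pupilGainMm = 0.10, pupilContextOffsetMm = 0.04,
                      pupilNoiseSd = 0.05, blinkRateHz = 0.10,
                      trialsPerCell = 18L, seed = 1L) {
  new("GenParams", nSubjects = as.integer(nSubjects), f0Hz = f0Hz,
      a1Base = a1Base, a1ContextOffset = a1ContextOffset,
      a2Base = a2Base, a2GradientPeak = a2GradientPeak,
      a2GradientWidthDeg = a2GradientWidthDeg,
      phase1 = phase1, phase2 = phase2, topoKappa = topoKappa,
      noiseExponent = noiseExponent, noiseScale = noiseScale,
      subjectSd = subjectSd,
      ratingFloor = ratingFloor, ratingGradient = ratingGradient,
      ratingContextOffset = ratingContextOffset,
      ratingSubjectSd = ratingSubjectSd, ratingNoiseSd = ratingNoiseSd,
      pupilGainMm = pupilGainMm, pupilContextOffsetMm = pupilContextOffsetMm,
      pupilNoiseSd = pupilNoiseSd, blinkRateHz = blinkRateHz,
      trialsPerCell = as.integer(trialsPerCell), seed = as.integer(seed))
}
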