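#' Cohort specification for synthetic experiments
#'
#' Describes the two-group design: group a emulates healthy controls
#' (n = 19 in the reference design), group b a patient group matched on
#' task performance by the staircase (n = 14). A single seed fixes all
#' downstream randomness.
#'
#' @param n_group_a,n_group_b participants per group (>= 1).
#' @param trials_per_participant trials per participant (>= 0).
#' @param labels group labels, default `c("control", "ssd")`.
#' @param seed integer master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 19, n_group_b = 14,
                        trials_per_participant = 300,
                        labels = c("control", "ssd"), seed = 1L) {
  stopifnot(n_group_a >= 1, n_group_b >= 1, trials_per_participant >= 0,
            length(labels) == 2, is.numeric(seed))
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 trials_per_participant = as.integer(trials_per_participant),
                 labels = labels, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Observer specification
#'
#' Generative model of a single participant: a Weibull-type psychometric
#' function linking motion coherence to accuracy, lognormal movement
#' onsets, and a confidence read-out of the internal evidence that may be
#' coupled (negatively) to the standardized movement onset. The coupling
#' slope is the quantity whose group difference the behavioural
#' interaction model recovers: the reference design uses -0.04 (proportion
#' confidence per SD of onset) for controls and -0.01 for the matched
#' group, an injected interaction of +0.03.
#'
#' @param sensitivity evidence units per unit coherence (d' at coherence 1
#'   is `sensitivity`).
#' @param lapse lapse rate in `[0, 0.1]`.
#' @param confidence_noise_sd sd of additive confidence noise on the 0-1
#'   scale.
#' @param confidence_rt_coupling slope of confidence (0-1) per standardized
#'   movement onset; negative values mean slower onsets get lower
#'   confidence.
#' @param mean_onset,onset_sd mean and sd (seconds) of the lognormal
#'   movement-onset distribution.
#' @param p_early,p_late probability that a trial is generated as an
#'   early (< 100 ms) or late (> 6 s) movement, emulating the excluded
#'   trial classes.
#' @param p_com probability of a pre-response change of mind.
#' @return object of class `observer_spec`.
#' @export
observer_spec <- function(sensitivity = 2.2, lapse = 0.02,
                          confidence_noise_sd = 0.10,
                          confidence_rt_coupling = -0.04,
                          mean_onset = 1.3, onset_sd = 0.65,
                          p_early = 0.05, p_late = 0.03, p_com = 0.07) {
  stopifnot(lapse >= 0, lapse <= 0.1, confidence_noise_sd >= 0,
            mean_onset > 0, onset_sd > 0,
            p_early >= 0, p_late >= 0, p_com >= 0)
  structure(list(sensitivity = sensitivity, lapse = lapse,
                 confidence_noise_sd = confidence_noise_sd,
                 confidence_rt_coupling = confidence_rt_coupling,
                 mean_onset = mean_onset, onset_sd = onset_sd,
                 p_early = p_early, p_late = p_late, p_com = p_com),
            class = "observer_spec")
}

#' A single synthetic ERP component
#'
#' Each component is a separable spatio-temporal pattern: a topography over
#' channels (unit peak) times a Gaussian temporal kernel, scaled by a gain
#' and a per-trial modulator.
#'
#' @param name component name.
#' @param modulator one of `"correctness"` (coded correct = 1,
#'   incorrect = 0), `"confidence"` (z-scored per participant),
#'   `"movementRT"` (z-scored per participant onset) or `"constant"`.
#' @param gain microvolts per modulator unit at the topography peak.
#' @param peak,width peak latency and Gaussian sd of the temporal kernel,
#'   seconds relative to movement onset.
#' @param center channel at which the topography peaks.
#' @param spread spatial Gaussian sd, in head-coordinate units.
#' @return object of class `erp_component`.
#' @export
erp_component <- function(name, modulator = c("correctness", "confidence",
                                              "movementRT", "constant"),
                          gain, peak, width = 0.05,
                          center = "Cz", spread = 0.35) {
  modulator <- match.arg(modulator)
  stopifnot(is.finite(gain), is.finite(peak), width > 0, spread > 0)
  structure(list(name = name, modulator = modulator, gain = gain,
                 peak = peak, width = width, center = center,
                 spread = spread),
            class = "erp_component")
}

#' Default ERP template set
#'
#' Three components matching the reference design:
#' a central correctness-modulated component peaking 266 ms after movement
#' onset with a correct-minus-incorrect difference of -0.34 uV at the peak
#' channel (Cz); a fronto-central confidence component peaking at 102 ms
#' (0.2 uV per confidence SD); and a fronto-central movement-onset
#' component peaking at 133 ms (0.3 uV per onset SD). A constant
#' motor-evoked wave provides a nonzero grand-average ERP.
#'
#' @param correctness_gain,confidence_gain,rt_gain gains in microvolts;
#'   set any to 0 for null simulations.
#' @return list of [erp_component()] objects.
#' @export
default_erp_templates <- function(correctness_gain = -0.34,
                                  confidence_gain = 0.2,
                                  rt_gain = 0.3) {
  list(
    erp_component("ern",  "correctness", gain = correctness_gain,
                  peak = 0.266, width = 0.055, center = "Cz", spread = 0.30),
    erp_component("conf", "confidence",  gain = confidence_gain,
                  peak = 0.102, width = 0.060, center = "FCz", spread = 0.40),
    erp_component("mrt",  "movementRT",  gain = rt_gain,
                  peak = 0.133, width = 0.060, center = "FCz", spread = 0.40),
    erp_component("mep",  "constant",    gain = 2.0,
                  peak = 0.050, width = 0.080, center = "Cz", spread = 0.45)
  )
}

#' Noise specification for synthetic epochs
#'
#' @param pink_sd sd (uV) of 1/f-shaped noise per channel and trial.
#' @param white_sd sd (uV) of white noise.
#' @param intercept_sd sd (uV) of the per-participant DC offset.
#' @param artifact_rate probability per trial of a large transient
#'   artifact (used to exercise artifact rejection).
#' @param artifact_amp amplitude (uV) of injected artifacts.
#' @param bad_channels number of channels per participant with 10x noise.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(pink_sd = 2, white_sd = 1, intercept_sd = 2,
                       artifact_rate = 0, artifact_amp = 200,
                       bad_channels = 0) {
  stopifnot(pink_sd >= 0, white_sd >= 0, intercept_sd >= 0,
            artifact_rate >= 0, artifact_rate <= 1, bad_channels >= 0)
  structure(list(pink_sd = pink_sd, white_sd = white_sd,
                 intercept_sd = intercept_sd, artifact_rate = artifact_rate,
                 artifact_amp = artifact_amp,
                 bad_channels = as.integer(bad_channels)),
            class = "noise_spec")
}
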