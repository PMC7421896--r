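#' Analysis configuration
#'
#' Fixed constants of the pupil analysis: epoch, baseline, and evoked windows
#' (half-open millisecond intervals), the block-level validity threshold, the
#' component retention rule, and the PCA sampling window.
#'
#' Defaults follow the paradigm's analysis conventions: tone-locked epochs of
#' `[0, 3000)` ms at 250 Hz (750 samples), a 500-ms pre-tone baseline, an
#' evoked window of `[1000, 2000)` ms where the tone-evoked dilation is
#' maximal, blocks with < 50% valid samples excluded, and mean-eigenvalue
#' component retention (the Kaiser criterion analogue appropriate for
#' covariance-metric PCA).
#'
#' @param epoch_window_ms Half-open epoch window in ms relative to tone onset.
#' @param baseline_window_ms Half-open baseline window in ms (negative = before onset).
#' @param evoked_window_ms Half-open evoked-measurement window in ms.
#' @param min_valid_fraction Blocks with a valid-sample fraction strictly
#'   below this are excluded.
#' @param retention_rule `"mean_eigenvalue"` (eigenvalue at or above the mean
#'   of the positive spectrum) or `"unit_eigenvalue"` (eigenvalue > 1; only
#'   meaningful for correlation-metric input).
#' @param pca_window_ms PCA sampling window length: 3000 (tones + following
#'   images) or 1500 (tone period only).
#' @param min_trials Minimum trials per participant-condition cell entering
#'   the waveform matrix.
#' @param velocity_mads Artifact velocity threshold in median absolute
#'   deviations of the sample-to-sample difference.
#' @param artifact_pad_ms Dilation pad applied on both sides of detected
#'   artifact runs, in ms.
#' @param score_method Component score estimator: `"regression"`
#'   (least-squares) or `"correlation"` (loading-weighted).
#' @param rng_seed Integer seed used by pipeline stages that draw random numbers.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(epoch_window_ms = c(0, 3000),
                            baseline_window_ms = c(-500, 0),
                            evoked_window_ms = c(1000, 2000),
                            min_valid_fraction = 0.5,
                            retention_rule = c("mean_eigenvalue", "unit_eigenvalue"),
                            pca_window_ms = 3000,
                            min_trials = 5,
                            velocity_mads = 5,
                            artifact_pad_ms = 50,
                            score_method = c("regression", "correlation"),
                            rng_seed = 1L) {
  retention_rule <- match.arg(retention_rule)
  score_method <- match.arg(score_method)
  cfg <- list(
    epoch_window_ms = as.numeric(epoch_window_ms),
    baseline_window_ms = as.numeric(baseline_window_ms),
    evoked_window_ms = as.numeric(evoked_window_ms),
    min_valid_fraction = min_valid_fraction,
    retention_rule = retention_rule,
    pca_window_ms = pca_window_ms,
    min_trials = min_trials,
    velocity_mads = velocity_mads,
    artifact_pad_ms = artifact_pad_ms,
    score_method = score_method,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "analysis_config"
  validate_analysis_config(cfg)
}

#' @rdname analysis_config
#' @param cfg An `analysis_config` to validate.
#' @export
validate_analysis_config <- function(cfg) {
  w <- function(x) length(x) == 2 && x[2] > x[1]
  .assert(w(cfg$epoch_window_ms), "epoch_window_ms must be an increasing length-2 interval")
  .assert(w(cfg$baseline_window_ms), "baseline_window_ms must be an increasing length-2 interval")
  .assert(w(cfg$evoked_window_ms), "evoked_window_ms must be an increasing length-2 interval")
  .assert(cfg$evoked_window_ms[1] >= cfg$epoch_window_ms[1] &&
            cfg$evoked_window_ms[2] <= cfg$epoch_window_ms[2],
          "evoked window must lie inside the epoch window", "pupilbound_config_error")
  .assert(cfg$min_valid_fraction > 0 && cfg$min_valid_fraction <= 1,
          "min_valid_fraction must be in (0, 1]")
  .assert(cfg$pca_window_ms %in% c(1500, 3000), "pca_window_ms must be 1500 or 3000")
  .assert(cfg$min_trials >= 1, "min_trials must be >= 1")
  cfg
}

#' Simulation configuration
#'
#' Parameters of the synthetic experiment generator. The defaults state the
#' world the pipeline is validated against: 65 participants (the two
#' eye-tracking samples pooled), 14 analyzed lists of 32 items in 4 auditory
#' events of 8, pupil sampled at 250 Hz, four planted temporal components of
#' tone-evoked dilation with peak latencies 2424, 1316, 308 and 800 ms whose
#' between-participant variances reproduce the late-to-early variance
#' ordering, a boundary amplitude advantage on components 1-3 only, and
#' boundary effects on the three memory tests of roughly d = 0.5-0.8.
#'
#' Amplitudes are in arbitrary device units. For component `k` the amplitude
#' of participant `i` in condition `c` is
#' `amp_mean[k, c] + u[i, k] + e[i, k, c]` with `u ~ N(0, amp_between_sd[k]^2)`
#' shared between conditions and `e ~ N(0, amp_within_sd[k]^2)` condition
#' specific; the planted boundary-minus-same-context amplitude delta of a
#' participant is therefore `diff(amp_mean[k, ]) + e[i,k,2] - e[i,k,1]`.
#'
#' @param n_participants,n_blocks Sample sizes (blocks = analyzed lists).
#' @param sampling_rate_hz Pupil sampling rate.
#' @param lag Intervening items between tested pair members: 2 (Experiments
#'   1-2) or 4 (Experiment 3).
#' @param component_latencies_ms,component_widths_ms Peak latency and width
#'   (Gaussian-equivalent sd near the peak) of the planted gamma-family
#'   component kernels.
#' @param amp_mean 4 x 2 matrix of mean amplitudes, columns
#'   `same_context`, `boundary`.
#' @param amp_between_sd,amp_within_sd Between-participant (condition-shared)
#'   and condition-specific amplitude sds per component.
#' @param image_amp Amplitude of the image-evoked response (constant across
#'   participants and conditions, so it shapes the mean trace but is invisible
#'   to covariance PCA).
#' @param image_latency_ms,image_width_ms Image-response kernel parameters.
#' @param baseline_mean,baseline_sd Participant-level mean pupil size.
#' @param tonic_ar1_phi,tonic_sd AR(1) coefficient (per sample) and stationary
#'   sd of the slow tonic drift.
#' @param noise_sd White measurement noise sd per sample.
#' @param blink_rate_per_min Poisson rate of blink/dropout events.
#' @param blink_duration_meanlog,blink_duration_sdlog Log-normal blink
#'   duration parameters (ms).
#' @param order_logit_intercept,order_logit_boundary,order_effect_sd,order_intercept_sd
#'   Temporal order model: Bernoulli with logit = intercept + participant
#'   intercept (sd `order_intercept_sd`) + boundary term (mean
#'   `order_logit_boundary`, participant sd `order_effect_sd`) for
#'   boundary-spanning pairs.
#' @param distance_shift_boundary,distance_effect_sd,distance_intercept_sd
#'   Distance model: latent normal (sd 1) cut at -1, 0, 1 into ratings 1-4;
#'   boundary pairs shift the latent mean.
#' @param source_logit_intercept,source_logit_boundary,source_effect_sd,source_intercept_sd
#'   Source model: Bernoulli correct-ear report with a boundary-item logit bonus.
#' @param coupling 4 x 3 matrix (component x measure, columns `distance`,
#'   `order`, `source`): latent-scale coefficient applied to the standardized
#'   planted amplitude delta of the component, added to the participant's
#'   boundary effect for that measure.
#' @param stability_order_slope,stability_distance_slope Latent-scale
#'   coefficients of the standardized between-pair pupil sd on the pair's
#'   order logit / distance latent mean (0 = no coupling).
#' @param pitch_amp_slope Increase in boundary-tone component amplitudes per
#'   100 Hz of pitch change (0 = boundary salience does not scale amplitudes).
#' @param rng_seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 65,
                       n_blocks = 14,
                       sampling_rate_hz = 250,
                       lag = 2,
                       component_latencies_ms = c(2424, 1316, 308, 800),
                       component_widths_ms = c(450, 350, 300, 150),
                       amp_mean = cbind(same_context = c(100, 40, 50, 60),
                                        boundary     = c(140, 64, 64, 60)),
                       amp_between_sd = c(51.7, 29.0, 32.0, 15.0),
                       amp_within_sd = c(18.5, 9.5, 8.0, 42.0),
                       image_amp = 150,
                       image_latency_ms = 800,
                       image_width_ms = 250,
                       baseline_mean = 5000,
                       baseline_sd = 300,
                       tonic_ar1_phi = 0.998,
                       tonic_sd = 30,
                       noise_sd = 50,
                       blink_rate_per_min = 12,
                       blink_duration_meanlog = log(180),
                       blink_duration_sdlog = 0.4,
                       order_logit_intercept = 0.45,
                       order_logit_boundary = -0.35,
                       order_effect_sd = 0.25,
                       order_intercept_sd = 0.35,
                       distance_shift_boundary = 0.25,
                       distance_effect_sd = 0.2,
                       distance_intercept_sd = 0.3,
                       source_logit_intercept = 0.6,
                       source_logit_boundary = 0.4,
                       source_effect_sd = 0.25,
                       source_intercept_sd = 0.35,
                       coupling = matrix(0, 4, 3,
                                         dimnames = list(NULL, c("distance", "order", "source"))),
                       stability_order_slope = 0,
                       stability_distance_slope = 0,
                       pitch_amp_slope = 0,
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  cfg$rng_seed <- as.integer(rng_seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
validate_sim_config <- function(cfg) {
  .assert(cfg$n_participants >= 1 && cfg$n_blocks >= 1, "need at least 1 participant and block")
  .assert(cfg$sampling_rate_hz > 0, "sampling_rate_hz must be positive")
  .assert(cfg$lag >= 1 && cfg$lag <= 6,
          sprintf("lag %d is incompatible with 8-item events (need 1..6)", cfg$lag),
          "pupilbound_config_error")
  k <- length(cfg$component_latencies_ms)
  .assert(length(cfg$component_widths_ms) == k &&
            nrow(cfg$amp_mean) == k &&
            length(cfg$amp_between_sd) == k && length(cfg$amp_within_sd) == k,
          "component parameter lengths disagree")
  .assert(all(cfg$component_latencies_ms > 0 & cfg$component_latencies_ms < 3000),
          "component latencies must lie inside the [0, 3000) ms epoch window",
          "pupilbound_config_error")
  .assert(all(c(cfg$amp_between_sd, cfg$amp_within_sd, cfg$tonic_sd, cfg$noise_sd) >= 0),
          "all standard deviations must be >= 0")
  .assert(cfg$tonic_ar1_phi >= 0 && cfg$tonic_ar1_phi < 1, "tonic_ar1_phi must be in [0, 1)")
  .assert(is.matrix(cfg$coupling) && nrow(cfg$coupling) == k && ncol(cfg$coupling) == 3,
          "coupling must be a k x 3 matrix")
  .assert(all(abs(cfg$coupling) < 3), "|coupling| must be < 3")
  cfg
}
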