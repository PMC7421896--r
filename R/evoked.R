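#' Tone-evoked pupil dilation
#'
#' Per-trial evoked dilation is the mean of the baseline-corrected epoch over
#' the evoked window (`[1000, 2000)` ms after tone onset by default, where
#' the tone-evoked response is maximal). Participant-condition means
#' aggregate trials across blocks; list-initial tones are excluded from the
#' two contrast conditions.
#'
#' @param epochs An `epoch_matrix` (see [epoch_pupil]).
#' @param cfg An [analysis_config].
#' @return A list of class `evoked_summary`: `trials` (per-trial values with
#'   keys) and `by_participant` (participant x condition means for
#'   `boundary` and `same_context`).
#' @export
evoked_dilation <- function(epochs, cfg = analysis_config()) {
  .assert(cfg$evoked_window_ms[1] >= cfg$epoch_window_ms[1] &&
            cfg$evoked_window_ms[2] <= cfg$epoch_window_ms[2],
          "evoked window outside epoch window", "pupilbound_config_error")
  sel <- epochs$times_ms >= cfg$evoked_window_ms[1] &
    epochs$times_ms < cfg$evoked_window_ms[2]
  trials <- epochs$info
  trials$evoked <- rowMeans(epochs$x[, sel, drop = FALSE])
  contrast <- trials[trials$tone_condition %in% c("boundary", "same_context"), ]
  by_participant <- aggregate(evoked ~ participant + tone_condition, contrast, mean)
  structure(list(trials = trials, by_participant = by_participant),
            class = "evoked_summary")
}

#' Paired condition contrast
#'
#' Two-tailed paired t-test on participant condition means, with Cohen's
#' d (dz: mean difference over the sd of differences) and a t-based 95%
#' confidence interval for the mean difference.
#'
#' @param x,y Paired participant-level values (x - y is tested), or `x` can
#'   be an `evoked_summary`, in which case the boundary minus same-context
#'   contrast is computed.
#' @param conf_level Confidence level for the CI.
#' @return A list: `t`, `df`, `p`, `d`, `ci`, `mean_diff`, `n`,
#'   `zero_variance` flag (when all differences are equal, `p` and `d` are
#'   undefined and returned as `NA`).
#' @export
paired_contrast <- function(x, y = NULL, conf_level = 0.95) {
  if (inherits(x, "evoked_summary")) {
    w <- x$by_participant
    b <- w[w$tone_condition == "boundary", ]
    s <- w[w$tone_condition == "same_context", ]
    common <- intersect(b$participant, s$participant)
    x <- b$evoked[match(common, b$participant)]
    y <- s$evoked[match(common, s$participant)]
  }
  .assert(length(x) == length(y), "paired vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  .assert(length(d) >= 3, "need at least 3 paired observations",
          "pupilbound_insufficient_data")
  .one_sample(d, conf_level)
}

#' One-sample test against zero
#'
#' Two-tailed one-sample t-test of participant values against 0 (used for
#' dilation-versus-baseline tests), with dz and CI as in [paired_contrast].
#'
#' @param values Participant-level values.
#' @param mu Null value (default 0).
#' @param conf_level Confidence level.
#' @return As [paired_contrast].
#' @export
against_baseline <- function(values, mu = 0, conf_level = 0.95) {
  values <- values[!is.na(values)]
  .assert(length(values) >= 3, "need at least 3 observations",
          "pupilbound_insufficient_data")
  .one_sample(values - mu, conf_level)
}

.one_sample <- function(d, conf_level = 0.95) {
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    return(list(t = if (m == 0) 0 else NA_real_, df = n - 1, p = NA_real_,
                d = if (m == 0) 0 else NA_real_, ci = c(m, m), mean_diff = m,
                n = n, zero_variance = TRUE))
  }
  se <- s / sqrt(n)
  tval <- m / se
  alpha <- 1 - conf_level
  list(t = tval, df = n - 1, p = 2 * pt(-abs(tval), n - 1),
       d = m / s, ci = m + c(-1, 1) * qt(1 - alpha / 2, n - 1) * se,
       mean_diff = m, n = n, zero_variance = FALSE)
}
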