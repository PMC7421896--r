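# shared helpers for building small fixtures in code

# a tiny but complete simulation config (full traces remain affordable)
tiny_sim_config <- function(n_participants = 4, n_blocks = 2, ...) {
  sim_config(n_participants = n_participants, n_blocks = n_blocks, ...)
}

# deterministic recording on the standard 4-ms grid
make_recording <- function(pupil, participant = "P01", block = 1L,
                           valid = NULL, step = 4) {
  pupil_recording(participant, block, time = (seq_along(pupil) - 1) * step,
                  pupil = pupil, valid = valid)
}

# single-tone event table row (plus its image), for epoching tests
make_tone_events <- function(onsets_ms, participant = "P01", block = 1L,
                             condition = "same_context") {
  n <- length(onsets_ms)
  data.frame(participant = participant, block = block, onset_ms = onsets_ms,
             event_type = "tone", list_index = block,
             event_index = if (condition == "boundary") 2L else 1L,
             position_in_event = if (condition == "same_context") 2L else 1L,
             tone_condition = condition, frequency_hz = 500, ear = "left",
             item_id = sprintf("i%02d", seq_len(n)))
}

# greedy one-to-one matching of solution components to planted waveforms by
# absolute correlation; returns planted index per solution component and the
# matched |r|
match_components <- function(loadings, planted) {
  cc <- cor(loadings, planted)
  k <- min(dim(cc))
  m <- rep(NA_integer_, ncol(loadings))
  tmp <- abs(cc)
  for (i in seq_len(k)) {
    w <- which(tmp == max(tmp), arr.ind = TRUE)[1, ]
    m[w[1]] <- w[2]
    tmp[w[1], ] <- -1
    tmp[, w[2]] <- -1
  }
  list(match = m,
       r = vapply(seq_along(m), function(j) cc[j, m[j]], numeric(1)))
}

# paired boundary-vs-same-context contrast on a solution's scores, per
# component, returned as a list of paired_contrast results
score_contrasts <- function(sol) {
  keys <- sol$keys
  b <- keys$condition == "boundary"
  s <- keys$condition == "same_context"
  ord_b <- order(keys$participant[b])
  ord_s <- order(keys$participant[s])
  lapply(seq_len(sol$k), function(j)
    paired_contrast(sol$scores[b, j][ord_b], sol$scores[s, j][ord_s]))
}

# closed-form oracle: expected mean 1-4 rating of the latent-normal cutpoint
# model with participant-intercept sd `icpt_sd` and latent shift `shift`
expected_rating <- function(shift, icpt_sd) {
  s <- sqrt(1 + icpt_sd^2)
  p_le <- pnorm((c(-1, 0, 1) - shift) / s)
  p <- c(p_le[1], diff(p_le), 1 - p_le[3])
  sum(1:4 * p)
}

# numeric-integration oracle: expected accuracy of the random-intercept
# logistic model
expected_accuracy <- function(logit, icpt_sd) {
  if (icpt_sd == 0) return(plogis(logit))
  integrate(function(u) plogis(logit + u) * dnorm(u, sd = icpt_sd),
            -Inf, Inf)$value
}
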