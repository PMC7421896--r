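#' Spearman rank correlation
#'
#' rho from Pearson correlation of average (mid)ranks; the two-tailed p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' df, or the exact permutation distribution (all distinct arrangements of
#' the y ranks) for `exact = TRUE` with n <= 10.
#'
#' @param x,y Paired numeric vectors (complete cases are used).
#' @param exact Use the exact permutation p-value (n <= 10 only).
#' @return A list: `rho`, `p`, `n`, `method`. Zero variance in either input
#'   gives `rho = NA` with a `degenerate` flag.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  .assert(n >= 5, "spearman_cor needs at least 5 complete pairs",
          "pupilbound_insufficient_data")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "degenerate",
                degenerate = TRUE))
  rho <- cor(rx, ry)
  if (exact) {
    .assert(n <= 10, "exact permutation p only supported for n <= 10")
    p <- spearman_exact_p(rx, ry)
    method <- "exact_permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tval), n - 2)
    }
    method <- "t_approximation"
  }
  list(rho = rho, p = p, n = n, method = method, degenerate = FALSE)
}

#' Participant-level subtraction scores
#'
#' Boundary minus same-context differences per participant: component scores
#' from a fitted `component_solution` (or any per-participant-condition score
#' table) and the three memory measures. These are the inputs of the
#' individual-differences pupil-memory correlations.
#'
#' @param solution A `component_solution` whose rows are
#'   participant-condition waveforms, or `NULL` to return memory deltas only.
#' @param outcomes A [memory_outcomes] object.
#' @param modes Optional named vector mapping participant to experiment mode
#'   (e.g., the pair lag); copied into the output for per-mode analyses.
#' @return Data frame, one row per participant: `delta_score_k` per
#'   component, `delta_order`, `delta_distance`, `delta_source`, `mode`.
#' @export
subtraction_scores <- function(solution, outcomes, modes = NULL) {
  mem <- .memory_deltas(outcomes)
  if (!is.null(solution)) {
    keys <- solution$keys
    .assert(!anyDuplicated(paste(keys$participant, keys$condition)),
            "duplicate participant-condition rows in solution",
            "pupilbound_join_error")
    sc <- as.data.frame(solution$scores)
    sc$participant <- keys$participant
    sc$condition <- keys$condition
    b <- sc[sc$condition == "boundary", , drop = FALSE]
    s <- sc[sc$condition == "same_context", , drop = FALSE]
    common <- intersect(b$participant, s$participant)
    comp_cols <- grep("^c[0-9]+$", names(sc), value = TRUE)
    d <- b[match(common, b$participant), comp_cols, drop = FALSE] -
      s[match(common, s$participant), comp_cols, drop = FALSE]
    names(d) <- sub("^c", "delta_score_", comp_cols)
    d$participant <- common
    mem <- merge(d, mem, by = "participant", all = FALSE)
  }
  if (!is.null(modes)) mem$mode <- unname(modes[mem$participant])
  mem
}

.memory_deltas <- function(outcomes) {
  ow <- score_order(outcomes)
  dw <- score_distance(outcomes)
  sw <- score_source(outcomes)
  delta_of <- function(df, value, cond_col, a, b) {
    w <- tapply(df[[value]], list(df$participant, df[[cond_col]]), mean)
    out <- w[, a] - w[, b]
    data.frame(participant = rownames(w), delta = unname(out))
  }
  d1 <- delta_of(ow, "prop_correct", "pair_condition", "boundary_span", "same_context")
  names(d1)[2] <- "delta_order"
  d2 <- delta_of(dw, "mean_rating", "pair_condition", "boundary_span", "same_context")
  names(d2)[2] <- "delta_distance"
  d3 <- delta_of(sw, "prop_correct", "item_type", "boundary", "same_context")
  names(d3)[2] <- "delta_source"
  merge(merge(d1, d2, by = "participant"), d3, by = "participant")
}

#' Pupil-memory subtraction-score correlations
#'
#' Spearman correlations between every component's score delta and every
#' memory delta, pooled across participants and (when a `mode` column is
#' present) per experiment mode. No multiple-comparison adjustment is applied
#' (flagged in the output), mirroring the planned-comparison convention of
#' the analysis.
#'
#' @param subtractions Output of [subtraction_scores].
#' @param exact Passed to [spearman_cor].
#' @return Data frame: component, memory_measure, mode ("pooled" or the mode
#'   value), rho, p, n; with attribute `multiple_comparison_adjustment =
#'   "none"`.
#' @export
pupil_memory_correlations <- function(subtractions, exact = FALSE) {
  .assert(!anyDuplicated(subtractions$participant),
          "duplicate participant rows in subtraction scores",
          "pupilbound_join_error")
  comp_cols <- grep("^delta_score_", names(subtractions), value = TRUE)
  .assert(length(comp_cols) > 0, "no component score deltas present")
  mem_cols <- c(distance = "delta_distance", order = "delta_order",
                source = "delta_source")
  slices <- list(pooled = subtractions)
  if (!is.null(subtractions$mode))
    for (m in sort(unique(subtractions$mode)))
      slices[[as.character(m)]] <- subtractions[subtractions$mode == m, ]
  rows <- list()
  for (mode_name in names(slices)) {
    sl <- slices[[mode_name]]
    for (cc in comp_cols) for (mm in names(mem_cols)) {
      r <- spearman_cor(sl[[cc]], sl[[mem_cols[mm]]], exact = exact)
      rows[[length(rows) + 1L]] <- data.frame(
        component = as.integer(sub("delta_score_", "", cc)),
        memory_measure = mm, mode = mode_name,
        rho = r$rho, p = r$p, n = r$n)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "multiple_comparison_adjustment") <- "none"
  out
}

#' Per-trial phasic and tonic pupil measures
#'
#' Phasic arousal is the tone-evoked dilation (baseline-corrected mean over
#' the evoked window); tonic arousal is the raw mean pupil in the pre-tone
#' baseline window. For boundary tones the pitch change relative to the
#' previous event's tone frequency is attached.
#'
#' @param evoked An `evoked_summary` (see [evoked_dilation]).
#' @return Data frame of tone trials with `phasic`, `tonic`,
#'   `pitch_change_hz` (NA off boundaries).
#' @export
trial_measures <- function(evoked) {
  tr <- evoked$trials
  tr$phasic <- tr$evoked
  tr$tonic <- tr$baseline_mean
  tr$pitch_change_hz <- NA_real_
  key <- paste(tr$participant, tr$block, tr$event_index)
  prev_key <- paste(tr$participant, tr$block, tr$event_index - 1L)
  freq_of <- tapply(tr$frequency_hz, key, function(v) v[1])
  is_bnd <- tr$tone_condition == "boundary"
  tr$pitch_change_hz[is_bnd] <- abs(tr$frequency_hz[is_bnd] -
                                      freq_of[prev_key[is_bnd]])
  tr
}

.fit_mixed <- function(formula, data, binary) {
  fit <- tryCatch({
    if (binary)
      lme4::glmer(formula, data = data, family = stats::binomial,
                  control = lme4::glmerControl(calc.derivs = FALSE))
    else
      lme4::lmer(formula, data = data,
                 control = lme4::lmerControl(calc.derivs = FALSE))
  }, error = function(e) NULL)
  if (is.null(fit)) return(list(coefficients = NULL, converged = FALSE))
  co <- coef(summary(fit))
  tab <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    z = co[, 1] / co[, 2],
                    p = 2 * pnorm(-abs(co[, 1] / co[, 2])), row.names = NULL)
  msgs <- fit@optinfo$conv$lme4$messages
  list(coefficients = tab, converged = is.null(msgs), fit = fit)
}

#' Trial-level phasic/tonic mixed models
#'
#' For each memory outcome, a mixed model with a participant random intercept
#' and standardized phasic and tonic predictors: logistic link for order and
#' source correctness, identity link for distance ratings. Pair-level
#' outcomes are joined to the tone preceding the pair's second item;
#' item-level source outcomes to the item's own tone. Coefficients carry Wald
#' tests.
#'
#' @param trials Output of [trial_measures].
#' @param outcomes A [memory_outcomes] object.
#' @return Named list (`order`, `distance`, `source`) of coefficient tables
#'   with convergence flags.
#' @export
trial_level_models <- function(trials, outcomes) {
  tkey <- paste(trials$participant, trials$block, trials$item_id)
  join_pairs <- function(p) {
    idx <- match(paste(p$participant, p$block, p$item_b), tkey)
    ok <- !is.na(idx)
    cbind(p[ok, , drop = FALSE],
          phasic = as.numeric(scale(trials$phasic[idx[ok]])),
          tonic = as.numeric(scale(trials$tonic[idx[ok]])))
  }
  pd <- join_pairs(outcomes$pairs)
  degenerate <- function(y) length(unique(y)) < 2
  res <- list()
  res$order <- if (degenerate(pd$order_correct)) {
    .warn("order outcome is degenerate (constant)"); list(coefficients = NULL, converged = FALSE)
  } else .fit_mixed(order_correct ~ phasic + tonic + (1 | participant), pd, TRUE)
  res$distance <- .fit_mixed(distance_rating ~ phasic + tonic + (1 | participant),
                             pd, FALSE)
  it <- outcomes$items
  idx <- match(paste(it$participant, it$block, it$item_id), tkey)
  ok <- !is.na(idx)
  id <- cbind(it[ok, , drop = FALSE],
              phasic = as.numeric(scale(trials$phasic[idx[ok]])),
              tonic = as.numeric(scale(trials$tonic[idx[ok]])))
  res$source <- if (degenerate(id$source_correct)) {
    .warn("source outcome is degenerate (constant)"); list(coefficients = NULL, converged = FALSE)
  } else .fit_mixed(source_correct ~ phasic + tonic + (1 | participant), id, TRUE)
  res
}

#' Boundary pitch-change analysis
#'
#' Association of the tone pitch change at boundaries (100-500 Hz) with (a)
#' the boundary tone's evoked dilation and (b) memory for the boundary item
#' and the boundary-spanning pair, via participant random-intercept models.
#'
#' @param trials Output of [trial_measures].
#' @param outcomes A [memory_outcomes] object.
#' @return Named list of model results (`evoked`, `source`, `order`,
#'   `distance`); a zero-variance pitch predictor is flagged.
#' @export
pitch_change_analysis <- function(trials, outcomes) {
  bt <- trials[trials$tone_condition == "boundary", , drop = FALSE]
  .assert(all(bt$pitch_change_hz >= 100 & bt$pitch_change_hz <= 500, na.rm = TRUE),
          "boundary pitch changes outside 100..500 Hz", "pupilbound_data_error")
  if (sd(bt$pitch_change_hz) == 0) {
    .warn("pitch change has zero variance; analysis skipped")
    return(list(degenerate = TRUE))
  }
  bt$pitch_std <- as.numeric(scale(bt$pitch_change_hz))
  res <- list(degenerate = FALSE)
  res$evoked <- .fit_mixed(phasic ~ pitch_std + (1 | participant), bt, FALSE)
  # boundary item source memory vs the pitch change of its own tone
  it <- outcomes$items[outcomes$items$item_type == "boundary", , drop = FALSE]
  bkey <- paste(bt$participant, bt$block, bt$item_id)
  idx <- match(paste(it$participant, it$block, it$item_id), bkey)
  ok <- !is.na(idx)
  id <- cbind(it[ok, , drop = FALSE], pitch_std = bt$pitch_std[idx[ok]])
  res$source <- if (nrow(id) > 0 && length(unique(id$source_correct)) > 1)
    .fit_mixed(source_correct ~ pitch_std + (1 | participant), id, TRUE)
  else list(coefficients = NULL, converged = FALSE)
  # boundary-spanning pairs vs the pitch change of the spanned boundary tone
  p <- outcomes$pairs[outcomes$pairs$pair_condition == "boundary_span", , drop = FALSE]
  # item_b sits in the event after the boundary; the spanned boundary tone is
  # that event's first tone, recoverable from (participant, block, event of b)
  all_t <- trials
  bidx <- match(paste(p$participant, p$block, p$item_b),
                paste(all_t$participant, all_t$block, all_t$item_id))
  ev_b <- all_t$event_index[bidx]
  pidx <- match(paste(p$participant, p$block, ev_b),
                paste(bt$participant, bt$block, bt$event_index))
  ok <- !is.na(pidx)
  pp <- cbind(p[ok, , drop = FALSE], pitch_std = bt$pitch_std[pidx[ok]])
  res$order <- if (nrow(pp) > 0 && length(unique(pp$order_correct)) > 1)
    .fit_mixed(order_correct ~ pitch_std + (1 | participant), pp, TRUE)
  else list(coefficients = NULL, converged = FALSE)
  res$distance <- if (nrow(pp) > 0)
    .fit_mixed(distance_rating ~ pitch_std + (1 | participant), pp, FALSE)
  else list(coefficients = NULL, converged = FALSE)
  res
}

#' Between-pair pupil variability
#'
#' For every tested pair, the standard deviation of the preprocessed pupil
#' trace over the span from the first item's image onset to the second item's
#' image offset — an index of the temporal stability of arousal between the
#' to-be-tested items.
#'
#' @param recordings Named list of preprocessed recordings.
#' @param pairs Pair schedule / outcomes rows with `participant`, `block`,
#'   `item_a`, `item_b`.
#' @param events Event table (image onsets are looked up there).
#' @param valid_only Compute the sd over valid (measured) samples only; used
#'   by the generator, where blink dropouts have not yet been interpolated.
#' @return `pairs` with a `pair_sd` column; pairs whose span exceeds the
#'   recording are dropped with a warning.
#' @export
between_pair_sd <- function(recordings, pairs, events, valid_only = FALSE) {
  img <- events[events$event_type == "image", , drop = FALSE]
  ikey <- paste(img$participant, img$block, img$item_id)
  on_a <- img$onset_ms[match(paste(pairs$participant, pairs$block, pairs$item_a), ikey)]
  on_b <- img$onset_ms[match(paste(pairs$participant, pairs$block, pairs$item_b), ikey)]
  sds <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    rec <- recordings[[paste0(pairs$participant[i], ".", pairs$block[i])]]
    if (is.null(rec) || is.na(on_a[i]) || is.na(on_b[i])) next
    span <- rec$time >= on_a[i] & rec$time < on_b[i] + 2500
    if (!any(span) || max(rec$time) < on_b[i] + 2500 - 1000 / rec$sampling_rate) next
    if (valid_only) span <- span & rec$valid
    sds[i] <- sd(rec$pupil[span])
  }
  if (anyNA(sds))
    .warn(sprintf("between_pair_sd: dropping %d pair(s) without full span coverage",
                  sum(is.na(sds))))
  out <- pairs
  out$pair_sd <- sds
  out[!is.na(sds), , drop = FALSE]
}

#' Arousal-stability analysis
#'
#' Tests whether lower trial-by-trial pupil variability between the
#' to-be-tested items (see [between_pair_sd]) predicts memory integration:
#' participant random-intercept models of order correctness (logistic) and
#' distance rating (linear) on the standardized between-pair sd. A positive
#' distance coefficient means higher variability goes with larger rated
#' distances.
#'
#' @param recordings Named list of preprocessed recordings.
#' @param outcomes A [memory_outcomes] object.
#' @param events Event table.
#' @return A list: `measures` (pairs with `pair_sd`), `order`, `distance`
#'   model results, and the boundary vs same-context `sd_contrast`.
#' @export
stability_analysis <- function(recordings, outcomes, events) {
  m <- between_pair_sd(recordings, outcomes$pairs, events)
  m$sd_std <- as.numeric(scale(m$pair_sd))
  res <- list(measures = m)
  res$order <- if (length(unique(m$order_correct)) > 1)
    .fit_mixed(order_correct ~ sd_std + (1 | participant), m, TRUE)
  else list(coefficients = NULL, converged = FALSE)
  res$distance <- .fit_mixed(distance_rating ~ sd_std + (1 | participant), m, FALSE)
  w <- tapply(m$pair_sd, list(m$participant, m$pair_condition), mean)
  w <- w[!apply(is.na(w), 1, any), , drop = FALSE]
  res$sd_contrast <- if (nrow(w) >= 3)
    paired_contrast(w[, "boundary_span"], w[, "same_context"])
  else NULL
  res
}
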