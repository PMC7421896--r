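#' Unit-peak pupil response kernel
#'
#' Gamma-family waveform used as the planted temporal component shape:
#' `h(t) = (t / L)^s * exp(s * (1 - t / L))` with shape `s = (L / W)^2`, which
#' is non-negative, smooth, has a single interior maximum of exactly 1 at the
#' sample nearest the latency `L`, and near the peak behaves like a Gaussian
#' of sd `W`.
#'
#' @param latency_ms Peak latency in ms; must lie inside the evaluation window.
#' @param width_ms Width (Gaussian-equivalent sd near the peak) in ms; > 0.
#' @param times_ms Times (ms from stimulus onset) at which to evaluate;
#'   defaults to the standard 3-s epoch grid at 250 Hz.
#' @return Numeric waveform, `max = 1`, `min >= 0`.
#' @export
pupil_kernel <- function(latency_ms, width_ms, times_ms = seq(0, 2996, by = 4)) {
  .assert(width_ms > 0, "width_ms must be > 0", "pupilbound_config_error")
  .assert(latency_ms > min(times_ms) && latency_ms < max(times_ms),
          sprintf("latency %g ms outside evaluation window [%g, %g]",
                  latency_ms, min(times_ms), max(times_ms)),
          "pupilbound_config_error")
  s <- (latency_ms / width_ms)^2
  h <- ifelse(times_ms <= 0, 0,
              exp(s * (log(times_ms / latency_ms) + 1 - times_ms / latency_ms)))
  h / max(h)
}

.FREQS <- seq(500, 1000, by = 100)

#' Generate the task design for one simulated experiment
#'
#' Builds, for every participant and block, the tone/image event table and
#' the test schedule of the auditory event-boundary paradigm: 32 items per
#' block in 4 events of 8; images shown 2.5 s with a 3-s inter-stimulus
#' interval; a 1-s pure tone 1.5 s post-image (i.e., 1.5 s before each image);
#' 4 distinct tone frequencies per block, none reused across events; the ear
#' alternating between events with the first ear alternating across blocks.
#' Per block, 4 same-context and 3 boundary-spanning test pairs at the
#' configured lag are scheduled, excluding the first item, the last item and
#' the boundary items so the 18 untested items always include all four source
#' item types.
#'
#' @param cfg A [sim_config].
#' @return A list with `events` (tone and image rows) and `pairs` (test-pair
#'   schedule with `item_a`, `item_b`, `pair_condition`, `lag`) data frames,
#'   plus `source_items` (items scheduled for the source test with
#'   `item_type`).
#' @export
generate_design <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  lag <- cfg$lag
  span <- lag + 1L          # positional distance between pair members
  boundary_pos <- c(9L, 17L, 25L)
  bnd_a <- c(8L, 16L, 24L)
  reserved <- c(1L, 32L, boundary_pos, bnd_a, bnd_a + span)
  # admissible same-context pair start positions per event (same for all
  # blocks; only the random choice among them varies)
  cand <- lapply(0:3, function(e) {
    a <- (e * 8L + 1L):(e * 8L + 8L - span)
    a[!(a %in% reserved) & !((a + span) %in% reserved)]
  })
  .assert(all(lengths(cand) > 0),
          sprintf("no admissible same-context pair in some event at lag %d", lag),
          "pupilbound_config_error")
  n_p <- cfg$n_participants; n_b <- cfg$n_blocks
  n_blk <- n_p * n_b
  blk_p <- rep(seq_len(n_p), each = n_b)       # participant of each block
  blk_b <- rep(seq_len(n_b), times = n_p)
  # per-block random draws (loop kept tiny: 2 small samples per block)
  freqs_mat <- t(vapply(seq_len(n_blk), function(i) sample(.FREQS, 4L), numeric(4)))
  sc_a_mat <- t(vapply(seq_len(n_blk), function(i)
    vapply(cand, function(v) if (length(v) == 1L) v else sample(v, 1L), integer(1)),
    integer(4)))

  pos <- 1:32
  event_index <- ((pos - 1L) %/% 8L) + 1L
  pos_in_event <- ((pos - 1L) %% 8L) + 1L
  cond <- tone_condition_label(event_index, pos_in_event)
  blk_of_row <- rep(seq_len(n_blk), each = 32L)
  pid_row <- sprintf("P%02d", blk_p[blk_of_row])
  b_row <- blk_b[blk_of_row]
  pos_row <- rep(pos, n_blk)
  ev_row <- rep(event_index, n_blk)
  first_left <- b_row %% 2L == 1L
  ear_row <- ifelse(xor(first_left, ev_row %% 2L == 1L), "right", "left")
  item_row <- sprintf("%s_b%02d_i%02d", pid_row, b_row, pos_row)
  tones <- data.frame(
    participant = pid_row, block = b_row,
    onset_ms = 1500 + (pos_row - 1L) * 5500, event_type = "tone",
    list_index = b_row, event_index = ev_row,
    position_in_event = rep(pos_in_event, n_blk),
    tone_condition = rep(cond, n_blk),
    frequency_hz = freqs_mat[cbind(blk_of_row, ev_row)],
    ear = ear_row, item_id = item_row)
  images <- tones
  images$event_type <- "image"
  images$onset_ms <- tones$onset_ms + 1500

  pair_a <- cbind(sc_a_mat, matrix(bnd_a, n_blk, 3, byrow = TRUE))
  blk_of_pair <- rep(seq_len(n_blk), times = 7L)
  a_vec <- as.integer(pair_a)
  b_vec <- a_vec + span
  row_of <- function(blk, p) (blk - 1L) * 32L + p
  pairs <- data.frame(
    participant = sprintf("P%02d", blk_p[blk_of_pair]),
    block = blk_b[blk_of_pair],
    item_a = item_row[row_of(blk_of_pair, a_vec)],
    item_b = item_row[row_of(blk_of_pair, b_vec)],
    pos_a = a_vec, pos_b = b_vec,
    pair_condition = rep(c("same_context", "boundary_span"), c(4L, 3L) * n_blk),
    lag = lag)

  untested <- matrix(TRUE, 32L, n_blk)
  untested[cbind(c(a_vec, b_vec), rep(blk_of_pair, 2L))] <- FALSE
  src_idx <- which(untested, arr.ind = TRUE)   # ordered by block
  src_pos <- src_idx[, 1L]; src_blk <- src_idx[, 2L]
  item_type <- rep("same_context", length(src_pos))
  item_type[src_pos %in% boundary_pos] <- "boundary"
  item_type[src_pos == 1L] <- "first"
  item_type[src_pos == 32L] <- "last"
  src <- data.frame(
    participant = sprintf("P%02d", blk_p[src_blk]),
    block = blk_b[src_blk],
    item_id = item_row[row_of(src_blk, src_pos)],
    pos = src_pos, item_type = item_type)
  list(events = rbind(tones, images), pairs = pairs, source_items = src)
}

# participant-level amplitude draws; returns amplitudes [n, k, 2] and the
# planted boundary-minus-same-context deltas
.draw_amplitudes <- function(cfg) {
  n <- cfg$n_participants; k <- length(cfg$component_latencies_ms)
  u <- matrix(rnorm(n * k, 0, rep(cfg$amp_between_sd, each = n)), n, k)
  e_s <- matrix(rnorm(n * k, 0, rep(cfg$amp_within_sd, each = n)), n, k)
  e_b <- matrix(rnorm(n * k, 0, rep(cfg$amp_within_sd, each = n)), n, k)
  amp <- array(NA_real_, c(n, k, 2),
               dimnames = list(NULL, NULL, c("same_context", "boundary")))
  amp[, , "same_context"] <- sweep(u + e_s, 2, cfg$amp_mean[, "same_context"], "+")
  amp[, , "boundary"] <- sweep(u + e_b, 2, cfg$amp_mean[, "boundary"], "+")
  delta <- amp[, , "boundary", drop = FALSE][, , 1] - amp[, , "same_context", drop = FALSE][, , 1]
  delta <- matrix(delta, n, k)
  list(amplitudes = amp, delta = delta)
}

# standardized planted amplitude deltas (0 when a component has no
# condition-specific variance)
.standardized_delta <- function(cfg, delta) {
  k <- ncol(delta)
  z <- matrix(0, nrow(delta), k)
  sds <- sqrt(2) * cfg$amp_within_sd
  dm <- cfg$amp_mean[, "boundary"] - cfg$amp_mean[, "same_context"]
  for (j in seq_len(k)) {
    if (sds[j] > 0) z[, j] <- (delta[, j] - dm[j]) / sds[j]
  }
  z
}

#' Generate continuous pupil recordings with known ground truth
#'
#' Each participant-block trace is the superposition of a participant mean,
#' a slow AR(1) tonic drift, tone-evoked responses (one gamma kernel per
#' planted component, with participant- and condition-specific amplitudes),
#' image-evoked responses (constant amplitude, so they shape the mean trace
#' but carry no between-row variance), white measurement noise, and blink
#' dropouts (pupil set to 0, validity flag cleared).
#'
#' @param design Output of [generate_design].
#' @param cfg A [sim_config].
#' @param amplitudes Optional pre-drawn amplitude structure (internal use).
#' @param mu Optional pre-drawn participant mean pupil sizes (internal use).
#' @param participants Optional integer subset of participants to generate
#'   (used by [simulate_epochs] to stream the experiment without holding all
#'   traces in memory).
#' @return A list: `recordings` (list of [pupil_recording]) and
#'   `ground_truth` (planted unit-peak component waveforms over the 3-s epoch
#'   window, per-participant amplitude draws and deltas).
#' @export
generate_pupil <- function(design, cfg, amplitudes = NULL, mu = NULL,
                           participants = NULL) {
  cfg <- validate_sim_config(cfg)
  k <- length(cfg$component_latencies_ms)
  step <- 1000 / cfg$sampling_rate_hz
  support_ms <- 6000
  kern_t <- seq(0, support_ms - step, by = step)
  kernels <- sapply(seq_len(k), function(j)
    pupil_kernel(cfg$component_latencies_ms[j], cfg$component_widths_ms[j],
                 c(kern_t, support_ms)))[seq_along(kern_t), , drop = FALSE]
  image_kernel <- pupil_kernel(cfg$image_latency_ms, cfg$image_width_ms,
                               c(kern_t, support_ms))[seq_along(kern_t)]
  epoch_t <- seq(0, 2996, by = step)
  gt_wave <- kernels[seq_along(epoch_t), , drop = FALSE]

  if (is.null(amplitudes)) amplitudes <- .draw_amplitudes(cfg)
  if (is.null(mu)) mu <- rnorm(cfg$n_participants, cfg$baseline_mean, cfg$baseline_sd)

  tones <- design$events[design$events$event_type == "tone", , drop = FALSE]
  pids <- sprintf("P%02d", seq_len(cfg$n_participants))
  if (is.null(participants)) participants <- seq_along(pids)
  block_len_ms <- max(tones$onset_ms) + 1500 + 2500 + 2000
  n_samp <- ceiling(block_len_ms / step)
  innov_sd <- cfg$tonic_sd * sqrt(1 - cfg$tonic_ar1_phi^2)
  klen <- nrow(kernels)

  recordings <- list()
  for (i in participants) {
    pid <- pids[i]
    ptones <- tones[tones$participant == pid, , drop = FALSE]
    for (b in unique(ptones$block)) {
      bt <- ptones[ptones$block == b, , drop = FALSE]
      x <- rep(mu[i], n_samp)
      if (cfg$tonic_sd > 0)
        x <- x + as.numeric(filter(rnorm(n_samp, 0, innov_sd),
                                   cfg$tonic_ar1_phi, method = "recursive"))
      if (cfg$noise_sd > 0) x <- x + rnorm(n_samp, 0, cfg$noise_sd)
      # combined per-condition tone responses, computed once per block
      resp <- list(
        same_context = as.numeric(kernels %*% amplitudes$amplitudes[i, , "same_context"]),
        boundary = as.numeric(kernels %*% amplitudes$amplitudes[i, , "boundary"]))
      img_resp <- cfg$image_amp * image_kernel
      for (r in seq_len(nrow(bt))) {
        cond <- bt$tone_condition[r]
        amp_cond <- if (cond == "boundary") "boundary" else "same_context"
        if (cond == "boundary" && cfg$pitch_amp_slope != 0) {
          prev <- bt$frequency_hz[bt$event_index == bt$event_index[r] - 1L][1]
          dpitch <- abs(bt$frequency_hz[r] - prev)
          a <- amplitudes$amplitudes[i, , "boundary"] +
            cfg$pitch_amp_slope * (dpitch - 300) / 100 * cfg$amp_within_sd
          tone_resp <- as.numeric(kernels %*% a)
        } else {
          tone_resp <- resp[[amp_cond]]
        }
        i0 <- round(bt$onset_ms[r] / step) + 1L
        idx <- i0:min(i0 + klen - 1L, n_samp)
        x[idx] <- x[idx] + tone_resp[seq_along(idx)]
        # image-evoked response, 1.5 s after the tone
        j0 <- i0 + round(1500 / step)
        jdx <- j0:min(j0 + klen - 1L, n_samp)
        x[jdx] <- x[jdx] + img_resp[seq_along(jdx)]
      }
      valid <- rep(TRUE, n_samp)
      if (cfg$blink_rate_per_min > 0) {
        n_blinks <- rpois(1, cfg$blink_rate_per_min * (n_samp * step / 60000))
        if (n_blinks > 0) {
          starts <- sort(sample.int(n_samp, n_blinks))
          durs <- pmax(1L, round(rlnorm(n_blinks, cfg$blink_duration_meanlog,
                                        cfg$blink_duration_sdlog) / step))
          for (bl in seq_len(n_blinks)) {
            run <- starts[bl]:min(starts[bl] + durs[bl] - 1L, n_samp)
            x[run] <- 0
            valid[run] <- FALSE
          }
        }
      }
      # constructed on a regular grid, so skip the constructor's checks
      recordings[[paste0(pid, ".", b)]] <-
        structure(list(participant_id = pid, block_id = as.integer(b),
                       sampling_rate = cfg$sampling_rate_hz,
                       time = (seq_len(n_samp) - 1L) * step,
                       pupil = x, valid = valid),
                  class = "pupil_recording")
    }
  }
  ground_truth <- list(waveforms = gt_wave,
                       waveform_times_ms = epoch_t,
                       image_waveform = image_kernel[seq_along(epoch_t)],
                       amplitudes = amplitudes$amplitudes,
                       amplitude_delta = amplitudes$delta,
                       participant_mean = mu,
                       participants = pids)
  list(recordings = recordings, ground_truth = ground_truth)
}

#' Generate memory outcomes with planted boundary effects and couplings
#'
#' Temporal order: Bernoulli with logit = intercept + participant intercept +
#' boundary term for boundary-spanning pairs. Temporal distance: a latent
#' standard normal shifted by the participant's boundary shift for boundary
#' pairs, cut at fixed thresholds (-1, 0, 1) into ratings 1-4. Source:
#' Bernoulli with a boundary-item logit bonus. Each participant's boundary
#' effects receive, per component `k`, an additive term
#' `coupling[k, measure] * z_ik` where `z_ik` is the standardized planted
#' amplitude delta, so the population association between planted pupil
#' deltas and memory deltas is controlled by the coupling matrix.
#'
#' @param design Output of [generate_design].
#' @param ground_truth Ground truth from [generate_pupil] (or `NULL` when all
#'   couplings are zero).
#' @param cfg A [sim_config].
#' @param pair_measures Optional data frame keyed by
#'   (`participant`, `block`, `item_a`) with a `pair_sd` column (between-pair
#'   pupil variability); required when a stability slope is non-zero.
#' @return A list: `outcomes` ([memory_outcomes]) and `effects`
#'   (per-participant planted memory-effect draws).
#' @export
generate_memory <- function(design, ground_truth = NULL, cfg, pair_measures = NULL) {
  cfg <- validate_sim_config(cfg)
  n <- cfg$n_participants
  k <- length(cfg$component_latencies_ms)
  if (any(cfg$coupling != 0)) {
    .assert(!is.null(ground_truth),
            "non-zero couplings require ground-truth amplitude deltas")
    z <- .standardized_delta(cfg, ground_truth$amplitude_delta)
  } else {
    z <- matrix(0, n, k)
  }
  if (cfg$stability_order_slope != 0 || cfg$stability_distance_slope != 0)
    .assert(!is.null(pair_measures), "stability slopes require pair_measures")

  eff <- data.frame(
    participant = sprintf("P%02d", seq_len(n)),
    order_intercept = rnorm(n, 0, cfg$order_intercept_sd),
    order_boundary = cfg$order_logit_boundary + rnorm(n, 0, cfg$order_effect_sd) +
      as.numeric(z %*% cfg$coupling[, "order"]),
    distance_intercept = rnorm(n, 0, cfg$distance_intercept_sd),
    distance_boundary = cfg$distance_shift_boundary + rnorm(n, 0, cfg$distance_effect_sd) +
      as.numeric(z %*% cfg$coupling[, "distance"]),
    source_intercept = rnorm(n, 0, cfg$source_intercept_sd),
    source_boundary = cfg$source_logit_boundary + rnorm(n, 0, cfg$source_effect_sd) +
      as.numeric(z %*% cfg$coupling[, "source"]))

  pairs <- design$pairs
  pi <- match(pairs$participant, eff$participant)
  is_bnd <- pairs$pair_condition == "boundary_span"
  sd_term_o <- sd_term_d <- 0
  if (!is.null(pair_measures)) {
    m <- merge(pairs[, c("participant", "block", "item_a")], pair_measures,
               by = c("participant", "block", "item_a"), sort = FALSE)
    .assert(nrow(m) == nrow(pairs), "pair_measures do not cover all pairs")
    key_p <- paste(pairs$participant, pairs$block, pairs$item_a)
    key_m <- paste(m$participant, m$block, m$item_a)
    std_sd <- as.numeric(scale(m$pair_sd[match(key_p, key_m)]))
    sd_term_o <- cfg$stability_order_slope * std_sd
    sd_term_d <- cfg$stability_distance_slope * std_sd
  }
  logit_o <- cfg$order_logit_intercept + eff$order_intercept[pi] +
    ifelse(is_bnd, eff$order_boundary[pi], 0) + sd_term_o
  pairs$order_correct <- rbinom(nrow(pairs), 1, plogis(logit_o))
  latent <- eff$distance_intercept[pi] + ifelse(is_bnd, eff$distance_boundary[pi], 0) +
    sd_term_d + rnorm(nrow(pairs))
  pairs$distance_rating <- as.integer(cut(latent, c(-Inf, -1, 0, 1, Inf), labels = FALSE))

  items <- design$source_items
  ii <- match(items$participant, eff$participant)
  logit_s <- cfg$source_logit_intercept + eff$source_intercept[ii] +
    ifelse(items$item_type == "boundary", eff$source_boundary[ii], 0)
  items$source_correct <- rbinom(nrow(items), 1, plogis(logit_s))

  list(outcomes = memory_outcomes(pairs, items), effects = eff)
}

#' Simulate a full synthetic experiment
#'
#' Draws the design, pupil recordings (optional) and memory outcomes under a
#' single seed. With `traces = FALSE` only the amplitude draws and behavioral
#' outcomes are generated, which is orders of magnitude faster and sufficient
#' for analyses that consume planted amplitude deltas rather than raw traces.
#'
#' @param cfg A [sim_config].
#' @param traces Generate continuous pupil recordings?
#' @return A list with `design`, `recordings` (or `NULL`), `ground_truth`,
#'   `memory` (a [memory_outcomes]) and `effects`.
#' @export
simulate_experiment <- function(cfg, traces = TRUE) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$rng_seed)
  design <- generate_design(cfg)
  amplitudes <- .draw_amplitudes(cfg)
  if (traces) {
    pup <- generate_pupil(design, cfg, amplitudes = amplitudes)
    recordings <- pup$recordings
    ground_truth <- pup$ground_truth
  } else {
    recordings <- NULL
    step <- 1000 / cfg$sampling_rate_hz
    epoch_t <- seq(0, 3000 - step, by = step)
    ground_truth <- list(
      waveforms = sapply(seq_along(cfg$component_latencies_ms), function(j)
        pupil_kernel(cfg$component_latencies_ms[j], cfg$component_widths_ms[j],
                     c(epoch_t, 3000))[seq_along(epoch_t)]),
      waveform_times_ms = epoch_t,
      amplitudes = amplitudes$amplitudes,
      amplitude_delta = amplitudes$delta,
      participants = sprintf("P%02d", seq_len(cfg$n_participants)))
  }
  pair_measures <- NULL
  if ((cfg$stability_order_slope != 0 || cfg$stability_distance_slope != 0)) {
    .assert(traces, "stability couplings require traces = TRUE")
    # couple memory to the variability of the generated trace, ignoring
    # blink dropouts (the analysis side sees them interpolated instead)
    pair_measures <- between_pair_sd(recordings, design$pairs, design$events,
                                     valid_only = TRUE)
  }
  mem <- generate_memory(design, ground_truth, cfg, pair_measures = pair_measures)
  list(design = design, recordings = recordings, ground_truth = ground_truth,
       memory = mem$outcomes, effects = mem$effects,
       pair_measures = pair_measures)
}

#' Simulate, preprocess and epoch an experiment participant-by-participant
#'
#' Memory-efficient equivalent of running [simulate_experiment] followed by
#' [preprocess_recordings] and [epoch_all]: traces are generated, cleaned and
#' epoched one participant at a time and discarded, so the peak footprint is
#' one participant's recordings plus the epoch matrix. Draws random numbers
#' in the same order as [simulate_experiment], so results are identical to
#' the non-streamed path for a given `cfg$rng_seed`.
#'
#' @param cfg A [sim_config].
#' @param acfg An [analysis_config] for preprocessing/epoching.
#' @return A list: `epochs` (stacked `epoch_matrix`), `exclusions`,
#'   `design`, `ground_truth`, `memory`, `effects`.
#' @export
simulate_epochs <- function(cfg, acfg = analysis_config()) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$rng_seed)
  design <- generate_design(cfg)
  amplitudes <- .draw_amplitudes(cfg)
  mu <- rnorm(cfg$n_participants, cfg$baseline_mean, cfg$baseline_sd)
  eps <- list(); reports <- list(); gt <- NULL
  for (i in seq_len(cfg$n_participants)) {
    pup <- generate_pupil(design, cfg, amplitudes = amplitudes, mu = mu,
                          participants = i)
    if (is.null(gt)) gt <- pup$ground_truth
    pre <- preprocess_recordings(pup$recordings, acfg)
    reports[[i]] <- pre$report
    if (length(pre$recordings) > 0)
      eps[[length(eps) + 1L]] <- epoch_all(pre$recordings, design$events, acfg)
  }
  .assert(length(eps) > 0, "all blocks excluded", "pupilbound_empty_error")
  epochs <- structure(list(
    info = do.call(rbind, c(lapply(eps, `[[`, "info"),
                            list(make.row.names = FALSE))),
    x = do.call(rbind, lapply(eps, `[[`, "x")),
    times_ms = eps[[1]]$times_ms), class = "epoch_matrix")
  mem <- generate_memory(design, gt, cfg)
  list(epochs = epochs, exclusions = do.call(rbind, reports), design = design,
       ground_truth = gt, memory = mem$outcomes, effects = mem$effects)
}

#' Solve for the coupling that plants a target population Spearman
#'
#' Finds the latent coupling coefficient `gamma` such that the population
#' Spearman correlation between a component's planted amplitude delta and the
#' participant-level memory subtraction score equals `rho_target`, given the
#' configured effect heterogeneity and the finite trial counts of the design.
#' The population correlation is evaluated by Monte Carlo over a large
#' synthetic population (common random numbers across candidate gammas), and
#' the root is found by bisection.
#'
#' @param cfg A [sim_config].
#' @param component Component index the coupling acts on.
#' @param measure `"distance"`, `"order"` or `"source"`.
#' @param rho_target Target population Spearman (sign is respected).
#' @param n_mc Monte-Carlo population size.
#' @param mc_seed Seed for the internal Monte-Carlo draws.
#' @return The calibrated `gamma` (scalar).
#' @export
calibrate_coupling <- function(cfg, component = 4, measure = "distance",
                               rho_target = 0.5, n_mc = 8000,
                               mc_seed = 104729L) {
  measure <- match.arg(measure, c("distance", "order", "source"))
  n_b <- 3L * cfg$n_blocks   # boundary-spanning pair trials per participant
  n_s <- 4L * cfg$n_blocks   # same-context pair trials
  if (measure == "source") { n_b <- 3L * cfg$n_blocks; n_s <- 13L * cfg$n_blocks }
  set.seed(mc_seed)
  z <- rnorm(n_mc)
  het <- switch(measure,
                distance = rnorm(n_mc, 0, cfg$distance_effect_sd),
                order = rnorm(n_mc, 0, cfg$order_effect_sd),
                source = rnorm(n_mc, 0, cfg$source_effect_sd))
  icpt <- switch(measure,
                 distance = rnorm(n_mc, 0, cfg$distance_intercept_sd),
                 order = rnorm(n_mc, 0, cfg$order_intercept_sd),
                 source = rnorm(n_mc, 0, cfg$source_intercept_sd))
  eps_b <- matrix(rnorm(n_mc * n_b), n_mc, n_b)
  eps_s <- matrix(rnorm(n_mc * n_s), n_mc, n_s)
  u_b <- matrix(runif(n_mc * n_b), n_mc, n_b)
  u_s <- matrix(runif(n_mc * n_s), n_mc, n_s)

  delta_at <- function(gamma) {
    if (measure == "distance") {
      shift <- cfg$distance_shift_boundary + het + gamma * z
      rate_b <- rowMeans(matrix(as.integer(cut(icpt + shift + eps_b,
                                               c(-Inf, -1, 0, 1, Inf), labels = FALSE)),
                                n_mc, n_b))
      rate_s <- rowMeans(matrix(as.integer(cut(icpt + eps_s,
                                               c(-Inf, -1, 0, 1, Inf), labels = FALSE)),
                                n_mc, n_s))
    } else {
      b0 <- if (measure == "order") cfg$order_logit_intercept else cfg$source_logit_intercept
      bfx <- if (measure == "order") cfg$order_logit_boundary else cfg$source_logit_boundary
      p_b <- plogis(b0 + icpt + bfx + het + gamma * z)
      p_s <- plogis(b0 + icpt)
      rate_b <- rowMeans(u_b < p_b)
      rate_s <- rowMeans(u_s < p_s)
    }
    rate_b - rate_s
  }
  f <- function(gamma) cor(z, delta_at(gamma), method = "spearman") - rho_target
  lim <- if (rho_target >= 0) c(0, 2.9) else c(-2.9, 0)
  .assert(f(lim[1]) * f(lim[2]) < 0,
          "rho_target not attainable with |gamma| < 3", "pupilbound_config_error")
  uniroot(f, lim, tol = 1e-3)$root
}

#' Write a simulated experiment to disk
#'
#' Writes `samples.tsv`, `events.tsv`, `pairs.tsv`, `items.tsv` and a
#' `ground_truth.json` (waveforms, amplitudes, effects, seed) into a directory.
#'
#' @param sim Output of [simulate_experiment].
#' @param dir Output directory (created if needed).
#' @param cfg The [sim_config] used (stored in the ground-truth JSON).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim$recordings))
    write_samples(sim$recordings, file.path(dir, "samples.tsv"))
  ev <- sim$design$events
  write_events(ev[order(ev$participant, ev$block, ev$onset_ms), ],
               file.path(dir, "events.tsv"))
  write_behavior(sim$memory, file.path(dir, "pairs.tsv"), file.path(dir, "items.tsv"))
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(waveforms = gt$waveforms, waveform_times_ms = gt$waveform_times_ms,
         amplitude_delta = gt$amplitude_delta, effects = sim$effects,
         rng_seed = if (!is.null(cfg)) cfg$rng_seed else NA),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
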