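#' Detect blink and signal-dropout artifacts
#'
#' Flags samples that are non-positive or missing, samples whose validity
#' flag is cleared, and samples whose absolute sample-to-sample change
#' exceeds `velocity_mads` median absolute deviations of the first
#' difference (a standard pupillometry velocity criterion; the original
#' block-exclusion rule is separate, see [exclude_blocks]). The resulting
#' mask is dilated by `pad_ms` on both sides of every flagged run.
#'
#' @param rec A [pupil_recording].
#' @param velocity_mads Velocity threshold in MADs of `diff(pupil)`.
#' @param pad_ms Dilation pad in ms on each side.
#' @return Logical mask, `TRUE` where the sample is invalid.
#' @export
detect_artifacts <- function(rec, velocity_mads = 5, pad_ms = 50) {
  x <- rec$pupil
  bad <- is.na(x) | x <= 0 | !rec$valid
  dx <- diff(x)
  mad_dx <- median(abs(dx - median(dx)))
  if (mad_dx > 0) {
    fast <- abs(dx - median(dx)) > velocity_mads * mad_dx
    # a fast difference implicates both of its samples
    bad[c(fast, FALSE)] <- TRUE
    bad[c(FALSE, fast)] <- TRUE
  }
  if (any(bad) && pad_ms > 0) {
    pad <- round(pad_ms * rec$sampling_rate / 1000)
    if (pad > 0) {
      # dilate flagged runs by interval painting (O(n + runs))
      n <- length(bad)
      r <- rle(bad)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      starts <- pmax(1L, starts[r$values] - pad)
      ends <- pmin(n, ends[r$values] + pad)
      d <- integer(n + 1L)
      for (j in seq_along(starts)) {
        d[starts[j]] <- d[starts[j]] + 1L
        d[ends[j] + 1L] <- d[ends[j] + 1L] - 1L
      }
      bad <- cumsum(d[seq_len(n)]) > 0L
    }
  }
  bad
}

#' Linearly interpolate flagged samples
#'
#' Flagged samples are replaced by linear interpolation between the nearest
#' unflagged neighbors; unflagged samples are untouched; flagged runs at the
#' start or end of a recording are filled by nearest-value extension. If all
#' samples are flagged the trace is returned unchanged (the block is then
#' removed by [exclude_blocks]).
#'
#' @param rec A [pupil_recording].
#' @param mask Logical mask from [detect_artifacts]; same length as the trace.
#' @return A [pupil_recording] with the interpolated trace; the `valid` field
#'   records which samples were measured (i.e., `!mask`).
#' @export
interpolate_artifacts <- function(rec, mask) {
  .assert(length(mask) == length(rec$pupil), "mask length must match the trace")
  out <- rec
  out$valid <- !mask
  if (!any(mask) || all(mask)) return(out)
  good <- which(!mask)
  fill <- which(mask)
  out$pupil[fill] <- approx(rec$time[good], rec$pupil[good],
                            xout = rec$time[fill], method = "linear",
                            rule = 2, ties = "ordered")$y
  out
}

#' Exclude blocks with insufficient valid data
#'
#' A block is dropped iff its fraction of valid (unflagged) samples is
#' strictly below `min_valid_fraction`; a block at exactly the threshold is
#' retained.
#'
#' @param recordings Named list of [pupil_recording] objects.
#' @param masks Named list of artifact masks aligned with `recordings`.
#' @param min_valid_fraction Exclusion threshold (default 0.5).
#' @return A list: `retained` (recordings), `report` (data frame with one row
#'   per block: participant, block, valid fraction, dropped flag).
#' @export
exclude_blocks <- function(recordings, masks, min_valid_fraction = 0.5) {
  .assert(length(recordings) == length(masks), "recordings and masks differ in length")
  frac <- vapply(seq_along(recordings), function(i) mean(!masks[[i]]), numeric(1))
  dropped <- frac < min_valid_fraction
  report <- data.frame(
    participant = vapply(recordings, function(r) r$participant_id, character(1)),
    block = vapply(recordings, function(r) r$block_id, integer(1)),
    valid_fraction = frac,
    dropped = dropped,
    row.names = NULL)
  if (any(dropped))
    .warn(sprintf("exclude_blocks: dropping %d/%d block(s) below %.0f%% valid",
                  sum(dropped), length(dropped), 100 * min_valid_fraction))
  list(retained = recordings[!dropped], report = report)
}

#' Run the full artifact pipeline over a recording collection
#'
#' Detection, interpolation and block exclusion in one pass.
#'
#' @param recordings Named list of [pupil_recording] objects.
#' @param cfg An [analysis_config].
#' @return A list: `recordings` (retained, interpolated), `report` (exclusion
#'   report).
#' @export
preprocess_recordings <- function(recordings, cfg = analysis_config()) {
  masks <- lapply(recordings, detect_artifacts,
                  velocity_mads = cfg$velocity_mads, pad_ms = cfg$artifact_pad_ms)
  excl <- exclude_blocks(recordings, masks, cfg$min_valid_fraction)
  kept <- names(excl$retained)
  cleaned <- lapply(kept, function(nm) interpolate_artifacts(recordings[[nm]], masks[[nm]]))
  names(cleaned) <- kept
  list(recordings = cleaned, report = excl$report)
}

#' Epoch a recording around tone onsets with baseline correction
#'
#' Cuts one row per tone from the preprocessed trace over the half-open
#' epoch window and subtracts the mean of the pre-tone baseline window
#' (`[-500, 0)` ms by default). The per-row baseline mean is retained
#' separately as the tonic measure. Tones whose epoch or baseline is not
#' fully covered by the recording are dropped with a warning. List-initial
#' tones are epoched and labelled `list_first` but belong to neither contrast
#' condition.
#'
#' @param rec A preprocessed [pupil_recording].
#' @param events Event table rows (tones of this participant-block are
#'   selected automatically).
#' @param cfg An [analysis_config].
#' @return A list of class `epoch_matrix`: `info` (trial key data frame,
#'   including the tonic `baseline_mean`), `x` (trials x timepoints matrix of
#'   baseline-corrected pupil), `times_ms` (column times).
#' @export
epoch_pupil <- function(rec, events, cfg = analysis_config()) {
  step <- 1000 / rec$sampling_rate
  tones <- events[events$event_type == "tone" &
                    events$participant == rec$participant_id &
                    events$block == rec$block_id, , drop = FALSE]
  .assert(nrow(tones) > 0, "no epochable tones for this recording",
          "pupilbound_empty_error")
  n_col <- round((cfg$epoch_window_ms[2] - cfg$epoch_window_ms[1]) / step)
  n_bas <- round((cfg$baseline_window_ms[2] - cfg$baseline_window_ms[1]) / step)
  t0 <- rec$time[1]
  onset_idx <- round((tones$onset_ms - t0 + cfg$epoch_window_ms[1]) / step) + 1L
  bas_idx <- round((tones$onset_ms - t0 + cfg$baseline_window_ms[1]) / step) + 1L
  ok <- bas_idx >= 1L & (onset_idx + n_col - 1L) <= length(rec$pupil)
  if (any(!ok)) .warn(sprintf("epoch_pupil: dropping %d tone(s) without full window coverage",
                              sum(!ok)))
  tones <- tones[ok, , drop = FALSE]
  onset_idx <- onset_idx[ok]; bas_idx <- bas_idx[ok]
  .assert(nrow(tones) > 0, "no tone with full epoch coverage",
          "pupilbound_empty_error")
  x <- matrix(rec$pupil[outer(onset_idx, 0:(n_col - 1L), "+")], nrow = nrow(tones))
  baseline <- rowMeans(matrix(rec$pupil[outer(bas_idx, 0:(n_bas - 1L), "+")],
                              nrow = nrow(tones)))
  x <- x - baseline
  info <- data.frame(participant = tones$participant, block = tones$block,
                     list_index = tones$list_index, event_index = tones$event_index,
                     position_in_event = tones$position_in_event,
                     tone_condition = tones$tone_condition,
                     frequency_hz = tones$frequency_hz, ear = tones$ear,
                     item_id = tones$item_id, onset_ms = tones$onset_ms,
                     baseline_mean = baseline, row.names = NULL)
  structure(list(info = info, x = x,
                 times_ms = cfg$epoch_window_ms[1] + (0:(n_col - 1L)) * step),
            class = "epoch_matrix")
}

#' Epoch many recordings and stack the result
#'
#' @param recordings Named list of preprocessed recordings.
#' @param events Event table covering the recordings.
#' @param cfg An [analysis_config].
#' @return A single `epoch_matrix` with all trials stacked.
#' @export
epoch_all <- function(recordings, events, cfg = analysis_config()) {
  .assert(length(recordings) > 0, "no retained recordings to epoch",
          "pupilbound_empty_error")
  eps <- lapply(recordings, epoch_pupil, events = events, cfg = cfg)
  structure(list(info = do.call(rbind, c(lapply(eps, `[[`, "info"),
                                         list(make.row.names = FALSE))),
                 x = do.call(rbind, lapply(eps, `[[`, "x")),
                 times_ms = eps[[1]]$times_ms),
            class = "epoch_matrix")
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat(sprintf("<epoch_matrix> %d trials x %d timepoints [%g, %g) ms\n",
              nrow(x$x), ncol(x$x), min(x$times_ms),
              max(x$times_ms) + diff(x$times_ms[1:2])))
  invisible(x)
}
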