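#' Construct a pupil recording
#'
#' One participant-block continuous pupil trace: integer-ms timestamps at a
#' constant sampling step, pupil size in device arbitrary units, and a
#' validity mask.
#'
#' @param participant_id Participant token.
#' @param block_id Integer block (list) index, 1-based.
#' @param time Integer millisecond timestamps, strictly increasing with
#'   constant step `1000 / sampling_rate`.
#' @param pupil Numeric pupil sizes, same length as `time`.
#' @param valid Logical validity mask, same length as `time`.
#' @param sampling_rate Sampling rate in Hz; inferred from `time` if `NULL`.
#' @return An object of class `pupil_recording`.
#' @export
pupil_recording <- function(participant_id, block_id, time, pupil, valid = NULL,
                            sampling_rate = NULL) {
  time <- as.numeric(time)
  if (is.null(valid)) valid <- rep(TRUE, length(time))
  .assert(length(time) == length(pupil) && length(time) == length(valid),
          "time, pupil and valid must have equal length")
  .assert(length(time) >= 2, "a recording needs at least 2 samples")
  dt <- diff(time)
  .assert(all(dt > 0),
          sprintf("time must be strictly increasing within block %s/%s",
                  participant_id, block_id), "pupilbound_data_error")
  step <- median(dt)
  .assert(all(abs(dt - step) < 0.5),
          sprintf("non-constant sampling step within block %s/%s",
                  participant_id, block_id), "pupilbound_data_error")
  if (is.null(sampling_rate)) sampling_rate <- 1000 / step
  .assert(sampling_rate > 0, "sampling_rate must be positive")
  structure(list(participant_id = as.character(participant_id),
                 block_id = as.integer(block_id),
                 sampling_rate = sampling_rate,
                 time = time,
                 pupil = as.numeric(pupil),
                 valid = as.logical(valid)),
            class = "pupil_recording")
}

#' @export
print.pupil_recording <- function(x, ...) {
  cat(sprintf("<pupil_recording> participant %s, block %d: %d samples @ %g Hz, %.1f%% valid\n",
              x$participant_id, x$block_id, length(x$time), x$sampling_rate,
              100 * mean(x$valid)))
  invisible(x)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  .assert(length(missing) == 0,
          sprintf("%s is missing required column(s): %s", what,
                  paste(missing, collapse = ", ")),
          "pupilbound_schema_error")
}

#' Read pupil sample files
#'
#' Reads a tab-separated samples file with columns `participant`, `block`,
#' `time_ms`, `pupil`, `valid` (0/1) and returns one [pupil_recording] per
#' participant-block, grouped and time-sorted.
#'
#' @param path Path to a samples TSV.
#' @return A named list of `pupil_recording` objects; names are
#'   `"<participant>.<block>"`.
#' @export
read_samples <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  .require_columns(df, c("participant", "block", "time_ms", "pupil", "valid"),
                   "samples file")
  keep <- !is.na(df$time_ms) & !is.na(df$pupil) & !is.na(df$participant) & !is.na(df$block)
  if (any(!keep)) {
    .warn(sprintf("read_samples: dropping %d malformed row(s)", sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  key <- interaction(df$participant, df$block, drop = TRUE, lex.order = TRUE)
  recs <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    g <- df[idx, , drop = FALSE]
    # rows may arrive unordered; sorting is allowed, duplicated/irregular
    # timestamps are not
    g <- g[order(g$time_ms), , drop = FALSE]
    pupil_recording(g$participant[1], g$block[1], g$time_ms, g$pupil,
                    as.logical(g$valid))
  })
  recs
}

#' Write pupil recordings to a samples TSV
#'
#' @param recordings A list of [pupil_recording] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(recordings, path) {
  df <- do.call(rbind, lapply(recordings, function(r) {
    data.frame(participant = r$participant_id, block = r$block_id,
               time_ms = r$time, pupil = r$pupil, valid = as.integer(r$valid))
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a task event table
#'
#' Reads a tab-separated event table (tone and image onsets with full task
#' annotation) and validates its structure. Condition labels are recomputed
#' from `(event_index, position_in_event)` and must match the file's labels.
#'
#' @param path Path to an events TSV with columns `participant`, `block`,
#'   `onset_ms`, `event_type`, `list_index`, `event_index`,
#'   `position_in_event`, `tone_condition`, `frequency_hz`, `ear`, `item_id`.
#' @param check Check the within-block design invariants (4 events x 8
#'   positions, no within-block frequency reuse across events, alternating
#'   ears). Set `FALSE` for partial tables.
#' @return A validated `data.frame`.
#' @export
read_events <- function(path, check = TRUE) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    .warn("read_events: empty event table")
    return(df)
  }
  .require_columns(df, c("participant", "block", "onset_ms", "event_type",
                         "list_index", "event_index", "position_in_event",
                         "tone_condition", "frequency_hz", "ear", "item_id"),
                   "events file")
  validate_events(df, check = check)
}

#' @rdname read_events
#' @param events An event table `data.frame` to validate.
#' @export
validate_events <- function(events, check = TRUE) {
  tones <- events[events$event_type == "tone", , drop = FALSE]
  expected <- tone_condition_label(tones$event_index, tones$position_in_event)
  bad <- which(expected != tones$tone_condition)
  .assert(length(bad) == 0,
          sprintf("tone_condition labels inconsistent with (event_index, position) in row(s): %s",
                  paste(head(rownames(tones)[bad], 10), collapse = ", ")),
          "pupilbound_consistency_error")
  if (check) {
    for (key in split(seq_len(nrow(tones)),
                      interaction(tones$participant, tones$block, drop = TRUE))) {
      g <- tones[key, , drop = FALSE]
      .assert(nrow(g) == 32 &&
                all(table(g$event_index) == 8) &&
                all(sort(unique(g$position_in_event)) == 1:8),
              sprintf("block %s/%s: expected 4 events x 8 positions",
                      g$participant[1], g$block[1]),
              "pupilbound_consistency_error")
      fr <- unique(g[, c("event_index", "frequency_hz")])
      .assert(!anyDuplicated(fr$frequency_hz),
              sprintf("block %s/%s: a tone frequency recurs across events",
                      g$participant[1], g$block[1]),
              "pupilbound_consistency_error")
      ev_ear <- unique(g[, c("event_index", "ear")])
      ev_ear <- ev_ear[order(ev_ear$event_index), ]
      .assert(all(ev_ear$ear[-1] != ev_ear$ear[-nrow(ev_ear)]),
              sprintf("block %s/%s: ear does not alternate between events",
                      g$participant[1], g$block[1]),
              "pupilbound_consistency_error")
    }
  }
  events
}

#' Read behavioral response tables
#'
#' @param pairs_path TSV with pair-level temporal-memory responses: columns
#'   `participant`, `block`, `item_a`, `item_b`, `pair_condition`
#'   (`boundary_span`/`same_context`), `lag`, `order_correct` (0/1),
#'   `distance_rating` (1-4).
#' @param items_path TSV with item-level source-memory responses: columns
#'   `participant`, `block`, `item_id`, `item_type`
#'   (`boundary`/`same_context`/`first`/`last`), `source_correct` (0/1).
#' @return A list with elements `pairs` and `items` of class `memory_outcomes`.
#' @export
read_behavior <- function(pairs_path, items_path) {
  pairs <- read.delim(pairs_path, sep = "\t", stringsAsFactors = FALSE)
  items <- read.delim(items_path, sep = "\t", stringsAsFactors = FALSE)
  .require_columns(pairs, c("participant", "block", "item_a", "item_b",
                            "pair_condition", "lag", "order_correct",
                            "distance_rating"), "pairs file")
  .require_columns(items, c("participant", "block", "item_id", "item_type",
                            "source_correct"), "items file")
  memory_outcomes(pairs, items)
}

#' @rdname read_behavior
#' @param pairs,items Behavioral data frames (see `read_behavior`).
#' @export
memory_outcomes <- function(pairs, items) {
  .assert(all(pairs$distance_rating %in% 1:4),
          "distance ratings must be integers 1..4", "pupilbound_data_error")
  .assert(all(pairs$order_correct %in% 0:1), "order_correct must be 0/1",
          "pupilbound_data_error")
  .assert(all(pairs$pair_condition %in% c("boundary_span", "same_context")),
          "pair_condition must be boundary_span or same_context")
  .assert(all(items$item_type %in% c("boundary", "same_context", "first", "last")),
          "item_type must be one of boundary/same_context/first/last")
  .assert(all(items$source_correct %in% 0:1), "source_correct must be 0/1",
          "pupilbound_data_error")
  structure(list(pairs = pairs, items = items), class = "memory_outcomes")
}

#' @export
print.memory_outcomes <- function(x, ...) {
  cat(sprintf("<memory_outcomes> %d pair trials, %d source trials, %d participants\n",
              nrow(x$pairs), nrow(x$items),
              length(unique(c(x$pairs$participant, x$items$participant)))))
  invisible(x)
}

#' Write a behavioral table pair
#'
#' @param outcomes A `memory_outcomes` object.
#' @param pairs_path,items_path Output paths.
#' @export
write_behavior <- function(outcomes, pairs_path, items_path) {
  write.table(outcomes$pairs, pairs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(outcomes$items, items_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname read_events
#' @param events Event table to write.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
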