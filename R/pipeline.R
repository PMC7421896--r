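#' Run the full analysis pipeline
#'
#' End-to-end orchestration: read (or accept in-memory) samples, events and
#' behavior; preprocess and epoch the pupil data; compute evoked dilation
#' measures and condition contrasts; run the temporal PCA (3-s window, plus
#' the 1.5-s and condition-split variants); score the three memory tests and
#' their condition statistics; and compute the subtraction-score pupil-memory
#' correlations and trial-level models. Results are returned and, when
#' `out_dir` is given, written as TSV/JSON files. Deterministic given
#' `cfg$rng_seed`.
#'
#' @param cfg An [analysis_config].
#' @param samples Path to a samples TSV or a list of [pupil_recording]s.
#' @param events Path to an events TSV or an event table data frame.
#' @param behavior Character vector `c(pairs_path, items_path)` or a
#'   [memory_outcomes] object.
#' @param out_dir Optional output directory.
#' @param trial_models Fit the trial-level mixed models (slower)?
#' @return A list of class `pupilbound_results` with elements `exclusions`,
#'   `evoked`, `evoked_stats`, `pca`, `pca_short`, `pca_splits`,
#'   `behavior_scores`, `behavior_stats`, `subtractions`, `correlations`, and
#'   (optionally) `trial_models`, `stability`, `pitch`.
#' @export
run_pipeline <- function(cfg = analysis_config(), samples, events, behavior,
                         out_dir = NULL, trial_models = TRUE) {
  set.seed(cfg$rng_seed)
  recs <- if (is.character(samples)) read_samples(samples) else samples
  ev <- if (is.character(events)) read_events(events) else validate_events(events)
  mem <- if (is.character(behavior)) read_behavior(behavior[1], behavior[2])
  else behavior
  .assert(inherits(mem, "memory_outcomes"), "behavior must be a memory_outcomes")

  p_rec <- unique(vapply(recs, function(r) r$participant_id, character(1)))
  p_ev <- unique(ev$participant)
  p_mem <- unique(mem$pairs$participant)
  .assert(length(intersect(intersect(p_rec, p_ev), p_mem)) > 0,
          "no participant key shared by samples, events and behavior",
          "pupilbound_join_error")
  .assert(all(p_rec %in% p_ev),
          sprintf("participants in samples but not in events: %s",
                  paste(setdiff(p_rec, p_ev), collapse = ", ")),
          "pupilbound_join_error")

  message(sprintf("preprocess: %d recording(s)", length(recs)))
  pre <- preprocess_recordings(recs, cfg)
  .assert(length(pre$recordings) > 0,
          "all blocks excluded; pipeline aborted", "pupilbound_empty_error")
  epochs <- epoch_all(pre$recordings, ev, cfg)
  message(sprintf("epoch: %d trial(s) x %d timepoint(s)",
                  nrow(epochs$x), ncol(epochs$x)))

  evk <- evoked_dilation(epochs, cfg)
  evoked_stats <- list(
    boundary_vs_same = paired_contrast(evk),
    boundary_vs_baseline = against_baseline(
      evk$by_participant$evoked[evk$by_participant$tone_condition == "boundary"]),
    same_vs_baseline = against_baseline(
      evk$by_participant$evoked[evk$by_participant$tone_condition == "same_context"]))

  pca <- temporal_pca(epochs, cfg)
  message(sprintf("pca: k = %d over %d timepoints", pca$k, nrow(pca$loadings)))
  cfg_short <- cfg
  cfg_short$pca_window_ms <- 1500
  pca_short <- temporal_pca(epochs, cfg_short)
  pca_splits <- list(boundary = condition_split_pca(epochs, "boundary", cfg),
                     same_context = condition_split_pca(epochs, "same_context", cfg))

  behavior_scores <- list(order = score_order(mem), distance = score_distance(mem),
                          source = score_source(mem))
  behavior_stats <- condition_tests(mem)

  modes <- tapply(mem$pairs$lag, mem$pairs$participant, function(v) v[1])
  subs <- subtraction_scores(pca, mem, modes = modes)
  correlations <- pupil_memory_correlations(subs)

  res <- list(exclusions = pre$report, evoked = evk, evoked_stats = evoked_stats,
              pca = pca, pca_short = pca_short, pca_splits = pca_splits,
              behavior_scores = behavior_scores, behavior_stats = behavior_stats,
              subtractions = subs, correlations = correlations)
  if (trial_models) {
    tm <- trial_measures(evk)
    message("fitting trial-level mixed models")
    res$trial_models <- trial_level_models(tm, mem)
    res$pitch <- pitch_change_analysis(tm, mem)
    res$stability <- stability_analysis(pre$recordings, mem, ev)
  }
  class(res) <- "pupilbound_results"
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' Write pipeline results to a directory
#'
#' @param res A `pupilbound_results` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) write.table(df, file.path(out_dir, name), sep = "\t",
                                        quote = FALSE, row.names = FALSE)
  tsv(res$exclusions, "exclusions.tsv")
  tsv(res$evoked$by_participant, "evoked_means.tsv")
  loadings <- data.frame(time_ms = res$pca$times_ms, res$pca$loadings)
  names(loadings)[-1] <- paste0("c", seq_len(res$pca$k))
  tsv(loadings, "loadings.tsv")
  scores <- cbind(res$pca$keys[, c("participant", "condition")],
                  as.data.frame(res$pca$scores))
  tsv(scores, "scores.tsv")
  tsv(res$subtractions, "subtractions.tsv")
  tsv(res$correlations, "correlations.tsv")
  num <- function(x) if (is.numeric(x)) unname(x) else x
  jsonlite::write_json(list(
    evoked_stats = res$evoked_stats,
    pca_summary = res$pca$summary,
    pca_eigenvalues = res$pca$eigenvalues[seq_len(min(20, length(res$pca$eigenvalues)))],
    pca_short_summary = res$pca_short$summary,
    behavior_stats = res$behavior_stats),
    file.path(out_dir, "stats.json"), digits = NA, auto_unbox = TRUE,
    force = TRUE)
  invisible(out_dir)
}
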