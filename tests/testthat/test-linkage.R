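test_that("spearman_cor matches the rank formula and cor.test", {
  # hand example: d = (-2, 1, -1, 2, 0), Sum d^2 = 10, rho = 1 - 6*10/120 = 0.5
  r <- spearman_cor(1:5, c(3, 1, 4, 2, 5))
  expect_equal(r$rho, 1 - 6 * 10 / (5 * 24))
  expect_equal(r$rho, 0.5)

  # monotone function: rho = 1
  x <- c(0.2, 1.5, 3, 7, 9, 12)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)

  # invariance under strictly monotone transforms of either input
  set.seed(19)
  x <- rnorm(30); y <- rnorm(30)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, base$rho)
  expect_equal(spearman_cor(x, qlogis(plogis(y)))$p, base$p)

  # t approximation agrees with cor.test's asymptotic p
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(base$rho, unname(ct$estimate))
  expect_equal(base$p, ct$p.value, tolerance = 1e-6)

  # zero variance flagged
  expect_true(spearman_cor(rep(1, 6), 1:6)$degenerate)
  expect_error(spearman_cor(1:3, 1:3), class = "pupilbound_insufficient_data")
})

test_that("exact permutation p agrees with cor.test's exact distribution", {
  set.seed(29)
  for (i in 1:3) {
    x <- rnorm(7); y <- rnorm(7)
    mine <- spearman_cor(x, y, exact = TRUE)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  # ties are handled (midranks); p stays a valid probability
  r <- spearman_cor(c(1, 1, 2, 3, 4, 5), c(2, 1, 2, 5, 4, 4), exact = TRUE)
  expect_true(r$p >= 0 && r$p <= 1)
  expect_error(spearman_cor(rnorm(11), rnorm(11), exact = TRUE))
})

test_that("subtraction scores and the correlation matrix line up by key", {
  sim <- simulate_experiment(sim_config(n_participants = 12, rng_seed = 31),
                             traces = FALSE)
  subs <- subtraction_scores(NULL, sim$memory)
  expect_equal(nrow(subs), 12)
  # planted deltas stand in for component scores
  ord <- match(subs$participant, sim$ground_truth$participants)
  for (j in 1:4) subs[[paste0("delta_score_", j)]] <-
    sim$ground_truth$amplitude_delta[ord, j]
  cors <- pupil_memory_correlations(subs)
  expect_equal(nrow(cors), 12)  # 4 components x 3 measures, pooled only
  expect_equal(attr(cors, "multiple_comparison_adjustment"), "none")
  # duplicated participants are a join error
  expect_error(pupil_memory_correlations(rbind(subs, subs[1, ])),
               class = "pupilbound_join_error")
})

test_that("planted coupling lands in the right correlation cell", {
  cfg <- sim_config(n_participants = 65, rng_seed = 53)
  cfg$coupling[4, "distance"] <- 1.2
  sim <- simulate_experiment(cfg, traces = FALSE)
  subs <- subtraction_scores(NULL, sim$memory)
  ord <- match(subs$participant, sim$ground_truth$participants)
  for (j in 1:4) subs[[paste0("delta_score_", j)]] <-
    sim$ground_truth$amplitude_delta[ord, j]
  cors <- pupil_memory_correlations(subs)
  hot <- cors[cors$component == 4 & cors$memory_measure == "distance", ]
  expect_lt(hot$p, 0.01)
  expect_gt(hot$rho, 0.3)
  # the planted cell carries the largest |rho|
  expect_equal(which.max(abs(cors$rho)),
               which(cors$component == 4 & cors$memory_measure == "distance"))
})

test_that("trial-level models recover forced structure and flag degeneracy", {
  sim <- simulate_experiment(tiny_sim_config(n_participants = 8, n_blocks = 3,
                                             rng_seed = 61))
  pre <- preprocess_recordings(sim$recordings)
  ep <- epoch_all(pre$recordings, sim$design$events)
  tm <- trial_measures(evoked_dilation(ep))
  expect_true(all(tm$pitch_change_hz[tm$tone_condition == "boundary"] %in%
                    seq(100, 500, by = 100)))
  expect_true(all(is.na(tm$pitch_change_hz[tm$tone_condition != "boundary"])))

  # deterministic outcome = 1[phasic > median]: strongly positive coefficient
  mem <- sim$memory
  tkey <- paste(tm$participant, tm$block, tm$item_id)
  idx <- match(paste(mem$pairs$participant, mem$pairs$block, mem$pairs$item_b), tkey)
  mem$pairs$order_correct <- as.integer(tm$phasic[idx] > median(tm$phasic[idx]))
  res <- suppressWarnings(suppressMessages(trial_level_models(tm, mem)))
  co <- res$order$coefficients
  if (is.null(co)) {
    # complete separation can defeat the fit entirely; it must be flagged
    expect_false(res$order$converged)
  } else {
    expect_gt(co$estimate[co$term == "phasic"], 1)
  }

  # intercept-only (all-correct) outcome: degenerate warning
  mem$pairs$order_correct <- 1L
  expect_warning(suppressMessages(trial_level_models(tm, mem)), "degenerate")
})

test_that("null pupil-memory coupling yields null trial-level coefficients", {
  sim <- simulate_experiment(tiny_sim_config(n_participants = 10, n_blocks = 4,
                                             rng_seed = 67))
  pre <- preprocess_recordings(sim$recordings)
  ep <- epoch_all(pre$recordings, sim$design$events)
  tm <- trial_measures(evoked_dilation(ep))
  res <- suppressWarnings(trial_level_models(tm, sim$memory))
  for (nm in c("order", "distance", "source")) {
    co <- res[[nm]]$coefficients
    expect_true(all(abs(co$z[co$term %in% c("phasic", "tonic")]) < 4))
  }
})

test_that("pitch-change coupling is recovered and nulls stay null", {
  cfg <- tiny_sim_config(n_participants = 10, n_blocks = 5,
                         pitch_amp_slope = 2, rng_seed = 71)
  sim <- simulate_experiment(cfg)
  pre <- preprocess_recordings(sim$recordings)
  ep <- epoch_all(pre$recordings, sim$design$events)
  tm <- trial_measures(evoked_dilation(ep))
  res <- suppressWarnings(pitch_change_analysis(tm, sim$memory))
  co <- res$evoked$coefficients
  expect_gt(co$estimate[co$term == "pitch_std"], 0)
  expect_lt(co$p[co$term == "pitch_std"], 0.01)

  # no planted slope: coefficient near zero
  cfg0 <- tiny_sim_config(n_participants = 10, n_blocks = 5, rng_seed = 73)
  sim0 <- simulate_experiment(cfg0)
  pre0 <- preprocess_recordings(sim0$recordings)
  tm0 <- trial_measures(evoked_dilation(epoch_all(pre0$recordings, sim0$design$events)))
  res0 <- suppressWarnings(pitch_change_analysis(tm0, sim0$memory))
  co0 <- res0$evoked$coefficients
  expect_lt(abs(co0$z[co0$term == "pitch_std"]), 4)
})

test_that("between-pair variability behaves and couples to memory", {
  cfg <- tiny_sim_config(n_participants = 10, n_blocks = 5,
                         stability_order_slope = -1.2, rng_seed = 79)
  sim <- simulate_experiment(cfg)
  pre <- preprocess_recordings(sim$recordings)
  res <- suppressWarnings(stability_analysis(pre$recordings, sim$memory,
                                             sim$design$events))
  # boundary-spanning pairs contain a boundary-evoked bump: higher sd
  expect_gt(res$sd_contrast$mean_diff, 0)
  expect_lt(res$sd_contrast$p, 0.05)
  # planted low-sd -> better order memory: negative logistic coefficient
  co <- res$order$coefficients
  expect_lt(co$estimate[co$term == "sd_std"], 0)
  expect_lt(co$p[co$term == "sd_std"], 0.05)

  # a constant trace has sd = 0 for all pairs
  flat <- lapply(pre$recordings[1:2], function(r) { r$pupil[] <- 7; r })
  m <- between_pair_sd(flat, sim$memory$pairs[sim$memory$pairs$participant == "P01" &
                                                sim$memory$pairs$block == 1, ],
                       sim$design$events)
  expect_true(all(m$pair_sd == 0))
})
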