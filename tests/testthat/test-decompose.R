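test_that("covariance_pca matches brute-force oracles", {
  # rank-1: rows +-v give one nonzero eigenvalue with loading proportional to v
  v <- sin(seq(0, pi, length.out = 40))
  x <- rbind(v, -v, v, -v)
  p <- covariance_pca(x)
  expect_length(p$eigenvalues, 1)
  expect_gt(abs(cor(p$loadings[, 1], v)), 1 - 1e-12)

  # eigenvalue sum equals the covariance trace
  set.seed(5)
  x <- matrix(rnorm(30 * 50), 30, 50)
  p <- covariance_pca(x)
  expect_equal(sum(p$eigenvalues), sum(diag(cov(x))), tolerance = 1e-8)

  # 4 orthonormal planted waveforms: eigenvalues equal the brute-force
  # eigenvalues of the amplitude covariance (computed independently)
  q <- qr.Q(qr(matrix(rnorm(100 * 4), 100, 4)))
  amps <- matrix(rnorm(200 * 4), 200, 4) %*% diag(c(10, 4, 1, 0.5))
  x <- amps %*% t(q)
  p <- covariance_pca(x)
  oracle <- sort(eigen(cov(amps), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(p$eigenvalues[1:4], oracle, tolerance = 1e-8)
  # and the n >= p eigen path agrees with the n < p inner-product path
  p2 <- covariance_pca(x[1:60, ])
  expect_equal(sum(p2$eigenvalues), sum(diag(cov(x[1:60, ]))), tolerance = 1e-8)
})

test_that("retention rules follow their definitions", {
  expect_equal(retain_components(c(5, 3, 1, 0.5, 0.5), "mean_eigenvalue"), 2L)
  expect_equal(retain_components(rep(2, 6), "mean_eigenvalue"), 6L)
  expect_equal(retain_components(c(5, 3, 1, 0.5), "unit_eigenvalue"), 2L)
  expect_warning(k <- retain_components(c(0.5, 0.3), "unit_eigenvalue"),
                 "forcing")
  expect_equal(k, 1L)
})

test_that("varimax preserves communalities and reconstructs its input", {
  set.seed(3)
  for (k in 2:4) {
    x <- matrix(rnorm(40 * k), 40, k)
    r <- varimax_rotate(x)
    expect_true(r$converged)
    # orthogonality of the rotation
    expect_equal(crossprod(r$rotation), diag(k), tolerance = 1e-8)
    # communalities preserved
    expect_equal(rowSums(r$loadings^2), rowSums(x^2), tolerance = 1e-8)
    # rotated %*% t(rotation) recovers the unrotated loadings
    expect_equal(r$loadings %*% t(r$rotation), x, tolerance = 1e-8)
    # canonical form: extrema positive, columns variance-ordered
    expect_true(all(apply(r$loadings, 2, function(v) v[which.max(abs(v))]) > 0))
    ss <- colSums(r$loadings^2)
    expect_true(all(diff(ss) <= 1e-12))
  }
  # k = 1 is the identity rotation
  x <- matrix(abs(rnorm(20)), 20, 1)
  r <- varimax_rotate(x)
  expect_equal(r$loadings, x)
  expect_equal(r$rotation, matrix(1, 1, 1))
})

test_that("varimax agrees with the reference implementation", {
  set.seed(17)
  for (i in 1:5) {
    x <- matrix(rnorm(30 * 3), 30, 3)
    mine <- varimax_rotate(x, kaiser_normalize = TRUE, tol = 1e-10)
    ref <- stats::varimax(x, normalize = TRUE, eps = 1e-10)
    # solutions match up to column order/sign: compare the criterion and the
    # sorted squared-loading profiles
    sc <- sqrt(rowSums(x^2))
    expect_equal(varimax_criterion(mine$loadings / sc),
                 varimax_criterion(unclass(ref$loadings) / sc),
                 tolerance = 1e-8)
    # near the optimum the criterion is flat, so per-column sums of squares
    # agree less tightly than the criterion itself
    expect_equal(sort(colSums(mine$loadings^2)),
                 sort(colSums(unclass(ref$loadings)^2)), tolerance = 1e-3)
  }
})

test_that("component scores are centered regression scores", {
  set.seed(23)
  l <- cbind(pupil_kernel(800, 200), pupil_kernel(2000, 400))
  amps <- matrix(rnorm(12 * 2, sd = c(4, 2)), 12, 2, byrow = TRUE)
  x <- amps %*% t(l)
  sc <- component_scores(x, l)
  expect_equal(colMeans(sc), c(c1 = 0, c2 = 0), tolerance = 1e-10)
  # row exactly 2 x loading_1: score (2, 0) up to centering
  expect_equal(unname(sc - sweep(amps, 2, colMeans(amps))),
               matrix(0, 12, 2), tolerance = 1e-8)
})

test_that("waveform matrix averages trials per participant-condition", {
  # two trials [0-vector, 2-vector] average to a constant-1 row
  x <- rbind(rep(0, 750), rep(2, 750), rep(1, 750))
  info_cond <- c("boundary", "boundary", "same_context")
  ep <- structure(list(
    info = data.frame(participant = "P01", block = 1L, list_index = 1L,
                      event_index = c(2L, 3L, 1L), position_in_event = c(1L, 1L, 2L),
                      tone_condition = info_cond, frequency_hz = 500,
                      ear = "left", item_id = c("a", "b", "c"), onset_ms = 0,
                      baseline_mean = 0),
    x = x, times_ms = seq(0, 2996, by = 4)), class = "epoch_matrix")
  wm <- build_waveform_matrix(ep, analysis_config(min_trials = 1))
  expect_equal(nrow(wm$x), 2)
  expect_equal(unname(wm$x[wm$keys$condition == "boundary", 1]), 1)
  # a participant missing one condition is dropped with a warning
  ep$info$tone_condition <- c("boundary", "boundary", "boundary")
  expect_warning(wm2 <- build_waveform_matrix(ep, analysis_config(min_trials = 1)),
                 "missing a condition")
  expect_equal(nrow(wm2$x), 0)
})

test_that("noise-free synthetic scores recover planted amplitudes", {
  cfg <- tiny_sim_config(n_participants = 8, n_blocks = 2, tonic_sd = 0,
                         noise_sd = 0, blink_rate_per_min = 0, rng_seed = 6)
  sim <- simulate_experiment(cfg)
  # epoch the raw traces: with measurement noise off, the MAD-based velocity
  # criterion would flag genuine evoked slopes
  ep <- epoch_all(sim$recordings, sim$design$events)
  wm <- build_waveform_matrix(ep)
  # the noise-free spectrum is exactly rank 4
  pca <- covariance_pca(wm)
  if (length(pca$eigenvalues) > 4)
    expect_lt(pca$eigenvalues[5], 1e-6 * pca$eigenvalues[1])
  # scoring against the true waveforms returns the planted amplitudes
  # (small-sample Varimax rotations need not align with the planted basis;
  # full-scale rotation recovery is covered by the acceptance suite)
  sc <- component_scores(wm, sim$ground_truth$waveforms)
  amp <- sim$ground_truth$amplitudes
  pid <- match(wm$keys$participant, sim$ground_truth$participants)
  cond <- ifelse(wm$keys$condition == "boundary", "boundary", "same_context")
  for (j in 1:4) {
    planted <- vapply(seq_len(nrow(wm$x)),
                      function(i) amp[pid[i], j, cond[i]], numeric(1))
    expect_gt(abs(cor(sc[, j], planted)), 0.999)
  }
})

test_that("condition-split and short-window variants keep the contracts", {
  cfg <- tiny_sim_config(n_participants = 6, n_blocks = 2, rng_seed = 41)
  sim <- simulate_experiment(cfg)
  pre <- preprocess_recordings(sim$recordings)
  ep <- epoch_all(pre$recordings, sim$design$events)
  acfg <- analysis_config(pca_window_ms = 1500)
  sol <- temporal_pca(ep, acfg)
  expect_equal(nrow(sol$loadings), 375)  # 1.5-s window at 250 Hz
  split_b <- condition_split_pca(ep, "boundary", acfg)
  expect_equal(nrow(split_b$scores), 6)  # one row per participant
  expect_equal(nrow(split_b$loadings), 375)
  # identical condition data give identical solutions
  split_b2 <- condition_split_pca(ep, "boundary", acfg)
  expect_identical(split_b$loadings, split_b2$loadings)
  # summaries: latency equals the loading's extremum location
  sol3 <- temporal_pca(ep, analysis_config())
  expect_equal(sol3$summary$peak_latency_ms,
               sol3$times_ms[apply(abs(sol3$loadings), 2, which.max)])
  # a one-component rotation is the identity up to the sign convention
  l1 <- covariance_pca(build_waveform_matrix(ep))$loadings[, 1, drop = FALSE]
  one <- varimax_rotate(l1)
  s <- sign(l1[which.max(abs(l1)), 1])
  expect_equal(one$loadings, s * l1)
})
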