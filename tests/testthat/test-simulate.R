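test_that("pupil_kernel honors its contract", {
  t_ms <- seq(0, 2996, by = 4)
  for (par in list(c(800, 300), c(2424, 450), c(308, 300))) {
    k <- pupil_kernel(par[1], par[2], t_ms)
    expect_gte(min(k), 0)
    expect_equal(max(k), 1)
    expect_lte(abs(t_ms[which.max(k)] - par[1]), 4)  # argmax at latency +- 1 sample
  }
  # numeric-integration oracle: wider kernel has larger area
  area <- function(w) integrate(function(x) {
    s <- (800 / w)^2
    exp(s * (log(x / 800) + 1 - x / 800))
  }, 1e-6, 3000)$value
  k_narrow <- pupil_kernel(800, 150, t_ms)
  k_wide <- pupil_kernel(800, 300, t_ms)
  expect_gt(sum(k_wide), sum(k_narrow))
  expect_gt(area(300), area(150))
  # trapezoid area of the sampled kernel agrees with quadrature
  expect_equal(sum(k_wide) * 4, area(300), tolerance = 1e-2)

  expect_error(pupil_kernel(3500, 300, t_ms), class = "pupilbound_config_error")
})

test_that("generate_design lays out the paradigm correctly", {
  set.seed(11)
  d <- generate_design(sim_config(n_participants = 2, n_blocks = 4))
  expect_silent(validate_events(d$events))
  for (b in 1:4) {
    p <- d$pairs[d$pairs$participant == "P01" & d$pairs$block == b, ]
    bnd <- p[p$pair_condition == "boundary_span", ]
    # three boundary-spanning pairs straddle positions 8 -> 8 + lag + 1
    expect_setequal(bnd$pos_a, c(8, 16, 24))
    expect_equal(bnd$pos_b, bnd$pos_a + 3)
    expect_equal(nrow(p[p$pair_condition == "same_context", ]), 4)
    src <- d$source_items[d$source_items$participant == "P01" &
                            d$source_items$block == b, ]
    # 14 paired + 18 source items partition the 32-item list
    expect_equal(nrow(src), 18)
    expect_equal(sort(table(src$item_type))[["first"]], 1)
    expect_equal(as.vector(table(src$item_type)[c("boundary", "same_context")]),
                 c(3, 13))
  }
  # tones sit 1.5 s before their images, and images 5.5 s apart
  t1 <- d$events[d$events$participant == "P01" & d$events$block == 1, ]
  expect_equal(unique(t1$onset_ms[t1$event_type == "image"] -
                        t1$onset_ms[t1$event_type == "tone"]), 1500)
  # exp-3 mode: four intervening items
  d4 <- generate_design(sim_config(n_participants = 1, n_blocks = 1, lag = 4))
  p4 <- d4$pairs
  expect_true(all(p4$pos_b - p4$pos_a == 5))
  expect_error(sim_config(lag = 8), class = "pupilbound_config_error")
})

test_that("generate_pupil superposes components exactly when noise is off", {
  cfg <- tiny_sim_config(n_participants = 1, n_blocks = 1,
                         tonic_sd = 0, noise_sd = 0, blink_rate_per_min = 0,
                         baseline_sd = 0, rng_seed = 3)
  sim <- simulate_experiment(cfg)
  rec <- sim$recordings[[1]]
  expect_true(all(rec$valid))  # blink_rate = 0
  # before the first tone the trace is exactly the participant mean
  pre <- rec$pupil[rec$time < 1500]
  expect_equal(pre, rep(cfg$baseline_mean, length(pre)))
  # first tone epoch equals the same-context amplitude mix of the kernels
  ev <- sim$design$events
  on1 <- min(ev$onset_ms[ev$event_type == "tone"])
  idx <- rec$time >= on1 & rec$time < on1 + 1500  # before the image response
  amps <- sim$ground_truth$amplitudes[1, , "same_context"]
  expected <- cfg$baseline_mean +
    as.numeric(sim$ground_truth$waveforms[seq_len(sum(idx)), ] %*% amps)
  expect_equal(rec$pupil[idx], expected, tolerance = 1e-6)
})

test_that("planted waveforms are mutually distinguishable", {
  cfg <- sim_config()
  t_ms <- seq(0, 2996, by = 4)
  k <- sapply(seq_along(cfg$component_latencies_ms), function(j)
    pupil_kernel(cfg$component_latencies_ms[j], cfg$component_widths_ms[j], t_ms))
  cc <- cor(k)
  diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.8)
})

test_that("memory marginals converge to the closed-form oracles", {
  # large single-participant-free check: intercept-only, many participants
  cfg <- sim_config(n_participants = 400, n_blocks = 4,
                    order_effect_sd = 0, distance_effect_sd = 0,
                    source_effect_sd = 0, rng_seed = 21)
  sim <- simulate_experiment(cfg, traces = FALSE)
  p <- sim$memory$pairs
  sc <- p$pair_condition == "same_context"
  acc_same <- mean(p$order_correct[sc])
  acc_bnd <- mean(p$order_correct[!sc])
  expect_equal(acc_same,
               expected_accuracy(cfg$order_logit_intercept, cfg$order_intercept_sd),
               tolerance = 0.02)
  expect_equal(acc_bnd,
               expected_accuracy(cfg$order_logit_intercept + cfg$order_logit_boundary,
                                 cfg$order_intercept_sd),
               tolerance = 0.02)
  m_same <- mean(p$distance_rating[sc])
  m_bnd <- mean(p$distance_rating[!sc])
  expect_equal(m_same, expected_rating(0, cfg$distance_intercept_sd),
               tolerance = 0.02)
  expect_equal(m_bnd,
               expected_rating(cfg$distance_shift_boundary, cfg$distance_intercept_sd),
               tolerance = 0.02)
  expect_gt(m_bnd, m_same)  # planted time-expansion direction
  it <- sim$memory$items
  expect_equal(mean(it$source_correct[it$item_type == "boundary"]),
               expected_accuracy(cfg$source_logit_intercept + cfg$source_logit_boundary,
                                 cfg$source_intercept_sd),
               tolerance = 0.02)
})

test_that("chance behavior emerges when all effects are zero", {
  cfg <- sim_config(order_logit_intercept = 0, order_logit_boundary = 0,
                    order_intercept_sd = 0, order_effect_sd = 0, rng_seed = 5)
  sim <- simulate_experiment(cfg, traces = FALSE)
  acc <- mean(sim$memory$pairs$order_correct)
  n <- nrow(sim$memory$pairs)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n))  # binomial MC error
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_experiment(tiny_sim_config(rng_seed = 99))
  b <- simulate_experiment(tiny_sim_config(rng_seed = 99))
  expect_identical(a$recordings[[3]]$pupil, b$recordings[[3]]$pupil)
  expect_identical(a$memory$pairs, b$memory$pairs)
  expect_identical(a$ground_truth$amplitude_delta, b$ground_truth$amplitude_delta)
})

test_that("calibrate_coupling hits the requested population Spearman", {
  cfg <- sim_config()
  gamma <- calibrate_coupling(cfg, component = 4, measure = "distance",
                              rho_target = 0.5, n_mc = 4000)
  expect_gt(gamma, 0)
  expect_lt(gamma, 3)
  # verify on an independent large population
  cfg2 <- cfg
  cfg2$coupling[4, "distance"] <- gamma
  cfg2$n_participants <- 3000
  cfg2$rng_seed <- 12345L
  sim <- simulate_experiment(cfg2, traces = FALSE)
  subs <- subtraction_scores(NULL, sim$memory)
  ord <- match(subs$participant, sim$ground_truth$participants)
  rho <- spearman_cor(sim$ground_truth$amplitude_delta[ord, 4],
                      subs$delta_distance)$rho
  expect_equal(rho, 0.5, tolerance = 0.06)
})

test_that("write_simulation emits the full TSV/JSON bundle", {
  dir <- withr::local_tempdir()
  cfg <- tiny_sim_config(n_participants = 2, n_blocks = 1, rng_seed = 2)
  sim <- simulate_experiment(cfg)
  write_simulation(sim, dir, cfg)
  for (f in c("samples.tsv", "events.tsv", "pairs.tsv", "items.tsv",
              "ground_truth.json"))
    expect_true(file.size(file.path(dir, f)) > 0)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$rng_seed, 2)
  expect_equal(dim(gt$waveforms), c(750, 4))
})
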