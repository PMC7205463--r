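test_that("ring connectivity is normalized and shaped correctly", {
  net <- build_network(attractor_params(scaled = TRUE))
  # defaults: w(0) = J+ and monotone decay to the J- floor
  expect_equal(net$w_profile[1], 1.6)
  half <- net$w_profile[1:129]
  expect_true(all(diff(half) <= 1e-12))
  expect_true(all(net$w_profile >= net$j_neg - 1e-12))
  # normalization: mean connection weight is 1 for every row
  expect_equal(rowMeans(net$W_ee), rep(1, 256), tolerance = 1e-12)
  # J+ = 1 gives uniform weights
  net1 <- build_network(attractor_params(scaled = TRUE, j_pos = 1))
  expect_equal(net1$w_profile, rep(1, 256), tolerance = 1e-12)
  # infeasible (J+, sigma): J- would be negative
  expect_error(build_network(attractor_params(scaled = TRUE, j_pos = 6,
                                              sigma_weight_deg = 60)),
               "J-")
  # normalization holds across the feasible sweep range
  for (jp in c(1.0, 1.6, 2.2))
    expect_equal(mean(build_network(attractor_params(scaled = TRUE,
                                                     j_pos = jp))$w_profile),
                 1, tolerance = 1e-12)
})

test_that("population-vector persistence readout behaves at the extremes", {
  expect_error(detect_persistence(1, 1, window_ms = c(900, 900),
                                  stim_center_deg = 0), "empty")
  r0 <- detect_persistence(numeric(0), numeric(0), c(800, 1000), 90)
  expect_false(r0$bump_sustained)
  expect_equal(r0$readout_amplitude, 0)
  # all spikes within +-10 degrees of the stimulus: amplitude near 1
  set.seed(2)
  t <- runif(200, 800, 1000); a <- runif(200, 80, 100)
  r1 <- detect_persistence(t, a, c(800, 1000), 90)
  expect_true(r1$bump_sustained)
  expect_gt(r1$readout_amplitude, 0.9)
  expect_lt(popglm:::ang_dist(r1$readout_angle, 90), 10)
  # uniform spiking: amplitude near 0, not sustained
  r2 <- detect_persistence(t, runif(200, 0, 360), c(800, 1000), 90)
  expect_false(r2$bump_sustained)
  expect_lt(r2$readout_amplitude, 0.2)
})

test_that("a small attractor session exports a valid deterministic Session", {
  expect_error(attractor_params(trial_len_s = 0.6), "trial_len_s")
  p <- attractor_params(n_excitatory = 128, n_inhibitory = 32,
                        weight_scaling = 16, scaled = FALSE)
  # scaled = FALSE keeps the requested sizes; bump the stimulus as the
  # scaled transform would
  p$stim_strength_namp <- 0.18
  s <- simulate_attractor_session(p, n_trials = 3, n_sampled = 5, seed = 12)
  expect_s3_class(s, "spike_session")
  expect_equal(nrow(s$units), 5)
  expect_true(all(s$units$area == "SYNTH"))
  expect_equal(nrow(s$trials), 3)
  expect_length(s$metadata$sustained, 3)
  expect_identical(
    simulate_attractor_session(p, n_trials = 3, n_sampled = 5,
                               seed = 12)$spikes,
    s$spikes)
  # events follow the stimulus protocol
  expect_true(all(s$trials$target_on >= 0.2 & s$trials$target_on <= 0.5))
  expect_equal(s$trials$target_off - s$trials$target_on, rep(0.2, 3))
})

test_that("without a stimulus there is no location-selective response", {
  p <- attractor_params(scaled = TRUE, j_pos = 1.3, stim_strength_namp = 0)
  s <- simulate_attractor_session(p, n_trials = 3, n_sampled = 5, seed = 8)
  expect_true(all(!s$metadata$sustained))
  expect_true(all(s$metadata$readout_amplitude < 0.2))
})

test_that("the sampled ensemble is fixed and localized on the ring", {
  p <- attractor_params(scaled = TRUE, j_pos = 1.6)
  s <- simulate_attractor_session(p, n_trials = 2, n_sampled = 8, seed = 3)
  ang <- s$metadata$sampled_angle
  expect_length(unique(s$metadata$sampled_index), 8)
  ctr <- (Arg(sum(exp(1i * ang * pi / 180))) * 180 / pi) %% 360
  expect_true(all(popglm:::ang_dist(ang, ctr) <= 45))
  expect_error(simulate_attractor_session(p, n_trials = 1, n_sampled = 100,
                                          sample_arc_deg = 30, seed = 1),
               "arc")
})
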