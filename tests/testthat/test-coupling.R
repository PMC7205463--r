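test_that("coupling weight and gain follow their definitions", {
  expect_identical(coupling_weight(rep(0, 250)), 0)
  expect_equal(coupling_weight(c(0.2, -0.1, 0.05)), 0.15)
  expect_lt(coupling_weight(-0.3 * exp(-(1:250) / 50)), 0)
  expect_identical(coupling_gain(rep(0, 250)), 1)
  expect_equal(coupling_gain(c(0.1, log(1.34), -2)), 1.34)
  # gain invariant to values below the max; gain = 1 iff max = 0
  k <- c(0.5, 0.1, 0.2)
  expect_equal(coupling_gain(k), coupling_gain(c(0.5, -3, -8)))
  expect_gt(coupling_gain(c(0.01, -1)), 1)
  expect_lt(coupling_gain(c(-0.01, -1)), 1)
})

test_that("interaction classes are directed", {
  expect_identical(classify_interaction("LIP", "LIP"), "LIP-LIP")
  expect_identical(classify_interaction("LIP", "FEF"), "LIP-FEF")
  expect_identical(classify_interaction("FEF", "LIP"), "FEF-LIP")
  expect_identical(classify_interaction("SYNTH", "LIP"), "SYNTH-SYNTH")
  expect_error(classify_interaction("V4", "LIP"), "unknown area")
  # a full session yields n(n-1) directed pairs
  fxd <- fixture_session()
  ct <- coupling_table(fit_population(design_cache(fxd$binned,
                                                   fxd$sim$truth$spec)))
  expect_equal(nrow(ct), 4 * 3)
  expect_false(any(ct$from == ct$to))
})

test_that("identity trial ordering reproduces the original fit exactly", {
  fxd <- fixture_session()
  cache <- design_cache(fxd$binned, fxd$sim$truth$spec)
  n_tr <- length(cache$trials_used)
  ident <- matrix(rep(seq_len(n_tr), 4), n_tr, 4)
  d0 <- build_design(cache, "u02")
  d1 <- build_design(cache, "u02", partner_perm = ident)
  expect_identical(d0$X, d1$X)
})

test_that("permutation null flags a strongly coupled pair", {
  spec <- model_spec(include_terms = c("history", "coupling"),
                     condition_split = FALSE)
  pf_true <- two_unit_popfit(c_amp = 0.9, c_tau = 40, spec = spec)
  s <- simulate_population(pf_true, plain_trials(80), seed = 33)
  binned <- bin_spikes(s)
  cache <- design_cache(binned, spec)
  pf <- fit_population(cache)
  ct <- coupling_table(pf)
  nd <- permutation_null(cache, n_perm = 10, seed = 4, init = pf$fits)
  expect_equal(nrow(nd$weights), 2 * 10)
  w_ab <- ct$weight[ct$from == "A" & ct$to == "B"]
  nw <- nd$weights$weight[nd$weights$from == "A" & nd$weights$to == "B"]
  expect_gt(w_ab, mean(nw) + 2 * sd(nw))
  # the uncoupled direction is not flagged
  w_ba <- ct$weight[ct$from == "B" & ct$to == "A"]
  nw_ba <- nd$weights$weight[nd$weights$from == "B" & nd$weights$to == "A"]
  expect_lt(w_ba, mean(nw_ba) + 2 * sd(nw_ba))
})

test_that("significant_fraction matches the Gaussian tail oracle", {
  set.seed(31)
  real <- data.frame(interaction = "LIP-LIP", weight = rnorm(20000, 1, 2))
  null <- data.frame(interaction = "LIP-LIP", weight = rnorm(50000, 1, 2))
  sf <- significant_fraction(real, null)
  expect_lt(abs(sf$fraction - pnorm(-2)), 0.01)
  # all real weights huge -> 1.0
  real$weight <- real$weight + 100
  expect_equal(significant_fraction(real, null)$fraction, 1)
  null$weight <- 0
  expect_error(significant_fraction(real, null), "degenerate null")
})

test_that("kernel PCA recovers low-rank structure", {
  lags <- 1:250
  slow <- exp(-lags / 150); fast <- exp(-lags / 10)
  set.seed(6)
  # rank-1 case: one shape with varying amplitude plus tiny noise
  K1 <- outer(runif(20, 0.2, 1), slow) + matrix(rnorm(20 * 250, 0, 1e-4), 20)
  p1 <- pca_kernels(K1)
  expect_gt(p1$var_fraction[1], 0.99)
  # with all kernels strictly identical the group is degenerate
  expect_error(pca_kernels(t(replicate(5, slow))), "degenerate")
  # two orthogonalized shapes: two components recover the span
  fast_o <- fast - slow * sum(fast * slow) / sum(slow^2)
  K2 <- t(sapply(1:30, function(i)
    rnorm(1, 0, 1) * slow + rnorm(1, 0, 1) * fast_o))
  p2 <- pca_kernels(K2)
  expect_gt(sum(p2$var_fraction[1:2]), 0.999)
  proj <- lm.fit(cbind(slow, fast_o), p2$components[, 1:2])
  expect_lt(max(abs(proj$residuals)), 1e-6)
  # variance fractions valid; full reconstruction is exact
  expect_true(all(diff(p2$var_fraction) <= 1e-12))
  expect_true(all(p2$var_fraction >= 0 & p2$var_fraction <= 1))
  expect_lte(sum(p2$var_fraction), 1 + 1e-12)
  recon <- p2$scores %*% t(p2$components) +
    matrix(p2$center, 30, 250, byrow = TRUE)
  expect_equal(recon, K2, tolerance = 1e-9, ignore_attr = TRUE)
  # sign convention: positive integral
  expect_true(all(colSums(p2$components) >= 0))
  expect_error(pca_kernels(K2[1:2, ]), "at least 3")
})

test_that("double-exponential time constants are recovered or excluded", {
  lags <- 1:250
  # single exponential, tau = 100 ms
  tc <- fit_time_constant(0.5 * exp(-lags / 100), lags)
  expect_false(tc$excluded)
  expect_lt(abs(tc$tau - 100) / 100, 0.05)
  # mixture: tau of the larger-amplitude component is reported
  tc2 <- fit_time_constant(0.3 * exp(-lags / 30) + 0.2 * exp(-lags / 200),
                           lags)
  expect_false(tc2$excluded)
  expect_lt(abs(tc2$tau - 30) / 30, 0.15)
  expect_lt(min(abs(sort(tc2$tau_pair) - c(30, 200)) / c(30, 200)), 0.15)
  expect_true(all(abs(sort(tc2$tau_pair) - c(30, 200)) / c(30, 200) < 0.15))
  # refractory-dominated kernels are excluded by rule
  refr <- -2 * exp(-lags / 2) + 0.05 * exp(-lags / 60)
  tc3 <- fit_time_constant(refr, lags)
  expect_true(tc3$excluded)
  expect_match(tc3$reason, "refractory")
  # noise-dominated kernels are excluded by the R^2 threshold
  set.seed(12)
  tc4 <- fit_time_constant(rnorm(250, 0, 0.2), lags)
  expect_true(tc4$excluded)
  expect_error(fit_time_constant(exp(-(1:50) / 10), 1:50), "too short")
})

test_that("predictive indices follow their identities", {
  expect_equal(predictive_index(0.4, 0.4), 0)
  expect_equal(predictive_index(0.4, 0.3), 0.25)
  expect_equal(predictive_index(0.4, 0), 1)       # reduced explains nothing
  expect_equal(predictive_index(0.4, -0.2), 1)    # clipped to [0, 1]
  expect_equal(predictive_index(0.3, 0.5), 0)     # clipped below
  expect_true(is.na(predictive_index(0, 0.1)))    # degenerate full model
  expect_error(predictive_index(NaN, 0.1), "finite")
})

test_that("circular tuning curves recover synthetic preferences", {
  set.seed(22)
  ang <- runif(150, 0, 360)
  rate <- 5 + 20 * exp(-popglm:::ang_dist(ang, 120)^2 / (2 * 40^2)) +
    rnorm(150, 0, 1.5)
  tf <- fit_tuning_curve(ang, rate)
  expect_lt(popglm:::ang_dist(tf$preferred_angle, 120), 10)
  expect_true(tf$reliable)
  expect_lt(abs(tf$width - 40), 15)
  # flat responses -> small amplitude, flagged unreliable
  tf0 <- fit_tuning_curve(ang, rnorm(150, 10, 0.5))
  expect_false(tf0$reliable)
  expect_error(fit_tuning_curve(c(0, 90, 180), c(1, 2, 1)), "4 target angles")
})

test_that("coupling tracks tuning similarity in a constructed population", {
  # pairs with closer preferred angles get larger generator coupling
  prefs <- c(a = 0, b = 30, c = 180)
  tun <- lapply(prefs, function(p)
    structure(list(preferred_angle = p, width = 40, amplitude = 10,
                   baseline = 5, r2 = 0.9, reliable = TRUE),
              class = "tuning_fit"))
  stats <- expand.grid(from = names(prefs), to = names(prefs),
                       stringsAsFactors = FALSE)
  stats <- stats[stats$from != stats$to, ]
  d <- popglm:::ang_dist(prefs[stats$from], prefs[stats$to])
  stats$weight <- 2 * exp(-d / 60)
  stats$interaction <- "SYNTH-SYNTH"
  rel <- coupling_vs_tuning(stats, tun, breaks = c(0, 60, 120, 180))
  ok <- !is.na(rel$mean_weight)
  expect_true(all(diff(rel$mean_weight[ok]) < 0))
})
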