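test_that("poisson_loglik matches hand computations and brute force", {
  # counts [0,1,0], dt 1 ms, lambda [10,20,10] sp/s -> log(0.02) - 0.04
  expect_equal(poisson_loglik(c(10, 20, 10), c(0, 1, 0), 0.001),
               log(0.02) - 0.04)
  # all-zero counts -> -dt * sum(lambda)
  lam <- c(5, 50, 500)
  expect_equal(poisson_loglik(lam, c(0, 0, 0), 0.002), -0.002 * sum(lam))
  # doubling dt with lambda halved leaves the penalty term unchanged
  y <- c(0, 2, 1)
  l1 <- poisson_loglik(lam, y, 0.001)
  l2 <- poisson_loglik(lam / 2, y, 0.002)
  expect_equal(l1, l2)
  # brute force via dpois (constants restored) on random inputs
  set.seed(5)
  for (i in 1:10) {
    n <- 50
    lam <- runif(n, 1, 80); y <- rpois(n, lam * 0.001)
    brute <- sum(dpois(y, lam * 0.001, log = TRUE)) + sum(lfactorial(y))
    expect_equal(poisson_loglik(lam, y, 0.001), brute, tolerance = 1e-10)
  }
  expect_error(poisson_loglik(c(1, 2, 3), c(-1, 0, 0), 0.001), "negative")
  expect_error(poisson_loglik(c(0, 1, 1), c(0, 0, 0), 0.001), "positive")
})

test_that("predict_rate is the exponential of the linear predictor", {
  spec <- model_spec(include_terms = c("history", "coupling"),
                     condition_split = FALSE)
  tr <- plain_trials(2)
  set.seed(2)
  sp <- lapply(1:2, function(i) lapply(1:2, function(j) sort(runif(20, 0, 0.999))))
  names(sp) <- c("a", "b")
  s <- new_session(data.frame(unit_id = c("a", "b"), area = "LIP",
                              channel = 1:2), tr, sp)
  d <- build_design(bin_spikes(s), "a", spec)
  f <- fit_neuron(d)
  lam <- predict_rate(f, d)
  expect_true(all(lam > 0))
  w <- popglm:::fit_coef_vector(f, d)
  expect_equal(lam, exp(drop(d$X %*% w) + f$b) / 0.001, tolerance = 1e-12)

  # all weights zero -> constant rate exp(b)/dt
  f0 <- f; for (nm in names(f0$weights)) f0$weights[[nm]][] <- 0
  expect_equal(unique(round(predict_rate(f0, d), 9)),
               round(exp(f0$b) / 0.001, 9))

  # +1 on one history weight multiplies the rate by exp(B[tau, j]) at
  # matching lags (log-linearity / gain interpretation)
  f1 <- f; f1$weights$history[3] <- f1$weights$history[3] + 1
  bases <- popglm:::spec_bases(spec)
  gain <- predict_rate(f1, d) / lam
  hist_cols <- d$column_map$history
  # reconstruct the expected gain from the design's own history column 3
  expect_equal(log(gain), d$X[, hist_cols[3]], tolerance = 1e-9)
})

test_that("MAP fitting satisfies the classical identities", {
  fxd <- fixture_session()
  cache <- design_cache(fxd$binned, fxd$sim$truth$spec)
  d <- build_design(cache, "u03")

  # ridge -> infinity: penalized weights -> 0, b -> log(mean count)
  sp_inf <- fxd$sim$truth$spec; sp_inf$ridge_strength <- 1e9
  d_inf <- build_design(cache, "u03", sp_inf)
  f_inf <- fit_neuron(d_inf)
  expect_lt(max(abs(unlist(f_inf$weights))), 1e-4)
  expect_equal(f_inf$b, log(mean(d$y)), tolerance = 1e-3)

  # score equation for the intercept at ridge = 0: sum(lambda * dt) = sum(y)
  sp0 <- fxd$sim$truth$spec; sp0$ridge_strength <- 0
  d0 <- build_design(cache, "u03", sp0)
  f0 <- fit_neuron(d0)
  expect_equal(sum(predict_rate(f0, d0) * 0.001), sum(d0$y),
               tolerance = 1e-6 * sum(d0$y))

  # concavity: the fitted optimum beats random perturbations
  pen_obj <- function(f, d) {
    w <- popglm:::fit_coef_vector(f, d)
    eta <- drop(d$X %*% w) + f$b
    sum(d$y * eta - exp(eta)) - d$spec$ridge_strength * sum(w^2)
  }
  f <- fit_neuron(d)
  base <- pen_obj(f, d)
  set.seed(13)
  for (i in 1:5) {
    fp <- f
    fp$b <- fp$b + rnorm(1, 0, 0.02)
    for (nm in names(fp$weights))
      fp$weights[[nm]] <- fp$weights[[nm]] + rnorm(length(fp$weights[[nm]]),
                                                   0, 0.02)
    expect_lt(pen_obj(fp, d), base)
  }
  expect_lt(f$grad_norm, 1e-6 * max(1, sum(d$y)))
})

test_that("single-neuron parameter recovery from simulated data", {
  # data simulated from a known GLM: recovered kernels correlate with truth
  sim <- simulate_glm_session(3, 150, seed = 19, coupling_prob = 0.8)
  pf <- fit_population(bin_spikes(sim$session), sim$truth$spec)
  bases <- popglm:::spec_bases(sim$truth$spec)
  cors <- c()
  for (uid in names(pf$fits))
    for (nm in names(pf$fits[[uid]]$weights)) {
      bs <- if (grepl("^(history|coupling)", nm)) bases$hist else bases$task
      kt <- reconstruct_kernel(bs, sim$truth$fits[[uid]]$weights[[nm]])
      ke <- reconstruct_kernel(bs, pf$fits[[uid]]$weights[[nm]])
      if (sqrt(mean(kt^2)) > 0.05)
        cors <- c(cors, cor(kt, ke))
    }
  expect_gte(median(cors), 0.9)
})

test_that("bits_per_spike and deviance_explained behave per definition", {
  set.seed(8)
  y <- rpois(5000, 0.02)
  mean_rate <- sum(y) / length(y) / 0.001
  # the homogeneous mean-rate model scores exactly 0
  expect_identical(bits_per_spike(rep(mean_rate, length(y)), y, 0.001), 0)
  expect_equal(deviance_explained(rep(mean_rate, length(y)), y, 0.001), 0)
  # the generating model is positive in expectation
  lam <- rep(c(5, 40), each = 2500)
  y2 <- rpois(5000, lam * 0.001)
  expect_gt(bits_per_spike(lam, y2, 0.001), 0)
  dev <- deviance_explained(lam, y2, 0.001)
  expect_gt(dev, 0); expect_lt(dev, 1)
  # saturated prediction approaches 1
  eps <- 1e-9
  lam_sat <- pmax(y2, eps) / 0.001
  expect_gt(deviance_explained(lam_sat, y2, 0.001), 0.99)
  # zero spikes -> flagged missing
  expect_warning(v <- bits_per_spike(rep(10, 5), rep(0, 5), 0.001))
  expect_true(is.na(v))
})

test_that("variance_explained_psth matches the R^2 definition", {
  set.seed(4)
  obs <- rnorm(100, 20, 5)
  expect_equal(variance_explained_psth(obs, obs), 1)
  expect_equal(variance_explained_psth(rep(mean(obs), 100), obs), 0)
  pred <- obs + rnorm(100, 0, 2)
  r2 <- variance_explained_psth(pred, obs)
  expect_equal(r2, 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
  expect_warning(v <- variance_explained_psth(obs, rep(1, 100)))
  expect_true(is.na(v))
})

test_that("cross-validation folds partition trials deterministically", {
  fxd <- fixture_session()
  spec <- fxd$sim$truth$spec
  cv1 <- crossval_fit(fxd$binned, spec, k_folds = 5, seed = 3,
                      units = "u01")
  cv2 <- crossval_fit(fxd$binned, spec, k_folds = 5, seed = 3,
                      units = "u01")
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$cv$test_ll, cv2$cv$test_ll)
  expect_equal(sort(unique(cv1$folds)), 1:5)
  expect_equal(as.vector(table(cv1$folds)), rep(12, 5))  # 60 trials
  expect_equal(nrow(cv1$cv), 5)
  expect_error(crossval_fit(fxd$binned, spec, k_folds = 70), "trials")
})
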