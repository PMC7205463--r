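test_that("binning follows the half-open convention and conserves counts", {
  tr <- plain_trials(1)
  s <- new_session(data.frame(unit_id = "u1", area = "LIP", channel = 1),
                   tr, list(u1 = list(c(0.0104, 0.5, 0.9995))))
  b <- bin_spikes(s, 0.001)
  expect_equal(b$counts[[1]][11, 1], 1L)  # 0.0104 s -> 0-based bin 10
  expect_equal(b$counts[[1]][501, 1], 1L)
  expect_equal(sum(b$counts[[1]]), 3L)
  expect_equal(nrow(b$counts[[1]]), 1000L)

  # empty spike lists give all-zero counts
  s0 <- new_session(s$units, tr, list(u1 = list(numeric(0))))
  expect_true(all(bin_spikes(s0)$counts[[1]] == 0L))

  # conservation across bin widths, ragged trials, multiple units
  sim <- fixture_session()$sim
  n_spk <- sum(vapply(sim$session$spikes, function(u) sum(lengths(u)), 1))
  for (bw in c(0.001, 0.0025, 0.01))
    expect_equal(sum(vapply(bin_spikes(sim$session, bw)$counts, sum, 1)),
                 n_spk)
})

test_that("invalid sessions are rejected with a diagnostic", {
  tr <- plain_trials(1)
  u <- data.frame(unit_id = "u1", area = "LIP", channel = 1)
  expect_error(new_session(u, tr, list(u1 = list(c(0.5, 1.5)))),
               "unit u1, trial 1")
  expect_error(new_session(u, tr, list(u1 = list(c(0.5, 0.5)))),
               "strictly sorted")
  expect_error(new_session(u, tr, list(u1 = list(c(-0.1)))),
               "outside")
  bad_tr <- tr; bad_tr$target_on <- 0.01  # before fixation_on
  expect_error(new_session(u, bad_tr, list(u1 = list(numeric(0)))),
               "event ordering")
  u2 <- rbind(u, u)
  expect_error(new_session(u2, tr, list(list(numeric(0)), list(numeric(0)))),
               "duplicate unit_id")
})

test_that("binned Poisson spike trains recover the generating rate", {
  set.seed(3)
  rate <- 20; n_tr <- 100
  sp <- lapply(seq_len(n_tr), function(i) {
    n <- rpois(1, rate)
    sort(runif(n, 0, 1 - 1e-9))
  })
  s <- new_session(data.frame(unit_id = "u1", area = "LIP", channel = 1),
                   plain_trials(n_tr), list(u1 = sp))
  b <- bin_spikes(s)
  est <- mean(do.call(rbind, b$counts)) / 0.001
  se <- sqrt(rate / (n_tr * 1)) # SE of the rate over 100 one-second trials
  expect_lt(abs(est - rate), 3 * se)
})

test_that("PSTH is flat for constant rates and exact when unsmoothed", {
  set.seed(9)
  n_tr <- 30
  sp <- lapply(seq_len(n_tr), function(i) sort(runif(25, 0, 1 - 1e-9)))
  s <- new_session(data.frame(unit_id = "u1", area = "LIP", channel = 1),
                   plain_trials(n_tr), list(u1 = sp))
  b <- bin_spikes(s)
  p0 <- compute_psth(b, "target_on", c(-0.1, 0.4), smoothing_sd = 0,
                     group_by_condition = FALSE)
  # unsmoothed equals the trial-averaged rate computed by hand
  acc <- Reduce(`+`, lapply(b$counts, function(m) m[101:600, 1]))
  expect_equal(p0$rate, acc / n_tr / 0.001)
  # smoothing preserves the mean rate (reflection padding, no edge loss)
  p1 <- compute_psth(b, "target_on", c(-0.1, 0.4), smoothing_sd = 0.03,
                     group_by_condition = FALSE)
  expect_equal(mean(p1$rate), mean(p0$rate), tolerance = 0.02)
  # merged identical trials equal the single-trial rate exactly
  s1 <- new_session(s$units, plain_trials(3),
                    list(u1 = rep(list(sp[[1]]), 3)))
  p_m <- compute_psth(bin_spikes(s1), "target_on", c(0, 0.5),
                      smoothing_sd = 0, group_by_condition = FALSE)
  expect_equal(unique(round(p_m$n_trials)), 3L)
  expect_equal(p_m$rate,
               bin_spikes(s1)$counts[[1]][201:700, 1] / 0.001)
})

test_that("PSTH flags empty conditions instead of zero-filling", {
  tr <- plain_trials(4)  # all IN_RF
  sp <- list(u1 = rep(list(c(0.1, 0.2)), 4))
  s <- new_session(data.frame(unit_id = "u1", area = "LIP", channel = 1),
                   tr, sp)
  p <- compute_psth(bin_spikes(s), "target_on", c(0, 0.2))
  expect_true("u1/OUT_RF" %in% attr(p, "empty_conditions"))
  expect_false(any(p$condition == "OUT_RF"))
})

test_that("PSTH peak recovers a simulated transient response", {
  # 50 spikes/s during the 200 ms target epoch over 10 s of data
  set.seed(11)
  n_tr <- 10
  tr <- plain_trials(n_tr)
  sp <- lapply(seq_len(n_tr), function(i) {
    base <- runif(rpois(1, 5), 0, 1 - 1e-9)             # 5 sp/s background
    burst <- runif(rpois(1, 10), 0.2, 0.4)              # +50 sp/s in epoch
    sort(unique(c(base, burst)))
  })
  s <- new_session(data.frame(unit_id = "u1", area = "LIP", channel = 1),
                   tr, list(u1 = sp))
  p <- compute_psth(bin_spikes(s), "target_on", c(-0.1, 0.4),
                    group_by_condition = FALSE)
  peak <- max(p$rate)
  expect_lt(abs(peak - 55), 0.25 * 55)
})

test_that("session write/read round trip is lossless", {
  sim <- fixture_session()$sim
  path <- withr::local_tempdir()
  write_session(sim$session, path)
  back <- read_session(path)
  expect_equal(back$units, sim$session$units)
  expect_equal(back$trials$target_on, sim$session$trials$target_on)
  expect_equal(back$trials$condition, sim$session$trials$condition)
  for (u in back$units$unit_id)
    for (j in seq_len(nrow(back$trials)))
      expect_equal(back$spikes[[u]][[j]], sim$session$spikes[[u]][[j]],
                   tolerance = 1.1e-6)
  # re-binned counts are identical
  b0 <- bin_spikes(sim$session); b1 <- bin_spikes(back)
  expect_identical(lapply(b0$counts, unname), lapply(b1$counts, unname))
})

test_that("malformed containers produce structured errors", {
  path <- withr::local_tempdir()
  expect_error(read_session(path), "session.json")
  writeLines('{"units": {"unit_id": ["u1"]}}', file.path(path, "session.json"))
  expect_error(read_session(path), "spikes.csv")
  writeLines("unit_id,trial,time", file.path(path, "spikes.csv"))
  expect_error(read_session(path), "trials")
})
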