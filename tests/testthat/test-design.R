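test_that("design matrix has the conventional column layout", {
  fxd <- fixture_session()
  spec <- fxd$sim$truth$spec
  cache <- design_cache(fxd$binned, spec)
  d <- build_design(cache, "u01")
  # 8 task params x 2 events x 2 conditions + 10 history + 10 x (n-1) coupling
  expect_equal(ncol(d$X), 8 * 2 * 2 + 10 + 10 * 3)
  expect_setequal(names(d$column_map),
                  c("target_IN_RF", "target_OUT_RF", "saccade_IN_RF",
                    "saccade_OUT_RF", "history",
                    paste0("coupling:", c("u02", "u03", "u04"))))
  expect_equal(length(d$y), sum(vapply(fxd$binned$counts, nrow, 1L)))
  expect_equal(d$y, unlist(lapply(fxd$binned$counts, function(m) m[, 1])),
               ignore_attr = TRUE)

  # spec without coupling: no coupling entries (uncoupled model)
  sp2 <- spec; sp2$include_terms <- c("target", "saccade", "history")
  d2 <- build_design(cache, "u01", sp2)
  expect_false(any(grepl("coupling", names(d2$column_map))))
  expect_equal(ncol(d2$X), 32 + 10)
  expect_error(build_design(design_cache(
    bin_spikes(new_session(fxd$binned$units[1, ],
                           fxd$sim$session$trials,
                           fxd$sim$session$spikes[1])), spec), "u01"),
    "fewer than 2 units")
})

test_that("a single partner spike yields shifted basis columns at lag 1", {
  spec <- model_spec(include_terms = c("history", "coupling"),
                     condition_split = FALSE)
  tr <- plain_trials(1)
  s <- new_session(
    data.frame(unit_id = c("a", "b"), area = "LIP", channel = 1:2),
    tr, list(a = list(c(0.3001)), b = list(c(0.0005))))
  d <- build_design(bin_spikes(s), "a", spec)
  bases <- popglm:::spec_bases(spec)
  blk <- d$X[, d$column_map[["coupling:b"]]]
  # partner spike in bin 1 (0-based bin 0): columns equal basis at lags 1..250
  expect_equal(blk[2:251, ], bases$hist$B, tolerance = 1e-9)
  expect_true(all(blk[1, ] == 0))
})

test_that("design rows depend only on within-trial data", {
  fxd <- fixture_session()
  spec <- fxd$sim$truth$spec
  cache <- design_cache(fxd$binned, spec)
  d <- build_design(cache, "u02")

  # permuting whole trials permutes whole row blocks, leaving rows unchanged
  sess2 <- fxd$sim$session
  perm <- c(2:1, 3:nrow(sess2$trials))
  sess2$trials <- sess2$trials[perm, ]
  sess2$spikes <- lapply(sess2$spikes, function(u) u[perm])
  d_perm <- build_design(design_cache(bin_spikes(sess2), spec), "u02")
  rows_tr1 <- d$X[d$trial_id == 1, ]
  rows_tr1_perm <- d_perm$X[d_perm$trial_id == 2, ]
  expect_equal(rows_tr1_perm, rows_tr1, tolerance = 1e-12)

  # history/coupling columns are zero at each trial's first lag bin
  first_rows <- match(unique(d$trial_id), d$trial_id)
  hist_cols <- d$column_map$history
  expect_true(all(d$X[first_rows, hist_cols] == 0))
})

test_that("saccade columns are shifted by the pre-saccadic lead", {
  spec <- model_spec(include_terms = "saccade", condition_split = FALSE,
                     saccade_pre_ms = 400)
  tr <- plain_trials(1)  # saccade_onset 0.9 -> delta at 0.5 s
  s <- new_session(data.frame(unit_id = "u", area = "FEF", channel = 1),
                   tr, list(u = list(numeric(0))))
  d <- build_design(bin_spikes(s), "u", spec)
  bases <- popglm:::spec_bases(spec)
  col1 <- d$X[, d$column_map$saccade_all[1]]
  expect_true(all(col1[1:500] == 0))
  expect_equal(col1[501:1000], bases$task$B[1:500, 1], tolerance = 1e-9)
})
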