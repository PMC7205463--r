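#' Poisson log-likelihood of a rate series
#'
#' \eqn{L = \sum_t [ y_t \log(\Delta \lambda_t) - \Delta \lambda_t ]}, the
#' Poisson log-likelihood with the data-dependent constant terms dropped.
#'
#' @param lambda Rate series in spikes/s, strictly positive.
#' @param counts Per-bin spike counts (non-negative integers).
#' @param bin_width Bin width \eqn{\Delta} in seconds.
#' @return Log-likelihood in nats.
#' @export
poisson_loglik <- function(lambda, counts, bin_width) {
  if (length(lambda) != length(counts))
    stopf("lambda and counts lengths differ (%d vs %d)",
          length(lambda), length(counts))
  if (any(counts < 0)) stopf("negative counts at bin %d", which(counts < 0)[1])
  if (any(lambda <= 0)) stopf("lambda must be strictly positive")
  mu <- lambda * bin_width
  sum(counts * log(mu) - mu)
}

#' Predicted conditional intensity of a fitted neuron
#'
#' \eqn{\lambda_t = \exp(X_t w + b)/\Delta} in spikes/s.
#'
#' @param fit A `neuron_fit` (see [fit_neuron()]).
#' @param design A `glm_design` sharing the fit's model spec.
#' @param rows Optional row subset.
#' @return Numeric vector of rates, strictly positive.
#' @export
predict_rate <- function(fit, design, rows = NULL) {
  stopifnot(inherits(fit, "neuron_fit"), inherits(design, "glm_design"))
  w <- fit_coef_vector(fit, design)
  eta <- drop(design$X %*% w) + fit$b
  if (!is.null(rows)) eta <- eta[rows]
  bad <- which(!is.finite(eta))
  if (length(bad)) stopf("non-finite linear predictor at bin %d", bad[1])
  exp(eta) / design$bin_width
}

# assemble the flat coefficient vector of a fit in the column order of a
# design (errors if a design block has no counterpart in the fit)
fit_coef_vector <- function(fit, design) {
  w <- numeric(ncol(design$X))
  for (nm in names(design$column_map)) {
    block <- fit$weights[[nm]]
    if (is.null(block))
      stopf("fit has no weights for design block '%s'", nm)
    w[design$column_map[[nm]]] <- block
  }
  w
}

#' Fit one neuron's encoding model by penalized maximum a posteriori
#'
#' Maximizes the Poisson log-likelihood minus the ridge penalty
#' \eqn{\lambda_r (\|k\|^2 + \|h\|^2 + \|c\|^2)} — a Gaussian prior on all
#' kernel weights; the baseline `b` is unpenalized. The objective is concave,
#' so the Newton solver converges to the unique optimum; convergence is
#' declared when the gradient infinity-norm falls below
#' `tol_grad_rel * max(1, sum(counts))`.
#'
#' @param design A `glm_design` from [build_design()].
#' @param rows Optional integer subset of rows to fit on (e.g. CV training
#'   rows or an epoch window); default all.
#' @param init Optional warm start: a previous `neuron_fit` with the same
#'   columns.
#' @param ridge_strength Optional override of the spec's penalty.
#' @param tol_grad_rel Relative gradient tolerance (default 1e-6).
#' @param max_iter Newton iteration cap (default 100).
#' @return Object of class `neuron_fit`: baseline `b` (log spikes/bin),
#'   `weights` (list of weight blocks named as in `design$column_map`),
#'   convergence diagnostics, and the model spec.
#' @export
fit_neuron <- function(design, rows = NULL, init = NULL,
                       ridge_strength = NULL,
                       tol_grad_rel = 1e-6, max_iter = 100) {
  stopifnot(inherits(design, "glm_design"))
  X <- design$X; y <- design$y
  if (!is.null(rows)) { X <- X[rows, , drop = FALSE]; y <- y[rows] }
  if (sum(y) < 1) stopf("unit %s: no spikes in the training data",
                        design$target_unit)
  init_vec <- if (inherits(init, "neuron_fit"))
    c(fit_coef_vector(init, design), init$b) else numeric(0)
  res <- cpp_fit_poisson_ridge(
    X, y, penalized = rep(1, ncol(X)),
    lambda = ridge_strength %||% design$spec$ridge_strength, init = init_vec,
    tol_grad = tol_grad_rel * max(1, sum(y)), max_iter = max_iter)
  if (!res$converged)
    stopf("unit %s: Newton solver did not converge in %d iterations (final gradient norm %.3g)",
          design$target_unit, max_iter, res$grad_norm)
  weights <- lapply(design$column_map, function(ix) res$coef[ix])
  structure(list(unit_id = design$target_unit, b = res$intercept,
                 weights = weights, spec = design$spec,
                 column_map = design$column_map,
                 grad_norm = res$grad_norm, iterations = res$iterations,
                 objective = res$objective),
            class = "neuron_fit")
}

#' @export
print.neuron_fit <- function(x, ...) {
  cat(sprintf("neuron_fit for %s: b = %.3f (%.1f spikes/s at %g ms bins), blocks: %s\n",
              x$unit_id, x$b, exp(x$b) / x$spec$bin_width,
              x$spec$bin_width * 1000,
              paste(names(x$weights), collapse = ", ")))
  invisible(x)
}

#' Reconstruct a fitted kernel in the time domain
#'
#' @param fit A `neuron_fit`.
#' @param which Block name: `"history"`, `"coupling:<unit>"`,
#'   `"target_IN_RF"`, `"saccade_OUT_RF"`, ... (see `names(fit$weights)`).
#' @param bases Optional bases (defaults to the spec's).
#' @return Numeric kernel over the block's lag grid (attribute `lags_ms`).
#' @export
fit_kernel <- function(fit, which, bases = NULL) {
  stopifnot(inherits(fit, "neuron_fit"))
  if (is.null(fit$weights[[which]])) stopf("fit has no block '%s'", which)
  bases <- bases %||% spec_bases(fit$spec)
  b <- if (grepl("^(history|coupling)", which)) bases$hist else bases$task
  k <- reconstruct_kernel(b, fit$weights[[which]])
  attr(k, "lags_ms") <- b$lags_ms
  k
}

#' Fit the full population (one model per unit, no cross-validation)
#'
#' @param cache A `design_cache` (or `binned_session`).
#' @param spec Optional `model_spec` override.
#' @param units Unit ids to fit (default all).
#' @param init Optional named list of warm-start `neuron_fit`s.
#' @param partner_perm Passed through to [build_design()] (permutation null).
#' @param ... Passed to [fit_neuron()].
#' @return Object of class `population_fit` (list of `neuron_fit`s).
#' @export
fit_population <- function(cache, spec = NULL, units = NULL, init = NULL,
                           partner_perm = NULL, ...) {
  if (inherits(cache, "binned_session"))
    cache <- design_cache(cache, spec %||% model_spec())
  spec <- spec %||% cache$spec
  units <- units %||% cache$units$unit_id
  fits <- lapply(units, function(uid) {
    d <- build_design(cache, uid, spec, partner_perm = partner_perm)
    fit_neuron(d, init = init[[uid]], ...)
  })
  names(fits) <- units
  structure(list(fits = fits, spec = spec, units = cache$units),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("population_fit: %d units (%s)\n", length(x$fits),
              paste(x$spec$include_terms, collapse = " + ")))
  invisible(x)
}

#' Cross-validated population fit
#'
#' 5-fold cross-validation in which the folds partition *trials* (never time
#' bins), preserving within-trial dependence: each model is trained on 80%
#' of the trials and scored on the withheld 20%. Stores per-fold held-out
#' log-likelihood, bits/spike and deviance explained for every unit, plus a
#' final fit on all trials. Deterministic given `seed`.
#'
#' @param binned A `binned_session` (or `spike_session`, binned at the spec's
#'   bin width).
#' @param spec A `model_spec`.
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param units Unit ids to fit (default all).
#' @param select_ridge If `TRUE`, the ridge strength is selected per unit and
#'   per fold by nested cross-validation: an inner 75/25 trial split of each
#'   training fold scores every value of `ridge_grid` and the best one is
#'   used to refit on the full training fold. The final all-data fit uses the
#'   per-unit median (in log space) of the selected values.
#' @param ridge_grid Log-spaced penalty grid for `select_ridge`.
#' @return A `population_fit` whose `cv` element is a data frame with one row
#'   per unit x fold (`test_ll`, `train_ll`, `bits_per_spike`,
#'   `deviance_explained`, `ridge`), and `folds` the trial assignment.
#' @export
crossval_fit <- function(binned, spec = model_spec(), k_folds = 5, seed = 1,
                         units = NULL, select_ridge = FALSE,
                         ridge_grid = 10^c(-2, -1, 0, 1, 2)) {
  if (inherits(binned, "spike_session"))
    binned <- bin_spikes(binned, spec$bin_width)
  cache <- design_cache(binned, spec)
  n_tr <- length(cache$trials_used)
  if (n_tr < k_folds)
    stopf("need at least %d trials for %d-fold CV, have %d",
          k_folds, k_folds, n_tr)
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n_tr)))
  inner <- with_seed(derive_seed(seed, "inner"),
                     stats::runif(n_tr) < 0.25)
  units <- units %||% cache$units$unit_id

  cv_rows <- list(); fits <- list()
  for (uid in units) {
    d <- build_design(cache, uid)
    full <- fit_neuron(d)
    trial_fold <- folds[match(d$trial_id, cache$trials_used)]
    row_inner <- inner[match(d$trial_id, cache$trials_used)]
    lam_sel <- numeric(k_folds)
    for (f in seq_len(k_folds)) {
      tr_rows <- which(trial_fold != f)
      te_rows <- which(trial_fold == f)
      ridge_f <- spec$ridge_strength
      if (select_ridge) {
        in_tr <- which(trial_fold != f & !row_inner)
        in_va <- which(trial_fold != f & row_inner)
        best <- -Inf; warm <- full
        for (lam in ridge_grid) {
          fi <- fit_neuron(d, rows = in_tr, init = warm,
                           ridge_strength = lam)
          warm <- fi
          ll <- poisson_loglik(predict_rate(fi, d)[in_va], d$y[in_va],
                               d$bin_width)
          if (ll > best) { best <- ll; ridge_f <- lam }
        }
      }
      lam_sel[f] <- ridge_f
      ft <- fit_neuron(d, rows = tr_rows, init = full,
                       ridge_strength = ridge_f)
      lam_te <- predict_rate(ft, d)[te_rows]
      y_te <- d$y[te_rows]
      train_rate <- sum(d$y[tr_rows]) / length(tr_rows) / d$bin_width
      cv_rows[[length(cv_rows) + 1L]] <- data.frame(
        unit_id = uid, fold = f,
        train_ll = ft$objective,
        test_ll = poisson_loglik(lam_te, y_te, d$bin_width),
        bits_per_spike = bits_per_spike(lam_te, y_te, d$bin_width,
                                        null_rate = train_rate),
        deviance_explained = deviance_explained(lam_te, y_te, d$bin_width,
                                                null_rate = train_rate),
        ridge = ridge_f)
    }
    fits[[uid]] <- if (select_ridge)
      fit_neuron(d, init = full,
                 ridge_strength = exp(stats::median(log(lam_sel)))) else full
  }
  structure(list(fits = fits, spec = spec, units = cache$units,
                 folds = folds, seed = seed,
                 cv = do.call(rbind, cv_rows)),
            class = "population_fit")
}

#' Single-trial prediction accuracy in bits per spike
#'
#' Log-likelihood of the model relative to a homogeneous mean-rate model,
#' normalized by the spike count and converted to bits:
#' \eqn{(L(\lambda; r) - L(\bar\lambda; r)) / \sum_t r_t / \log 2}. The
#' mean-rate model scores exactly 0.
#'
#' @param lambda Model rate series (spikes/s).
#' @param counts Observed counts.
#' @param bin_width Bin width in seconds.
#' @param null_rate Mean firing rate \eqn{\bar\lambda} of the reference model
#'   (spikes/s); defaults to the empirical mean rate of `counts`.
#' @return Bits per spike; `NA` (with a warning) when `counts` has no spikes.
#' @export
bits_per_spike <- function(lambda, counts, bin_width,
                           null_rate = sum(counts) / length(counts) / bin_width) {
  n_sp <- sum(counts)
  if (n_sp == 0) {
    warning("bits_per_spike undefined for a spikeless segment")
    return(NA_real_)
  }
  ll_m <- poisson_loglik(lambda, counts, bin_width)
  ll_0 <- poisson_loglik(rep(null_rate, length(counts)), counts, bin_width)
  (ll_m - ll_0) / n_sp / log(2)
}

#' Fraction of Poisson deviance explained
#'
#' \eqn{1 - D_{model}/D_{null}}, with \eqn{D} the Poisson deviance against
#' the saturated model and the null a homogeneous mean-rate model.
#'
#' @inheritParams bits_per_spike
#' @return Fraction in \eqn{(-\infty, 1]}; `NA` when `counts` has no spikes.
#' @export
deviance_explained <- function(lambda, counts, bin_width,
                               null_rate = sum(counts) / length(counts) / bin_width) {
  if (sum(counts) == 0) return(NA_real_)
  ll_sat <- sum(counts[counts > 0] * (log(counts[counts > 0]) - 1))
  d_m <- 2 * (ll_sat - poisson_loglik(lambda, counts, bin_width))
  d_0 <- 2 * (ll_sat - poisson_loglik(rep(null_rate, length(counts)), counts,
                                      bin_width))
  1 - d_m / d_0
}

#' PSTH variance explained
#'
#' \eqn{R^2 = 1 - SSE/SST} over concatenated condition-wise PSTHs.
#'
#' @param predicted,observed Aligned rate series (same length).
#' @return R-squared in \eqn{(-\infty, 1]}; `NA` (flagged by a warning) when
#'   the observed series has zero variance.
#' @export
variance_explained_psth <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stopf("predicted and observed series lengths differ")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    warning("observed PSTH has zero variance; R^2 undefined")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / sst
}
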