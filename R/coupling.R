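#' Coupling weight of a kernel
#'
#' The overall coupling strength of a directed pair: the sum of the
#' reconstructed time-domain kernel over its support (per-ms log-gain summed
#' over the 250 ms window). Positive weights denote excitatory interactions,
#' negative weights inhibitory ones. The sum is taken in the time domain, not
#' over raw basis weights, so it is invariant to the basis parameterization.
#'
#' @param kernel Numeric time-domain kernel.
#' @return Scalar weight (dimensionless log-gain).
#' @export
coupling_weight <- function(kernel) sum(kernel)

#' Maximum multiplicative gain of a kernel
#'
#' `exp(max(kernel))`: the peak gain one spike of the source neuron exerts on
#' the target's rate. Equals 1 exactly when the kernel's maximum is 0.
#'
#' @param kernel Numeric time-domain kernel.
#' @return Scalar gain, >= 0.
#' @export
coupling_gain <- function(kernel) exp(max(kernel))

#' Directed interaction class of a unit pair
#'
#' @param from_area,to_area Area labels ("LIP", "FEF", "SYNTH").
#' @return One of "LIP-LIP", "FEF-FEF", "LIP-FEF", "FEF-LIP", "SYNTH-SYNTH";
#'   direction matters (LIP-FEF is from LIP to FEF).
#' @export
classify_interaction <- function(from_area, to_area) {
  known <- c("LIP", "FEF", "SYNTH")
  if (!(from_area %in% known) || !(to_area %in% known))
    stopf("unknown area in pair (%s, %s)", from_area, to_area)
  if (from_area == "SYNTH" || to_area == "SYNTH") return("SYNTH-SYNTH")
  paste(from_area, to_area, sep = "-")
}

#' Summarize all coupling kernels of a population fit
#'
#' @param popfit A `population_fit` whose spec includes coupling.
#' @param bases Optional precomputed bases.
#' @return Data frame with one row per directed pair: `from`, `to`,
#'   `interaction`, `weight` (summed log-gain), `gain` (max multiplicative
#'   gain).
#' @export
coupling_table <- function(popfit, bases = NULL) {
  stopifnot(inherits(popfit, "population_fit"))
  bases <- bases %||% spec_bases(popfit$spec)
  units <- popfit$units
  rows <- list()
  for (to_id in names(popfit$fits)) {
    f <- popfit$fits[[to_id]]
    cnames <- grep("^coupling:", names(f$weights), value = TRUE)
    for (cn in cnames) {
      from_id <- sub("^coupling:", "", cn)
      kern <- reconstruct_kernel(bases$hist, f$weights[[cn]])
      rows[[length(rows) + 1L]] <- data.frame(
        from = from_id, to = to_id,
        interaction = classify_interaction(
          units$area[units$unit_id == from_id],
          units$area[units$unit_id == to_id]),
        weight = coupling_weight(kern), gain = coupling_gain(kern),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Permutation null distribution for coupling
#'
#' Re-fits the model after permuting, for each fitted neuron, the trial order
#' of every predictor neuron (each partner gets its own random reordering;
#' the fitted neuron's spikes and the task events stay aligned within each
#' trial). This destroys the trial-by-trial noise correlations between
#' neurons while preserving the spike times and the model-based treatment of
#' the task events, yielding the coupling expected by chance alone.
#'
#' @param cache A `design_cache` (or `binned_session`).
#' @param spec Optional `model_spec` override.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param init Optional named list of `neuron_fit`s (e.g. the real fit) used
#'   as warm starts.
#' @param ... Passed to [fit_neuron()].
#' @return Object of class `null_distribution`: a coupling table with an
#'   extra `perm` column, plus `n_perm` and `seed`.
#' @export
permutation_null <- function(cache, spec = NULL, n_perm = 20, seed = 1,
                             init = NULL, ...) {
  if (inherits(cache, "binned_session"))
    cache <- design_cache(cache, spec %||% model_spec())
  spec <- spec %||% cache$spec
  if (n_perm < 1) stopf("n_perm must be >= 1")
  n_units <- nrow(cache$units)
  if (n_units < 2) stopf("permutation null needs at least 2 units")
  n_tr <- length(cache$trials_used)
  tabs <- with_seed(seed, lapply(seq_len(n_perm), function(p) {
    perm <- vapply(seq_len(n_units), function(i) sample.int(n_tr),
                   integer(n_tr))
    pf <- fit_population(cache, spec, init = init, partner_perm = perm, ...)
    tb <- coupling_table(pf, cache$bases)
    tb$perm <- p
    tb
  }))
  structure(list(weights = do.call(rbind, tabs), n_perm = n_perm,
                 seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %d permutations, %d pair-samples\n",
              x$n_perm, nrow(x$weights)))
  invisible(x)
}

#' Fraction of coupling weights exceeding the permutation null
#'
#' For each interaction class, the one-sided fraction of real coupling
#' weights above the null mean + 2 null SD (a two-sided variant counts
#' exceedances of either tail).
#'
#' @param stats Coupling table of the real fit ([coupling_table()]).
#' @param null A `null_distribution` (or its `weights` data frame).
#' @param by_interaction Compute per interaction class (default) or pooled.
#' @param two_sided Count |weight - null mean| > 2 SD instead (default
#'   `FALSE`, matching the excitatory-exceedance convention).
#' @return Data frame with `interaction`, `n_pairs`, `null_mean`, `null_sd`,
#'   `fraction`.
#' @export
significant_fraction <- function(stats, null, by_interaction = TRUE,
                                 two_sided = FALSE) {
  nw <- if (inherits(null, "null_distribution")) null$weights else null
  groups <- if (by_interaction) unique(stats$interaction) else "all"
  rows <- lapply(groups, function(g) {
    re <- if (g == "all") stats$weight else
      stats$weight[stats$interaction == g]
    nu <- if (g == "all") nw$weight else nw$weight[nw$interaction == g]
    m <- mean(nu); s <- stats::sd(nu)
    if (!is.finite(s) || s == 0)
      stopf("degenerate null (SD = 0) for interaction %s", g)
    frac <- if (two_sided) mean(abs(re - m) > 2 * s) else
      mean(re > m + 2 * s)
    data.frame(interaction = g, n_pairs = length(re), null_mean = m,
               null_sd = s, fraction = frac, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Principal components of a set of kernels
#'
#' PCA of the mean-centered kernel matrix (one kernel per row), e.g. all
#' coupling kernels of one interaction class. Component signs follow the
#' convention that each component has a positive integral.
#'
#' @param kernels Matrix with one kernel per row (>= 3 rows).
#' @param n_components Number of components to keep (default all).
#' @return Object of class `kernel_pca`: `components` (lag x component),
#'   `var_fraction`, `scores`, `center`, `n_kernels`.
#' @export
pca_kernels <- function(kernels, n_components = NULL) {
  kernels <- as.matrix(kernels)
  if (nrow(kernels) < 3) stopf("need at least 3 kernels, got %d", nrow(kernels))
  if (all(abs(kernels - kernels[rep(1, nrow(kernels)), ]) < 1e-300))
    stopf("degenerate kernel group: all kernels identical")
  pc <- stats::prcomp(kernels, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- n_components %||% ncol(pc$rotation)
  k <- min(k, ncol(pc$rotation))
  comp <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  flip <- ifelse(colSums(comp) < 0, -1, 1)
  comp <- sweep(comp, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  structure(list(components = comp, var_fraction = vf[seq_len(k)],
                 scores = scores, center = pc$center,
                 n_kernels = nrow(kernels)),
            class = "kernel_pca")
}

#' @export
print.kernel_pca <- function(x, ...) {
  cat(sprintf("kernel_pca: %d kernels; variance fractions %s\n", x$n_kernels,
              paste(signif(x$var_fraction, 3), collapse = " ")))
  invisible(x)
}

#' Double-exponential time constant of a kernel
#'
#' Least-squares fit of \eqn{a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}} to a
#' history or coupling kernel; the reported `tau` is the time constant of the
#' component with the larger positive amplitude. Kernels dominated by a
#' refractory period (most-negative value in the first 5 ms exceeding the
#' positive peak in magnitude) or poorly fit by an exponential decay
#' (R^2 below `r2_threshold`) are excluded with a reason rather than given a
#' meaningless tau.
#'
#' @param kernel Numeric time-domain kernel over >= 100 ms of support.
#' @param lags_ms Lag grid in ms (defaults to 1..length(kernel)).
#' @param r2_threshold Exclusion threshold on the fit R^2 (default 0.5).
#' @param refractory_window_ms Window for the refractory-dominance rule
#'   (default 5).
#' @return Object of class `time_constant`: `tau` (ms), `amplitudes`,
#'   `tau_pair`, `fit_r2`, `excluded`, `reason`.
#' @export
fit_time_constant <- function(kernel, lags_ms = seq_along(kernel),
                              r2_threshold = 0.5,
                              refractory_window_ms = 5) {
  if (max(lags_ms) < 100)
    stopf("kernel support (%g ms) too short for a time-constant fit",
          max(lags_ms))
  out <- function(tau = NA_real_, amps = c(NA_real_, NA_real_),
                  taus = c(NA_real_, NA_real_), r2 = NA_real_,
                  excluded = FALSE, reason = NA_character_)
    structure(list(tau = tau, amplitudes = amps, tau_pair = taus,
                   fit_r2 = r2, excluded = excluded, reason = reason),
              class = "time_constant")

  early <- kernel[lags_ms <= refractory_window_ms]
  if (length(early) && min(early) < 0 && -min(early) > max(kernel))
    return(out(excluded = TRUE, reason = "refractory-dominated"))

  df <- data.frame(t = lags_ms, y = kernel)
  best <- NULL
  for (t1 in c(5, 20)) for (t2 in c(60, 150)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2), data = df,
        start = list(a1 = kernel[1], tau1 = t1,
                     a2 = max(kernel) / 2, tau2 = t2),
        lower = c(-Inf, 0.5, -Inf, 0.5),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(out(excluded = TRUE, reason = "optimizer failure"))
  cf <- stats::coef(best$fit)
  r2 <- 1 - best$rss / sum((kernel - mean(kernel))^2)
  if (!is.finite(r2) || r2 < r2_threshold)
    return(out(r2 = r2, excluded = TRUE, reason = "poor exponential fit"))
  amps <- cf[c("a1", "a2")]; taus <- cf[c("tau1", "tau2")]
  if (all(amps <= 0))
    return(out(amps = unname(amps), taus = unname(taus), r2 = r2,
               excluded = TRUE, reason = "no positive component"))
  pick <- which.max(replace(amps, amps <= 0, -Inf))
  out(tau = unname(taus[pick]), amps = unname(amps), taus = unname(taus),
      r2 = r2)
}

#' @export
print.time_constant <- function(x, ...) {
  if (x$excluded) cat("time_constant: excluded (", x$reason, ")\n", sep = "")
  else cat(sprintf("time_constant: tau = %.1f ms (R^2 = %.2f)\n",
                   x$tau, x$fit_r2))
  invisible(x)
}

#' Predictive index from full and reduced deviance explained
#'
#' \eqn{(d_{full} - d_{reduced}) / d_{full}}, clipped to `[0, 1]`. With the
#' coupling terms removed from the reduced model this is the coupling index
#' (1 = the neuron's spike trains are completely predictable from the other
#' neurons' spiking; 0 = coupling adds nothing over task and history); with
#' history removed it is the history index.
#'
#' @param dev_full Deviance explained by the full model.
#' @param dev_reduced Deviance explained by the reduced model.
#' @param eps Threshold below which `dev_full` is considered degenerate.
#' @return Index in `[0, 1]`, or `NA` when `dev_full <= eps`.
#' @export
predictive_index <- function(dev_full, dev_reduced, eps = 1e-8) {
  if (!is.finite(dev_full)) stopf("dev_full must be finite")
  if (dev_full <= eps) return(NA_real_)
  min(max((dev_full - dev_reduced) / dev_full, 0), 1)
}

#' Coupling and history indices for every unit
#'
#' Fits the full model and the two reduced models (without coupling, without
#' history) with trial-wise cross-validation and converts the held-out
#' deviance explained into predictive indices.
#'
#' @param binned A `binned_session`.
#' @param spec Full `model_spec` (must include history and coupling).
#' @param k_folds,seed Cross-validation settings.
#' @return Data frame: `unit_id`, `coupling_index`, `history_index`,
#'   `dev_full`, `dev_nocoupling`, `dev_nohistory`.
#' @export
compute_predictive_indices <- function(binned, spec = model_spec(),
                                       k_folds = 5, seed = 1) {
  stopifnot(all(c("history", "coupling") %in% spec$include_terms))
  dev_of <- function(sp) {
    cv <- crossval_fit(binned, sp, k_folds = k_folds, seed = seed)$cv
    tapply(cv$deviance_explained, cv$unit_id, mean, na.rm = TRUE)
  }
  drop_term <- function(term) {
    sp <- spec; sp$include_terms <- setdiff(sp$include_terms, term); sp
  }
  d_full <- dev_of(spec)
  d_noc <- dev_of(drop_term("coupling"))
  d_noh <- dev_of(drop_term("history"))
  uids <- names(d_full)
  data.frame(
    unit_id = uids,
    coupling_index = vapply(uids, function(u)
      predictive_index(d_full[[u]], d_noc[[u]]), numeric(1)),
    history_index = vapply(uids, function(u)
      predictive_index(d_full[[u]], d_noh[[u]]), numeric(1)),
    dev_full = as.numeric(d_full[uids]),
    dev_nocoupling = as.numeric(d_noc[uids]),
    dev_nohistory = as.numeric(d_noh[uids]),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Epoch-restricted population fits and paired comparison
#'
#' Fits the model with the likelihood restricted to matched time windows
#' (e.g. fixation vs delay, or early vs late delay) and compares coupling
#' weights pair by pair across epochs. Windows are defined relative to task
#' events and must have equal lengths across compared epochs; trials on which
#' a window cannot be resolved are dropped (their number is reported).
#'
#' @param binned A `binned_session`.
#' @param spec A `model_spec`.
#' @param epochs Named list; each element `list(event = <event name>,
#'   offset = c(start, end))` in seconds relative to the event. Example:
#'   `list(fixation = list(event = "target_on", offset = c(-0.4, 0)),
#'         delay = list(event = "target_off", offset = c(0, 0.4)))`.
#' @param ... Passed to [fit_neuron()].
#' @return List: `tables` (named coupling tables per epoch, merged into
#'   `pairs` with one weight column per epoch), `comparison` (per epoch pair:
#'   Wilcoxon signed-rank p for a shift, mean shift, Pearson correlation
#'   across pairs), `dropped_trials` per epoch.
#' @export
fit_epoch_models <- function(binned, spec = model_spec(), epochs, ...) {
  stopifnot(length(epochs) >= 2, !is.null(names(epochs)))
  widths <- vapply(epochs, function(e) diff(e$offset), numeric(1))
  if (max(widths) - min(widths) > 1e-9)
    stopf("epoch windows must have equal lengths (got %s)",
          paste(signif(widths, 3), collapse = ", "))
  cache <- design_cache(binned, spec)
  tr <- cache$trials
  dt <- cache$bin_width

  fit_epoch <- function(ep) {
    e_t <- tr[[ep$event]][cache$trials_used]
    w0 <- e_t + ep$offset[1]; w1 <- e_t + ep$offset[2]
    durs <- tr$duration[cache$trials_used]
    ok <- w0 >= 0 & w1 <= durs
    row_trial <- rep(seq_along(cache$trials_used), cache$n_bins)
    bin_t <- (unlist(lapply(cache$n_bins, seq_len), use.names = FALSE) - 0.5) * dt
    rows <- which(ok[row_trial] & bin_t >= w0[row_trial] &
                    bin_t < w1[row_trial])
    fits <- lapply(cache$units$unit_id, function(uid) {
      d <- build_design(cache, uid)
      fit_neuron(d, rows = rows, ...)
    })
    names(fits) <- cache$units$unit_id
    list(fit = structure(list(fits = fits, spec = spec,
                              units = cache$units),
                         class = "population_fit"),
         dropped = sum(!ok))
  }

  res <- lapply(epochs, fit_epoch)
  tables <- lapply(res, function(r) coupling_table(r$fit, cache$bases))
  pairs <- tables[[1]][, c("from", "to", "interaction")]
  for (nm in names(tables)) pairs[[paste0("weight_", nm)]] <-
    tables[[nm]]$weight

  comb <- utils::combn(names(epochs), 2)
  comparison <- do.call(rbind, lapply(seq_len(ncol(comb)), function(k) {
    a <- pairs[[paste0("weight_", comb[1, k])]]
    b <- pairs[[paste0("weight_", comb[2, k])]]
    data.frame(epoch_a = comb[1, k], epoch_b = comb[2, k],
               mean_shift = mean(b - a),
               p_shift = stats::wilcox.test(a, b, paired = TRUE)$p.value,
               pearson_r = stats::cor(a, b),
               stringsAsFactors = FALSE)
  }))
  list(tables = tables, pairs = pairs, comparison = comparison,
       dropped_trials = vapply(res, function(r) r$dropped, numeric(1)))
}

#' Fit a 1D circular Gaussian tuning curve
#'
#' Least-squares fit of `baseline + amplitude * exp(-d(theta, mu)^2 / (2 w^2))`
#' with `d` the circular angular distance in degrees, to per-trial (or
#' per-angle-bin) responses.
#'
#' @param angle Target angles in degrees.
#' @param rate Responses in spikes/s.
#' @return Object of class `tuning_fit`: `preferred_angle` (deg, in
#'   `[0, 360)`), `width` (deg), `amplitude`, `baseline`, `r2`, `reliable`
#'   (FALSE for near-flat responses).
#' @export
fit_tuning_curve <- function(angle, rate) {
  if (length(unique(round(angle))) < 4)
    stopf("tuning fit needs responses at >= 4 target angles")
  df <- data.frame(th = angle, y = rate)
  best <- NULL
  for (mu0 in seq(0, 315, by = 45)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + a * exp(-(pmin(abs(th - mu) %% 360,
                               360 - abs(th - mu) %% 360))^2 / (2 * w^2)),
        data = df,
        start = list(b = min(rate), a = diff(range(rate)), mu = mu0, w = 40),
        lower = c(-Inf, -Inf, -360, 5), upper = c(Inf, Inf, 720, 180),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stopf("tuning curve fit failed")
  cf <- stats::coef(best$fit)
  sst <- sum((rate - mean(rate))^2)
  r2 <- if (sst > 0) 1 - best$rss / sst else 0
  amp <- unname(cf["a"])
  reliable <- is.finite(amp) && abs(amp) > 0.05 * max(abs(rate), 1) && r2 > 0.05
  structure(list(preferred_angle = unname(cf["mu"]) %% 360,
                 width = unname(cf["w"]), amplitude = amp,
                 baseline = unname(cf["b"]), r2 = r2, reliable = reliable),
            class = "tuning_fit")
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf("tuning_fit: preferred %.0f deg, width %.0f deg, amplitude %.1f (%s)\n",
              x$preferred_angle, x$width, x$amplitude,
              if (x$reliable) "reliable" else "unreliable"))
  invisible(x)
}

#' Spatial tuning of every unit from target-epoch responses
#'
#' Per-trial mean rate in a window after target onset, regressed on target
#' angle with [fit_tuning_curve()].
#'
#' @param binned A `binned_session`.
#' @param window Response window in seconds relative to target onset
#'   (default `c(0, 0.3)`).
#' @return Named list of `tuning_fit`s by unit id.
#' @export
unit_tuning <- function(binned, window = c(0, 0.3)) {
  tr <- binned$trials
  dt <- binned$bin_width
  angle <- (atan2(tr$target_y, tr$target_x) * 180 / pi) %% 360
  fits <- lapply(seq_len(nrow(binned$units)), function(ui) {
    rate <- vapply(seq_len(nrow(tr)), function(j) {
      b0 <- floor((tr$target_on[j] + window[1]) / dt) + 1L
      b1 <- min(floor((tr$target_on[j] + window[2]) / dt),
                nrow(binned$counts[[j]]))
      sum(binned$counts[[j]][b0:b1, ui]) / ((b1 - b0 + 1) * dt)
    }, numeric(1))
    fit_tuning_curve(angle, rate)
  })
  names(fits) <- binned$units$unit_id
  fits
}

#' Coupling strength as a function of tuning similarity
#'
#' Bins directed pairs by the circular distance between the preferred angles
#' of their 1D tuning curves and reports the mean coupling weight per bin.
#'
#' @param stats Coupling table ([coupling_table()]).
#' @param tunings Named list of `tuning_fit`s ([unit_tuning()]).
#' @param breaks Tuning-distance bin edges in degrees
#'   (default `c(0, 45, 90, 135, 180)`).
#' @param reliable_only Drop pairs with an unreliable tuning fit (default
#'   `TRUE`).
#' @return Data frame: `bin` (label), `mid` (deg), `n_pairs`, `mean_weight`.
#' @export
coupling_vs_tuning <- function(stats, tunings,
                               breaks = c(0, 45, 90, 135, 180),
                               reliable_only = TRUE) {
  pref <- vapply(tunings, function(t) t$preferred_angle, numeric(1))
  rel <- vapply(tunings, function(t) isTRUE(t$reliable), logical(1))
  d <- ang_dist(pref[stats$from], pref[stats$to])
  keep <- if (reliable_only) rel[stats$from] & rel[stats$to] else
    rep(TRUE, nrow(stats))
  bin <- cut(d[keep], breaks, include.lowest = TRUE)
  w <- stats$weight[keep]
  mids <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  data.frame(bin = levels(bin), mid = mids,
             n_pairs = as.integer(table(bin)),
             mean_weight = as.numeric(tapply(w, bin, mean)),
             stringsAsFactors = FALSE)
}
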