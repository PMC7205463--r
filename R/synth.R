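#' Generate memory-guided saccade trials
#'
#' Emulates the task's variable event timing and jittered target geometry.
#' In `"task"` style the fixation point leads the target by 1--1.5 s, the
#' target is flashed for 0.2 s, the delay (target off to go signal) is drawn
#' uniformly from 0.5--2 s, and the saccade follows the go signal by
#' 0.15--0.3 s. In `"compact"` style trials are 1 s long with the same target
#' flash but compressed delays — the configuration used for desk-scale
#' recovery studies where total bin count dominates runtime. Target
#' eccentricity is Gaussian (mean 10 deg, SD 5 deg, truncated at 1 deg) with
#' the x/y jitter applied in the visual field; IN_RF/OUT_RF is assigned by
#' target hemifield sign (the receptive-field constellation is taken to be
#' contralateral, at positive x).
#'
#' @param n_trials Number of trials.
#' @param style `"task"` or `"compact"`.
#' @param rf_angle Receptive-field direction in degrees (default 0 = positive
#'   x hemifield).
#' @param fixed_timing If `TRUE`, all trials share identical event times
#'   (exchangeable trials). Trial-permutation nulls are exactly calibrated
#'   only when trials are exchangeable, so calibration studies use this mode.
#' @param seed Optional seed.
#' @return Trials data frame in the session layout.
#' @export
make_trials <- function(n_trials, style = c("task", "compact"),
                        rf_angle = 0, fixed_timing = FALSE, seed = NULL) {
  style <- match.arg(style)
  jit <- function(lo, hi) if (fixed_timing)
    rep((lo + hi) / 2, n_trials) else stats::runif(n_trials, lo, hi)
  with_seed(seed, {
    if (style == "task") {
      fixation_on <- rep(0.1, n_trials)
      target_on <- fixation_on + jit(1.0, 1.5)
      target_off <- target_on + 0.2
      go_signal <- target_off + jit(0.5, 2.0)
      saccade_onset <- go_signal + jit(0.15, 0.3)
      duration <- saccade_onset + 0.3
    } else {
      # compressed 1 s trials; all event times still jittered so task
      # kernels stay mutually identifiable
      fixation_on <- rep(0.05, n_trials)
      target_on <- jit(0.1, 0.3)
      target_off <- target_on + 0.2
      go_signal <- jit(0.72, 0.88)
      saccade_onset <- go_signal + 0.1
      duration <- rep(1.0, n_trials)
    }
    cond <- sample(c("IN_RF", "OUT_RF"), n_trials, replace = TRUE)
    ecc <- pmax(stats::rnorm(n_trials, 10, 5), 1)
    ang <- rf_angle + ifelse(cond == "IN_RF", 0, 180) +
      stats::rnorm(n_trials, 0, 15)
    data.frame(fixation_on = fixation_on, target_on = target_on,
               target_off = target_off, go_signal = go_signal,
               saccade_onset = saccade_onset,
               target_x = ecc * cospi(ang / 180),
               target_y = ecc * sinpi(ang / 180),
               condition = cond, duration = duration, valid = TRUE)
  })
}

#' Kernel libraries for the ground-truth generator
#'
#' Shape generators for each kernel class, drawing their randomness from the
#' current RNG stream: a transient-plus-sustained visual response for the
#' target, a peri-saccadic Gaussian bump, a refractory-plus-slow history
#' kernel, and an exponentially decaying coupling kernel. All shapes are in
#' log-gain units per ms bin. The arguments are uniform draw ranges, so named
#' scenarios (e.g. strongly modulated units, fast strong coupling) are just
#' explicit parameter choices.
#'
#' @param target_in_amp,target_in_sus Transient amplitude and sustained
#'   (delay-period) amplitude ranges for IN_RF targets.
#' @param target_out_amp Transient amplitude range for OUT_RF targets (the
#'   sustained component is 0 out of the receptive field).
#' @param target_peak_ms Transient peak latency range.
#' @param saccade_amp Peri-saccadic amplitude range.
#' @param history_slow Slow history amplitude range (negative = adaptation,
#'   positive = burstiness); the fast refractory component is fixed at -5
#'   log-gain with a 3 ms decay.
#' @param coupling_tau Coupling kernel decay-constant range in ms.
#' @return Named list of functions `target(lags_ms, cond)`,
#'   `saccade(lags_ms, center_ms)`, `history(lags_ms)`,
#'   `coupling(lags_ms, amp)`.
#' @export
kernel_library <- function(target_in_amp = c(1.0, 1.8),
                           target_in_sus = c(0.2, 0.6),
                           target_out_amp = c(-0.2, 0.4),
                           target_peak_ms = c(50, 90),
                           saccade_amp = c(0.6, 1.4),
                           history_slow = c(-0.4, 0.1),
                           coupling_tau = c(30, 120)) {
  ru <- function(r) stats::runif(1, r[1], r[2])
  list(
    target = function(lags_ms, cond = "IN_RF") {
      amp <- if (cond == "OUT_RF") ru(target_out_amp) else ru(target_in_amp)
      sus <- if (cond == "OUT_RF") 0 else ru(target_in_sus)
      tp <- ru(target_peak_ms)
      amp * (lags_ms / tp) * exp(1 - lags_ms / tp) +
        sus * exp(-lags_ms / 400)
    },
    saccade = function(lags_ms, center_ms = 400) {
      ru(saccade_amp) * exp(-(lags_ms - center_ms)^2 / (2 * 60^2))
    },
    history = function(lags_ms) {
      -5 * exp(-lags_ms / 3) + ru(history_slow) * exp(-lags_ms / 80)
    },
    coupling = function(lags_ms, amp) {
      amp * exp(-lags_ms / ru(coupling_tau))
    }
  )
}

#' @rdname kernel_library
#' @export
default_kernel_library <- function() kernel_library()

#' Construct a ground-truth population model
#'
#' Builds a valid `population_fit` with known kernels, for parameter-recovery
#' and calibration studies: kernels are drawn from a kernel library,
#' projected onto the model bases (so the truth lies exactly in the model
#' class), and baselines are adjusted by a stationarity correction so the
#' realized mean rates land near the nominal ones despite recurrent drive.
#' Coupling amplitudes are configurable per directed area interaction,
#' emulating e.g. stronger local (within-area) functional connectivity.
#'
#' @param n_units Number of units.
#' @param areas Area labels per unit (recycled; default half LIP, half FEF).
#' @param spec A `model_spec` (terms without ground truth get no kernels).
#' @param kernel_library See [default_kernel_library()].
#' @param rates Nominal mean rates in spikes/s (recycled; default drawn
#'   uniformly from 8--25).
#' @param coupling_prob Probability that a directed pair is truly coupled
#'   (default 0.35).
#' @param coupling_amp Named list of amplitude ranges (log-gain at lag 1) per
#'   interaction class; see Details for defaults.
#' @param inhib_frac Fraction of coupled pairs that are inhibitory
#'   (default 0.25).
#' @param min_incoming Minimum number of truly coupled inputs per unit
#'   (default 0); extra partners are promoted at random until every unit has
#'   at least this in-degree, so "coupled data" can be made to mean every
#'   unit is coupled.
#' @param stability_budget Cap on each unit's total incoming excitatory
#'   coupling gain, measured as \eqn{\sum_i r_i \Delta \sum_t [c_{ij}]_+} at
#'   the nominal rates (default 0.5). Draws exceeding the cap have all their
#'   incoming kernels scaled down to it. With the exponential link, recurrent
#'   excitation is explosive once this loop gain approaches 1, so the cap
#'   guarantees stable sessions for any random draw.
#' @param seed Optional seed.
#' @return A `population_fit` with attribute `truth = TRUE`; element
#'   `coupled_pairs` lists the truly coupled directed pairs.
#' @details Default peak log-gain amplitude ranges: within-area 0.12--0.3
#'   (LIP-LIP) and 0.1--0.25 (FEF-FEF), between-area 0.06--0.15, SYNTH-SYNTH
#'   0.1--0.25 — stronger local than long-range functional connectivity, at
#'   per-pair gains small enough that recurrent excitation stays stable at
#'   realistic ensemble sizes (5--20 units).
#' @export
make_ground_truth_population <- function(n_units, areas = NULL,
                                         spec = model_spec(),
                                         kernel_library = default_kernel_library(),
                                         rates = NULL,
                                         coupling_prob = 0.35,
                                         coupling_amp = NULL,
                                         inhib_frac = 0.25,
                                         min_incoming = 0,
                                         stability_budget = 0.5,
                                         seed = NULL) {
  areas <- rep_len(areas %||% rep(c("LIP", "FEF"),
                                  c(ceiling(n_units / 2),
                                    floor(n_units / 2))), n_units)
  coupling_amp <- coupling_amp %||% list(
    "LIP-LIP" = c(0.12, 0.3), "FEF-FEF" = c(0.1, 0.25),
    "LIP-FEF" = c(0.06, 0.15), "FEF-LIP" = c(0.06, 0.15),
    "SYNTH-SYNTH" = c(0.1, 0.25))
  units <- data.frame(unit_id = sprintf("u%02d", seq_len(n_units)),
                      area = areas, channel = seq_len(n_units),
                      stringsAsFactors = FALSE)
  bases <- spec_bases(spec)
  conds <- if (spec$condition_split) c("IN_RF", "OUT_RF") else "all"

  with_seed(seed, {
    rates <- rep_len(rates %||% stats::runif(n_units, 8, 25), n_units)
    dt <- spec$bin_width
    fits <- list()
    coup_kern <- vector("list", n_units)  # [[j]][[i]] kernel i -> j
    coupled <- list()
    for (j in seq_len(n_units)) {
      w <- list()
      if ("target" %in% spec$include_terms)
        for (cn in conds)
          w[[paste0("target_", cn)]] <- project_kernel(
            bases$task, kernel_library$target(bases$task$lags_ms, cn))
      if ("saccade" %in% spec$include_terms)
        for (cn in conds)
          w[[paste0("saccade_", cn)]] <- project_kernel(
            bases$task,
            kernel_library$saccade(bases$task$lags_ms, spec$saccade_pre_ms))
      if ("history" %in% spec$include_terms)
        w[["history"]] <- project_kernel(
          bases$hist, kernel_library$history(bases$hist$lags_ms))
      if ("coupling" %in% spec$include_terms) {
        coup_kern[[j]] <- vector("list", n_units)
        partners <- setdiff(seq_len(n_units), j)
        chosen <- partners[stats::runif(length(partners)) < coupling_prob]
        short <- min(min_incoming, length(partners)) - length(chosen)
        if (short > 0)
          chosen <- c(chosen, sample(setdiff(partners, chosen), short))
        for (i in partners) {
          key <- paste0("coupling:", units$unit_id[i])
          if (i %in% chosen) {
            cls <- classify_interaction(areas[i], areas[j])
            rng <- coupling_amp[[cls]]
            amp <- stats::runif(1, rng[1], rng[2])
            if (stats::runif(1) < inhib_frac) amp <- -amp
            kern <- kernel_library$coupling(bases$hist$lags_ms, amp)
            w[[key]] <- project_kernel(bases$hist, kern)
            coup_kern[[j]][[i]] <- reconstruct_kernel(bases$hist, w[[key]])
            coupled[[length(coupled) + 1L]] <- data.frame(
              from = units$unit_id[i], to = units$unit_id[j],
              interaction = cls, amp = amp, stringsAsFactors = FALSE)
          } else {
            w[[key]] <- numeric(bases$hist$n_basis)
          }
        }
      }
      fits[[units$unit_id[j]]] <- structure(
        list(unit_id = units$unit_id[j], b = log(rates[j] * dt),
             weights = w, spec = spec),
        class = "neuron_fit")
    }
    # stability cap on incoming excitatory coupling gain
    if ("coupling" %in% spec$include_terms) {
      coupled_df <- if (length(coupled)) do.call(rbind, coupled) else NULL
      for (j in seq_len(n_units)) {
        gain_j <- 0
        for (i in seq_len(n_units))
          if (!is.null(coup_kern[[j]][[i]]))
            gain_j <- gain_j + rates[i] * dt * sum(pmax(coup_kern[[j]][[i]], 0))
        if (gain_j > stability_budget) {
          sc <- stability_budget / gain_j
          for (i in seq_len(n_units)) {
            if (is.null(coup_kern[[j]][[i]])) next
            key <- paste0("coupling:", units$unit_id[i])
            fits[[j]]$weights[[key]] <- fits[[j]]$weights[[key]] * sc
            coup_kern[[j]][[i]] <- coup_kern[[j]][[i]] * sc
            if (!is.null(coupled_df)) {
              sel <- coupled_df$to == units$unit_id[j] &
                coupled_df$from == units$unit_id[i]
              coupled_df$amp[sel] <- coupled_df$amp[sel] * sc
            }
          }
        }
      }
      coupled <- coupled_df
    } else if (length(coupled)) coupled <- do.call(rbind, coupled)
    # stationarity correction: subtract the expected recurrent log drive at
    # the nominal rates so realized rates stay near nominal
    for (j in seq_len(n_units)) {
      shift <- 0
      if ("history" %in% spec$include_terms)
        shift <- shift + rates[j] * dt *
          sum(reconstruct_kernel(bases$hist, fits[[j]]$weights$history))
      if ("coupling" %in% spec$include_terms)
        for (i in seq_len(n_units))
          if (!is.null(coup_kern[[j]][[i]]))
            shift <- shift + rates[i] * dt * sum(coup_kern[[j]][[i]])
      fits[[j]]$b <- fits[[j]]$b - shift
    }
    structure(list(fits = fits, spec = spec, units = units,
                   rates = rates,
                   coupled_pairs = if (is.data.frame(coupled)) coupled else
                     if (length(coupled)) do.call(rbind, coupled) else NULL,
                   truth = TRUE),
              class = "population_fit")
  })
}

# per-trial task drive (log per-bin counts) for all units of a population fit
task_drive_matrix <- function(popfit, trial, n_bins, bases) {
  spec <- popfit$spec
  dt <- spec$bin_width
  n <- length(popfit$fits)
  drive <- matrix(rep(vapply(popfit$fits, function(f) f$b, numeric(1)),
                      each = n_bins), n_bins, n)
  add_event <- function(drive, kernel_name_stem, e_t) {
    key <- if (spec$condition_split)
      paste0(kernel_name_stem, "_", trial$condition) else
        paste0(kernel_name_stem, "_all")
    e_bin <- max(0L, floor(e_t / dt))
    if (e_bin >= n_bins) return(drive)
    for (ui in seq_len(n)) {
      wts <- popfit$fits[[ui]]$weights[[key]]
      if (is.null(wts)) next
      kern <- reconstruct_kernel(bases$task, wts)
      idx <- e_bin + seq_along(kern)
      keep <- idx <= n_bins
      drive[idx[keep], ui] <- drive[idx[keep], ui] + kern[keep]
    }
    drive
  }
  if ("target" %in% spec$include_terms)
    drive <- add_event(drive, "target", trial$target_on)
  if ("saccade" %in% spec$include_terms)
    drive <- add_event(drive, "saccade",
                       trial$saccade_onset - spec$saccade_pre_ms / 1000)
  drive
}

# deterministic placement of y spikes inside bin t (0-based): strictly
# sorted, strictly inside the bin, stable under microsecond rounding
counts_to_times <- function(counts, bin_width) {
  bins <- which(counts > 0L)
  if (!length(bins)) return(numeric(0))
  unlist(lapply(bins, function(t) {
    y <- counts[t]
    (t - 1 + seq_len(y) / (y + 1)) * bin_width
  }), use.names = FALSE)
}

#' Simulate spike trains from a population model
#'
#' Sequential sampling over 1 ms bins: at each bin every neuron's conditional
#' intensity is computed from the task events, its own sampled history and
#' its partners' sampled spikes at lags >= 1 bin, and counts are drawn
#' conditionally Poisson. Deterministic given `seed`. A runaway-rate guard
#' aborts (with a diagnostic) if any per-bin mean exceeds `mu_cap`, which
#' protects against unstable fitted models.
#'
#' @param popfit A `population_fit` (ground truth or fitted; for coupled
#'   simulation all units must share the same spec).
#' @param trials Trials data frame (e.g. from [make_trials()]).
#' @param seed Optional seed.
#' @param mu_cap Per-bin mean abort threshold (default 20, i.e. 20,000
#'   spikes/s at 1 ms bins).
#' @return A `spike_session` with the simulated spike trains.
#' @export
simulate_population <- function(popfit, trials, seed = NULL, mu_cap = 20) {
  stopifnot(inherits(popfit, "population_fit"))
  spec <- popfit$spec
  bases <- spec_bases(spec)
  dt <- spec$bin_width
  n <- length(popfit$fits)
  uids <- names(popfit$fits)
  L <- nrow(bases$hist$B)

  hist_k <- matrix(0, L, n)
  if ("history" %in% spec$include_terms)
    for (ui in seq_len(n)) {
      wts <- popfit$fits[[ui]]$weights$history
      if (!is.null(wts)) hist_k[, ui] <- reconstruct_kernel(bases$hist, wts)
    }
  coup_k <- matrix(0, L, n * n)
  if ("coupling" %in% spec$include_terms)
    for (j in seq_len(n)) for (i in seq_len(n)) {
      if (i == j) next
      wts <- popfit$fits[[j]]$weights[[paste0("coupling:", uids[i])]]
      if (!is.null(wts) && any(wts != 0))
        coup_k[, (i - 1) * n + j] <- reconstruct_kernel(bases$hist, wts)
    }

  with_seed(seed, {
    spikes <- lapply(seq_len(n), function(i) vector("list", nrow(trials)))
    for (tr in seq_len(nrow(trials))) {
      # whole bins only, so sampled spike times always fall inside the trial
      n_bins <- as.integer(floor(trials$duration[tr] / dt + 1e-9))
      drive <- task_drive_matrix(popfit, trials[tr, ], n_bins, bases)
      cnt <- cpp_simulate_trial(drive, hist_k, coup_k, mu_cap)
      for (i in seq_len(n))
        spikes[[i]][[tr]] <- counts_to_times(cnt[, i], dt)
    }
    names(spikes) <- uids
    new_session(popfit$units, trials, spikes,
                metadata = list(generator = "population_glm",
                                seed = seed %||% NA))
  })
}

#' One-call coupled synthetic session
#'
#' Convenience wrapper: draws a ground-truth population, simulates a session,
#' and returns both.
#'
#' @inheritParams make_ground_truth_population
#' @param n_trials Number of trials.
#' @param style Trial style, see [make_trials()].
#' @param seed Master seed (trials, truth and simulation seeds derive from
#'   it).
#' @param ... Passed to [make_ground_truth_population()].
#' @return List with `session` (a `spike_session`) and `truth` (the
#'   generating `population_fit`).
#' @export
simulate_glm_session <- function(n_units, n_trials, spec = model_spec(),
                                 style = "compact", seed = 1, ...) {
  trials <- make_trials(n_trials, style, seed = derive_seed(seed, "trials"))
  truth <- make_ground_truth_population(n_units, spec = spec,
                                        seed = derive_seed(seed, "truth"), ...)
  session <- simulate_population(truth, trials,
                                 seed = derive_seed(seed, "simulate"))
  list(session = session, truth = truth)
}
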