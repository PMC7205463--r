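#' Parameters of the ring bump-attractor network
#'
#' Bundles the parameters of a classic spiking network model of spatial
#' working memory: a ring of conductance-based leaky integrate-and-fire
#' excitatory neurons with NMDA-mediated recurrent excitation whose strength
#' follows a Gaussian profile of the angular distance between preferred
#' directions, a uniform GABAergic inhibitory population, and external
#' Poisson drive through AMPA-type synapses.
#'
#' @param n_excitatory,n_inhibitory Population sizes (defaults 1024 / 256).
#' @param n_extern_poisson Independent external Poisson sources per neuron
#'   (default 1000).
#' @param poisson_rate_hz Rate of each external source (default 1.3 Hz).
#' @param weight_scaling Dimensionless scaling of all recurrent conductances
#'   (default 2.0 at the full size; scale inversely with `n_excitatory` when
#'   shrinking the network so the mean recurrent input is preserved).
#' @param sigma_weight_deg Width of the E-to-E ring profile (default 20).
#' @param j_pos Peak recurrent strength \eqn{J^+} of the E-to-E profile
#'   (default 1.6); the floor \eqn{J^-} follows from the normalization that
#'   the mean connection weight is 1.
#' @param stim_width_deg Angular width of the stimulated arc (default 30).
#' @param stim_strength_namp Stimulus current in nA (default 0.06).
#' @param tau_nmda_ms NMDA decay time constant (default 65 ms).
#' @param trial_len_s Trial duration (default 1 s).
#' @param stim_dur_s Stimulus duration (default 0.2 s).
#' @param stim_onset_range_s Uniform jitter range of the stimulus onset
#'   (default 0.2--0.5 s).
#' @param dt_ms Integration step (default 0.1 ms).
#' @param conductances Named list of maximal synaptic conductances in nS:
#'   `ext2e`, `ext2i` (external AMPA onto E/I), and the recurrent `e2e`
#'   (NMDA, ring-weighted), `e2i` (NMDA, uniform), `i2e`, `i2i` (GABA,
#'   uniform), the last four multiplied by `weight_scaling`. The defaults are
#'   calibrated so the network shows the classic operating regime: a stable
#'   low-rate spontaneous state, a stimulus-triggered bump, and bistability
#'   (bump decay vs persistence) across the `j_pos` range.
#' @param scaled If `TRUE`, a desk-scale variant: 256 excitatory / 64
#'   inhibitory neurons with `weight_scaling` increased by the size ratio so
#'   the mean recurrent input matches the full-size network.
#' @return Object of class `attractor_params`.
#' @export
attractor_params <- function(n_excitatory = 1024, n_inhibitory = 256,
                             n_extern_poisson = 1000, poisson_rate_hz = 1.3,
                             weight_scaling = 2.0, sigma_weight_deg = 20,
                             j_pos = 1.6, stim_width_deg = 30,
                             stim_strength_namp = 0.06, tau_nmda_ms = 65,
                             trial_len_s = 1, stim_dur_s = 0.2,
                             stim_onset_range_s = c(0.2, 0.5), dt_ms = 0.1,
                             conductances = list(), scaled = FALSE) {
  conductances <- utils::modifyList(
    list(ext2e = 2.2, ext2i = 0.6, e2e = 0.381, e2i = 0.6,
         i2e = 0.4, i2i = 0.2), conductances)
  if (scaled) {
    weight_scaling <- weight_scaling * n_excitatory / 256
    n_excitatory <- 256L; n_inhibitory <- 64L
    # finite-size noise in the bump mode grows as the network shrinks; the
    # per-neuron stimulus current is scaled up so the collective stimulus
    # keeps selecting the bump location against that noise
    stim_strength_namp <- stim_strength_namp * 3
  }
  if (j_pos < 0) stopf("j_pos must be >= 0")
  if (sigma_weight_deg <= 0) stopf("sigma_weight_deg must be positive")
  if (n_excitatory < 2 || n_inhibitory < 1) stopf("population sizes too small")
  if (trial_len_s < stim_onset_range_s[2] + stim_dur_s + 0.05)
    stopf("trial_len_s too short for the stimulus protocol (need >= %.2f s)",
          stim_onset_range_s[2] + stim_dur_s + 0.05)
  structure(list(n_excitatory = as.integer(n_excitatory),
                 n_inhibitory = as.integer(n_inhibitory),
                 n_extern_poisson = n_extern_poisson,
                 poisson_rate_hz = poisson_rate_hz,
                 weight_scaling = weight_scaling,
                 sigma_weight_deg = sigma_weight_deg, j_pos = j_pos,
                 stim_width_deg = stim_width_deg,
                 stim_strength_namp = stim_strength_namp,
                 tau_nmda_ms = tau_nmda_ms, trial_len_s = trial_len_s,
                 stim_dur_s = stim_dur_s,
                 stim_onset_range_s = stim_onset_range_s, dt_ms = dt_ms,
                 conductances = conductances),
            class = "attractor_params")
}

#' @export
print.attractor_params <- function(x, ...) {
  cat(sprintf("attractor_params: %d E / %d I, J+ = %g, sigma = %g deg, tau_NMDA = %g ms\n",
              x$n_excitatory, x$n_inhibitory, x$j_pos, x$sigma_weight_deg,
              x$tau_nmda_ms))
  invisible(x)
}

#' Build the ring network description
#'
#' Computes the preferred angles, the E-to-E ring weight profile
#' \deqn{w(\Delta\theta) = J^- + (J^+ - J^-)\exp(-\Delta\theta^2/(2\sigma^2))}
#' with \eqn{J^-} chosen so the mean connection weight over the ring is
#' exactly 1, and the full weight matrix used by the integrator.
#'
#' @param params An `attractor_params`.
#' @return List: `angles_deg` (preferred angles of the excitatory neurons),
#'   `w_profile` (weight vs angular offset), `j_neg`, `W_ee` (weight matrix),
#'   `params`.
#' @export
build_network <- function(params) {
  stopifnot(inherits(params, "attractor_params"))
  nE <- params$n_excitatory
  angles <- (seq_len(nE) - 1) * 360 / nE
  dtheta <- ang_dist(angles, angles[1])
  g <- exp(-dtheta^2 / (2 * params$sigma_weight_deg^2))
  gbar <- mean(g)
  j_neg <- (1 - params$j_pos * gbar) / (1 - gbar)
  if (j_neg < 0)
    stopf(paste("infeasible ring profile: J+ = %g with sigma = %g deg needs",
                "J- = %.3f < 0 to keep the mean connection weight at 1;",
                "reduce J+ or sigma"), params$j_pos, params$sigma_weight_deg,
          j_neg)
  w_profile <- j_neg + (params$j_pos - j_neg) * g
  # circulant weight matrix: W[i, j] = w(theta_i - theta_j)
  idx <- outer(seq_len(nE), seq_len(nE), function(i, j) ((i - j) %% nE) + 1L)
  W <- matrix(w_profile[idx], nE, nE)
  list(angles_deg = angles, w_profile = w_profile, j_neg = j_neg, W_ee = W,
       params = params)
}

#' Population-vector persistence readout
#'
#' Circular mean of preferred angles weighted by spiking in a window, with
#' the resultant amplitude measuring how concentrated the bump is. A trial
#' counts as sustained when the amplitude exceeds `threshold` over the window
#' AND the readout angle lies within the stimulus arc.
#'
#' @param spike_t_ms,spike_angle_deg Spike times and the preferred angles of
#'   the spiking neurons.
#' @param window_ms Readout window (default the final 200 ms of a 1 s trial).
#' @param stim_center_deg Stimulus center for the angle check.
#' @param stim_width_deg Allowed deviation of the readout from the stimulus
#'   center (default 30).
#' @param threshold Amplitude threshold (default 0.2).
#' @return List: `bump_sustained`, `readout_angle`, `readout_amplitude`,
#'   `n_spikes`.
#' @export
detect_persistence <- function(spike_t_ms, spike_angle_deg,
                               window_ms = c(800, 1000), stim_center_deg,
                               stim_width_deg = 30, threshold = 0.2) {
  if (diff(window_ms) <= 0) stopf("empty persistence window")
  sel <- spike_t_ms >= window_ms[1] & spike_t_ms < window_ms[2]
  n <- sum(sel)
  if (n == 0)
    return(list(bump_sustained = FALSE, readout_angle = NA_real_,
                readout_amplitude = 0, n_spikes = 0L))
  th <- spike_angle_deg[sel] * pi / 180
  z <- complex(real = mean(cos(th)), imaginary = mean(sin(th)))
  amp <- Mod(z)
  ang <- (Arg(z) * 180 / pi) %% 360
  sustained <- amp > threshold && ang_dist(ang, stim_center_deg) <= stim_width_deg
  list(bump_sustained = sustained, readout_angle = ang,
       readout_amplitude = amp, n_spikes = as.integer(n))
}

#' Simulate a session of attractor-network trials
#'
#' Per trial, a stimulus center is drawn uniformly on the ring, the onset is
#' jittered within the configured range, and a current is injected into the
#' stimulated arc of excitatory neurons for the stimulus duration. The spike
#' times of a fixed random sample of excitatory neurons are exported as a
#' `spike_session` (the sample stays the same across all trials of the
#' session). IN_RF/OUT_RF labels are assigned by proximity of the stimulus
#' to the sampled ensemble's mean preferred angle. Deterministic given
#' `seed`, including the external Poisson streams.
#'
#' @param params An `attractor_params`.
#' @param n_trials Trials per session (default 500).
#' @param n_sampled Size of the exported ensemble (default 20).
#' @param sample_arc_deg Width of the ring arc the ensemble is sampled from
#'   (default 40). Like a real recording, the exported units share a
#'   receptive-field constellation, which is what makes the IN_RF/OUT_RF
#'   condition split meaningful; use 360 for uniform sampling.
#' @param seed Integer seed.
#' @return A `spike_session`; `metadata` records the sampled neuron angles,
#'   per-trial stimulus centers and persistence readouts
#'   ([detect_persistence()] over the full excitatory population).
#' @export
simulate_attractor_session <- function(params, n_trials = 500,
                                       n_sampled = 20, sample_arc_deg = 40,
                                       seed = 1) {
  net <- build_network(params)
  nE <- params$n_excitatory
  trial_ms <- params$trial_len_s * 1000
  with_seed(seed, {
    arc_center <- stats::runif(1, 0, 360)
    pool <- which(ang_dist(net$angles_deg, arc_center) <= sample_arc_deg / 2)
    if (length(pool) < n_sampled)
      stopf("sampling arc of %g deg holds only %d of the requested %d units",
            sample_arc_deg, length(pool), n_sampled)
    sampled <- sort(sample(pool, n_sampled))
    samp_angle <- net$angles_deg[sampled]
    ens_mean <- (Arg(sum(exp(1i * samp_angle * pi / 180))) * 180 / pi) %% 360

    spikes <- lapply(seq_len(n_sampled), function(i) vector("list", n_trials))
    stim_center <- numeric(n_trials)
    persistence <- vector("list", n_trials)
    trials <- data.frame(fixation_on = numeric(n_trials))

    for (tr in seq_len(n_trials)) {
      ctr <- stats::runif(1, 0, 360)
      onset <- stats::runif(1, params$stim_onset_range_s[1],
                            params$stim_onset_range_s[2])
      stim_idx <- which(ang_dist(net$angles_deg, ctr) <
                          params$stim_width_deg / 2) - 1L
      res <- cpp_attractor_trial(net$W_ee, unclass(params),
                                 as.integer(stim_idx),
                                 onset * 1000,
                                 (onset + params$stim_dur_s) * 1000, trial_ms)
      st <- res$spike_t_ms; sid <- res$spike_unit + 1L
      for (k in seq_len(n_sampled)) {
        tt <- st[sid == sampled[k]] / 1000
        # jitter-free dedup: LIF refractoriness guarantees > 1 ms gaps,
        # so times are already strictly sorted per neuron
        spikes[[k]][[tr]] <- tt[tt < params$trial_len_s]
      }
      stim_center[tr] <- ctr
      persistence[[tr]] <- detect_persistence(
        st, net$angles_deg[sid],
        window_ms = c(trial_ms - 200, trial_ms), stim_center_deg = ctr,
        stim_width_deg = params$stim_width_deg, threshold = 0.2)
      trials[tr, c("fixation_on", "target_on", "target_off", "go_signal",
                   "saccade_onset", "duration")] <-
        c(0.01, onset, onset + params$stim_dur_s,
          params$trial_len_s - 0.02, params$trial_len_s - 0.01,
          params$trial_len_s)
    }
    trials$target_x <- 10 * cospi(stim_center / 180)
    trials$target_y <- 10 * sinpi(stim_center / 180)
    trials$condition <- ifelse(ang_dist(stim_center, ens_mean) < 90,
                               "IN_RF", "OUT_RF")
    trials$valid <- TRUE

    units <- data.frame(unit_id = sprintf("e%04d", sampled), area = "SYNTH",
                        channel = seq_len(n_sampled), stringsAsFactors = FALSE)
    names(spikes) <- units$unit_id
    new_session(units, trials, spikes, metadata = list(
      generator = "attractor", seed = seed, j_pos = params$j_pos,
      sampled_index = sampled, sampled_angle = samp_angle,
      stim_center_deg = stim_center,
      sustained = vapply(persistence, function(p) p$bump_sustained,
                         logical(1)),
      readout_amplitude = vapply(persistence,
                                 function(p) p$readout_amplitude,
                                 numeric(1))))
  })
}

#' Sweep the recurrent strength and track the estimated coupling
#'
#' Simulates one session per \eqn{J^+} value (all other parameters held at
#' their defaults), optionally fits the population encoding model to each
#' exported ensemble, and summarizes mean estimated coupling and the fraction
#' of trials with a sustained bump — the coupling-vs-recurrent-strength
#' relationship that lets GLM coupling act as a proxy for attractor
#' connection strength.
#'
#' @param jpos_values Numeric vector of \eqn{J^+} values (>= 3).
#' @param params Base `attractor_params` (its `j_pos` is overridden).
#' @param n_trials,n_sampled Session settings.
#' @param seed Master seed; per-value session seeds derive from it.
#' @param fit_glm Fit the GLM and report mean coupling (default `TRUE`).
#' @param spec `model_spec` for the fits (default: target + history +
#'   coupling with the IN_RF/OUT_RF split, no saccade term — the attractor
#'   trials have no saccade event).
#' @return List: `summary` (data frame `j_pos`, `mean_coupling`,
#'   `sustained_fraction`), `sessions`, `min_persistent_jpos` (smallest value
#'   with sustained fraction > 0.5, `NA` if none).
#' @export
sweep_jpos <- function(jpos_values, params = attractor_params(scaled = TRUE),
                       n_trials = 100, n_sampled = 10, seed = 1,
                       fit_glm = TRUE,
                       spec = model_spec(include_terms = c("target", "history",
                                                           "coupling"),
                                         condition_split = TRUE)) {
  if (length(jpos_values) < 3) stopf("sweep needs >= 3 j_pos values")
  sessions <- list(); rows <- list()
  for (k in seq_along(jpos_values)) {
    p <- params; p$j_pos <- jpos_values[k]
    s <- simulate_attractor_session(p, n_trials = n_trials,
                                    n_sampled = n_sampled,
                                    seed = derive_seed(seed, paste0("jpos", k)))
    mean_coup <- NA_real_
    if (fit_glm) {
      pf <- fit_population(bin_spikes(s, spec$bin_width), spec)
      mean_coup <- mean(coupling_table(pf)$weight)
    }
    sessions[[k]] <- s
    rows[[k]] <- data.frame(j_pos = jpos_values[k], mean_coupling = mean_coup,
                            sustained_fraction = mean(s$metadata$sustained))
  }
  summary <- do.call(rbind, rows)
  persistent <- summary$j_pos[summary$sustained_fraction > 0.5]
  list(summary = summary, sessions = sessions,
       min_persistent_jpos = if (length(persistent)) min(persistent) else
         NA_real_)
}
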