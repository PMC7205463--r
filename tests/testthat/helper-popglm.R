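# shared fixtures, built in code once per test run

# a small coupled synthetic session with known ground truth
fx <- new.env()
fixture_session <- function() {
  if (is.null(fx$sim)) {
    fx$sim <- simulate_glm_session(4, 60, seed = 7)
    fx$binned <- bin_spikes(fx$sim$session)
  }
  fx
}

# hand-built two-unit population with one strong directed coupling A -> B
two_unit_popfit <- function(c_amp = 0.8, c_tau = 40, rates = c(15, 15),
                            spec = model_spec(include_terms = c("history",
                                                                "coupling"),
                                              condition_split = FALSE)) {
  bases <- popglm:::spec_bases(spec)
  hist_w <- project_kernel(bases$hist, -4 * exp(-bases$hist$lags_ms / 3))
  coup_w <- project_kernel(bases$hist,
                           c_amp * exp(-bases$hist$lags_ms / c_tau))
  zero_w <- numeric(bases$hist$n_basis)
  units <- data.frame(unit_id = c("A", "B"), area = c("LIP", "FEF"),
                      channel = 1:2, stringsAsFactors = FALSE)
  mk <- function(uid, partner, cw, rate) structure(
    list(unit_id = uid, b = log(rate * spec$bin_width),
         weights = stats::setNames(list(hist_w, cw),
                                   c("history", paste0("coupling:", partner))),
         spec = spec),
    class = "neuron_fit")
  structure(list(fits = list(A = mk("A", "B", zero_w, rates[1]),
                             B = mk("B", "A", coup_w, rates[2])),
                 spec = spec, units = units),
            class = "population_fit")
}

# plain trials for simulation-only tests (no task kernels needed)
plain_trials <- function(n, duration = 1) {
  data.frame(fixation_on = 0.05, target_on = 0.2, target_off = 0.4,
             go_signal = 0.8, saccade_onset = 0.9,
             target_x = 10, target_y = 0, condition = "IN_RF",
             duration = duration, valid = TRUE)[rep(1, n), ]
}
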