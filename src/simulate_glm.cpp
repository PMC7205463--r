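// Sequential sampler for the coupled population GLM on one trial.
// At each 1 ms bin the per-bin mean of neuron i is
//   mu_i = exp(drive_i), drive = task drive + accumulated history/coupling
// Spike counts are drawn conditionally Poisson; sampled spikes immediately
// feed the future drive of the neuron itself (history kernel) and of its
// partners (coupling kernels), at lags >= 1 bin. Uses R's RNG so results
// are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// task_drive: T x n (baseline + task kernels, in log per-bin counts)
// hist_k:     L x n, column i = history kernel of neuron i (time domain)
// coup_k:     L x (n*n), column (i-1)*n + j = kernel from neuron i to j
//             (zero where no coupling); diagonal columns unused.
// mu_cap:     abort threshold on the per-bin mean (guards runaway fits)
// [[Rcpp::export]]
arma::imat cpp_simulate_trial(const arma::mat& task_drive,
                              const arma::mat& hist_k,
                              const arma::mat& coup_k, double mu_cap) {
  const uword T = task_drive.n_rows, n = task_drive.n_cols,
              L = hist_k.n_rows;
  mat drive = task_drive;  // accumulates recurrent contributions
  imat counts(T, n, fill::zeros);

  for (uword t = 0; t < T; ++t) {
    for (uword i = 0; i < n; ++i) {
      double mu = std::exp(drive(t, i));
      if (mu > mu_cap)
        Rcpp::stop("runaway rate in simulation: per-bin mean %.2f > cap %.2f "
                   "at bin %d, unit %d", mu, mu_cap, (int)t + 1, (int)i + 1);
      int y = (int)R::rpois(mu);
      if (y == 0) continue;
      counts(t, i) = y;
      uword lmax = std::min(L, T - t - 1);
      if (lmax == 0) continue;
      // history of i onto itself
      drive.col(i).subvec(t + 1, t + lmax) +=
          (double)y * hist_k.col(i).head(lmax);
      // coupling from i onto each partner j
      for (uword j = 0; j < n; ++j) {
        if (j == i) continue;
        const vec& ck = coup_k.unsafe_col(i * n + j);
        if (!any(ck)) continue;
        drive.col(j).subvec(t + 1, t + lmax) += (double)y * ck.head(lmax);
      }
    }
  }
  return counts;
}
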