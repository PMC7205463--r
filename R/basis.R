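#' Nonlinearly time-scaled raised-cosine temporal basis
#'
#' Constructs a bank of raised-cosine bumps whose peaks are evenly spaced in
#' log-warped time, so that early lags are finely resolved and late lags
#' coarsely. Column `j` is
#' \deqn{b_j(t) = \tfrac12\,[1 + \cos(u_j(t))], \qquad
#'       u_j(t) = \pi\,(\log(t + \psi) - \phi_j)/\delta}
#' on \eqn{|u_j(t)| \le \pi} and zero elsewhere, where \eqn{\psi} is the warp
#' offset, \eqn{\phi_j} are the warped peak positions and \eqn{\delta} their
#' spacing, chosen so the first peak sits at the first lag of the support and
#' the last column decays to zero at `window_ms`. Columns are normalized to a
#' peak value of exactly 1, so kernel weights read as log-gain amplitudes.
#'
#' These bases parameterize the task-event, spike-history and interneuronal
#' coupling kernels of the population encoding model. Conventional defaults
#' are 8 basis functions over 800 ms for task kernels and 10 over 250 ms for
#' history/coupling kernels. History and coupling bases are strictly causal
#' (`lag0_inclusive = FALSE`): support starts at lag 1 bin, so the current
#' time bin never predicts itself and coupling stays directional.
#'
#' @param n_basis Number of basis functions (>= 2).
#' @param window_ms Duration of the support in ms.
#' @param warp_offset Positive log-warp offset \eqn{\psi} in ms. Smaller
#'   values concentrate resolution at short lags. Default 1.
#' @param lag0_inclusive Logical; if `TRUE` the support includes lag 0
#'   (appropriate for task-event kernels), otherwise it starts at lag 1 bin
#'   (history/coupling).
#' @param bin_ms Bin width of the lag grid in ms (default 1).
#' @return An object of class `cosine_basis`: a list with the basis matrix
#'   `B` (lag bin x basis index), the lag grid `lags_ms`, peak lags
#'   `peaks_ms`, and the construction parameters.
#' @examples
#' hb <- make_raised_cosine_basis(10, 250)          # history/coupling
#' tb <- make_raised_cosine_basis(8, 800, lag0_inclusive = TRUE)  # task
#' matplot(hb$lags_ms, hb$B, type = "l")
#' @export
make_raised_cosine_basis <- function(n_basis, window_ms, warp_offset = 1,
                                     lag0_inclusive = FALSE, bin_ms = 1) {
  if (n_basis < 2) stopf("n_basis must be >= 2 (got %s)", n_basis)
  if (window_ms <= 0) stopf("window_ms must be positive")
  if (warp_offset <= 0) stopf("warp_offset must be positive")

  n_lag <- round(window_ms / bin_ms)
  lags <- if (lag0_inclusive) seq.int(0L, n_lag - 1L) else seq.int(1L, n_lag)
  lags_ms <- lags * bin_ms

  nl <- function(t) log(t + warp_offset)
  t_first <- lags_ms[1]
  delta <- (nl(window_ms) - nl(t_first)) / n_basis
  if (delta <= 0) stopf("window too short for the requested basis")
  phis <- nl(t_first) + (seq_len(n_basis) - 1) * delta

  u <- outer(nl(lags_ms), phis, `-`) * pi / delta
  B <- 0.5 * (1 + cos(pmax(pmin(u, pi), -pi)))

  peak_bin <- apply(B, 2, which.max)
  if (any(diff(peak_bin) < 1))
    stopf("window too short for %d basis functions: peaks are not distinct",
          n_basis)
  # enforce exact peak normalization on the discrete lag grid
  B <- sweep(B, 2, apply(B, 2, max), `/`)

  structure(
    list(B = B, lags_ms = lags_ms, peaks_ms = lags_ms[peak_bin],
         n_basis = n_basis, window_ms = window_ms, warp_offset = warp_offset,
         lag0_inclusive = lag0_inclusive, bin_ms = bin_ms),
    class = "cosine_basis"
  )
}

#' @export
print.cosine_basis <- function(x, ...) {
  cat(sprintf(
    "raised-cosine basis: %d functions over %g ms (warp offset %g ms, lag0 %s)\n",
    x$n_basis, x$window_ms, x$warp_offset,
    if (x$lag0_inclusive) "included" else "excluded"))
  cat("peak lags (ms):", paste(signif(x$peaks_ms, 3), collapse = " "), "\n")
  invisible(x)
}

#' Reconstruct a time-domain kernel from basis weights
#'
#' Maps a weight vector back to the time domain: `kernel(t) = sum_j w_j B[t, j]`,
#' the per-bin log-gain over the basis support.
#'
#' @param basis A `cosine_basis`.
#' @param weights Numeric vector of length `basis$n_basis`.
#' @return Numeric vector over `basis$lags_ms`.
#' @export
reconstruct_kernel <- function(basis, weights) {
  stopifnot(inherits(basis, "cosine_basis"))
  if (length(weights) != basis$n_basis)
    stopf("expected %d weights, got %d", basis$n_basis, length(weights))
  drop(basis$B %*% weights)
}

#' Project a time-domain kernel onto a basis
#'
#' Least-squares projection onto the span of the basis columns; the inverse
#' of [reconstruct_kernel()] for kernels inside the span. Used by the
#' ground-truth generators so that true kernels are exactly representable.
#'
#' @param basis A `cosine_basis`.
#' @param kernel Numeric vector over `basis$lags_ms`.
#' @return Weight vector of length `basis$n_basis`.
#' @export
project_kernel <- function(basis, kernel) {
  stopifnot(inherits(basis, "cosine_basis"))
  if (length(kernel) != nrow(basis$B))
    stopf("kernel length %d does not match the %d-bin basis support",
          length(kernel), nrow(basis$B))
  qr.solve(basis$B, kernel)
}

#' Convolve an event train with a basis
#'
#' Produces the design-matrix columns for one predictor on one trial:
#' column `j` at bin `t` is `sum_tau event[t - tau] * B[tau, j]`, with `tau`
#' running over the basis lag grid. The convolution is causal under the
#' basis' lag convention and never crosses trial boundaries (each trial is
#' convolved independently, so history and coupling columns are zero over
#' each trial's first lags).
#'
#' @param event_train Numeric vector of per-bin event or spike counts for a
#'   single trial, on the same bin grid as the basis (`basis$bin_ms`).
#' @param basis A `cosine_basis`.
#' @return Matrix `length(event_train)` x `basis$n_basis`.
#' @export
basis_convolve <- function(event_train, basis) {
  stopifnot(inherits(basis, "cosine_basis"))
  n_t <- length(event_train)
  out <- matrix(0, n_t, basis$n_basis)
  if (n_t == 0 || !any(event_train != 0)) return(out)
  # full-length kernels including the lag offset (0 rows before support)
  lag0 <- basis$lags_ms[1] / basis$bin_ms
  k_len <- lag0 + nrow(basis$B)
  nfft <- stats::nextn(n_t + k_len, 2)
  fx <- stats::fft(c(event_train, numeric(nfft - n_t)))
  for (j in seq_len(basis$n_basis)) {
    kj <- c(numeric(lag0), basis$B[, j], numeric(nfft - k_len))
    conv <- Re(stats::fft(fx * stats::fft(kj), inverse = TRUE)) / nfft
    out[, j] <- conv[seq_len(n_t)]
  }
  # FFT round-off: snap exact zeros where no event could have contributed
  out[abs(out) < 1e-12] <- 0
  out
}
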