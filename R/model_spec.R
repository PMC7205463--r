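#' Specify a population encoding model
#'
#' Defines which predictor classes enter the conditional intensity
#' \deqn{\lambda_t = \exp(k * x_t + h * r_{t-1} + c * s_t + b)/\Delta}
#' and how each is parameterized: task-event kernels (`target`, `saccade`)
#' on a raised-cosine basis (conventionally 8 functions over 800 ms),
#' the neuron's own spike-history kernel and the interneuronal coupling
#' kernels (10 functions over 250 ms, strictly causal at lags >= 1 bin).
#'
#' @param include_terms Subset of `c("target", "saccade", "history",
#'   "coupling")`.
#' @param task_basis List `(n_basis, window_ms, warp_offset)` for the task
#'   kernels.
#' @param hist_basis List `(n_basis, window_ms, warp_offset)` for history and
#'   coupling kernels.
#' @param condition_split Fit separate IN_RF/OUT_RF task kernels jointly in
#'   one model (default `TRUE`).
#' @param saccade_pre_ms Lead time in ms by which the saccade event delta is
#'   shifted earlier, so the saccade kernel covers pre-saccadic bins
#'   (default 400: an 800 ms kernel spans -400..+400 ms around saccade
#'   onset).
#' @param ridge_strength Non-negative ridge penalty multiplying
#'   \eqn{\|k\|^2 + \|h\|^2 + \|c\|^2}; the baseline `b` is never penalized.
#' @param bin_width Time bin in seconds (default 0.001).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(include_terms = c("target", "saccade", "history",
                                         "coupling"),
                       task_basis = list(n_basis = 8, window_ms = 800,
                                         warp_offset = 1),
                       hist_basis = list(n_basis = 10, window_ms = 250,
                                         warp_offset = 1),
                       condition_split = TRUE,
                       saccade_pre_ms = 400,
                       ridge_strength = 1,
                       bin_width = 0.001) {
  include_terms <- match.arg(include_terms,
                             c("target", "saccade", "history", "coupling"),
                             several.ok = TRUE)
  if (ridge_strength < 0) stopf("ridge_strength must be >= 0")
  if (bin_width <= 0) stopf("bin_width must be positive")
  structure(list(include_terms = include_terms, task_basis = task_basis,
                 hist_basis = hist_basis, condition_split = condition_split,
                 saccade_pre_ms = saccade_pre_ms,
                 ridge_strength = ridge_strength, bin_width = bin_width),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", paste(x$include_terms, collapse = " + "),
      if (x$condition_split) "(IN_RF/OUT_RF split)" else "", "\n")
  cat(sprintf("  task basis %d/%g ms, history/coupling basis %d/%g ms, ridge %g\n",
              x$task_basis$n_basis, x$task_basis$window_ms,
              x$hist_basis$n_basis, x$hist_basis$window_ms, x$ridge_strength))
  invisible(x)
}

# materialize the two bases of a spec on its bin grid
spec_bases <- function(spec) {
  bm <- spec$bin_width * 1000
  list(
    task = make_raised_cosine_basis(spec$task_basis$n_basis,
                                    spec$task_basis$window_ms,
                                    spec$task_basis$warp_offset %||% 1,
                                    lag0_inclusive = TRUE, bin_ms = bm),
    hist = make_raised_cosine_basis(spec$hist_basis$n_basis,
                                    spec$hist_basis$window_ms,
                                    spec$hist_basis$warp_offset %||% 1,
                                    lag0_inclusive = FALSE, bin_ms = bm)
  )
}

#' Precompute per-trial design blocks for a session
#'
#' Computes, once per session, the task-event columns (shared by all fitted
#' neurons) and each unit's spike train convolved with the history/coupling
#' basis (reused as the history block of that unit and the coupling block of
#' every other unit, and reassembled under trial permutations for the null).
#'
#' @param binned A `binned_session`.
#' @param spec A `model_spec`.
#' @return Object of class `design_cache`.
#' @export
design_cache <- function(binned, spec) {
  stopifnot(inherits(binned, "binned_session"), inherits(spec, "model_spec"))
  if (abs(binned$bin_width - spec$bin_width) > 1e-12)
    stopf("binned session uses %g s bins but spec declares %g s",
          binned$bin_width, spec$bin_width)
  bases <- spec_bases(spec)
  tr <- binned$trials
  dt <- spec$bin_width
  trials_used <- which(tr$valid)
  n_units <- nrow(binned$units)

  task_names <- character(0)
  task_blocks <- NULL
  if (any(c("target", "saccade") %in% spec$include_terms)) {
    events <- intersect(c("target", "saccade"), spec$include_terms)
    conds <- if (spec$condition_split) c("IN_RF", "OUT_RF") else "all"
    # names in the same (event-major) order the blocks are filled below
    task_names <- as.vector(t(outer(events, conds, paste, sep = "_")))
    task_blocks <- lapply(trials_used, function(j) {
      nb <- nrow(binned$counts[[j]])
      blk <- matrix(0, nb, length(task_names) * bases$task$n_basis)
      col0 <- 0L
      for (ev in events) for (cond in conds) {
        if (cond == "all" || tr$condition[j] == cond) {
          e_t <- if (ev == "target") tr$target_on[j] else
            tr$saccade_onset[j] - spec$saccade_pre_ms / 1000
          e_bin <- max(0L, floor(e_t / dt))
          delta <- numeric(nb)
          if (e_bin < nb) delta[e_bin + 1L] <- 1
          blk[, col0 + seq_len(bases$task$n_basis)] <-
            basis_convolve(delta, bases$task)
        }
        col0 <- col0 + bases$task$n_basis
      }
      blk
    })
  }

  spk_conv <- NULL
  if (any(c("history", "coupling") %in% spec$include_terms)) {
    spk_conv <- lapply(seq_len(n_units), function(i)
      lapply(trials_used, function(j)
        basis_convolve(binned$counts[[j]][, i], bases$hist)))
  }

  structure(list(task_blocks = task_blocks, task_names = task_names,
                 spk_conv = spk_conv, trials_used = trials_used,
                 n_bins = vapply(trials_used,
                                 function(j) nrow(binned$counts[[j]]),
                                 integer(1)),
                 units = binned$units, trials = tr, bases = bases,
                 spec = spec, bin_width = dt,
                 counts = binned$counts),
            class = "design_cache")
}

# take the first min(n, nrow) rows of m, zero-padding to n rows (used when a
# permuted partner trial is shorter/longer than the fitted neuron's trial)
crop_pad <- function(m, n) {
  if (nrow(m) == n) return(m)
  out <- matrix(0, n, ncol(m))
  k <- min(n, nrow(m))
  out[seq_len(k), ] <- m[seq_len(k), ]
  out
}

#' Build the design matrix for one fitted neuron
#'
#' Assembles, from a [design_cache()], the full design matrix for the target
#' unit: task-event columns (split by IN_RF/OUT_RF when the spec says so),
#' the unit's own spike history at lags >= 1 bin, and one coupling block per
#' partner unit at lags >= 1 bin. Rows are the concatenated bins of the valid
#' trials; no row mixes bins from two trials and convolutions never cross
#' trial boundaries.
#'
#' @param cache A `design_cache` (or a `binned_session`, from which a cache
#'   is built on the fly).
#' @param target_unit Unit id of the fitted neuron.
#' @param spec Optional `model_spec`; defaults to the cache's spec. May only
#'   restrict `include_terms` relative to the cache.
#' @param partner_perm Optional: integer matrix (n trials used x n units) of
#'   permuted trial indices per predictor unit, used by the permutation null.
#' @return Object of class `glm_design`: `X` (dense matrix, no intercept
#'   column), `y` (counts of the target unit), `column_map` (predictor ->
#'   column indices), `trial_id` and `bin_in_trial` per row.
#' @export
build_design <- function(cache, target_unit, spec = NULL,
                         partner_perm = NULL) {
  if (inherits(cache, "binned_session"))
    cache <- design_cache(cache, spec %||% model_spec())
  stopifnot(inherits(cache, "design_cache"))
  spec <- spec %||% cache$spec
  ti <- match(target_unit, cache$units$unit_id)
  if (is.na(ti)) stopf("unknown unit '%s'", target_unit)
  n_units <- nrow(cache$units)
  if ("coupling" %in% spec$include_terms && n_units < 2)
    stopf("coupling requested but the session has fewer than 2 units")

  nb <- cache$n_bins
  n_rows <- sum(nb)
  col_map <- list(); blocks <- list()

  if (any(c("target", "saccade") %in% spec$include_terms)) {
    keep <- grepl(paste0("^(",
                         paste(intersect(c("target", "saccade"),
                                         spec$include_terms), collapse = "|"),
                         ")_?"), cache$task_names)
    nb_task <- cache$bases$task$n_basis
    keep_cols <- as.vector(vapply(which(keep), function(k)
      as.integer((k - 1L) * nb_task) + seq_len(nb_task), integer(nb_task)))
    blocks$task <- do.call(rbind, lapply(cache$task_blocks,
                                         function(b) b[, keep_cols,
                                                       drop = FALSE]))
    nm <- rep(cache$task_names[keep], each = nb_task)
    for (g in unique(nm)) col_map[[g]] <- which(nm == g)
  }
  offset <- sum(vapply(blocks, ncol, integer(1)))

  nb_h <- cache$bases$hist$n_basis
  if ("history" %in% spec$include_terms) {
    blocks$history <- do.call(rbind, cache$spk_conv[[ti]])
    col_map[["history"]] <- offset + seq_len(nb_h)
    offset <- offset + nb_h
  }
  if ("coupling" %in% spec$include_terms) {
    partners <- setdiff(seq_len(n_units), ti)
    cp <- lapply(partners, function(pi) {
      mats <- cache$spk_conv[[pi]]
      if (!is.null(partner_perm)) {
        ord <- partner_perm[, pi]
        mats <- lapply(seq_along(mats),
                       function(k) crop_pad(mats[[ord[k]]], nb[k]))
      }
      do.call(rbind, mats)
    })
    for (k in seq_along(partners)) {
      key <- paste0("coupling:", cache$units$unit_id[partners[k]])
      col_map[[key]] <- offset + seq_len(nb_h)
      offset <- offset + nb_h
    }
    blocks$coupling <- do.call(cbind, cp)
  }

  X <- do.call(cbind, blocks)
  y <- unlist(lapply(seq_along(cache$trials_used), function(k)
    cache$counts[[cache$trials_used[k]]][, ti]), use.names = FALSE)
  trial_id <- rep(cache$trials_used, nb)
  bin_in_trial <- unlist(lapply(nb, seq_len), use.names = FALSE)

  structure(list(X = X, y = as.numeric(y), column_map = col_map,
                 trial_id = trial_id, bin_in_trial = bin_in_trial,
                 target_unit = target_unit, units = cache$units,
                 spec = spec, bases = cache$bases,
                 bin_width = cache$bin_width),
            class = "glm_design")
}

#' @export
print.glm_design <- function(x, ...) {
  cat(sprintf("glm_design for unit %s: %d bins x %d columns (%s)\n",
              x$target_unit, nrow(x$X), ncol(x$X),
              paste(names(x$column_map), collapse = ", ")))
  invisible(x)
}
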