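#' Assemble a session of simultaneously recorded spike trains
#'
#' The session is the exchange object between real or synthetic recordings
#' and the fitting pipeline: a set of units with area labels, a table of
#' trials with task-event times and target geometry, and per-unit per-trial
#' spike times in seconds from trial start.
#'
#' @param units Data frame with columns `unit_id` (unique character),
#'   `area` (one of "LIP", "FEF", "SYNTH"), `channel` (integer).
#' @param trials Data frame with columns `fixation_on`, `target_on`,
#'   `target_off`, `go_signal`, `saccade_onset` (seconds from trial start),
#'   `target_x`, `target_y` (degrees of visual angle), `condition`
#'   ("IN_RF"/"OUT_RF"), `duration` (seconds), and optionally `valid`
#'   (logical, default `TRUE`; only valid trials enter analyses).
#' @param spikes List over units (named by `unit_id`), each a list over
#'   trials of strictly sorted numeric spike times in `[0, duration)`.
#' @param metadata Named list of provenance (generator parameters, seeds, ...).
#' @return Object of class `spike_session`.
#' @seealso [bin_spikes()], [compute_psth()], [write_session()]
#' @export
new_session <- function(units, trials, spikes, metadata = list()) {
  units <- as.data.frame(units)
  trials <- as.data.frame(trials)
  if (is.null(trials$valid)) trials$valid <- TRUE
  s <- structure(list(units = units, trials = trials, spikes = spikes,
                      metadata = metadata),
                 class = "spike_session")
  validate_session(s)
  s
}

#' Validate a session against its invariants
#'
#' Checks event-time ordering, unit-id uniqueness, spike-time range and
#' strict sortedness. Called by [new_session()] and [read_session()].
#'
#' @param session A `spike_session`.
#' @return The session, invisibly; errors name the first offending field.
#' @export
validate_session <- function(session) {
  u <- session$units
  tr <- session$trials
  req_u <- c("unit_id", "area", "channel")
  req_t <- c("fixation_on", "target_on", "target_off", "go_signal",
             "saccade_onset", "target_x", "target_y", "condition", "duration")
  miss <- setdiff(req_u, names(u))
  if (length(miss)) stopf("units table missing field '%s'", miss[1])
  miss <- setdiff(req_t, names(tr))
  if (length(miss)) stopf("trials table missing field '%s'", miss[1])
  if (anyDuplicated(u$unit_id))
    stopf("duplicate unit_id '%s'", u$unit_id[duplicated(u$unit_id)][1])
  if (!all(u$area %in% c("LIP", "FEF", "SYNTH")))
    stopf("unknown area label '%s'", setdiff(u$area, c("LIP","FEF","SYNTH"))[1])
  ok <- tr$fixation_on < tr$target_on & tr$target_on < tr$target_off &
    tr$target_off < tr$go_signal & tr$go_signal <= tr$saccade_onset
  if (!all(ok)) stopf("trial %d violates event ordering", which(!ok)[1])
  if (!all(tr$duration >= tr$saccade_onset))
    stopf("trial %d: duration < saccade_onset",
          which(tr$duration < tr$saccade_onset)[1])
  ecc <- sqrt(tr$target_x^2 + tr$target_y^2)
  if (!all(is.finite(ecc) & ecc > 0))
    stopf("trial %d: target eccentricity not finite and positive",
          which(!(is.finite(ecc) & ecc > 0))[1])
  if (!all(tr$condition %in% c("IN_RF", "OUT_RF")))
    stopf("unknown condition '%s'",
          setdiff(tr$condition, c("IN_RF", "OUT_RF"))[1])
  if (length(session$spikes) != nrow(u))
    stopf("spikes list has %d units, units table has %d",
          length(session$spikes), nrow(u))
  for (i in seq_len(nrow(u))) {
    sp_u <- session$spikes[[i]]
    if (length(sp_u) != nrow(tr))
      stopf("unit %s: %d spike lists for %d trials",
            u$unit_id[i], length(sp_u), nrow(tr))
    for (j in seq_len(nrow(tr))) {
      st <- sp_u[[j]]
      if (length(st) == 0) next
      if (any(st < 0) || any(st >= tr$duration[j]))
        stopf("unit %s, trial %d: spike time outside [0, duration)",
              u$unit_id[i], j)
      if (is.unsorted(st, strictly = TRUE))
        stopf("unit %s, trial %d: spike times not strictly sorted",
              u$unit_id[i], j)
    }
  }
  invisible(session)
}

#' @export
print.spike_session <- function(x, ...) {
  nsp <- sum(vapply(x$spikes, function(u) sum(lengths(u)), numeric(1)))
  cat(sprintf("spike_session: %d units (%s), %d trials, %d spikes\n",
              nrow(x$units), paste(names(table(x$units$area)), collapse = "/"),
              nrow(x$trials), nsp))
  invisible(x)
}

#' Discretize spike trains into count bins
#'
#' Bins each unit's spike times on each trial into half-open bins
#' `[t, t + bin_width)`, 0-based in time from trial start. Trials keep their
#' own (ragged) lengths: trial `j` has `ceiling(duration_j / bin_width)` bins,
#' so no phantom bins enter downstream likelihoods. The total spike count is
#' conserved exactly.
#'
#' @param session A `spike_session`.
#' @param bin_width Bin width in seconds (default 0.001, i.e. 1 ms).
#' @return Object of class `binned_session`: `counts` is a list over trials
#'   of integer matrices (time bin x unit), plus the units/trials tables and
#'   `bin_width`.
#' @export
bin_spikes <- function(session, bin_width = 0.001) {
  stopifnot(inherits(session, "spike_session"))
  if (bin_width <= 0) stopf("bin_width must be positive")
  validate_session(session)
  tr <- session$trials
  n_units <- nrow(session$units)
  counts <- vector("list", nrow(tr))
  for (j in seq_len(nrow(tr))) {
    nb <- as.integer(ceiling(tr$duration[j] / bin_width - 1e-9))
    m <- matrix(0L, nb, n_units)
    for (i in seq_len(n_units)) {
      st <- session$spikes[[i]][[j]]
      if (length(st))
        m[, i] <- tabulate(floor(st / bin_width) + 1L, nbins = nb)
    }
    counts[[j]] <- m
  }
  structure(list(counts = counts, units = session$units, trials = tr,
                 bin_width = bin_width, metadata = session$metadata),
            class = "binned_session")
}

#' @export
print.binned_session <- function(x, ...) {
  cat(sprintf("binned_session: %d units, %d trials, %g ms bins, %d spikes\n",
              nrow(x$units), nrow(x$trials), x$bin_width * 1000,
              sum(vapply(x$counts, sum, numeric(1)))))
  invisible(x)
}

# Gaussian smoothing with reflection padding at the window edges, so rates
# are not suppressed at the boundaries. sd in bins; sd = 0 is the identity.
gauss_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  r <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(seq(-r, r), sd = sd_bins)
  k <- k / sum(k)
  n <- length(x)
  pad <- function(v, m) {
    # reflect; recycle if the series is shorter than the pad
    idx_l <- rev(seq_len(min(m, n)))
    idx_r <- rev(n + 1 - seq_len(min(m, n)))
    c(v[rep_len(idx_l, m)], v, v[rep_len(idx_r, m)])
  }
  xp <- pad(x, r)
  stats::convolve(xp, rev(k), type = "filter")
}

#' Peristimulus time histogram
#'
#' Event-aligned, trial-averaged firing rates: counts are aligned to a task
#' event, averaged across the included trials, divided by the bin width and
#' smoothed with a Gaussian filter (default SD 30 ms, reflection padding at
#' the window edges). Trials whose alignment window falls outside
#' `[0, duration]` are dropped; a condition with no remaining trials is
#' returned as an empty (flagged) series rather than zero-filled.
#'
#' @param binned A `binned_session`.
#' @param align_event One of `"fixation_on"`, `"target_on"`, `"target_off"`,
#'   `"go_signal"`, `"saccade_onset"`.
#' @param window Numeric pair: window around the event in seconds,
#'   e.g. `c(-0.2, 0.8)`.
#' @param smoothing_sd Gaussian smoothing SD in seconds (default 0.03; 0
#'   returns the unsmoothed trial-averaged rate).
#' @param group_by_condition Split trials by IN_RF/OUT_RF (default `TRUE`).
#' @param units Character vector of unit ids (default all).
#' @return Data frame with columns `unit_id`, `condition`, `time` (seconds
#'   relative to the event), `rate` (spikes/s) and `n_trials`. Attribute
#'   `empty_conditions` lists unit/condition pairs with no usable trials.
#' @export
compute_psth <- function(binned, align_event = "target_on",
                         window = c(-0.2, 0.8), smoothing_sd = 0.03,
                         group_by_condition = TRUE, units = NULL) {
  stopifnot(inherits(binned, "binned_session"))
  if (smoothing_sd < 0) stopf("smoothing_sd must be >= 0")
  ev_cols <- c("fixation_on", "target_on", "target_off", "go_signal",
               "saccade_onset")
  if (!align_event %in% ev_cols) stopf("unknown align event '%s'", align_event)
  tr <- binned$trials
  dt <- binned$bin_width
  off <- round(window / dt)
  rel_bins <- seq.int(off[1], off[2] - 1L)
  time <- (rel_bins + 0.5) * dt
  keep_trial <- which(tr$valid)
  units <- units %||% binned$units$unit_id
  conds <- if (group_by_condition) c("IN_RF", "OUT_RF") else "all"

  out <- list(); empties <- character(0)
  for (uid in units) {
    ui <- match(uid, binned$units$unit_id)
    if (is.na(ui)) stopf("unknown unit '%s'", uid)
    for (cond in conds) {
      tt <- if (cond == "all") keep_trial else
        keep_trial[tr$condition[keep_trial] == cond]
      acc <- numeric(length(rel_bins)); n_used <- 0L
      for (j in tt) {
        e_bin <- floor(tr[[align_event]][j] / dt)
        idx <- e_bin + rel_bins + 1L
        if (idx[1] < 1L || idx[length(idx)] > nrow(binned$counts[[j]])) next
        acc <- acc + binned$counts[[j]][idx, ui]
        n_used <- n_used + 1L
      }
      if (n_used == 0L) {
        empties <- c(empties, paste(uid, cond, sep = "/"))
        next
      }
      rate <- gauss_smooth(acc / n_used / dt, smoothing_sd / dt)
      out[[length(out) + 1L]] <- data.frame(
        unit_id = uid, condition = cond, time = time, rate = rate,
        n_trials = n_used, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(unit_id = character(0), condition = character(0),
               time = numeric(0), rate = numeric(0), n_trials = integer(0))
  attr(res, "empty_conditions") <- empties
  res
}

#' Write a session to a plain-text container
#'
#' The container is a directory holding `session.json` (units, trials,
#' metadata) and `spikes.csv` (columns `unit_id, trial, time`, times printed
#' to microsecond precision). [read_session()] restores an identical session
#' (spike times to 1e-6 s).
#'
#' @param session A `spike_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "spike_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(units = session$units, trials = session$trials,
               metadata = session$metadata)
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  uid <- session$units$unit_id
  rows <- list()
  for (i in seq_along(uid)) for (j in seq_along(session$spikes[[i]])) {
    st <- session$spikes[[i]][[j]]
    if (length(st))
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = uid[i], trial = j, time = sprintf("%.6f", st),
        stringsAsFactors = FALSE)
  }
  sp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(0), trial = integer(0), time = character(0))
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a session from the plain-text container
#'
#' @param path Directory written by [write_session()] (or assembled by hand
#'   in the same documented CSV+JSON layout).
#' @return A validated `spike_session`.
#' @export
read_session <- function(path) {
  jf <- file.path(path, "session.json")
  cf <- file.path(path, "spikes.csv")
  if (!file.exists(jf)) stopf("container missing required file 'session.json'")
  if (!file.exists(cf)) stopf("container missing required file 'spikes.csv'")
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  for (f in c("units", "trials"))
    if (is.null(meta[[f]])) stopf("session.json missing required group '%s'", f)
  units <- as.data.frame(meta$units)
  trials <- as.data.frame(meta$trials)
  sp_tab <- utils::read.csv(cf, stringsAsFactors = FALSE,
                            colClasses = c(unit_id = "character",
                                           trial = "integer",
                                           time = "numeric"))
  spikes <- lapply(units$unit_id, function(uid) {
    rows <- sp_tab[sp_tab$unit_id == uid, ]
    lapply(seq_len(nrow(trials)),
           function(j) sort(rows$time[rows$trial == j]))
  })
  names(spikes) <- units$unit_id
  new_session(units, trials, spikes,
              metadata = meta$metadata %||% list())
}
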