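#' Read and validate a pipeline configuration
#'
#' The configuration is a single declarative YAML file. Top-level keys:
#' \describe{
#'   \item{data}{`source`: one of `"path"`, `"synth-glm"`,
#'     `"synth-attractor"`; plus `path`, or generator settings (`n_units`,
#'     `n_trials`, `style`; for the attractor `scaled`, `j_pos`,
#'     `n_sampled`).}
#'   \item{model}{Any argument of [model_spec()].}
#'   \item{analysis}{`n_perm` (permutation null size, 0 disables), `k_folds`,
#'     `indices` (fit reduced models for predictive indices), `epochs`
#'     (named windows as in [fit_epoch_models()]), `tuning` (logical).}
#'   \item{out_dir}{Artifact directory.}
#'   \item{seed}{Master seed; every stochastic stage derives its seed from it
#'     and the stage name.}
#' }
#'
#' @param path YAML file path.
#' @return Validated config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg Config list (already parsed).
#' @export
validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$data$source))
    stopf("config key 'data.source' is required")
  if (!cfg$data$source %in% c("path", "synth-glm", "synth-attractor"))
    stopf("config key 'data.source': unknown source '%s'", cfg$data$source)
  if (cfg$data$source == "path" && is.null(cfg$data$path))
    stopf("config key 'data.path' is required for source 'path'")
  if (is.null(cfg$out_dir)) stopf("config key 'out_dir' is required")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$analysis <- cfg$analysis %||% list()
  cfg$model <- cfg$model %||% list()
  structure(cfg, class = "pipeline_config")
}

# serialize a population fit to JSON (weights, spec, diagnostics)
write_fit_json <- function(popfit, path) {
  obj <- list(
    spec = unclass(popfit$spec),
    units = popfit$units,
    fits = lapply(popfit$fits, function(f)
      list(unit_id = f$unit_id, b = f$b, weights = f$weights,
           grad_norm = f$grad_norm, iterations = f$iterations)))
  if (!is.null(popfit$cv)) obj$cv <- popfit$cv
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Run the end-to-end analysis pipeline
#'
#' Data acquisition (load or synthesize), cross-validated population fit,
#' permutation null, coupling summaries (weights, gains, per-interaction
#' significant fractions, PCA, time constants), optional predictive indices,
#' epoch comparison and tuning analysis, and a run manifest. Partial outputs
#' are removed if a stage fails. Reruns with the same config and seed produce
#' identical outputs.
#'
#' @param config A `pipeline_config`, a config list, or a YAML path.
#' @param out_dir Optional override of `config$out_dir`.
#' @return The artifact directory path, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- validate_pipeline_config(config)
  out <- out_dir %||% config$out_dir
  seed <- config$seed
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out, recursive = TRUE), add = TRUE)

  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = file.path(out, "pipeline.log"), append = TRUE)
  }

  # --- data stage -----------------------------------------------------
  dcfg <- config$data
  session <- switch(
    dcfg$source,
    "path" = read_session(dcfg$path),
    "synth-glm" = simulate_glm_session(
      n_units = dcfg$n_units %||% 6, n_trials = dcfg$n_trials %||% 200,
      spec = do.call(model_spec, config$model),
      style = dcfg$style %||% "compact",
      seed = derive_seed(seed, "data"))$session,
    "synth-attractor" = simulate_attractor_session(
      do.call(attractor_params,
              dcfg[intersect(names(dcfg), names(formals(attractor_params)))]),
      n_trials = dcfg$n_trials %||% 100, n_sampled = dcfg$n_sampled %||% 10,
      seed = derive_seed(seed, "data")))
  log_line("data: %d units, %d trials (%s)", nrow(session$units),
           nrow(session$trials), dcfg$source)
  write_session(session, file.path(out, "session"))

  spec <- do.call(model_spec, config$model)
  if (dcfg$source == "synth-attractor" && is.null(config$model$include_terms)) {
    spec <- model_spec(include_terms = c("target", "history", "coupling"),
                       condition_split = FALSE,
                       ridge_strength = spec$ridge_strength)
  }
  binned <- bin_spikes(session, spec$bin_width)
  acfg <- config$analysis

  # --- fit stage ------------------------------------------------------
  popfit <- crossval_fit(binned, spec, k_folds = acfg$k_folds %||% 5,
                         seed = derive_seed(seed, "fit"))
  write_fit_json(popfit, file.path(out, "fits.json"))
  utils::write.csv(popfit$cv, file.path(out, "cv.csv"), row.names = FALSE)
  log_line("fit: %d units, %d folds", length(popfit$fits),
           acfg$k_folds %||% 5)

  ctab <- coupling_table(popfit)
  # --- null stage -----------------------------------------------------
  n_perm <- acfg$n_perm %||% 20
  sig <- NULL
  if (n_perm > 0 && "coupling" %in% spec$include_terms) {
    cache <- design_cache(binned, spec)
    null <- permutation_null(cache, n_perm = n_perm,
                             seed = derive_seed(seed, "null"),
                             init = popfit$fits)
    nm <- stats::aggregate(weight ~ from + to, null$weights, mean)
    ns <- stats::aggregate(weight ~ from + to, null$weights, stats::sd)
    names(nm)[3] <- "null_mean"; names(ns)[3] <- "null_sd"
    ctab <- merge(merge(ctab, nm, by = c("from", "to")), ns,
                  by = c("from", "to"))
    sig <- significant_fraction(ctab, null)
    cls_stats <- sig
    ctab$significant <- ctab$weight >
      sig$null_mean[match(ctab$interaction, sig$interaction)] +
      2 * sig$null_sd[match(ctab$interaction, sig$interaction)]
    utils::write.csv(null$weights, file.path(out, "null.csv"),
                     row.names = FALSE)
    utils::write.csv(sig, file.path(out, "significant_fraction.csv"),
                     row.names = FALSE)
    log_line("null: %d permutations", n_perm)
  }
  ctab <- ctab[order(ctab$from, ctab$to), ]
  utils::write.csv(ctab, file.path(out, "coupling.csv"), row.names = FALSE)

  # --- analyze stage --------------------------------------------------
  bases <- spec_bases(spec)
  unit_rows <- list()
  if ("coupling" %in% spec$include_terms) {
    for (cls in unique(ctab$interaction)) {
      ids <- which(ctab$interaction == cls)
      if (length(ids) >= 3) {
        K <- t(vapply(ids, function(r) reconstruct_kernel(
          bases$hist,
          popfit$fits[[ctab$to[r]]]$weights[[paste0("coupling:",
                                                    ctab$from[r])]]),
          numeric(nrow(bases$hist$B))))
        pca <- pca_kernels(K)
        utils::write.csv(
          data.frame(lag_ms = bases$hist$lags_ms, pca$components,
                     check.names = FALSE),
          file.path(out, sprintf("pca_coupling_%s.csv", cls)),
          row.names = FALSE)
      }
    }
  }
  for (uid in names(popfit$fits)) {
    f <- popfit$fits[[uid]]
    tau_h <- if (!is.null(f$weights$history))
      fit_time_constant(reconstruct_kernel(bases$hist, f$weights$history),
                        bases$hist$lags_ms) else NULL
    cw <- grep("^coupling:", names(f$weights), value = TRUE)
    tau_c <- if (length(cw)) {
      mk <- rowMeans(vapply(cw, function(k)
        reconstruct_kernel(bases$hist, f$weights[[k]]),
        numeric(nrow(bases$hist$B))))
      fit_time_constant(mk, bases$hist$lags_ms)
    } else NULL
    unit_rows[[uid]] <- data.frame(
      unit_id = uid,
      bits_per_spike = mean(popfit$cv$bits_per_spike[popfit$cv$unit_id == uid],
                            na.rm = TRUE),
      deviance_explained = mean(
        popfit$cv$deviance_explained[popfit$cv$unit_id == uid], na.rm = TRUE),
      tau_history = if (!is.null(tau_h) && !tau_h$excluded) tau_h$tau else NA,
      tau_history_excluded = !is.null(tau_h) && tau_h$excluded,
      tau_coupling = if (!is.null(tau_c) && !tau_c$excluded) tau_c$tau else NA,
      stringsAsFactors = FALSE)
  }
  units_tab <- do.call(rbind, unit_rows)

  if (isTRUE(acfg$indices)) {
    idx <- compute_predictive_indices(binned, spec,
                                      k_folds = acfg$k_folds %||% 5,
                                      seed = derive_seed(seed, "indices"))
    units_tab <- merge(units_tab, idx[, c("unit_id", "coupling_index",
                                          "history_index")], by = "unit_id")
  }
  utils::write.csv(units_tab, file.path(out, "units.csv"), row.names = FALSE)

  if (!is.null(acfg$epochs)) {
    epochs <- lapply(acfg$epochs, function(e)
      list(event = e$event, offset = as.numeric(e$offset)))
    ep <- fit_epoch_models(binned, spec, epochs)
    utils::write.csv(ep$pairs, file.path(out, "epoch_pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(ep$comparison, file.path(out, "epoch_comparison.csv"),
                     row.names = FALSE)
    log_line("epochs: %s", paste(names(epochs), collapse = ", "))
  }
  if (isTRUE(acfg$tuning)) {
    tun <- unit_tuning(binned)
    ttab <- data.frame(
      unit_id = names(tun),
      preferred_angle = vapply(tun, function(t) t$preferred_angle, numeric(1)),
      width = vapply(tun, function(t) t$width, numeric(1)),
      amplitude = vapply(tun, function(t) t$amplitude, numeric(1)),
      reliable = vapply(tun, function(t) t$reliable, logical(1)))
    utils::write.csv(ttab, file.path(out, "tuning.csv"), row.names = FALSE)
    if ("coupling" %in% spec$include_terms) {
      cvt <- coupling_vs_tuning(ctab, tun)
      utils::write.csv(cvt, file.path(out, "coupling_vs_tuning.csv"),
                       row.names = FALSE)
    }
  }

  # --- manifest + report ----------------------------------------------
  manifest <- list(
    config = unclass(config), master_seed = seed,
    stage_seeds = list(data = derive_seed(seed, "data"),
                       fit = derive_seed(seed, "fit"),
                       null = derive_seed(seed, "null")),
    package_version = as.character(utils::packageVersion("popglm")),
    n_units = nrow(session$units), n_trials = nrow(session$trials))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)

  rep <- c(
    "# Population encoding model report", "",
    sprintf("- data: %s (%d units, %d trials)", dcfg$source,
            nrow(session$units), nrow(session$trials)),
    sprintf("- model: %s%s", paste(spec$include_terms, collapse = " + "),
            if (spec$condition_split) " with IN_RF/OUT_RF split" else ""),
    sprintf("- mean held-out bits/spike: %.4f",
            mean(popfit$cv$bits_per_spike, na.rm = TRUE)),
    sprintf("- mean coupling weight: %.4f",
            if ("coupling" %in% spec$include_terms) mean(ctab$weight) else NA),
    if (!is.null(sig)) sprintf("- significant coupling fraction (%s): %s",
                               paste(sig$interaction, collapse = ", "),
                               paste(signif(sig$fraction, 3), collapse = ", ")),
    "")
  writeLines(rep, file.path(out, "report.md"))
  ok <- TRUE
  invisible(out)
}
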