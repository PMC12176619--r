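#' Load and validate a pipeline configuration
#'
#' Configuration has two blocks: `sim` (arguments of [sim_config()]) and
#' `analysis` (analysis parameters below). Unknown keys are an error that
#' names the offending fields. Accepts a YAML or JSON file path, or a list.
#'
#' Analysis defaults follow the standard operating point of the method:
#' 5% FDR for selectivity, decoder penalty `lambda = 1`, 1-s / 150-ms
#' decoding windows, 0.5 posterior peak threshold, 1-min / 30-s
#' reactivation-rate windows, 100-ms PETH smoothing.
#'
#' @param config path to a YAML/JSON file, or a list.
#' @return validated list with `sim` (a [sim_config()]) and `analysis`.
#' @export
load_pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) .invalid_input("config must be a list or file path")
  bad_top <- setdiff(names(config), c("sim", "analysis"))
  if (length(bad_top)) {
    .invalid_input(paste("unknown config keys:", paste(bad_top, collapse = ", ")))
  }
  sim_args <- config$sim
  if (!is.null(sim_args)) {
    bad <- setdiff(names(sim_args), names(formals(sim_config)))
    if (length(bad)) {
      .invalid_input(paste("unknown sim keys:", paste(bad, collapse = ", ")))
    }
  }
  analysis <- list(q = 0.05, lambda = 1, decode_window = 1,
                   decode_step = 0.15, peak_threshold = 0.5,
                   rate_window = 60, rate_step = 30, peth_smooth_sd = 0.1,
                   gmm_replicates = 100, write_spikes = FALSE,
                   run_multiday = TRUE)
  if (!is.null(config$analysis)) {
    bad <- setdiff(names(config$analysis), names(analysis))
    if (length(bad)) {
      .invalid_input(paste("unknown analysis keys:", paste(bad, collapse = ", ")))
    }
    analysis[names(config$analysis)] <- config$analysis
  }
  list(sim = do.call(sim_config, as.list(sim_args)), analysis = analysis)
}

#' Run the full analysis chain on a simulated experiment
#'
#' simulate -> classify -> PETHs -> decode -> trajectories -> plasticity,
#' writing CSV/JSON artifacts for every stage plus a run manifest with the
#' seeds, configuration hash and md5 checksum of every output file.
#' Re-running with the same config and seed reproduces identical artifacts.
#'
#' @param config configuration (path or list; see [load_pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @param seed master seed for all substreams.
#' @return the run manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1) {
  cfg <- load_pipeline_config(config)
  an <- cfg$analysis
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)

  # --- simulate -------------------------------------------------------------
  sess <- simulate_session(cfg$sim, seed = seed)
  events <- sess$events; spikes <- sess$spikes
  write_events_csv(events, pth("events.csv"), pth("epochs.json"))
  utils::write.csv(sess$truth, pth("ground_truth.csv"), row.names = FALSE)
  if (isTRUE(an$write_spikes)) write_spikes_csv(spikes, pth("spikes.csv"))

  # --- selectivity ----------------------------------------------------------
  labels <- classify_session(spikes, events, q = an$q)
  utils::write.csv(labels, pth("selectivity.csv"), row.names = FALSE)

  # --- PETHs ----------------------------------------------------------------
  cons_stats <- consumption_stats(spikes, events)
  pf <- reward_peth(spikes, events, "flavour", cons_stats,
                    smooth_sd = an$peth_smooth_sd)
  pw <- reward_peth(spikes, events, "water", cons_stats,
                    smooth_sd = an$peth_smooth_sd)
  write_peth(pf, pth("peth_flavour.csv"), pth("peth_flavour.json"))
  write_peth(pw, pth("peth_water.csv"), pth("peth_water.json"))
  has_bouts <- nrow(events$bouts) > 0
  if (has_bouts) {
    ps <- stim_bout_peth(spikes, events, cons_stats,
                         smooth_sd = an$peth_smooth_sd)
    write_peth(ps, pth("peth_stim.csv"), pth("peth_stim.json"))
  }

  # --- decoder --------------------------------------------------------------
  train <- build_training_set(spikes, events)
  model <- fit_multinomial_l1(train$features, train$labels,
                              lambda = an$lambda,
                              train_stats = train$train_stats)
  jsonlite::write_json(
    list(classes = model$classes, lambda = model$lambda,
         converged = model$converged, n_iter = model$n_iter,
         intercepts = model$intercepts, weights = model$weights,
         train_mean = train$train_stats$mean, train_sd = train$train_stats$sd),
    pth("decoder.json"), auto_unbox = TRUE, digits = NA)
  post_name <- intersect(c("stim", "malaise"), names(events$epochs))[1]
  eval_span <- c(events$epochs$delay$start, events$epochs[[post_name]]$end)
  dstats <- delay_window_stats(spikes, events, width = an$decode_window)
  series <- sliding_posteriors(model, spikes, dstats, eval_span,
                               window = an$decode_window,
                               step = an$decode_step)
  utils::write.csv(
    data.frame(time = series$times, series$posteriors, check.names = FALSE),
    pth("posteriors.csv"), row.names = FALSE)
  stim_span <- c(events$epochs[[post_name]]$start,
                 events$epochs[[post_name]]$end)
  rates <- lapply(c("flavour", "water"), function(cl) {
    ev <- detect_reactivations(series, cl, an$peak_threshold)
    in_stim <- ev$times >= stim_span[1] & ev$times < stim_span[2]
    rr <- reactivation_rate(ev$times, span = eval_span,
                            window = an$rate_window, step = an$rate_step)
    utils::write.csv(data.frame(time = ev$times),
                     pth(sprintf("reactivations_%s.csv", cl)),
                     row.names = FALSE)
    utils::write.csv(rr, pth(sprintf("reactivation_rate_%s.csv", cl)),
                     row.names = FALSE)
    sum(in_stim) / ((stim_span[2] - stim_span[1]) / 60)
  })
  names(rates) <- c("flavour", "water")

  # --- trajectories ---------------------------------------------------------
  selective <- !is.na(labels$label) & labels$label != "nonselective"
  traj_summary <- NULL
  if (sum(selective) >= 3) {
    inp <- build_pca_input(pf, pw, selective)
    pca <- fit_pca(inp, n_pcs = min(10, nrow(inp$matrix)))
    utils::write.csv(data.frame(unit_id = pca$unit_ids, pca$loadings),
                     pth("pc_loadings.csv"), row.names = FALSE)
    tf <- project_trajectory(pf, pca)
    tw <- project_trajectory(pw, pca)
    traj_summary <- list(var_explained_pc1_pc2 = sum(pca$var_explained[1:2]))
    if (has_bouts) {
      ts <- project_stim_trajectory(ps, pca)
      traj_summary$stim_cos_flavour <- trajectory_cosine(
        ts, tf, lags_a = ts$lags > 0, lags_b = tf$lags > 0 & tf$lags <= 5)
      traj_summary$stim_cos_water <- trajectory_cosine(
        ts, tw, lags_a = ts$lags > 0, lags_b = tw$lags > 0 & tw$lags <= 5)
      utils::write.csv(data.frame(lag = ts$lags, ts$values),
                       pth("stim_trajectory.csv"), row.names = FALSE)
    }
    utils::write.csv(data.frame(lag = tf$lags, flavour = tf$values[, 1:2],
                                water = tw$values[, 1:2]),
                     pth("reward_trajectories.csv"), row.names = FALSE)
  }

  # --- plasticity (ground-truth cross-day analysis) -------------------------
  plast_summary <- NULL
  if (isTRUE(an$run_multiday)) {
    md <- simulate_multiday(cfg$sim, seed = seed, spikes = FALSE)
    tr <- md$truth
    flav <- tr$label == "flavour"
    if (sum(flav) >= 3 && stats::sd(tr$react_gain[flav]) > 0) {
      reg <- delta_vs_cgrp_regression(
        (tr$gain_day2 - tr$gain_day1)[flav], tr$react_gain[flav])
      plast_summary <- list(slope = reg$all$slope, r = reg$all$r,
                            p = reg$all$p, n = reg$all$n,
                            true_beta = cfg$sim$plasticity_beta)
      jsonlite::write_json(plast_summary, pth("plasticity.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  # --- GMM response typing --------------------------------------------------
  gmm_summary <- NULL
  if (has_bouts && length(spikes) >= 16) {
    acute <- stim_bout_peth(spikes, events, cons_stats, window = c(-1, 2))
    gmm <- gmm_response_types(acute, replicates = an$gmm_replicates,
                              seed = seed)
    utils::write.csv(data.frame(unit_id = names(spikes), type = gmm$type),
                     pth("response_types.csv"), row.names = FALSE)
    gmm_summary <- list(loglik = gmm$loglik,
                        counts = as.list(table(gmm$type)))
  }

  # --- manifest -------------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("cfareact")),
    seed = seed,
    substream_seeds = vapply(
      c("events", "ground_truth", "spikes", "plasticity", "gmm", "cv_folds"),
      function(s) substream_seed(seed, s), numeric(1)),
    config_hash = local({
      tmp <- tempfile(fileext = ".json")
      on.exit(unlink(tmp))
      writeLines(jsonlite::toJSON(list(sim = unclass(cfg$sim), analysis = an),
                                  auto_unbox = TRUE, digits = NA), tmp)
      unname(tools::md5sum(tmp))
    }),
    summary = list(
      n_neurons = length(spikes),
      n_rewards = nrow(events$rewards),
      selective_fraction = mean(selective),
      reactivation_rate_stim = rates,
      trajectories = traj_summary,
      plasticity = plast_summary,
      gmm = gmm_summary),
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
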