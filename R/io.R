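# On-disk formats: epoch bundles (directory of JSON metadata + CSV arrays),
# RDM CSVs, cluster JSON. All plain text; numeric arrays are written with
# 17 significant digits, which round-trips IEEE doubles exactly.

write_num_csv <- function(m, path) {
  ch <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  colnames(ch) <- colnames(m) %||% sprintf("V%d", seq_len(ncol(ch)))
  data.table::fwrite(as.data.frame(ch), path, quote = FALSE)
  invisible(path)
}

#' Write / read an epoch bundle
#'
#' A bundle is a directory with `meta.json` (participant, sampling rate,
#' category list, array dimensions), `times.csv`, `trials.csv` (trial id,
#' label, validity), and `voltages.csv` (electrodes x samples rows, one
#' column per trial). The round trip is lossless.
#'
#' @param epochs An `eeg_epochs`.
#' @param dir Bundle directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs$voltages)
  meta <- list(
    participant_id = epochs$participant_id,
    sampling_hz = epochs$sampling_hz,
    categories = epochs$categories,
    electrodes = dimnames(epochs$voltages)[[1]],
    n_electrodes = d[1], n_samples = d[2], n_trials = d[3],
    artifact_trials = epochs$artifact_trials
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_num_csv(matrix(epochs$times, ncol = 1, dimnames = list(NULL, "time_ms")),
                file.path(dir, "times.csv"))
  data.table::fwrite(
    data.frame(trial_id = epochs$trial_ids, label = epochs$labels, valid = epochs$valid),
    file.path(dir, "trials.csv")
  )
  write_num_csv(matrix(epochs$voltages, nrow = d[1] * d[2]),
                file.path(dir, "voltages.csv"))
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  need <- c("meta.json", "times.csv", "trials.csv", "voltages.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      abort(sprintf("epoch bundle missing %s", f), class = "strsa_schema_error")
    }
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  times <- data.table::fread(file.path(dir, "times.csv"), data.table = FALSE)$time_ms
  trials <- data.table::fread(file.path(dir, "trials.csv"), data.table = FALSE)
  v <- as.matrix(data.table::fread(file.path(dir, "voltages.csv"), data.table = FALSE))
  if (length(times) != meta$n_samples) {
    abort("times.csv length does not match meta n_samples.", class = "strsa_schema_error")
  }
  if (nrow(trials) != meta$n_trials || ncol(v) != meta$n_trials) {
    abort("trials.csv/voltages.csv trial count does not match meta n_trials.",
          class = "strsa_schema_error")
  }
  if (nrow(v) != meta$n_electrodes * meta$n_samples) {
    abort("voltages.csv row count does not match electrodes x samples.",
          class = "strsa_schema_error")
  }
  unknown <- setdiff(unique(trials$label), meta$categories)
  if (length(unknown)) {
    abort(paste0("trials.csv has labels outside the category list: ",
                 paste(unknown, collapse = ", ")),
          class = "strsa_schema_error")
  }
  vol <- array(v, dim = c(meta$n_electrodes, meta$n_samples, meta$n_trials),
               dimnames = list(meta$electrodes, NULL, NULL))
  new_eeg_epochs(vol, trials$label, times, meta$sampling_hz, meta$participant_id,
                 valid = trials$valid, trial_ids = trials$trial_id,
                 categories = meta$categories,
                 artifact_trials = as.integer(meta$artifact_trials))
}

#' Write / read a square RDM CSV
#' @param x An `rdm`.
#' @param path CSV path (header row = category ids).
#' @export
write_rdm_csv <- function(x, path) {
  stopifnot(inherits(x, "rdm"))
  df <- as.data.frame(x$values)
  names(df) <- x$categories
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_rdm_csv
#' @export
read_rdm_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  rdm(m, colnames(m))
}

#' Export scalp clusters as JSON
#' @param clusters A `scalp_clusters` tibble (possibly empty).
#' @param path JSON path.
#' @export
write_clusters_json <- function(clusters, path) {
  items <- lapply(seq_len(nrow(clusters)), function(i) {
    list(cluster = clusters$cluster[i],
         electrodes = unlist(clusters$electrodes[i]),
         onset_ms = clusters$onset_ms[i],
         offset_ms = clusters$offset_ms[i],
         peak_z = clusters$peak_z[i])
  })
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every stage parameter with the conventional defaults: 40 ms
#' windows, 20% sub-averages, +/-100 uV rejection, last-100-ms baseline,
#' permutation count, alpha 0.05, pointwise clustering alpha 0.001, 20 ms
#' persistence, 50-250 ms residual window, 0-100/101-200/200-300 ms bins.
#' Parameters are validated against the stage preconditions at build time.
#'
#' @param preset Generator preset ([desk_preset()] or [study_preset()]).
#' @param seed Master seed for every stochastic stage.
#' @param ... Overrides of any config field.
#' @return A validated `run_config` list.
#' @export
run_config <- function(preset = desk_preset(), seed = 1, ...) {
  cfg <- list(
    preset = preset, seed = as.integer(seed),
    low_hz = 0.1, high_hz = 45, filter = TRUE, rereference = FALSE,
    reject_uv = 100, baseline_ms = c(-100, 0),
    subavg_fraction = 0.2,
    window_ms = 40, step_ms = 4 * 1000 / preset$sampling_hz,
    n_permutations = 200, alpha = 0.05, point_alpha = 0.001,
    min_cluster_ms = 20, cluster_n_sim = 200,
    residual_window = c(50, 250),
    bins = list(c(0, 100), c(101, 200), c(200, 300)),
    n_folds = 5, artifact_rate = 0
  )
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  ok <- function(test, msg) if (!test) abort(paste0("invalid config: ", msg),
                                             class = "strsa_bad_config")
  ok(cfg$window_ms > 0, "window_ms must be positive")
  ok(cfg$step_ms >= 1000 / cfg$preset$sampling_hz, "step_ms below one sample")
  ok(cfg$subavg_fraction > 0 && cfg$subavg_fraction <= 1, "subavg_fraction outside (0,1]")
  ok(cfg$reject_uv > 0, "reject_uv must be positive")
  ok(cfg$low_hz > 0 && cfg$low_hz < cfg$high_hz &&
       cfg$high_hz < cfg$preset$sampling_hz / 2, "filter band violates Nyquist")
  ok(cfg$alpha > 0 && cfg$alpha < 1, "alpha outside (0,1)")
  ok(cfg$point_alpha > 0 && cfg$point_alpha < 1, "point_alpha outside (0,1)")
  ok(cfg$n_permutations >= 1, "n_permutations must be positive")
  ok(cfg$artifact_rate >= 0 && cfg$artifact_rate < 1, "artifact_rate outside [0,1)")
  ok(diff(cfg$residual_window) > 0, "residual_window empty")
  invisible(cfg)
}

config_hash <- function(cfg) {
  cfg$preset <- cfg$preset[order(names(cfg$preset))]
  rlang::hash(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA))
}

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, sliding-window RDMs, joint and per-layer
#' encoding with permutation cluster-extent correction, noise ceiling,
#' scalp clustering with per-cluster encoding summaries, superordinate
#' residual analysis, and layer decoding, writing every scientific output
#' (CSV/JSON, each stamped with the config hash) under `out_dir`. All
#' randomness derives from `config$seed`, so two runs with the same config
#' produce byte-identical scientific outputs; wall-clock stage timings go
#' only to `log.json`, which is excluded from that guarantee.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @return A report list: config hash, stage timings, and the main result
#'   tables.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  timings <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  notices <- list()

  sim <- tick("simulate", simulate_study(config$preset, seed = config$seed,
                                         artifact_rate = config$artifact_rate))
  write_layout_csv(sim$layout, file.path(out_dir, "layout.csv"))

  pre <- tick("preprocess", lapply(sim$epochs, function(ep) {
    if (config$filter) ep <- bandpass(ep, config$low_hz, config$high_hz)
    ep <- reject_artifacts(ep, config$reject_uv)
    notices[[ep$participant_id]] <<- list(rejection_fraction = ep$rejection_fraction)
    if (config$rereference) ep <- rereference_average(ep)
    ep <- baseline_correct(ep, config$baseline_ms)
    ep <- subaverage_bootstrap(ep, config$subavg_fraction, seed = config$seed)
    category_means(ep)
  }))

  series <- tick("rdm", lapply(pre, sliding_rdms,
                               window_ms = config$window_ms, step_ms = config$step_ms))
  layer_rdms <- lapply(sim$banks, feature_rdm)
  for (l in seq_along(layer_rdms)) {
    write_rdm_csv(layer_rdms[[l]], file.path(out_dir, sprintf("rdm_layer%d.csv", l)))
  }

  enc <- tick("encode", {
    traces <- lapply(series, trace_over_time, layers = layer_rdms, mode = "all")
    traces_single <- lapply(series, trace_over_time, layers = layer_rdms, mode = "single")
    list(all = scalp_average(group_trace(traces)),
         single = scalp_average(group_trace(traces_single)))
  })

  st <- tick("stats", {
    null_all <- build_null(series, layer_rdms, mode = "all", unit = "scalp",
                           n_permutations = config$n_permutations, seed = config$seed)
    mask_all <- cluster_extent_correct(null = null_all, alpha = config$alpha)
    tr_all <- apply_sig_mask(enc$all, mask_all, unit = "scalp", layer = "all")
    tr_single <- enc$single
    n_layers <- length(layer_rdms)
    for (l in seq_len(n_layers)) {
      nl <- build_null(series, layer_rdms, mode = "single", layer = l,
                       unit = "scalp", n_permutations = config$n_permutations,
                       seed = derive_seed(config$seed, 100 + l))
      ml <- cluster_extent_correct(null = nl, alpha = config$alpha,
                                   n_comparisons = n_layers)
      tr_single <- apply_sig_mask(tr_single, ml, unit = "scalp",
                                  layer = layer_rdms[[l]]$source)
    }
    ceiling <- noise_ceiling_series(series, unit = "scalp")
    list(tr_all = tr_all, tr_single = tr_single, ceiling = ceiling)
  })
  data.table::fwrite(cbind(as.data.frame(st$tr_all), config_hash = hash),
                     file.path(out_dir, "trace_all.csv"))
  data.table::fwrite(cbind(as.data.frame(st$tr_single), config_hash = hash),
                     file.path(out_dir, "trace_layers.csv"))
  data.table::fwrite(cbind(as.data.frame(st$ceiling), config_hash = hash),
                     file.path(out_dir, "noise_ceiling.csv"))

  summaries <- bind_rows(
    summarize_trace(st$tr_all, config$bins),
    summarize_trace(st$tr_single, config$bins)
  )
  data.table::fwrite(cbind(as.data.frame(summaries), config_hash = hash),
                     file.path(out_dir, "summaries.csv"))

  res <- tick("residuals", {
    res_list <- lapply(series, encoding_residuals, layers = layer_rdms)
    residual_analysis(res_list, window = config$residual_window)
  })
  sup <- as.data.frame(res$superordinate_matrix)
  sup <- cbind(group = rownames(res$superordinate_matrix), sup, config_hash = hash)
  data.table::fwrite(sup, file.path(out_dir, "residual_superordinate.csv"))

  cl <- tick("clusters", {
    grand <- Reduce(`+`, lapply(pre, function(e) rowMeans(e$voltages, dims = 2))) /
      length(pre)
    zm <- z_topography(grand, times = pre[[1]]$times, baseline = config$baseline_ms)
    find_clusters(zm, sim$layout, point_alpha = config$point_alpha,
                  min_duration_ms = config$min_cluster_ms,
                  n_sim = config$cluster_n_sim, seed = config$seed)
  })
  write_clusters_json(cl, file.path(out_dir, "clusters.json"))

  dec <- tick("decode", decode_all_layers(sim$banks, n_folds = config$n_folds,
                                          seed = config$seed))
  data.table::fwrite(cbind(as.data.frame(tidy(dec)), config_hash = hash),
                     file.path(out_dir, "decoding.csv"))

  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed,
         stage_timings_s = timings, notices = notices),
    file.path(out_dir, "log.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  cfg_out <- config
  cfg_out$bins <- lapply(cfg_out$bins, as.numeric)
  jsonlite::write_json(c(list(config_hash = hash), cfg_out[setdiff(names(cfg_out), "preset")],
                         list(preset = cfg_out$preset)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(config_hash = hash, timings = timings, clusters = cl, decoding = dec,
       summaries = summaries, ceiling = st$ceiling,
       residuals = res, truth = sim$truth, out_dir = out_dir)
}
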