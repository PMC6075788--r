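#' Study-scale and desk-scale simulation presets
#'
#' `study_preset()` mirrors the scale of the emulated experiment: 30 scene
#' categories with 75 exemplars each, 8 feature layers, 256 electrodes
#' sampled at 1000 Hz, 850 ms epochs (100 ms baseline + 750 ms stimulus),
#' 13 participants. `desk_preset()` is a reduced configuration for tests and
#' examples (10 exemplars, 32 electrodes, 250 Hz, 5 participants).
#' `default_study_preset()` returns both.
#'
#' @return A named list of generator parameters.
#' @export
study_preset <- function() {
  list(
    name = "study",
    n_categories = 30L, n_exemplars = 75L,
    n_layers = 8L, layer_dims = rep(50L, 8), separability = seq(1.6, 2.8, length.out = 8),
    n_electrodes = 256L, sampling_hz = 1000, baseline_ms = 100, stim_ms = 750,
    n_participants = 13L, n_trials_per_category = 75L,
    noise_sd = 3, evoked_uv = 10, signal_uv = 5,
    latency_start_ms = 70, latency_step_ms = 25, width_ms = 60,
    n_regions = 4L, region_size = 28L
  )
}

#' @rdname study_preset
#' @export
desk_preset <- function() {
  p <- study_preset()
  p$name <- "desk"
  p$n_exemplars <- 10L
  p$layer_dims <- rep(20L, 8)
  p$n_electrodes <- 32L
  p$sampling_hz <- 250
  p$n_participants <- 5L
  p$n_trials_per_category <- 10L
  p$region_size <- 6L
  p
}

#' @rdname study_preset
#' @export
default_study_preset <- function() {
  list(study = study_preset(), desk = desk_preset())
}

new_feature_bank <- function(layer_id, activations, labels) {
  stopifnot(nrow(activations) == length(labels))
  cats <- unique(labels)
  cm <- t(vapply(cats, function(cc) colMeans(activations[labels == cc, , drop = FALSE]),
                 numeric(ncol(activations))))
  rownames(cm) <- cats
  structure(
    list(layer_id = layer_id, activations = activations, labels = labels,
         categories = cats, category_means = cm),
    class = "feature_bank"
  )
}

#' @export
print.feature_bank <- function(x, ...) {
  cat("<feature_bank> layer", x$layer_id, "-", nrow(x$activations), "exemplars x",
      ncol(x$activations), "features,", length(x$categories), "categories\n")
  invisible(x)
}

#' Generate layered feature banks with planted category geometry
#'
#' Each category gets a latent embedding; layer-wise embeddings follow an
#' autoregressive chain across layers (correlation `layer_corr` between
#' neighbours), so neighbouring layers share most of their representational
#' geometry while remaining distinguishable, as successive stages of a deep
#' network do. An exemplar's layer-`l` activation is its category's layer-`l`
#' embedding projected into `layer_dims[l]` dimensions, scaled by
#' `separability[l]`, plus unit-variance exemplar noise; larger separability
#' means more decodable category structure.
#'
#' @param n_categories,n_exemplars Categories and exemplars per category.
#' @param layer_dims Integer vector, one feature count per layer.
#' @param separability Non-negative signal scale per layer (same length).
#' @param seed Integer seed; the generator is a pure function of it.
#' @param n_latent Latent embedding dimensionality.
#' @param layer_corr Autoregressive correlation between neighbouring layers'
#'   embeddings.
#'
#' @return List with `banks` (list of `feature_bank`) and `truth`
#'   (a `ground_truth` holding the embeddings; spatiotemporal fields are
#'   added by [plant_structure()]).
#' @export
gen_feature_banks <- function(n_categories, n_exemplars, layer_dims, separability,
                              seed = 1, n_latent = 5L, layer_corr = 0.5) {
  if (length(layer_dims) != length(separability)) {
    abort("`layer_dims` and `separability` must have one entry per layer.",
          class = "strsa_bad_arg")
  }
  if (any(layer_dims <= 0)) abort("`layer_dims` must be positive.", class = "strsa_bad_arg")
  if (any(separability < 0)) abort("`separability` must be non-negative.", class = "strsa_bad_arg")
  n_layers <- length(layer_dims)
  cats <- sprintf("cat%02d", seq_len(n_categories))
  labels <- rep(cats, each = n_exemplars)
  with_seed(seed, {
    emb <- vector("list", n_layers)
    e <- matrix(rnorm(n_categories * n_latent), n_categories, n_latent)
    for (l in seq_len(n_layers)) {
      if (l > 1) {
        e <- layer_corr * emb[[l - 1]] +
          sqrt(1 - layer_corr^2) * matrix(rnorm(n_categories * n_latent), n_categories, n_latent)
      }
      rownames(e) <- cats
      emb[[l]] <- e
    }
    banks <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      d <- layer_dims[l]
      proj <- matrix(rnorm(n_latent * d, sd = 1 / sqrt(n_latent)), n_latent, d)
      sig <- separability[l] * (emb[[l]][labels, , drop = FALSE] %*% proj)
      act <- sig + matrix(rnorm(length(labels) * d), length(labels), d)
      banks[[l]] <- new_feature_bank(sprintf("layer%d", l), act, labels)
    }
    truth <- structure(
      list(categories = cats, n_layers = n_layers, n_latent = n_latent,
           separability = separability, layer_corr = layer_corr,
           embeddings = emb, seed = as.integer(seed)),
      class = "ground_truth"
    )
    list(banks = banks, truth = truth)
  })
}

#' Plant spatiotemporal structure into a ground truth
#'
#' Assigns each layer a temporal envelope (Gaussian bump; `width_ms` is the
#' full width at half maximum, zero before stimulus onset), a scalp region
#' (a compact blob of electrodes; layers map to the `n_regions` regions
#' cyclically so temporally adjacent layers occupy spatially separated
#' regions), smooth per-latent-component waveforms, a category-independent
#' evoked amplitude, and a noise scale. Latency centers increase strictly
#' with layer index (the "ordered" arrangement).
#'
#' @param truth A `ground_truth` from [gen_feature_banks()].
#' @param layout A `sensor_layout`.
#' @param latency_start_ms,latency_step_ms Envelope centers are
#'   `latency_start_ms + (l-1) * latency_step_ms`.
#' @param width_ms Envelope FWHM in ms.
#' @param n_regions,region_size Planted scalp regions (blobs of
#'   `region_size` electrodes nearest to equally spaced anchor points).
#' @param evoked_uv Category-independent evoked amplitude (uV).
#' @param signal_uv Category-signal amplitude scale (uV).
#' @param noise_sd Trial noise standard deviation (uV).
#' @param seed Seed for waveform draws; defaults to the truth's seed.
#' @return The `ground_truth` with spatiotemporal fields filled in.
#' @export
plant_structure <- function(truth, layout,
                            latency_start_ms = 70, latency_step_ms = 25,
                            width_ms = 60, n_regions = 4L, region_size = 5L,
                            evoked_uv = 10, signal_uv = 5, noise_sd = 5,
                            seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(layout, "sensor_layout"))
  seed <- seed %||% truth$seed
  L <- truth$n_layers
  k <- truth$n_latent
  n_el <- nrow(layout)
  lat <- latency_start_ms + (seq_len(L) - 1) * latency_step_ms
  anchors <- cbind(0.55 * cos(2 * pi * (seq_len(n_regions) - 1) / n_regions + pi / 7),
                   0.55 * sin(2 * pi * (seq_len(n_regions) - 1) / n_regions + pi / 7))
  regions <- grow_regions(layout, anchors, region_size)
  loadings <- matrix(0, n_el, L, dimnames = list(layout$electrode, NULL))
  layer_region <- ((seq_len(L) - 1) %% n_regions) + 1L
  for (l in seq_len(L)) loadings[regions[[layer_region[l]]], l] <- 1
  wf <- with_seed(derive_seed(seed, 77), {
    list(freq = matrix(runif(k * L, 8, 25), k, L),
         phase = matrix(runif(k * L, 0, 2 * pi), k, L))
  })
  truth$latency_ms <- lat
  truth$width_ms <- rep(width_ms, L)
  truth$loadings <- loadings
  truth$regions <- regions
  truth$layer_region <- layer_region
  truth$waveform <- wf
  truth$evoked_uv <- evoked_uv
  truth$signal_uv <- signal_uv
  truth$noise_sd <- noise_sd
  truth
}

# Build pairwise non-adjacent, internally connected scalp regions by
# round-robin constrained growth: each region starts at the free electrode
# nearest its anchor and repeatedly adds the candidate nearest its anchor
# that is adjacent to the region but not adjacent to (or a member of) any
# other region. Non-adjacency across regions guarantees each recovers as
# its own contiguous cluster.
grow_regions <- function(layout, anchors, region_size) {
  adj <- layout_adjacency(layout)
  n_regions <- nrow(anchors)
  ids <- layout$electrode
  d_anchor <- sapply(seq_len(n_regions), function(r) {
    sqrt((layout$x - anchors[r, 1])^2 + (layout$y - anchors[r, 2])^2)
  })
  regions <- vector("list", n_regions)
  owner <- rep(0L, length(ids))          # 0 = free, r = member of region r
  blocked <- function(i, r) owner[i] != 0 || any(adj[i, ] & owner != 0 & owner != r)
  # seeds in order of anchor distance
  for (r in seq_len(n_regions)) {
    cand <- order(d_anchor[, r])
    cand <- cand[!vapply(cand, blocked, logical(1), r = r)]
    if (length(cand) == 0) abort("cannot place non-adjacent regions on this layout.",
                                 class = "strsa_bad_arg")
    owner[cand[1]] <- r
    regions[[r]] <- cand[1]
  }
  grown <- TRUE
  while (grown && any(lengths(regions) < region_size)) {
    grown <- FALSE
    for (r in seq_len(n_regions)) {
      if (length(regions[[r]]) >= region_size) next
      nb <- which(apply(adj[regions[[r]], , drop = FALSE], 2, any))
      nb <- nb[!vapply(nb, blocked, logical(1), r = r)]
      if (length(nb) == 0) next
      pick <- nb[which.min(d_anchor[nb, r])]
      owner[pick] <- r
      regions[[r]] <- c(regions[[r]], pick)
      grown <- TRUE
    }
  }
  lapply(regions, function(ii) sort(ids[ii]))
}

gauss_envelope <- function(times, center_ms, width_ms) {
  s <- width_ms / (2 * sqrt(2 * log(2)))   # FWHM -> sd
  env <- exp(-(times - center_ms)^2 / (2 * s^2))
  env[times < 0] <- 0
  env
}

#' Noise-free planted category signal
#'
#' Evaluates the forward model: for layer l, electrode e, time t, category c,
#' the contribution is `loading_l(e) * env_l(t) * (evoked + signal_uv *
#' sum_m w_lm(t) E_l[c, m] / sqrt(k))`, where `w_lm` are smooth sinusoidal
#' component waveforms. The category-mean ERP of a noiseless epoch set equals
#' this signal exactly.
#'
#' @param truth A planted `ground_truth` (see [plant_structure()]).
#' @param layout The `sensor_layout` used for planting.
#' @param times Sample latencies in ms relative to stimulus onset.
#' @return Array electrodes x samples x categories (uV).
#' @export
planted_signal <- function(truth, layout, times) {
  if (is.null(truth$latency_ms)) {
    abort("ground truth has no planted structure; call plant_structure() first.",
          class = "strsa_bad_arg")
  }
  L <- truth$n_layers; k <- truth$n_latent
  cats <- truth$categories
  n_el <- nrow(layout); n_s <- length(times); n_c <- length(cats)
  out <- array(0, dim = c(n_el, n_s, n_c),
               dimnames = list(layout$electrode, NULL, cats))
  for (l in seq_len(L)) {
    env <- gauss_envelope(times, truth$latency_ms[l], truth$width_ms[l])
    # component waveforms: k x n_s
    w <- sapply(seq_len(k), function(m) {
      sin(2 * pi * truth$waveform$freq[m, l] * (times - truth$latency_ms[l]) / 1000 +
            truth$waveform$phase[m, l])
    })
    cat_sig <- truth$embeddings[[l]] %*% t(w) / sqrt(k)      # n_c x n_s
    time_cat <- env * (truth$evoked_uv + truth$signal_uv * t(cat_sig))  # n_s x n_c
    load <- truth$loadings[, l]
    for (c_i in seq_len(n_c)) {
      out[, , c_i] <- out[, , c_i] + outer(load, time_cat[, c_i])
    }
  }
  out
}

new_eeg_epochs <- function(voltages, labels, times, sampling_hz, participant_id,
                           valid = NULL, trial_ids = NULL, categories = NULL,
                           artifact_trials = integer(0)) {
  n_tr <- dim(voltages)[3]
  structure(
    list(
      voltages = voltages,
      labels = labels,
      times = times,
      sampling_hz = sampling_hz,
      participant_id = participant_id,
      valid = valid %||% rep(TRUE, n_tr),
      trial_ids = trial_ids %||% seq_len(n_tr),
      categories = categories %||% unique(labels),
      artifact_trials = artifact_trials
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$voltages)
  cat("<eeg_epochs>", x$participant_id, "-", d[1], "electrodes x", d[2],
      "samples x", d[3], "trials (", sum(x$valid), "valid ),",
      length(x$categories), "categories @", x$sampling_hz, "Hz\n")
  invisible(x)
}

#' Generate synthetic ERP epochs from a planted ground truth
#'
#' Voltage for a trial of category c is the planted signal ([planted_signal()])
#' plus white Gaussian noise of sd `truth$noise_sd` (optionally 1/f-shaped).
#' A fraction `artifact_rate` of trials receives an injected spike exceeding
#' 100 uV at a random electrode and sample; the injected trial indices are
#' recorded in the returned object's `artifact_trials` field so rejection can
#' be checked exactly.
#'
#' @param layout A `sensor_layout`.
#' @param truth A planted `ground_truth`.
#' @param n_trials_per_category Trials per category.
#' @param epoch List with `baseline_ms`, `stim_ms`, `sampling_hz`.
#' @param artifact_rate Proportion of trials spiked, in `[0, 1)`.
#' @param seed Integer seed.
#' @param participant_id Identifier stored in the epoch set.
#' @param noise One of `"white"` or `"pink"` (1/f-shaped) trial noise.
#' @return An `eeg_epochs` object (voltages electrodes x samples x trials, uV).
#' @export
gen_epochs <- function(layout, truth, n_trials_per_category,
                       epoch = list(baseline_ms = 100, stim_ms = 750, sampling_hz = 250),
                       artifact_rate = 0, seed = 1, participant_id = "P01",
                       noise = c("white", "pink")) {
  noise <- match.arg(noise)
  if (artifact_rate < 0 || artifact_rate >= 1) {
    abort("`artifact_rate` must be in [0, 1).", class = "strsa_bad_arg")
  }
  dt <- 1000 / epoch$sampling_hz
  n_s <- floor((epoch$baseline_ms + epoch$stim_ms) * epoch$sampling_hz / 1000)
  times <- seq(-epoch$baseline_ms, by = dt, length.out = n_s)
  sig <- planted_signal(truth, layout, times)
  cats <- truth$categories
  n_c <- length(cats)
  n_tr <- n_c * n_trials_per_category
  labels <- rep(cats, each = n_trials_per_category)
  n_el <- nrow(layout)
  with_seed(derive_seed(seed, string_key(participant_id)), {
    v <- array(0, dim = c(n_el, n_s, n_tr))
    if (truth$noise_sd > 0) {
      if (noise == "white") {
        v[] <- rnorm(length(v), sd = truth$noise_sd)
      } else {
        pn <- pink_noise(n_el * n_tr, n_s, truth$noise_sd)
        for (tr in seq_len(n_tr)) {
          v[, , tr] <- pn[(tr - 1) * n_el + seq_len(n_el), ]
        }
      }
    }
    if (max(abs(sig)) > 0) {
      for (tr in seq_len(n_tr)) {
        v[, , tr] <- v[, , tr] + sig[, , match(labels[tr], cats)]
      }
    }
    spiked <- which(runif(n_tr) < artifact_rate)
    for (tr in spiked) {
      e <- sample.int(n_el, 1); s <- sample.int(n_s, 1)
      v[e, s, tr] <- v[e, s, tr] + sample(c(-1, 1), 1) * 150
    }
    dimnames(v) <- list(layout$electrode, NULL, NULL)
    new_eeg_epochs(v, labels, times, epoch$sampling_hz, participant_id,
                   categories = cats, artifact_trials = spiked)
  })
}

# 1/f-shaped noise: n series of length len, each scaled to sd `sd`.
# Spectral shaping of white noise: weight 1/sqrt(f) on the physical frequency.
pink_noise <- function(n, len, sd) {
  k <- 0:(len - 1)
  f <- pmin(k, len - k)
  w <- 1 / sqrt(pmax(f, 1))
  out <- matrix(0, n, len)
  for (i in seq_len(n)) {
    x <- Re(stats::fft(stats::fft(rnorm(len)) * w, inverse = TRUE)) / len
    out[i, ] <- x / stats::sd(x) * sd
  }
  out
}

#' Simulate a full multi-participant study
#'
#' Generates layout, feature banks, planted ground truth, and one epoch set
#' per participant with participant-specific noise draws (deterministic per
#' seed).
#'
#' @param preset A preset list (see [desk_preset()]).
#' @param seed Integer master seed.
#' @param artifact_rate Proportion of spiked trials per participant.
#' @param noise_sd Override the preset's noise sd (e.g. 0 for noiseless).
#' @param signal_uv,evoked_uv Optional overrides of the planted amplitudes.
#' @return List with `layout`, `banks`, `truth`, and `epochs` (one
#'   `eeg_epochs` per participant).
#' @export
simulate_study <- function(preset = desk_preset(), seed = 1, artifact_rate = 0,
                           noise_sd = NULL, signal_uv = NULL, evoked_uv = NULL) {
  layout <- gen_layout(preset$n_electrodes, seed = derive_seed(seed, 1))
  fb <- gen_feature_banks(preset$n_categories, preset$n_exemplars,
                          preset$layer_dims, preset$separability,
                          seed = derive_seed(seed, 2))
  truth <- plant_structure(
    fb$truth, layout,
    latency_start_ms = preset$latency_start_ms,
    latency_step_ms = preset$latency_step_ms,
    width_ms = preset$width_ms,
    n_regions = preset$n_regions, region_size = preset$region_size,
    evoked_uv = evoked_uv %||% preset$evoked_uv,
    signal_uv = signal_uv %||% preset$signal_uv,
    noise_sd = noise_sd %||% preset$noise_sd
  )
  ep <- list(baseline_ms = preset$baseline_ms, stim_ms = preset$stim_ms,
             sampling_hz = preset$sampling_hz)
  pid <- sprintf("P%02d", seq_len(preset$n_participants))
  epochs <- lapply(pid, function(p) {
    gen_epochs(layout, truth, preset$n_trials_per_category, ep,
               artifact_rate = artifact_rate, seed = seed, participant_id = p)
  })
  names(epochs) <- pid
  list(layout = layout, banks = fb$banks, truth = truth, epochs = epochs)
}
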