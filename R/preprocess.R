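#' Zero-phase band-pass filter an epoch set
#'
#' Per electrode and trial: removes the series mean (epochs are too short
#' for a 0.1 Hz recursive high-pass to settle, so the DC offset is taken
#' out exactly), then applies a 2nd-order Butterworth high-pass at `low_hz`
#' and a 4th-order Butterworth low-pass at `high_hz`, each run forward and
#' backward (zero phase; squared magnitude response). With the conventional
#' 0.1-45 Hz band this removes DC/drift and attenuates 60 Hz line noise by
#' more than 20 dB.
#'
#' @param epochs An `eeg_epochs` object.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `low_hz < high_hz < sampling_hz / 2`.
#' @return The filtered `eeg_epochs`.
#' @export
bandpass <- function(epochs, low_hz = 0.1, high_hz = 45) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  nyq <- epochs$sampling_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    abort("band edges must satisfy 0 < low_hz < high_hz < sampling_hz/2.",
          class = "strsa_bad_arg")
  }
  hp <- signal::butter(2, low_hz / nyq, type = "high")
  lp <- signal::butter(4, high_hz / nyq, type = "low")
  v <- epochs$voltages
  d <- dim(v)
  for (tr in seq_len(d[3])) {
    sl <- v[, , tr, drop = FALSE]
    dim(sl) <- d[1:2]
    v[, , tr] <- t(apply(sl, 1, function(x) {
      x <- x - mean(x)
      signal::filtfilt(lp, signal::filtfilt(hp, x))
    }))
  }
  epochs$voltages <- v
  epochs$filter <- c(low_hz = low_hz, high_hz = high_hz)
  epochs
}

#' Reject trials containing voltage artifacts
#'
#' Clears the validity flag of any trial containing at least one sample at
#' any electrode with `|V| > threshold_uv` (strict inequality: voltage
#' *exceeding* the threshold). Other trials are untouched. Errors if more
#' than half of the trials end up rejected, mirroring participant-level
#' exclusion.
#'
#' @param epochs An `eeg_epochs` object.
#' @param threshold_uv Rejection threshold in uV (default 100).
#' @return The `eeg_epochs` with an updated `valid` mask and a
#'   `rejection_fraction` field.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 100) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (threshold_uv <= 0) abort("`threshold_uv` must be positive.", class = "strsa_bad_arg")
  d <- dim(epochs$voltages)
  peak <- apply(abs(epochs$voltages), 3, max)
  bad <- peak > threshold_uv
  epochs$valid <- epochs$valid & !bad
  frac <- mean(bad)
  epochs$rejection_fraction <- frac
  if (mean(!epochs$valid) > 0.5) {
    abort(sprintf("participant %s: %.0f%% of trials rejected (fewer than half valid).",
                  epochs$participant_id, 100 * mean(!epochs$valid)),
          class = "strsa_participant_excluded")
  }
  epochs
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per electrode and trial, the mean voltage over the baseline
#' interval (default: the last 100 ms before stimulus onset, i.e. the whole
#' pre-stimulus period of the standard epoch).
#'
#' @param epochs An `eeg_epochs` object.
#' @param baseline_ms Length-2 interval `c(start, end)` in ms; samples with
#'   `start <= t < end` are used. Must lie in the pre-stimulus period and be
#'   non-empty.
#' @return The corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, baseline_ms = c(-100, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- which(epochs$times >= baseline_ms[1] & epochs$times < baseline_ms[2])
  if (length(idx) == 0) abort("empty baseline interval.", class = "strsa_bad_arg")
  if (any(epochs$times[idx] >= 0)) {
    abort("baseline interval must be pre-stimulus.", class = "strsa_bad_arg")
  }
  v <- epochs$voltages
  d <- dim(v)
  bl <- colMeans(aperm(v[, idx, , drop = FALSE], c(2, 1, 3)))  # electrodes x trials
  v <- v - aperm(array(bl, c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs$voltages <- v
  epochs$baseline_ms <- baseline_ms
  epochs
}

#' Sub-average bootstrapping of trials
#'
#' Replaces every valid trial by a surrogate: the mean of
#' `ceil(fraction * n_c)` distinct valid trials of the same category,
#' sampled uniformly without replacement with the anchor trial always
#' included. Output trial count equals the valid input trial count. Raises
#' the effective signal-to-noise ratio while keeping one surrogate per
#' trial. Sampling seeds are derived per (participant, category, trial id)
#' from the master seed, so results do not depend on trial ordering.
#'
#' @param epochs An `eeg_epochs` object.
#' @param fraction Proportion of same-category trials averaged into each
#'   surrogate, in `(0, 1]` (default 0.2).
#' @param seed Integer master seed.
#' @return An `eeg_epochs` of surrogate trials (all valid).
#' @export
subaverage_bootstrap <- function(epochs, fraction = 0.2, seed = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1].", class = "strsa_bad_arg")
  }
  keep <- which(epochs$valid)
  labels <- epochs$labels[keep]
  for (cc in epochs$categories) {
    if (sum(labels == cc) < 2) {
      abort(sprintf("category %s has fewer than 2 valid trials.", cc),
            class = "strsa_bad_arg")
    }
  }
  v <- epochs$voltages
  out <- array(0, dim = c(dim(v)[1], dim(v)[2], length(keep)),
               dimnames = dimnames(v))
  pkey <- string_key(epochs$participant_id)
  for (ci in seq_along(epochs$categories)) {
    cc <- epochs$categories[ci]
    members <- keep[labels == cc]
    n_c <- length(members)
    m <- ceiling(fraction * n_c)
    for (pos in seq_along(members)) {
      tr <- members[pos]
      others <- setdiff(members, tr)
      pick <- if (m > 1) {
        s <- derive_seed(seed, pkey, ci, epochs$trial_ids[tr])
        # sample by trial identity over a canonical ordering so the draw is
        # invariant to the storage order of trials
        ids <- sort(epochs$trial_ids[others])
        chosen <- with_seed(s, sample(ids, m - 1))
        others[match(chosen, epochs$trial_ids[others])]
      } else integer(0)
      sel <- c(tr, pick)
      out[, , match(tr, keep)] <-
        if (length(sel) == 1) v[, , sel] else rowMeans(v[, , sel, drop = FALSE], dims = 2)
    }
  }
  new_eeg_epochs(out, epochs$labels[keep], epochs$times, epochs$sampling_hz,
                 epochs$participant_id, trial_ids = epochs$trial_ids[keep],
                 categories = epochs$categories)
}

#' Per-category mean ERPs
#'
#' Averages valid trials within each category, yielding the category ERP
#' array the sliding-window RDM analysis consumes.
#'
#' @param epochs An `eeg_epochs` object; every category needs at least one
#'   valid trial.
#' @return A `category_erp`: list with `voltages` (electrodes x samples x
#'   categories), `times`, `sampling_hz`, `categories`, `n_trials_used`.
#' @export
category_means <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  v <- epochs$voltages
  cats <- epochs$categories
  out <- array(0, dim = c(dim(v)[1], dim(v)[2], length(cats)),
               dimnames = list(dimnames(v)[[1]], NULL, cats))
  n_used <- integer(length(cats))
  for (ci in seq_along(cats)) {
    sel <- which(epochs$valid & epochs$labels == cats[ci])
    if (length(sel) == 0) {
      abort(sprintf("category %s has no valid trials.", cats[ci]),
            class = "strsa_empty_category")
    }
    n_used[ci] <- length(sel)
    out[, , ci] <- if (length(sel) == 1) v[, , sel] else
      rowMeans(v[, , sel, drop = FALSE], dims = 2)
  }
  structure(
    list(voltages = out, times = epochs$times, sampling_hz = epochs$sampling_hz,
         categories = cats, n_trials_used = setNames(n_used, cats),
         participant_id = epochs$participant_id),
    class = "category_erp"
  )
}

#' @export
print.category_erp <- function(x, ...) {
  d <- dim(x$voltages)
  cat("<category_erp>", x$participant_id %||% "", "-", d[1], "electrodes x",
      d[2], "samples x", d[3], "categories @", x$sampling_hz, "Hz\n")
  invisible(x)
}

#' Re-reference epochs to the net (all-electrode) average
#'
#' Optional step: subtracts, per sample and trial, the mean across
#' electrodes. Off by default in the pipeline for synthetic data.
#' @param epochs An `eeg_epochs` object.
#' @return The re-referenced `eeg_epochs`.
#' @export
rereference_average <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  v <- epochs$voltages
  mu <- colMeans(v)                       # samples x trials
  epochs$voltages <- sweep(v, c(2, 3), mu)
  epochs
}
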