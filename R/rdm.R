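#' Construct a representational dissimilarity matrix
#'
#' Validates the RDM invariants: symmetry, zero diagonal, entries in
#' `[0, 2]`. The diagonal is stored as 0 but is never consumed by analyses
#' (only the lower triangle is).
#'
#' @param values Square numeric matrix of dissimilarities.
#' @param categories Ordered category identifiers.
#' @param source Provenance tag (e.g. layer id or electrode/window).
#' @return An `rdm` object.
#' @export
rdm <- function(values, categories = rownames(values), source = NULL) {
  if (is.null(categories)) categories <- sprintf("cat%02d", seq_len(nrow(values)))
  stopifnot(nrow(values) == ncol(values), length(categories) == nrow(values))
  if (max(abs(values - t(values))) > 1e-10) {
    abort("RDM must be symmetric.", class = "strsa_invalid_rdm")
  }
  if (max(abs(diag(values))) > 1e-10) {
    abort("RDM diagonal must be zero.", class = "strsa_invalid_rdm")
  }
  if (min(values) < -1e-10 || max(values) > 2 + 1e-10) {
    abort("RDM entries must lie in [0, 2].", class = "strsa_invalid_rdm")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(categories, categories)
  structure(list(values = values, categories = categories, source = source),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat("<rdm>", length(x$categories), "categories",
      if (!is.null(x$source)) paste0("(", x$source, ")"), "\n")
  invisible(x)
}

# 1 - Spearman between columns of m; errors on zero-variance columns unless
# `degenerate_ok`, in which case returns NULL with attribute naming them.
spearman_dissim <- function(m, names_for_error, degenerate_ok = FALSE) {
  r <- col_ranks(m)
  sds <- apply(r, 2, stats::sd)
  bad <- sds < 1e-12
  if (any(bad)) {
    if (degenerate_ok) {
      return(structure(NULL, degenerate = names_for_error[bad]))
    }
    abort(paste0("degenerate (zero rank variance) input for: ",
                 paste(names_for_error[bad], collapse = ", ")),
          class = "strsa_degenerate")
  }
  d <- 1 - stats::cor(r)
  diag(d) <- 0
  d
}

#' Feature-bank RDM
#'
#' Dissimilarity between categories i and j is 1 minus the Spearman rank
#' correlation (average ranks on ties) between the category-mean activation
#' rows of the bank.
#'
#' @param bank A `feature_bank` (>= 3 categories, >= 2 features).
#' @return An `rdm` tagged with the bank's layer id.
#' @export
feature_rdm <- function(bank) {
  stopifnot(inherits(bank, "feature_bank"))
  cm <- bank$category_means
  if (nrow(cm) < 3) abort("need >= 3 categories.", class = "strsa_bad_arg")
  if (ncol(cm) < 2) abort("need >= 2 features.", class = "strsa_bad_arg")
  d <- spearman_dissim(t(cm), rownames(cm))
  rdm(d, rownames(cm), source = bank$layer_id)
}

#' Single-electrode, single-window ERP RDM
#'
#' The feature vector of a category is its mean ERP voltage at the given
#' electrode over the samples of the half-open window
#' `[window_start_ms, window_start_ms + window_ms)`; the window is truncated
#' at the end of the epoch and must retain at least 3 samples.
#'
#' @param erp A `category_erp`.
#' @param electrode Electrode identifier.
#' @param window_start_ms Window start (ms relative to stimulus onset).
#' @param window_ms Window length in ms (default 40).
#' @return An `rdm` tagged `electrode@window_start`.
#' @export
erp_window_rdm <- function(erp, electrode, window_start_ms, window_ms = 40) {
  stopifnot(inherits(erp, "category_erp"))
  idx <- window_samples(erp$times, window_start_ms, window_ms)
  if (length(idx) < 3) {
    abort(sprintf("window at %g ms retains %d samples (< 3) after truncation.",
                  window_start_ms, length(idx)),
          class = "strsa_short_window")
  }
  e_i <- match(electrode, dimnames(erp$voltages)[[1]])
  if (is.na(e_i)) abort(sprintf("unknown electrode %s", electrode), class = "strsa_bad_arg")
  m <- erp$voltages[e_i, idx, ]             # samples x categories
  d <- spearman_dissim(m, erp$categories)
  rdm(d, erp$categories, source = sprintf("%s@%gms", electrode, window_start_ms))
}

window_samples <- function(times, start_ms, window_ms) {
  which(times >= start_ms & times < start_ms + window_ms)
}

#' Sliding-window RDM series over all electrodes
#'
#' Applies [erp_window_rdm()] at every electrode and every window start from
#' the beginning of the baseline to the end of the epoch at the given step.
#' Windows whose category vectors have zero rank variance (degenerate) are
#' flagged and stored as `NA`; windows truncated below 3 samples are
#' skipped. Only lower-triangle vectors are stored (row-major, j < i).
#'
#' @param erp A `category_erp`.
#' @param window_ms Window length in ms (default 40).
#' @param step_ms Step between window starts; default one sample.
#' @return An `rdm_series`: list with `values` (pairs x windows x
#'   electrodes), `window_starts`, `electrodes`, `categories`, `window_ms`,
#'   `step_ms`, `degenerate` (windows x electrodes logical), `skipped`
#'   (window starts dropped by truncation).
#' @export
sliding_rdms <- function(erp, window_ms = 40, step_ms = NULL) {
  stopifnot(inherits(erp, "category_erp"))
  dt <- 1000 / erp$sampling_hz
  step_ms <- step_ms %||% dt
  if (step_ms < dt) abort("`step_ms` must be at least one sample.", class = "strsa_bad_arg")
  starts <- seq(erp$times[1], max(erp$times), by = step_ms)
  keep <- vapply(starts, function(s) length(window_samples(erp$times, s, window_ms)) >= 3,
                 logical(1))
  skipped <- starts[!keep]
  starts <- starts[keep]
  cats <- erp$categories
  n_c <- length(cats)
  pim <- lt_pairs(n_c)
  electrodes <- dimnames(erp$voltages)[[1]]
  vals <- array(NA_real_, dim = c(nrow(pim), length(starts), length(electrodes)),
                dimnames = list(NULL, NULL, electrodes))
  degen <- matrix(FALSE, length(starts), length(electrodes),
                  dimnames = list(NULL, electrodes))
  win_idx <- lapply(starts, function(s) window_samples(erp$times, s, window_ms))
  win_len <- lengths(win_idx)
  for (len in unique(win_len)) {
    wsel <- which(win_len == len)
    # stack every (electrode, window) of this length: len x (n_c * |wsel| * E)
    blocks <- length(wsel) * length(electrodes)
    M <- matrix(0, len, n_c * blocks)
    b <- 0L
    for (e_i in seq_along(electrodes)) {
      for (w_i in wsel) {
        M[, b * n_c + seq_len(n_c)] <- erp$voltages[e_i, win_idx[[w_i]], ]
        b <- b + 1L
      }
    }
    R <- unit_center(col_ranks_grouped(M))
    bad <- attr(R, "degenerate")
    R[is.na(R)] <- 0
    b <- 0L
    for (e_i in seq_along(electrodes)) {
      for (w_i in wsel) {
        cols <- b * n_c + seq_len(n_c)
        if (any(bad[cols])) {
          degen[w_i, e_i] <- TRUE
        } else {
          d <- 1 - crossprod(R[, cols, drop = FALSE])
          vals[, w_i, e_i] <- d[pim]
        }
        b <- b + 1L
      }
    }
  }
  structure(
    list(values = vals, window_starts = starts, electrodes = electrodes,
         categories = cats, window_ms = window_ms, step_ms = step_ms,
         degenerate = degen, skipped = skipped,
         participant_id = erp$participant_id),
    class = "rdm_series"
  )
}

#' @export
print.rdm_series <- function(x, ...) {
  cat("<rdm_series>", x$participant_id %||% "", "-", length(x$electrodes),
      "electrodes x", length(x$window_starts), "windows,",
      length(x$categories), "categories,", x$window_ms, "ms window /",
      x$step_ms, "ms step\n")
  invisible(x)
}

#' Extract one RDM from a series
#' @param series An `rdm_series`.
#' @param electrode Electrode identifier.
#' @param window_start_ms A stored window start.
#' @return An `rdm`.
#' @export
series_rdm <- function(series, electrode, window_start_ms) {
  w_i <- which(abs(series$window_starts - window_start_ms) < 1e-9)
  stopifnot(length(w_i) == 1)
  v <- series$values[, w_i, electrode]
  rdm(square_from_lower(v, length(series$categories)), series$categories,
      source = sprintf("%s@%gms", electrode, window_start_ms))
}

#' Lower-triangle vector of an RDM
#'
#' Returns the `n(n-1)/2` below-diagonal entries in row-major order with
#' `j < i`: (2,1), (3,1), (3,2), (4,1), ... This fixed order is used for all
#' dissimilarity vectors in the package.
#'
#' @param x An `rdm` object or square symmetric matrix.
#' @return Numeric vector of length `n(n-1)/2`.
#' @export
lower_triangle <- function(x) {
  m <- if (inherits(x, "rdm")) x$values else x
  m[lt_pairs(nrow(m))]
}

#' Rebuild a square symmetric matrix from a lower-triangle vector
#' @param v Lower-triangle vector in the package's row-major order.
#' @param n Matrix dimension.
#' @return An `n` x `n` symmetric matrix with zero diagonal.
#' @export
square_from_lower <- function(v, n) {
  p <- lt_pairs(n)
  m <- matrix(0, n, n)
  m[p] <- v
  m[p[, c(2, 1), drop = FALSE]] <- v
  m
}

#' @export
tidy.rdm <- function(x, ...) {
  p <- lt_pairs(length(x$categories))
  tibble(
    category_i = x$categories[p[, 1]],
    category_j = x$categories[p[, 2]],
    dissimilarity = x$values[p]
  )
}

#' @export
autoplot.rdm <- function(object, ...) {
  df <- expand.grid(i = object$categories, j = object$categories)
  df$dissimilarity <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$dissimilarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 2)) +
    ggplot2::labs(title = object$source %||% "RDM", x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
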