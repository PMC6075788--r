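# Rank-based encoding of neural dissimilarity vectors on layer predictors.
#
# All fits operate on rank-transformed lower-triangle vectors (consistent
# with the Spearman dissimilarities they are built from). "Variance
# explained" for the joint model is the OLS R-squared on that rank scale.

# Orthonormal basis of cbind(1, X) handling rank deficiency via pivoting.
design_basis <- function(X, warn_collinear = TRUE) {
  M <- cbind(1, X)
  q <- qr(M)
  r <- q$rank
  if (r < ncol(M) && warn_collinear) {
    warn("collinear layer predictors; fitting via pseudoinverse.",
         class = "strsa_collinear")
  }
  qr.Q(q)[, seq_len(r), drop = FALSE]
}

#' Joint encoding of a neural dissimilarity vector on all layers
#'
#' Rank-transforms the neural vector and each layer vector, fits ordinary
#' least squares of the neural ranks on all layer ranks plus intercept, and
#' returns the R-squared together with per-pair residuals
#' (observed - fitted). Residuals are computed on the rank scale and
#' rescaled back to dissimilarity units by the ratio of the neural vector's
#' dissimilarity-scale to rank-scale standard deviation, so their sign and
#' relative magnitude are interpretable as under-/over-prediction of
#' dissimilarity.
#'
#' @param neural Lower-triangle dissimilarity vector.
#' @param layers List of layer dissimilarity vectors (same length), or a
#'   matrix with one column per layer.
#' @return List with `r2`, `residuals` (dissimilarity units),
#'   `residuals_rank`, and `collinear` flag.
#' @export
encode_all_layers <- function(neural, layers) {
  X <- if (is.matrix(layers)) layers else do.call(cbind, layers)
  m <- length(neural)
  stopifnot(nrow(X) == m)
  if (m < ncol(X) + 2) {
    abort("need at least 2 more observations than predictors.", class = "strsa_bad_arg")
  }
  yr <- rank(neural)
  Xr <- col_ranks(X)
  collinear <- qr(cbind(1, Xr))$rank < ncol(Xr) + 1
  Q <- design_basis(Xr)
  fitted <- Q %*% crossprod(Q, yr)
  res_rank <- yr - fitted
  tss <- sum((yr - mean(yr))^2)
  r2 <- if (tss < 1e-12) NA_real_ else 1 - sum(res_rank^2) / tss
  scale_back <- stats::sd(neural) / stats::sd(yr)
  list(r2 = as.numeric(r2),
       residuals = as.numeric(res_rank) * scale_back,
       residuals_rank = as.numeric(res_rank),
       collinear = collinear)
}

#' Single-layer encoding (signed Spearman correlation)
#'
#' @param neural,layer Dissimilarity vectors of equal length.
#' @return List with `rho` (Spearman correlation), `r2` (`rho^2`), and
#'   `sign`.
#' @export
encode_single_layer <- function(neural, layer) {
  stopifnot(length(neural) == length(layer))
  if (stats::sd(rank(neural)) < 1e-12 || stats::sd(rank(layer)) < 1e-12) {
    abort("degenerate (zero rank variance) dissimilarity vector.",
          class = "strsa_degenerate")
  }
  rho <- stats::cor(neural, layer, method = "spearman")
  list(rho = rho, r2 = rho^2, sign = sign(rho))
}

# Rank + center + unit-norm columns of the series value matrix; NA columns
# (degenerate windows) stay NA.
series_rank_matrix <- function(series) {
  Y <- matrix(series$values, nrow = dim(series$values)[1])
  ok <- !colSums(is.na(Y)) > 0
  Yc <- matrix(NA_real_, nrow(Y), ncol(Y))
  if (any(ok)) {
    Yc[, ok] <- unit_center(col_ranks(Y[, ok, drop = FALSE]))
  }
  Yc
}

layer_rank_design <- function(layer_rdms, categories) {
  X <- sapply(layer_rdms, function(r) {
    if (!identical(r$categories, categories)) {
      abort("layer RDM category order does not match the series.",
            class = "strsa_bad_arg")
    }
    lower_triangle(r)
  })
  colnames(X) <- vapply(layer_rdms, function(r) r$source %||% "layer", character(1))
  X
}

#' Time-resolved encoding traces for every electrode
#'
#' Applies the joint ([encode_all_layers()]) or single-layer
#' ([encode_single_layer()]) encoder at every (electrode, window start) of
#' an RDM series. Degenerate windows propagate as `NA` and are excluded
#' from downstream summaries. The significance column is left `NA` until a
#' permutation null is applied.
#'
#' @param series An `rdm_series`.
#' @param layers List of layer `rdm` objects (category order must match).
#' @param mode `"all"` (joint OLS R-squared) or `"single"` (per-layer
#'   signed Spearman).
#' @return An `encoding_trace` tibble with columns `unit`, `time`, `layer`,
#'   `rho`, `r2`, `sig`.
#' @export
trace_over_time <- function(series, layers, mode = c("all", "single")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "rdm_series"))
  X <- layer_rank_design(layers, series$categories)
  Yc <- series_rank_matrix(series)
  W <- length(series$window_starts); E <- length(series$electrodes)
  grid <- expand.grid(time = series$window_starts, unit = series$electrodes,
                      stringsAsFactors = FALSE)
  if (mode == "all") {
    Xr <- col_ranks(X)
    Q <- design_basis(Xr, warn_collinear = FALSE)
    r2 <- colSums(crossprod(Q, ifelse(is.na(Yc), 0, Yc))^2)
    r2[colSums(is.na(Yc)) > 0] <- NA_real_
    out <- tibble(unit = grid$unit, time = grid$time, layer = "all",
                  rho = NA_real_, r2 = r2, sig = NA)
  } else {
    Xc <- unit_center(col_ranks(X))
    R <- crossprod(Xc, ifelse(is.na(Yc), 0, Yc))   # layers x (W*E)
    R[, colSums(is.na(Yc)) > 0] <- NA_real_
    out <- bind_rows(lapply(seq_len(ncol(X)), function(l) {
      tibble(unit = grid$unit, time = grid$time, layer = colnames(X)[l],
             rho = R[l, ], r2 = R[l, ]^2, sig = NA)
    }))
  }
  structure(out, class = c("encoding_trace", class(tibble())),
            mode = mode, window_starts = series$window_starts,
            participant_id = series$participant_id)
}

#' Average encoding traces over participants
#' @param traces List of `encoding_trace` tibbles on the same grid.
#' @return Group-level `encoding_trace` (statistics averaged).
#' @export
group_trace <- function(traces) {
  out <- bind_rows(traces) |>
    group_by(.data$unit, .data$time, .data$layer) |>
    summarise(rho = mean(.data$rho), r2 = mean(.data$r2), .groups = "drop") |>
    mutate(sig = NA)
  structure(out, class = c("encoding_trace", class(tibble())),
            mode = attr(traces[[1]], "mode"),
            window_starts = attr(traces[[1]], "window_starts"))
}

#' Average an encoding trace over electrodes into one scalp unit
#' @param trace An `encoding_trace`.
#' @return `encoding_trace` with a single unit `"scalp"`.
#' @export
scalp_average <- function(trace) {
  out <- trace |>
    group_by(.data$time, .data$layer) |>
    summarise(rho = mean(.data$rho, na.rm = TRUE),
              r2 = mean(.data$r2, na.rm = TRUE), .groups = "drop") |>
    mutate(unit = "scalp", sig = NA) |>
    select("unit", "time", "layer", "rho", "r2", "sig")
  structure(out, class = c("encoding_trace", class(tibble())),
            mode = attr(trace, "mode"), window_starts = attr(trace, "window_starts"))
}

#' Onset / maximum / latency summaries of an encoding trace
#'
#' For each (unit, layer): the onset is the first significant time point at
#' or after stimulus onset (pre-stimulus windows cannot carry
#' stimulus-driven signal, so onsets are reported on post-stimulus time
#' only); within each requested time bin, the
#' maximum explained variance and its latency are computed over non-missing
#' time points. Units or layers with no significant cluster report an
#' absent (`NA`) onset, never 0.
#'
#' @param trace An `encoding_trace` whose `sig` column has been populated.
#' @param bins List of `c(start, end)` intervals in ms (default the
#'   0-100 / 101-200 / 200-300 ms partition).
#' @return Tibble with columns `unit`, `layer`, `onset_ms`, `bin`,
#'   `max_r2`, `latency_ms`.
#' @export
summarize_trace <- function(trace,
                            bins = list(c(0, 100), c(101, 200), c(200, 300))) {
  if (all(is.na(trace$sig))) {
    abort("significance mask not populated; run the permutation stage first.",
          class = "strsa_bad_arg")
  }
  bin_lab <- vapply(bins, function(b) sprintf("%g-%g", b[1], b[2]), character(1))
  trace |>
    group_by(.data$unit, .data$layer) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$time)
      sig_t <- df$time[!is.na(df$sig) & df$sig & df$time >= 0]
      onset <- if (length(sig_t) == 0) NA_real_ else sig_t[1]
      bind_rows(lapply(seq_along(bins), function(bi) {
        b <- bins[[bi]]
        sel <- df$time >= b[1] & df$time <= b[2] & !is.na(df$r2)
        if (!any(sel)) {
          tibble(onset_ms = onset, bin = bin_lab[bi],
                 max_r2 = NA_real_, latency_ms = NA_real_)
        } else {
          k <- which(sel)[which.max(df$r2[sel])]
          tibble(onset_ms = onset, bin = bin_lab[bi],
                 max_r2 = df$r2[k], latency_ms = df$time[k])
        }
      }))
    }) |>
    ungroup()
}

#' Mean all-layer encoding residuals over electrodes
#'
#' Runs the joint encoder at every (electrode, window) of a series and
#' returns the residual vectors (dissimilarity units) averaged over
#' electrodes: a pairs x windows matrix for one participant.
#'
#' @param series An `rdm_series`.
#' @param layers List of layer `rdm` objects.
#' @return Matrix pairs x windows with attribute `window_starts`.
#' @export
encoding_residuals <- function(series, layers) {
  X <- layer_rank_design(layers, series$categories)
  Xr <- col_ranks(X)
  Q <- design_basis(Xr, warn_collinear = FALSE)
  n_pair <- dim(series$values)[1]
  W <- length(series$window_starts); E <- length(series$electrodes)
  acc <- matrix(0, n_pair, W)
  cnt <- matrix(0, 1, W)
  for (e_i in seq_len(E)) {
    Y <- series$values[, , e_i]
    ok <- colSums(is.na(Y)) == 0
    if (!any(ok)) next
    Yr <- col_ranks(Y[, ok, drop = FALSE])
    fitted <- Q %*% crossprod(Q, Yr)
    res <- Yr - fitted
    scale_back <- apply(Y[, ok, drop = FALSE], 2, stats::sd) /
      pmax(apply(Yr, 2, stats::sd), 1e-12)
    res <- sweep(res, 2, scale_back, "*")
    acc[, ok] <- acc[, ok] + res
    cnt[ok] <- cnt[ok] + 1
  }
  out <- sweep(acc, 2, pmax(cnt, 1), "/")
  out[, cnt == 0] <- NA_real_
  attr(out, "window_starts") <- series$window_starts
  attr(out, "categories") <- series$categories
  out
}

#' Default superordinate grouping of categories
#'
#' Splits the ordered category list into three equal blocks labelled
#' `indoor`, `urban_outdoor`, `natural_outdoor` (the synthetic analogue of
#' the three superordinate scene classes).
#' @param categories Ordered category identifiers (length divisible by 3).
#' @return Named character vector category -> superordinate.
#' @export
superordinate_grouping <- function(categories) {
  n <- length(categories)
  g <- rep(c("indoor", "urban_outdoor", "natural_outdoor"), each = ceiling(n / 3))[seq_len(n)]
  setNames(g, categories)
}

#' Superordinate residual analysis
#'
#' Averages residual vectors over the windows inside a time interval and
#' over participants, reshapes the result into the symmetric category x
#' category matrix, and block-averages it into the 3 x 3 superordinate
#' matrix. Within-block cells average only the block's off-diagonal pairs.
#' Residuals follow the convention observed minus fitted dissimilarity: a
#' negative value means the observed neural dissimilarity fell short of the
#' model's prediction (the model over-predicted dissimilarity). The
#' `sign_flip` argument returns the similarity-space reading instead.
#'
#' @param residuals_list List (one per participant) of pairs x windows
#'   residual matrices from [encoding_residuals()].
#' @param window `c(start, end)` in ms (default 50-250).
#' @param grouping Named vector category -> superordinate covering all
#'   categories.
#' @param sign_flip If `TRUE`, negate residuals (similarity-space view).
#' @return A `residual_summary`: list with `residual_matrix` (category x
#'   category), `superordinate_matrix` (3 x 3), and `grouping`.
#' @export
residual_analysis <- function(residuals_list, window = c(50, 250),
                              grouping = NULL, sign_flip = FALSE) {
  ws <- attr(residuals_list[[1]], "window_starts")
  cats <- attr(residuals_list[[1]], "categories")
  grouping <- grouping %||% superordinate_grouping(cats)
  miss <- setdiff(cats, names(grouping))
  if (length(miss)) {
    abort(paste0("grouping missing categories: ", paste(miss, collapse = ", ")),
          class = "strsa_bad_arg")
  }
  sel <- which(ws >= window[1] & ws <= window[2])
  if (length(sel) == 0) abort("no windows inside the residual interval.", class = "strsa_bad_arg")
  v <- rowMeans(sapply(residuals_list, function(r) rowMeans(r[, sel, drop = FALSE], na.rm = TRUE)))
  if (sign_flip) v <- -v
  n <- length(cats)
  m <- square_from_lower(v, n)
  dimnames(m) <- list(cats, cats)
  groups <- unique(unname(grouping[cats]))
  sup <- matrix(NA_real_, length(groups), length(groups), dimnames = list(groups, groups))
  p <- lt_pairs(n)
  gi <- grouping[cats[p[, 1]]]; gj <- grouping[cats[p[, 2]]]
  for (a in groups) for (b in groups) {
    sel_ab <- (gi == a & gj == b) | (gi == b & gj == a)
    sup[a, b] <- mean(v[sel_ab])
  }
  structure(list(residual_matrix = m, superordinate_matrix = sup,
                 grouping = grouping, window = window),
            class = "residual_summary")
}

#' @export
print.residual_summary <- function(x, ...) {
  cat("<residual_summary> window", x$window[1], "-", x$window[2], "ms\n")
  print(round(x$superordinate_matrix, 4))
  invisible(x)
}

#' @export
tidy.encoding_trace <- function(x, ...) as_tibble(x)

#' @export
autoplot.encoding_trace <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$r2, colour = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~unit) +
    ggplot2::labs(x = "time from stimulus onset (ms)", y = expression(r^2),
                  title = "Time-resolved explained variance") +
    ggplot2::theme_minimal()
  if (!all(is.na(df$sig))) {
    sig <- df[!is.na(df$sig) & df$sig, ]
    if (nrow(sig)) {
      p <- p + ggplot2::geom_point(data = sig, ggplot2::aes(y = -0.002), shape = 15, size = 0.8)
    }
  }
  p
}
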