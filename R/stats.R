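#' Permute the category labels of an RDM
#'
#' Jointly reindexes rows and columns, preserving symmetry — the label
#' exchange that generates the permutation null.
#'
#' @param x An `rdm`.
#' @param perm Integer permutation of `seq_along(x$categories)` (a
#'   bijection).
#' @return The relabelled `rdm` (categories keep their original order;
#'   values move).
#' @export
permute_rdm_labels <- function(x, perm) {
  stopifnot(inherits(x, "rdm"))
  n <- length(x$categories)
  if (length(perm) != n || !setequal(perm, seq_len(n))) {
    abort("`perm` must be a bijection over the categories.", class = "strsa_bad_arg")
  }
  rdm(x$values[perm, perm], x$categories, source = x$source)
}

#' Build a group-level permutation null for an encoding statistic
#'
#' For permutation b >= 1, every participant's neural RDMs get an
#' independent category relabelling, the encoder is recomputed at every
#' time point, and the group-mean statistic (mean over participants, and
#' over electrodes for the `"scalp"` unit) is stored. Permutation 0 is the
#' identity, reproducing the observed statistic. Relabelling the neural
#' vector by a permutation equals relabelling the predictors by its
#' inverse, which is how the computation is vectorised.
#'
#' @param series_list One `rdm_series` per participant (shared category
#'   order and time grid).
#' @param layers List of layer `rdm` objects.
#' @param mode `"all"` (joint R-squared) or `"single"` (one layer's
#'   squared Spearman); for `"single"` supply `layer` as index into
#'   `layers`.
#' @param layer Layer index used when `mode = "single"`.
#' @param unit `"scalp"` (average over electrodes) or one electrode id.
#' @param n_permutations Number of relabellings (default 1000; fewer than
#'   100 triggers a warning about unstable tails).
#' @param seed Integer seed; the null is deterministic per seed.
#' @return A `perm_null`: list with `stat` ((n_permutations + 1) x windows,
#'   row 1 observed), `window_starts`, `n_permutations`, `seed`.
#' @export
build_null <- function(series_list, layers, mode = c("all", "single"),
                       layer = 1L, unit = "scalp", n_permutations = 1000,
                       seed = 1) {
  mode <- match.arg(mode)
  if (n_permutations < 100) {
    warn("fewer than 100 permutations: null tail quantiles are unstable.",
         class = "strsa_few_permutations")
  }
  s0 <- series_list[[1]]
  for (s in series_list) {
    stopifnot(identical(s$categories, s0$categories),
              isTRUE(all.equal(s$window_starts, s0$window_starts)))
  }
  n_cat <- length(s0$categories)
  W <- length(s0$window_starts)
  pim <- pair_index_matrix(n_cat)
  X <- layer_rank_design(layers, s0$categories)
  B <- n_permutations
  stat <- matrix(0, B + 1, W)
  contrib <- matrix(0, B + 1, W)   # participants contributing (non-degenerate)
  perms <- with_seed(derive_seed(seed, 13), {
    lapply(seq_along(series_list), function(p) {
      cbind(seq_len(n_cat), replicate(B, sample.int(n_cat)))
    })
  })
  for (p_i in seq_along(series_list)) {
    s <- series_list[[p_i]]
    if (unit == "scalp") {
      Yc <- series_rank_matrix(s)
      E <- length(s$electrodes)
    } else {
      e_i <- match(unit, s$electrodes)
      if (is.na(e_i)) abort(sprintf("unknown unit %s", unit), class = "strsa_bad_arg")
      sub <- s
      sub$values <- s$values[, , e_i, drop = FALSE]
      Yc <- series_rank_matrix(sub)
      E <- 1L
    }
    na_col <- colSums(is.na(Yc)) > 0
    Yc0 <- ifelse(is.na(Yc), 0, Yc)
    pp <- perms[[p_i]]
    if (mode == "all") {
      Xr <- col_ranks(X)
      Xc <- sweep(Xr, 2, colMeans(Xr))
      # the Gram matrix is invariant under row permutation, so factor once:
      # R^2(y; X[pe, ]) = c' G^-1 c with c = X[pe, ]' y
      L <- tryCatch(t(chol(crossprod(Xc))), error = function(e) NULL)
      sb <- if (!is.null(L)) {
        vapply(seq_len(B + 1), function(b) {
          pe <- pair_permutation(pp[, b], pim)
          C <- crossprod(Xc[pe, , drop = FALSE], Yc0)
          colSums(forwardsolve(L, C)^2)
        }, numeric(ncol(Yc0)))
      } else {
        # collinear design: pivoted-QR fallback
        vapply(seq_len(B + 1), function(b) {
          pe <- pair_permutation(pp[, b], pim)
          Q <- design_basis(Xr[pe, , drop = FALSE], warn_collinear = FALSE)
          colSums(crossprod(Q, Yc0)^2)
        }, numeric(ncol(Yc0)))
      }
    } else {
      xc <- unit_center(col_ranks(X[, layer, drop = FALSE]))
      Xp <- vapply(seq_len(B + 1), function(b) {
        xc[pair_permutation(pp[, b], pim), 1]
      }, numeric(nrow(xc)))
      sb <- crossprod(Yc0, Xp)^2      # (W*E) x (B+1)
    }
    sb[na_col, ] <- NA_real_
    # average over electrodes within participant, then accumulate
    dim(sb) <- c(W, E, B + 1)
    m_we <- apply(sb, c(1, 3), mean, na.rm = TRUE)   # W x (B+1)
    good <- apply(sb, c(1, 3), function(z) any(!is.na(z)))
    m_we[!good] <- 0
    stat <- stat + t(m_we)
    contrib <- contrib + t(good)
  }
  stat <- stat / pmax(contrib, 1)
  stat[contrib == 0] <- NA_real_
  structure(list(stat = stat, window_starts = s0$window_starts,
                 n_permutations = B, seed = as.integer(seed),
                 mode = mode, unit = unit),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat("<perm_null>", x$n_permutations, "permutations x",
      length(x$window_starts), "windows (", x$mode, ",", x$unit, ")\n")
  invisible(x)
}

#' Cluster-extent multiple-comparison correction
#'
#' Thresholds the observed per-time statistic at the pointwise `1 - alpha`
#' quantile of the permutation null (one-sided). Contiguous suprathreshold
#' runs form temporal clusters; a cluster survives iff its length strictly
#' exceeds the `1 - alpha / n_comparisons` quantile of the null
#' distribution of maximum cluster length (each null permutation
#' thresholded the same way; the Bonferroni divisor corrects the
#' cluster-level test over the units tested simultaneously).
#'
#' @param observed Per-time statistic; defaults to the null's identity
#'   permutation (row 1).
#' @param null A `perm_null`.
#' @param alpha Significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor (default 1).
#' @return Logical significance mask over time, with attributes
#'   `pointwise_threshold` and `max_run_critical`.
#' @export
cluster_extent_correct <- function(observed = NULL, null, alpha = 0.05,
                                   n_comparisons = 1) {
  stopifnot(inherits(null, "perm_null"))
  if (nrow(null$stat) < 2) abort("empty permutation null.", class = "strsa_bad_arg")
  observed <- observed %||% null$stat[1, ]
  perm <- null$stat[-1, , drop = FALSE]
  thr <- apply(perm, 2, quantile, probs = 1 - alpha, na.rm = TRUE, names = FALSE)
  above <- function(x) !is.na(x) & !is.na(thr) & x > thr
  max_runs <- apply(perm, 1, function(row) max_run_length(above(row)))
  crit <- quantile(max_runs, probs = 1 - alpha / n_comparisons,
                   names = FALSE, type = 1)
  obs_mask <- above(observed)
  r <- rle(obs_mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > crit
  mask <- rep(FALSE, length(obs_mask))
  for (k in which(keep)) mask[starts[k]:ends[k]] <- TRUE
  attr(mask, "pointwise_threshold") <- thr
  attr(mask, "max_run_critical") <- crit
  mask
}

#' Attach a significance mask to an encoding trace
#'
#' @param trace An `encoding_trace`.
#' @param mask Logical mask over the trace's time grid.
#' @param unit,layer Which (unit, layer) rows receive the mask.
#' @return The trace with its `sig` column populated for those rows.
#' @export
apply_sig_mask <- function(trace, mask, unit, layer = "all") {
  ws <- sort(unique(trace$time))
  stopifnot(length(mask) == length(ws))
  sel <- trace$unit == unit & trace$layer == layer
  trace$sig[sel] <- mask[match(trace$time[sel], ws)]
  trace
}

#' Noise ceiling from per-participant RDMs
#'
#' Upper bound: mean over participants of the Spearman correlation between
#' each participant's lower-triangle vector and the group-mean vector
#' (overfit, hence an overestimate). Lower bound: mean correlation of each
#' participant with the mean of the remaining participants (leave one out).
#' Degenerate participant vectors are excluded with a notice.
#'
#' @param subject_rdms List of `rdm` objects or lower-triangle vectors, one
#'   per participant (>= 3 after exclusions).
#' @param squared Return squared-correlation scale.
#' @return List with `lower`, `upper`, `n_participants`.
#' @export
noise_ceiling <- function(subject_rdms, squared = FALSE) {
  vecs <- lapply(subject_rdms, function(x) if (inherits(x, "rdm")) lower_triangle(x) else x)
  ok <- vapply(vecs, function(v) stats::sd(rank(v)) > 1e-12, logical(1))
  if (any(!ok)) {
    inform(sprintf("excluding %d degenerate participant RDM(s) from the noise ceiling.",
                   sum(!ok)))
  }
  vecs <- vecs[ok]
  n <- length(vecs)
  if (n < 3) abort("noise ceiling needs at least 3 participants.", class = "strsa_bad_arg")
  V <- do.call(cbind, vecs)
  grand <- rowMeans(V)
  upper <- mean(vapply(seq_len(n), function(i) {
    stats::cor(V[, i], grand, method = "spearman")
  }, numeric(1)))
  lower <- mean(vapply(seq_len(n), function(i) {
    stats::cor(V[, i], rowMeans(V[, -i, drop = FALSE]), method = "spearman")
  }, numeric(1)))
  if (squared) {
    upper <- sign(upper) * upper^2
    lower <- sign(lower) * lower^2
  }
  list(lower = lower, upper = upper, n_participants = n)
}

#' Time-resolved noise ceiling for an electrode (or scalp mean)
#'
#' @param series_list One `rdm_series` per participant.
#' @param unit One electrode id, or `"scalp"` to use the mean dissimilarity
#'   vector over electrodes per participant.
#' @param squared Squared-correlation scale.
#' @return Tibble with columns `time`, `lower`, `upper`.
#' @export
noise_ceiling_series <- function(series_list, unit = "scalp", squared = FALSE) {
  s0 <- series_list[[1]]
  ws <- s0$window_starts
  rows <- lapply(seq_along(ws), function(w_i) {
    vecs <- lapply(series_list, function(s) {
      if (unit == "scalp") {
        rowMeans(s$values[, w_i, , drop = TRUE], na.rm = TRUE)
      } else {
        s$values[, w_i, unit]
      }
    })
    keep <- vapply(vecs, function(v) !anyNA(v) && stats::sd(rank(v)) > 1e-12, logical(1))
    if (sum(keep) < 3) {
      tibble(time = ws[w_i], lower = NA_real_, upper = NA_real_)
    } else {
      nc <- noise_ceiling(vecs[keep], squared = squared)
      tibble(time = ws[w_i], lower = nc$lower, upper = nc$upper)
    }
  })
  bind_rows(rows)
}
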