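#' Baseline-normalized voltage topography
#'
#' z-transforms a grand-average ERP against its pre-stimulus baseline: for
#' electrode e and time t, `z(e, t) = (V(e, t) - mean_baseline(e)) /
#' sd_baseline(e)`.
#'
#' @param erp A `category_erp` (averaged over participants beforehand) or a
#'   plain electrodes x samples matrix; a `category_erp` is first averaged
#'   over categories.
#' @param times Sample latencies (taken from the `category_erp` if given).
#' @param baseline `c(start, end)` ms interval, pre-stimulus, with at least
#'   10 samples.
#' @return A `z_map`: list with `z` (electrodes x samples), `times`,
#'   `baseline`.
#' @export
z_topography <- function(erp, times = NULL, baseline = c(-100, 0)) {
  if (inherits(erp, "category_erp")) {
    times <- erp$times
    v <- rowMeans(erp$voltages, dims = 2)
  } else {
    v <- erp
    if (is.null(times)) abort("`times` required for a matrix input.", class = "strsa_bad_arg")
  }
  idx <- which(times >= baseline[1] & times < baseline[2])
  if (length(idx) < 10) abort("baseline needs at least 10 samples.", class = "strsa_bad_arg")
  if (any(times[idx] >= 0)) abort("baseline must be pre-stimulus.", class = "strsa_bad_arg")
  mu <- rowMeans(v[, idx, drop = FALSE])
  s <- apply(v[, idx, drop = FALSE], 1, stats::sd)
  bad <- s < 1e-12
  if (any(bad)) {
    abort(paste0("zero baseline variance at electrode(s): ",
                 paste(rownames(v)[bad], collapse = ", ")),
          class = "strsa_degenerate")
  }
  z <- (v - mu) / s
  structure(list(z = z, times = times, baseline = baseline), class = "z_map")
}

# Expected neighbour correlation of a graph-smoothed field x + w * N x,
# where N averages each electrode's neighbours. Closed form from the
# covariance (I + wN)(I + wN)'.
smoothed_neighbor_cor <- function(w, adj) {
  deg <- rowSums(adj)
  N <- adj / deg
  A <- diag(nrow(adj)) + w * N
  Cov <- tcrossprod(A)
  s <- sqrt(diag(Cov))
  mean((Cov / outer(s, s))[adj])
}

# Monte-Carlo null of the maximum suprathreshold component size on
# smoothness-matched Gaussian maps.
cluster_size_null <- function(adj, zcrit, target_cor, n_sim, seed) {
  w <- 0
  if (!is.na(target_cor) && target_cor > 0.01) {
    f <- function(w) smoothed_neighbor_cor(w, adj) - target_cor
    hi <- 5
    w <- if (f(hi) < 0) hi else stats::uniroot(f, c(0, hi))$root
  }
  deg <- rowSums(adj)
  N <- adj / deg
  A <- diag(nrow(adj)) + w * N
  s <- sqrt(rowSums(A^2))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      z <- drop(A %*% rnorm(nrow(adj))) / s
      on <- abs(z) > zcrit
      if (!any(on)) return(0L)
      comp <- igraph::components(igraph::induced_subgraph(g, which(on)))
      as.integer(max(comp$csize))
    }, integer(1))
  })
}

#' Find spatially contiguous electrode clusters over time
#'
#' At each time point, electrodes whose |z| exceeds the two-sided
#' `point_alpha` normal quantile are grouped into connected components of
#' the layout adjacency graph. Components smaller than a Monte-Carlo
#' cluster-size threshold — the 95th percentile of the maximum component
#' size on Gaussian noise maps spatially smoothed to match the baseline
#' data's neighbour correlation — are dropped. Surviving components are
#' tracked across consecutive time points by electrode-set Jaccard overlap
#' (> 0.5); tracks persisting no more than `min_duration_ms` are discarded.
#'
#' @param zmap A `z_map` from [z_topography()].
#' @param layout The `sensor_layout` (same electrodes).
#' @param point_alpha Pointwise two-sided significance level (default
#'   0.001).
#' @param min_duration_ms Minimum persistence (default 20 ms; strict).
#' @param size_calibration Use the Monte-Carlo size threshold (default
#'   `TRUE`; set `FALSE` to keep all component sizes).
#' @param n_sim Monte-Carlo maps for the size null.
#' @param seed Seed for the size null.
#' @return A `scalp_clusters` tibble: `cluster`, `electrodes` (list-col,
#'   union over the track), `n_electrodes`, `onset_ms`, `offset_ms`,
#'   `peak_z`.
#' @export
find_clusters <- function(zmap, layout, point_alpha = 0.001,
                          min_duration_ms = 20, size_calibration = TRUE,
                          n_sim = 500, seed = 1) {
  stopifnot(inherits(zmap, "z_map"), inherits(layout, "sensor_layout"))
  adj <- layout_adjacency(layout)
  if (nrow(adj) == 0) abort("empty layout.", class = "strsa_bad_arg")
  if (!identical(rownames(adj), rownames(zmap$z))) {
    if (is.null(rownames(zmap$z))) rownames(zmap$z) <- rownames(adj)
    else abort("zmap and layout electrodes differ.", class = "strsa_bad_arg")
  }
  zcrit <- qnorm(1 - point_alpha / 2)
  size_crit <- 0L
  if (size_calibration) {
    bidx <- which(zmap$times >= zmap$baseline[1] & zmap$times < zmap$baseline[2])
    zb <- zmap$z[, bidx, drop = FALSE]
    nb_cor <- mean(stats::cor(t(zb))[adj])
    sizes <- cluster_size_null(adj, zcrit, nb_cor, n_sim, seed)
    size_crit <- quantile(sizes, 0.95, names = FALSE, type = 1)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  dt <- diff(zmap$times[1:2])
  ids <- rownames(adj)
  # per-time surviving components
  comp_at <- lapply(seq_along(zmap$times), function(t_i) {
    on <- which(abs(zmap$z[, t_i]) > zcrit)
    if (length(on) == 0) return(list())
    cc <- igraph::components(igraph::induced_subgraph(g, on))
    out <- split(ids[on], cc$membership)
    out[lengths(out) > size_crit]
  })
  # track components over time by Jaccard > 0.5
  tracks <- list()   # each: list(members=list of sets, t=time indices)
  active <- list()
  for (t_i in seq_along(comp_at)) {
    comps <- comp_at[[t_i]]
    matched_active <- rep(FALSE, length(active))
    new_active <- list()
    for (cmp in comps) {
      best <- 0; best_j <- 0
      for (j in seq_along(active)) {
        if (matched_active[j]) next
        prev <- active[[j]]$members[[length(active[[j]]$members)]]
        jac <- length(intersect(cmp, prev)) / length(union(cmp, prev))
        if (jac > best) { best <- jac; best_j <- j }
      }
      if (best > 0.5) {
        tr <- active[[best_j]]
        tr$members <- c(tr$members, list(cmp))
        tr$t <- c(tr$t, t_i)
        new_active <- c(new_active, list(tr))
        matched_active[best_j] <- TRUE
      } else {
        new_active <- c(new_active, list(list(members = list(cmp), t = t_i)))
      }
    }
    tracks <- c(tracks, active[!matched_active])
    active <- new_active
  }
  tracks <- c(tracks, active)
  rows <- lapply(tracks, function(tr) {
    onset <- zmap$times[min(tr$t)]
    offset <- zmap$times[max(tr$t)] + dt
    if (offset - onset <= min_duration_ms) return(NULL)
    all_els <- sort(unique(unlist(tr$members)))
    # stable membership: electrodes present in more than half of the
    # track's time points (transient accretions excluded); union kept too
    counts <- table(unlist(tr$members))
    core <- sort(names(counts)[counts > length(tr$t) / 2])
    if (length(core) == 0) core <- all_els
    if (length(core) > 1) {
      sub <- igraph::induced_subgraph(g, match(core, ids))
      comp <- igraph::components(sub)
      core <- sort(core[comp$membership == which.max(comp$csize)])
    }
    tibble(electrodes = list(core), n_electrodes = length(core),
           electrodes_union = list(all_els),
           onset_ms = onset, offset_ms = offset,
           peak_z = max(abs(zmap$z[all_els, tr$t])))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) bind_rows(rows) else
    tibble(electrodes = list(), n_electrodes = integer(),
           electrodes_union = list(), onset_ms = numeric(),
           offset_ms = numeric(), peak_z = numeric())
  out <- arrange(out, .data$onset_ms)
  out <- mutate(out, cluster = sprintf("C%d", dplyr::row_number()),
                .before = 1)
  structure(out, class = c("scalp_clusters", class(tibble())),
            size_critical = size_crit, point_alpha = point_alpha)
}

#' Average a category ERP over a cluster's electrodes
#'
#' @param erp A `category_erp`.
#' @param cluster A `scalp_clusters` row, list of electrode ids, or
#'   character vector of electrode ids.
#' @return A `category_erp` with a single virtual electrode.
#' @export
cluster_erp <- function(erp, cluster) {
  stopifnot(inherits(erp, "category_erp"))
  els <- if (is.character(cluster)) cluster else unlist(cluster$electrodes)
  miss <- setdiff(els, dimnames(erp$voltages)[[1]])
  if (length(miss)) {
    abort(paste0("cluster electrodes absent from ERP: ", paste(miss, collapse = ", ")),
          class = "strsa_bad_arg")
  }
  v <- erp$voltages[els, , , drop = FALSE]
  m <- apply(v, c(2, 3), mean)
  out <- erp
  out$voltages <- array(m, dim = c(1, dim(m)),
                        dimnames = c(list("cluster"), dimnames(m)))
  dimnames(out$voltages) <- list("cluster", NULL, erp$categories)
  out
}

#' Jaccard overlap between two electrode sets
#' @param a,b Character vectors of electrode ids.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' @export
tidy.scalp_clusters <- function(x, ...) {
  as_tibble(x) |>
    mutate(electrodes = vapply(.data$electrodes, paste, character(1), collapse = ";"))
}

#' @export
autoplot.scalp_clusters <- function(object, layout, ...) {
  stopifnot(inherits(layout, "sensor_layout"))
  mem <- bind_rows(lapply(seq_len(nrow(object)), function(i) {
    tibble(cluster = object$cluster[i], electrode = unlist(object$electrodes[i]))
  }))
  df <- left_join(as_tibble(layout), mem, by = "electrode")
  df$cluster[is.na(df$cluster)] <- "none"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$cluster)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Scalp clusters", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
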