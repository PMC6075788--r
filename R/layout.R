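#' Generate a sensor layout on the unit disc
#'
#' Places electrodes on concentric rings covering the unit disc and derives a
#' neighbourhood (adjacency) relation from inter-electrode distance. The
#' adjacency graph is what the scalp clustering stage uses to decide spatial
#' contiguity.
#'
#' @param n_electrodes Number of electrodes (>= 8).
#' @param adjacency_radius Two electrodes are neighbours iff their Euclidean
#'   distance is strictly below this radius. Default: 1.5 times the median
#'   nearest-neighbour distance of the generated positions.
#' @param seed Integer seed; fixes the angular phase of each ring.
#'
#' @return A `sensor_layout` object: a tibble with columns `electrode`, `x`,
#'   `y`, plus an `adjacency` attribute (symmetric logical matrix with an
#'   all-`FALSE` diagonal).
#' @export
gen_layout <- function(n_electrodes, adjacency_radius = NULL, seed = 1) {
  if (n_electrodes < 8) {
    abort("`n_electrodes` must be at least 8.", class = "strsa_bad_arg")
  }
  n <- as.integer(n_electrodes)
  # ring radii and per-ring counts proportional to circumference
  n_rings <- max(1L, round(sqrt(n / 3)))
  radii <- seq_len(n_rings) / n_rings * 0.95
  raw <- radii / sum(radii) * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    top <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1L
  }
  phases <- with_seed(seed, runif(n_rings, 0, 2 * pi))
  xs <- ys <- numeric(0)
  for (r in seq_len(n_rings)) {
    k <- counts[r]
    if (k == 0) next
    th <- phases[r] + 2 * pi * (seq_len(k) - 1) / k
    xs <- c(xs, radii[r] * cos(th))
    ys <- c(ys, radii[r] * sin(th))
  }
  ids <- sprintf("E%03d", seq_len(n))
  d <- as.matrix(stats::dist(cbind(xs, ys)))
  if (is.null(adjacency_radius)) {
    diag(d) <- Inf
    nn <- apply(d, 1, min)
    adjacency_radius <- 1.5 * stats::median(nn)
    diag(d) <- 0
  }
  if (adjacency_radius <= 0) {
    abort("`adjacency_radius` must be positive.", class = "strsa_bad_arg")
  }
  adj <- d < adjacency_radius
  diag(adj) <- FALSE
  dimnames(adj) <- list(ids, ids)
  if (any(rowSums(adj) == 0)) {
    iso <- ids[rowSums(adj) == 0]
    abort(
      paste0("adjacency_radius ", signif(adjacency_radius, 4),
             " leaves isolated electrode(s): ", paste(iso, collapse = ", ")),
      class = "strsa_isolated_electrode"
    )
  }
  out <- tibble(electrode = ids, x = xs, y = ys)
  attr(out, "adjacency") <- adj
  attr(out, "adjacency_radius") <- adjacency_radius
  class(out) <- c("sensor_layout", class(out))
  out
}

#' Adjacency matrix of a sensor layout
#' @param layout A `sensor_layout`.
#' @return Symmetric logical matrix, electrodes in layout order.
#' @export
layout_adjacency <- function(layout) {
  stopifnot(inherits(layout, "sensor_layout"))
  attr(layout, "adjacency")
}

#' Write / read a sensor layout as CSV
#'
#' The CSV holds `electrode,x,y`; adjacency is reconstructed from the stored
#' `adjacency_radius` column attribute (kept as a header comment-free extra
#' column `adjacency_radius`, constant).
#' @param layout A `sensor_layout`.
#' @param path CSV path.
#' @export
write_layout_csv <- function(layout, path) {
  df <- as.data.frame(layout[, c("electrode", "x", "y")])
  df$adjacency_radius <- attr(layout, "adjacency_radius")
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_layout_csv
#' @param path CSV path.
#' @export
read_layout_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("electrode", "x", "y", "adjacency_radius")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("layout CSV missing column(s): ", paste(miss, collapse = ", ")),
          class = "strsa_schema_error")
  }
  r <- df$adjacency_radius[1]
  d <- as.matrix(stats::dist(cbind(df$x, df$y)))
  adj <- d < r
  diag(adj) <- FALSE
  dimnames(adj) <- list(df$electrode, df$electrode)
  out <- tibble(electrode = df$electrode, x = df$x, y = df$y)
  attr(out, "adjacency") <- adj
  attr(out, "adjacency_radius") <- r
  class(out) <- c("sensor_layout", class(out))
  out
}

#' @export
autoplot.sensor_layout <- function(object, ...) {
  adj <- layout_adjacency(object)
  p <- lt_pairs(nrow(object))
  seg <- tibble(
    x = object$x[p[, 1]], y = object$y[p[, 1]],
    xend = object$x[p[, 2]], yend = object$y[p[, 2]],
    adj = adj[p]
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = seg[seg$adj, ],
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Sensor layout", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
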