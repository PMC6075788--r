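# Internal helpers shared across modules.

.datatable.aware <- TRUE

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG stream. All of the package's stochastic stages use this, so they
#' are pure functions of their seed arguments.
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic 32-bit-safe integer mixing of a master seed and any
#' number of stream identifiers; the result stays in `[0, 2^31 - 2]`.
#' Used to give every participant, permutation, fold and waveform its own
#' reproducible stream.
#' @param seed Master integer seed.
#' @param ... Numeric stream identifiers.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), vapply(list(...), as.numeric, numeric(1)))
  h <- 0
  m <- 2147483629
  for (p in parts) h <- (h * 48271 + abs(p) + 11) %% m
  as.integer(h)
}

# Integer hash of a character string (for keying sub-seeds to identifiers).
string_key <- function(x) {
  sum(utf8ToInt(paste(x, collapse = "\r"))) %% 65521
}

# Lower-triangle pair index, row-major with j < i:
# (2,1), (3,1), (3,2), (4,1), (4,2), (4,3), ... (cached per n)
.lt_cache <- new.env(parent = emptyenv())
lt_pairs <- function(n) {
  key <- as.character(n)
  if (!exists(key, .lt_cache)) {
    i <- rep(seq_len(n), times = seq_len(n) - 1L)
    j <- unlist(lapply(seq_len(n), function(k) seq_len(k - 1L)), use.names = FALSE)
    assign(key, cbind(i = i, j = j), .lt_cache)
  }
  get(key, .lt_cache)
}

# n x n matrix giving, for each (i, j), the position of the unordered pair
# {i, j} in the row-major lower-triangle order; diagonal is NA.
pair_index_matrix <- function(n) {
  p <- lt_pairs(n)
  m <- matrix(NA_integer_, n, n)
  m[p] <- seq_len(nrow(p))
  m[p[, c(2, 1), drop = FALSE]] <- seq_len(nrow(p))
  m
}

# Map a category permutation to the induced permutation of lower-triangle
# pair positions: entry q of the result is the source position holding the
# dissimilarity of pair q after relabelling.
pair_permutation <- function(perm, pim = NULL) {
  n <- length(perm)
  if (is.null(pim)) pim <- pair_index_matrix(n)
  p <- lt_pairs(n)
  pim[cbind(perm[p[, 1]], perm[p[, 2]])]
}

# Column ranks (average ties), as used for Spearman statistics.
col_ranks <- function(m) {
  apply(m, 2, rank)
}

# Same, via a single ordering pass (fast for many short columns). Columns
# containing ties fall back to rank() for average-tie handling.
col_ranks_grouped <- function(m) {
  len <- nrow(m); n <- ncol(m)
  g <- rep.int(seq_len(n), rep.int(len, n))
  v <- as.vector(m)
  ord <- order(g, v)
  r <- numeric(length(v))
  r[ord] <- rep.int(seq_len(len), n)
  out <- matrix(r, len, n)
  vs <- v[ord]
  same_col <- g[ord][-1] == g[ord][-length(v)]
  tie <- which(diff(vs) == 0 & same_col)
  if (length(tie)) {
    cols <- unique(g[ord][c(tie, tie + 1L)])
    out[, cols] <- apply(m[, cols, drop = FALSE], 2, rank)
  }
  out
}

# Center and scale columns to unit Euclidean norm; columns with (near-)zero
# variance come back as NA columns and are reported via the "degenerate"
# attribute.
unit_center <- function(m, tol = 1e-12) {
  m <- sweep(m, 2, colMeans(m))
  nrm <- sqrt(colSums(m^2))
  bad <- nrm < tol
  nrm[bad] <- 1
  m <- sweep(m, 2, nrm, "/")
  m[, bad] <- NA_real_
  attr(m, "degenerate") <- bad
  m
}

# Spearman rho between columns of a and the single vector b, via centered
# unit-norm ranks.
spearman_vec <- function(a, b) {
  ra <- unit_center(col_ranks(a))
  rb <- unit_center(matrix(rank(b), ncol = 1))
  drop(crossprod(ra, rb))
}

first_true_run <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(r$values)
  if (length(k) == 0) return(NULL)
  c(starts[k[1]], ends[k[1]])
}

max_run_length <- function(mask) {
  r <- rle(mask)
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}

`%||%` <- rlang::`%||%`
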