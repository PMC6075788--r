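test_that("RDM label permutation preserves structure and inverts cleanly", {
  set.seed(4)
  r <- rdm(oracle_spearman_rdm(matrix(rnorm(48), 8, 6)))
  expect_equal(permute_rdm_labels(r, 1:8)$values, r$values)
  perm <- sample(8)
  p <- permute_rdm_labels(r, perm)
  back <- permute_rdm_labels(p, order(perm))
  expect_equal(back$values, r$values)
  # pair-lookup oracle on the lower triangle
  lp <- strsa:::lt_pairs(8)
  v <- lower_triangle(p)
  for (k in seq_len(nrow(lp))) {
    expect_equal(v[k], r$values[perm[lp[k, 1]], perm[lp[k, 2]]])
  }
  expect_error(permute_rdm_labels(r, c(1, 1, 2:7)), class = "strsa_bad_arg")
})

make_noise_series <- function(n_participants, seed, n_cat = 10, n_el = 2,
                              n_win = 30) {
  lapply(seq_len(n_participants), function(p) {
    set.seed(seed * 100 + p)
    vals <- array(runif(choose(n_cat, 2) * n_win * n_el),
                  dim = c(choose(n_cat, 2), n_win, n_el),
                  dimnames = list(NULL, NULL, sprintf("E%03d", seq_len(n_el))))
    structure(
      list(values = vals, window_starts = seq(0, by = 8, length.out = n_win),
           electrodes = sprintf("E%03d", seq_len(n_el)),
           categories = sprintf("cat%02d", seq_len(n_cat)),
           window_ms = 40, step_ms = 8,
           degenerate = matrix(FALSE, n_win, n_el), skipped = numeric(0),
           participant_id = sprintf("P%02d", p)),
      class = "rdm_series"
    )
  })
}

make_layers <- function(n_layers, n_cat = 10, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_layers), function(l) {
    rdm(oracle_spearman_rdm(matrix(rnorm(n_cat * 8), n_cat, 8)),
        sprintf("cat%02d", seq_len(n_cat)), source = sprintf("layer%d", l))
  })
}

test_that("permutation 0 reproduces the observed statistic, deterministically", {
  ser <- make_noise_series(3, seed = 6)
  lr <- make_layers(3)
  nl <- build_null(ser, lr, mode = "all", n_permutations = 120, seed = 9)
  tr <- lapply(ser, trace_over_time, layers = lr, mode = "all")
  obs <- scalp_average(group_trace(tr))
  expect_equal(nl$stat[1, ], obs$r2, tolerance = 1e-10)
  nl2 <- build_null(ser, lr, mode = "all", n_permutations = 120, seed = 9)
  expect_identical(nl$stat, nl2$stat)
  expect_warning(build_null(ser, lr, n_permutations = 50, seed = 1),
                 class = "strsa_few_permutations")
})

test_that("single-layer nulls reproduce the observed squared correlation", {
  ser <- make_noise_series(3, seed = 2)
  lr <- make_layers(2)
  nl <- build_null(ser, lr, mode = "single", layer = 2, n_permutations = 100, seed = 3)
  tr <- scalp_average(group_trace(lapply(ser, trace_over_time, layers = lr,
                                         mode = "single")))
  obs <- tr$r2[tr$layer == "layer2"]
  expect_equal(nl$stat[1, ], obs, tolerance = 1e-10)
})

test_that("cluster extent keeps sustained effects and removes blips", {
  set.seed(5)
  n_win <- 100
  null_stat <- matrix(runif(201 * n_win), 201, n_win)
  nl <- structure(
    list(stat = null_stat, window_starts = seq(0, by = 4, length.out = n_win),
         n_permutations = 200, seed = 1, mode = "all", unit = "scalp"),
    class = "perm_null"
  )
  # observed at the null median: nothing survives
  obs <- apply(null_stat[-1, ], 2, stats::median)
  m0 <- cluster_extent_correct(obs, nl, alpha = 0.05)
  expect_false(any(m0))
  # planted 100 ms (25-window) suprathreshold block survives intact;
  # two 5 ms blips (single windows) are removed
  obs2 <- obs
  obs2[30:54] <- 2
  obs2[5] <- 2; obs2[90] <- 2
  m1 <- cluster_extent_correct(obs2, nl, alpha = 0.05)
  expect_true(all(m1[30:54]))
  expect_false(m1[5])
  expect_false(m1[90])
  expect_error(cluster_extent_correct(obs, structure(list(stat = null_stat[1, , drop = FALSE]),
                                                     class = "perm_null")),
               class = "strsa_bad_arg")
})

test_that("null distribution is invariant to pre-relabelling the observed data", {
  ser <- make_noise_series(3, seed = 12, n_el = 1, n_win = 10)
  lr <- make_layers(2, seed = 5)
  nl_a <- build_null(ser, lr, mode = "all", n_permutations = 300, seed = 21)
  # relabel each participant's data first
  pim <- strsa:::pair_index_matrix(10)
  ser_b <- lapply(seq_along(ser), function(i) {
    s <- ser[[i]]
    perm <- strsa:::with_seed(400 + i, sample(10))
    pe <- strsa:::pair_permutation(perm, pim)
    s$values <- s$values[pe, , , drop = FALSE]
    s
  })
  nl_b <- build_null(ser_b, lr, mode = "all", n_permutations = 300, seed = 22)
  ks <- suppressWarnings(stats::ks.test(as.vector(nl_a$stat[-1, ]),
                                        as.vector(nl_b$stat[-1, ])))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("signal-free observations sit below the pointwise null 95th percentile ~95% of the time", {
  lr <- make_layers(3, seed = 8)
  rates <- vapply(1:20, function(seed) {
    ser <- make_noise_series(3, seed = 500 + seed, n_el = 1, n_win = 40)
    nl <- build_null(ser, lr, mode = "all", n_permutations = 200,
                     seed = 700 + seed)
    thr <- apply(nl$stat[-1, ], 2, quantile, probs = 0.95, names = FALSE)
    mean(nl$stat[1, ] <= thr)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.95), 0.02)
})

test_that("noise ceiling bounds behave as the defining construction implies", {
  v <- lower_triangle(oracle_spearman_rdm(matrix(rnorm(60), 10, 6)))
  same <- lapply(1:4, function(i) v)
  nc <- noise_ceiling(same)
  expect_equal(nc$lower, 1)
  expect_equal(nc$upper, 1)
  expect_error(noise_ceiling(same[1:2]), class = "strsa_bad_arg")
  # common signal + independent noise: lower <= upper on every draw
  for (seed in 1:100) {
    set.seed(seed)
    base <- runif(45)
    subj <- lapply(1:5, function(i) base + rnorm(45, sd = 0.5))
    nc <- noise_ceiling(subj)
    expect_lte(nc$lower, nc$upper + 1e-12)
  }
})
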