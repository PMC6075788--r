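test_that("a neural vector equal to one layer is fully explained", {
  set.seed(1)
  x <- runif(45)
  fit <- encode_all_layers(x, list(x, runif(45)))
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-9)
  s <- encode_single_layer(x, x)
  expect_equal(s$rho, 1)
  expect_equal(s$r2, 1)
})

test_that("rank reversal gives rho -1 with full signed variance", {
  x <- runif(45)
  y <- -x
  s <- encode_single_layer(x, y)
  expect_equal(s$rho, -1)
  expect_equal(s$r2, 1)
  expect_equal(s$sign, -1)
})

test_that("single-layer encoding matches the explicit-rank oracle", {
  set.seed(11)
  a <- runif(435); b <- runif(435)
  s <- encode_single_layer(a, b)
  ra <- rank(a); rb <- rank(b)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_lt(abs(s$rho - oracle), 1e-12)
  expect_error(encode_single_layer(rep(1, 10), runif(10)), class = "strsa_degenerate")
})

test_that("independent predictors explain R2 ~ p/(m-1) on average", {
  set.seed(7)
  m <- 45; p <- 3
  r2 <- replicate(300, {
    encode_all_layers(runif(m), replicate(p, runif(m), simplify = FALSE))$r2
  })
  # permutation-simulation oracle for the same expectation
  oracle <- mean(replicate(300, {
    y <- rank(runif(m)); X <- replicate(p, rank(runif(m)))
    summary(stats::lm(y ~ X))$r.squared
  }))
  expect_lt(abs(mean(r2) - p / (m - 1)), 0.02)
  expect_lt(abs(mean(r2) - oracle), 0.02)
})

test_that("joint R2 agrees with lm() and dominates single layers (nesting)", {
  set.seed(21)
  for (i in 1:20) {
    m <- 66
    X <- replicate(4, runif(m))
    y <- X %*% runif(4) + rnorm(m, sd = 0.5)
    fit <- encode_all_layers(y, lapply(seq_len(4), function(j) X[, j]))
    ref <- summary(stats::lm(rank(y) ~ apply(X, 2, rank)))$r.squared
    expect_equal(fit$r2, ref, tolerance = 1e-10)
    singles <- vapply(seq_len(4), function(j) encode_single_layer(y, X[, j])$r2,
                      numeric(1))
    expect_gte(fit$r2 + 1e-12, max(singles))
  }
})

test_that("collinear predictor sets fall back to a pseudoinverse fit with a warning", {
  set.seed(3)
  x <- runif(45)
  expect_warning(fit <- encode_all_layers(runif(45), list(x, x, 2 * x)),
                 class = "strsa_collinear")
  expect_true(fit$collinear)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)
})

test_that("encoding is invariant to consistent category relabelling", {
  set.seed(14)
  n <- 10
  neural <- oracle_spearman_rdm(matrix(rnorm(n * 6), n, 6))
  layers <- lapply(1:3, function(i) oracle_spearman_rdm(matrix(rnorm(n * 6), n, 6)))
  v0 <- encode_all_layers(lower_triangle(neural),
                          lapply(layers, lower_triangle))$r2
  perm <- sample(n)
  vp <- encode_all_layers(lower_triangle(neural[perm, perm]),
                          lapply(layers, function(l) lower_triangle(l[perm, perm])))$r2
  expect_equal(vp, v0, tolerance = 1e-10)
})

test_that("single-layer traces peak near the planted latency", {
  lay <- gen_layout(32, seed = 7)
  for (latency in c(90, 180)) {
    fb <- gen_feature_banks(12, 6, 15L, 2.5, seed = 41)
    truth <- plant_structure(fb$truth, lay, latency_start_ms = latency,
                             n_regions = 1L, region_size = 6L, noise_sd = 1)
    ep <- gen_epochs(lay, truth, 8, seed = 31)
    erp <- category_means(baseline_correct(ep))
    ser <- sliding_rdms(erp, 40, 8)
    layer_rdms <- lapply(fb$banks, feature_rdm)
    tr <- scalp_average(trace_over_time(ser, layer_rdms, mode = "single"))
    df <- tr[!is.na(tr$r2), ]
    peak <- df$time[which.max(df$r2)]
    # window [t, t+40) centred ~20 ms after t; allow one envelope width
    expect_lt(abs(peak + 20 - latency), truth$width_ms[1] + 1)
    # pre-stimulus windows carry no signal: r2 there is bounded by noise
    pre <- df[df$time < -60, ]
    post <- df[abs(df$time + 20 - latency) < 20, ]
    expect_gt(mean(post$r2), max(pre$r2))
  }
})

test_that("trace summaries report onsets, bin maxima and absent onsets", {
  tr <- tibble::tibble(
    unit = "scalp", layer = "all",
    time = seq(0, 296, by = 8), rho = NA_real_,
    r2 = 0.01, sig = FALSE
  )
  tr$r2[tr$time >= 80 & tr$time <= 120] <- 0.2
  tr$sig[tr$time >= 80 & tr$time <= 120] <- TRUE
  s <- summarize_trace(tr)
  expect_equal(unique(s$onset_ms), 80)
  expect_equal(s$max_r2[s$bin == "0-100"], 0.2)
  expect_equal(s$latency_ms[s$bin == "200-300"], 200)  # flat ties break earliest
  tr$sig <- FALSE
  s2 <- summarize_trace(tr)
  expect_true(all(is.na(s2$onset_ms)))
})

test_that("superordinate residual blocks average the right pairs", {
  cats <- sprintf("cat%02d", 1:6)
  grouping <- setNames(rep(c("indoor", "urban_outdoor", "natural_outdoor"), each = 2), cats)
  p <- strsa:::lt_pairs(6)
  v <- numeric(15)
  # plant over-prediction (negative residual) for the natural_outdoor block
  nat <- cats[5:6]
  for (k in seq_len(15)) {
    both_nat <- all(cats[p[k, ]] %in% nat)
    v[k] <- if (both_nat) -0.5 else 0.1
  }
  res <- matrix(v, 15, 3)
  attr(res, "window_starts") <- c(60, 100, 140)
  attr(res, "categories") <- cats
  out <- residual_analysis(list(res, res), window = c(50, 250), grouping = grouping)
  expect_equal(out$superordinate_matrix["natural_outdoor", "natural_outdoor"], -0.5)
  expect_equal(out$superordinate_matrix["indoor", "urban_outdoor"], 0.1)
  expect_true(isSymmetric(out$superordinate_matrix))
  # enumeration oracle for a block mean
  sel <- apply(p, 1, function(ij) {
    setequal(unname(grouping[cats[ij]]), c("indoor", "natural_outdoor"))
  })
  expect_equal(out$superordinate_matrix["indoor", "natural_outdoor"],
               mean(v[sel]), tolerance = 1e-12)
  # zero residuals give zero matrices
  z <- res; z[] <- 0
  outz <- residual_analysis(list(z), window = c(50, 250), grouping = grouping)
  expect_equal(max(abs(outz$residual_matrix)), 0)
  expect_error(residual_analysis(list(res), grouping = grouping[-1]),
               class = "strsa_bad_arg")
})
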