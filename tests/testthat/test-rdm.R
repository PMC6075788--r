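test_that("feature RDM endpoints: identical rows give 0, reversed ranks give 2", {
  rows <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1))
  bank <- make_bank(rows)
  r <- feature_rdm(bank)
  expect_equal(r$values[1, 2], 0)
  expect_equal(r$values[1, 3], 2)
  expect_true(isSymmetric(r$values))
  expect_equal(diag(r$values), setNames(rep(0, 3), r$categories))
})

test_that("feature RDM matches the explicit-rank oracle", {
  set.seed(3)
  rows <- matrix(rnorm(30), 5, 6)
  r <- feature_rdm(make_bank(rows))
  expect_lt(max(abs(r$values - oracle_spearman_rdm(rows))), 1e-12)
})

test_that("degenerate category rows are rejected by name", {
  rows <- rbind(c(1, 1, 1, 1), c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_error(feature_rdm(make_bank(rows)), "cat01", class = "strsa_degenerate")
})

test_that("window RDMs use the stated window length and truncate at epoch end", {
  set.seed(8)
  n_s <- 850
  v <- array(rnorm(2 * n_s * 5), dim = c(2, n_s, 5),
             dimnames = list(c("E001", "E002"), NULL, sprintf("cat%02d", 1:5)))
  erp <- make_erp(v, seq(-100, by = 1, length.out = n_s), 1000)
  # 40 ms window at 1000 Hz = 40 samples
  idx <- which(erp$times >= 100 & erp$times < 140)
  expect_length(idx, 40)
  r <- erp_window_rdm(erp, "E001", 100, 40)
  expect_lt(max(abs(r$values - oracle_spearman_rdm(t(v[1, idx, ])))), 1e-12)
  # truncated: 30 samples remain before epoch end
  last <- max(erp$times)
  r2 <- erp_window_rdm(erp, "E002", last - 29, 40)
  idx2 <- which(erp$times >= last - 29)
  expect_length(idx2, 30)
  expect_lt(max(abs(r2$values - oracle_spearman_rdm(t(v[2, idx2, ])))), 1e-12)
  expect_error(erp_window_rdm(erp, "E001", last - 1, 40), class = "strsa_short_window")
})

test_that("sliding series covers the window starts an enumeration oracle predicts", {
  set.seed(2)
  n_s <- 212
  v <- array(rnorm(3 * n_s * 6), dim = c(3, n_s, 6),
             dimnames = list(sprintf("E%03d", 1:3), NULL, sprintf("cat%02d", 1:6)))
  times <- seq(-100, by = 4, length.out = n_s)
  erp <- make_erp(v, times, 250)
  ser <- sliding_rdms(erp, window_ms = 40, step_ms = 4)
  # oracle: enumerate starts with at least 3 samples remaining
  starts <- seq(-100, max(times), by = 4)
  keep <- vapply(starts, function(s) sum(times >= s & times < s + 40) >= 3, logical(1))
  expect_equal(ser$window_starts, starts[keep])
  expect_equal(ser$skipped, starts[!keep])
  # values agree with the single-window operation
  r <- erp_window_rdm(erp, "E002", 0, 40)
  wi <- which(ser$window_starts == 0)
  expect_lt(max(abs(ser$values[, wi, "E002"] - lower_triangle(r))), 1e-12)
})

test_that("constant-in-time ERPs flag every window as degenerate", {
  v <- array(rep(1:6, each = 2 * 60), dim = c(2, 60, 6),
             dimnames = list(c("E001", "E002"), NULL, sprintf("cat%02d", 1:6)))
  erp <- make_erp(v, seq(-100, by = 4, length.out = 60), 250)
  ser <- sliding_rdms(erp, 40, 4)
  expect_true(all(ser$degenerate))
  expect_true(all(is.na(ser$values)))
})

test_that("permuting electrodes permutes the series identically", {
  set.seed(5)
  v <- array(rnorm(3 * 60 * 5), dim = c(3, 60, 5),
             dimnames = list(sprintf("E%03d", 1:3), NULL, sprintf("cat%02d", 1:5)))
  erp <- make_erp(v, seq(-100, by = 4, length.out = 60), 250)
  a <- sliding_rdms(erp, 40, 8)
  erp2 <- erp
  erp2$voltages <- v[c(3, 1, 2), , ]
  b <- sliding_rdms(erp2, 40, 8)
  expect_equal(b$values[, , "E003"], a$values[, , "E003"])
  expect_equal(b$values[, , "E001"], a$values[, , "E001"])
})

test_that("lower triangle order is row-major with j < i and round-trips", {
  m <- matrix(0, 3, 3)
  m[2, 1] <- m[1, 2] <- 0.3
  m[3, 1] <- m[1, 3] <- 0.7
  m[3, 2] <- m[2, 3] <- 1.1
  r <- rdm(m)
  expect_equal(lower_triangle(r), c(0.3, 0.7, 1.1))
  expect_equal(choose(30, 2), 435)
  set.seed(1)
  big <- oracle_spearman_rdm(matrix(rnorm(30 * 8), 30, 8))
  v <- lower_triangle(big)
  expect_length(v, 435)
  expect_equal(v, oracle_lower_triangle(big))
  expect_equal(square_from_lower(v, 30), big, tolerance = 1e-15)
})

test_that("1 - Spearman is invariant to monotone transforms", {
  set.seed(9)
  rows <- matrix(rnorm(40), 4, 10)
  base <- feature_rdm(make_bank(rows))$values
  cubic <- feature_rdm(make_bank(rows^3))$values
  expo <- feature_rdm(make_bank(exp(rows)))$values
  expect_equal(cubic, base, tolerance = 1e-12)
  expect_equal(expo, base, tolerance = 1e-12)
})

test_that("orthogonal random category vectors concentrate near dissimilarity 1", {
  set.seed(12)
  rows <- matrix(rnorm(10 * 1000), 10, 1000)
  r <- feature_rdm(make_bank(rows))
  expect_lt(abs(mean(lower_triangle(r)) - 1), 0.05)
})

test_that("RDM invariants are enforced at construction", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(rdm(m), class = "strsa_invalid_rdm")           # asymmetric
  m2 <- matrix(c(0.5, 1, 1, 0), 2, 2)
  expect_error(rdm(m2), class = "strsa_invalid_rdm")          # nonzero diagonal
  m3 <- matrix(c(0, 3, 3, 0), 2, 2)
  expect_error(rdm(m3), class = "strsa_invalid_rdm")          # out of [0, 2]
})
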