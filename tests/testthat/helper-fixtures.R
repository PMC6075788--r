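# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# Small layout + planted truth + one low-noise participant.
fix_small_sim <- function() {
  fixture("small_sim", function() {
    lay <- gen_layout(32, seed = 7)
    fb <- gen_feature_banks(12, 6, rep(15L, 4), rep(2, 4), seed = 5)
    truth <- plant_structure(fb$truth, lay, n_regions = 4L, region_size = 4L,
                             noise_sd = 0)
    ep <- gen_epochs(lay, truth, 4, seed = 3)
    list(layout = lay, banks = fb$banks, truth = truth, epochs = ep)
  })
}

# Noisy version of the same configuration.
fix_noisy_epochs <- function() {
  fixture("noisy_epochs", function() {
    s <- fix_small_sim()
    truth <- s$truth
    truth$noise_sd <- 3
    gen_epochs(s$layout, truth, 8, seed = 9)
  })
}

# Brute-force 1 - Spearman oracle: explicit ranks + the Pearson formula,
# independent of cor().
oracle_spearman_rdm <- function(rows) {
  n <- nrow(rows)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ri <- rank(rows[i, ]); rj <- rank(rows[j, ])
      num <- sum((ri - mean(ri)) * (rj - mean(rj)))
      den <- sqrt(sum((ri - mean(ri))^2) * sum((rj - mean(rj))^2))
      d[i, j] <- 1 - num / den
    }
  }
  diag(d) <- 0
  d
}

# Lower triangle in the package's documented order, by explicit loops.
oracle_lower_triangle <- function(m) {
  out <- numeric(0)
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(i - 1)) out <- c(out, m[i, j])
  }
  out
}

make_bank <- function(category_rows, n_rep = 1) {
  n <- nrow(category_rows)
  labels <- rep(sprintf("cat%02d", seq_len(n)), each = n_rep)
  act <- category_rows[rep(seq_len(n), each = n_rep), , drop = FALSE]
  strsa:::new_feature_bank("test", act, labels)
}

make_erp <- function(voltages, times, sampling_hz) {
  structure(
    list(voltages = voltages, times = times, sampling_hz = sampling_hz,
         categories = dimnames(voltages)[[3]],
         n_trials_used = setNames(rep(1L, dim(voltages)[3]), dimnames(voltages)[[3]]),
         participant_id = "T01"),
    class = "category_erp"
  )
}
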