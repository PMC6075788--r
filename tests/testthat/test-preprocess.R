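make_epochs_from_array <- function(v, sampling_hz = 250, baseline_ms = 100) {
  dt <- 1000 / sampling_hz
  times <- seq(-baseline_ms, by = dt, length.out = dim(v)[2])
  labels <- rep(sprintf("cat%02d", seq_len(max(1, dim(v)[3] %/% 2))),
                length.out = dim(v)[3])
  strsa:::new_eeg_epochs(v, labels, times, sampling_hz, "T01",
                         categories = sort(unique(labels)))
}

test_that("band-pass removes DC and preserves in-band tones", {
  fs <- 250; n <- 500
  v <- array(0, dim = c(2, n, 2))
  t <- seq_len(n) / fs
  v[1, , ] <- 5                                 # DC
  v[2, , ] <- sin(2 * pi * 10 * t)              # in-band tone
  ep <- make_epochs_from_array(v, fs)
  out <- bandpass(ep, 0.1, 45)
  mid <- 100:400                                 # avoid filter edge effects
  expect_lt(mean(abs(out$voltages[1, mid, 1])), 0.5)
  amp_ratio <- max(abs(out$voltages[2, mid, 1])) / 1
  expect_gt(20 * log10(amp_ratio), -1)
  expect_lt(20 * log10(amp_ratio), 1)
})

test_that("out-of-band tones are attenuated as the designed filter predicts", {
  fs <- 250; n <- 1000
  t <- seq_len(n) / fs
  v <- array(sin(2 * pi * 60 * t), dim = c(1, n, 1))
  ep <- make_epochs_from_array(v, fs)
  out <- bandpass(ep, 0.1, 45)
  mid <- 200:800
  att_db <- 20 * log10(max(abs(out$voltages[1, mid, 1])))
  expect_lt(att_db, -20)
  # oracle: direct evaluation of the designed transfer functions at 60 Hz
  # (forward-backward filtering squares each magnitude response)
  eval_h <- function(filt, f) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(filt$b * z^(seq_along(filt$b) - 1)) /
          sum(filt$a * z^(seq_along(filt$a) - 1)))
  }
  hp <- signal::butter(2, 0.1 / (fs / 2), type = "high")
  lp <- signal::butter(4, 45 / (fs / 2), type = "low")
  oracle_db <- 20 * log10((eval_h(hp, 60) * eval_h(lp, 60))^2)
  expect_lt(abs(att_db - oracle_db), 3)
  expect_error(bandpass(ep, 0.1, 130), class = "strsa_bad_arg")
})

test_that("artifact rejection uses strict inequality and reports fractions", {
  v <- array(0, dim = c(2, 50, 4))
  ep <- make_epochs_from_array(v)
  expect_equal(reject_artifacts(ep)$rejection_fraction, 0)
  v[1, 10, 2] <- 100.5
  v[2, 20, 3] <- -100.0          # exactly at threshold: kept
  ep <- make_epochs_from_array(v)
  out <- reject_artifacts(ep, 100)
  expect_identical(which(!out$valid), 2L)
  expect_equal(out$rejection_fraction, 0.25)
})

test_that("rejection is idempotent and excludes half-invalid participants", {
  s <- fix_small_sim()
  truth <- s$truth; truth$noise_sd <- 2
  ep <- gen_epochs(s$layout, truth, 10, artifact_rate = 0.1, seed = 21)
  once <- reject_artifacts(ep)
  twice <- reject_artifacts(once)
  expect_identical(once$valid, twice$valid)
  v <- array(0, dim = c(1, 20, 10))
  v[1, 1, 1:6] <- 200
  expect_error(reject_artifacts(make_epochs_from_array(v)),
               class = "strsa_participant_excluded")
})

test_that("baseline correction subtracts the baseline mean exactly", {
  v <- array(3, dim = c(2, 50, 3))
  ep <- make_epochs_from_array(v)
  out <- baseline_correct(ep)
  expect_equal(max(abs(out$voltages)), 0)
  # ramp oracle: output equals input minus its baseline-window mean
  n <- 50
  v <- array(rep(seq(0, 10, length.out = n), each = 2), dim = c(2, n, 1))
  ep <- make_epochs_from_array(v)
  out <- baseline_correct(ep, c(-100, 0))
  idx <- which(ep$times >= -100 & ep$times < 0)
  oracle <- v[, , 1] - rowMeans(v[, idx, 1])
  expect_equal(out$voltages[, , 1], oracle, tolerance = 1e-12)
  # defining property + idempotence
  ep2 <- fix_noisy_epochs()
  c1 <- baseline_correct(ep2)
  idx2 <- which(c1$times >= -100 & c1$times < 0)
  expect_lt(max(abs(apply(c1$voltages[, idx2, , drop = FALSE], c(1, 3), mean))), 1e-9)
  c2 <- baseline_correct(c1)
  expect_equal(c1$voltages, c2$voltages, tolerance = 1e-12)
  expect_error(baseline_correct(ep2, c(-1000, -900)), class = "strsa_bad_arg")
})

test_that("sub-averaging with fraction 1 returns category means", {
  ep <- fix_noisy_epochs()
  out <- subaverage_bootstrap(ep, 1, seed = 1)
  cm <- category_means(ep)
  for (tr in seq_len(dim(out$voltages)[3])) {
    expect_equal(out$voltages[, , tr],
                 cm$voltages[, , match(out$labels[tr], cm$categories)],
                 tolerance = 1e-12)
  }
})

test_that("each surrogate averages exactly ceil(fraction * n_c) real trials", {
  ep <- fix_noisy_epochs()          # 8 trials per category
  out <- subaverage_bootstrap(ep, 0.25, seed = 2)   # ceil(2) = 2 trials
  # surrogate * 2 - anchor must equal some other trial of the category
  for (tr in c(1, 5, 20)) {
    anchor <- ep$voltages[, , tr]
    resid <- 2 * out$voltages[, , tr] - anchor
    mates <- which(ep$labels == ep$labels[tr] & seq_along(ep$labels) != tr)
    hit <- any(vapply(mates, function(m) {
      max(abs(resid - ep$voltages[, , m])) < 1e-9
    }, logical(1)))
    expect_true(hit)
  }
  expect_error(subaverage_bootstrap(ep, 0, seed = 1), class = "strsa_bad_arg")
})

test_that("sub-averaging is deterministic and invariant to trial order", {
  ep <- fix_noisy_epochs()
  a <- subaverage_bootstrap(ep, 0.25, seed = 3)
  b <- subaverage_bootstrap(ep, 0.25, seed = 3)
  expect_identical(a$voltages, b$voltages)
  perm <- rev(seq_along(ep$labels))
  epp <- ep
  epp$voltages <- ep$voltages[, , perm]
  epp$labels <- ep$labels[perm]
  epp$trial_ids <- ep$trial_ids[perm]
  epp$valid <- ep$valid[perm]
  p <- subaverage_bootstrap(epp, 0.25, seed = 3)
  # same surrogate for the same trial identity
  expect_equal(p$voltages[, , match(1, p$trial_ids)],
               a$voltages[, , match(1, a$trial_ids)], tolerance = 1e-12)
})

test_that("sub-averaging reduces within-category variance on noisy data", {
  wins <- 0L
  for (seed in 1:20) {
    s <- fix_small_sim()
    truth <- s$truth; truth$noise_sd <- 4
    ep <- gen_epochs(s$layout, truth, 8, seed = seed)
    sa <- subaverage_bootstrap(ep, 0.25, seed = seed)
    cc <- ep$categories[1]
    raw_v <- apply(ep$voltages[, , ep$labels == cc], c(1, 2), var)
    sur_v <- apply(sa$voltages[, , sa$labels == cc], c(1, 2), var)
    if (mean(sur_v) < mean(raw_v)) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("category means match a naive summation oracle", {
  ep <- fix_noisy_epochs()
  cm <- category_means(ep)
  cc <- ep$categories[2]
  sel <- which(ep$labels == cc & ep$valid)
  acc <- array(0, dim = dim(ep$voltages)[1:2])
  for (tr in sel) acc <- acc + ep$voltages[, , tr]
  expect_equal(cm$voltages[, , cc], acc / length(sel), tolerance = 1e-12)
  expect_identical(unname(cm$n_trials_used[cc]), length(sel))
  bad <- ep
  bad$valid[bad$labels == cc] <- FALSE
  expect_error(category_means(bad), class = "strsa_empty_category")
})
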