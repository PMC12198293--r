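test_that("DPSS tapers are orthonormal and concentrated", {
  h <- dpss_tapers(400, nw = 2.5, k = 4)
  expect_equal(crossprod(h), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  # first taper is bell-shaped: positive, peaked near the center
  expect_true(all(h[, 1] > 0))
  expect_lt(abs(which.max(h[, 1]) - 200), 5)
})

test_that("a pure 20 Hz tone has maximal, time-flat power at 20 Hz", {
  fs <- 200
  t <- (0:(5 * fs - 1)) / fs
  x <- sin(2 * pi * 20 * t)
  ep <- make_epochs(array(x, c(1, 1, length(t))), fs)
  mt <- multitaper_power(ep, fmin = 12, fmax = 30, window_s = 2)
  p <- mt$power[1, 1, , ]
  peak_freq <- mt$freqs[apply(p, 2, which.max)]
  expect_true(all(abs(peak_freq - 20) <= 1))
  tone_row <- p[which.min(abs(mt$freqs - 20)), ]
  expect_lt(sd(tone_row) / mean(tone_row), 0.01)
})

test_that("white-noise power is flat across the beta band", {
  set.seed(21)
  fs <- 200
  ep <- make_epochs(array(rnorm(40 * 1 * 5 * fs), c(40, 1, 5 * fs)), fs)
  mt <- multitaper_power(ep, fmin = 12, fmax = 30, window_s = 2,
                         step_s = 0.5)
  per_freq <- apply(mt$power[, 1, , ], 2, mean)  # average trials and time
  expect_lt((max(per_freq) - min(per_freq)) / mean(per_freq), 0.25)
})

test_that("multitaper power of unit-variance noise integrates to its variance", {
  set.seed(22)
  fs <- 100
  wlen <- 2 * fs
  x <- rnorm(20 * wlen)
  ep <- make_epochs(array(x, c(20, 1, wlen)), fs)
  mt <- multitaper_power(ep, fmin = 0, fmax = fs / 2 - 0.5, window_s = 2)
  # two-sided Parseval sum: DC once, interior bins twice
  p <- apply(mt$power[, 1, , 1], 2, mean)
  total <- (p[1] + 2 * sum(p[-1])) / wlen
  expect_equal(total, var(x), tolerance = 0.05)
})

test_that("band outside Nyquist and short windows are rejected", {
  ep <- make_epochs(array(rnorm(2 * 1 * 400), c(2, 1, 400)), 100)
  expect_error(multitaper_power(ep, fmin = 12, fmax = 60), "fs/2")
  expect_error(multitaper_power(ep, fmin = 12, fmax = 30, window_s = 10),
               "shorter")
})

test_that("percent change is zero at baseline-equal power, +100 at double", {
  mt <- structure(list(
    power = array(1, c(3, 1, 2, 10)), freqs = c(15, 20),
    times = seq(-1.5, 3, length.out = 10)), class = "mt_power")
  mt$power[, , , 6:10] <- 2
  pc <- percent_change(mt, baseline_window = c(-1.5, -0.6))
  expect_true(all(abs(pc$pct[, , 1:5]) < 1e-12))
  expect_true(all(abs(pc$pct[, , 6:10] - 100) < 1e-12))
})

test_that("percent change is per-trial and scale-invariant", {
  set.seed(23)
  fs <- 100
  data <- array(rnorm(6 * 1 * 5 * fs), c(6, 1, 5 * fs))
  ep1 <- make_epochs(data, fs, t_start = -2)
  ep2 <- make_epochs(data * 7, fs, t_start = -2)
  mt1 <- multitaper_power(ep1, 12, 30, step_s = 0.25)
  mt2 <- multitaper_power(ep2, 12, 30, step_s = 0.25)
  pc1 <- percent_change(mt1, baseline_window = c(-1, 0))
  pc2 <- percent_change(mt2, baseline_window = c(-1, 0))
  expect_equal(pc1$pct, pc2$pct, tolerance = 1e-9)
})

test_that("zero baseline power triggers the division guard", {
  mt <- structure(list(power = array(0, c(2, 1, 1, 4)), freqs = 20,
                       times = c(-1, -0.5, 0, 1)), class = "mt_power")
  expect_error(percent_change(mt, baseline_window = c(-1, -0.4)),
               "baseline power")
})

test_that("the baseline t-test mask is empty without a response and marked
           visualization-only", {
  set.seed(24)
  mt <- structure(list(
    power = array(1, c(10, 1, 2, 8)), freqs = c(15, 20),
    times = seq(-1, 2.5, length.out = 8)), class = "mt_power")
  pc <- percent_change(mt, baseline_window = c(-1, 0))
  mask <- baseline_ttest_mask(pc)
  expect_false(any(mask))
  expect_true(attr(mask, "visualization_only"))
  one_trial <- pc
  one_trial$pct_trials <- pc$pct_trials[1, , , , drop = FALSE]
  expect_error(baseline_ttest_mask(one_trial), "2 trials")
})

test_that("an injected band response is covered by the t-test mask", {
  set.seed(25)
  fs <- 200
  n_tr <- 30
  t <- seq(-3, 3, by = 1 / fs)[-1]
  data <- array(rnorm(n_tr * 1 * length(t), sd = 1), c(n_tr, 1, length(t)))
  carrier <- sin(2 * pi * 20 * t)
  for (k in seq_len(n_tr))
    data[k, 1, ] <- data[k, 1, ] +
      carrier * (2 + 1.5 * (t > 0 & t < 2))   # +75% amplitude after onset
  ep <- make_epochs(data, fs, t_start = t[1])
  mt <- multitaper_power(ep, 12, 30, step_s = 0.25)
  # 2 s windows: a center at -1.05 still sees only pre-onset samples
  pc <- percent_change(mt, baseline_window = c(-2.1, -1.05))
  mask <- baseline_ttest_mask(pc, alpha = 0.05)
  f20 <- which.min(abs(pc$freqs - 20))
  inside <- pc$times > 0.8 & pc$times < 1.2
  expect_true(mean(mask[1, f20, inside]) > 0.9)
})

test_that("the Hilbert envelope of a tone is its amplitude", {
  fs <- 200
  t <- (0:(4 * fs - 1)) / fs
  ep <- make_epochs(array(3.5 * sin(2 * pi * 20 * t),
                          c(1, 1, length(t))), fs)
  env <- beta_envelope(ep, fs_env = NULL)
  core <- env$envelope[1, 1, 100:(length(t) - 100)]
  expect_true(all(abs(core - 3.5) < 0.05))
})

test_that("the envelope recovers a slow positive modulator", {
  fs <- 200
  t <- (0:(6 * fs - 1)) / fs
  modulator <- 1 + 0.8 * sin(2 * pi * 0.7 * t)
  x <- modulator * sin(2 * pi * 20 * t)
  ep <- make_epochs(array(x, c(1, 1, length(t))), fs)
  env <- beta_envelope(ep, fs_env = 50)
  keep <- 30:(dim(env$envelope)[3] - 30)
  mod_ds <- modulator[seq(1, length(t), by = 4)]
  expect_gt(cor(env$envelope[1, 1, keep], mod_ds[keep]), 0.99)
  expect_true(all(env$envelope >= 0))
  expect_equal(env$fs_env, 50)
})

test_that("the envelope is invariant to carrier phase", {
  fs <- 200
  t <- (0:(4 * fs - 1)) / fs
  modulator <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  e <- lapply(c(0, pi / 3), function(ph) {
    ep <- make_epochs(array(modulator * sin(2 * pi * 20 * t + ph),
                            c(1, 1, length(t))), fs)
    beta_envelope(ep, fs_env = NULL)$envelope[1, 1, 100:700]
  })
  expect_equal(e[[1]], e[[2]], tolerance = 0.01)
})

test_that("degenerate bands are rejected", {
  ep <- make_epochs(array(rnorm(200), c(1, 1, 200)), 100)
  expect_error(beta_envelope(ep, band = c(30, 12)), "fmin < fmax")
  expect_error(beta_envelope(ep, band = c(12, 60)), "Nyquist")
})
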