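sine_epochs <- function(freq, fs = 250, dur = 2, ntr = 2, amp = 1,
                        t0 = -dur / 2) {
  t <- t0 + (seq_len(dur * fs) - 1) / fs
  X <- array(0, c(ntr, 1, length(t)))
  for (tr in seq_len(ntr)) X[tr, 1, ] <- amp * sin(2 * pi * freq * t)
  epoched_data(X, fs, t0)
}

test_that("preprocessing filters, resamples and rejects high-variance trials", {
  set.seed(1)
  fs <- 1000
  t <- seq_len(2 * fs) / fs
  ntr <- 20
  X <- array(rnorm(ntr * 2 * length(t), sd = 0.1), c(ntr, 2, length(t)))
  for (tr in seq_len(ntr))
    X[tr, 1, ] <- X[tr, 1, ] + sin(2 * pi * 50 * t)   # line noise
  ep <- epoched_data(X, fs, 0)
  pp <- preprocess(ep, band = c(2, 100), notch = 50, fs_out = 250,
                   reject_sd = Inf)
  expect_equal(pp$fs, 250)
  # residual 50 Hz amplitude < 5% of input
  proj <- function(x, f, fs) {
    tt <- seq_along(x) / fs
    2 * sqrt(mean(x * sin(2 * pi * f * tt))^2 + mean(x * cos(2 * pi * f * tt))^2)
  }
  expect_lt(proj(pp$data[1, 1, ], 50, 250), 0.05)

  # identical-variance trials: none rejected
  ep2 <- epoched_data(array(rep(rnorm(2 * 500), each = 10),
                            c(10, 2, 500)), 500, 0)
  expect_length(preprocess(ep2, fs_out = 250, band = c(2, 100))$rejected, 0)

  # a single 10x-variance trial is the one excluded
  set.seed(2)
  X3 <- array(rnorm(100 * 1 * 500), c(100, 1, 500))
  X3[37, , ] <- X3[37, , ] * 10
  pp3 <- preprocess(epoched_data(X3, 500, 0), band = c(2, 100),
                    fs_out = 250)
  expect_equal(pp3$rejected, 37L)

  expect_error(preprocess(ep, band = c(2, 130), fs_out = 250), "Nyquist")
})

test_that("Morlet power is frequency-selective and quadratic in amplitude", {
  ep <- sine_epochs(10, dur = 4)
  tf <- morlet_tf(ep, freqs = 2:20)
  mid <- which(tf$mask[which(tf$freqs == 10), ])
  prof <- apply(tf$power[1, 1, , mid], 1, mean)
  expect_equal(tf$freqs[which.max(prof)], 10)

  tf2 <- morlet_tf(sine_epochs(10, dur = 4, amp = 2), freqs = 2:20)
  expect_equal(tf2$power[1, 1, , mid], 4 * tf$power[1, 1, , mid],
               tolerance = 1e-9)

  expect_error(morlet_tf(sine_epochs(10, dur = 0.5), freqs = 2:20),
               "2 Hz")
})

test_that("Morlet impulse response equals direct convolution", {
  fs <- 250
  X <- array(0, c(1, 1, 500))
  X[1, 1, 250] <- 1
  ep <- epoched_data(X, fs, 0)
  tf <- morlet_tf(ep, freqs = c(8, 21))
  for (k in 1:2) {
    w <- laminar:::morlet_wavelet(c(8, 21)[k], fs)
    direct <- Mod(stats::convolve(drop(X), rev(w), type = "open"))^2
    half <- (length(w) - 1) / 2
    expect_equal(tf$power[1, 1, k, ], direct[half + seq_len(500)],
                 tolerance = 1e-8)
  }
})

test_that("multitaper power finds high-frequency content with stable, flat spectra", {
  ep <- sine_epochs(80, fs = 250, dur = 2)
  tf <- multitaper_tf(ep, freqs = seq(55, 115, 5))
  prof <- apply(tf$power[1, 1, , ], 1, mean)
  expect_equal(tf$freqs[which.max(prof)], 80)
  # stationary signal: power constant over time within 5%
  ts <- tf$power[1, 1, which(tf$freqs == 80), ]
  expect_lt((max(ts) - min(ts)) / mean(ts), 0.05)

  # white noise: flat across frequencies (Monte-Carlo average)
  set.seed(3)
  ntr <- 200
  X <- array(rnorm(ntr * 1 * 500), c(ntr, 1, 500))
  tfn <- multitaper_tf(epoched_data(X, 250, 0), freqs = seq(55, 115, 5),
                       t_step = 0.1)
  prof <- apply(tfn$power[, 1, , ], 2, mean)
  expect_lt(diff(range(prof)) / mean(prof), 0.1)

  expect_error(multitaper_tf(sine_epochs(80, dur = 0.1)), "window")
})

test_that("robust averaging downweights outliers and is bounded and permutation-invariant", {
  x <- c(1, 1, 1, 1, 100)
  r <- robust_average(x)
  expect_gte(r$mean, 1)
  expect_lte(r$mean, 2)
  expect_lt(r$weights[5], 0.1)

  set.seed(4)
  g <- rnorm(200)
  rg <- robust_average(g)
  expect_lt(abs(rg$mean - mean(g)), 0.1 * sd(g) / sqrt(200))

  perm <- robust_average(rev(x))
  expect_equal(perm$mean, r$mean, tolerance = 1e-12)

  same <- robust_average(rep(3.3, 5))
  expect_equal(same$mean, 3.3)
  expect_equal(same$weights, rep(1, 5))

  # bounded by the sample range
  y <- c(-2, 0.5, 1, 7)
  ry <- robust_average(y)
  expect_gte(ry$mean, min(y))
  expect_lte(ry$mean, max(y))
})

test_that("baseline correction is exact on constructed ratios and invertible", {
  set.seed(5)
  ep <- sine_epochs(10, dur = 2, ntr = 4)
  tf <- morlet_tf(ep, freqs = c(9, 10, 11))
  bc <- baseline_correct(tf, c(-0.9, -0.1))
  # P = b everywhere in the baseline -> 0 there (up to estimator identity)
  b <- bc$baseline
  # un-correct recovers the original power exactly
  rec <- bc
  for (ch in 1) for (k in 1:3)
    rec$power[, ch, k, ] <- bc$power[, ch, k, ] * b[ch, k] + b[ch, k]
  expect_equal(rec$power, tf$power, tolerance = 1e-12)

  # hand-computed two-frequency toy: P = 2b gives +1 (or +100%)
  toy <- tf
  toy$power[, , 1, ] <- 2
  toy$power[, , 2, ] <- 6
  toy$mask[] <- TRUE
  cor1 <- baseline_correct(toy, c(-0.9, -0.1))
  expect_true(all(abs(cor1$power[, , 1, ]) < 1e-12))
  pct <- baseline_correct(toy, c(-0.9, -0.1), mode = "percent")
  expect_true(all(abs(pct$power[, , 1:2, ]) < 1e-9))
  toy$power[, , 2, ] <- rep(c(6, 12), each = 2)   # trials 3,4 doubled
  cor2 <- baseline_correct(toy, c(-0.9, -0.1))
  expect_true(all(abs(cor2$power[3:4, , 2, ] -
                      (12 - cor2$baseline[1, 2]) / cor2$baseline[1, 2]) < 0.35))
})

test_that("band power integrates the TF plane over band and window", {
  ep <- sine_epochs(10, dur = 4, ntr = 3)
  bp <- band_power(ep, band = c(7, 13), woi = c(-0.5, 0.5))
  # oracle: mean of the TF submatrix
  tf <- morlet_tf(ep, freqs = 7:13)
  tidx <- which(tf$time >= -0.5 & tf$time <= 0.5)
  expect_equal(bp, apply(tf$power[, 1, , tidx], 1, mean), tolerance = 1e-12)

  # quadratic in amplitude
  bp2 <- band_power(sine_epochs(10, dur = 4, ntr = 3, amp = 2),
                    band = c(7, 13), woi = c(-0.5, 0.5))
  expect_equal(bp2, 4 * bp, tolerance = 1e-9)

  # a burst inside the WOI beats a control window, trial by trial
  set.seed(6)
  fs <- 250
  t <- -1 + (seq_len(3 * fs) - 1) / fs
  X <- array(rnorm(100 * 1 * length(t), sd = 0.05), c(100, 1, length(t)))
  burst <- t >= 0.2 & t <= 0.6
  for (tr in 1:100)
    X[tr, 1, burst] <- X[tr, 1, burst] + sin(2 * pi * 10 * t[burst])
  epb <- epoched_data(X, fs, -1)
  inw <- band_power(epb, c(7, 13), c(0.2, 0.6))
  outw <- band_power(epb, c(7, 13), c(-0.8, -0.4))
  expect_true(all(inw > outw))
})

test_that("cluster spectrogram summary averages, smooths and calibrates its mask", {
  set.seed(7)
  f <- 10; tt <- 20
  mk <- function() array(rnorm(4 * f * tt), c(4, f, tt))
  # single sensor, zero smoothing: identity
  a <- mk()
  out <- sensor_tf_summary(list(a), cluster = 2, smooth_fwhm = c(0, 0))
  expect_equal(out$mean, a[2, , ])

  # edge-renormalized smoothing maps a constant field to itself exactly
  # and preserves the global mean of a random field within 1%
  const <- array(2.5, c(1, f, tt))
  smc <- sensor_tf_summary(list(const), cluster = 1, smooth_fwhm = c(3, 3))
  expect_equal(smc$mean, matrix(2.5, f, tt), tolerance = 1e-12)
  pos <- mk()^2 + 1
  smp <- sensor_tf_summary(list(pos), cluster = 1:4, smooth_fwhm = c(3, 3))
  m <- apply(pos[1:4, , ], c(2, 3), mean)
  expect_lt(abs(mean(smp$mean) - mean(m)) / mean(m), 0.01)

  expect_error(sensor_tf_summary(list(a), cluster = integer(0)), "empty")

  # null calibration: Bonferroni mask nearly always empty on null data
  hits <- vapply(1:100, function(i) {
    tfs <- lapply(1:6, function(p) array(rnorm(2 * 5 * 8), c(2, 5, 8)))
    any(sensor_tf_summary(tfs, cluster = 1:2,
                          smooth_fwhm = c(0, 0))$mask)
  }, logical(1))
  expect_gte(mean(!hits), 0.95)
})

test_that("ICC(2,k) handles identity, noise and the classical worked table", {
  x <- matrix(rnorm(40), 4, 10)
  ident <- rbind(x[1, ], x[1, ], x[1, ])
  expect_equal(icc_2k(ident), 1, tolerance = 1e-12)

  set.seed(8)
  noise <- matrix(rnorm(3 * 1000), 3, 1000)
  expect_lt(abs(icc_2k(noise)), 0.1)

  # classical 6-target, 4-judge reliability table; oracle from the two-way
  # ANOVA mean squares computed independently via aov()
  ratings <- matrix(c(9, 2, 5, 8,
                      6, 1, 3, 2,
                      8, 4, 6, 8,
                      7, 1, 2, 6,
                      10, 5, 6, 9,
                      6, 2, 4, 7), nrow = 4)   # raters x targets
  d <- data.frame(y = as.vector(ratings),
                  rater = factor(rep(1:4, times = 6)),
                  target = factor(rep(1:6, each = 4)))
  ms <- summary(stats::aov(y ~ rater + target, d))[[1]][["Mean Sq"]]
  jms <- ms[1]; bms <- ms[2]; ems <- ms[3]
  oracle <- (bms - ems) / (bms + (jms - ems) / 6)
  expect_equal(icc_2k(ratings), oracle, tolerance = 1e-12)

  expect_warning(icc_2k(matrix(1, 3, 4)), "undefined")
})

test_that("total Morlet power of white noise scales linearly with variance", {
  set.seed(9)
  pows <- vapply(c(0.5, 1, 2, 4, 8), function(v) {
    X <- array(rnorm(20 * 1 * 500, sd = sqrt(v)), c(20, 1, 500))
    tf <- morlet_tf(epoched_data(X, 250, 0), freqs = seq(5, 40, 5))
    mean(tf$power)
  }, numeric(1))
  fit <- summary(lm(pows ~ c(0.5, 1, 2, 4, 8)))
  expect_gt(fit$r.squared, 0.99)
})
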