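toy_epochs <- function(ntr = 5, nch = 10, ns = 50, seed = 1) {
  set.seed(seed)
  epoched_data(array(rnorm(ntr * nch * ns), c(ntr, nch, ns)),
               fs = 100, t0 = -0.1)
}

test_that("SVD reduction captures variance as the singular values dictate", {
  ep <- toy_epochs()
  red <- svd_reduce(ep, n_spatial = 4, n_temporal = 6)
  expect_equal(dim(red$Y), c(4, 6 * 5))
  expect_equal(tcrossprod(red$spatial), diag(4), tolerance = 1e-12)
  expect_equal(tcrossprod(red$temporal), diag(6), tolerance = 1e-12)

  # direct SVD oracle for the captured spatial variance
  wide <- matrix(aperm(ep$data, c(2, 3, 1)), nrow = 10)
  d <- svd(wide)$d
  expect_equal(unname(red$var_captured["spatial"]),
               sum(d[1:4]^2) / sum(d^2), tolerance = 1e-12)

  # rank-1 data: one mode captures everything
  sp <- rnorm(10); tc <- sin(seq_len(50) / 3)
  X <- array(0, c(3, 10, 50))
  for (tr in 1:3) X[tr, , ] <- outer(sp, tc) * tr
  red1 <- svd_reduce(epoched_data(X, 100, 0), n_spatial = 1, n_temporal = 1)
  expect_equal(unname(red1$var_captured), c(1, 1), tolerance = 1e-12)

  # full reduction is lossless for a single trial's window
  redf <- svd_reduce(ep, n_spatial = 10, n_temporal = 50)
  X1 <- matrix(ep$data[1, , ], 10, 50)
  Y1 <- redf$Y[, 1:50]
  expect_equal(t(redf$spatial) %*% Y1 %*% redf$temporal, X1,
               tolerance = 1e-9)

  expect_warning(svd_reduce(ep, n_spatial = 4, n_temporal = 60), "truncated")
})

test_that("beamformer prior matches the closed form for white data", {
  set.seed(4)
  L <- matrix(rnorm(6 * 9), 6, 9)
  # exactly white covariance: YY' = sigma^2 I by construction
  sigma2 <- 2.3
  Q <- qr.Q(qr(matrix(rnorm(100 * 6), 100, 6)))   # orthonormal columns
  Y <- sqrt(sigma2) * t(Q)                        # YY' = sigma2 * I
  pr <- ebb_prior(Y, L, lambda = 0)
  expect_equal(pr$q, sigma2 / colSums(L^2)^2, tolerance = 1e-10)

  # scaling the data by c scales q by c^2; scaling L by c scales q by 1/c^4
  # (both follow from substituting into the prior formula)
  pr2 <- ebb_prior(3 * Y, L)
  expect_equal(pr2$q, 9 * pr$q, tolerance = 1e-10)
  pr3 <- ebb_prior(Y, 2 * L)
  expect_equal(pr3$q, pr$q / 16, tolerance = 1e-10)
})

test_that("beamformer prior matches a hand-computed 3-channel, 2-source toy", {
  L <- matrix(c(1, 0, 1,
                0, 2, 1), 3, 2)
  Y <- matrix(c(1, 0, 0,
                0, 1, 1,
                1, 1, 0,
                0, 0, 2), 3, 4)
  YY <- tcrossprod(Y)
  q_hand <- vapply(1:2, function(i) {
    Li <- L[, i]
    1 / (sum(Li * Li) * drop(t(Li) %*% solve(YY) %*% Li))
  }, numeric(1))
  expect_equal(ebb_prior(Y, L)$q, q_hand, tolerance = 1e-12)

  # singular YY' without regularization is an error; lambda > 0 succeeds
  Ysing <- matrix(c(1, 0, 0, 2, 0, 0), 3, 2)
  expect_error(ebb_prior(Ysing, L, lambda = 0), "lambda")
  expect_silent(ebb_prior(Ysing, L, lambda = 0.05))
})

test_that("ReML recovers generating hyperparameters and rejects absent sources", {
  set.seed(9)
  L <- matrix(rnorm(8 * 20), 8, 20)
  q <- runif(20, 0.2, 1)
  prior <- structure(list(q = q, lambda = 0), class = "source_prior")
  Q2 <- L %*% (q * t(L))
  Ctrue <- 2 * diag(8) + 3 * Q2
  Y <- t(chol(Ctrue)) %*% matrix(rnorm(8 * 20000), 8)
  fit <- reml_mix(Y, L, prior)
  expect_lt(abs(fit$h[1] - 2) / 2, 0.1)
  expect_lt(abs(fit$h[2] - 3) / 3, 0.1)
  expect_true(is.finite(fit$F))

  # pure noise: source scale collapses
  Yn <- matrix(rnorm(8 * 20000), 8)
  fitn <- reml_mix(Yn, L, prior)
  expect_lt(fitn$h[2] * sum(diag(Q2)),
            1e-3 * fitn$h[1] * 8)
})

test_that("free energy prefers the generating lead field over a shuffled one", {
  set.seed(10)
  L <- matrix(rnorm(10 * 30), 10, 30)
  q <- c(rep(2, 5), rep(0.01, 25))
  prior <- structure(list(q = q, lambda = 0), class = "source_prior")
  wins <- 0L
  for (rep in 1:20) {
    C <- diag(10) + 4 * L %*% (q * t(L))
    Y <- t(chol(C)) %*% matrix(rnorm(10 * 500), 10)
    f1 <- reml_mix(Y, L, prior)
    Lshuf <- L[, sample(30)]
    f2 <- reml_mix(Y, Lshuf, ebb_prior(Y, Lshuf))
    wins <- wins + (f1$F >= f2$F)
  }
  expect_equal(wins, 20L)
})

test_that("MAP estimate equals the dense formula and is linear in the data", {
  set.seed(11)
  L <- matrix(rnorm(5 * 8), 5, 8)
  q <- runif(8)
  prior <- structure(list(q = q, lambda = 0), class = "source_prior")
  Y <- matrix(rnorm(5 * 40), 5)
  fit <- reml_mix(Y, L, prior)
  J <- ebb_invert(Y, fit)
  Qs <- fit$h[2] * diag(q)
  Jdense <- Qs %*% t(L) %*%
    solve(fit$h[1] * diag(5) + L %*% Qs %*% t(L), Y)
  expect_equal(J, Jdense, tolerance = 1e-10)

  # linearity and the zero-data limit
  expect_equal(ebb_invert(2 * Y, fit), 2 * J, tolerance = 1e-12)
  expect_equal(ebb_invert(matrix(0, 5, 3), fit), matrix(0, 8, 3))
  expect_error(ebb_invert(matrix(0, 4, 3), fit), "mismatch")
})

test_that("a lone active source with orthogonal lead fields is recovered at its vertex", {
  set.seed(14)
  L <- qr.Q(qr(matrix(rnorm(16), 4)))    # 4 orthonormal columns
  tc <- sin(seq(0, 6 * pi, length.out = 64))
  Y <- L[, 2, drop = FALSE] %*% rbind(tc) * 5
  pr <- ebb_prior(Y + 1e-6 * matrix(rnorm(length(Y)), nrow(Y)), L,
                  lambda = 0.05)
  fit <- reml_mix(Y, L, pr)
  J <- ebb_invert(Y, fit)
  pow <- rowMeans(J^2)
  expect_equal(which.max(pow), 2L)
})

test_that("multi-regularization inversion scores all candidates and picks argmax F", {
  set.seed(12)
  model <- small_model()
  lf <- small_leadfield()
  s <- simulate_session(model, small_sensors(), lf = lf, n_trials = 8,
                        snr_db = 5, seed = 3)
  red <- svd_reduce(s$epochs, n_spatial = 20, n_temporal = 8)
  res <- multi_reg_invert(red, lf)
  expect_equal(res$candidates$lambda_percent, c(0, 5, 10, 50, 100, 1000))
  expect_true(all(is.finite(res$candidates$F)))
  expect_equal(res$F, max(res$candidates$F))

  single <- multi_reg_invert(red, lf, lambdas = 50)
  direct <- reml_mix(red, lf, ebb_prior(red, lf, lambda = 0.5))
  expect_equal(single$F, direct$F, tolerance = 1e-9)
  expect_equal(single$h, direct$h, tolerance = 1e-9)
})

test_that("relative free energies across patch sizes sum to zero", {
  model <- small_model()
  lf <- small_leadfield()
  s <- simulate_session(model, small_sensors(), lf = lf, n_trials = 6,
                        snr_db = 5, seed = 4)
  red <- svd_reduce(s$epochs, n_spatial = 20, n_temporal = 8)
  tab <- suppressWarnings(
    patch_size_sweep(red, model, lf, fwhms = c(0.01, 0.02)))
  expect_equal(sum(tab$F_rel), 0, tolerance = 1e-9)
  single <- suppressWarnings(patch_size_sweep(red, model, lf, fwhms = 0.02))
  expect_equal(single$F_rel, 0)
})

test_that("free energy is invariant to joint orthonormal rotation of channels", {
  set.seed(13)
  L <- matrix(rnorm(6 * 10), 6, 10)
  q <- runif(10)
  prior <- structure(list(q = q, lambda = 0), class = "source_prior")
  Y <- t(chol(diag(6) + L %*% (q * t(L)))) %*% matrix(rnorm(6 * 300), 6)
  R <- qr.Q(qr(matrix(rnorm(36), 6)))
  f1 <- reml_mix(Y, L, prior)
  f2 <- reml_mix(R %*% Y, R %*% L, prior)
  expect_equal(f1$F, f2$F, tolerance = 1e-6 * abs(f1$F))
  expect_equal(f1$h, f2$h, tolerance = 1e-4)
})
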