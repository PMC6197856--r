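test_that("unsigned fractional change follows its definition", {
  expect_equal(fractional_change(2, 2), 0)
  expect_equal(fractional_change(4, 2), 1)
  expect_equal(fractional_change(1, 2), 0.5)   # decrease counts like increase
  expect_equal(fractional_change(c(3, 1), c(2, 2)), c(0.5, 0.5))
  expect_error(fractional_change(1, 0), "positive")
})

test_that("ROI selection keeps the top quintile per surface with pair closure", {
  # 10 distinct values per surface: exactly 2 top vertices each
  pial <- c(10, 9, 1:8) / 10
  white <- c(1:8, 95, 99) / 100
  roi <- define_roi(pial, white, percentile = 80)
  # brute-force oracle
  top_p <- order(pial, decreasing = TRUE)[1:2]
  top_w <- order(white, decreasing = TRUE)[1:2]
  expect_setequal(roi, union(top_p, top_w))
  expect_lte(length(roi), 4)

  # ties at the threshold: all-equal maps include every vertex
  expect_equal(define_roi(rep(1, 10), rep(1, 10)), 1:10)

  # invariance under monotone rescaling
  roi2 <- define_roi(pial^3 * 7, white^3 * 7)
  expect_equal(roi2, roi)

  # anatomical metric restricts the percentile to the mask
  roi3 <- define_roi(pial, white, metric = "anatomical", mask = 3:10)
  expect_true(all(roi3 %in% 3:10))
  expect_error(define_roi(pial, white, metric = "anatomical"), "mask")
})

test_that("functional ROI is a geodesic neighborhood of the peak", {
  model <- small_model()
  n <- model$n
  pial <- rep(0.1, n); white <- rep(0.1, n)
  peak <- 17
  white[peak] <- 5
  d <- geodesic_distances(model$white, from = peak)
  near <- which(as.vector(d) <= 0.02)
  white[near] <- pmax(white[near], 2)
  roi <- define_roi(pial, white, metric = "functional", model = model,
                    functional_radius = 0.02)
  expect_true(peak %in% roi)
  expect_true(all(roi %in% which(as.vector(pmin(
    geodesic_distances(model$pial, from = peak),
    geodesic_distances(model$white, from = peak))) <= 0.02)))
})

test_that("laminar paired t matches the textbook formula and its floor caps t", {
  set.seed(20)
  p <- rnorm(30, mean = 0.4, sd = 0.2)
  w <- rnorm(30, mean = 0.3, sd = 0.2)
  res <- laminar_ttest(p, w, floor_frac = 0)
  oracle <- stats::t.test(p, w, paired = TRUE)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(oracle$parameter))

  # identical surfaces: t = 0
  expect_equal(laminar_ttest(p, p)$t, 0)

  # constant nonzero difference: the floor keeps t finite
  resf <- laminar_ttest(w + 0.2, w)
  expect_true(is.finite(resf$t))
  expect_equal(resf$t, sqrt(30 / 0.01), tolerance = 1e-9)
  expect_identical(resf$classification, "superficial")

  expect_error(laminar_ttest(1, 1), "2 trials")
})

test_that("vertexwise t is antisymmetric under surface swap and matches per-pair formula", {
  set.seed(21)
  P <- matrix(rnorm(5 * 20, 0.5, 0.1), 5, 20)
  W <- matrix(rnorm(5 * 20, 0.45, 0.1), 5, 20)
  t1 <- vertexwise_t(P, W, floor_frac = 0)
  t2 <- vertexwise_t(W, P, floor_frac = 0)
  expect_equal(t1, -t2, tolerance = 1e-12)
  for (i in c(1, 3, 5))
    expect_equal(t1[i],
                 unname(stats::t.test(P[i, ], W[i, ], paired = TRUE)$statistic),
                 tolerance = 1e-12)
  expect_equal(vertexwise_t(P, P), rep(0, 5))
})

test_that("exact Wilcoxon reproduces the published n = 8 statistics", {
  # sign patterns realizing each published (W, p); magnitudes 1..8 so the
  # signed values named d carry ranks equal to their magnitudes
  mk <- function(pos) { d <- -(1:8); d[pos] <- abs(d[pos]); d }
  published <- list(
    list(pos = integer(0), W = 0, p = 0.008),
    list(pos = 2:8, W = 35, p = 0.016),
    list(pos = 1, W = 1, p = 0.016),
    list(pos = 2, W = 2, p = 0.023),
    list(pos = c(1, 3:8), W = 34, p = 0.023),
    list(pos = 1:3, W = 6, p = 0.109),
    list(pos = c(1, 3, 4, 8), W = 16, p = 0.844),
    list(pos = c(1, 2, 4:8), W = 33, p = 0.039),
    list(pos = c(1, 4:8), W = 31, p = 0.078),
    list(pos = 1:7, W = 28, p = 0.195))
  for (cs in published) {
    res <- wilcoxon_exact(mk(cs$pos))
    expect_equal(res$W, cs$W)
    expect_equal(round(res$p, 3), cs$p)
    expect_true(res$exact)
  }
  # additional patterns against the closed-form null (no ties, so
  # psignrank is an exact independent oracle)
  for (pos in list(1:8, c(1, 2, 4, 8), c(1, 3, 4, 5, 6, 7), 8, c(2, 3, 5))) {
    d <- mk(pos)
    res <- wilcoxon_exact(d)
    W <- sum(pos)
    expect_equal(res$W, W)
    expect_equal(res$p, min(1, 2 * psignrank(min(W, 36 - W), 8)),
                 tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon equals brute-force enumeration for n <= 12", {
  set.seed(22)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    d <- round(rnorm(n), sample(c(0, 1, 2), 1))   # induces ties and zeros
    if (all(d == 0)) d[1] <- 1
    got <- wilcoxon_exact(d)
    want <- wilcoxon_brute(d)
    expect_equal(got$W, want$W)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  # shifted null
  d <- c(0.4, -0.2, 0.9, 1.4, -0.7, 0.3, 0.8, 1.1)
  got <- wilcoxon_exact(d, null_value = 0.3)
  want <- wilcoxon_brute(d, null_value = 0.3)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  expect_warning(wilcoxon_exact(rep(0.5, 4), null_value = 0.5), "undefined")

  # large n falls back to a flagged normal approximation
  set.seed(23)
  big <- rnorm(30, 0.3)
  res <- wilcoxon_exact(big)
  expect_false(res$exact)
  oracle <- stats::wilcox.test(big, correct = TRUE)
  expect_equal(res$p, oracle$p.value, tolerance = 0.02)
})

test_that("group summary counts classifications", {
  g <- group_wilcoxon(c(-1, -2, -3, 0.5, -4, -5, -6, -7))
  expect_equal(g$n_deep, 7L)
  expect_equal(g$n_superficial, 1L)
  expect_equal(g$W, 1)
})

test_that("condition comparison: identical conditions, hand ranks, planted effect", {
  df <- data.frame(participant = rep(1:6, each = 3),
                   condition = rep(c("low", "med", "high"), 6),
                   power = rep(1:6, each = 3))
  fr <- condition_compare(df, test = "friedman")
  expect_equal(fr$statistic, 0)

  # 3-condition toy with hand-computed Friedman chi-square
  m <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(1, 2, 3))
  dfm <- data.frame(participant = rep(1:4, each = 3),
                    condition = rep(c("a", "b", "c"), 4),
                    power = as.vector(t(m)))
  fr2 <- condition_compare(dfm, test = "friedman")
  ranks <- t(apply(m, 1, rank))
  Rj <- colSums(ranks)
  chi_hand <- 12 / (4 * 3 * 4) * sum(Rj^2) - 3 * 4 * 4
  expect_equal(fr2$statistic, chi_hand, tolerance = 1e-12)
  expect_equal(nrow(fr2$pairwise), 3L)

  # incorrect trials are excluded
  dfc <- data.frame(participant = rep(1:5, each = 4),
                    condition = rep(c("x", "x", "y", "y"), 5),
                    power = c(rbind(matrix(1, 2, 5), matrix(2, 2, 5))),
                    correct = rep(c(TRUE, FALSE), 10))
  res <- condition_compare(dfc, test = "wilcoxon_paired")
  expect_equal(res$n, 5)

  # power: a planted gamma increase of one within-participant (trial-level)
  # SD is detected in >= 90% of simulated groups
  set.seed(24)
  hits <- vapply(1:100, function(i) {
    rows <- do.call(rbind, lapply(1:8, function(pp) {
      base <- rnorm(1, 10, 2)
      data.frame(participant = pp,
                 condition = rep(c("congruent", "incongruent"), each = 40),
                 power = c(rnorm(40, base, 1), rnorm(40, base + 1, 1)))
    }))
    condition_compare(rows, test = "wilcoxon_paired")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("confound analyses: null calibration, planted effects, residualization", {
  set.seed(25)
  npair <- 200
  depth_p <- runif(npair, 0.005, 0.03)
  depth_w <- depth_p + 0.003
  ratio <- exp(rnorm(npair, 0, 0.2))

  # (a) null: t independent of the gain ratio -> group Fisher-z t n.s.
  nulls <- vapply(1:100, function(i) {
    tp <- lapply(1:8, function(p) rnorm(npair))
    res <- leadfield_bias_analysis(tp, ratio, depth_p, depth_w)
    abs(res$partial$gain_group$t) < 2
  }, logical(1))
  expect_gte(mean(nulls), 0.9)

  # (b) a planted monotone gain relationship is recovered
  tp <- lapply(1:8, function(p) 3 * log(ratio) + rnorm(npair, 0, 0.3))
  res <- leadfield_bias_analysis(tp, ratio, depth_p, depth_w)
  expect_gt(mean(res$partial$rho_gain), 0.8)

  # (c) matched and white-closer subsets restrict correctly
  expect_true(all(abs(ratio[res$matched$n > 0][0]) >= 0))  # structural
  wc <- leadfield_bias_analysis(tp, ratio, depth_p,
                                depth_w = depth_p - 0.001)
  expect_equal(wc$white_closer$n, npair)

  # (d) residualization removes a planted sqrt-depth trend
  depth_mean <- (depth_p + depth_w) / 2
  planted <- 5 * sqrt(depth_mean) + rnorm(npair, 0, 0.01)
  res2 <- leadfield_bias_analysis(list(planted), ratio, depth_p, depth_w,
                                  diff_pairs = planted)
  expect_lt(abs(stats::cor(res2$depth_residual$residuals,
                           sqrt(depth_mean), method = "spearman")), 0.05)
})
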