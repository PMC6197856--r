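#' Unsigned fractional power change
#'
#' `|P_woi - P_baseline| / P_baseline`, the quantity compared between
#' surfaces: a decrease counts the same as an increase of equal size.
#'
#' @param power_woi,power_baseline numeric (scalars, vectors or matrices of
#'   matching shape); baseline must be strictly positive.
#' @return unsigned fractional change, same shape as the inputs.
#' @export
fractional_change <- function(power_woi, power_baseline) {
  if (any(power_baseline <= 0)) stop("baseline power must be positive")
  abs(power_woi - power_baseline) / power_baseline
}

#' Define the laminar region of interest
#'
#' Vertices on either surface whose trial-mean unsigned fractional power
#' change is at or above the given percentile for that surface are included,
#' together with their partners on the other surface (pair closure). Because
#' the defining statistic is the trial mean on each surface separately, the
#' ROI contrast is orthogonal to the subsequent pial-versus-white contrast.
#' Ties at the threshold are included (at-or-above rule).
#'
#' Metrics: `"global"` uses all vertices; `"functional"` restricts the ROI
#' to a geodesic neighborhood (radius `functional_radius`) of the peak
#' vertex of the combined map; `"anatomical"` computes the percentile within
#' a vertex mask (a label set standing in for an anatomical region).
#'
#' @param pial_map,white_map per-vertex trial-mean unsigned fractional
#'   change (length N each).
#' @param percentile percentile defining "top" vertices (default 80 = top
#'   20 percent).
#' @param metric `"global"`, `"functional"` or `"anatomical"`.
#' @param model the `laminar_model` (required for `"functional"`).
#' @param mask integer vertex indices (per-surface, 1..N; required for
#'   `"anatomical"`).
#' @param functional_radius geodesic radius in meters around the peak for
#'   the functional metric.
#' @return sorted integer vector of pair indices (1..N).
#' @export
define_roi <- function(pial_map, white_map, percentile = 80,
                       metric = c("global", "functional", "anatomical"),
                       model = NULL, mask = NULL, functional_radius = 0.010) {
  metric <- match.arg(metric)
  n <- length(pial_map)
  stopifnot(length(white_map) == n)
  cand <- seq_len(n)
  if (metric == "anatomical") {
    if (is.null(mask)) stop("anatomical metric requires a vertex mask")
    cand <- sort(unique(as.integer(mask)))
  } else if (metric == "functional") {
    if (is.null(model)) stop("functional metric requires the laminar model")
    peak <- which.max(pmax(pial_map, white_map))
    d <- pmin(geodesic_distances(model$pial, from = peak),
              geodesic_distances(model$white, from = peak))
    cand <- which(as.vector(d) <= functional_radius)
  }
  if (!length(cand)) stop("no candidate vertices for ROI definition")
  top <- function(map) {
    thr <- stats::quantile(map[cand], percentile / 100, type = 7, names = FALSE)
    cand[map[cand] >= thr]
  }
  roi <- sort(union(top(pial_map), top(white_map)))
  if (!length(roi)) stop("empty ROI")
  roi
}

#' Paired laminar t-test with variance floor
#'
#' Paired t over trials of the per-trial ROI means (pial minus white).
#' Positive t means the greater change was on the pial (superficial)
#' surface, negative means white (deep). The denominator variance is floored
#' at `floor_frac` times the squared mean paired difference, attenuating
#' artifactually large t values when the paired differences are nearly
#' constant; set `floor_frac = 0` to disable.
#'
#' @param pial_trials,white_trials per-trial ROI values (equal length >= 2).
#' @param floor_frac variance floor as a fraction of `mean(d)^2` (default
#'   0.01).
#' @return list: `t`, `df`, `p` (two-sided), `classification`
#'   (`"superficial"` when t > 0 else `"deep"`), `mean_diff`.
#' @export
laminar_ttest <- function(pial_trials, white_trials, floor_frac = 0.01) {
  n <- length(pial_trials)
  if (length(white_trials) != n) stop("unequal trial counts")
  if (n < 2) stop("need at least 2 trials")
  d <- pial_trials - white_trials
  md <- mean(d)
  v <- stats::var(d)
  v <- max(v, floor_frac * md^2)
  if (v == 0) {                          # all-zero differences
    return(list(t = 0, df = n - 1, p = 1, classification = "deep",
                mean_diff = 0))
  }
  tval <- md / sqrt(v / n)
  list(t = tval, df = n - 1,
       p = 2 * stats::pt(-abs(tval), df = n - 1),
       classification = if (tval > 0) "superficial" else "deep",
       mean_diff = md)
}

#' Vertexwise paired t-statistics across the ROI
#'
#' One paired t (over trials) per white/pial vertex pair, for inspecting the
#' distribution of laminar preference across an ROI.
#'
#' @param pial_power,white_power matrices vertices x trials of per-trial
#'   unsigned fractional change.
#' @param roi pair indices to evaluate (default all rows).
#' @param floor_frac variance floor (see [laminar_ttest()]).
#' @return numeric vector of t values, one per pair in `roi`.
#' @export
vertexwise_t <- function(pial_power, white_power, roi = NULL,
                         floor_frac = 0.01) {
  if (is.null(roi)) roi <- seq_len(nrow(pial_power))
  vapply(roi, function(i)
    laminar_ttest(pial_power[i, ], white_power[i, ], floor_frac)$t,
    numeric(1))
}

#' Exact Wilcoxon signed-rank test
#'
#' Signed ranks of `differences - null_value`; zeros are dropped, ties get
#' midranks, `W` is the sum of positive ranks. The two-sided p-value doubles
#' the smaller tail of the exact permutation null (all `2^n` sign
#' assignments, evaluated by dynamic programming), capped at 1. For
#' `n > max_exact` a normal approximation with continuity correction is used
#' and flagged.
#'
#' @param differences numeric vector.
#' @param null_value hypothesized location (default 0); may be a vector for
#'   per-element shifted nulls.
#' @param max_exact largest n for exact enumeration (default 25).
#' @return list: `W`, `p`, `n` (non-zero differences), `exact` (logical).
#' @export
wilcoxon_exact <- function(differences, null_value = 0, max_exact = 25) {
  d <- differences - null_value
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences equal the null value; test undefined")
    return(list(W = NA_real_, p = NA_real_, n = 0L, exact = NA))
  }
  r <- rank(abs(d))                      # midranks for ties
  W <- sum(r[d > 0])
  maxW <- n * (n + 1) / 2
  if (n <= max_exact) {
    # distribution of W over all 2^n sign assignments; double ranks so
    # midranks (x.5) become integers for the DP table
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    cnt <- numeric(tot + 1)              # counts over possible 2W values
    cnt[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), cnt[seq_len(tot + 1 - ri)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- round(2 * W)
    lower <- sum(probs[seq_len(min(w2, tot - w2) + 1)])
    p <- min(1, 2 * lower)
    exact <- TRUE
  } else {
    mu <- maxW / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (W - mu - sign(W - mu) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(W = W, p = p, n = n, exact = exact)
}

#' Group-level laminar classification summary
#'
#' Exact Wilcoxon on per-participant pial-minus-white differences, plus the
#' per-surface classification counts.
#'
#' @param differences per-participant pial - white ROI differences.
#' @param null_value see [wilcoxon_exact()]; a per-participant vector of
#'   shuffled-null values may be supplied.
#' @return list: `W`, `p`, `n`, `n_superficial`, `n_deep`.
#' @export
group_wilcoxon <- function(differences, null_value = 0) {
  res <- wilcoxon_exact(differences, null_value)
  c(res, list(n_superficial = sum(differences > 0),
              n_deep = sum(differences < 0)))
}

#' Compare band power between task conditions
#'
#' Per-participant condition means (correct trials only) compared with a
#' paired exact Wilcoxon (two conditions) or a Friedman test (three or more
#' levels of one factor) followed by Tukey-Kramer corrected pairwise
#' comparisons on the rank sums.
#'
#' @param values data frame with columns `participant`, `condition`,
#'   `power`, and optionally `correct` (logical; only correct trials enter).
#' @param test `"wilcoxon_paired"` or `"friedman"`.
#' @return list with the group statistic, p-value, per-condition means, and
#'   (Friedman) a pairwise table.
#' @export
condition_compare <- function(values, test = c("wilcoxon_paired", "friedman")) {
  test <- match.arg(test)
  if (!is.null(values$correct)) values <- values[as.logical(values$correct), ]
  agg <- stats::aggregate(power ~ participant + condition, values, mean)
  wide <- stats::reshape(agg, idvar = "participant", timevar = "condition",
                         direction = "wide")
  cond_cols <- setdiff(names(wide), "participant")
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    warning(sum(!complete), " participant(s) missing a condition; dropped")
    wide <- wide[complete, ]
  }
  m <- as.matrix(wide[, cond_cols])
  colnames(m) <- sub("^power\\.", "", cond_cols)
  if (test == "wilcoxon_paired") {
    if (ncol(m) != 2) stop("paired Wilcoxon needs exactly two conditions")
    res <- wilcoxon_exact(m[, 1] - m[, 2])
    return(list(test = "wilcoxon_paired", W = res$W, p = res$p,
                means = colMeans(m), n = nrow(m)))
  }
  fr <- stats::friedman.test(m)
  if (!is.finite(fr$statistic)) {       # fully tied rows: no rank variance
    fr$statistic[] <- 0
    fr$p.value <- 1
  }
  k <- ncol(m); n <- nrow(m)
  ranks <- t(apply(m, 1, rank))
  mean_rank <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (12 * n))
  pairs <- utils::combn(k, 2)
  pw <- data.frame(
    a = colnames(m)[pairs[1, ]], b = colnames(m)[pairs[2, ]],
    diff_rank = mean_rank[pairs[1, ]] - mean_rank[pairs[2, ]])
  pw$p <- stats::ptukey(abs(pw$diff_rank) / se * sqrt(2), nmeans = k,
                        df = Inf, lower.tail = FALSE)
  list(test = "friedman", statistic = unname(fr$statistic),
       p = fr$p.value, means = colMeans(m), mean_rank = mean_rank,
       pairwise = pw, n = n)
}

#' Lead-field and depth confound analyses
#'
#' Four checks that a set of vertexwise laminar t-statistics is not a
#' trivial consequence of forward-model gain or cortical depth:
#' (a) per-participant Spearman partial correlations between t and the
#' pial/white lead-field RMS ratio (controlling depth) and between t and
#' relative depth (controlling the gain ratio), Fisher-z transformed and
#' tested against zero over participants;
#' (b) the laminar test restricted to pairs matched for lead-field strength
#' (gain ratio within `match_tol` of parity relative to the observed range);
#' (c) the laminar test restricted to pairs whose white vertex lies closer
#' to the scalp than its pial partner;
#' (d) the laminar test on the residuals of a robust linear regression of
#' the pial-white difference on the square root of scalp distance.
#'
#' @param t_pairs list of per-participant numeric vectors (vertexwise t per
#'   pair), or a single vector.
#' @param rms_ratio per-pair pial/white lead-field RMS ratio (shared across
#'   participants), length = pairs.
#' @param depth_pial,depth_white per-pair scalp distances, meters.
#' @param diff_pairs per-pair pial-white mean difference (for the
#'   residualization), defaults to the participant-mean of `t_pairs`.
#' @param match_tol lead-field matching tolerance as a fraction of the
#'   observed ratio range (default 0.01).
#' @return list with elements `partial` (per-participant correlations and
#'   the group Fisher-z t-tests), `matched`, `white_closer`,
#'   `depth_residual`.
#' @export
leadfield_bias_analysis <- function(t_pairs, rms_ratio, depth_pial,
                                    depth_white, diff_pairs = NULL,
                                    match_tol = 0.01) {
  if (!is.list(t_pairs)) t_pairs <- list(t_pairs)
  rel_depth <- depth_pial - depth_white
  spearman_partial <- function(x, y, z) {
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    rxy <- stats::cor(rx, ry); rxz <- stats::cor(rx, rz)
    ryz <- stats::cor(ry, rz)
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  rho_gain <- vapply(t_pairs, spearman_partial, numeric(1),
                     y = rms_ratio, z = rel_depth)
  rho_depth <- vapply(t_pairs, spearman_partial, numeric(1),
                      y = rel_depth, z = rms_ratio)
  fisher_t <- function(rho) {
    z <- atanh(pmin(pmax(rho, -0.999999), 0.999999))
    if (length(z) < 2) return(list(t = NA_real_, p = NA_real_))
    tt <- stats::t.test(z)
    list(t = unname(tt$statistic), p = tt$p.value)
  }
  partial <- list(rho_gain = rho_gain, rho_depth = rho_depth,
                  gain_group = fisher_t(rho_gain),
                  depth_group = fisher_t(rho_depth))

  mean_t <- Reduce(`+`, t_pairs) / length(t_pairs)
  subset_test <- function(idx) {
    if (!length(idx))
      return(list(n = 0L, mean_t = NA_real_, wilcoxon = NULL,
                  skipped = TRUE))
    w <- wilcoxon_exact(mean_t[idx])
    list(n = length(idx), mean_t = mean(mean_t[idx]), wilcoxon = w,
         skipped = FALSE)
  }
  rng <- diff(range(rms_ratio))
  matched_idx <- which(abs(rms_ratio - 1) <= match_tol * max(rng, 1e-12))
  white_closer_idx <- which(depth_white < depth_pial)

  if (is.null(diff_pairs)) diff_pairs <- mean_t
  depth_mean <- (depth_pial + depth_white) / 2
  fit <- MASS::rlm(diff_pairs ~ sqrt(depth_mean), maxit = 50)
  resid_test <- wilcoxon_exact(stats::residuals(fit))

  list(partial = partial,
       matched = subset_test(matched_idx),
       white_closer = subset_test(white_closer_idx),
       depth_residual = list(fit = fit, wilcoxon = resid_test,
                             residuals = stats::residuals(fit)))
}
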