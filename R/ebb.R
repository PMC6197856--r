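#' SVD reduction of epoched sensor data
#'
#' Projects epoched data onto its dominant spatial and temporal modes before
#' inversion. Spatial modes are the top left singular vectors of the
#' channels-by-(samples * trials) matrix; temporal modes are the top right
#' singular vectors of the trial-stacked (trials * channels)-by-samples
#' matrix, so induced (non-phase-locked) structure is captured even when the
#' phase-locked average is near zero. Defaults follow common practice for
#' large arrays (180 spatial modes, 16 temporal modes), truncated to the
#' channel count / rank for smaller arrays.
#'
#' @param epochs an [epoched_data()] object.
#' @param n_spatial number of spatial modes (default `min(channels, 180)`).
#' @param n_temporal number of temporal modes (default 16).
#' @param window optional time window (s, length 2) to reduce over; default
#'   the whole epoch.
#' @return object of class `reduced_data`: `Y` (n_spatial x
#'   (n_temporal * trials)), `spatial` (n_spatial x channels, orthonormal
#'   rows), `temporal` (n_temporal x samples-in-window), `n_trials`,
#'   `var_captured` (spatial and temporal fractions).
#' @export
svd_reduce <- function(epochs, n_spatial = NULL, n_temporal = 16,
                       window = NULL) {
  X <- epochs$data                       # trials x channels x samples
  nt <- dim(X)[1]; nch <- dim(X)[2]
  idx <- seq_len(dim(X)[3])
  if (!is.null(window))
    idx <- which(epochs$time >= window[1] & epochs$time <= window[2])
  ns <- length(idx)
  if (is.null(n_spatial)) n_spatial <- min(nch, 180)
  if (n_spatial > nch) {
    warning("n_spatial exceeds channel count; truncated")
    n_spatial <- nch
  }
  if (n_temporal > ns) {
    warning("n_temporal exceeds sample count; truncated")
    n_temporal <- ns
  }
  # channels x (samples*trials); left singular vectors via the (small)
  # channel covariance eigendecomposition
  wide <- matrix(aperm(X[, , idx, drop = FALSE], c(2, 3, 1)), nrow = nch)
  eg <- eigen(tcrossprod(wide), symmetric = TRUE)
  sv <- list(d = sqrt(pmax(eg$values, 0)), u = eg$vectors)
  r <- sum(sv$d > sv$d[1] * 1e-12)
  if (n_spatial > r) {
    warning("requested spatial modes exceed rank; truncated to ", r)
    n_spatial <- r
  }
  U <- t(sv$u[, seq_len(n_spatial), drop = FALSE])   # n_spatial x channels
  # (trials*channels) x samples
  tall <- matrix(aperm(X[, , idx, drop = FALSE], c(1, 2, 3)), ncol = ns)
  Ct <- crossprod(tall)
  tot_t <- sum(diag(Ct))
  if (ns <= 256 || n_temporal > ns / 4) {
    egt <- eigen(Ct, symmetric = TRUE)
    tvals <- pmax(egt$values, 0)
    tvecs <- egt$vectors
  } else {
    # top temporal modes by deterministic subspace iteration: exact
    # eigenvectors are overkill for a truncated basis at this sample count
    k <- min(ns, n_temporal + 8)
    V0 <- qr.Q(qr(Ct[, seq_len(k), drop = FALSE]))
    for (it in 1:25) V0 <- qr.Q(qr(Ct %*% V0))
    B <- crossprod(V0, Ct %*% V0)
    eb <- eigen(B, symmetric = TRUE)
    tvals <- pmax(eb$values, 0)
    tvecs <- V0 %*% eb$vectors
  }
  rt <- sum(tvals > tvals[1] * 1e-24)
  if (n_temporal > rt) {
    warning("requested temporal modes exceed rank; truncated to ", rt)
    n_temporal <- rt
  }
  st <- list(d = sqrt(tvals), v = tvecs)
  V <- t(st$v[, seq_len(n_temporal), drop = FALSE])  # n_temporal x samples
  Y <- matrix(0, n_spatial, n_temporal * nt)
  for (tr in seq_len(nt)) {
    Xt <- matrix(X[tr, , idx], nch, ns)
    Y[, (tr - 1) * n_temporal + seq_len(n_temporal)] <- (U %*% Xt) %*% t(V)
  }
  structure(list(Y = Y, spatial = U, temporal = V, n_trials = nt,
                 window_idx = idx,
                 var_captured = c(
                   spatial = sum(sv$d[seq_len(n_spatial)]^2) / sum(sv$d^2),
                   temporal = sum(st$d[seq_len(n_temporal)]^2) / tot_t)),
            class = "reduced_data")
}

reduced_leadfield <- function(reduced, lf) {
  reduced$spatial %*% lf$L
}

#' Beamformer source prior from sensor data
#'
#' Per-source prior variance
#' `Q(i) = (1 / Li'Li) * (Li' (YY')^{-1} Li + lambda * mu)^{-1}`
#' with fixed (normal) orientation, where `mu` is the mean eigenvalue of
#' `YY'` so that `lambda` is expressed as a fraction of it (a value of 0.05
#' corresponds to 5 percent regularization). `lambda = 0` gives the
#' highest-resolution estimate and is the default.
#'
#' @param reduced a [svd_reduce()] result (or a plain data matrix).
#' @param lf a `lead_field` (columns are reduced internally).
#' @param lambda regularization as a fraction of the mean eigenvalue of
#'   `YY'`.
#' @return object of class `source_prior`: `q` (per-source variance),
#'   `lambda`.
#' @export
ebb_prior <- function(reduced, lf, lambda = 0) {
  if (inherits(reduced, "reduced_data")) {
    Y <- reduced$Y
    L <- reduced_leadfield(reduced, lf)
  } else {
    Y <- as.matrix(reduced)
    L <- if (inherits(lf, "lead_field")) lf$L else lf
  }
  YY <- tcrossprod(Y)
  mu <- mean(diag(YY))                   # = mean eigenvalue (trace / n)
  if (lambda > 0) YY <- YY + lambda * mu * diag(nrow(YY))
  YYinv <- tryCatch(chol2inv(chol(YY)), error = function(e)
    stop("YY' is singular; use lambda > 0 for regularization"))
  lnorm <- colSums(L^2)
  proj <- colSums(L * (YYinv %*% L))
  q <- 1 / (lnorm * proj)
  # sources whose lead field is (near-)zero are unobservable: the formula
  # would assign them unbounded prior variance, so they get none instead
  weak <- lnorm < (1e-6 * max(lnorm))
  q[weak | !is.finite(q)] <- 0
  structure(list(q = q, lambda = lambda), class = "source_prior")
}

#' ReML mixing of noise and source covariance components
#'
#' Scales the sensor-noise covariance and the beamformer source covariance
#' to maximize the restricted (Gaussian) likelihood of the model covariance
#' `C = h_eps * Qeps + h_q * L diag(q) L'` given the sample covariance of
#' the reduced data. Hyperparameters are log-parameterized (hence positive)
#' and updated by Fisher scoring with step-halving; convergence is declared
#' when the free-energy change falls below `tol` or after `max_iter`
#' iterations. The returned free energy,
#' `F = -N/2 (logdet C + tr(C^{-1} S))`,
#' omits constants shared by all models on the same data, so it is
#' comparable only within a candidate set.
#'
#' @param reduced a [svd_reduce()] result or plain data matrix.
#' @param lf `lead_field` (reduced internally when `reduced` is a
#'   `reduced_data`).
#' @param prior a [ebb_prior()] result.
#' @param noise_cov sensor-noise covariance in the (reduced) channel space;
#'   default identity. An empty-room estimate can be passed here.
#' @param max_iter,tol convergence controls.
#' @return object of class `inversion_result`: `h` (noise, source scales),
#'   `F` (free energy), `lambda`, `C` (model covariance), plus the
#'   projectors needed by [ebb_invert()] / [source_filters()].
#' @export
reml_mix <- function(reduced, lf, prior, noise_cov = NULL,
                     max_iter = 128, tol = 1e-4) {
  if (inherits(reduced, "reduced_data")) {
    Y <- reduced$Y
    L <- reduced_leadfield(reduced, lf)
  } else {
    Y <- as.matrix(reduced)
    L <- if (inherits(lf, "lead_field")) lf$L else lf
  }
  n <- nrow(Y); N <- ncol(Y)
  S <- tcrossprod(Y) / N
  Q1 <- if (is.null(noise_cov)) diag(n) else as.matrix(noise_cov)
  Q2 <- L %*% (prior$q * t(L))
  # init: each component scaled to explain half the observed trace
  h <- c(max(sum(diag(S)), 1e-300) / (2 * sum(diag(Q1))),
         max(sum(diag(S)), 1e-300) / (2 * max(sum(diag(Q2)), 1e-300)))
  if (!is.finite(h[2]) || h[2] <= 0) h[2] <- 1e-12
  theta <- log(h)
  Fe <- function(C) {
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(list(F = -Inf))
    Cinv <- chol2inv(ch)
    list(F = -N / 2 * (2 * sum(log(diag(ch))) + sum(Cinv * S)), Cinv = Cinv)
  }
  comp <- function(th) exp(th[1]) * Q1 + exp(th[2]) * Q2
  cur <- Fe(comp(theta))
  if (!is.finite(cur$F)) stop("initial model covariance not positive definite")
  for (it in seq_len(max_iter)) {
    h <- exp(theta)
    Cinv <- cur$Cinv
    A1 <- Cinv %*% Q1; A2 <- Cinv %*% Q2
    SC <- S %*% Cinv
    g <- -N / 2 * c(sum(diag(A1)) - sum(A1 * t(SC)),
                    sum(diag(A2)) - sum(A2 * t(SC))) * h
    H <- N / 2 * matrix(c(sum(A1 * t(A1)), sum(A1 * t(A2)),
                          sum(A2 * t(A1)), sum(A2 * t(A2))), 2, 2) *
      outer(h, h)
    step <- tryCatch(solve(H + diag(1e-8 * max(diag(H)) + 1e-300, 2), g),
                     error = function(e) g / max(abs(g), 1))
    step <- pmin(pmax(step, -8), 8)      # trust region in log space
    ok <- FALSE
    for (half in 0:12) {                 # step-halving on F decrease / non-PSD
      cand <- theta + step / 2^half
      new <- Fe(comp(cand))
      if (is.finite(new$F) && new$F >= cur$F - 1e-12 * abs(cur$F)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) break
    dF <- new$F - cur$F
    theta <- cand
    cur <- new
    if (abs(dF) < tol) break
  }
  h <- exp(theta)
  C <- comp(theta)
  structure(list(h = c(noise = h[1], source = h[2]), F = cur$F,
                 lambda = prior$lambda, C = C, Cinv = cur$Cinv,
                 q = prior$q, L_reduced = L,
                 spatial = if (inherits(reduced, "reduced_data"))
                   reduced$spatial else NULL,
                 iterations = it),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("<inversion_result> F = %.2f, h = (%.3g, %.3g), lambda = %g\n",
              x$F, x$h[1], x$h[2], x$lambda))
  invisible(x)
}

#' MAP source estimate
#'
#' Evaluates `Jhat = Qs L' (he Qeps + L Qs L')^{-1} Y` with the
#' hyperparameter-scaled covariances from [reml_mix()] (`Qs = h_q diag(q)`).
#'
#' @param reduced the [svd_reduce()] result used for the fit (or a matrix in
#'   the same reduced channel space).
#' @param fit an `inversion_result`.
#' @return matrix sources x (temporal modes * trials).
#' @export
ebb_invert <- function(reduced, fit) {
  Y <- if (inherits(reduced, "reduced_data")) reduced$Y else as.matrix(reduced)
  if (nrow(Y) != nrow(fit$C)) stop("dimension mismatch between data and fit")
  M <- fit$h[2] * (fit$q * t(fit$L_reduced)) %*% fit$Cinv
  M %*% Y
}

#' Per-source spatial filters in sensor space
#'
#' Returns `M` (sources x channels) such that `M %*% sensor_data` is the MAP
#' source estimate; the composition of the MAP projector with the spatial
#' reduction.
#'
#' @param fit an `inversion_result` from a [svd_reduce()]d fit.
#' @return sources x channels matrix.
#' @export
source_filters <- function(fit) {
  if (is.null(fit$spatial))
    stop("fit was not computed from reduced data; no sensor-space projector")
  fit$h[2] * (fit$q * t(fit$L_reduced)) %*% fit$Cinv %*% fit$spatial
}

#' Multi-regularization ("augmented") EBB inversion
#'
#' Builds one candidate beamformer prior per regularization level, scores
#' each by ReML free energy, and returns the winner (argmax F) with the full
#' free-energy table.
#'
#' @param reduced a [svd_reduce()] result.
#' @param lf a `lead_field`.
#' @param lambdas regularization levels as percent of the mean eigenvalue of
#'   `YY'`; default the standard ladder `c(0, 5, 10, 50, 100, 1000)`.
#' @param noise_cov optional noise covariance (see [reml_mix()]).
#' @return the winning `inversion_result`, with a data frame of all
#'   candidates as element `candidates` (`lambda_percent`, `F`).
#' @export
multi_reg_invert <- function(reduced, lf, lambdas = c(0, 5, 10, 50, 100, 1000),
                             noise_cov = NULL) {
  if (length(lambdas) < 1) stop("need at least one lambda")
  fits <- list()
  Fs <- rep(NA_real_, length(lambdas))
  for (i in seq_along(lambdas)) {
    fits[[i]] <- tryCatch({
      pr <- ebb_prior(reduced, lf, lambda = lambdas[i] / 100)
      reml_mix(reduced, lf, pr, noise_cov = noise_cov)
    }, error = function(e) NULL)
    if (!is.null(fits[[i]])) Fs[i] <- fits[[i]]$F
  }
  if (all(is.na(Fs))) stop("all regularization candidates failed")
  win <- which.max(Fs)
  out <- fits[[win]]
  out$candidates <- data.frame(lambda_percent = lambdas, F = Fs)
  out
}

#' Free-energy comparison across patch sizes
#'
#' Runs one inversion per candidate patch FWHM (coherence-smoothed lead
#' field) and reports each model's free energy relative to the mean over
#' all candidates, so the relative values sum to zero by construction.
#'
#' @param reduced a [svd_reduce()] result.
#' @param model the `laminar_model`.
#' @param lf the unsmoothed `lead_field`.
#' @param fwhms candidate FWHMs in meters (default 2.5-20 mm).
#' @param lambda regularization fraction for the priors.
#' @return data frame with `fwhm`, `F`, `F_rel`.
#' @export
patch_size_sweep <- function(reduced, model, lf,
                             fwhms = c(0.0025, 0.005, 0.010, 0.020),
                             lambda = 0) {
  Fs <- vapply(fwhms, function(fw) {
    lfs <- suppressWarnings(coherence_smooth(lf, model, fw))
    pr <- ebb_prior(reduced, lfs, lambda = lambda)
    reml_mix(reduced, lfs, pr)$F
  }, numeric(1))
  data.frame(fwhm = fwhms, F = Fs, F_rel = Fs - mean(Fs))
}
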