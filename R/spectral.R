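#' Epoched sensor data
#'
#' @param data numeric array, trials x channels x samples.
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample relative to the alignment event, s.
#' @param event alignment event label (`"RDK"`, `"cue"`, `"response"`).
#' @param trials data frame of per-trial condition labels (congruence,
#'   coherence, correctness, ...); one row per trial.
#' @return object of class `epoched_data` with a `time` axis.
#' @export
epoched_data <- function(data, fs, t0, event = "RDK", trials = NULL) {
  stopifnot(length(dim(data)) == 3)
  ntr <- dim(data)[1]
  if (is.null(trials)) trials <- data.frame(trial = seq_len(ntr))
  if (nrow(trials) != ntr) stop("trial table rows must equal trial count")
  structure(list(data = data, fs = fs, event = event,
                 time = t0 + (seq_len(dim(data)[3]) - 1) / fs,
                 trials = trials),
            class = "epoched_data")
}

#' @export
print.epoched_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_data> %d trials x %d channels x %d samples @ %g Hz, t = [%.3f, %.3f] s (%s-aligned)\n",
              d[1], d[2], d[3], x$fs, min(x$time), max(x$time), x$event))
  invisible(x)
}

time_indices <- function(epochs, woi) {
  idx <- which(epochs$time >= woi[1] - 1e-9 & epochs$time <= woi[2] + 1e-9)
  if (!length(idx)) stop("window [", woi[1], ", ", woi[2], "] outside epoch")
  idx
}

#' Standard MEG preprocessing for epoched data
#'
#' Zero-phase (forward-backward) 5th-order Butterworth bandpass, zero-phase
#' notch, integer-ratio downsampling, and variance-based trial rejection
#' (trials whose variance exceeds the across-trial mean by more than
#' `reject_sd` standard deviations are dropped; the rejection mask is
#' recorded in the trial table).
#'
#' @param epochs an [epoched_data()].
#' @param band bandpass edges, Hz.
#' @param notch notch (line) frequency, Hz; `NULL` disables.
#' @param fs_out output sampling rate; must divide the input rate.
#' @param reject_sd variance rejection threshold in SD units; `Inf` disables.
#' @return a filtered, resampled [epoched_data()]; dropped trials are
#'   removed and flagged in `$rejected` (original indices).
#' @export
preprocess <- function(epochs, band = c(2, 100), notch = 50, fs_out = 250,
                       reject_sd = 2.5) {
  fs <- epochs$fs
  if (fs_out > fs) stop("fs_out exceeds input sampling rate")
  if (abs(fs / fs_out - round(fs / fs_out)) > 1e-9)
    stop("fs_out must divide the input sampling rate")
  if (band[2] >= fs_out / 2)
    stop("upper band edge at or above Nyquist after resampling")
  # high- and low-pass applied separately: a direct-form order-5 bandpass
  # with a near-zero lower edge is numerically unstable
  hp <- signal::butter(5, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(5, band[2] / (fs / 2), type = "low")
  nt <- if (!is.null(notch))
    signal::butter(3, c(notch - 2, notch + 2) / (fs / 2), type = "stop")
  X <- epochs$data
  dec <- as.integer(round(fs / fs_out))
  keep <- seq(1, dim(X)[3], by = dec)
  out <- array(0, c(dim(X)[1], dim(X)[2], length(keep)))
  for (tr in seq_len(dim(X)[1])) {
    for (ch in seq_len(dim(X)[2])) {
      x <- signal::filtfilt(lp, signal::filtfilt(hp, X[tr, ch, ]))
      if (!is.null(notch)) x <- signal::filtfilt(nt, x)
      out[tr, ch, ] <- x[keep]
    }
  }
  res <- epoched_data(out, fs_out, epochs$time[1], epochs$event, epochs$trials)
  v <- apply(res$data, 1, function(x) stats::var(as.vector(x)))
  bad <- which(v > mean(v) + reject_sd * stats::sd(v))
  res$rejected <- bad
  if (length(bad)) {
    res$data <- res$data[-bad, , , drop = FALSE]
    res$trials <- res$trials[-bad, , drop = FALSE]
  }
  res
}

morlet_wavelet <- function(f, fs, n_cycles = 7) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(3.5 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))                # unit energy
}

#' Morlet wavelet time-frequency power
#'
#' Complex Morlet convolution (default seven cycles) per trial and channel.
#' Samples within one wavelet half-length of the epoch edges are flagged in
#' the `mask` element (freqs x times, `TRUE` = valid) so callers can pad or
#' exclude them.
#'
#' @param epochs an [epoched_data()].
#' @param freqs frequency grid, Hz.
#' @param n_cycles wavelet cycles.
#' @return object of class `tf_power`: `power` (trials x channels x freqs x
#'   times), `freqs`, `time`, `mask`, `method = "morlet"`.
#' @export
morlet_tf <- function(epochs, freqs = 2:45, n_cycles = 7) {
  fs <- epochs$fs
  ns <- dim(epochs$data)[3]
  need <- ceiling(n_cycles / min(freqs) * fs)
  if (ns < need)
    stop("epoch too short for ", n_cycles, " cycles at ", min(freqs),
         " Hz (need ", need, " samples, have ", ns, ")")
  ntr <- dim(epochs$data)[1]; nch <- dim(epochs$data)[2]
  wavs <- lapply(freqs, morlet_wavelet, fs = fs, n_cycles = n_cycles)
  halves <- vapply(wavs, function(w) (length(w) - 1L) / 2L, numeric(1))
  nfft <- stats::nextn(ns + max(lengths(wavs)), 2)
  wf <- lapply(wavs, function(w) stats::fft(c(w, rep(0, nfft - length(w)))))
  power <- array(0, c(ntr, nch, length(freqs), ns))
  for (tr in seq_len(ntr)) {
    X <- matrix(epochs$data[tr, , ], nch, ns)
    Xf <- stats::mvfft(rbind(t(X), matrix(0, nfft - ns, nch)))
    for (k in seq_along(freqs)) {
      Cf <- stats::mvfft(Xf * wf[[k]], inverse = TRUE) / nfft
      sel <- halves[k] + seq_len(ns)     # center of full convolution
      power[tr, , k, ] <- t(Mod(Cf[sel, , drop = FALSE])^2)
    }
  }
  mask <- matrix(TRUE, length(freqs), ns)
  for (k in seq_along(freqs)) {
    h <- halves[k]
    if (h >= 1) mask[k, c(seq_len(min(h, ns)),
                          seq.int(max(1, ns - h + 1), ns))] <- FALSE
  }
  structure(list(power = power, freqs = freqs, time = epochs$time,
                 mask = mask, method = "morlet", baseline_corrected = FALSE),
            class = "tf_power")
}

sine_tapers <- function(nw, k) {
  t(vapply(seq_len(k), function(j)
    sqrt(2 / (nw + 1)) * sin(pi * j * seq_len(nw) / (nw + 1)), numeric(nw)))
}

#' Sliding-window multitaper power (sine tapers)
#'
#' Spectral power on a sliding window with sine tapers, for the high-band
#' (gamma) range where wavelet bandwidth becomes inefficient.
#'
#' @param epochs an [epoched_data()].
#' @param freqs frequency grid, Hz.
#' @param t_window window length, s.
#' @param t_step window step, s.
#' @param n_tapers number of sine tapers.
#' @return a `tf_power` object (times are window centers).
#' @export
multitaper_tf <- function(epochs, freqs = seq(55, 115, 5), t_window = 0.2,
                          t_step = 0.01, n_tapers = 3) {
  fs <- epochs$fs
  ns <- dim(epochs$data)[3]
  nw <- round(t_window * fs)
  if (nw > ns) stop("multitaper window exceeds epoch length")
  ntr <- dim(epochs$data)[1]; nch <- dim(epochs$data)[2]
  starts <- seq(1, ns - nw + 1, by = max(1, round(t_step * fs)))
  centers <- epochs$time[starts] + (nw - 1) / (2 * fs)
  tap <- sine_tapers(nw, n_tapers)
  tt <- seq_len(nw) / fs
  # per frequency: taper-modulated complex exponentials, nw x n_tapers
  basis <- lapply(freqs, function(f)
    t(tap) * exp(-2i * pi * f * tt))
  power <- array(0, c(ntr, nch, length(freqs), length(starts)))
  for (tr in seq_len(ntr)) {
    X <- matrix(epochs$data[tr, , ], nch, ns)
    for (wi in seq_along(starts)) {
      seg <- X[, starts[wi] + seq_len(nw) - 1, drop = FALSE]
      for (k in seq_along(freqs)) {
        C <- seg %*% basis[[k]]          # nch x n_tapers complex
        power[tr, , k, wi] <- rowMeans(Mod(C)^2)
      }
    }
  }
  structure(list(power = power, freqs = freqs, time = centers,
                 mask = matrix(TRUE, length(freqs), length(starts)),
                 method = "multitaper", baseline_corrected = FALSE),
            class = "tf_power")
}

#' Robust (iteratively reweighted) average
#'
#' Bisquare-weighted mean: residuals from the current estimate are scaled by
#' a MAD-based sigma and mapped to weights in `[0, 1]`; iterated to
#' convergence. Reduces the influence of outlying samples on the mean.
#'
#' @param x numeric samples (length >= 2 unless all equal).
#' @param tuning bisquare tuning constant (4.685 gives 95 percent Gaussian
#'   efficiency).
#' @param max_iter,tol iteration controls.
#' @return list with `mean` and `weights`.
#' @export
robust_average <- function(x, tuning = 4.685, max_iter = 20, tol = 1e-6) {
  x <- as.numeric(x)
  if (length(x) < 1) stop("need at least one sample")
  m <- mean(x)
  w <- rep(1, length(x))
  for (it in seq_len(max_iter)) {
    u <- x - m
    s <- stats::median(abs(u)) / 0.6745
    if (!is.finite(s) || s < 1e-12 * max(abs(x), 1)) {
      return(list(mean = m, weights = w))
    }
    w <- pmax(1 - (u / (tuning * s))^2, 0)^2
    if (sum(w) == 0) return(list(mean = m, weights = w))
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < tol * max(1, abs(m))) {
      m <- m_new
      break
    }
    m <- m_new
  }
  list(mean = m, weights = w)
}

#' Baseline-correct a time-frequency representation
#'
#' Computes a per-frequency (and per-channel) robust-average baseline over
#' the baseline window, pooling trials and baseline time bins, and rescales
#' power to the fractional (or percent) change from it.
#'
#' @param tf a `tf_power` object.
#' @param baseline_woi baseline window, s (within the epoch).
#' @param mode `"fractional"` (`(P - b)/b`) or `"percent"` (x100).
#' @return a `tf_power` with corrected power, `baseline_corrected = TRUE`
#'   and the baseline stored as `baseline` (channels x freqs).
#' @export
baseline_correct <- function(tf, baseline_woi, mode = c("fractional", "percent")) {
  mode <- match.arg(mode)
  bidx <- which(tf$time >= baseline_woi[1] - 1e-9 &
                tf$time <= baseline_woi[2] + 1e-9)
  if (!length(bidx)) stop("baseline window outside epoch")
  d <- dim(tf$power)
  b <- matrix(0, d[2], d[3])
  out <- tf
  for (ch in seq_len(d[2])) {
    for (k in seq_len(d[3])) {
      valid <- bidx[tf$mask[k, bidx]]
      if (!length(valid)) valid <- bidx
      b[ch, k] <- robust_average(as.vector(tf$power[, ch, k, valid]))$mean
      if (b[ch, k] <= 0)
        stop("non-positive baseline power at channel ", ch, ", ",
             tf$freqs[k], " Hz")
      out$power[, ch, k, ] <- (tf$power[, ch, k, ] - b[ch, k]) / b[ch, k]
    }
  }
  if (mode == "percent") out$power <- out$power * 100
  out$baseline_corrected <- TRUE
  out$baseline <- b
  out$baseline_woi <- baseline_woi
  out
}

#' Per-trial band power of a set of single time courses
#'
#' Mean time-frequency power over a band and window of interest, one scalar
#' per trial. Follows the low/high band split: Morlet for bands at or below
#' 45 Hz, sliding-window multitaper above.
#'
#' @param x matrix trials x samples (a single sensor or source), or an
#'   [epoched_data()] with one channel.
#' @param fs sampling rate (ignored when `x` is `epoched_data`).
#' @param t0 time of first sample (ignored when `x` is `epoched_data`).
#' @param band frequency band, Hz, length 2.
#' @param woi window of interest, s.
#' @param method `"auto"`, `"morlet"` or `"multitaper"`.
#' @return numeric vector, one value per trial.
#' @export
band_power <- function(x, band, woi, fs = NULL, t0 = NULL,
                       method = c("auto", "morlet", "multitaper")) {
  method <- match.arg(method)
  if (!inherits(x, "epoched_data")) {
    x <- epoched_data(array(as.matrix(x), c(nrow(as.matrix(x)), 1,
                                            ncol(as.matrix(x)))),
                      fs = fs, t0 = t0)
  }
  if (method == "auto")
    method <- if (band[2] <= 45) "morlet" else "multitaper"
  tf <- if (method == "morlet") {
    morlet_tf(x, freqs = seq(band[1], band[2]))
  } else {
    multitaper_tf(x, freqs = seq(band[1], band[2], by = 5))
  }
  tidx <- which(tf$time >= woi[1] - 1e-9 & tf$time <= woi[2] + 1e-9)
  if (!length(tidx)) stop("window of interest outside the epoch")
  apply(tf$power[, 1, , tidx, drop = FALSE], 1, mean)
}

gaussian_kernel <- function(fwhm_bins) {
  if (fwhm_bins <= 0) return(1)
  sigma <- fwhm_bins / (2 * sqrt(2 * log(2)))
  half <- ceiling(3 * sigma)
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

smooth_matrix <- function(m, fwhm_rows, fwhm_cols) {
  kr <- gaussian_kernel(fwhm_rows)
  kc <- gaussian_kernel(fwhm_cols)
  conv1 <- function(v, k) {
    if (length(k) == 1) return(v)
    n <- length(v)
    h <- (length(k) - 1) / 2
    padded <- c(rep(NA, h), v, rep(NA, h))
    out <- numeric(n)
    for (i in seq_len(n)) {
      seg <- padded[i:(i + 2 * h)]
      ok <- !is.na(seg)
      out[i] <- sum(seg[ok] * k[ok]) / sum(k[ok])  # edge-renormalized
    }
    out
  }
  m <- t(apply(m, 1, conv1, k = kc))
  apply(m, 2, conv1, k = kr)
}

#' Cluster-averaged, smoothed spectrogram with significance mask
#'
#' Averages baseline-corrected spectrograms over a sensor cluster, smooths
#' with a separable Gaussian kernel, and (when several participants are
#' supplied) marks time-frequency pixels whose group mean differs from zero
#' by a per-pixel one-sample t-test, Bonferroni-corrected over pixels.
#'
#' @param tfs list of per-participant arrays (channels x freqs x times),
#'   baseline-corrected, all the same shape.
#' @param cluster integer channel indices to average.
#' @param smooth_fwhm c(frequency bins, time bins) FWHM of the kernel; 0
#'   disables.
#' @param alpha significance level before Bonferroni correction.
#' @return list: `mean` (freqs x times, group mean of smoothed cluster
#'   averages), `mask` (logical, significant pixels; all `NA` when fewer
#'   than 3 participants), `per_participant`.
#' @export
sensor_tf_summary <- function(tfs, cluster, smooth_fwhm = c(8, 20),
                              alpha = 0.05) {
  if (!length(cluster)) stop("empty sensor cluster")
  if (!is.list(tfs)) tfs <- list(tfs)
  per <- lapply(tfs, function(a) {
    m <- apply(a[cluster, , , drop = FALSE], c(2, 3), mean)
    smooth_matrix(m, smooth_fwhm[1], smooth_fwhm[2])
  })
  gm <- Reduce(`+`, per) / length(per)
  mask <- matrix(NA, nrow(gm), ncol(gm))
  if (length(per) >= 3) {
    npix <- length(gm)
    arr <- simplify2array(per)           # f x t x participants
    mn <- apply(arr, c(1, 2), mean)
    sdv <- apply(arr, c(1, 2), stats::sd)
    tstat <- mn / (sdv / sqrt(length(per)))
    p <- 2 * stats::pt(-abs(tstat), df = length(per) - 1)
    mask <- p < alpha / npix
  }
  list(mean = gm, mask = mask, per_participant = per)
}

#' Intra-class correlation ICC(2,k)
#'
#' Two-way random-effects, average-measures intra-class correlation from the
#' classical mean squares: `(BMS - EMS) / (BMS + (JMS - EMS)/n)` with `BMS`
#' the between-item, `JMS` the between-rater and `EMS` the residual mean
#' square, `n` items.
#'
#' @param x matrix raters (runs/sessions) x items.
#' @return the ICC estimate (scalar).
#' @export
icc_2k <- function(x) {
  x <- as.matrix(x)
  k <- nrow(x)                           # raters (runs)
  n <- ncol(x)                           # items
  if (k < 2 || n < 2) stop("need >= 2 raters and >= 2 items")
  grand <- mean(x)
  item_m <- colMeans(x)
  rater_m <- rowMeans(x)
  BMS <- k * sum((item_m - grand)^2) / (n - 1)
  JMS <- n * sum((rater_m - grand)^2) / (k - 1)
  EMS <- (sum((x - outer(rater_m, item_m, `+`) + grand)^2)) /
    ((n - 1) * (k - 1))
  if (BMS + (JMS - EMS) / n == 0 || !is.finite(BMS)) {
    warning("zero between-item variance; ICC undefined")
    return(NA_real_)
  }
  (BMS - EMS) / (BMS + (JMS - EMS) / n)
}
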