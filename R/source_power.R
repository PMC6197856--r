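# Source-level band power. Time-frequency transforms are linear in the data
# and the MAP estimate is a linear projection, so wavelet / taper
# coefficients are computed once at the sensor level and projected through
# the per-source spatial filters; power is the squared modulus of the
# projected coefficients. This is exactly the power of the transformed
# source time courses at a fraction of the cost.

#' Per-trial source band power in a window and its baseline
#'
#' Computes, for every source and trial, mean time-frequency power over
#' `band` in `woi` and in `baseline_woi`, using the low/high band split
#' (Morlet at or below 45 Hz, sliding sine-taper multitaper above).
#'
#' @param filters sources x channels projection matrix
#'   (see [source_filters()]).
#' @param epochs the sensor-level [epoched_data()].
#' @param band frequency band, Hz.
#' @param woi,baseline_woi analysis and baseline windows, s.
#' @param method `"auto"`, `"morlet"` or `"multitaper"`.
#' @param n_freqs number of frequencies sampled across the band.
#' @param time_decim spacing (s) of time points at which power is sampled
#'   within each window.
#' @return list with matrices `woi` and `baseline` (sources x trials).
#' @export
source_band_power <- function(filters, epochs, band, woi, baseline_woi,
                              method = c("filter", "morlet", "multitaper",
                                         "auto"),
                              n_freqs = 4, time_decim = 0.04) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (band[2] <= 45) "morlet" else "multitaper"
  if (method == "filter") {
    source_band_power_filter(filters, epochs, band, woi, baseline_woi)
  } else if (method == "morlet") {
    source_band_power_morlet(filters, epochs, band, woi, baseline_woi,
                             n_freqs, time_decim)
  } else {
    source_band_power_multitaper(filters, epochs, band, woi, baseline_woi)
  }
}

# Band power as the time-domain mean square of the zero-phase band-filtered
# projected signal. By Parseval this is the band power, and it uses the full
# time-bandwidth product of each window -- the highest-dof per-trial
# estimate available, which matters for short baseline windows. Default at
# source level.
source_band_power_filter <- function(filters, epochs, band, woi,
                                     baseline_woi) {
  filtered <- attr(epochs, "band_filtered")
  if (is.null(filtered) || !isTRUE(all.equal(attr(filtered, "band"), band))) {
    filtered <- filter_epochs(epochs, band)
  }
  iw <- time_indices(filtered, woi)
  ib <- time_indices(filtered, baseline_woi)
  ntr <- dim(filtered$data)[1]
  nch <- dim(filtered$data)[2]
  nsrc <- nrow(filters)
  pw <- matrix(0, nsrc, ntr)
  pb <- matrix(0, nsrc, ntr)
  need <- c(iw, ib)                      # project only the samples used
  jw <- seq_along(iw); jb <- length(iw) + seq_along(ib)
  for (tr in seq_len(ntr)) {
    X <- matrix(filtered$data[tr, , ], nch)[, need, drop = FALSE]
    J <- filters %*% X
    pw[, tr] <- rowMeans(J[, jw, drop = FALSE]^2)
    pb[, tr] <- rowMeans(J[, jb, drop = FALSE]^2)
  }
  list(woi = pw, baseline = pb, method = "filter", band = band)
}

source_band_power_morlet <- function(filters, epochs, band, woi, baseline_woi,
                                     n_freqs = 4, time_decim = 0.04) {
  fs <- epochs$fs
  ns <- dim(epochs$data)[3]
  ntr <- dim(epochs$data)[1]
  nch <- dim(epochs$data)[2]
  freqs <- seq(band[1], band[2], length.out = max(2, n_freqs))
  wavs <- lapply(freqs, morlet_wavelet, fs = fs)
  halves <- vapply(wavs, function(w) (length(w) - 1L) %/% 2L, integer(1))
  nfft <- stats::nextn(ns + max(lengths(wavs)), 2)
  wf <- lapply(wavs, function(w) stats::fft(c(w, rep(0, nfft - length(w)))))
  dec <- max(1L, round(time_decim * fs))
  pick <- function(wnd, h) {
    idx <- which(epochs$time >= wnd[1] - 1e-9 & epochs$time <= wnd[2] + 1e-9)
    idx <- idx[idx > h & idx <= ns - h]  # stay clear of edge artifacts
    if (!length(idx))
      idx <- which(epochs$time >= wnd[1] - 1e-9 & epochs$time <= wnd[2] + 1e-9)
    idx[seq(1, length(idx), by = dec)]
  }
  nsrc <- nrow(filters)
  pw <- matrix(0, nsrc, ntr)
  pb <- matrix(0, nsrc, ntr)
  for (tr in seq_len(ntr)) {
    X <- matrix(epochs$data[tr, , ], nch, ns)
    Xf <- stats::mvfft(rbind(t(X), matrix(0, nfft - ns, nch)))
    accw <- accb <- 0
    nw <- nb <- 0L
    for (k in seq_along(freqs)) {
      Cf <- stats::mvfft(Xf * wf[[k]], inverse = TRUE) / nfft
      coefs <- t(Cf[halves[k] + seq_len(ns), , drop = FALSE])  # nch x ns
      iw <- pick(woi, halves[k]); ib <- pick(baseline_woi, halves[k])
      Zw <- coefs[, iw, drop = FALSE]
      Zb <- coefs[, ib, drop = FALSE]
      Pw <- (filters %*% Re(Zw))^2 + (filters %*% Im(Zw))^2
      Pb <- (filters %*% Re(Zb))^2 + (filters %*% Im(Zb))^2
      accw <- accw + rowSums(Pw); nw <- nw + ncol(Zw)
      accb <- accb + rowSums(Pb); nb <- nb + ncol(Zb)
    }
    pw[, tr] <- accw / nw
    pb[, tr] <- accb / nb
  }
  list(woi = pw, baseline = pb, freqs = freqs, method = "morlet")
}

source_band_power_multitaper <- function(filters, epochs, band, woi,
                                         baseline_woi, t_window = 0.2,
                                         t_step = 0.05, n_tapers = 3,
                                         freq_step = 10) {
  fs <- epochs$fs
  ns <- dim(epochs$data)[3]
  ntr <- dim(epochs$data)[1]
  nch <- dim(epochs$data)[2]
  nwin <- round(t_window * fs)
  if (nwin > ns) stop("multitaper window exceeds epoch")
  freqs <- seq(band[1], band[2], by = freq_step)
  tap <- sine_tapers(nwin, n_tapers)
  tt <- seq_len(nwin) / fs
  basis <- lapply(freqs, function(f) t(tap) * exp(-2i * pi * f * tt))
  win_starts <- function(wnd) {
    lo <- wnd[1]; hi <- wnd[2]
    centers <- seq(lo + t_window / 2, max(lo + t_window / 2, hi - t_window / 2),
                   by = t_step)
    starts <- round((centers - epochs$time[1]) * fs) + 1 - round(nwin / 2)
    unique(pmin(pmax(starts, 1L), ns - nwin + 1L))
  }
  sw <- win_starts(woi); sb <- win_starts(baseline_woi)
  nsrc <- nrow(filters)
  pw <- matrix(0, nsrc, ntr)
  pb <- matrix(0, nsrc, ntr)
  accum <- function(X, starts) {
    acc <- 0; cnt <- 0L
    for (s0 in starts) {
      seg <- X[, s0 + seq_len(nwin) - 1, drop = FALSE]
      for (k in seq_along(freqs)) {
        C <- seg %*% basis[[k]]          # nch x tapers, complex
        P <- (filters %*% Re(C))^2 + (filters %*% Im(C))^2
        acc <- acc + rowSums(P)
        cnt <- cnt + ncol(C)
      }
    }
    acc / cnt
  }
  for (tr in seq_len(ntr)) {
    X <- matrix(epochs$data[tr, , ], nch, ns)
    pw[, tr] <- accum(X, sw)
    pb[, tr] <- accum(X, sb)
  }
  list(woi = pw, baseline = pb, freqs = freqs, method = "multitaper")
}
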