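#!/usr/bin/env Rscript
# Sensor-level time-frequency overview of the simulated session: Morlet
# power in the low band and multitaper power in the high band over the
# task-responsive sensor cluster, trial-averaged in chunks (the full
# trials x channels x freqs x times array would not fit in memory),
# robust-average baseline-corrected, then smoothed.

library(laminar)

session <- readRDS("results/session/session.rds")
dir.create("results/sensor", showWarnings = FALSE, recursive = TRUE)

# per-band clusters: the 15 sensors with the strongest band-filtered signal
band_cluster <- function(band) {
  ep <- filter_epochs(session$epochs, band)
  strength <- apply(ep$data, 2, function(x) mean(x^2))
  order(strength, decreasing = TRUE)[1:15]
}
cl_low <- band_cluster(c(7, 13))
cl_high <- band_cluster(c(60, 90))
message("low-band cluster: ", paste(cl_low, collapse = ", "))
message("high-band cluster: ", paste(cl_high, collapse = ", "))

cluster_epochs <- function(cl)
  epoched_data(session$epochs$data[, cl, , drop = FALSE],
               session$epochs$fs, session$epochs$time[1],
               trials = session$epochs$trials)

# chunked trial-average of per-trial power
chunked_tf <- function(epochs, fun, chunk = 5) {
  ntr <- dim(epochs$data)[1]
  acc <- NULL; template <- NULL
  for (start in seq(1, ntr, by = chunk)) {
    idx <- start:min(start + chunk - 1, ntr)
    sub <- epoched_data(epochs$data[idx, , , drop = FALSE], epochs$fs,
                        epochs$time[1])
    tf <- fun(sub)
    m <- apply(tf$power, c(2, 3, 4), sum)
    acc <- if (is.null(acc)) m else acc + m
    if (is.null(template)) template <- tf
  }
  template$power <- array(acc / ntr, c(1, dim(acc)))
  template
}

message("Morlet 2-45 Hz (trial-averaged) ...")
tf_low <- chunked_tf(cluster_epochs(cl_low), function(e)
  morlet_tf(e, freqs = seq(2, 45, 1)))
tf_low <- baseline_correct(tf_low, c(-1, -0.5), mode = "percent")
message("multitaper 55-115 Hz (trial-averaged) ...")
tf_high <- chunked_tf(cluster_epochs(cl_high), function(e)
  multitaper_tf(e, freqs = seq(55, 115, 5), t_step = 0.02))
tf_high <- baseline_correct(tf_high, c(-1, -0.5), mode = "percent")

summ <- function(tf) sensor_tf_summary(list(tf$power[1, , , ]),
                                       cluster = 1:15,
                                       smooth_fwhm = c(8, 20))
lo <- summ(tf_low)
hi <- summ(tf_high)

write_tf <- function(m, freqs, times, path) {
  d <- data.frame(freq = rep(freqs, times = length(times)),
                  time = rep(times, each = length(freqs)),
                  percent_change = as.vector(m))
  write.csv(d, path, row.names = FALSE)
}
write_tf(lo$mean, tf_low$freqs, tf_low$time,
         "results/sensor/tf_low_cluster.csv")
write_tf(hi$mean, tf_high$freqs, tf_high$time,
         "results/sensor/tf_high_cluster.csv")

# headline numbers: mean percent change in each band's window of interest
alpha_woi <- tf_low$time >= 0 & tf_low$time <= 2
alpha_rows <- tf_low$freqs >= 7 & tf_low$freqs <= 13
gamma_woi <- tf_high$time >= 0.25 & tf_high$time <= 0.5
gamma_rows <- tf_high$freqs >= 60 & tf_high$freqs <= 90
message(sprintf("alpha 7-13 Hz, WOI [0,2] s: %+.1f%% from baseline",
                mean(lo$mean[alpha_rows, alpha_woi])))
message(sprintf("gamma 60-90 Hz, WOI [0.25,0.5] s: %+.1f%% from baseline",
                mean(hi$mean[gamma_rows, gamma_woi])))
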