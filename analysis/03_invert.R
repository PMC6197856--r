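#!/usr/bin/env Rscript
# Source inversion of the example session: per-band empirical Bayesian
# beamformer fits, the multi-regularization (augmented) variant, and the
# free-energy patch-size sweep.

library(laminar)

session <- readRDS("results/session/session.rds")
dir.create("results/inversion", showWarnings = FALSE, recursive = TRUE)

lfs <- coherence_smooth(session$lf, session$model, 0.010)

for (band in list(alpha = c(7, 13), gamma = c(60, 90))) {
  sfit <- fit_session(session, lf = lfs, band = band, patch_fwhm = 0)
  message(sprintf("band %g-%g Hz: F = %.1f, h = (%.3g, %.3g), %d ReML iterations",
                  band[1], band[2], sfit$fit$F, sfit$fit$h[1], sfit$fit$h[2],
                  sfit$fit$iterations))
}

message("multi-regularization candidates (alpha band):")
ep <- filter_epochs(session$epochs, c(7, 13))
red <- svd_reduce(ep)
multi <- multi_reg_invert(red, lfs)
print(multi$candidates)
write.csv(multi$candidates, "results/inversion/multireg_alpha.csv",
          row.names = FALSE)
message(sprintf("winner: lambda = %g%% of the mean eigenvalue",
                multi$candidates$lambda_percent[which.max(multi$candidates$F)]))

message("patch-size sweep (free energy relative to the candidate mean):")
sweep <- patch_size_sweep(red, session$model, session$lf,
                          fwhms = c(0.005, 0.010, 0.020))
print(sweep)
write.csv(sweep, "results/inversion/patch_sweep_alpha.csv", row.names = FALSE)
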