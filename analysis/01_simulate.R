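#!/usr/bin/env Rscript
# Build the synthetic study geometry and one example session, and export
# everything a downstream stage (or an external tool) needs: surfaces (OBJ),
# sensor layout (CSV), task schedule (CSV), ground truth (CSV), and the
# session object (RDS) for the later stages.

library(laminar)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- "results/session"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("building two-layer model (642 vertices per surface) ...")
model <- make_two_layer_model(subdivisions = 3)
sensors <- make_sensor_array(130)
lf <- build_lead_field(model, sensors)

message("simulating a 100-trial session at 0 dB SNR ...")
session <- simulate_session(model, sensors, lf = lf, n_trials = 100,
                            snr_db = 0, seed = seed)

write_surface(model$pial, file.path(out, "pial.obj"), role = "pial")
write_surface(model$white, file.path(out, "white.obj"), role = "white")
write_surface(model$scalp, file.path(out, "scalp.obj"), role = "scalp")
write_sensor_csv(sensors, file.path(out, "sensors.csv"))
write.csv(session$epochs$trials, file.path(out, "schedule.csv"),
          row.names = FALSE)
write.csv(session$truth, file.path(out, "truth.csv"), row.names = FALSE)
saveRDS(session, file.path(out, "session.rds"))

message(sprintf("session written to %s: %d trials, %d channels, SNR %g dB",
                out, dim(session$epochs$data)[1],
                dim(session$epochs$data)[2], session$snr_db))
print(session$truth[, c("source", "surface", "vertex", "band_lo", "band_hi",
                        "modulation")])
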