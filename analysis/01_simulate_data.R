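#!/usr/bin/env Rscript
# Generate the synthetic study data: a confocal photon-burst stream from a
# two-state exchanging chromatin model (stacked E = 0.8 <-> open E = 0.15,
# relaxation 3.7 ms, 25% locked molecules, 10% donor-only contaminant) and
# a panel of slow-switching camera traces at 100 ms frames.

library(fiberFRET)
dir.create("results", showWarnings = FALSE)

pair <- dye_pair(52, 4, "Alexa488/647")
model <- kinetic_model(
  list(fret_species("stacked", pair, efficiency = 0.8),
       fret_species("open", pair, efficiency = 0.15)),
  matrix(c(0, 135, 135, 0), 2, 2, byrow = TRUE),
  static_fraction = 0.25)
write_kinetic_model(model, "results/01_model.yaml")

calib <- calibration_config(alpha = 0.02, gamma = 1, bg_donor = 500,
                            bg_acceptor = 400, donor_only_fraction = 0.1)
cfg <- confocal_sim_config(burst_count = 1500, mean_burst_duration = 0.004,
                           molecule_brightness = 5e4, calib = calib,
                           seed = 101)
sim <- simulate_bursts(model, cfg)
write_photon_stream(sim$stream, "results/01_photon_stream.tsv")
write.table(sim$truth, "results/01_burst_truth.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("confocal stream: %d photons over %.1f s, %d transits\n",
            nrow(sim$stream), max(sim$stream$macro_time), nrow(sim$truth)))

slow <- kinetic_model(
  list(fret_species("open", pair, efficiency = 0.15),
       fret_species("stacked", pair, efficiency = 0.5)),
  matrix(c(0, 2.5, 2.5, 0), 2, 2, byrow = TRUE))
tcfg <- tirf_sim_config(n_traces = 100, n_frames = 1200, seed = 102)
tirf <- simulate_tirf_traces(slow, tcfg)
write_tirf_traces(tirf, "results/01_tirf_traces.tsv")
cat(sprintf("TIRF panel: %d traces x %d frames at %.0f ms\n",
            tcfg$n_traces, tcfg$n_frames, 1000 * tcfg$frame_time))
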