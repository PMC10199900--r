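#!/usr/bin/env Rscript
# Stage 1: generate the synthetic recordings analysed by the later stages.
#
# Simulates one recording per (analyte, device) study condition from the
# packaged per-device signal library: a 3 nA open-pore baseline sampled at
# 100 kHz, Poisson translocation events (25/s), ~0.01 nA post-filter noise,
# and a causal 10 kHz second-order low-pass acquisition filter. Each
# recording is sized for roughly 2000 events (5000 for the bimodal H
# population). Traces are written in the binary raw format with a JSON
# sidecar, ground truth as TSV.
#
# Output: scratch/traces/<tag>.bin(.json), scratch/traces/<tag>_truth.tsv

suppressPackageStartupMessages(library(porecall))

seed <- 20260928L
out_dir <- "scratch/traces"  # large binary intermediates; later stages read from here
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

lib <- load_signal_library()
conditions <- rbind(
  data.frame(label = c("G", "GG", "GGG"), device = "Device #3", n = 2000L),
  data.frame(label = c("G", "A"), device = "Device #4", n = 2000L),
  data.frame(label = c("S", "T"), device = "Device #9", n = 2000L),
  data.frame(label = "H", device = "Device #6", n = 5000L),
  data.frame(label = c("Y", "p-Y", "R"), device = "Device #5", n = 2000L)
)

for (i in seq_len(nrow(conditions))) {
  lab <- conditions$label[i]; dev <- conditions$device[i]
  model <- get_signal_model(lib, lab, dev)
  cfg <- simulation_config(
    duration = 1.15 * conditions$n[i] / 25,
    analytes = data.frame(label = lab, device = dev, abundance = 1),
    voltage = -200 * model$charge_sign, event_rate = 25,
    seed = seed + i)
  sim <- simulate_trace(cfg, lib)
  tag <- gsub("[^A-Za-z0-9]+", "_", paste(lab, dev))
  write_trace(sim$trace, file.path(out_dir, paste0(tag, ".bin")), "raw")
  write_events(sim$truth, file.path(out_dir, paste0(tag, "_truth.tsv")),
               meta = list(label = lab, device = dev, seed = cfg$seed,
                           voltage_mV = cfg$voltage))
  cat(sprintf("%-16s %6.0f s, %5d true events, voltage %+d mV\n",
              paste(lab, dev), cfg$duration, nrow(sim$truth), cfg$voltage))
}
cat("traces written to", out_dir, "\n")
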