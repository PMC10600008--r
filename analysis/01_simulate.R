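#!/usr/bin/env Rscript
# Stage 1: generate the synthetic datasets every later stage analyses.
# A cohort of in vivo session recordings (bimodal basal bursting, a subset
# of units suppressed after injection), eEPSC sweeps, a concentration decay
# series, and model-predicted washout series are written as plain-text
# CSV/JSON under results/data/.

suppressMessages(library(habtrap))
seed <- 20260930
set.seed(seed)
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

message("Simulating 97 in vivo units (10-min baseline, 30-min post)...")
sessions <- gen_session(97, frac_inhibited = 0.25, inhibition_factor = 0.1,
                        inhibit_high_only = TRUE, seed = seed)
write_spikes_csv(sessions, "results/data/sessions.csv")
message(sprintf("  %d units, %d of them suppressed after injection",
                length(sessions), sum(attr(sessions, "inhibited"))))
jsonlite::write_json(
  list(inhibited = attr(sessions, "inhibited"),
       basal_freq = attr(sessions, "basal_freq")),
  "results/data/sessions_truth.json", digits = NA)

message("Simulating eEPSC sweep pairs for 16 neurons...")
dir.create("results/data/sweeps", showWarnings = FALSE)
ratio_true <- 0.35            # target for the measured t35/peak ratio
nmda_peak <- ratio_true / nmda_t35_fraction()
for (i in seq_len(16)) {
  sd_i <- seed %% 100000 + 7 * i
  ampa <- stats::rlnorm(1, log(120), 0.3)  # cell-to-cell amplitude spread
  nm <- gen_epsc_sweep(40, ampa_amp = ampa, nmda_amp = ampa * nmda_peak,
                       noise_sd = 2, seed = sd_i)
  am <- gen_epsc_sweep(-70, ampa_amp = ampa, nmda_amp = ampa * nmda_peak,
                       noise_sd = 2, seed = sd_i + 3)
  write_sweep_csv(nm, sprintf("results/data/sweeps/n%02d_plus40.csv", i))
  write_sweep_csv(am, sprintf("results/data/sweeps/n%02d_minus70.csv", i))
}

message("Simulating the brain concentration decay series (t_half 13 min)...")
pk <- gen_pk_series(16, 13, times = c(2, 5, 10, 20, 30, 45, 60),
                    noise_cv = 0.1, seed = seed %% 100000 + 900)
write_pk_csv(pk, "results/data/pk_series.csv")

message("Simulating washout series for the drug presets (100 uM, 10-min wash-in)...")
for (p in c("ketamine", "memantine")) {
  ws <- gen_washout_dataset(build_model(p), 100, noise_sd = 0.02,
                            seed = seed %% 100000 + 1000)
  write_csv_series <- data.frame(time_s = ws$pulse_times,
                                 normalized = ws$normalized_amplitude)
  utils::write.csv(write_csv_series,
                   sprintf("results/data/washout_%s.csv", p),
                   row.names = FALSE)
}
message("Done: synthetic inputs under results/data/")
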