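#!/usr/bin/env Rscript
# Generate the demo session and write it to the session layout, with the
# ground truth alongside. Later drivers load from disk, exercising the
# round trip.

source("analysis/00_config.R")

dm <- demo_config()
gen <- generate_session(dm$cfg)
print(gen$session)
print(gen$truth)

write_session(gen$session, SESSION_DIR, gen$truth)

tab <- data.frame(
  n_units = gen$session$meta$n_units,
  n_days = gen$session$meta$n_days,
  n_trials = nrow(gen$session$trials),
  n_spikes = nrow(gen$session$spikes),
  n_true_swrs = nrow(gen$truth$swr_events),
  duration_s = round(gen$session$meta$t_end))
write.csv(tab, file.path(RESULTS_DIR, "01_session_summary.csv"),
          row.names = FALSE)
cat("session written to", SESSION_DIR, "\n")
print(tab)
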