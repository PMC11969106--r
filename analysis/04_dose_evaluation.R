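#!/usr/bin/env Rscript
# Stage 4: toy-dose planning on the homogenized sessions. The thickest
# session provides the reference (planned) D95%; each session is evaluated
# under the replayed reference plan (scheduled) and a renormalized plan
# (adapted), and the adapted dose is gamma-checked against the same plan
# forward-computed on the coarse clinical dose lattice.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_config.R"))

series <- make_weight_loss_series(cfg$spec, cfg$thicknesses_cm)
sessions <- lapply(seq_along(series), function(i) {
  s <- series[[i]]
  s$homogenized <- read_image(file.path(homog_dir,
                                        sprintf("session%d_homog.mha", i)))
  s
})
dose <- phantomQA:::run_dose_stage(sessions, cfg)
write.csv(dose$table, file.path(results_dir, "dose.csv"), row.names = FALSE)

cat(sprintf("planned D95%%: %.2f Gy\n", dose$summary$planned_d95_gy))
cat(sprintf("max |D95%% deviation|: scheduled %.1f%%, adapted %.1f%%\n",
            dose$summary$max_abs_scheduled_dev_percent,
            dose$summary$max_abs_adapted_dev_percent))
cat(sprintf("emulator vs forward gamma (3%%/3 mm): min pass %.1f%%\n",
            dose$summary$min_gamma_pass_percent))
stopifnot(dose$summary$max_abs_adapted_dev_percent <
            dose$summary$max_abs_scheduled_dev_percent)
saveRDS(dose, file.path(results_dir, "dose_summary.rds"))
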