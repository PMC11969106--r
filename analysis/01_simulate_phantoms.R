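#!/usr/bin/env Rscript
# Stage 1: generate the synthetic weight-loss series (raw bolus-plus-airgap
# images and their homogenized-truth twins) and the bolus clinical cases,
# and write the images plus a session manifest under results/phantoms/.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_config.R"))

dir.create(phantom_dir, showWarnings = FALSE, recursive = TRUE)

series <- make_weight_loss_series(cfg$spec, cfg$thicknesses_cm)
manifest <- list(seed = cfg$seed, thicknesses_cm = cfg$thicknesses_cm,
                 z_landmark = "z = 0 mm at the superior slab face",
                 sessions = list())
for (i in seq_along(series)) {
  s <- series[[i]]
  raw_p <- file.path(phantom_dir, sprintf("session%d_raw.mha", i))
  body_p <- file.path(phantom_dir, sprintf("session%d_truth_body.mha", i))
  tgt_p <- file.path(phantom_dir, sprintf("session%d_target.mha", i))
  write_image(s$raw$image, raw_p)
  write_image(s$truth$masks$body_outer, body_p)
  write_image(s$truth$masks$target, tgt_p)
  manifest$sessions[[i]] <- list(
    session = i, thickness_cm = s$thickness_cm,
    raw = basename(raw_p), truth_body = basename(body_p),
    target = basename(tgt_p),
    truth_body_volume_cm3 = volume_cm3(s$truth$masks$body_outer))
  cat(sprintf("session %d (%.1f cm): truth body %.1f cm^3\n", i,
              s$thickness_cm, volume_cm3(s$truth$masks$body_outer)))
}
jsonlite::write_json(manifest, file.path(phantom_dir, "manifest.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

vols <- vapply(manifest$sessions, `[[`, 0, "truth_body_volume_cm3")
stopifnot(all(diff(vols) < 0))  # shrinking body across the series
cat("wrote", length(series), "sessions; truth volumes strictly decreasing\n")
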