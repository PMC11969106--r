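# Shared configuration for the analysis scripts. Everything downstream is a
# deterministic function of this object; re-running any script reproduces
# its outputs byte for byte.

library(phantomQA)

results_dir <- "results"
phantom_dir <- file.path(results_dir, "phantoms")
homog_dir <- file.path(results_dir, "homogenized")

cfg <- study_config(seed = 20)
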