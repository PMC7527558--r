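# Shared configuration for the analysis scripts. Volumes (binary NIfTI) go
# under scratch/, final tables are copied to results/ by each stage script.
library(silicoct)

study_config <- function(seed = 1L) {
  default_run_config(seed = seed, out_dir = "scratch/study_run")
}

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

publish <- function(cfg, files) {
  for (f in files) {
    src <- file.path(cfg$out_dir, f)
    if (file.exists(src)) file.copy(src, file.path(results_dir, f),
                                    overwrite = TRUE)
  }
}
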