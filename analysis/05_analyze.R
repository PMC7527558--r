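#!/usr/bin/env Rscript
# Stage 5 — study statistics: derive eta = G/H and the Tiffeneau index,
# summarize the biomarker trajectories per group and week, correlate the
# imaging biomarkers with the endpoint readouts on silica animals
# (Sidak-adjusted over the 6-pair family), and run the delegated
# mixed-model group x time interaction test on the non-aerated volume.
source("analysis/00_config.R")

cfg <- study_config()
out <- stage_analyze(cfg)
cat("\nimaging-endpoint correlations (silica animals, n = 32):\n")
print(as.data.frame(out$correlations), digits = 4)
cat(sprintf("\nmixed-model group x week interaction p (non-aerated volume): %.3g\n",
            out$model_p))
publish(cfg, c("correlations.csv", "trajectory_summary.csv"))
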