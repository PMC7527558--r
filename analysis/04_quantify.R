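#!/usr/bin/env Rscript
# Stage 4 — quantify the imaging arm: for each rendered scan, take the
# end-expiration phase volume, apply the fitted HU mapping, build the lung
# VOI from the labels (lung + lesions, heart/vessels excluded) and extract
# mean lung density and the aerated/non-aerated/total volumes at -223 HU.
source("analysis/00_config.R")

cfg <- study_config()
tab <- stage_quantify(cfg)
print(as.data.frame(tab)[, c("animal_id", "week", "mean_lung_density_hu",
                             "aerated_ml", "non_aerated_ml", "total_ml")])
publish(cfg, "imaging_biomarkers.csv")
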