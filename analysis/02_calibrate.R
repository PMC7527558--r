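#!/usr/bin/env Rscript
# Stage 2 — fit the Hounsfield calibration from the phantom scan: the modal
# grayscale index of the water VOI anchors 0 HU, the air VOI anchors
# -1000 HU. With the protocol anchors (133, 9) the slope is ~8.06 HU per
# grayscale step and the -223 HU threshold sits at grayscale ~105.3.
source("analysis/00_config.R")

cfg <- study_config()
m <- stage_calibrate(cfg)
print(m)
cat(sprintf("-223 HU threshold in raw grayscale: %.3f\n",
            grayscale_threshold(m, -223)))
publish(cfg, "mapping.json")
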