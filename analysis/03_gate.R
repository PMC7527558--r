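#!/usr/bin/env Rscript
# Stage 3 — retrospective respiratory gating: sort the 2205 list-mode
# events into four phase bins by the breathing phase of their exposure
# midpoints (150 breaths/min timebase) and select the end-expiration bin.
source("analysis/00_config.R")

cfg <- study_config()
bn <- stage_gate(cfg)
print(bn)
cat(sprintf("end-expiration bin: %d\n",
            select_end_expiration(bn, respiratory_model())))
publish(cfg, "binning.csv")
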