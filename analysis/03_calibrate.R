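#!/usr/bin/env Rscript
# Stage 3 — fit the pulse-energy -> impulsive-force calibration.
#
# Ordinary least squares of F0 (uN) on L (nJ/pulse), constrained through the
# origin (no energy, no force).  The fitted model converts every loading
# energy used downstream into a total force.

suppressPackageStartupMessages(library(ringforce))

tab <- read_calibration_table("results/data/calibration.csv")
model <- fit_calibration(tab, through_origin = TRUE)
print(model)
write_calibration_model(model, "results/calibration_model.json")
message(sprintf("generating slope was 0.02 uN/nJ; fitted %.5f uN/nJ",
                model$slope_uN_per_nJ))
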