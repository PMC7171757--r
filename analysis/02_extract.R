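#!/usr/bin/env Rscript
# Stage 2 — radiomic feature extraction.
#
# Computes the full catalogue for every patient: 43 features per ROI per
# sequence (12 first-order/shape, 6 GLCM, 11 GLRLM, 3 NGLDM, 11 GLZLM) on
# 64-level min-max discretized intensities, i.e. 86 per structure and 172
# per patient. Writes the feature table under results/.

library(radsurv)

cohort <- readRDS("scratch/cohort.rds")
t0 <- Sys.time()
features <- extract_cohort(cohort, n_levels = 64)
write_feature_table(features, "results/02_features.csv")

cat("Extracted", ncol(features) - 1, "features for", nrow(features),
    "patients in", round(as.numeric(Sys.time() - t0, units = "secs")), "s\n")
fam <- table(vapply(strsplit(setdiff(names(features), "patient_id"), "_"),
                    `[[`, "", 3))
cat("Features per family (x 2 structures x 2 sequences):\n")
print(fam)
cat("Missing values:", sum(is.na(features)), "\n")
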