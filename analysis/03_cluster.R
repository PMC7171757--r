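#!/usr/bin/env Rscript
# Stage 3 — split and correlation-based dimensionality reduction.
#
# Randomly divides the cohort 62/31 (training/validation), then, per
# structure, clusters training features with |Spearman| > 0.90 (average
# linkage on 1 - |SC|) and replaces each cluster by the sign-aligned
# z-scored average of its members, iterating until no representative pair
# exceeds the threshold. The frozen maps are applied to the validation
# split. Correlation heat maps before and after reduction are saved for
# inspection.

library(radsurv)

split_seed <- 20260924L
features <- read_feature_table("results/02_features.csv")
sp <- split_cohort(features, train_fraction = 2 / 3, seed = split_seed)
cat("Split:", nrow(sp$train), "training /", nrow(sp$validation),
    "validation patients\n")

for (st in c("tumor", "node")) {
  tr <- structure_columns(sp$train, st)
  va <- structure_columns(sp$validation, st)
  prep <- prepare_feature_matrix(tr)
  va <- prepare_feature_matrix(va[, names(prep$table)], max_missing = 1,
                               medians = prep$medians)$table
  m_before <- spearman_matrix(prep$table)
  red <- reduce_until_stable(prep$table, threshold = 0.90)
  m_after <- spearman_matrix(red$table)
  red_va <- apply_reduction(va, red$maps)

  write_feature_table(red$table, sprintf("results/03_reduced_train_%s.csv", st))
  write_feature_table(red_va, sprintf("results/03_reduced_validation_%s.csv", st))

  off <- abs(m_after); diag(off) <- 0
  cat(sprintf("%s: %d features -> %d representatives (max |SC| after: %.3f)\n",
              st, ncol(prep$table) - 1, ncol(red$table) - 1, max(off)))

  if (requireNamespace("pheatmap", quietly = TRUE)) {
    for (nm in c("before", "after")) {
      m <- if (nm == "before") m_before else m_after
      png(sprintf("results/03_correlation_%s_%s.png", st, nm),
          width = 900, height = 900)
      pheatmap::pheatmap(m, cluster_rows = TRUE, cluster_cols = TRUE,
                         show_rownames = FALSE, show_colnames = FALSE,
                         main = sprintf("%s features, %s reduction", st, nm))
      dev.off()
    }
  }
}
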