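#!/usr/bin/env Rscript
# Stage 5 — model evaluation and risk stratification.
#
# For each endpoint x feature source: Harrell's C-index and 36-month IPCW
# time-dependent AUC on the validation split; a maximally selected log-rank
# cutpoint derived on the training risks and applied frozen to validation;
# per-group 3-year Kaplan-Meier survival and the two-group log-rank test.
# The headline comparison is the source ordering: tumour features should
# predict LC best, node features RC/DMFS/OS.

library(radsurv)

outcomes <- read_outcomes("results/01_outcomes.csv")
risks <- read.csv("results/04_risks.csv",
                  colClasses = c(patient_id = "character"))

rows <- list()
for (key in unique(paste(risks$endpoint, risks$structure))) {
  parts <- strsplit(key, " ")[[1]]
  ep <- parts[1]; st <- parts[2]
  r <- risks[risks$endpoint == ep & risks$structure == st, ]
  ep_out <- outcomes[outcomes$endpoint == ep, ]
  get <- function(split) {
    x <- r[r$split == split, ]
    idx <- match(x$patient_id, ep_out$patient_id)
    list(risk = x$risk, time = ep_out$time_months[idx],
         event = ep_out$event[idx])
  }
  tr <- get("train"); va <- get("validation")
  cut <- tryCatch(optimal_cutpoint(tr$risk, tr$time, tr$event)$cutpoint,
                  error = function(e) NA_real_)
  grp <- va$risk > cut
  lr_p <- if (!is.na(cut) && length(unique(grp)) == 2)
    logrank_test(va$time, va$event, grp)$p else NA_real_
  rows[[key]] <- data.frame(
    endpoint = ep, structure = st,
    cindex_train = harrell_cindex(tr$risk, tr$time, tr$event),
    cindex_validation = harrell_cindex(va$risk, va$time, va$event),
    auc36_validation = time_dependent_auc(va$risk, va$time, va$event, 36),
    cutpoint = cut, logrank_p_validation = lr_p,
    surv3y_low = if (!is.na(cut) && any(!grp))
      100 * km_estimate(va$time[!grp], va$event[!grp])$survival_at(36) else NA,
    surv3y_high = if (!is.na(cut) && any(grp))
      100 * km_estimate(va$time[grp], va$event[grp])$survival_at(36) else NA)
}
perf <- do.call(rbind, rows)
rownames(perf) <- NULL
write.csv(perf, "results/05_performance.csv", row.names = FALSE)
print(perf, digits = 3)

cv <- function(ep, st)
  perf$cindex_validation[perf$endpoint == ep & perf$structure == st]
cat("\nSource ordering on the validation split:\n")
cat(sprintf("  LC:   tumour C = %.3f vs node C = %.3f  (%s)\n",
            cv("LC", "tumor"), cv("LC", "node"),
            ifelse(cv("LC", "tumor") > cv("LC", "node"),
                   "tumour better, as constructed", "node better")))
for (ep in c("RC", "DMFS", "OS"))
  cat(sprintf("  %-4s: node C = %.3f vs tumour C = %.3f  (%s)\n", ep,
              cv(ep, "node"), cv(ep, "tumor"),
              ifelse(cv(ep, "node") > cv(ep, "tumor"),
                     "node better, as constructed", "tumour better")))
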