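#!/usr/bin/env Rscript
# Step 4 — which index screens best?
# Evaluates all twelve indices against the MetS diagnosis (whole group and
# per sex): ROC, DeLong-interval AUC, Youden cutoff, predictive values.
# Then compares the two leading indices head to head with the paired
# DeLong test.
suppressPackageStartupMessages(library(pedmets))

cohort <- read_cohort("results/cohort.csv")
ref <- read_reference_tables("results/reference_tables.csv")
bundle <- run_pipeline(cohort, ref)
write_report(bundle, "results/performance", seed = 101)

perf <- performance_table(bundle)
whole <- perf[perf$stratum == "all", ]
whole <- whole[order(-whole$auc), ]
print(whole[, c("index", "auc", "auc_lo", "auc_hi", "cutoff",
                "sens", "spec", "youden")], digits = 3, row.names = FALSE)

top2 <- whole$index[1:2]
cmp <- delong_compare(bundle$panel[[top2[1]]], bundle$panel[[top2[2]]],
                      bundle$classification$mets)
cat(sprintf("\ntop two: %s (AUC %.3f) vs %s (AUC %.3f): DeLong p = %.3f\n",
            top2[1], cmp$auc_a, top2[2], cmp$auc_b, cmp$p))
ref_idx <- "bmi"
cmp2 <- delong_compare(bundle$panel[[top2[1]]], bundle$panel[[ref_idx]],
                       bundle$classification$mets)
cat(sprintf("%s vs %s: DeLong p = %.4f\n", top2[1], ref_idx, cmp2$p))

pdf("results/roc_curves.pdf", width = 6, height = 6)
plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
     xlab = "1 - specificity", ylab = "Sensitivity",
     main = "ROC, whole group")
cols <- c(tg_hdl = "firebrick", cmi = "darkorange", bmi = "steelblue",
          wthr = "darkgreen", absi = "purple")
for (v in names(cols)) {
  roc <- bundle$reports[[v]]$all$roc
  lines(roc$fpr, roc$sens, col = cols[v], lwd = 2)
}
legend("bottomright", legend = names(cols), col = cols, lwd = 2, bty = "n")
invisible(dev.off())
cat("wrote results/performance/ and results/roc_curves.pdf\n")
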