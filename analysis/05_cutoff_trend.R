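#!/usr/bin/env Rscript
# Step 5 — TG/HDL-C as the working screener.
# Correlates the TG/HDL-C ratio with each MetS component (Spearman), then
# traces its age- and sex-specific Youden cutoff with the sliding-window
# reconstruction.
suppressPackageStartupMessages(library(pedmets))

cohort <- read_cohort("results/cohort.csv")
ref <- read_reference_tables("results/reference_tables.csv")
panel <- compute_indices(cohort, ref)
mets <- classify_mets(cohort, panel, ref)$mets

comp <- c(bmi = "bmi", bmi_sds = "bmi_sds", glucose = "glucose_mgdl",
          hdl = "hdl_mgdl", tg = "tg_mgdl", sbp = "sbp_mmhg", dbp = "dbp_mmhg")
cors <- do.call(rbind, lapply(names(comp), function(v) {
  x <- if (comp[[v]] %in% names(panel)) panel[[comp[[v]]]] else cohort[[comp[[v]]]]
  r <- spearman_rho(panel$tg_hdl, x)
  data.frame(component = v, rho = round(r$rho, 2), p = signif(r$p, 3))
}))
write.csv(cors, "results/tg_hdl_correlations.csv", row.names = FALSE)
print(cors, row.names = FALSE)

trend <- cutoff_trend(panel$tg_hdl, mets, cohort$age_years, cohort$sex,
                      window = 4, min_n = 10)
write.csv(trend, "results/tg_hdl_cutoff_trend.csv", row.names = FALSE)
ok <- !is.na(trend$cutoff)
cat(sprintf("\ncutoff trend: %d/%d grid points defined\n", sum(ok), nrow(trend)))
for (s in c("F", "M")) {
  tr <- trend[trend$sex == s & ok, ]
  if (nrow(tr) >= 2) {
    slope <- coef(lm(cutoff ~ age, tr))[2]
    cat(sprintf("  %s: cutoff %.2f-%.2f over ages %g-%g (slope %+.3f/yr)\n",
                s, min(tr$cutoff), max(tr$cutoff), min(tr$age), max(tr$age),
                slope))
  }
}
# do the sexes need different cutoffs? paired comparison at shared ages
shared <- merge(trend[trend$sex == "F", c("age", "cutoff")],
                trend[trend$sex == "M", c("age", "cutoff")], by = "age")
shared <- shared[stats::complete.cases(shared), ]
if (nrow(shared) >= 2) {
  rs <- rank_sum_test(shared$cutoff.x, shared$cutoff.y)
  cat(sprintf("female vs male cutoffs at shared ages: rank-sum p = %.3f\n", rs$p))
}
cat("wrote results/tg_hdl_correlations.csv and tg_hdl_cutoff_trend.csv\n")

pdf("results/cutoff_trend.pdf", width = 6, height = 4.5)
plot(range(trend$age), range(trend$cutoff, na.rm = TRUE), type = "n",
     xlab = "Age (years)", ylab = "TG/HDL-C Youden cutoff",
     main = "Age/sex-specific screening cutoff")
for (s in c("F", "M")) {
  tr <- trend[trend$sex == s, ]
  lines(tr$age, tr$cutoff, col = ifelse(s == "F", "firebrick", "steelblue"),
        lwd = 2, type = "b", pch = 16)
}
legend("topright", c("F", "M"), col = c("firebrick", "steelblue"),
       lwd = 2, bty = "n")
invisible(dev.off())
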