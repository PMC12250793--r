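#!/usr/bin/env Rscript
# Step 2 — index panel and descriptive screens.
# Computes the twelve indices plus HOMA-IR, screens every continuous
# variable for box-plot outliers (reported, never removed) and for
# normality, and tabulates medians by sex.
suppressPackageStartupMessages(library(pedmets))

if (!file.exists("results/cohort.csv"))
  stop("run analysis/01_simulate_cohort.R first")
cohort <- read_cohort("results/cohort.csv")
ref <- read_reference_tables("results/reference_tables.csv")

panel <- compute_indices(cohort, ref)
write.csv(panel, "results/indices.csv", row.names = FALSE)

cont <- c("weight_kg", "height_cm", "waist_cm", "glucose_mgdl",
          "insulin_uUml", "tc_mgdl", "hdl_mgdl", "tg_mgdl",
          "sbp_mmhg", "dbp_mmhg")
screen <- do.call(rbind, lapply(cont, function(v) {
  ks <- ks_normality(cohort[[v]])
  data.frame(variable = v, n_outliers = sum(tukey_outliers(cohort[[v]])),
             ks_D = round(ks$D, 4), ks_p = signif(ks$p, 3),
             normal_at_05 = ks$p >= 0.05)
}))
write.csv(screen, "results/variable_screen.csv", row.names = FALSE)
cat("variables with box-plot outliers:",
    sum(screen$n_outliers > 0), "of", nrow(screen), "\n")
cat("variables rejecting normality (Lilliefors p < 0.05):",
    sum(!screen$normal_at_05), "of", nrow(screen),
    "-> medians + rank tests downstream\n")

med <- aggregate(panel[, -1], list(sex = cohort$sex),
                 function(x) round(median(x, na.rm = TRUE), 2))
write.csv(med, "results/index_medians_by_sex.csv", row.names = FALSE)
print(med)
cat("wrote results/indices.csv, variable_screen.csv, index_medians_by_sex.csv\n")
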