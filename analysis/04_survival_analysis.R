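#!/usr/bin/env Rscript
# Survival analysis: maximally selected cutpoints for each immune
# feature, univariate DFS stratification with O/E hazard ratios,
# three-grade comparison, and the combined grade x T_RM strata. Runs the
# orchestrated pipeline so all reports land under results/pipeline/.

suppressPackageStartupMessages(library(tlsmaturity))

cohort <- read_cohort("results/cohort")
cfg <- pipeline_config(perm_B = 200L, seed = 20L)
bundle <- run_pipeline(cohort, cfg, out_dir = "results/pipeline")

uni <- bundle$survival_report$univariate
show <- uni[uni$feature %in% c("n_tls", "tls_density", "inside_CD3_TRM",
                               "inside_CD4_TRM", "inside_CD8_TRM",
                               "avg_CD3_TRM"), ]
cat("Univariate DFS stratification (high = feature >= cutoff):\n")
for (i in seq_len(nrow(show))) {
  cat(sprintf(
    "  %-15s cutoff %.3g  median high/low %.1f/%.1f  HR %.2f (%.2f, %.2f)  p=%.3g\n",
    show$feature[i], show$cutoff[i], show$median_high[i],
    show$median_low[i], show$hazard_ratio[i], show$hr_lower[i],
    show$hr_upper[i], show$p_value[i]))
}

cat("\nDFS by maturity grade:\n")
print(bundle$survival_report$grade$strata)
print(bundle$survival_report$grade$pairwise[
  c("stratum_a", "stratum_b", "chi_square", "p_value", "hazard_ratio")])

cat("\nCombined grade x CD3_TRM strata (medians):\n")
combo <- bundle$survival_report$combined_grade_trm$CD3_TRM
print(combo$strata)
cat("\nFull reports in results/pipeline/\n")
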