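#!/usr/bin/env Rscript
# Compartment quantification and group comparisons: per-patient subset
# percentages inside vs outside TLSs (paired Wilcoxon), subset
# proportions across grades (Kruskal-Wallis), and grade x covariate
# contingency tables with chi-square / Fisher dispatch.

suppressPackageStartupMessages(library(tlsmaturity))

cohort <- read_cohort("results/cohort")
summary_tab <- build_patient_summary(cohort)
write.csv(summary_tab, "results/patient_summary.csv", row.names = FALSE)

cat("Paired inside-vs-outside comparison (T_RM subsets):\n")
for (s in c("CD3_TRM", "CD4_TRM", "CD8_TRM")) {
  w <- wilcoxon_signed_rank(summary_tab[[paste0("inside_", s)]],
                            summary_tab[[paste0("outside_", s)]])
  cat(sprintf("  %-8s inside %.2f%%  outside %.2f%%  W=%g  p=%.2g\n", s,
              mean(summary_tab[[paste0("inside_", s)]]),
              mean(summary_tab[[paste0("outside_", s)]]),
              w$statistic, w$p_value))
}

cat("\nKruskal-Wallis of inside-TLS proportions across grades:\n")
for (s in c("B_cell", "CD3_TRM", "CD4_TRM", "CD8_TRM")) {
  kw <- kruskal_wallis(split(summary_tab[[paste0("inside_", s)]],
                             summary_tab$grade))
  cat(sprintf("  %-8s H=%.2f  p=%.3g\n", s, kw$statistic, kw$p_value))
}

cat("\nGrade x covariate association tests:\n")
for (cv in c("sex", "tnm_stage", "egfr", "smoking")) {
  tab <- table(summary_tab[[cv]], summary_tab$grade)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  res <- association_test(tab)
  cat(sprintf("  %-14s %s p=%.3f\n", cv, res$test, res$p_value))
}
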