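# tlsmaturity

Quantitative analysis of **tertiary lymphoid structure (TLS) maturity**
and **tissue-resident memory T cells (T_RM)** from cell-level multiplex
immunofluorescence data, for researchers studying the tumor immune
microenvironment and its relation to patient outcome.

The input is the standard product of a multiplex-IF imaging pipeline:
one row per segmented nucleated cell with binary positivity calls for
CD3, CD4, CD20, CD21, CD103 and Bcl-6, assigned to a region (a TLS or a
field outside the TLSs). From that, the package computes:

1. **Immune-subset phenotyping** by combinatorial gating — CD4 T
   (CD3⁺CD4⁺), CD8 T (CD3⁺CD4⁻), B (CD20⁺), FDC (CD21⁺), CD3/CD4/CD8
   T_RM (CD103⁺ variants), GC-B (CD20⁺Bcl-6⁺).
2. **TLS maturity staging**, GC-first: SFL-TLS if a germinal-center
   reaction is present (≥ *gc_min* CD20⁺Bcl-6⁺ cells), else PFL-TLS if
   an FDC network is present (≥ *fdc_min* CD21⁺ cells), else E-TLS.
3. **Patient maturity grade**: grade 1 = only E-TLS; grade 2 = ≥ 1
   PFL-TLS, no SFL-TLS; grade 3 = ≥ 1 SFL-TLS; plus TLS count and
   density (TLS/mm²).
4. **Compartment quantification**: each subset as a percentage of
   nucleated cells per region, averaged per patient over inside-TLS
   regions, outside fields, and all fields pooled.
5. **Survival statistics from first principles**: Kaplan–Meier curves
   (median = smallest t with S(t) ≤ 0.5), the k-group log-rank test
   with the O/E hazard ratio HR = (O₁/E₁)/(O₂/E₂) and CI
   exp(log HR ± 1.96·√(1/E₁+1/E₂)), maximally selected rank-statistic
   cutpoints (argmax of |U|/√V over admissible splits, permutation
   p-value), and stratified grade × T_RM analyses.
6. **Exact nonparametric group statistics**: Wilcoxon signed-rank
   (exact under midrank ties via the shift algorithm), Kruskal–Wallis,
   Pearson χ², Fisher's exact test for 2×c tables, with the
   expected-count < 5 dispatch rule.
7. A **seeded synthetic-cohort generator** with planted maturity mixes,
   T_RM enrichment and hazards, so the entire chain is testable by
   ground-truth recovery.

## Worked example

The `analysis/` scripts run the whole workflow on the default synthetic
cohort (49 patients, grade mix ~6/26/17, ~16 TLSs per section):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_classify_and_grade.R
Rscript analysis/03_compartment_stats.R
Rscript analysis/04_survival_analysis.R
```

The staging/grading step prints, for seed 20:

```
TLS maturity distribution:
  E_TLS PFL_TLS SFL_TLS
    546     267      40
Patient grade distribution:
 1  2  3
 9 28 12
grade recovery vs simulated truth: 100%
```

i.e. every simulated TLS maturity and patient grade is recovered
exactly from the generated cells. The compartment step recovers the
planted ×3 inside-TLS T_RM enrichment:

```
  CD3_TRM  inside 3.96%  outside 0.80%  W=0  p=1.1e-09
```

(paired Wilcoxon across the 49 patients), and the survival step
recovers the planted protective hazards — higher grade and higher
inside-TLS T_RM both associate with longer disease-free survival:

```
  inside_CD3_TRM  cutoff 2.7  median high/low NA/11.3  HR 0.29 (0.12, 0.65)
  grade1 vs grade3: chi2 = 14.7, p = 1.3e-04, HR = 7.9
```

(`NA` = median not reached; the HR orients the first-named stratum
against the second). `results/pipeline/` then contains the full
machine-readable reports (`survival_report.json`,
`group_stats_report.json`, per-region proportions, patient summaries
and rendered tables).

For programmatic use, the same chain is four calls:

```r
library(tlsmaturity)
cohort <- simulate_cohort(sim_config(seed = 20))     # or read_cohort(dir)
summary <- build_patient_summary(cohort)
cp <- max_selected_cutpoint(summary$inside_CD3_TRM,
                            summary$dfs_months, summary$event)
logrank_test(summary$dfs_months, summary$event,
             dichotomize(summary$inside_CD3_TRM, cp$cutoff))
```

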