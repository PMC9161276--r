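---
title: "Methods: TLS maturity grading and T_RM survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TLS maturity grading and T_RM survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

Tertiary lymphoid structures (TLS) are ectopic lymphoid aggregates that
form in chronically inflamed tissue, including tumors. Their degree of
organisation — from a loose lymphocytic aggregate to a follicle with a
CD21^+^ follicular dendritic cell (FDC) network and finally a germinal
center (GC) reaction — is prognostically informative, as is the density
of tissue-resident memory T cells (T_RM, marked by the integrin
CD103). This package implements the complete quantitative chain for
studying both from cell-level multiplex immunofluorescence (mIF) data:
each input row is one segmented, DAPI^+^ nucleated cell with binary
positivity calls for CD3, CD4, CD20, CD21, CD103 and Bcl-6 and a region
assignment (a manually delineated TLS, or a field sampled outside the
TLSs).

Upstream steps — staining, spectral unmixing, segmentation, thresholding
and TLS delineation — are the imaging platform's job and are out of
scope; the package consumes the resulting cell table.

## Marker gating

Subsets are gated combinatorially on the six binary calls:

| subset     | gate                  |
|------------|-----------------------|
| CD4 T      | CD3^+^CD4^+^          |
| CD8 T      | CD3^+^CD4^−^          |
| B cell     | CD20^+^               |
| FDC        | CD21^+^               |
| CD3 T_RM   | CD3^+^CD103^+^        |
| CD4 T_RM   | CD3^+^CD4^+^CD103^+^  |
| CD8 T_RM   | CD3^+^CD4^−^CD103^+^  |
| GC B       | CD20^+^Bcl-6^+^       |

The panel carries no CD8 antibody, so CD8 T cells are operationally
CD4-negative T cells; labels are deliberately non-exclusive (every CD8
T_RM is also a CD8 T cell and a CD3 T_RM), and the test suite asserts
these nesting inequalities on every generated region.

A genuinely open gating question is whether the CD4 subsets should
require CD3 co-positivity: the printed gate is bare "CD4^+^CD103^+^",
but without CD3 the gate would also capture CD4^+^ myeloid cells. We
default to requiring CD3 (the biologically intended population) and
expose `require_cd3_for_cd4 = FALSE` plus a user-editable rules file for
the literal reading.

## TLS maturity and patient grade

Each TLS is staged from two counts with **GC-first precedence**:

* **SFL-TLS** (secondary follicle-like) if ≥ `gc_min` CD20^+^Bcl-6^+^
  cells — a GC reaction is present;
* else **PFL-TLS** (primary follicle-like) if ≥ `fdc_min` CD21^+^ cells;
* else **E-TLS** (early).

`fdc_min = gc_min = 1` by default: the published staging is defined by
presence/absence of CD21 expression and of a GC reaction, with no count
threshold; both knobs exist so sensitivity to stray positives can be
probed. The GC-first precedence resolves the corner case of a GC
reaction without detected FDCs; the stage-score table that accompanies
the published grading marks all three TLS types present in grade-3
patients, but the prose rule ("at least one SFL-TLS") does not require
PFL co-occurrence, so the prose rule is what we implement and the table
is read as describing the typical cohort.

The patient grade is the maximum maturity present: grade 1 — only
E-TLS; grade 2 — at least one PFL-TLS and no SFL-TLS; grade 3 — at
least one SFL-TLS. Patients with zero TLSs are rejected with an error
rather than assigned a grade-0 category, mirroring the cohort inclusion
criterion (TLS-positive tissue only). TLS burden is summarised as a
count and as a density (TLS per mm² of tumor).

## Compartment quantification

A region's subset proportion is `100 · count / total nucleated cells`.
Patient-level aggregates treat **fields as the unit**: the inside-TLS
value is the unweighted mean over the patient's TLS regions, the
outside value the mean over outside fields, and the section "average"
pools all regions with equal weight. Whether the original "average"
pooled fields or averaged the two compartment means is ambiguous; the
pooled reading is primary and `average_mode = "mean_of_means"` computes
the alternative. A cell-count-weighted mean would down-weight small
TLSs and is deliberately not the default. Empty compartments yield
missing values, excluded downstream — never imputed zeros.

## Survival machinery

All survival statistics are computed from counting-process first
principles; no proportional-hazards regression is fitted anywhere.

* **Kaplan–Meier**: product-limit over distinct event times, deaths
  before censorings at ties; the median is the smallest event time with
  S(t) ≤ 0.5 and is reported as not reached (NA) when the curve never
  crosses 0.5 — never extrapolated.
* **Log-rank** (k ≥ 2 groups): the quadratic form in O − E with the
  hypergeometric covariance, χ² on k − 1 df; for two groups this equals
  U²/V exactly, which a test asserts.
* **Hazard ratio**: the observed-over-expected convention
  HR = (O₁/E₁)/(O₂/E₂), with 95% CI exp(log HR ± 1.96·√(1/E₁ + 1/E₂)).
  This is the HR the log-rank machinery itself provides; it is known to
  attenuate slightly toward the null for strong effects, which the
  coverage simulation in the test suite quantifies under the default
  censoring (≈95% CI coverage at a planted HR of 0.25, n = 400).
* **Maximally selected cutpoint**: candidate cutoffs are the observed
  feature values whose "high = value ≥ cutoff" split leaves at least
  `minprop · n` patients on both sides (`minprop = 0.1`, the
  conventional minimum group fraction); the selected cutoff maximises
  the standardized log-rank statistic |U|/√V, ties broken toward the
  smallest cutoff. The selection-adjusted p-value is obtained by
  permuting the pairing between feature and outcome (seeded, B
  configurable, default 1000) rather than by the improved-Bonferroni
  approximation: exact by simulation, no distributional approximation,
  at the price of runtime. `B = 0` skips it where only the cutoff is
  needed.

## Group statistics

The paired inside/outside comparison uses the Wilcoxon signed-rank test
with Wilcoxon's original zero-handling (zero differences dropped, the
convention of the mainstream software this field uses) and midranks for
ties. For n ≤ 25 the p-value is exact via the shift algorithm over the
doubled-rank generating function — midrank ties included, a case where
standard exact routines fall back to approximations — and for larger n
a tie-corrected normal approximation with continuity correction is
used. Kruskal–Wallis (tie-corrected) compares proportions across
grades. Contingency analyses dispatch deterministically: Fisher's exact
test (two-sided by probability ordering, margins fixed) whenever any
expected count is below 5, else Pearson's χ² without continuity
correction; expected counts are returned so the dispatch is auditable.
No multiple-testing correction is applied anywhere by default, matching
the unadjusted reporting convention of the source analyses; a Holm
adjustment can be applied by the user downstream.

## The synthetic cohort generator

No raw per-cell or per-patient data are deposited for the motivating
study, so the generator is a first-class module: it emulates the
*structure* of such a cohort with known ground truth, making every
downstream stage testable by recovery. Defaults encode the study-scale
conditions: 49 patients with grade mix 6/26/17; 8–25 TLSs and 3–5
outside fields per section (about 850 TLSs and 190 outside fields per
cohort, matching the reported aggregate magnitudes of ~800 TLSs and
~150 fields; the true per-patient distributions are unpublished, so
these ranges claim only the right order of magnitude); 300–800
nucleated cells per field; T_RM subsets enriched ×3 inside TLSs and
×2.5 further in SFL-TLSs; exponential DFS times with baseline hazard
0.12/month (grade-1 median ≈ 5.8 months) and planted log-hazard ratios
log(0.418), log(0.226) and log(0.433) for grade 2, grade 3 and
T_RM-high — the published univariate effect sizes.

Design choices worth recording:

* **Binary marker calls** are generated directly (the analysis
  quantifies positivity, not intensity); an optional lognormal intensity
  mode with a fixed threshold of 1.0 exists for exercising readers, off
  by default.
* **No spatial coordinates**: regions were manually delineated in the
  source workflow, so region membership is assigned directly; geometry
  would add nothing testable.
* Cells are drawn per-region from a **categorical distribution over
  marker-combination archetypes** (CD4 T, CD8 T, B, GC-B, FDC, CD4 T_RM,
  CD8 T_RM, unlabelled); impossible combinations have probability 0 by
  construction. If configured frequencies sum past 1 they are clipped
  proportionally with a logged message.
* **Maturity determines the staging markers**: E-TLS regions have FDC
  and GC-B frequency 0, PFL-TLS have GC-B frequency 0, and PFL/SFL
  regions are guaranteed at least one FDC (SFL: also one GC-B) cell by
  converting an unlabelled cell if the draw produced none. This floor
  makes maturity classification recover the simulated truth exactly at
  the default presence thresholds, which is the property the test suite
  asserts for every seed.
* **Censoring** is independent: with probability `censor_rate` a
  uniform censoring time on [0, max_followup], otherwise administrative
  censoring at max_followup — the simplest mechanism satisfying the
  non-informative censoring assumed by KM/log-rank.
* **One substream per patient**, split in documented order (grade →
  TLS maturities → area → regions → cells → covariates → survival), so
  extending the cohort never changes earlier patients.

What the generator does *not* emulate: spatial point patterns,
correlated clinical covariates, between-section staining batch effects,
intensity-threshold miscalibration, or segmentation errors. Passing
recovery tests therefore demonstrate the correctness of the analysis
chain, not the robustness of the upstream imaging pipeline.

## Validation suite: problem sizes

The test suite checks calibration and recovery at sizes chosen to give
tight binomial bounds while keeping a laptop-scale run: log-rank type-I
error over 2000 null simulations at n = 50/arm (rejection at α = 0.05
must land in [0.04, 0.06]); cutpoint recovery of a planted
40th-percentile threshold (HR 0.3, n = 200) within ±5 percentile points
in ≥ 90% of 200 replicates plus argmax equality with exhaustive search
at n = 15; O/E HR CI coverage of a planted grade-3 HR of 0.25 on
400-patient cohorts within 3 binomial SDs of 95% over 200 replicates;
and full-chain recovery of the ×3 inside-TLS T_RM enrichment (paired
Wilcoxon rejection in ≥ 90% of 10 default-scale cohorts, inside mean >
outside mean in ≥ 95% of patients). Exact tests are compared against
brute-force enumeration oracles (2ⁿ sign assignments, margin-fixed
table enumeration) at n ≤ 12.

## Known limitations

* The cohort-specific published numbers (median DFS per stratum, the
  printed HRs and cutoffs) are not reproducible without the undeposited
  patient data; the package reproduces the *rules and arithmetic* that
  are printed (grading worked examples, contingency percentages, the
  EGFR Fisher p-value) and validates everything else by simulation.
* The O/E hazard ratio is attenuated for large effects relative to a
  Cox estimate; it is used deliberately for fidelity to the log-rank
  convention.
* Cutpoints are derived on the full analysed set (whether the original
  analysis derived them before or after subgrouping is unstated), and
  dichotomisation at a data-derived cutoff inherits the usual
  overfitting caveats that the permutation p-value only partially
  addresses.
* Some printed confidence intervals in the source tables span 1 while
  the accompanying p-value is < 0.05; they are internally inconsistent
  as printed and are not targets.
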