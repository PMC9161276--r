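# TLS maturity classification, patient grading and TLS burden metrics.

#' Maturity stage labels
#' @return Character vector of the three maturity stages, in increasing
#'   maturity order: early (`E_TLS`), primary follicle-like (`PFL_TLS`),
#'   secondary follicle-like (`SFL_TLS`).
#' @export
maturity_levels <- function() c("E_TLS", "PFL_TLS", "SFL_TLS")

#' Classify the maturity of one TLS
#'
#' A TLS is staged by the presence of a CD21+ follicular dendritic cell
#' (FDC) network and of a germinal-center (GC) reaction (CD20+Bcl-6+
#' cells):
#' * `SFL_TLS` (secondary follicle-like) if the GC-B count is at least
#'   `gc_min`;
#' * else `PFL_TLS` (primary follicle-like) if the FDC count is at least
#'   `fdc_min`;
#' * else `E_TLS` (early): dense lymphocytic aggregate with neither.
#'
#' The GC test takes precedence, so a structure with a GC reaction is
#' secondary follicle-like whether or not FDCs were detected. The default
#' thresholds of one positive cell encode presence/absence staging; raise
#' them to probe sensitivity to stray positives.
#'
#' @param counts Result of [count_subsets()] for a TLS region, or a named
#'   numeric vector containing `FDC` and `GC_B` counts.
#' @param fdc_min,gc_min Minimum positive-cell counts (>= 1) for calling
#'   the FDC network / GC reaction present.
#' @param region_id Optional region identifier carried into the result.
#' @param region_type Region class; must be `"tls"` (outside fields are
#'   not staged).
#' @return List with `region_id`, `maturity`, `n_fdc`, `n_gcb`.
#' @export
classify_tls_maturity <- function(counts, fdc_min = 1L, gc_min = 1L,
                                  region_id = NA_character_,
                                  region_type = "tls") {
  if (!identical(region_type, "tls")) {
    stop("maturity classification applies to TLS regions only; got ",
         "region_type='", region_type, "'")
  }
  if (fdc_min < 1 || gc_min < 1) {
    stop("fdc_min and gc_min must be >= 1")
  }
  cc <- if (is.list(counts) && !is.null(counts$counts)) counts$counts else counts
  if (!all(c("FDC", "GC_B") %in% names(cc))) {
    stop("counts must contain 'FDC' and 'GC_B' entries")
  }
  n_fdc <- as.integer(cc[["FDC"]])
  n_gcb <- as.integer(cc[["GC_B"]])
  maturity <- if (n_gcb >= gc_min) {
    "SFL_TLS"
  } else if (n_fdc >= fdc_min) {
    "PFL_TLS"
  } else {
    "E_TLS"
  }
  list(region_id = region_id, maturity = maturity,
       n_fdc = n_fdc, n_gcb = n_gcb)
}

#' Patient maturity grade from the TLS maturity list
#'
#' Patients are graded by the most mature TLS present anywhere in their
#' tumor tissue:
#' * grade 3 — at least one secondary follicle-like TLS;
#' * grade 2 — at least one primary follicle-like TLS, no SFL-TLS;
#' * grade 1 — early TLS only.
#'
#' The grade depends only on the set of maturities, not their order or
#' multiplicity. The cohort inclusion criterion restricts analysis to
#' TLS-positive tissue, so an empty maturity list is an error rather than
#' a grade-0 category.
#'
#' @param maturities Character vector of maturity labels (see
#'   [maturity_levels()]) for all TLSs of one patient.
#' @return Integer grade, 1, 2 or 3.
#' @examples
#' grade_patient(c("E_TLS", "E_TLS"))              # 1
#' grade_patient(c("E_TLS", "PFL_TLS", "PFL_TLS")) # 2
#' grade_patient(c("E_TLS", "PFL_TLS", "SFL_TLS")) # 3
#' @export
grade_patient <- function(maturities) {
  if (length(maturities) == 0) {
    stop("patient has no TLS; outside study inclusion criteria")
  }
  bad <- setdiff(maturities, maturity_levels())
  if (length(bad) > 0) {
    stop("unknown maturity label(s): ", paste(unique(bad), collapse = ", "))
  }
  if (any(maturities == "SFL_TLS")) return(3L)
  if (any(maturities == "PFL_TLS")) return(2L)
  1L
}

#' TLS density per square millimetre of tumor
#'
#' @param n_tls Number of TLSs in the section (>= 0).
#' @param tumor_area_mm2 Tumor area of the section in mm^2 (> 0).
#' @return TLS count per mm^2.
#' @export
tls_density <- function(n_tls, tumor_area_mm2) {
  if (any(tumor_area_mm2 <= 0)) {
    stop("tumor_area_mm2 must be positive")
  }
  if (any(n_tls < 0)) stop("n_tls must be non-negative")
  n_tls / tumor_area_mm2
}

#' Classify every TLS of a cohort
#'
#' Applies the gating rules and [classify_tls_maturity()] to every TLS
#' region of a cohort cell table.
#'
#' @param cells,regions Cohort tables (see [read_cohort()] schemas).
#' @param rules Gating rules.
#' @param fdc_min,gc_min Staging thresholds.
#' @return Data.frame: `region_id`, `maturity`, `n_fdc`, `n_gcb`, one row
#'   per TLS region, in `regions` order.
#' @export
classify_cohort_tls <- function(cells, regions,
                                rules = default_phenotype_rules(),
                                fdc_min = 1L, gc_min = 1L) {
  tls_ids <- regions$region_id[regions$region_type == "tls"]
  mem <- subset_membership(cells, rules)
  fdc <- rowsum(as.numeric(mem[, "FDC"]), group = cells$region_id)
  gcb <- rowsum(as.numeric(mem[, "GC_B"]), group = cells$region_id)
  lookup <- function(tab, id) {
    if (id %in% rownames(tab)) unname(tab[id, 1]) else 0
  }
  out <- data.frame(
    region_id = tls_ids,
    maturity = NA_character_,
    n_fdc = NA_integer_,
    n_gcb = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(tls_ids)) {
    cl <- classify_tls_maturity(
      c(FDC = lookup(fdc, tls_ids[i]), GC_B = lookup(gcb, tls_ids[i])),
      fdc_min = fdc_min, gc_min = gc_min, region_id = tls_ids[i]
    )
    out$maturity[i] <- cl$maturity
    out$n_fdc[i] <- cl$n_fdc
    out$n_gcb[i] <- cl$n_gcb
  }
  out
}

#' Grade every patient of a cohort
#'
#' Combines per-TLS maturity calls into patient grades and TLS burden
#' metrics (TLS count and density).
#'
#' @param classification Output of [classify_cohort_tls()].
#' @param regions,sections Cohort tables.
#' @return Data.frame: `patient_id`, `grade`, `n_tls`, `tls_density`.
#' @export
grade_cohort <- function(classification, regions, sections) {
  tls_regions <- regions[regions$region_type == "tls", , drop = FALSE]
  merged <- merge(classification, tls_regions[c("region_id", "patient_id")],
                  by = "region_id")
  patients <- sort(unique(tls_regions$patient_id))
  area <- tapply(sections$tumor_area_mm2, sections$patient_id, sum)
  out <- data.frame(
    patient_id = patients,
    grade = NA_integer_,
    n_tls = NA_integer_,
    tls_density = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(patients)) {
    mats <- merged$maturity[merged$patient_id == patients[i]]
    out$grade[i] <- grade_patient(mats)
    out$n_tls[i] <- length(mats)
    out$tls_density[i] <- tls_density(length(mats), area[[patients[i]]])
  }
  out
}
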