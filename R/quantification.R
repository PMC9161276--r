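# Subset proportions per region and per-patient compartment aggregates.

#' Proportion of a subset among nucleated cells
#'
#' @param counts Named numeric vector of subset counts (or the list
#'   returned by [count_subsets()]).
#' @param total Total nucleated-cell count of the region (>= 1).
#' @param subset Subset name; if `NULL`, proportions for all subsets are
#'   returned.
#' @return Percentage(s) in \[0, 100\]: `100 * count / total`.
#' @export
region_proportion <- function(counts, total = NULL, subset = NULL) {
  if (is.list(counts) && !is.null(counts$counts)) {
    total <- counts$total
    counts <- counts$counts
  }
  if (is.null(total) || total < 1) {
    stop("proportion undefined: region has no nucleated cells (total < 1)")
  }
  if (!is.null(subset)) counts <- counts[subset]
  100 * counts / total
}

#' Region-level proportion table for a cohort
#'
#' Computes, for every region, the percentage of nucleated cells carrying
#' each subset label. Regions with zero cells are excluded with a warning
#' (their proportion is undefined).
#'
#' @param cells,regions Cohort tables.
#' @param rules Gating rules.
#' @return Long data.frame: `region_id`, `subset`, `proportion`, plus the
#'   region's `total` nucleated count.
#' @export
region_proportions <- function(cells, regions,
                               rules = default_phenotype_rules()) {
  mem <- subset_membership(cells, rules)
  counts <- rowsum(mem + 0, group = cells$region_id)
  totals <- as.vector(table(cells$region_id)[rownames(counts)])
  empty <- setdiff(regions$region_id, rownames(counts))
  if (length(empty) > 0) {
    warning("excluding ", length(empty),
            " region(s) with zero cells (proportion undefined): ",
            paste(utils::head(empty, 5), collapse = ", "))
  }
  prop <- 100 * counts / totals
  out <- data.frame(
    region_id = rep(rownames(counts), times = ncol(counts)),
    subset = rep(colnames(counts), each = nrow(counts)),
    proportion = as.vector(prop),
    total = rep(totals, times = ncol(counts)),
    stringsAsFactors = FALSE
  )
  out[order(out$region_id, out$subset), , drop = FALSE]
}

#' Mean subset proportion over the regions of one compartment
#'
#' Fields (regions) are the unit of aggregation: the patient-level value
#' is the unweighted arithmetic mean of region percentages, matching
#' quantification by "average proportion over fields". `"all"` pools TLS
#' and outside fields with equal region weight.
#'
#' @param proportions Numeric vector of region percentages belonging to
#'   the requested compartment.
#' @param compartment One of `"inside"`, `"outside"`, `"all"` (used only
#'   for the message on empty input).
#' @return Mean percentage, or `NA` (with a message) when the compartment
#'   has no regions — never an imputed zero.
#' @export
patient_compartment_mean <- function(proportions,
                                     compartment = c("inside", "outside",
                                                     "all")) {
  compartment <- match.arg(compartment)
  proportions <- proportions[!is.na(proportions)]
  if (length(proportions) == 0) {
    message("compartment '", compartment,
            "' has no regions; returning NA (not zero)")
    return(NA_real_)
  }
  mean(proportions)
}

#' Patient-level summary table
#'
#' One row per patient: maturity grade, TLS count and density, and for
#' every subset the three compartment aggregates
#' * `inside_<subset>` — mean percentage over the patient's TLS regions,
#' * `outside_<subset>` — mean over the outside-TLS fields,
#' * `avg_<subset>` — the section average over all fields pooled with
#'   equal region weight (TLS and outside together); with
#'   `average_mode = "mean_of_means"` the mean of the two compartment
#'   means is used instead.
#'
#' Clinical covariates are joined by `patient_id`. A patient present in
#' the cell table but absent from the clinical table is a referential
#' integrity error.
#'
#' @param cohort List with `cells`, `regions`, `sections`, `clinical`
#'   tables (as returned by [read_cohort()] or [simulate_cohort()]).
#' @param rules Gating rules.
#' @param fdc_min,gc_min Maturity staging thresholds.
#' @param average_mode `"pooled"` (default) or `"mean_of_means"`.
#' @return Data.frame, one row per patient, ordered by `patient_id`.
#' @export
build_patient_summary <- function(cohort, rules = default_phenotype_rules(),
                                  fdc_min = 1L, gc_min = 1L,
                                  average_mode = c("pooled",
                                                   "mean_of_means")) {
  average_mode <- match.arg(average_mode)
  cells <- cohort$cells
  regions <- cohort$regions
  missing_pat <- setdiff(unique(cells$patient_id),
                         cohort$clinical$patient_id)
  if (length(missing_pat) > 0) {
    stop("referential integrity: patient(s) present in cells but absent ",
         "from clinical table: ", paste(missing_pat, collapse = ", "))
  }
  props <- region_proportions(cells, regions, rules)
  props <- merge(props, regions[c("region_id", "patient_id", "region_type")],
                 by = "region_id")
  classification <- classify_cohort_tls(cells, regions, rules,
                                        fdc_min = fdc_min, gc_min = gc_min)
  grades <- grade_cohort(classification, regions, cohort$sections)

  patients <- sort(unique(regions$patient_id))
  subsets <- rules$subset
  out <- grades[match(patients, grades$patient_id), , drop = FALSE]
  out$patient_id <- patients
  rownames(out) <- NULL
  for (s in subsets) {
    ps <- props[props$subset == s, , drop = FALSE]
    inside <- outside <- avg <- rep(NA_real_, length(patients))
    for (i in seq_along(patients)) {
      pp <- ps[ps$patient_id == patients[i], , drop = FALSE]
      pin <- pp$proportion[pp$region_type == "tls"]
      pout <- pp$proportion[pp$region_type == "outside"]
      inside[i] <- if (length(pin)) mean(pin) else NA_real_
      outside[i] <- if (length(pout)) mean(pout) else NA_real_
      avg[i] <- if (average_mode == "pooled") {
        if (nrow(pp)) mean(pp$proportion) else NA_real_
      } else {
        mean(c(inside[i], outside[i]), na.rm = TRUE)
      }
    }
    out[[paste0("inside_", s)]] <- inside
    out[[paste0("outside_", s)]] <- outside
    out[[paste0("avg_", s)]] <- avg
  }
  merge(out, cohort$clinical, by = "patient_id", sort = TRUE)
}
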