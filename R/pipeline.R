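# End-to-end orchestration: validated I/O, configuration, the full
# phenotype -> classify -> grade -> quantify -> cutpoint -> survival /
# group-statistics chain, and human-readable table rendering.

cohort_schemas <- function() {
  list(
    cells = c("patient_id", "section_id", "region_id", "cell_id",
              marker_panel()),
    regions = c("patient_id", "section_id", "region_id", "region_type"),
    sections = c("patient_id", "section_id", "tumor_area_mm2"),
    clinical = c("patient_id", "dfs_months", "event")
  )
}

#' Read and validate a cohort from CSV files
#'
#' Expects `cells.csv`, `regions.csv`, `sections.csv`, `clinical.csv`
#' in `dir` (UTF-8, comma-separated, header row). Validation covers
#' column schemas, 0/1 marker calls (errors name the offending cell),
#' region types, non-negative survival times, 0/1 event indicators, and
#' referential integrity cells -> regions -> sections and
#' cells -> clinical (orphan identifiers are listed).
#'
#' @param dir Directory containing the four CSVs.
#' @return List of class `tls_cohort` with the four validated tables; the
#'   `validation` attribute records warnings for flagged (non-fatal)
#'   findings.
#' @export
read_cohort <- function(dir) {
  schemas <- cohort_schemas()
  paths <- file.path(dir, paste0(names(schemas), ".csv"))
  names(paths) <- names(schemas)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  tabs <- lapply(paths, utils::read.csv, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  warnings <- character(0)
  for (nm in names(schemas)) {
    lack <- setdiff(schemas[[nm]], names(tabs[[nm]]))
    if (length(lack) > 0) {
      stop(nm, ".csv lacks required column(s): ",
           paste(lack, collapse = ", "))
    }
  }
  check_marker_matrix(tabs$cells)   # errors name cell_id and marker
  bad_type <- setdiff(unique(tabs$regions$region_type),
                      c("tls", "outside"))
  if (length(bad_type) > 0) {
    stop("regions.csv: region_type must be 'tls' or 'outside'; got: ",
         paste(bad_type, collapse = ", "))
  }
  if (nrow(tabs$clinical) > 0) {
    if (any(is.na(tabs$clinical$dfs_months)) ||
        any(tabs$clinical$dfs_months < 0)) {
      stop("clinical.csv: dfs_months must be non-negative")
    }
    if (!all(tabs$clinical$event %in% c(0, 1))) {
      stop("clinical.csv: event must be 0/1")
    }
  }
  orphan_regions <- setdiff(unique(tabs$cells$region_id),
                            tabs$regions$region_id)
  if (length(orphan_regions) > 0) {
    stop("referential integrity: cells reference region_id(s) absent ",
         "from regions.csv: ", paste(orphan_regions, collapse = ", "))
  }
  orphan_sections <- setdiff(unique(tabs$regions$section_id),
                             tabs$sections$section_id)
  if (length(orphan_sections) > 0) {
    stop("referential integrity: regions reference section_id(s) absent ",
         "from sections.csv: ", paste(orphan_sections, collapse = ", "))
  }
  orphan_patients <- setdiff(unique(tabs$cells$patient_id),
                             tabs$clinical$patient_id)
  if (length(orphan_patients) > 0) {
    stop("referential integrity: cells reference patient_id(s) absent ",
         "from clinical.csv: ", paste(orphan_patients, collapse = ", "))
  }
  empty_regions <- setdiff(tabs$regions$region_id,
                           unique(tabs$cells$region_id))
  if (length(empty_regions) > 0) {
    warnings <- c(warnings, paste0(
      length(empty_regions), " region(s) contain no cells: ",
      paste(utils::head(empty_regions, 5), collapse = ", ")
    ))
  }
  out <- structure(tabs, class = "tls_cohort")
  attr(out, "validation") <- warnings
  out
}

#' Pipeline configuration
#'
#' @param fdc_min,gc_min Maturity staging thresholds (positive cells).
#' @param minprop Minimum group fraction for cutpoint candidates.
#' @param perm_B Permutations for cutpoint p-values (0 disables them).
#' @param seed Seed for all stochastic steps (permutation draws).
#' @param average_mode Patient-level section average: `"pooled"` over all
#'   fields (primary) or `"mean_of_means"` of the two compartments.
#' @param rules Gating rules (see [default_phenotype_rules()]).
#' @param subsets_survival Subsets whose compartment aggregates enter the
#'   univariate survival stratification.
#' @param trm_subsets T_RM subsets used for the paired inside/outside
#'   comparison and the combined grade x T_RM strata.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fdc_min = 1L, gc_min = 1L, minprop = 0.1,
                            perm_B = 200L, seed = 1L,
                            average_mode = "pooled",
                            rules = default_phenotype_rules(),
                            subsets_survival = rules$subset,
                            trm_subsets = c("CD3_TRM", "CD4_TRM",
                                            "CD8_TRM")) {
  validate_phenotype_rules(rules)
  structure(list(fdc_min = fdc_min, gc_min = gc_min, minprop = minprop,
                 perm_B = as.integer(perm_B), seed = as.integer(seed),
                 average_mode = average_mode, rules = rules,
                 subsets_survival = subsets_survival,
                 trm_subsets = trm_subsets),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes phenotype -> TLS classification -> patient grading ->
#' compartment quantification -> cutpoint selection -> survival and
#' group statistics, and (optionally) writes every module output plus a
#' run manifest to `out_dir`. Byte-identical outputs for identical
#' cohort, config and seed (the manifest, which carries a timestamp, is
#' the only exception).
#'
#' @param cohort A `tls_cohort` (from [read_cohort()] or
#'   [simulate_cohort()]), or a directory path to read.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; `NULL` for no files.
#' @return List: `classification`, `grades`, `proportions`, `summary`,
#'   `survival_report`, `group_report`, `tables`, `manifest`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  rules <- config$rules
  classification <- run_stage("classify", classify_cohort_tls(
    cohort$cells, cohort$regions, rules,
    fdc_min = config$fdc_min, gc_min = config$gc_min
  ))
  grades <- run_stage("grade", grade_cohort(
    classification, cohort$regions, cohort$sections
  ))
  proportions <- run_stage("quantify", region_proportions(
    cohort$cells, cohort$regions, rules
  ))
  summary_tab <- run_stage("summarize", build_patient_summary(
    cohort, rules, fdc_min = config$fdc_min, gc_min = config$gc_min,
    average_mode = config$average_mode
  ))
  survival_report <- run_stage("survival", survival_analyses(
    summary_tab, config
  ))
  group_report <- run_stage("group_stats", group_analyses(
    summary_tab, config
  ))
  tables <- run_stage("render", render_tables(list(
    summary = summary_tab, survival_report = survival_report,
    group_report = group_report
  )))
  manifest <- list(
    package_version = as.character(utils::packageVersion("tlsmaturity")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = config[c("fdc_min", "gc_min", "minprop", "perm_B",
                      "average_mode")],
    n_patients = nrow(summary_tab),
    n_regions = nrow(cohort$regions),
    n_cells = nrow(cohort$cells),
    warnings = attr(cohort, "validation")
  )
  bundle <- list(classification = classification, grades = grades,
                 proportions = proportions, summary = summary_tab,
                 survival_report = survival_report,
                 group_report = group_report, tables = tables,
                 manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(classification,
                     file.path(out_dir, "tls_classification.csv"),
                     row.names = FALSE)
    utils::write.csv(grades, file.path(out_dir, "patient_grades.csv"),
                     row.names = FALSE)
    utils::write.csv(proportions, file.path(out_dir, "proportions.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tab,
                     file.path(out_dir, "patient_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(survival_report,
                         file.path(out_dir, "survival_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", dataframe = "rows")
    jsonlite::write_json(group_report,
                         file.path(out_dir, "group_stats_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", dataframe = "rows")
    writeLines(tables$text, file.path(out_dir, "tables.txt"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  bundle
}

# Univariate survival stratification of every configured feature
# (TLS burden plus the three compartment aggregates of each subset),
# the three-grade comparison, and the combined grade x T_RM strata.
survival_analyses <- function(summary_tab, config) {
  time <- summary_tab$dfs_months
  event <- summary_tab$event
  features <- c("n_tls", "tls_density",
                as.vector(outer(c("inside_", "outside_", "avg_"),
                                config$subsets_survival, paste0)))
  features <- intersect(features, names(summary_tab))
  rows <- list()
  for (fi in seq_along(features)) {
    f <- features[fi]
    v <- summary_tab[[f]]
    res <- tryCatch({
      cp <- max_selected_cutpoint(v, time, event,
                                  minprop = config$minprop,
                                  B = config$perm_B,
                                  seed = config$seed + fi)
      grp <- dichotomize(v, cp$cutoff)
      keep <- !is.na(grp)
      lr <- logrank_test(time[keep], event[keep], grp[keep])
      km_high <- km_curve(time[keep][grp[keep] == "high"],
                          event[keep][grp[keep] == "high"])
      km_low <- km_curve(time[keep][grp[keep] == "low"],
                         event[keep][grp[keep] == "low"])
      # HR oriented high vs low to match the ">= cutoff vs < cutoff"
      # stratum convention
      hr_hl <- (lr$observed["high"] / lr$expected["high"]) /
        (lr$observed["low"] / lr$expected["low"])
      se_hl <- sqrt(1 / lr$expected["high"] + 1 / lr$expected["low"])
      data.frame(
        feature = f, cutoff = cp$cutoff,
        cutpoint_statistic = cp$statistic,
        cutpoint_p = cp$p_value,
        n_high = sum(grp[keep] == "high"), n_low = sum(grp[keep] == "low"),
        median_high = km_high$median, median_low = km_low$median,
        chi_square = lr$statistic, p_value = lr$p_value,
        hazard_ratio = unname(hr_hl),
        hr_lower = unname(exp(log(hr_hl) - 1.96 * se_hl)),
        hr_upper = unname(exp(log(hr_hl) + 1.96 * se_hl)),
        note = "", stringsAsFactors = FALSE
      )
    }, error = function(e) {
      data.frame(feature = f, cutoff = NA_real_,
                 cutpoint_statistic = NA_real_, cutpoint_p = NA_real_,
                 n_high = NA_integer_, n_low = NA_integer_,
                 median_high = NA_real_, median_low = NA_real_,
                 chi_square = NA_real_, p_value = NA_real_,
                 hazard_ratio = NA_real_, hr_lower = NA_real_,
                 hr_upper = NA_real_, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[fi]] <- res
  }
  univariate <- do.call(rbind, rows)
  rownames(univariate) <- NULL

  grade_strata <- stratified_analysis(
    time, event, paste0("grade", summary_tab$grade)
  )

  combined <- list()
  for (s in intersect(config$trm_subsets, config$subsets_survival)) {
    f <- paste0("inside_", s)
    if (!f %in% names(summary_tab)) next
    combo <- tryCatch({
      cp <- max_selected_cutpoint(summary_tab[[f]], time, event,
                                  minprop = config$minprop, B = 0)
      grp <- dichotomize(summary_tab[[f]], cp$cutoff)
      strata <- ifelse(summary_tab$grade == 3, "grade3", "grade1+2")
      strata <- paste0(strata, "_", as.character(grp))
      res <- stratified_analysis(time, event, strata)
      list(subset = s, cutoff = cp$cutoff, strata = res$strata,
           pairwise = res$pairwise)
    }, error = function(e) list(subset = s, error = conditionMessage(e)))
    combined[[s]] <- combo
  }
  list(univariate = univariate,
       grade = list(strata = grade_strata$strata,
                    pairwise = grade_strata$pairwise),
       combined_grade_trm = combined,
       seed = config$seed, minprop = config$minprop, B = config$perm_B)
}

# Paired inside/outside comparisons, grade-wise Kruskal-Wallis, and the
# grade x covariate / T_RM x covariate contingency analyses.
group_analyses <- function(summary_tab, config) {
  time_covars <- c("sex", "t_stage", "n_stage", "tnm_stage",
                   "micropapillary", "egfr", "smoking")
  covars <- intersect(time_covars, names(summary_tab))

  paired <- list()
  for (s in config$trm_subsets) {
    fi <- paste0("inside_", s); fo <- paste0("outside_", s)
    if (!all(c(fi, fo) %in% names(summary_tab))) next
    ok <- stats::complete.cases(summary_tab[c(fi, fo)])
    res <- tryCatch(
      wilcoxon_signed_rank(summary_tab[[fi]][ok], summary_tab[[fo]][ok]),
      error = function(e) list(statistic = NA_real_, p_value = NA_real_,
                               n_used = NA_integer_,
                               method = conditionMessage(e))
    )
    paired[[s]] <- list(
      subset = s, n_pairs = sum(ok),
      mean_inside = mean(summary_tab[[fi]][ok]),
      mean_outside = mean(summary_tab[[fo]][ok]),
      statistic = res$statistic, p_value = res$p_value,
      method = res$method
    )
  }

  kw <- list()
  for (s in config$subsets_survival) {
    f <- paste0("inside_", s)
    if (!f %in% names(summary_tab)) next
    groups <- split(summary_tab[[f]], summary_tab$grade)
    res <- tryCatch(kruskal_wallis(groups),
                    error = function(e) list(statistic = NA_real_,
                                             p_value = NA_real_))
    kw[[s]] <- list(subset = s, statistic = res$statistic,
                    p_value = res$p_value,
                    group_means = vapply(groups, mean, 0, na.rm = TRUE))
  }

  contingency <- list()
  grade_factor <- factor(summary_tab$grade, levels = 1:3)
  for (cv in covars) {
    tab <- table(summary_tab[[cv]], grade_factor)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    res <- if (nrow(tab) >= 2 && ncol(tab) >= 2) {
      tryCatch(association_test(tab),
               error = function(e) list(test = "none",
                                        p_value = NA_real_,
                                        statistic = NA_real_))
    } else {
      list(test = "none", p_value = NA_real_, statistic = NA_real_)
    }
    counts <- matrix(as.integer(tab), nrow = nrow(tab),
                     dimnames = dimnames(tab))
    contingency[[cv]] <- list(covariate = cv, grouping = "grade",
                              counts = counts, test = res$test,
                              p_value = res$p_value)
  }
  list(paired_inside_outside = paired, kruskal_wallis_by_grade = kw,
       contingency = contingency)
}

fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), "—", formatC(x, digits = digits, format = "fg"))
}

#' Render human-readable summary tables
#'
#' Produces (i) a grade-by-covariate contingency summary with row counts
#' and row percentages rounded to the nearest integer (full precision is
#' retained in the machine-readable outputs) and (ii) the univariate
#' stratification table (feature, cutoff, medians, HR with 95% CI, p).
#' Empty strata render as an em dash, never as zero.
#'
#' @param bundle List with `summary`, `survival_report`, `group_report`
#'   (as produced inside [run_pipeline()]).
#' @return List: `contingency` (data.frame), `univariate` (data.frame),
#'   `text` (character vector, the printable rendering).
#' @export
render_tables <- function(bundle) {
  gr <- bundle$group_report
  cont_rows <- list()
  for (cv in names(gr$contingency)) {
    entry <- gr$contingency[[cv]]
    counts <- entry$counts   # levels x grades
    for (r in seq_len(nrow(counts))) {
      n_row <- sum(counts[r, ])
      pct <- if (n_row > 0) round(100 * counts[r, ] / n_row) else
        rep(NA_real_, ncol(counts))
      cont_rows[[length(cont_rows) + 1L]] <- data.frame(
        covariate = cv, level = rownames(counts)[r], n = n_row,
        cells = paste(sprintf("%d (%s%%)", as.integer(counts[r, ]),
                              ifelse(is.na(pct), "—", pct)),
                      collapse = "\t"),
        test = entry$test,
        p_value = entry$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  contingency <- if (length(cont_rows)) do.call(rbind, cont_rows) else
    data.frame()

  uni <- bundle$survival_report$univariate
  univariate <- data.frame(
    feature = uni$feature,
    stratum = ifelse(is.na(uni$cutoff), "—",
                     sprintf(">=%.4g vs. <%.4g", uni$cutoff, uni$cutoff)),
    median_high = uni$median_high, median_low = uni$median_low,
    hr = uni$hazard_ratio, hr_lower = uni$hr_lower,
    hr_upper = uni$hr_upper, p_value = uni$p_value,
    stringsAsFactors = FALSE
  )
  text <- c(
    "== Grade x covariate contingency (row % in parentheses) ==",
    if (nrow(contingency)) apply(contingency, 1, paste, collapse = "\t"),
    "",
    "== Univariate DFS stratification ==",
    paste("feature", "stratum", "median_high", "median_low",
          "HR (95% CI)", "p", sep = "\t"),
    if (nrow(univariate)) sprintf(
      "%s\t%s\t%s\t%s\t%s (%s, %s)\t%s",
      univariate$feature, univariate$stratum,
      fmt_num(univariate$median_high), fmt_num(univariate$median_low),
      fmt_num(univariate$hr), fmt_num(univariate$hr_lower),
      fmt_num(univariate$hr_upper), fmt_num(univariate$p_value)
    )
  )
  list(contingency = contingency, univariate = univariate, text = text)
}
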