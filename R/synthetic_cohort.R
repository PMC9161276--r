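# Seeded synthetic-cohort generator with known ground truth: cells with
# binary marker calls, TLS / outside-field regions, sections, clinical
# outcomes with planted hazards. Every downstream stage of the workflow
# is testable by recovery against the generated truth.

# Cell archetypes: the marker combinations the generator draws from.
# Impossible combinations (e.g. CD4+CD3- "T cells") get probability 0 by
# construction because they are simply not in this dictionary.
cell_archetypes <- function() {
  rbind(
    other   = c(CD3 = 0, CD4 = 0, CD20 = 0, CD21 = 0, CD103 = 0, BCL6 = 0),
    cd4_t   = c(1, 1, 0, 0, 0, 0),
    cd8_t   = c(1, 0, 0, 0, 0, 0),
    b       = c(0, 0, 1, 0, 0, 0),
    gcb     = c(0, 0, 1, 0, 0, 1),
    fdc     = c(0, 0, 0, 1, 0, 0),
    cd4_trm = c(1, 1, 0, 0, 1, 0),
    cd8_trm = c(1, 0, 0, 0, 1, 0)
  )
}

archetype_names <- function() rownames(cell_archetypes())

#' Simulation configuration for a synthetic cohort
#'
#' Defaults emulate the aggregate structure of a 49-patient stage III
#' lung adenocarcinoma cohort: grade mix 6/26/17, roughly 16 TLSs and 3-5
#' outside fields per section (about 800 TLSs and 150 outside fields in
#' total), several hundred nucleated cells per field, tissue-resident
#' memory (T_RM) subsets enriched about threefold inside TLSs and further
#' enriched in secondary follicle-like TLSs, and exponential
#' disease-free-survival times whose hazard drops for grade-2/grade-3
#' patients and for T_RM-high patients.
#'
#' @param n_patients Number of patients.
#' @param grade_probs Probabilities of true grade 1/2/3 (sums to 1).
#' @param tls_per_patient Integer range `c(min, max)` of TLSs per patient.
#' @param outside_fields_per_patient Integer range of outside fields.
#' @param cells_per_region Integer range of nucleated cells per region.
#' @param maturity_mix_by_grade List of three length-3 probability vectors
#'   (E, PFL, SFL) giving the per-TLS maturity mix for each grade. Grade
#'   consistency is enforced: grade 1 must be all-E, grade 2 needs PFL
#'   probability > 0 and SFL probability 0, grade 3 needs SFL
#'   probability > 0; at simulation time at least one PFL (grade 2) /
#'   SFL (grade 3) is guaranteed per patient.
#' @param subset_base_freqs Named per-cell frequencies of the archetypes
#'   `cd4_t, cd8_t, b, gcb, fdc, cd4_trm, cd8_trm` in outside fields; the
#'   remainder is unlabelled ("other") cells.
#' @param enrichment Named multipliers applied to the base frequencies
#'   inside TLSs.
#' @param maturity_enrichment Named extra multipliers applied inside
#'   secondary follicle-like TLSs (on top of `enrichment`).
#' @param trm_high_prob Probability that a patient belongs to the planted
#'   T_RM-high stratum.
#' @param trm_high_multiplier Extra multiplier on the `cd4_trm`/`cd8_trm`
#'   frequencies inside TLSs for T_RM-high patients.
#' @param tumor_area_mm2 Range of section tumor areas (mm^2).
#' @param survival List: `baseline_hazard` (events/month, grade-1
#'   T_RM-low), `log_hr_grade2`, `log_hr_grade3`, `log_hr_trm_high`,
#'   `censor_rate` in \[0,1\], `max_followup_months` (may be `Inf`).
#' @param intensity_mode If `TRUE`, lognormal marker intensities
#'   consistent with the binary calls (fixed threshold 1.0) are appended
#'   as `<marker>_intensity` columns; off by default because the workflow
#'   quantifies positivity, not intensity.
#' @param seed Integer seed; the generator is deterministic given the
#'   seed, and patients are simulated on derived substreams so adding
#'   patients never changes earlier ones.
#' @return Validated configuration of class `sim_config`.
#' @export
sim_config <- function(n_patients = 49L,
                       grade_probs = c(6, 26, 17) / 49,
                       tls_per_patient = c(8L, 25L),
                       outside_fields_per_patient = c(3L, 5L),
                       cells_per_region = c(300L, 800L),
                       maturity_mix_by_grade = list(
                         c(E = 1, PFL = 0, SFL = 0),
                         c(E = 0.6, PFL = 0.4, SFL = 0),
                         c(E = 0.45, PFL = 0.35, SFL = 0.2)
                       ),
                       subset_base_freqs = c(
                         cd4_t = 0.035, cd8_t = 0.045, b = 0.10,
                         gcb = 0.0006, fdc = 0.002,
                         cd4_trm = 0.0026, cd8_trm = 0.0055
                       ),
                       enrichment = c(
                         cd4_t = 4, cd8_t = 1.1, b = 2, gcb = 8, fdc = 5,
                         cd4_trm = 3, cd8_trm = 3
                       ),
                       maturity_enrichment = c(
                         cd4_t = 1, cd8_t = 1, b = 1.3, gcb = 1, fdc = 1,
                         cd4_trm = 2.5, cd8_trm = 2.5
                       ),
                       trm_high_prob = 0.5,
                       trm_high_multiplier = 2,
                       tumor_area_mm2 = c(150, 500),
                       survival = list(
                         baseline_hazard = 0.12,
                         log_hr_grade2 = log(0.418),
                         log_hr_grade3 = log(0.226),
                         log_hr_trm_high = log(0.433),
                         censor_rate = 0.3,
                         max_followup_months = 40
                       ),
                       intensity_mode = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), grade_probs = grade_probs,
    tls_per_patient = as.integer(tls_per_patient),
    outside_fields_per_patient = as.integer(outside_fields_per_patient),
    cells_per_region = as.integer(cells_per_region),
    maturity_mix_by_grade = maturity_mix_by_grade,
    subset_base_freqs = subset_base_freqs, enrichment = enrichment,
    maturity_enrichment = maturity_enrichment,
    trm_high_prob = trm_high_prob,
    trm_high_multiplier = trm_high_multiplier,
    tumor_area_mm2 = tumor_area_mm2, survival = survival,
    intensity_mode = isTRUE(intensity_mode), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 0) stop("n_patients must be >= 0")
  if (length(cfg$grade_probs) != 3 || any(cfg$grade_probs < 0)) {
    stop("grade_probs must be three non-negative probabilities")
  }
  if (abs(sum(cfg$grade_probs) - 1) > 1e-12) {
    stop("grade_probs must sum to 1 (got ", sum(cfg$grade_probs), ")")
  }
  for (nm in c("tls_per_patient", "outside_fields_per_patient",
               "cells_per_region", "tumor_area_mm2")) {
    rng <- cfg[[nm]]
    if (length(rng) != 2 || rng[1] > rng[2] || any(rng < 0)) {
      stop(nm, " must be a range c(min, max) with 0 <= min <= max")
    }
  }
  if (cfg$tls_per_patient[1] < 1 && cfg$n_patients > 0) {
    stop("tls_per_patient minimum must be >= 1 (cohort is TLS-positive ",
         "by inclusion criterion)")
  }
  mix <- cfg$maturity_mix_by_grade
  if (length(mix) != 3) stop("maturity_mix_by_grade must have 3 entries")
  for (g in 1:3) {
    p <- mix[[g]]
    if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("maturity mix for grade ", g, " must be 3 probabilities ",
           "summing to 1")
    }
  }
  if (cfg$grade_probs[1] > 0 && (mix[[1]][2] > 0 || mix[[1]][3] > 0)) {
    stop("infeasible config: grade 1 patients carry only E-TLS, but the ",
         "grade-1 maturity mix assigns probability to PFL/SFL")
  }
  if (cfg$grade_probs[2] > 0) {
    if (mix[[2]][2] == 0) {
      stop("infeasible config: grade 2 requires at least one PFL-TLS, ",
           "but the grade-2 maturity mix gives PFL probability 0")
    }
    if (mix[[2]][3] > 0) {
      stop("infeasible config: grade 2 patients carry no SFL-TLS, but ",
           "the grade-2 maturity mix assigns probability to SFL")
    }
  }
  if (cfg$grade_probs[3] > 0 && mix[[3]][3] == 0) {
    stop("infeasible config: grade 3 requires at least one SFL-TLS, but ",
         "the grade-3 maturity mix gives SFL probability 0")
  }
  known <- setdiff(archetype_names(), "other")
  for (nm in c("subset_base_freqs", "enrichment", "maturity_enrichment")) {
    v <- cfg[[nm]]
    unknown <- setdiff(names(v), known)
    if (length(unknown) > 0) {
      stop(nm, " names unknown archetype(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(v < 0)) stop(nm, " must be non-negative")
  }
  if (any(cfg$subset_base_freqs > 1)) {
    stop("subset_base_freqs must lie in [0, 1]")
  }
  sv <- cfg$survival
  if (sv$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (sv$censor_rate < 0 || sv$censor_rate > 1) {
    stop("censor_rate must lie in [0, 1]")
  }
  if (sv$max_followup_months < 0) stop("max_followup_months must be >= 0")
  if (cfg$trm_high_prob < 0 || cfg$trm_high_prob > 1) {
    stop("trm_high_prob must lie in [0, 1]")
  }
  invisible(cfg)
}

# Archetype frequency vector for one region, given its class.
region_freqs <- function(cfg, region_class = c("outside", "E_TLS",
                                               "PFL_TLS", "SFL_TLS"),
                         trm_high = FALSE) {
  region_class <- match.arg(region_class)
  known <- setdiff(archetype_names(), "other")
  f <- stats::setNames(rep(0, length(known)), known)
  f[names(cfg$subset_base_freqs)] <- cfg$subset_base_freqs
  if (region_class != "outside") {
    mult <- stats::setNames(rep(1, length(known)), known)
    mult[names(cfg$enrichment)] <- cfg$enrichment
    f <- f * mult
    if (region_class == "SFL_TLS") {
      mm <- stats::setNames(rep(1, length(known)), known)
      mm[names(cfg$maturity_enrichment)] <- cfg$maturity_enrichment
      f <- f * mm
    }
    if (trm_high) {
      f[c("cd4_trm", "cd8_trm")] <-
        f[c("cd4_trm", "cd8_trm")] * cfg$trm_high_multiplier
    }
    # maturity determines presence of the staging markers: early TLSs
    # have no FDC network and no GC reaction; primary follicle-like TLSs
    # have FDCs but no GC reaction
    if (region_class == "E_TLS") f[c("fdc", "gcb")] <- 0
    if (region_class == "PFL_TLS") f["gcb"] <- 0
  }
  if (sum(f) > 1) {
    message("region frequencies sum to ", round(sum(f), 4),
            " > 1; clipping proportionally")
    f <- f / sum(f)
  }
  c(other = 1 - sum(f), f)
}

# Draw n cells for one region; guarantees the staging-marker floor for
# PFL/SFL regions (>= 1 FDC cell; >= 1 GC-B cell for SFL) by converting
# unlabelled cells, so that maturity classification recovers the truth
# exactly at the default presence thresholds.
draw_region_cells <- function(cfg, n, region_class, trm_high) {
  f <- region_freqs(cfg, region_class, trm_high)
  arch <- archetype_names()
  idx <- sample.int(length(arch), n, replace = TRUE, prob = f[arch])
  labels <- arch[idx]
  force_floor <- function(labels, what) {
    if (!any(labels == what)) {
      spot <- which(labels == "other")
      spot <- if (length(spot) > 0) spot[length(spot)] else length(labels)
      labels[spot] <- what
    }
    labels
  }
  if (region_class %in% c("PFL_TLS", "SFL_TLS")) {
    labels <- force_floor(labels, "fdc")
  }
  if (region_class == "SFL_TLS") labels <- force_floor(labels, "gcb")
  cell_archetypes()[labels, , drop = FALSE]
}

#' Simulate one disease-free-survival record
#'
#' Event time is exponential with hazard
#' `h0 * exp(b2 * [grade == 2] + b3 * [grade == 3] + bt * [trm_high])`.
#' Censoring is independent: with probability `censor_rate` a uniform
#' censoring time on `[0, max_followup_months]` applies; otherwise the
#' subject is administratively censored at `max_followup_months` (no
#' censoring at all when it is `Inf`). The observed time is the minimum
#' of event and censoring times. Draws come from the current RNG stream.
#'
#' @param grade True maturity grade, 1, 2 or 3.
#' @param trm_high Logical, planted T_RM stratum.
#' @param params Survival sub-configuration (see [sim_config()]).
#' @param n Number of records to draw.
#' @return Data.frame: `time`, `event`, `true_log_hazard`.
#' @export
simulate_survival <- function(grade, trm_high, params, n = 1L) {
  if (params$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (!grade %in% 1:3) stop("grade must be 1, 2 or 3")
  lh <- log(params$baseline_hazard) +
    (grade == 2) * params$log_hr_grade2 +
    (grade == 3) * params$log_hr_grade3 +
    as.logical(trm_high) * params$log_hr_trm_high
  t_event <- stats::rexp(n, rate = exp(lh))
  mf <- params$max_followup_months
  use_random <- stats::runif(n) < params$censor_rate
  t_cens <- ifelse(use_random,
                   stats::runif(n, 0, mf),
                   mf)
  t_cens[is.nan(t_cens)] <- Inf   # runif(0, Inf) guard when mf = Inf
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  data.frame(time = time, event = event, true_log_hazard = lh)
}

rand_int_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
}

#' Simulate a synthetic cohort
#'
#' Generates the four cohort tables (`cells`, `regions`, `sections`,
#' `clinical`) together with the ground truth (per-patient grade and
#' T_RM stratum, per-TLS maturity, true log-hazard). Deterministic given
#' `config$seed`: each patient is simulated on a substream derived from
#' the cohort seed (draw order within a patient: grade, TLS count and
#' maturities, tumor area, outside-field count, region cells, clinical
#' covariates, survival), so extending the cohort leaves earlier patients
#' byte-identical.
#'
#' @param config A [sim_config()].
#' @return List of class `tls_cohort` with elements `cells`, `regions`,
#'   `sections`, `clinical`, `truth` (list: `patients` data.frame,
#'   `tls` data.frame).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  cells_list <- list()
  regions_list <- list()
  sections_list <- list()
  clinical_list <- list()
  truth_pat <- list()
  truth_tls <- list()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  for (i in seq_len(cfg$n_patients)) {
    set.seed((cfg$seed %% 1000003L) * 2011L + i * 7L)
    pid <- sprintf("P%03d", i)
    sid <- paste0(pid, "_S1")
    grade <- sample(1:3, 1, prob = cfg$grade_probs)
    n_tls <- rand_int_range(cfg$tls_per_patient)
    mix <- cfg$maturity_mix_by_grade[[grade]]
    mats <- sample(maturity_levels(), n_tls, replace = TRUE, prob = mix)
    # guarantee the grade-defining maturity is present
    if (grade == 2 && !any(mats == "PFL_TLS")) mats[1] <- "PFL_TLS"
    if (grade == 3 && !any(mats == "SFL_TLS")) mats[1] <- "SFL_TLS"
    trm_high <- stats::runif(1) < cfg$trm_high_prob
    area <- stats::runif(1, cfg$tumor_area_mm2[1], cfg$tumor_area_mm2[2])
    n_out <- rand_int_range(cfg$outside_fields_per_patient)

    region_ids <- c(sprintf("%s_T%02d", pid, seq_len(n_tls)),
                    sprintf("%s_F%d", pid, seq_len(n_out)))
    region_class <- c(mats, rep("outside", n_out))
    regions_list[[i]] <- data.frame(
      patient_id = pid, section_id = sid, region_id = region_ids,
      region_type = c(rep("tls", n_tls), rep("outside", n_out)),
      stringsAsFactors = FALSE
    )
    sections_list[[i]] <- data.frame(
      patient_id = pid, section_id = sid, tumor_area_mm2 = area,
      stringsAsFactors = FALSE
    )
    pat_cells <- vector("list", length(region_ids))
    for (r in seq_along(region_ids)) {
      n_cells <- rand_int_range(cfg$cells_per_region)
      m <- draw_region_cells(cfg, n_cells, region_class[r], trm_high)
      rownames(m) <- NULL
      df <- as.data.frame(m)
      df <- cbind(
        data.frame(
          patient_id = pid, section_id = sid, region_id = region_ids[r],
          cell_id = sprintf("%s_C%04d", region_ids[r], seq_len(n_cells)),
          stringsAsFactors = FALSE
        ),
        df
      )
      if (cfg$intensity_mode) {
        for (mk in marker_panel()) {
          pos <- df[[mk]] == 1
          z <- abs(stats::rnorm(n_cells, 0, 0.6))
          df[[paste0(mk, "_intensity")]] <- ifelse(pos, exp(z), exp(-z - 0.05))
        }
      }
      pat_cells[[r]] <- df
    }
    cells_list[[i]] <- do.call(rbind, pat_cells)

    covars <- data.frame(
      sex = if (stats::runif(1) < 24 / 49) "Male" else "Female",
      age = if (stats::runif(1) < 21 / 49)
        round(stats::runif(1, 60, 80)) else round(stats::runif(1, 35, 59)),
      t_stage = if (stats::runif(1) < 29 / 49) "T1" else "T2-4",
      n_stage = if (stats::runif(1) < 6 / 49) "N3" else "N1-2",
      tnm_stage = if (stats::runif(1) < 39 / 49) "IIIA" else "IIIB",
      micropapillary = if (stats::runif(1) < 22 / 49)
        "Positive" else "Negative",
      egfr = if (stats::runif(1) < 0.6) "Positive" else "Negative",
      smoking = if (stats::runif(1) < 26 / 49) "Never" else "Smoking",
      stringsAsFactors = FALSE
    )
    surv <- simulate_survival(grade, trm_high, cfg$survival)
    clinical_list[[i]] <- cbind(
      data.frame(patient_id = pid,
                 dfs_months = surv$time, event = surv$event,
                 stringsAsFactors = FALSE),
      covars
    )
    truth_pat[[i]] <- data.frame(
      patient_id = pid, grade = grade, trm_high = trm_high,
      true_log_hazard = surv$true_log_hazard, stringsAsFactors = FALSE
    )
    truth_tls[[i]] <- data.frame(
      patient_id = pid,
      region_id = region_ids[seq_len(n_tls)],
      maturity = mats, stringsAsFactors = FALSE
    )
  }
  bind <- function(lst, template) {
    if (length(lst) == 0) template else do.call(rbind, lst)
  }
  empty_cells <- data.frame(
    patient_id = character(), section_id = character(),
    region_id = character(), cell_id = character(),
    CD3 = integer(), CD4 = integer(), CD20 = integer(), CD21 = integer(),
    CD103 = integer(), BCL6 = integer(), stringsAsFactors = FALSE
  )
  out <- list(
    cells = bind(cells_list, empty_cells),
    regions = bind(regions_list, data.frame(
      patient_id = character(), section_id = character(),
      region_id = character(), region_type = character(),
      stringsAsFactors = FALSE
    )),
    sections = bind(sections_list, data.frame(
      patient_id = character(), section_id = character(),
      tumor_area_mm2 = numeric(), stringsAsFactors = FALSE
    )),
    clinical = bind(clinical_list, data.frame(
      patient_id = character(), dfs_months = numeric(), event = integer(),
      sex = character(), age = numeric(), t_stage = character(),
      n_stage = character(), tnm_stage = character(),
      micropapillary = character(), egfr = character(),
      smoking = character(), stringsAsFactors = FALSE
    )),
    truth = list(
      patients = bind(truth_pat, data.frame(
        patient_id = character(), grade = integer(), trm_high = logical(),
        true_log_hazard = numeric(), stringsAsFactors = FALSE
      )),
      tls = bind(truth_tls, data.frame(
        patient_id = character(), region_id = character(),
        maturity = character(), stringsAsFactors = FALSE
      ))
    ),
    config = cfg
  )
  rownames(out$cells) <- NULL
  rownames(out$regions) <- NULL
  class(out) <- "tls_cohort"
  out
}

#' Write a cohort to CSV fixtures plus a ground-truth sidecar
#'
#' Emits `cells.csv`, `regions.csv`, `sections.csv`, `clinical.csv`
#' (UTF-8, comma-separated, header row, no index column) and
#' `truth.json`. The files round-trip losslessly through
#' [read_cohort()].
#'
#' @param cohort A `tls_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cells.csv", "regions.csv", "sections.csv",
                            "clinical.csv"))
  tabs <- cohort[c("cells", "regions", "sections", "clinical")]
  for (i in seq_along(tabs)) {
    utils::write.csv(tabs[[i]], paths[i], row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  if (!is.null(cohort$truth)) {
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(cohort$truth, truth_path, dataframe = "columns",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}
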