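# Fixtures built in code: tiny hand-constructed cohorts and random
# marker tables used across the test files.

# A cell row with explicit marker calls (all others zero).
make_cell <- function(region_id, cell_id, positive = character(0),
                      patient_id = "P1", section_id = "P1_S1") {
  row <- data.frame(patient_id = patient_id, section_id = section_id,
                    region_id = region_id, cell_id = cell_id,
                    CD3 = 0L, CD4 = 0L, CD20 = 0L, CD21 = 0L,
                    CD103 = 0L, BCL6 = 0L, stringsAsFactors = FALSE)
  for (m in positive) row[[m]] <- 1L
  row
}

# Random marker table drawn over the valid archetype combinations, so
# nonsensical calls (CD4+CD3- "T cells") never arise.
random_cells <- function(n, region_id = "R1", seed = 1) {
  set.seed(seed)
  combos <- rbind(
    c(0, 0, 0, 0, 0, 0), c(1, 1, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0),
    c(0, 0, 1, 0, 0, 0), c(0, 0, 1, 0, 0, 1), c(0, 0, 0, 1, 0, 0),
    c(1, 1, 0, 0, 1, 0), c(1, 0, 0, 0, 1, 0)
  )
  idx <- sample(nrow(combos), n, replace = TRUE)
  df <- as.data.frame(combos[idx, , drop = FALSE])
  names(df) <- c("CD3", "CD4", "CD20", "CD21", "CD103", "BCL6")
  df$region_id <- rep(region_id, n)
  df$cell_id <- if (n > 0) paste0(region_id, "_C", seq_len(n)) else
    character(0)
  df
}

# Independent enumeration oracle for the signed-rank test: walk all 2^n
# sign assignments explicitly (shared across test files).
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs + 1e-12)
  p_ge <- mean(w_all >= w_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# Hand-built two-region, one-patient cohort: one TLS of 4 cells, one
# outside field of 5 cells, with a known composition.
tiny_cohort <- function() {
  cells <- rbind(
    make_cell("P1_T1", "c1", c("CD3", "CD4", "CD103")),
    make_cell("P1_T1", "c2", c("CD20", "BCL6")),
    make_cell("P1_T1", "c3", c("CD21")),
    make_cell("P1_T1", "c4", character(0)),
    make_cell("P1_F1", "c5", c("CD3")),
    make_cell("P1_F1", "c6", c("CD20")),
    make_cell("P1_F1", "c7", character(0)),
    make_cell("P1_F1", "c8", character(0)),
    make_cell("P1_F1", "c9", c("CD3", "CD103"))
  )
  regions <- data.frame(
    patient_id = "P1", section_id = "P1_S1",
    region_id = c("P1_T1", "P1_F1"),
    region_type = c("tls", "outside"), stringsAsFactors = FALSE
  )
  sections <- data.frame(patient_id = "P1", section_id = "P1_S1",
                         tumor_area_mm2 = 100, stringsAsFactors = FALSE)
  clinical <- data.frame(patient_id = "P1", dfs_months = 12, event = 1L,
                         stringsAsFactors = FALSE)
  structure(list(cells = cells, regions = regions, sections = sections,
                 clinical = clinical), class = "tls_cohort")
}

# Small, fast simulation configuration for cohort-level tests;
# overrides in ... win over the speed defaults.
fast_sim_config <- function(n_patients = 12, seed = 1, ...) {
  args <- utils::modifyList(
    list(n_patients = n_patients, tls_per_patient = c(3L, 6L),
         cells_per_region = c(60L, 120L), seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}
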