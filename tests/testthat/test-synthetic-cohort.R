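test_that("the generator is deterministic and extendable by patient", {
  cfg <- fast_sim_config(n_patients = 6, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)

  # patient substreams: adding patients never changes earlier patients
  big <- simulate_cohort(fast_sim_config(n_patients = 9, seed = 123))
  first6 <- big$cells[big$cells$patient_id %in%
                        unique(a$cells$patient_id), ]
  rownames(first6) <- NULL
  expect_identical(first6, a$cells)
  expect_identical(big$clinical[1:6, ], a$clinical)
})

test_that("degenerate mixtures produce exactly what they promise", {
  cfg <- fast_sim_config(n_patients = 6, seed = 2,
                         grade_probs = c(1, 0, 0))
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$truth$patients$grade == 1))
  expect_true(all(coh$truth$tls$maturity == "E_TLS"))
  # early TLSs never carry staging markers
  tls_cells <- coh$cells[grepl("_T", coh$cells$region_id), ]
  expect_equal(sum(tls_cells$CD21), 0)
  expect_equal(sum(tls_cells$CD20 * tls_cells$BCL6), 0)
})

test_that("empirical grade frequencies match the mixture", {
  probs <- c(0.2, 0.5, 0.3)
  cfg <- sim_config(n_patients = 500, grade_probs = probs,
                    tls_per_patient = c(1L, 1L),
                    outside_fields_per_patient = c(1L, 1L),
                    cells_per_region = c(1L, 1L), seed = 77)
  coh <- simulate_cohort(cfg)
  freq <- tabulate(coh$truth$patients$grade, 3) / 500
  sd3 <- 3 * sqrt(probs * (1 - probs) / 500)
  expect_true(all(abs(freq - probs) <= sd3))
})

test_that("infeasible configurations are rejected with a named clash", {
  expect_error(sim_config(grade_probs = c(0.3, 0.3, 0.3)), "sum to 1")
  expect_error(
    sim_config(maturity_mix_by_grade = list(
      c(1, 0, 0), c(0.5, 0.5, 0), c(0.7, 0.3, 0)
    )),
    "grade 3 requires at least one SFL"
  )
  expect_error(
    sim_config(maturity_mix_by_grade = list(
      c(0.8, 0.2, 0), c(0.5, 0.5, 0), c(0.5, 0.3, 0.2)
    )),
    "grade 1 patients carry only E-TLS"
  )
  expect_error(
    sim_config(maturity_mix_by_grade = list(
      c(1, 0, 0), c(0.5, 0.4, 0.1), c(0.5, 0.3, 0.2)
    )),
    "grade 2 patients carry no SFL"
  )
  expect_error(sim_config(tls_per_patient = c(5, 2)), "min <= max")
  expect_error(sim_config(survival = list(
    baseline_hazard = -1, log_hr_grade2 = 0, log_hr_grade3 = 0,
    log_hr_trm_high = 0, censor_rate = 0, max_followup_months = 10
  )), "baseline_hazard")
})

test_that("simulated event times follow the planted exponential model", {
  params <- list(baseline_hazard = 0.1, log_hr_grade2 = 0,
                 log_hr_grade3 = 0, log_hr_trm_high = 0,
                 censor_rate = 0, max_followup_months = Inf)
  set.seed(10)
  s <- simulate_survival(1, FALSE, params, n = 10000)
  expect_true(all(s$event == 1))
  # exponential with hazard 0.1: mean 10, SE 10/sqrt(n)
  expect_lt(abs(mean(s$time) - 10), 3 * 10 / sqrt(10000))

  # zero follow-up: everything censored at 0
  p0 <- modifyList(params, list(max_followup_months = 0,
                                censor_rate = 0))
  s0 <- simulate_survival(2, TRUE, p0, n = 50)
  expect_true(all(s0$time == 0))
  expect_true(all(s0$event == 0))

  # protective grade-3 hazard: fewer events under a common follow-up
  p3 <- modifyList(params, list(log_hr_grade3 = log(0.25),
                                max_followup_months = 15))
  set.seed(11)
  e1 <- mean(simulate_survival(1, FALSE, p3, n = 4000)$event)
  e3 <- mean(simulate_survival(3, FALSE, p3, n = 4000)$event)
  expect_lt(e3, e1)

  expect_error(simulate_survival(1, FALSE,
                                 modifyList(params,
                                            list(baseline_hazard = 0))),
               "positive")
})

test_that("grading the simulated maturity lists reproduces the truth", {
  for (seed in c(1, 4, 9, 16)) {
    coh <- simulate_cohort(fast_sim_config(n_patients = 10, seed = seed,
                                           cells_per_region = c(5L, 9L)))
    by_pat <- split(coh$truth$tls$maturity, coh$truth$tls$patient_id)
    regraded <- vapply(by_pat, grade_patient, 1L)
    truth <- coh$truth$patients
    expect_equal(unname(regraded[truth$patient_id]), truth$grade)
  }
})

test_that("fixtures round-trip losslessly through the readers", {
  coh <- simulate_cohort(fast_sim_config(n_patients = 4, seed = 20))
  dir <- withr::local_tempdir()
  paths <- write_fixture(coh, dir)
  expect_true(all(file.exists(paths)))
  back <- read_cohort(dir)
  for (nm in c("cells", "regions", "sections", "clinical")) {
    expect_equal(back[[nm]], coh[[nm]], tolerance = 1e-8,
                 ignore_attr = TRUE, label = nm)
  }
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$patients$grade, coh$truth$patients$grade)
})

test_that("an empty cohort writes header-only files", {
  coh <- simulate_cohort(fast_sim_config(n_patients = 0, seed = 1))
  expect_equal(nrow(coh$cells), 0)
  dir <- withr::local_tempdir()
  write_fixture(coh, dir)
  lines <- readLines(file.path(dir, "clinical.csv"))
  expect_length(lines, 1)   # header only
  back <- read_cohort(dir)
  expect_equal(nrow(back$clinical), 0)
})

test_that("intensity mode appends intensities consistent with the calls", {
  coh <- simulate_cohort(fast_sim_config(n_patients = 2, seed = 5,
                                         intensity_mode = TRUE))
  for (m in marker_panel()) {
    icol <- coh$cells[[paste0(m, "_intensity")]]
    expect_false(is.null(icol))
    expect_true(all(icol[coh$cells[[m]] == 1] > 1))
    expect_true(all(icol[coh$cells[[m]] == 0] < 1))
  }
})
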