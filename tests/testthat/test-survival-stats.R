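test_that("product-limit curve matches hand computation", {
  km <- km_curve(c(5, 10, 15), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 10)

  all_cens <- km_curve(c(3, 7, 9), c(0, 0, 0))
  expect_length(all_cens$time, 0)
  expect_true(is.na(all_cens$median))

  single <- km_curve(7, 1)
  expect_equal(single$surv, 0)
  expect_equal(single$median, 7)

  expect_error(km_curve(c(-1, 3), c(1, 1)), "non-negative")
})

test_that("with no censoring the KM curve is the empirical survival", {
  set.seed(14)
  for (i in 1:5) {
    tm <- round(rexp(40, 0.2), 1)
    km <- km_curve(tm, rep(1, 40))
    emp <- vapply(km$time, function(t) mean(tm > t), 0)
    expect_equal(km$surv, emp)
    expect_true(all(diff(km$surv) <= 1e-12))
  }
})

test_that("KM matches survival::survfit including tie handling", {
  skip_if_not_installed("survival")
  set.seed(27)
  tm <- sample(1:15, 60, replace = TRUE)   # heavy ties
  ev <- rbinom(60, 1, 0.6)
  km <- km_curve(tm, ev)
  sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  at_events <- summary(sf, times = km$time)
  expect_equal(km$surv, at_events$surv, tolerance = 1e-12)
})

test_that("log-rank matches the worked observed/expected example", {
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(unname(lr$observed["A"]), 2)
  expect_equal(unname(lr$expected["A"]), 5 / 6, tolerance = 1e-12)
  expect_equal(lr$variance, 17 / 36, tolerance = 1e-12)
  expect_equal(lr$statistic, (2 - 5 / 6)^2 / (17 / 36), tolerance = 1e-12)
  expect_equal(round(lr$statistic, 2), 2.88)
})

test_that("log-rank symmetry: identical groups and label swaps", {
  tm <- c(2, 4, 6, 8); ev <- c(1, 0, 1, 1)
  dup <- logrank_test(c(tm, tm), c(ev, ev), rep(c("A", "B"), each = 4))
  expect_equal(dup$statistic, 0)
  expect_equal(dup$p_value, 1)
  expect_equal(dup$hazard_ratio, 1)

  set.seed(8)
  tm <- rexp(30); ev <- rbinom(30, 1, 0.7)
  g <- rep(c("A", "B"), 15)
  ab <- logrank_test(tm, ev, factor(g, levels = c("A", "B")))
  ba <- logrank_test(tm, ev, factor(g, levels = c("B", "A")))
  expect_equal(ab$statistic, ba$statistic)
  expect_equal(ab$hazard_ratio, 1 / ba$hazard_ratio)
})

test_that("log-rank chi-squared equals survival::survdiff", {
  skip_if_not_installed("survival")
  set.seed(33)
  for (i in 1:5) {
    n <- 50
    tm <- round(rexp(n, 0.1), 1)
    ev <- rbinom(n, 1, 0.7)
    g <- sample(c("A", "B"), n, replace = TRUE)
    ours <- logrank_test(tm, ev, g)
    ref <- survival::survdiff(survival::Surv(tm, ev) ~ g)
    expect_equal(ours$statistic, ref$chisq, tolerance = 1e-9)
    expect_equal(unname(ours$observed), unname(ref$obs))
    expect_equal(unname(ours$expected), unname(ref$exp),
                 tolerance = 1e-9)
  }
  # three-group extension
  g3 <- sample(c("A", "B", "C"), 60, replace = TRUE)
  tm <- round(rexp(60, 0.1), 1); ev <- rbinom(60, 1, 0.8)
  ours <- logrank_test(tm, ev, g3)
  ref <- survival::survdiff(survival::Surv(tm, ev) ~ g3)
  expect_equal(ours$statistic, ref$chisq, tolerance = 1e-9)
  expect_equal(ours$df, 2)
})

test_that("log-rank is invariant under monotone time transformations", {
  set.seed(41)
  tm <- rexp(40) + 0.1; ev <- rbinom(40, 1, 0.7)
  g <- rep(c("A", "B"), 20)
  base <- logrank_test(tm, ev, g)
  for (f in list(sqrt, log1p, function(x) x^3)) {
    tr <- logrank_test(f(tm), ev, g)
    expect_equal(tr$statistic, base$statistic, tolerance = 1e-12)
  }
})

test_that("log-rank input validation", {
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")), "no events")
  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")),
               "at least two groups")
})

test_that("cutpoint argmax equals exhaustive search on small n", {
  skip_if_not_installed("survival")
  set.seed(55)
  for (i in 1:5) {
    n <- 15
    v <- round(runif(n), 2)
    if (length(unique(v)) < 3) next
    tm <- rexp(n, ifelse(v >= median(v), 0.05, 0.2))
    ev <- rep(1L, n)
    cp <- max_selected_cutpoint(v, tm, ev, minprop = 0.15, B = 0)
    # oracle: brute-force standardized statistic via survdiff chi2
    min_n <- ceiling(0.15 * n)
    cands <- sort(unique(v))
    cands <- cands[vapply(cands, function(c) {
      h <- sum(v >= c); h >= min_n && (n - h) >= min_n
    }, TRUE)]
    stats <- vapply(cands, function(c) {
      g <- v >= c
      sqrt(survival::survdiff(survival::Surv(tm, ev) ~ g)$chisq)
    }, 0)
    expect_equal(cp$cutoff, cands[which.max(stats)])
    expect_equal(cp$statistic, max(stats), tolerance = 1e-9)
  }
})

test_that("cutpoint respects minprop and rejects degenerate features", {
  set.seed(17)
  v <- c(rep(0, 12), 1)   # only splits putting <10% on one side
  tm <- rexp(13); ev <- rep(1L, 13)
  expect_error(max_selected_cutpoint(v, tm, ev, minprop = 0.2, B = 0),
               "minprop")
  expect_error(max_selected_cutpoint(rep(2, 13), tm, ev, B = 0),
               "constant")
  expect_error(max_selected_cutpoint(v[1:5], tm[1:5], ev[1:5], B = 0),
               "at least 10")
  v20 <- runif(20)
  cp <- max_selected_cutpoint(v20, rexp(20), rep(1L, 20),
                              minprop = 0.25, B = 0)
  n_high <- vapply(cp$scan$cutoff, function(c) sum(v20 >= c), 0)
  expect_true(all(n_high >= 5 & (20 - n_high) >= 5))
})

test_that("cutpoint permutation p is seeded and leaves the RNG intact", {
  set.seed(99)
  v <- runif(30); tm <- rexp(30); ev <- rbinom(30, 1, 0.8)
  before <- .Random.seed
  p1 <- max_selected_cutpoint(v, tm, ev, B = 50, seed = 7)$p_value
  expect_identical(.Random.seed, before)
  p2 <- max_selected_cutpoint(v, tm, ev, B = 50, seed = 7)$p_value
  expect_equal(p1, p2)
  expect_true(p1 > 0 && p1 <= 1)
})

test_that("cutpoint permutation p is calibrated under the null", {
  set.seed(12)
  n_sims <- 120
  rej <- logical(n_sims)
  for (r in seq_len(n_sims)) {
    v <- runif(30)
    tm <- rexp(30, 0.1)
    ev <- as.integer(tm <= 25); tm <- pmin(tm, 25)
    p <- max_selected_cutpoint(v, tm, ev, B = 79, seed = r)$p_value
    rej[r] <- p <= 0.05
  }
  # 3 binomial SDs around the nominal 5% level
  band <- 0.05 + c(-3, 3) * sqrt(0.05 * 0.95 / n_sims)
  expect_gte(mean(rej), max(0, band[1]))
  expect_lte(mean(rej), band[2])
})

test_that("dichotomize follows the >= cutoff convention", {
  expect_equal(as.character(dichotomize(c(1, 2, 3), 2)),
               c("low", "high", "high"))
  expect_true(all(dichotomize(c(5, 9), 1) == "high"))
  expect_true(all(dichotomize(c(5, 9), 10) == "low"))
  expect_message(out <- dichotomize(c(1, NA, 3), 2), "missing")
  expect_true(is.na(out[2]))
  expect_error(dichotomize(1:3, Inf), "finite")
})

test_that("stratified analysis composes from pairwise log-rank tests", {
  set.seed(61)
  tm <- rexp(40); ev <- rbinom(40, 1, 0.8)
  strata <- sample(c("g1", "g2", "g3"), 40, replace = TRUE)
  res <- stratified_analysis(tm, ev, strata)
  expect_equal(nrow(res$pairwise), 3)
  # collapsing to a manual two-group test reproduces each pairwise row
  for (j in seq_len(nrow(res$pairwise))) {
    a <- res$pairwise$stratum_a[j]; b <- res$pairwise$stratum_b[j]
    sel <- strata %in% c(a, b)
    manual <- logrank_test(tm[sel], ev[sel],
                           factor(strata[sel], levels = c(a, b)))
    expect_equal(res$pairwise$chi_square[j], manual$statistic)
    expect_equal(res$pairwise$hazard_ratio[j], manual$hazard_ratio)
  }
  # two identical strata: all pairwise p = 1
  dup <- stratified_analysis(c(tm, tm), c(ev, ev),
                             rep(c("x", "y"), each = 40))
  expect_equal(dup$pairwise$p_value, 1)
  # a singleton stratum is flagged and excluded
  small <- stratified_analysis(c(tm, 5), c(ev, 1), c(strata, "tiny"))
  expect_true(small$strata$excluded[small$strata$stratum == "tiny"])
  expect_false("tiny" %in% c(small$pairwise$stratum_a,
                             small$pairwise$stratum_b))
})
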