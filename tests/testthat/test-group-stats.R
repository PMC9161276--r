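test_that("signed-rank exact p matches full sign enumeration", {
  # five concordant pairs: the smallest attainable two-sided exact p
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(0, 1, 2, 3, 4))
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$statistic, 0)
  expect_equal(res$method, "exact")

  set.seed(21)
  for (i in 1:4) {
    d <- round(rnorm(12), 1)
    d <- d[d != 0]
    res <- wilcoxon_signed_rank(d)
    expect_equal(res$p_value, wilcoxon_enum_p(d), tolerance = 1e-12,
                 label = paste("replicate", i))
  }
  # with deliberate midrank ties (base wilcox.test refuses exact here)
  d <- c(1.5, -1.5, 2, 2, -3, 4, 4, 5)
  expect_equal(wilcoxon_signed_rank(d)$p_value, wilcoxon_enum_p(d))
})

test_that("signed-rank agrees with wilcox.test where both are defined", {
  set.seed(4)
  x <- rnorm(15); y <- rnorm(15)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value)
  # large-n normal path with continuity correction
  x <- rnorm(40); y <- rnorm(40)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$method, "normal")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("signed-rank degenerate inputs error", {
  expect_error(wilcoxon_signed_rank(c(3, 3), c(3, 3)), "all differences")
  expect_error(wilcoxon_signed_rank(numeric(0)), "no pairs")
})

test_that("Kruskal-Wallis matches the rank formula and kruskal.test", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(round(res$statistic, 3), 4.571)
  expect_equal(res$df, 2)

  expect_equal(kruskal_wallis(list(c(1, 5, 9), c(1, 5, 9)))$statistic, 0)

  set.seed(6)
  g <- list(rnorm(8), rnorm(11), round(rnorm(7), 1))
  ref <- kruskal.test(g)
  ours <- kruskal_wallis(g)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)

  # k = 2 equals the squared standardized rank-sum statistic
  a <- rnorm(9); b <- rnorm(12)
  n1 <- 9; n2 <- 12; n <- n1 + n2
  r1 <- sum(rank(c(a, b))[1:9])
  z <- (r1 - n1 * (n + 1) / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  expect_equal(kruskal_wallis(list(a, b))$statistic, z^2)

  expect_error(kruskal_wallis(list(1:5)), "two non-empty")
})

test_that("chi-squared test matches hand computation and chisq.test", {
  even <- matrix(5, 2, 2)
  res <- chi_square_test(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  diag20 <- matrix(c(10, 0, 0, 10), 2, 2)
  res <- chi_square_test(diag20)
  expect_equal(res$statistic, 20)  # all expected counts are 5
  expect_equal(res$df, 1)
  expect_true(all(res$expected == 5))

  set.seed(12)
  tab <- matrix(rpois(12, 12) + 1, 3, 4)
  ours <- chi_square_test(tab)
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
  # invariance under row/column permutation
  perm <- chi_square_test(tab[c(2, 3, 1), c(4, 1, 3, 2)])
  expect_equal(perm$statistic, ours$statistic)

  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, 2)),
               "zero margin")
})

test_that("Fisher's exact p equals hypergeometric enumeration", {
  # EGFR-mutation style 2x2: positive 2/13, negative 4/6
  tab <- matrix(c(2, 13, 4, 6), 2, 2, byrow = TRUE)
  expect_equal(round(fisher_exact(tab)$p_value, 3), 0.175)

  expect_equal(fisher_exact(matrix(5, 2, 2))$p_value, 1)

  # oracle: direct enumeration over all tables with the same margins
  set.seed(31)
  for (i in 1:6) {
    tab <- matrix(rpois(4, 5) + 1, 2, 2)
    a_max <- min(sum(tab[1, ]), sum(tab[, 1]))
    a_min <- max(0, sum(tab[1, ]) - sum(tab[, 2]))
    probs <- dhyper(a_min:a_max, sum(tab[, 1]), sum(tab[, 2]),
                    sum(tab[1, ]))
    p_obs <- dhyper(tab[1, 1], sum(tab[, 1]), sum(tab[, 2]), sum(tab[1, ]))
    oracle <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    expect_equal(fisher_exact(tab)$p_value, oracle, tolerance = 1e-12)
    expect_equal(fisher_exact(tab)$p_value,
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }

  # 2x3 grade-style table against fisher.test's network algorithm
  tab3 <- matrix(c(3, 22, 14, 3, 4, 3), 2, 3, byrow = TRUE)
  expect_equal(fisher_exact(tab3)$p_value, fisher.test(tab3)$p.value,
               tolerance = 1e-9)

  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2, 2)), "integers")
})

test_that("test dispatch follows the expected-count rule", {
  expect_equal(choose_association_test(matrix(50, 2, 2))$test,
               "chi_square")
  small <- matrix(c(1, 14, 3, 7), 2, 2, byrow = TRUE)
  disp <- choose_association_test(small)
  expect_equal(disp$test, "fisher")
  expect_lt(disp$min_expected, 5)
  # deterministic: same table, same dispatch
  expect_identical(choose_association_test(small),
                   choose_association_test(small))
  # the wrapper runs whichever test was dispatched
  res <- association_test(small)
  expect_equal(res$test, "fisher")
  expect_equal(res$p_value, fisher_exact(small)$p_value)
})
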