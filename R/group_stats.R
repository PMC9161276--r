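# Nonparametric comparisons and contingency tests, implemented from
# scratch so that exact p-values remain available under midrank ties
# (which the usual exact routines refuse) and so every test can be
# checked against an enumeration oracle.

#' Exact/asymptotic Wilcoxon signed-rank test for paired samples
#'
#' Compares paired measurements (e.g., a subset's percentage inside vs
#' outside the TLS compartment for each patient). Zero differences are
#' dropped (Wilcoxon's original rule); absolute differences are ranked
#' with midranks for ties; the reported statistic is
#' `W = min(W+, W-)`.
#'
#' For `n <= exact_max` non-zero pairs the two-sided p-value is exact: the
#' full null distribution of `W+` over all `2^n` sign assignments is built
#' by the shift (generating-function) algorithm, which handles midrank
#' ties, and `p = min(1, 2 * min(P(W+ <= w+), P(W+ >= w+)))`. For larger
#' `n` a normal approximation with tie correction and a 0.5 continuity
#' correction is used.
#'
#' @param x,y Paired numeric vectors; alternatively supply differences in
#'   `x` and leave `y = NULL`.
#' @param exact_max Largest `n` for which the exact distribution is
#'   enumerated (default 25).
#' @return List: `statistic` (W), `w_plus`, `w_minus`, `n_used` (pairs
#'   after dropping zeros), `p_value`, `method` ("exact" or "normal").
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  if (length(d) == 0) stop("no pairs supplied")
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("all differences are zero; signed-rank test undefined")
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  if (n <= exact_max) {
    # Shift algorithm over doubled ranks (midranks are multiples of 0.5,
    # so 2r is integer); counts[k+1] = number of sign assignments with
    # 2*W+ == k.
    d2 <- as.integer(round(2 * r))
    counts <- c(1, rep(0, sum(d2)))
    for (k in d2) {
      shifted <- c(rep(0, k), counts[seq_len(length(counts) - k)])
      counts <- counts + shifted
    }
    tot <- 2^n
    w2 <- as.integer(round(2 * w_plus))
    p_le <- sum(counts[seq_len(w2 + 1)]) / tot
    p_ge <- sum(counts[seq.int(w2 + 1, length(counts))]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = min(w_plus, w_minus), w_plus = w_plus,
       w_minus = w_minus, n_used = n, p_value = p, method = method)
}

#' Kruskal-Wallis rank test across two or more groups
#'
#' Pooled midranks with tie correction; p-value from the chi-squared
#' distribution with `k - 1` degrees of freedom.
#'
#' @param groups List of numeric vectors (>= 2 non-empty groups, total
#'   n >= 3).
#' @return List: `statistic` (H, tie-corrected), `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, 1L) > 0]
  k <- length(groups)
  if (k < 2) stop("need at least two non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  n_tot <- length(x)
  if (n_tot < 3) stop("need total n >= 3")
  g <- rep(seq_len(k), times = vapply(groups, length, 1L))
  r <- rank(x)
  rs <- tapply(r, g, sum)
  nj <- tabulate(g, k)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(rs^2 / nj) - 3 * (n_tot + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n_tot^3 - n_tot)
  if (correction > 0) h <- h / correction
  list(statistic = h, df = k - 1,
       p_value = stats::pchisq(h, df = k - 1, lower.tail = FALSE),
       n = n_tot)
}

validate_contingency <- function(table, integer_entries = FALSE) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least a 2 x 2 table")
  if (any(is.na(m)) || any(m < 0)) stop("table entries must be non-negative")
  if (integer_entries && any(m != round(m))) {
    stop("table entries must be integers for an exact test")
  }
  rm <- rowSums(m)
  cm <- colSums(m)
  if (any(rm == 0)) {
    stop("degenerate table: row ", which(rm == 0)[1], " has zero margin")
  }
  if (any(cm == 0)) {
    stop("degenerate table: column ", which(cm == 0)[1], " has zero margin")
  }
  m
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction (the dispatch rule in
#' [choose_association_test()] routes small-expected-count tables to the
#' exact test instead). Expected counts are returned so the dispatch is
#' auditable.
#'
#' @param table Matrix-like r x c table of non-negative counts with
#'   positive margins.
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(table) {
  m <- validate_contingency(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       expected = expected)
}

# Enumerate all 2 x c tables with the observed margins; returns the
# log-probability of each under the multivariate hypergeometric null.
enumerate_2xc_tables <- function(col_sums, row1_sum) {
  c_n <- length(col_sums)
  rows <- list(integer(0))
  sums <- 0L
  for (j in seq_len(c_n)) {
    new_rows <- list()
    new_sums <- integer(0)
    remaining_max <- sum(col_sums[-seq_len(j)])
    for (i in seq_along(rows)) {
      lo <- max(0L, row1_sum - sums[i] - remaining_max)
      hi <- min(col_sums[j], row1_sum - sums[i])
      if (hi < lo) next
      for (a in lo:hi) {
        new_rows[[length(new_rows) + 1L]] <- c(rows[[i]], a)
        new_sums <- c(new_sums, sums[i] + a)
      }
    }
    rows <- new_rows
    sums <- new_sums
  }
  do.call(rbind, rows)
}

#' Fisher's exact test for 2 x c tables
#'
#' Two-sided p-value by probability ordering: the sum of multivariate
#' hypergeometric probabilities (margins fixed) of every table whose
#' probability does not exceed that of the observed table (within a
#' relative tolerance of 1e-7 for ties).
#'
#' @param table 2 x c matrix of non-negative integer counts.
#' @return List: `p_value`, `prob_observed`, `n_tables` enumerated.
#' @export
fisher_exact <- function(table) {
  m <- validate_contingency(table, integer_entries = TRUE)
  if (nrow(m) != 2) stop("fisher_exact handles 2 x c tables; got ",
                         nrow(m), " rows")
  col_sums <- as.integer(colSums(m))
  row1 <- as.integer(sum(m[1, ]))
  all_rows <- enumerate_2xc_tables(col_sums, row1)
  # log P(a) = sum_j log choose(m_j, a_j) - log choose(N, r1)
  logp <- rowSums(lchoose(matrix(col_sums, nrow(all_rows), ncol(m),
                                 byrow = TRUE), all_rows)) -
    lchoose(sum(col_sums), row1)
  obs <- rowSums(lchoose(matrix(col_sums, 1, ncol(m), byrow = TRUE),
                         matrix(as.integer(m[1, ]), 1)))[1] -
    lchoose(sum(col_sums), row1)
  keep <- logp <= obs + 1e-7
  list(p_value = min(1, sum(exp(logp[keep]))),
       prob_observed = exp(obs),
       n_tables = nrow(all_rows))
}

#' Choose between chi-squared and Fisher's exact test
#'
#' Dispatch policy: Fisher's exact test when any expected count under
#' independence is below 5, otherwise the Pearson chi-squared test. The
#' choice is deterministic given the table.
#'
#' @param table Contingency table.
#' @return List: `test` ("chi_square" or "fisher"), `min_expected`,
#'   `expected`.
#' @export
choose_association_test <- function(table) {
  m <- validate_contingency(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  test <- if (any(expected < 5)) "fisher" else "chi_square"
  list(test = test, min_expected = min(expected), expected = expected)
}

#' Run the dispatched association test
#'
#' Convenience wrapper: applies [choose_association_test()] and runs the
#' selected test, recording which was chosen.
#'
#' @param table Contingency table (2 x c required for the Fisher branch).
#' @return List: `test`, `p_value`, `statistic` (chi-squared branch only),
#'   `min_expected`.
#' @export
association_test <- function(table) {
  dispatch <- choose_association_test(table)
  if (dispatch$test == "fisher") {
    res <- fisher_exact(table)
    list(test = "fisher", p_value = res$p_value, statistic = NA_real_,
         min_expected = dispatch$min_expected)
  } else {
    res <- chi_square_test(table)
    list(test = "chi_square", p_value = res$p_value,
         statistic = res$statistic, min_expected = dispatch$min_expected)
  }
}
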