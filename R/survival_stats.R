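# Survival machinery: product-limit estimation, log-rank testing with
# observed/expected hazard ratios, and maximally selected rank-statistic
# cutpoint selection. Implemented directly from the counting-process
# quantities so that the cutpoint scan, the permutation null and the
# k-group statistic all share one set of definitions.

validate_survival <- function(time, event) {
  if (length(time) == 0) stop("no survival records supplied")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(is.na(time)) || any(time < 0)) {
    stop("survival times must be non-negative and non-missing")
  }
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  invisible(TRUE)
}

#' Kaplan-Meier product-limit curve
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times;
#' subjects censored at a time leave the risk set after that time, so at
#' tied times deaths are processed before censorings (the standard
#' convention). The median is the smallest event time with
#' `S(t) <= 0.5`, and `NA` ("not reached") when the curve never crosses
#' 0.5 — it is never extrapolated.
#'
#' @param time Non-negative follow-up times (months).
#' @param event 0/1 event indicator (1 = event observed).
#' @return Object of class `km_curve`: `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv`, `median`, `n`.
#' @export
km_curve <- function(time, event) {
  validate_survival(time, event)
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), 0)
  n_event <- vapply(et, function(t) sum(time == t & event == 1), 0)
  surv <- cumprod(1 - n_event / n_risk)
  med <- if (any(surv <= 0.5)) et[which(surv <= 0.5)[1]] else NA_real_
  structure(list(time = et, n_risk = n_risk, n_event = n_event,
                 surv = surv, median = med, n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", sum(x$n_event), "\n")
  cat("median survival:",
      if (is.na(x$median)) "not reached" else paste(x$median, "months"), "\n")
  invisible(x)
}

# Counting-process summary shared by the log-rank statistic and the
# cutpoint scan: per distinct event time, total at-risk and event counts.
risk_table <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  list(
    event_times = et,
    n = vapply(et, function(t) sum(time >= t), 0),
    d = vapply(et, function(t) sum(time == t & event == 1), 0)
  )
}

#' Log-rank test for k >= 2 groups, with O/E hazard ratio for k = 2
#'
#' Observed and expected event counts per group accumulate over the
#' pooled distinct event times; the statistic is the usual quadratic form
#' in `(O - E)` with the hypergeometric covariance, referred to
#' chi-squared with `k - 1` degrees of freedom. For two groups this
#' reduces exactly to `U^2 / V` with
#' `U = O_1 - E_1` and `V` the summed hypergeometric variances.
#'
#' The hazard ratio follows the log-rank (Mantel-Haenszel style)
#' observed-over-expected convention,
#' `HR = (O_1/E_1) / (O_2/E_2)`, with
#' `log HR +/- 1.96 * sqrt(1/E_1 + 1/E_2)` as the 95% CI — no
#' proportional-hazards regression is fitted anywhere.
#'
#' @param time,event Pooled survival records.
#' @param group Group labels (factor or vector coercible to factor) with
#'   k >= 2 levels present.
#' @return List: `statistic` (chi-squared), `df`, `p_value`, `observed`,
#'   `expected` (named per group), `variance` (of `O_1 - E_1`, two-group
#'   case), `hazard_ratio`, `hr_ci` (two-group case, else `NA`).
#' @export
logrank_test <- function(time, event, group) {
  validate_survival(time, event)
  group <- factor(group)
  group <- droplevels(group)
  k <- nlevels(group)
  if (k < 2) stop("need at least two groups with members")
  if (sum(event) == 0) stop("log-rank statistic undefined: no events")
  rt <- risk_table(time, event)
  J <- length(rt$event_times)
  lev <- levels(group)
  O <- E <- stats::setNames(numeric(k), lev)
  V <- matrix(0, k, k, dimnames = list(lev, lev))
  for (j in seq_len(J)) {
    t_j <- rt$event_times[j]
    at_risk <- time >= t_j
    n_j <- rt$n[j]
    d_j <- rt$d[j]
    n_gj <- vapply(lev, function(g) sum(at_risk & group == g), 0)
    d_gj <- vapply(lev, function(g) sum(time == t_j & event == 1 &
                                          group == g), 0)
    O <- O + d_gj
    E <- E + d_j * n_gj / n_j
    if (n_j > 1) {
      mult <- d_j * (n_j - d_j) / (n_j - 1)
      p_g <- n_gj / n_j
      V <- V + mult * (diag(p_g, nrow = k) - outer(p_g, p_g))
    }
  }
  # quadratic form on the first k-1 groups (the covariance is singular)
  idx <- seq_len(k - 1)
  u <- (O - E)[idx]
  Vsub <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vsub, u)),
                   error = function(e) NA_real_)
  hr <- hr_ci <- NA
  if (k == 2) {
    hr <- (O[1] / E[1]) / (O[2] / E[2])
    se <- sqrt(1 / E[1] + 1 / E[2])
    hr_ci <- exp(log(hr) + c(-1.96, 1.96) * se)
    names(hr_ci) <- c("lower", "upper")
  }
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       observed = O, expected = E,
       variance = if (k == 2) V[1, 1] else V,
       hazard_ratio = unname(hr), hr_ci = hr_ci)
}

# Standardized two-group log-rank statistic |U|/sqrt(V) for every
# candidate cutoff at once ("high" = value >= cutoff). Vectorized over
# candidates via at-risk/event indicator matrices.
logrank_scan <- function(values, time, event, candidates) {
  rt <- risk_table(time, event)
  J <- length(rt$event_times)
  C <- length(candidates)
  R <- outer(rt$event_times, time, FUN = function(a, b) b >= a) + 0
  D <- outer(rt$event_times, time,
             FUN = function(a, b) b == a) * rep(event, each = J)
  G <- outer(values, candidates, FUN = ">=") + 0
  n1 <- R %*% G                     # J x C at-risk in "high"
  d1 <- D %*% G                     # J x C events in "high"
  n_j <- rt$n
  d_j <- rt$d
  U <- colSums(d1 - d_j * n1 / n_j)
  p1 <- n1 / n_j
  vmult <- ifelse(n_j > 1, d_j * (n_j - d_j) / (n_j - 1), 0)
  V <- colSums(vmult * p1 * (1 - p1))
  stat <- ifelse(V > 0, abs(U) / sqrt(V), 0)
  data.frame(cutoff = candidates, statistic = stat, u = U, v = V)
}

#' Maximally selected rank-statistic cutpoint
#'
#' Scans every admissible observed value of a continuous per-patient
#' feature as a candidate cutoff, computes the standardized two-group
#' log-rank statistic `|U|/sqrt(V)` for the induced "high" (value >=
#' cutoff) vs "low" split, and returns the cutoff maximizing the
#' statistic. A candidate is admissible when both induced groups contain
#' at least `minprop * n` patients. Ties in the maximum are broken toward
#' the smallest cutoff.
#'
#' The p-value is computed by permutation: the pairing between feature
#' values and survival outcomes is permuted `B` times, the maximal
#' statistic recomputed each time, and
#' `p = (1 + #{perm >= observed}) / (B + 1)`. Set `B = 0` to skip the
#' permutation (p is then `NA`). This selection-adjusted p-value is exact
#' by simulation and makes no distributional approximation.
#'
#' @param values Per-patient continuous feature (e.g., a subset
#'   percentage).
#' @param time,event Survival records aligned with `values`.
#' @param minprop Minimum fraction of patients on each side of an
#'   admissible split (0 < minprop < 0.5; default 0.1).
#' @param B Number of permutations for the p-value (default 1000).
#' @param seed Optional integer seed for the permutation draw; the
#'   global RNG state is restored afterwards.
#' @return List of class `cutpoint_result`: `cutoff`, `statistic`
#'   (standardized), `p_value`, `minprop`, `n`, `scan` (per-candidate
#'   table), `B`.
#' @export
max_selected_cutpoint <- function(values, time, event, minprop = 0.1,
                                  B = 1000L, seed = NULL) {
  validate_survival(time, event)
  keep <- !is.na(values)
  if (any(!keep)) {
    message("max_selected_cutpoint: excluding ", sum(!keep),
            " record(s) with missing feature values")
    values <- values[keep]
    time <- time[keep]
    event <- event[keep]
  }
  n <- length(values)
  if (n < 10) stop("need at least 10 patients for cutpoint selection")
  if (length(unique(values)) < 2) {
    stop("no cutpoint: feature is constant")
  }
  if (minprop <= 0 || minprop >= 0.5) stop("minprop must be in (0, 0.5)")
  min_n <- ceiling(minprop * n)
  cand <- sort(unique(values))
  n_high <- vapply(cand, function(c) sum(values >= c), 0)
  admissible <- cand[n_high >= min_n & (n - n_high) >= min_n]
  if (length(admissible) == 0) {
    stop("no cutpoint: no candidate split satisfies minprop = ", minprop)
  }
  scan <- logrank_scan(values, time, event, admissible)
  best <- which(scan$statistic == max(scan$statistic))[1]
  obs_stat <- scan$statistic[best]
  p <- NA_real_
  if (B > 0) {
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (is.null(old_seed)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", old_seed, envir = globalenv())
        }
      }, add = TRUE)
      set.seed(seed)
    }
    exceed <- 0L
    for (b in seq_len(B)) {
      perm <- sample.int(n)
      pm <- logrank_scan(values[perm], time, event, admissible)
      if (max(pm$statistic) >= obs_stat) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (B + 1)
  }
  structure(list(cutoff = scan$cutoff[best], statistic = obs_stat,
                 p_value = p, minprop = minprop, n = n, scan = scan,
                 B = B),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("Maximally selected cutpoint: ", x$cutoff,
      " (standardized log-rank statistic ", round(x$statistic, 3), ")\n",
      sep = "")
  if (!is.na(x$p_value)) {
    cat("permutation p (B = ", x$B, "): ", x$p_value, "\n", sep = "")
  }
  invisible(x)
}

#' Dichotomize a feature at a cutoff
#'
#' Values at or above the cutoff are labelled `"high"`, below `"low"`
#' (strata are conventionally reported as ">= cutoff vs. < cutoff").
#' Missing values stay missing (a message reports how many) — they are
#' excluded downstream, never imputed.
#'
#' @param values Numeric vector.
#' @param cutoff Finite cutoff.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(values, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  if (any(is.na(values))) {
    message("dichotomize: ", sum(is.na(values)),
            " missing value(s) left NA (excluded downstream)")
  }
  factor(ifelse(values >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Stratified survival analysis
#'
#' Kaplan-Meier curve and median per stratum plus all pairwise log-rank
#' comparisons (chi-squared, p, O/E hazard ratio with 95% CI). Strata
#' with fewer than two patients are flagged and excluded from the
#' pairwise tests.
#'
#' @param time,event Survival records.
#' @param strata Stratum labels aligned with the records.
#' @return List: `strata` (data.frame: stratum, n, events, median,
#'   excluded flag), `pairwise` (data.frame: stratum_a, stratum_b,
#'   chi_square, p_value, hazard_ratio, hr_lower, hr_upper), `curves`
#'   (named list of `km_curve`s).
#' @export
stratified_analysis <- function(time, event, strata) {
  validate_survival(time, event)
  strata <- factor(strata)
  lev <- levels(droplevels(strata))
  info <- data.frame(stratum = lev, n = NA_integer_, events = NA_integer_,
                     median = NA_real_, excluded = FALSE,
                     stringsAsFactors = FALSE)
  curves <- list()
  for (i in seq_along(lev)) {
    sel <- strata == lev[i]
    info$n[i] <- sum(sel)
    info$events[i] <- sum(event[sel])
    if (sum(sel) < 2) {
      info$excluded[i] <- TRUE
      next
    }
    curves[[lev[i]]] <- km_curve(time[sel], event[sel])
    info$median[i] <- curves[[lev[i]]]$median
  }
  usable <- info$stratum[!info$excluded]
  pw <- NULL
  if (length(usable) >= 2) {
    combos <- utils::combn(usable, 2)
    rows <- vector("list", ncol(combos))
    for (j in seq_len(ncol(combos))) {
      a <- combos[1, j]; b <- combos[2, j]
      sel <- strata %in% c(a, b)
      res <- tryCatch(
        logrank_test(time[sel], event[sel],
                     factor(as.character(strata[sel]), levels = c(a, b))),
        error = function(e) NULL
      )
      rows[[j]] <- data.frame(
        stratum_a = a, stratum_b = b,
        chi_square = if (is.null(res)) NA_real_ else res$statistic,
        p_value = if (is.null(res)) NA_real_ else res$p_value,
        hazard_ratio = if (is.null(res)) NA_real_ else res$hazard_ratio,
        hr_lower = if (is.null(res)) NA_real_ else res$hr_ci[["lower"]],
        hr_upper = if (is.null(res)) NA_real_ else res$hr_ci[["upper"]],
        stringsAsFactors = FALSE
      )
    }
    pw <- do.call(rbind, rows)
  }
  list(strata = info, pairwise = pw, curves = curves)
}
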