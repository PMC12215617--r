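new_kiss_test <- function(statistic_name, statistic_value, p_raw,
                          method, mean_rank_delta = NA_real_,
                          df = NULL, n = NULL, extra = list()) {
  structure(c(list(statistic_name = statistic_name,
                   statistic_value = statistic_value,
                   mean_rank_delta = mean_rank_delta,
                   p_raw = p_raw, p_adjusted = NA_real_,
                   family_size = NA_integer_, df = df, n = n,
                   method = method), extra),
            class = "kiss_test")
}

#' @export
print.kiss_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  %s = %.4g", x$statistic_name, x$statistic_value))
  if (!is.null(x$df)) cat(sprintf(", df = %s", paste(round(x$df, 2),
                                                     collapse = ", ")))
  if (is.finite(x$mean_rank_delta))
    cat(sprintf(", mean rank delta = %.4g", x$mean_rank_delta))
  cat(sprintf(", p = %.4g", x$p_raw))
  if (is.finite(x$p_adjusted))
    cat(sprintf(" (adjusted %.4g, family %d)", x$p_adjusted, x$family_size))
  cat("\n")
  invisible(x)
}

# midranks (average ranks for ties)
midranks <- function(x) rank(x, ties.method = "average")

# distribution of the positive-signed-rank sum over all 2^n sign assignments,
# by dynamic programming over doubled midranks (exact, ties included)
signed_rank_exact_p <- function(ranks2, w2_obs) {
  total <- sum(ranks2)
  counts <- numeric(total + 1)           # index s+1 holds #assignments with sum s
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(ranks2)
  lo <- sum(probs[seq_len(w2_obs + 1)])          # P(W+ <= obs)
  hi <- sum(probs[(w2_obs + 1):(total + 1)])     # P(W+ >= obs)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Reports the statistic as the absolute sum of signed ranks (the printed-W
#' convention), with an exact two-sided p-value by full enumeration of the
#' 2^n sign assignments (dynamic programming, ties included via midranks) for
#' n <= `exact_max`, and a tie-corrected normal approximation with continuity
#' correction above.  Zero differences are dropped.
#'
#' @param before,after paired observations, equal length (one value per
#'   unit).
#' @param exact_max largest n for exact enumeration (default 25).
#' @return a `kiss_test` with `statistic_value` = |sum of signed ranks| and
#'   extras `w_plus`, `signed_rank_sum`, `n_used`, `exact`.
#' @examples
#' wilcoxon_signed_rank(before = c(20, 25, 18, 30, 24, 21),
#'                      after  = c(5, 6, 4, 8, 6, 5))   # W = 21, p = 0.03125
#' @export
wilcoxon_signed_rank <- function(before, after, exact_max = 25) {
  if (length(before) != length(after))
    stop_input("'before' and 'after' must have equal length")
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) stop_input("need at least 2 non-zero differences")
  r <- midranks(abs(d))
  signed_sum <- sum(sign(d) * r)
  w_plus <- sum(r[d > 0])
  exact <- n <= exact_max
  if (exact) {
    ranks2 <- round(2 * r)
    p <- signed_rank_exact_p(ranks2, round(2 * w_plus))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  new_kiss_test("W", abs(signed_sum), p,
                sprintf("Wilcoxon matched-pairs signed-rank test (%s, n = %d)",
                        if (exact) "exact" else "normal approximation", n),
                n = n,
                extra = list(w_plus = w_plus, signed_rank_sum = signed_sum,
                             n_used = n, exact = exact))
}

# distribution of group-2 rank sum over all choose(N, n2) assignments,
# by DP over doubled pooled midranks (exact, ties included)
rank_sum_exact_p <- function(ranks2, n2, r2_obs) {
  total <- sum(ranks2)
  # dp[k+1, s+1] = #subsets of size k with doubled-rank sum s
  dp <- matrix(0, nrow = n2 + 1, ncol = total + 1)
  dp[1, 1] <- 1
  for (r in ranks2) {
    for (k in n2:1) {
      shifted <- c(rep(0, r), dp[k, seq_len(total + 1 - r)])
      dp[k + 1, ] <- dp[k + 1, ] + shifted
    }
  }
  counts <- dp[n2 + 1, ]
  tot <- sum(counts)
  lo <- sum(counts[seq_len(r2_obs + 1)]) / tot
  hi <- sum(counts[(r2_obs + 1):(total + 1)]) / tot
  min(1, 2 * min(lo, hi))
}

#' Mann-Whitney U test
#'
#' Reports U = min(U1, U2) and the mean rank difference (mean rank of group 2
#' minus mean rank of group 1 on the pooled ranking), with an exact two-sided
#' p-value by enumeration of the rank-sum permutation distribution (dynamic
#' programming, ties included) for n1 + n2 <= `exact_max`, and a
#' tie-corrected normal approximation above.
#'
#' @param group1,group2 observation vectors (both non-empty).
#' @param exact_max largest combined n for exact enumeration (default 20).
#' @return a `kiss_test` with `statistic_value` = U and `mean_rank_delta`;
#'   extras `u1`, `u2`, `exact`.
#' @examples
#' mann_whitney(group1 = 11:24, group2 = 1:4)  # U = 0, mean rank delta = -9
#' @export
mann_whitney <- function(group1, group2, exact_max = 20) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 1 || n2 < 1) stop_input("both groups must be non-empty")
  pooled <- c(group1, group2)
  r <- midranks(pooled)
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  u1 <- sum(r1) - n1 * (n1 + 1) / 2
  u2 <- sum(r2) - n2 * (n2 + 1) / 2
  u <- min(u1, u2)
  mrd <- mean(r2) - mean(r1)
  exact <- (n1 + n2) <= exact_max
  if (exact) {
    p <- rank_sum_exact_p(round(2 * r), n2, round(2 * sum(r2)))
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    N <- n1 + n2
    v <- n1 * n2 / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  new_kiss_test("U", u, p,
                sprintf("Mann-Whitney U test (%s, n1 = %d, n2 = %d)",
                        if (exact) "exact" else "normal approximation", n1, n2),
                mean_rank_delta = mrd, n = c(n1, n2),
                extra = list(u1 = u1, u2 = u2, exact = exact))
}

#' Holm-Sidak step-down multiplicity adjustment
#'
#' Sorts raw p-values ascending and sets
#' `adjusted_(i) = 1 - (1 - p_(i))^(k - i + 1)` with `k = family_size`,
#' enforcing monotone non-decreasing adjusted values, returned in the
#' original order.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param family_size comparison family size `k`; at least `length(p_values)`
#'   (defaults to it).
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_sidak_adjust(c(6.54e-4), family_size = 4)  # ~2.6e-3
#' @export
holm_sidak_adjust <- function(p_values, family_size = length(p_values)) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop_input("p-values must lie in [0, 1]")
  k <- as.integer(family_size)
  m <- length(p_values)
  if (k < m) stop_input("family_size must be >= the number of p-values")
  ord <- order(p_values)
  ps <- p_values[ord]
  adj <- 1 - (1 - ps)^(k - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# attach an adjusted p to a kiss_test
adjust_test <- function(test, p_adjusted, family_size) {
  test$p_adjusted <- p_adjusted
  test$family_size <- as.integer(family_size)
  test
}

#' Paired and unpaired two-sample t-tests
#'
#' Thin wrappers around [stats::t.test()] returning the package's uniform
#' result object.  The unpaired variant first tests homogeneity of variance
#' with an F-test at the 0.05 level and uses the pooled-variance t-test when
#' homogeneity is not rejected, Welch's otherwise; the F-test outcome is
#' recorded in the method string.
#'
#' @param before,after paired observations (paired variant).
#' @param group1,group2 independent samples (unpaired variant).
#' @return a `kiss_test` with `statistic_value` = t, `df`, `p_raw`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after) || length(before) < 2)
    stop_input("paired t-test needs >= 2 complete pairs")
  if (sd(after - before) == 0)
    stop_input("zero-variance differences: t-test undefined")
  ht <- t.test(after, before, paired = TRUE)
  new_kiss_test("t", unname(ht$statistic), ht$p.value,
                "Two-tailed paired t-test", df = unname(ht$parameter),
                n = length(before))
}

#' @rdname paired_t
#' @export
unpaired_t <- function(group1, group2) {
  if (length(group1) < 2 || length(group2) < 2)
    stop_input("unpaired t-test needs >= 2 observations per group")
  if (sd(group1) == 0 && sd(group2) == 0)
    stop_input("zero variance in both groups: t-test undefined")
  ftest <- tryCatch(var.test(group1, group2), error = function(e) NULL)
  homogeneous <- !is.null(ftest) && ftest$p.value >= 0.05
  ht <- t.test(group1, group2, var.equal = homogeneous)
  new_kiss_test("t", unname(ht$statistic), ht$p.value,
                sprintf("Two-tailed unpaired t-test (%s; F-test p = %s)",
                        if (homogeneous) "pooled variance" else "Welch",
                        if (is.null(ftest)) "NA" else
                          format(ftest$p.value, digits = 3)),
                df = unname(ht$parameter), n = c(length(group1),
                                                 length(group2)))
}

#' One-way repeated-measures ANOVA with Holm-Sidak post-hoc contrasts
#'
#' Fits the standard within-subject one-way ANOVA (F on (k-1, (k-1)(n-1))
#' degrees of freedom via `aov` with an `Error(unit)` stratum) and follows it
#' with all pairwise condition contrasts as paired t-tests adjusted by
#' [holm_sidak_adjust()].
#'
#' @param m numeric matrix, units (rows) by conditions (columns), complete
#'   (no missing cells; no imputation is performed).
#' @return a `kiss_test` with `statistic_value` = F, `df`, `p_raw` and a
#'   `posthoc` data.frame (`contrast`, `t`, `p_raw`, `p_adjusted`).
#' @export
rm_one_way_anova <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop_input("missing cells: repeated-measures ANOVA requires ",
                           "a complete matrix (no imputation)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop_input("need >= 2 units and >= 2 conditions")
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(k))
  ss_cond <- n * sum((colMeans(m) - mean(m))^2)
  if (ss_cond < 1e-12 * max(1, sum((m - mean(m))^2))) {
    res <- new_kiss_test("F", 0, 1,
      "One-way repeated-measures ANOVA (degenerate: no condition effect)",
      df = c(k - 1, (k - 1) * (n - 1)), n = n)
  } else {
    d <- data.frame(value = as.vector(m),
                    condition = factor(rep(colnames(m), each = n)),
                    unit = factor(rep(seq_len(n), k)))
    fit <- aov(value ~ condition + Error(unit), data = d)
    tab <- summary(fit)[["Error: Within"]][[1]]
    res <- new_kiss_test("F", tab["condition", "F value"],
                         tab["condition", "Pr(>F)"],
                         "One-way repeated-measures ANOVA",
                         df = unname(tab[, "Df"]), n = n)
  }
  pairs <- utils::combn(colnames(m), 2)
  ph <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (sd(m[, b] - m[, a]) == 0)
      return(data.frame(contrast = paste(a, "vs", b), t = 0, p_raw = 1))
    ht <- t.test(m[, b], m[, a], paired = TRUE)
    data.frame(contrast = paste(a, "vs", b), t = unname(ht$statistic),
               p_raw = ht$p.value)
  })
  ph <- do.call(rbind, ph)
  ph$p_adjusted <- holm_sidak_adjust(ph$p_raw)
  res$posthoc <- ph
  res
}

#' Leave-one-animal-out sensitivity analysis
#'
#' Re-runs a test with each animal's full set of observations excluded in
#' turn, reporting the per-exclusion statistic and p-value, so that no single
#' animal can drive a conclusion.
#'
#' @param values_by_animal named list: per animal, the observations (any
#'   structure the `test` function accepts when concatenated with `c()` /
#'   `rbind()` — by default a numeric vector or a data.frame).
#' @param test function taking the pooled remaining data (list of per-animal
#'   elements) and returning a `kiss_test`.
#' @return class `loao_result`: data.frame with `excluded`, `statistic`,
#'   `p_raw`, `note` (exclusions where the test could not run are flagged and
#'   skipped, not silently dropped).
#' @examples
#' vals <- list(a1 = c(-9, -8), a2 = c(-10, -7), a3 = c(-11, -9))
#' leave_one_animal_out(vals, function(rest)
#'   wilcoxon_signed_rank(before = rep(0, length(unlist(rest))),
#'                        after = unlist(rest)))
#' @export
leave_one_animal_out <- function(values_by_animal, test) {
  if (!is.list(values_by_animal) || is.null(names(values_by_animal)))
    stop_input("values_by_animal must be a named list")
  if (length(values_by_animal) < 3)
    stop_input("need at least 3 animals")
  rows <- lapply(names(values_by_animal), function(a) {
    rest <- values_by_animal[names(values_by_animal) != a]
    res <- tryCatch(test(rest), error = function(e)
      structure(list(msg = conditionMessage(e)), class = "loao_skip"))
    if (inherits(res, "loao_skip")) {
      data.frame(excluded = a, statistic = NA_real_, p_raw = NA_real_,
                 note = paste("skipped:", res$msg))
    } else {
      data.frame(excluded = a, statistic = res$statistic_value,
                 p_raw = res$p_raw, note = "")
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("loao_result", "data.frame")
  res
}
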