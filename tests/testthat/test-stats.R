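test_that("signed-rank test reproduces the printed all-decreasing case", {
  # six pairs, every difference negative: W = 21, exact p = 2/64
  res <- wilcoxon_signed_rank(before = c(20, 25, 18, 30, 24, 21),
                              after = c(5, 6, 4, 8, 6, 5))
  expect_equal(res$statistic_value, 21)
  expect_equal(res$p_raw, 2 / 64)
  expect_true(res$exact)

  # balanced alternating differences: W near 0, p = 1
  res <- wilcoxon_signed_rank(before = rep(0, 6),
                              after = c(1, -1, 2, -2, 3, -3))
  expect_equal(res$statistic_value, 0)
  expect_equal(res$p_raw, 1)

  # zero differences are dropped; all-zero is a no-test error
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "non-zero")
})

test_that("signed-rank exact p matches literal 2^n enumeration", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, 0.3, 1), 2)
    d <- d[d != 0]
    if (length(d) < 4) next
    res <- wilcoxon_signed_rank(before = rep(0, length(d)), after = d)
    expect_equal(res$p_raw, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
  # with ties in |d|
  d <- c(1, -1, 2, 2, -3, 4, 4, -4)
  res <- wilcoxon_signed_rank(rep(0, 8), d)
  expect_equal(res$p_raw, oracle_signed_rank_p(d), tolerance = 1e-12)
})

test_that("Mann-Whitney reports U, mean rank delta and exact p", {
  # complete separation 14 vs 4 and 14 vs 3 (printed cases)
  r <- mann_whitney(group1 = 101:114, group2 = 1:4)
  expect_equal(r$statistic_value, 0)
  expect_equal(r$mean_rank_delta, -9.0)
  expect_equal(r$p_raw, 2 / choose(18, 4), tolerance = 1e-12)

  r <- mann_whitney(group1 = 101:114, group2 = 1:3)
  expect_equal(r$statistic_value, 0)
  expect_equal(r$mean_rank_delta, -8.5)

  # identical groups: zero mean rank difference
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$mean_rank_delta, 0)
})

test_that("Mann-Whitney exact p matches literal subset enumeration", {
  set.seed(13)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    g1 <- round(rnorm(n1), 1); g2 <- round(rnorm(n2, 0.5), 1)
    res <- mann_whitney(g1, g2)
    expect_equal(res$p_raw, oracle_ranksum_p(g1, g2), tolerance = 1e-12)
  }
})

test_that("complete separation gives U = 0 and |mean rank delta| = N/2", {
  for (n1 in c(2, 5, 9, 14, 20)) for (n2 in c(1, 3, 8, 16)) {
    g1 <- seq(100, 100 + n1 - 1)
    g2 <- seq(1, n2)
    r <- mann_whitney(g1, g2)
    expect_equal(r$statistic_value, 0)
    expect_equal(abs(r$mean_rank_delta), (n1 + n2) / 2)
  }
})

test_that("rank tests are invariant to common monotone rescaling", {
  set.seed(3)
  b <- rnorm(8); a <- rnorm(8, -1)
  r1 <- wilcoxon_signed_rank(b, a)
  r2 <- wilcoxon_signed_rank(3 * b + 2, 3 * a + 2)
  expect_equal(r1$statistic_value, r2$statistic_value)
  expect_equal(r1$p_raw, r2$p_raw)
  m1 <- mann_whitney(b, a)
  m2 <- mann_whitney(3 * b + 2, 3 * a + 2)
  expect_equal(m1$statistic_value, m2$statistic_value)
  expect_equal(m1$p_raw, m2$p_raw)
})

test_that("Holm-Sidak adjustment follows the step-down closed form", {
  # single p with family 1 is unchanged
  expect_equal(holm_sidak_adjust(0.04), 0.04, tolerance = 1e-12)
  # the printed antagonist family: p = 6.54e-4, k = 4
  p <- 2 / choose(18, 4)
  expect_equal(holm_sidak_adjust(p, family_size = 4),
               1 - (1 - p)^4, tolerance = 1e-12)
  # all ones stay one; order is preserved; monotone and never below raw
  expect_equal(holm_sidak_adjust(rep(1, 3)), rep(1, 3))
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(6)
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(holm_sidak_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(holm_sidak_adjust(c(0.1, 0.2), family_size = 1), "family_size")
})

test_that("t-test wrappers report the standard statistics", {
  # identical independent groups: t = 0, p = 1
  r <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic_value, 0)
  expect_equal(r$p_raw, 1)
  expect_match(r$method, "pooled")

  # textbook two-sample case, hand-computed pooled t
  g1 <- c(5, 7, 9); g2 <- c(1, 2, 3)
  sp2 <- (2 * var(g1) + 2 * var(g2)) / 4
  t_hand <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  r <- unpaired_t(g1, g2)
  expect_equal(r$statistic_value, t_hand, tolerance = 1e-12)
  expect_equal(r$p_raw, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)

  # constant-shift pairs have zero-variance differences: no-test error
  expect_error(paired_t(c(1, 2, 3), c(3, 4, 5)), "zero-variance")
  expect_error(unpaired_t(rep(1, 3), rep(2, 3)), "zero variance")
})

test_that("repeated-measures ANOVA matches its algebraic identities", {
  # no condition effect: F = 0, p = 1
  m <- matrix(rep(c(3, 5, 9, 2), 3), ncol = 3)
  r <- rm_one_way_anova(m)
  expect_equal(r$statistic_value, 0)
  expect_equal(r$p_raw, 1)

  # two conditions reduce to the paired t-test: F = t^2
  set.seed(21)
  m <- cbind(rnorm(8), rnorm(8, 1))
  colnames(m) <- c("veh", "cno")
  r <- rm_one_way_anova(m)
  t_ref <- t.test(m[, 2], m[, 1], paired = TRUE)
  expect_equal(r$statistic_value, unname(t_ref$statistic)^2, tolerance = 1e-9)
  expect_equal(r$p_raw, t_ref$p.value, tolerance = 1e-9)
  expect_equal(unname(r$df), c(1, 7))

  # missing cells are rejected, not imputed
  m[2, 1] <- NA
  expect_error(rm_one_way_anova(m), "missing")
})

test_that("repeated-measures ANOVA holds its nominal type-I error", {
  set.seed(31)
  reject <- logical(1000)
  for (i in seq_along(reject)) {
    m <- matrix(rnorm(6 * 3) + rnorm(6), ncol = 3)  # unit effects, no condition
    reject[i] <- rm_one_way_anova(m)$p_raw < 0.05
  }
  # binomial 3 SE band around 0.05 at 1000 replicates
  expect_lt(abs(mean(reject) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 1e-9)
})

test_that("leave-one-animal-out excludes whole animals and flags failures", {
  wtest <- function(rest) {
    v <- unlist(rest)
    wilcoxon_signed_rank(before = rep(0, length(v)), after = v)
  }
  # identical animals: identical exclusion results
  vals <- rep(list(c(-2, -3, -1.5)), 4)
  names(vals) <- paste0("a", 1:4)
  r <- leave_one_animal_out(vals, wtest)
  expect_equal(length(unique(r$p_raw)), 1L)
  expect_equal(length(unique(r$statistic)), 1L)

  # one outlier animal: its exclusion is the one that differs most
  vals <- list(a1 = c(-2, -2.5), a2 = c(-2.2, -1.9), a3 = c(-2.4, -2.1),
               a4 = c(8, 9, 10))
  r <- leave_one_animal_out(vals, wtest)
  expect_equal(r$excluded[which.min(r$p_raw)], "a4")

  # a simulated uniform-effect cohort: p < 1e-4 for every exclusion
  set.seed(8)
  cohort <- lapply(1:32, function(i) rnorm(sample(1:3, 1), -4, 1))
  names(cohort) <- paste0("m", 1:32)
  r <- leave_one_animal_out(cohort, wtest)
  expect_true(all(r$p_raw < 1e-4))

  # exclusions that leave too little data are flagged and skipped
  vals <- list(a1 = c(-1, -2), a2 = numeric(0), a3 = numeric(0))
  r <- leave_one_animal_out(vals, wtest)
  expect_match(r$note[r$excluded == "a1"], "skipped")
  expect_error(leave_one_animal_out(list(a = 1, b = 2), wtest), "3 animals")
})
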