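test_that("paired permutation p equals exhaustive sign-flip enumeration", {
  x <- c(0.50, 0.48, 0.55, 0.61)
  y <- c(0.59, 0.50, 0.56, 0.70)
  res <- paired_permutation_test(x, y, n_perm = 5000L, n_boot = 500L, seed = 1L)
  expect_true(res$exhaustive)

  # independent enumeration over all 2^4 sign patterns
  d <- y - x
  obs <- mean(d)
  count <- 0L
  for (b in 0:15) {
    signs <- ifelse(bitwAnd(b, 2^(0:3)) > 0, -1, 1)
    if (abs(mean(signs * d)) >= abs(obs) - 1e-12) count <- count + 1L
  }
  expect_equal(res$p_value, count / 16)

  # n = 10 pairs still exhaustive and still exact
  set.seed(4)
  x10 <- rnorm(10L); y10 <- x10 + rnorm(10L, 0.3, 0.4)
  res10 <- paired_permutation_test(x10, y10, n_perm = 5000L, n_boot = 500L,
                                   seed = 2L)
  expect_true(res10$exhaustive)
  d <- y10 - x10
  count <- 0L
  for (b in 0:(2^10 - 1)) {
    signs <- ifelse(bitwAnd(b, 2^(0:9)) > 0, -1, 1)
    if (abs(mean(signs * d)) >= abs(mean(d)) - 1e-12) count <- count + 1L
  }
  expect_equal(res10$p_value, count / 2^10)
})

test_that("degenerate and guard cases of the permutation test", {
  x <- c(1, 2, 3, 4)
  res <- paired_permutation_test(x, x, seed = 1L, n_boot = 200L)
  expect_identical(res$mean_diff, 0)
  expect_identical(res$p_value, 1)
  expect_identical(c(res$ci_low, res$ci_high), c(0, 0))
  expect_error(paired_permutation_test(1:2, 2:3), "sample-size")
  expect_error(paired_permutation_test(1:4, 1:5), "paired")
})

test_that("permutation test and BCa interval are seed-deterministic", {
  set.seed(8)
  x <- rnorm(20L); y <- x + rnorm(20L, 0.1)
  r1 <- paired_permutation_test(x, y, n_perm = 400L, n_boot = 400L, seed = 9L)
  r2 <- paired_permutation_test(x, y, n_perm = 400L, n_boot = 400L, seed = 9L)
  expect_identical(r1, r2)
  expect_false(r1$exhaustive)
  expect_gte(r1$p_value, 1 / 401)
  expect_true(r1$ci_low <= r1$mean_diff && r1$mean_diff <= r1$ci_high)
})

test_that("permutation test holds its type-I error rate under the null", {
  n_rep <- 400L
  n <- 12L
  set.seed(123)
  rej <- vapply(seq_len(n_rep), function(i) {
    x <- rnorm(n)
    y <- rnorm(n)
    paired_permutation_test(x, y, n_perm = 240L, n_boot = 50L,
                            seed = i)$p_value < 0.05
  }, logical(1L))
  rate <- mean(rej)
  # binomial 99.7% bounds around 0.05 (Monte-Carlo p-values are slightly
  # conservative with the add-one correction)
  bound <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(rate, 0.05 + bound)
  expect_gt(rate, 0.05 - bound - 1 / 240)
})

test_that("bonferroni adjusts, caps, and preserves order", {
  expect_equal(bonferroni(0.01, m = 5L), 0.05)
  expect_equal(bonferroni(0.5, m = 5L), 1.0)
  p <- c(0.001, 0.02, 0.04, 0.3)
  expect_identical(order(bonferroni(p, m = 10L)), order(p))
  expect_error(bonferroni(c(0.1, 0.2), m = 1L), "family size")
})

test_that("one-factor rm_anova matches aov with a subject error stratum", {
  set.seed(42)
  d <- expand.grid(subject = factor(1:6), session = factor(1:4))
  d$y <- 0.5 + 0.05 * as.integer(d$session) +
    rep(rnorm(6, 0, 0.1), 4) + rnorm(24, 0, 0.05)
  mine <- rm_anova(d, dv = "y", subject = "subject", within = "session")
  ref <- summary(aov(y ~ session + Error(subject / session), data = d))
  ref_tab <- ref[["Error: subject:session"]][[1L]]
  expect_equal(mine$F[1L], ref_tab["session", "F value"], tolerance = 1e-10)
  expect_equal(mine$p[1L], ref_tab["session", "Pr(>F)"], tolerance = 1e-10)
  expect_identical(c(mine$df_effect[1L], mine$df_error[1L]), c(3L, 15L))
})

test_that("two-factor rm_anova matches aov and is location invariant", {
  set.seed(17)
  d <- expand.grid(subject = factor(1:5), A = factor(1:3), B = factor(1:2))
  d$y <- rnorm(30) + rep(rnorm(5, 0, 0.5), 6) +
    0.3 * (d$A == "2") + 0.4 * (d$B == "2")
  mine <- rm_anova(d, dv = "y", subject = "subject", within = c("A", "B"))
  ref <- summary(aov(y ~ A * B + Error(subject / (A * B)), data = d))
  expect_equal(mine$F[mine$effect == "A"],
               ref[["Error: subject:A"]][[1L]]["A", "F value"],
               tolerance = 1e-10)
  expect_equal(mine$F[mine$effect == "B"],
               ref[["Error: subject:B"]][[1L]]["B", "F value"],
               tolerance = 1e-10)
  expect_equal(mine$F[mine$effect == "A:B"],
               ref[["Error: subject:A:B"]][[1L]]["A:B", "F value"],
               tolerance = 1e-10)

  d2 <- d
  d2$y <- d2$y + 100
  shifted <- rm_anova(d2, dv = "y", subject = "subject", within = c("A", "B"))
  expect_equal(shifted$F, mine$F, tolerance = 1e-8)

  # identical condition means per subject -> F ~ 0
  d3 <- expand.grid(subject = factor(1:4), A = factor(1:3))
  d3$y <- rep(rnorm(4), 3)
  flat <- rm_anova(d3, dv = "y", subject = "subject", within = "A")
  expect_lt(flat$F[1L], 1e-20)

  # unbalanced design is an error naming the cell
  expect_error(rm_anova(d[-1L, ], dv = "y", subject = "subject",
                        within = c("A", "B")),
               "design error")
})

test_that("rm_corr matches a brute-force ANCOVA by normal equations", {
  set.seed(5)
  d <- data.frame(subject = rep(c("a", "b", "c", "d"), each = 4L))
  d$x <- rnorm(16L)
  d$y <- 0.7 * d$x + rep(c(0, 1, 2, 3), each = 4L) + rnorm(16L, 0, 0.3)
  res <- rm_corr(d, "subject", "x", "y")

  # normal equations for y ~ subject dummies + common slope
  X <- cbind(model.matrix(~ 0 + factor(d$subject)), d$x)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  slope <- beta[5L]
  resid_full <- d$y - X %*% beta
  ss_err <- sum(resid_full^2)
  X0 <- X[, 1:4]
  resid_0 <- d$y - X0 %*% solve(t(X0) %*% X0, t(X0) %*% d$y)
  ss_x <- sum(resid_0^2) - ss_err
  r_oracle <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  df_oracle <- 16L - 4L - 1L
  F_oracle <- ss_x / (ss_err / df_oracle)
  expect_equal(res$r, r_oracle, tolerance = 1e-10)
  expect_identical(res$df, df_oracle)
  expect_equal(res$p, pf(F_oracle, 1, df_oracle, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("rm_corr recovers perfect within-subject association and nulls", {
  d <- data.frame(subject = rep(1:4, each = 5L), x = rep(1:5, 4L))
  d$y <- d$x + rep(c(0, 10, 20, 30), each = 5L)
  res <- rm_corr(d, "subject", "x", "y")
  expect_equal(res$r, 1, tolerance = 1e-12)

  # independent x, y: r near 0, p roughly uniform over replicates
  set.seed(77)
  ps <- replicate(200L, {
    dd <- data.frame(subject = rep(1:6, each = 6L),
                     x = rnorm(36L), y = rnorm(36L))
    rm_corr(dd, "subject", "x", "y")$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  d_bad <- rbind(d, data.frame(subject = 9L, x = 1, y = 1))
  expect_warning(rm_corr(d_bad, "subject", "x", "y"), "fewer than 2")
})

test_that("KS test matches a brute-force sup over pooled jump points", {
  set.seed(3)
  a <- rnorm(10L)
  b <- rnorm(10L, 0.5)
  res <- ks_two_sample(a, b)
  jumps <- sort(c(a, b))
  d_oracle <- max(abs(ecdf(a)(jumps) - ecdf(b)(jumps)))
  expect_equal(res$statistic, d_oracle, tolerance = 1e-12)

  same <- ks_two_sample(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(ks_two_sample(1:5, 6:10)$statistic, 1)
})

test_that("rank-sum test matches manual ranks and exact enumeration", {
  a <- c(1.2, 3.4, 0.8, 2.2)
  b <- c(2.9, 4.1, 3.8, 5.0)
  res <- ranksum(a, b)
  r <- rank(c(a, b))
  expect_equal(res$rank_sum, sum(r[1:4]))

  # exact null enumeration of the rank sum over all 4-subsets of ranks
  combos <- combn(8L, 4L)
  sums <- colSums(matrix(r[combos], nrow = 4L))
  p_exact <- mean(abs(sums - mean(sums)) >= abs(res$rank_sum - mean(sums)) - 1e-12)
  # normal approximation without continuity correction: close but not exact
  expect_lt(abs(res$p_value - p_exact), 0.05)

  # agreement with the reference normal-approximation implementation
  wt <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, wt$p.value, tolerance = 1e-10)

  expect_gt(ranksum(a, a)$p_value, 0.99)
  expect_lt(ranksum(a, a + 10)$p_value, 0.05)
})

test_that("spearman_pairwise is rank-based with monotone invariance", {
  set.seed(12)
  tab <- data.frame(u = rnorm(12L), v = rnorm(12L), w = rnorm(12L))
  res <- spearman_pairwise(tab)

  # brute-force rank computation
  rho_oracle <- cor(rank(tab$u), rank(tab$v))
  expect_equal(res$rho["u", "v"], rho_oracle, tolerance = 1e-12)

  tab2 <- tab
  tab2$u <- exp(tab2$u)                    # monotone transform
  res2 <- spearman_pairwise(tab2)
  expect_equal(res2$rho, res$rho, tolerance = 1e-12)

  tab3 <- data.frame(x = 1:6, y = (1:6)^3)
  expect_equal(spearman_pairwise(tab3)$rho["x", "y"], 1)

  tab4 <- data.frame(x = 1:6, y = rep(1, 6L))
  expect_true(is.na(spearman_pairwise(tab4)$rho["x", "y"]))
})
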