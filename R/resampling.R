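# Resampling and repeated-measures inference used throughout the pipeline:
# paired sign-flip permutation tests with BCa bootstrap intervals, Bonferroni
# correction, within-subject ANOVA from the definitional sums-of-squares
# partition, repeated-measures (ANCOVA) correlation, and the two-sample
# rank/distribution tests used by the ex-Gaussian fit validation.

#' Paired permutation test with BCa bootstrap confidence interval
#'
#' Tests the paired mean difference `mean(y - x)` against the null of zero
#' difference by sign-flipping each pair's difference. When the exhaustive
#' null (all `2^n` sign patterns) is no larger than `n_perm`, it is
#' enumerated exactly and the p-value is the exact proportion of patterns
#' with `|stat| >= |observed|`. Otherwise `n_perm` random sign patterns are
#' drawn and the add-one (Phipson-Smyth) correction is applied:
#' `p = (1 + #extreme) / (n_perm + 1)`.
#'
#' The 95% confidence interval for the mean difference comes from `n_boot`
#' paired bootstrap resamples with bias-corrected and accelerated (BCa)
#' endpoints; the acceleration constant is estimated by jackknife.
#'
#' @param x,y paired per-subject values (equal length, n >= 3).
#' @param n_perm number of sign-flip permutations (default 5000).
#' @param n_boot number of bootstrap resamples for the CI (default 5000).
#' @param seed integer seed; the caller's RNG stream is preserved.
#' @return An object of class `"permutation_test"`: `mean_diff`, `p_value`,
#'   `ci_low`, `ci_high`, `n_perm` (patterns actually evaluated),
#'   `exhaustive`, `n_boot`, `seed`, and `ci_contains_estimate`.
#' @examples
#' pre <- c(0.52, 0.49, 0.55, 0.61, 0.47)
#' post <- pre + c(0.08, 0.11, 0.09, 0.12, 0.10)
#' paired_permutation_test(pre, post, seed = 1)
#' @export
paired_permutation_test <- function(x, y, n_perm = 5000L, n_boot = 5000L,
                                    seed = NULL) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3L) stop("sample-size error: need at least 3 pairs, got ", n)
  if (anyNA(x) || anyNA(y)) stop("missing values in paired data")
  d <- y - x
  obs <- mean(d)
  eps <- 1e-12 * max(1, abs(obs))

  exhaustive <- n <= 30 && 2^n <= n_perm
  res <- with_seed(seed, {
    if (exhaustive) {
      m <- 2L^n
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      stats_null <- as.vector(signs %*% d) / n
      p <- mean(abs(stats_null) >= abs(obs) - eps)
      n_used <- m
    } else {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                      nrow = n_perm, ncol = n)
      stats_null <- as.vector(signs %*% d) / n
      p <- (1 + sum(abs(stats_null) >= abs(obs) - eps)) / (n_perm + 1)
      n_used <- n_perm
    }
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), nrow = n_boot)
    boot <- rowMeans(matrix(d[idx], nrow = n_boot))
    list(p = p, n_used = n_used, boot = boot)
  })

  ci <- .bca_interval(res$boot, obs, d, conf = 0.95)
  structure(list(
    mean_diff = obs,
    p_value = res$p,
    ci_low = ci[1L],
    ci_high = ci[2L],
    n_perm = res$n_used,
    exhaustive = exhaustive,
    n_boot = n_boot,
    seed = seed,
    ci_contains_estimate = ci[1L] <= obs && obs <= ci[2L]
  ), class = "permutation_test")
}

# BCa interval for the mean of `d` given bootstrap replicates `boot` of the
# observed statistic `obs`. Acceleration from the jackknife.
.bca_interval <- function(boot, obs, d, conf = 0.95) {
  alpha <- (1 - conf) / 2
  if (all(boot == boot[1L])) return(c(boot[1L], boot[1L]))
  nb <- length(boot)
  prop_less <- sum(boot < obs) / nb
  prop_less <- min(max(prop_less, 1 / (nb + 1)), nb / (nb + 1))
  z0 <- stats::qnorm(prop_less)
  n <- length(d)
  jack <- (sum(d) - d) / (n - 1)
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom < .Machine$double.eps) 0 else sum((jm - jack)^3) / (6 * denom)
  zlo <- stats::qnorm(alpha)
  zhi <- stats::qnorm(1 - alpha)
  a1 <- stats::pnorm(z0 + (z0 + zlo) / (1 - a * (z0 + zlo)))
  a2 <- stats::pnorm(z0 + (z0 + zhi) / (1 - a * (z0 + zhi)))
  unname(stats::quantile(boot, c(a1, a2), names = FALSE, type = 7))
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Paired permutation test (%s, %d patterns; BCa from %d resamples)\n",
              if (x$exhaustive) "exhaustive" else "Monte Carlo",
              x$n_perm, x$n_boot))
  cat(sprintf("  mean difference %.5g, 95%% CI [%.5g, %.5g], p = %.4g\n",
              x$mean_diff, x$ci_low, x$ci_high, x$p_value))
  if (!x$ci_contains_estimate) {
    cat("  note: BCa interval does not contain the point estimate\n")
  }
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p_values vector of raw p-values.
#' @param m size of the test family (must be >= `length(p_values)`).
#' @return adjusted p-values `pmin(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) stop("family size m must be >= number of tests")
  pmin(1, m * p_values)
}

#' Repeated-measures ANOVA with subject error terms
#'
#' One- or two-within-factor repeated-measures ANOVA on a complete balanced
#' long-format table (exactly one observation per subject x cell). Sums of
#' squares are computed from the cell and marginal means by the standard
#' within-subject partition; each effect is tested against its own
#' effect-by-subject interaction, `F = MS_effect / MS_(effect x subject)`.
#' No sphericity correction is applied.
#'
#' @param table long-format data.frame.
#' @param dv name of the response column.
#' @param subject name of the subject identifier column.
#' @param within character vector of one or two within-subject factor columns.
#' @return An object of class `"rm_anova"`: a data.frame with one row per
#'   effect (`effect`, `df_effect`, `df_error`, `F`, `p`).
#' @export
rm_anova <- function(table, dv, subject, within) {
  stopifnot(is.data.frame(table), length(within) %in% 1:2)
  for (col in c(dv, subject, within)) {
    if (!col %in% names(table)) stop("column not found: ", col)
  }
  y <- table[[dv]]
  if (anyNA(y)) stop("design error: missing response values")
  subj <- factor(table[[subject]])
  facs <- lapply(within, function(w) factor(table[[w]]))
  names(facs) <- within

  cell <- do.call(interaction, c(unname(facs), list(drop = FALSE)))
  counts <- table(subj, cell)
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)
    stop("design error: subject x cell not balanced/complete; e.g. subject '",
         rownames(counts)[bad[1, 1]], "' cell '", colnames(counts)[bad[1, 2]],
         "' has ", counts[bad[1, , drop = FALSE]], " observation(s)")
  }

  g <- mean(y)
  n <- nlevels(subj)
  cmean <- function(...) {
    args <- list(...)
    if (length(args) == 1L) tapply(y, args[[1L]], mean) else tapply(y, args, mean)
  }
  ss <- function(v) sum(v^2)
  rows <- list()
  add_row <- function(effect, ss_eff, df_eff, ss_err, df_err) {
    tol <- 1e-12 * (sum((y - g)^2) + 1)
    Fv <- if (ss_err <= tol) {
      if (ss_eff <= tol) 0 else Inf        # degenerate strata
    } else {
      (ss_eff / df_eff) / (ss_err / df_err)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = effect, df_effect = df_eff, df_error = df_err, F = Fv,
      p = stats::pf(Fv, df_eff, df_err, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }

  mS <- cmean(subj) - g
  if (length(facs) == 1L) {
    A <- facs[[1L]]
    a <- nlevels(A)
    mA <- cmean(A) - g
    ss_A <- n * ss(mA)
    mAS <- cmean(A, subj)
    ss_AS <- ss(sweep(sweep(mAS - g, 1L, mA, "-"), 2L, mS, "-"))
    add_row(within[1L], ss_A, a - 1L, ss_AS, (a - 1L) * (n - 1L))
  } else {
    A <- facs[[1L]]; B <- facs[[2L]]
    a <- nlevels(A); b <- nlevels(B)
    mA <- cmean(A) - g
    mB <- cmean(B) - g
    ss_A <- n * b * ss(mA)
    ss_B <- n * a * ss(mB)
    mAB <- cmean(A, B) - g
    dev_AB <- sweep(sweep(mAB, 1L, mA, "-"), 2L, mB, "-")
    ss_AB <- n * ss(dev_AB)
    mAS <- cmean(A, subj) - g
    ss_AS <- b * ss(sweep(sweep(mAS, 1L, mA, "-"), 2L, mS, "-"))
    mBS <- cmean(B, subj) - g
    ss_BS <- a * ss(sweep(sweep(mBS, 1L, mB, "-"), 2L, mS, "-"))
    ss_total <- ss(y - g)
    ss_S <- a * b * ss(mS)
    ss_ABS <- ss_total - ss_A - ss_B - ss_AB - ss_S - ss_AS - ss_BS
    ss_ABS <- max(ss_ABS, 0)
    add_row(within[1L], ss_A, a - 1L, ss_AS, (a - 1L) * (n - 1L))
    add_row(within[2L], ss_B, b - 1L, ss_BS, (b - 1L) * (n - 1L))
    add_row(paste(within, collapse = ":"), ss_AB, (a - 1L) * (b - 1L),
            ss_ABS, (a - 1L) * (b - 1L) * (n - 1L))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (error term by subject)\n")
  df <- as.data.frame(x)
  df$F <- sprintf("%.4f", df$F)
  df$p <- format.pval(df$p, digits = 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Repeated-measures correlation
#'
#' Common within-subject association between two repeatedly measured
#' variables, estimated by analysis of covariance: `y` is regressed on `x`
#' with subject-specific intercepts and a shared slope. The correlation is
#' `r = sign(slope) * sqrt(SS_x / (SS_x + SS_error))` where `SS_x` is the
#' sum of squares for `x` adjusted for subjects, with
#' `df = n_obs - n_subjects - 1`. The 95% CI uses the Fisher z transform
#' with standard error `1/sqrt(df - 1)`.
#'
#' @param table data.frame with repeated observations per subject.
#' @param subject,x,y column names.
#' @return An object of class `"rm_corr"`: `r`, `df`, `p`, `ci_low`,
#'   `ci_high`, `slope`, `n_obs`, `n_subjects`.
#' @export
rm_corr <- function(table, subject, x, y) {
  for (col in c(subject, x, y)) {
    if (!col %in% names(table)) stop("column not found: ", col)
  }
  d <- data.frame(s = factor(table[[subject]]), x = table[[x]], y = table[[y]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n_per <- table(d$s)
  few <- names(n_per)[n_per < 2L & n_per > 0L]
  if (length(few) > 0L) {
    warning("excluding subject(s) with fewer than 2 observations: ",
            paste(few, collapse = ", "))
    d <- d[!(as.character(d$s) %in% few), , drop = FALSE]
  }
  d$s <- droplevels(d$s)
  if (nlevels(d$s) < 3L) stop("need at least 3 subjects with repeated measures")

  fit <- stats::lm(y ~ s + x, data = d)
  reduced <- stats::lm(y ~ s, data = d)
  ss_err <- sum(stats::residuals(fit)^2)
  ss_x <- max(sum(stats::residuals(reduced)^2) - ss_err, 0)
  df <- stats::df.residual(fit)
  slope <- unname(stats::coef(fit)["x"])
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  Fv <- if (ss_err <= 1e-12 * (ss_x + ss_err + 1)) Inf else ss_x / (ss_err / df)
  p <- stats::pf(Fv, 1, df, lower.tail = FALSE)
  se_z <- 1 / sqrt(df - 1)
  zr <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  ci <- tanh(zr + c(-1, 1) * stats::qnorm(0.975) * se_z)
  structure(list(r = r, df = df, p = p, ci_low = ci[1L], ci_high = ci[2L],
                 slope = slope, n_obs = nrow(d), n_subjects = nlevels(d$s)),
            class = "rm_corr")
}

#' @export
print.rm_corr <- function(x, ...) {
  cat(sprintf("Repeated-measures correlation: r = %.4f, df = %d, p = %.4g, CI95%% [%.2f, %.2f]\n",
              x$r, x$df, x$p, x$ci_low, x$ci_high))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided sup-distance between the empirical CDFs of `a` and `b`;
#' p-value exact for small samples without ties, asymptotic otherwise
#' (delegates to [stats::ks.test()]).
#'
#' @param a,b numeric samples.
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Wilcoxon rank-sum test (normal approximation, tie corrected)
#'
#' Rank-sum z-test of identical location for two independent samples: the
#' pooled sample is mid-ranked, the rank sum of `a` is standardized with
#' the tie-corrected variance, and a two-sided normal p-value is returned
#' (no continuity correction, matching the conventional large-sample
#' rank-sums statistic).
#'
#' @param a,b numeric samples.
#' @return list with `statistic` (z), `rank_sum` (of `a`), and `p_value`.
#' @export
ranksum <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 > 0L, n2 > 0L)
  n <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(list(statistic = 0, rank_sum = w, p_value = 1))
  z <- (w - mu) / sqrt(v)
  list(statistic = z, rank_sum = w, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Pairwise Spearman rank correlations
#'
#' Spearman's rho between every pair of numeric columns with
#' pairwise-complete observations (average ranks for ties), with p-values
#' from the t approximation. Pairs with fewer than 3 complete rows or a
#' constant column yield `NA` entries.
#'
#' @param table data.frame of measures (numeric columns are used).
#' @return list of matrices `rho`, `p`, `n`.
#' @export
spearman_pairwise <- function(table) {
  num <- table[vapply(table, is.numeric, logical(1L))]
  k <- ncol(num)
  if (k < 2L) stop("need at least two numeric columns")
  nm <- names(num)
  rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- stats::complete.cases(num[[i]], num[[j]])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3L) next
      xi <- num[[i]][ok]; xj <- num[[j]][ok]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      ct <- suppressWarnings(stats::cor.test(xi, xj, method = "spearman",
                                             exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = p, n = nmat)
}
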