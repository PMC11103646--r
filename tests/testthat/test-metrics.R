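test_that("screening removes slow and error trials, conserving counts", {
  ds <- tiny_dataset()
  same <- screen_latencies(ds, max_latency_s = 3)
  # no latency > 3 s here; only the two error trials go
  expect_identical(same$meta$screen$n_latency_removed, 0L)
  expect_identical(same$meta$screen$n_error_removed, 2L)
  expect_identical(nrow(same$trials), 6L)

  ds$trials$latency_s[3L] <- 3.5
  scr <- screen_latencies(ds, max_latency_s = 3)
  expect_identical(scr$meta$screen$n_latency_removed, 1L)
  expect_identical(nrow(scr$trials) + scr$meta$screen$n_latency_removed +
                   scr$meta$screen$n_error_removed, nrow(ds$trials))
  expect_error(screen_latencies(ds, max_latency_s = 0), "configuration")
})

test_that("screening removal fraction tracks a planted contamination rate", {
  # contaminate a known fraction of latencies beyond the 3 s screen
  co <- small_cohort()
  set.seed(2)
  p <- 0.08
  n <- nrow(co$trials)
  slow <- runif(n) < p
  co$trials$latency_s[slow] <- 3 + runif(sum(slow))
  scr <- screen_latencies(co)
  removed <- scr$meta$screen$n_latency_removed
  expect_lt(abs(removed / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("median latency uses linear interpolation and per-group medians", {
  tr <- tiny_trials()[1:3, ]
  tr$is_error <- FALSE
  tr$chosen <- c("high", "low", "high")
  tr$latency_s <- c(0.4, 0.5, 0.6)
  ds <- trial_dataset(tr)
  med <- median_latency(ds, by = "rat_id", min_n = 1L)
  expect_equal(med$median_latency_s, 0.5)

  tr2 <- tr[1:2, ]
  tr2$latency_s <- c(0.4, 0.6)
  med2 <- median_latency(trial_dataset(tr2), by = "rat_id", min_n = 1L)
  expect_equal(med2$median_latency_s, 0.5)

  # groups below min_n yield missing medians but keep counts
  med3 <- median_latency(ds, by = "rat_id", min_n = 5L)
  expect_true(is.na(med3$median_latency_s))
  expect_identical(med3$n_trials, 3L)
})

test_that("sample median agrees with the numeric CDF-inversion oracle", {
  # distribution median of ExGauss(0.45, 0.05, 0.15), frozen from
  # quadrature + root finding on the density's CDF
  med_oracle <- 0.56181362
  x <- rexgauss(10000L, 0.45, 0.05, 0.15, seed = 13L)
  se_med <- 1 / (2 * sqrt(10000) * dexgauss(med_oracle, 0.45, 0.05, 0.15))
  expect_lt(abs(median(x) - med_oracle), 3 * se_med)
})

test_that("choice and error percentages are straight proportions", {
  tr <- tiny_trials()
  ds <- trial_dataset(tr)
  cp <- choice_percentage(ds)
  expect_equal(cp$choice_pct, c(100, 100))   # the one dual trial per rat is high
  ep <- error_percentage(ds)
  expect_equal(ep$error_pct, c(100 / 3, 100 / 3))
  expect_equal(ep$n_single, c(3L, 3L))

  # 8 high of 10 dual
  tr2 <- tr[rep(3L, 10L), ]
  tr2$trial_index <- 1:10
  tr2$trial_start_s <- seq(0, 90, by = 10)
  tr2$chosen[9:10] <- "low"
  cp2 <- choice_percentage(trial_dataset(tr2[tr2$rat_id == "r1", ]))
  expect_equal(cp2$choice_pct, 80)
  # no dual trials -> missing value
  cp3 <- choice_percentage(trial_dataset(tr[tr$trial_type == "single", ]))
  expect_true(all(is.na(cp3$choice_pct)))
})

test_that("offer effect is the dual-minus-single median difference", {
  # identical dual and single samples -> 0; +0.1 shift -> 0.1
  n <- 12L
  lat <- rexgauss(n, 0.4, 0.04, 0.1, seed = 3L)
  tr <- data.frame(
    rat_id = "r1", phase = "choice_learning", session_index = 1L,
    trial_index = 1:(2 * n),
    trial_type = rep(c("single", "dual"), each = n),
    offered_high = TRUE,
    offered_low = rep(c(FALSE, TRUE), each = n),
    high_side = "left", chosen = "high", is_error = FALSE,
    latency_s = c(lat, lat),
    trial_start_s = seq(0, by = 5, length.out = 2 * n),
    stringsAsFactors = FALSE)
  oe <- offer_effect(trial_dataset(tr))
  expect_equal(oe$offer_effect_s, 0)

  tr$latency_s[tr$trial_type == "dual"] <- lat + 0.1
  oe2 <- offer_effect(trial_dataset(tr))
  expect_equal(oe2$offer_effect_s, 0.1, tolerance = 1e-12)
})

test_that("Huber slowing equals OLS on clean data and resists outliers", {
  set.seed(21)
  n <- 300L
  x <- sort(runif(n, 0, 3600))
  # bounded noise: every standardized residual stays inside the Huber
  # threshold, so all weights are 1 and the fit must equal OLS exactly
  e <- sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.5, 1) * 0.05
  y <- 0.5 + 5e-5 * x + e
  tr <- data.frame(latency_s = y, trial_start_s = x)
  h <- within_session_slowing(tr)
  ols <- coef(lm(y ~ x))
  expect_true(h$converged)
  expect_equal(h$slope, unname(ols[2L]), tolerance = 1e-6)
  expect_equal(h$intercept, unname(ols[1L]), tolerance = 1e-6)
  y <- 0.5 + 5e-5 * x + rnorm(n, 0, 0.02)

  # zero slope stays zero
  y0 <- 0.5 + rnorm(n, 0, 0.05)
  h0 <- within_session_slowing(data.frame(latency_s = y0, trial_start_s = x))
  expect_lt(abs(h0$slope), 3 * 0.05 / (sd(x) * sqrt(n)))

  # 5% gross outliers: Huber stays within 10% of truth, OLS strays further
  yc <- y
  out_idx <- sample(n, 15L)
  yc[out_idx] <- yc[out_idx] + 3
  hc <- within_session_slowing(data.frame(latency_s = yc, trial_start_s = x))
  ols_c <- coef(lm(yc ~ x))
  expect_lt(abs(hc$slope - 5e-5) / 5e-5, 0.10)
  expect_gt(abs(ols_c[2L] - 5e-5) / 5e-5, abs(hc$slope - 5e-5) / 5e-5)
  expect_error(within_session_slowing(tr[1:5, ]), "at least 10")
})

test_that("Huber slowing agrees with the reference IRLS implementation", {
  skip_if_not_installed("MASS")
  set.seed(9)
  n <- 200L
  x <- sort(runif(n, 0, 3000))
  y <- 0.5 + 8e-5 * x + 0.06 * rt(n, df = 3)
  h <- within_session_slowing(data.frame(latency_s = y, trial_start_s = x))
  ref <- MASS::rlm(y ~ x, k = 1.345, scale.est = "MAD", maxit = 100)
  expect_equal(h$slope, unname(coef(ref)[2L]), tolerance = 0.02)
})
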