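cond82 <- ddm_condition(8, 2)

test_that("drift is linear in log luminance contrast", {
  expect_equal(drift_from_condition(1, cond82), log(4))
  expect_equal(drift_from_condition(2.5, cond82), 2.5 * log(4))
  expect_equal(drift_from_condition(1, ddm_condition(5, 5)), 0)
  expect_equal(drift_from_condition(1.3, ddm_condition(16, 4)),
               drift_from_condition(1.3, cond82))
  expect_error(ddm_condition(0, 2), "> 0")
})

test_that("parameter constructor enforces its invariants", {
  p <- ddm_params(1.5, 2.0, 0.3)
  expect_s3_class(p, "ddm_params")
  expect_equal(p$noise, 1.5)
  expect_equal(p$start_offset, 0.1)
  expect_equal(p$lapse_mix, 0.2)
  expect_error(ddm_params(1, -1, 0.3), "boundary")
  expect_error(ddm_params(1, 0.15, 0.3), "start point")
  expect_error(ddm_params(1, 2, -0.1), "nondecision")
  expect_error(ddm_params(1, 2, 0.3, lapse_mix = 1), "lapse_mix")
})

test_that("closed-form choice probability has the right limits", {
  p0 <- ddm_params(0, 2, 0.3, start_offset = 0)
  expect_equal(choice_prob_closed_form(p0, cond82), 0.5)
  pz <- ddm_params(0, 2, 0.3, start_offset = 0.1)
  expect_equal(choice_prob_closed_form(pz, cond82), 1.1 / 2)
  # strong drift saturates toward 1
  expect_gt(choice_prob_closed_form(ddm_params(8, 2, 0.3), cond82), 0.999)
})

test_that("choice probabilities are invariant to common diffusion rescaling", {
  # scaling (k, a, z0, s) together cannot change the choice probability:
  # the reason the noise is fixed at 1.5 in fitting
  for (c_scale in c(0.5, 2, 3.7)) {
    p1 <- ddm_params(1.2, 2.2, 0.3)
    p2 <- ddm_params(1.2 * c_scale, 2.2 * c_scale, 0.3,
                     noise = 1.5 * c_scale, start_offset = 0.1 * c_scale)
    expect_equal(choice_prob_closed_form(p2, cond82),
                 choice_prob_closed_form(p1, cond82), tolerance = 1e-12)
  }
})

test_that("first-passage solutions conserve probability and match the closed form", {
  for (k in c(0.5, 3)) {
    for (a in c(1.0, 2.0)) {
      p <- ddm_params(k, a, 0.3)
      pde <- fpt_solve(p, cond82, method = "pde")
      expect_lt(abs(pde$p_high + pde$p_low + pde$p_undecided - 1), 1e-4)
      expect_true(all(pde$dens_high >= 0) && all(pde$dens_low >= 0))
      p_cf <- choice_prob_closed_form(p, cond82)
      expect_lt(abs(pde$p_high - p_cf * (1 - pde$p_undecided)), 1e-3)
    }
  }
  expect_error(fpt_solve(ddm_params(1, 2, 0.3), cond82, dt = 0.02), "dt")
  expect_error(fpt_solve(ddm_params(1, 2, 0.3), cond82, T_max = 2), "T_max")
})

test_that("analytic series and Crank-Nicolson densities agree", {
  grid <- expand.grid(k = c(0.8, 2.0), a = c(1.6, 2.4))
  for (i in seq_len(nrow(grid))) {
    p <- ddm_params(grid$k[i], grid$a[i], 0.3)
    ser <- fpt_solve(p, cond82, method = "series")
    pde <- fpt_solve(p, cond82, method = "pde")
    expect_lt(max(abs(ser$dens_high - pde$dens_high),
                  abs(ser$dens_low - pde$dens_low)), 1e-3)
    expect_lt(abs(ser$p_high - pde$p_high), 1e-3)
  }
})

test_that("trial likelihood mixes the lapse process correctly", {
  p <- ddm_params(1.5, 2.0, 0.3)
  sol <- fpt_solve(p, cond82, method = "series")

  # below t0 with no lapse: floored at 1e-12
  p_nolapse <- ddm_params(1.5, 2.0, 0.3, lapse_mix = 0)
  expect_equal(trial_likelihood(p_nolapse, cond82, "high", 0.1, sol), 1e-12)

  # pure lapse: density is the lapse density regardless of k, a
  p_lapse <- ddm_params(1.5, 2.0, 0.3, lapse_mix = 1 - 1e-12)
  g <- trial_likelihood(p_lapse, cond82, "high", 0.7, sol)
  expect_equal(g, 0.5 * exp(-0.7), tolerance = 1e-6)
  p_lapse2 <- ddm_params(0.2, 4.0, 0.3, lapse_mix = 1 - 1e-12)
  sol2 <- fpt_solve(p_lapse2, cond82, method = "series")
  expect_equal(trial_likelihood(p_lapse2, cond82, "high", 0.7, sol2), g,
               tolerance = 1e-6)

  # normalization over choices and time by quadrature on the grid
  tg <- seq(0, 12, by = 0.002)
  f_hi <- trial_likelihood(p, cond82, rep("high", length(tg)), tg, sol)
  f_lo <- trial_likelihood(p, cond82, rep("low", length(tg)), tg, sol)
  total <- sum((f_hi + f_lo)[-1] + (f_hi + f_lo)[-length(tg)]) / 2 * 0.002
  expect_lt(abs(total - 1), 1e-3)
})

test_that("simulator matches the lapse-mixed closed form and the density", {
  p <- ddm_params(1.5, 2.0, 0.3)
  n <- 60000L
  sim <- simulate_ddm(p, cond82, n, dt = 0.001, seed = 42L)
  p_mix <- (1 - p$lapse_mix) * choice_prob_closed_form(p, cond82) +
    p$lapse_mix / 2
  se <- sqrt(p_mix * (1 - p_mix) / n)
  expect_lt(abs(mean(sim$choice == "high") - p_mix), 3 * se)

  # decision-time distribution vs the series solution (non-lapse trials)
  sol <- fpt_solve(p, cond82, method = "series")
  dl <- sim$latency_s[!sim$lapse] - p$nondecision_t
  dens <- sol$dens_high + sol$dens_low
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2) * sol$dt) /
    (sol$p_high + sol$p_low)
  ks <- max(abs(ecdf(dl)(sol$time_grid) - cdf))
  expect_lt(ks, 0.015)

  expect_identical(simulate_ddm(p, cond82, 500L, seed = 1L),
                   simulate_ddm(p, cond82, 500L, seed = 1L))
  # lapse fraction is binomial around the mixture weight
  expect_lt(abs(mean(sim$lapse) - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("percentile trimming retains the right fraction", {
  x <- seq_len(100) / 10
  tr <- trim_to_percentile(x, 95)
  expect_length(tr, 95L)
  expect_equal(attr(tr, "n_removed"), 5L)

  same <- trim_to_percentile(rep(1.5, 40), 95)
  expect_length(same, 40L)

  y <- rexgauss(10000L, 0.45, 0.05, 0.15, seed = 31L)
  frac <- length(trim_to_percentile(y, 95)) / 10000
  expect_lt(abs(frac - 0.95), 3 * sqrt(0.95 * 0.05 / 10000) + 1e-3)

  expect_error(trim_to_percentile(y, 40), "configuration")
  expect_error(trim_to_percentile(numeric(0), 95), "empty")
})

test_that("DDM fitting recovers parameters and respects its own objective", {
  truth <- ddm_params(1.5, 2.0, 0.3)
  sim <- simulate_ddm(truth, cond82, 1200L, dt = 0.001, seed = 5L)
  fit <- fit_ddm(sim, cond82, de_config = list(generations = 60L, seed = 2L))
  est <- coef(fit)
  expect_lt(abs(est["drift_coef"] - 1.5) / 1.5, 0.15)
  expect_lt(abs(est["boundary_sep"] - 2.0) / 2.0, 0.15)
  expect_lt(abs(est["nondecision_t"] - 0.3), 0.05)
  expect_false(fit$boundary_warning)

  # optimizer dominance: fitted loglik >= loglik at the generating point
  sol_t <- fpt_solve(truth, cond82, dt = fit$dt, T_max = fit$T_max,
                     method = "series")
  ll_truth <- sum(log(trial_likelihood(truth, cond82, sim$choice,
                                       sim$latency_s, sol_t)))
  expect_gte(fit$loglik, ll_truth - 1e-6)

  expect_error(fit_ddm(sim[1:10, ], cond82), "at least")
})
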