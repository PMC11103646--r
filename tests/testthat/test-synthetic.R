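test_that("default configuration states the experiment", {
  cfg <- default_config()
  expect_equal(cfg$dual_fraction, 1 / 3)
  expect_equal(cfg$luminance_high, 8)
  expect_equal(cfg$luminance_low, 2)
  expect_identical(cfg$n_rats, 15L)
  expect_identical(cfg$n_sessions, 5L)
  expect_identical(cfg$trials_per_session, 300L)
  expect_lt(cfg$single_error_rate, 0.10)
  a <- vapply(cfg$ddm_by_session, function(p) p$boundary_sep, numeric(1L))
  expect_true(all(diff(a) < 0))            # declining decision threshold
  expect_no_error(choicedyn:::.check_cohort_config(cfg))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(dual_fraction = 1.2), "dual_fraction")
  expect_error(cohort_config(luminance_high = 2, luminance_low = 8), "luminance")
  expect_error(cohort_config(trials_per_session = 0), "trials_per_session")
  expect_error(cohort_config(n_sessions = 3,
                             ddm_by_session = list(ddm_params(1, 2, 0.2))),
               "one entry per session")
})

test_that("session generation is deterministic and honors the trial mix", {
  cfg <- cohort_config(n_rats = 1L, n_sessions = 1L, trials_per_session = 200L,
                       seed = 5L)
  rp <- choicedyn:::rat_parameters(cfg, "ratA")
  s1 <- generate_session(rp, 1L, cfg, seed = 11L)
  s2 <- generate_session(rp, 1L, cfg, seed = 11L)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 200L)
  expect_true(all(diff(s1$trial_start_s) > 0))

  cfg0 <- cohort_config(n_rats = 1L, n_sessions = 1L,
                        trials_per_session = 100L, dual_fraction = 0)
  s0 <- generate_session(choicedyn:::rat_parameters(cfg0, "ratA"), 1L, cfg0,
                         seed = 3L)
  expect_true(all(s0$trial_type == "single"))
})

test_that("dual-offer choices track the closed-form probability", {
  cfg <- cohort_config(n_rats = 1L, n_sessions = 1L,
                       trials_per_session = 10000L, dual_fraction = 0.5,
                       rat_heterogeneity_sd = 0,
                       ddm_by_session = list(ddm_params(0.8, 2.1, 0.22)),
                       seed = 1L)
  rp <- choicedyn:::rat_parameters(cfg, "ratA")
  s <- generate_session(rp, 1L, cfg, seed = 21L)
  dual <- s[s$trial_type == "dual", ]
  p <- ddm_params(0.8, 2.1, 0.22)
  p_mix <- (1 - p$lapse_mix) *
    choice_prob_closed_form(p, ddm_condition(8, 2)) + p$lapse_mix / 2
  phat <- mean(dual$chosen == "high")
  expect_lt(abs(phat - p_mix), 3 * sqrt(p_mix * (1 - p_mix) / nrow(dual)))
})

test_that("structural rates stay inside binomial 99% bounds", {
  co <- small_cohort()                      # 4 rats x 2 sessions x 120 trials
  tr <- co$trials
  n <- nrow(tr)
  f_dual <- mean(tr$trial_type == "dual")
  bound99 <- function(p, n) qnorm(0.995) * sqrt(p * (1 - p) / n)
  expect_lt(abs(f_dual - 1 / 3), bound99(1 / 3, n))
  single <- tr[tr$trial_type == "single", ]
  expect_lt(abs(mean(single$is_error) - 0.05), bound99(0.05, nrow(single)))
})

test_that("single-offer latencies match the ex-Gaussian closed-form moments", {
  # no slowing and no heterogeneity so the draws are exactly ex-Gaussian
  cfg <- cohort_config(n_rats = 1L, n_sessions = 1L,
                       trials_per_session = 8000L, dual_fraction = 0,
                       single_error_rate = 0, slowing_slope_s_per_min = 0,
                       rat_heterogeneity_sd = 0,
                       ddm_by_session = list(ddm_params(0.8, 2.1, 0.22)))
  s <- generate_session(choicedyn:::rat_parameters(cfg, "r"), 1L, cfg, seed = 2L)
  for (v in c("high", "low")) {
    e <- cfg$single_offer_exgauss[[v]]
    lat <- s$latency_s[s$chosen == v]
    n <- length(lat)
    expect_lt(abs(mean(lat) - (e[1L] + e[3L])),
              3 * sqrt((e[2L]^2 + e[3L]^2) / n))
    m4 <- mean((lat - mean(lat))^4)
    expect_lt(abs(var(lat) - (e[2L]^2 + e[3L]^2)),
              3 * sqrt((m4 - var(lat)^2) / n))
  }
})

test_that("cohorts are reproducible, validated, and sized correctly", {
  co <- small_cohort()
  expect_identical(nrow(validate_dataset(co)), 0L)
  expect_identical(nrow(co$trials), 4L * 2L * 120L)

  co2 <- generate_cohort(cohort_config(n_rats = 4L, n_sessions = 2L,
                                       trials_per_session = 120L, seed = 99L))
  expect_identical(co$trials, co2$trials)   # byte-identical under same config

  co3 <- generate_cohort(cohort_config(n_rats = 4L, n_sessions = 2L,
                                       trials_per_session = 120L, seed = 100L))
  expect_false(identical(co$trials$latency_s, co3$trials$latency_s))

  empty <- generate_cohort(cohort_config(n_rats = 0L))
  expect_identical(nrow(empty$trials), 0L)
  expect_identical(nrow(validate_dataset(empty)), 0L)
})

test_that("rat heterogeneity jitters parameters but keeps them positive", {
  cfg <- cohort_config(rat_heterogeneity_sd = 0.2)
  rps <- lapply(sprintf("rat%02d", 1:8),
                function(r) choicedyn:::rat_parameters(cfg, r))
  ks <- vapply(rps, function(rp) rp$ddm_by_session[[1L]]$drift_coef, numeric(1L))
  expect_gt(sd(ks), 0)
  expect_true(all(ks > 0))
  taus <- vapply(rps, function(rp) rp$exgauss$high["tau"], numeric(1L))
  expect_true(all(taus > 0))
  # same rat id -> same bundle
  expect_identical(choicedyn:::rat_parameters(cfg, "rat01"),
                   choicedyn:::rat_parameters(cfg, "rat01"))
})
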