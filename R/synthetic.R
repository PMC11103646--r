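# Synthetic cohorts of simulated rats performing the choice-learning task.
#
# The generator mirrors the analysis models: dual-offer (choice, latency)
# pairs are drawn from the generalized DDM simulator under session-specific
# parameters, single-offer latencies from per-value ex-Gaussian
# distributions, single-offer errors are Bernoulli, and a linear
# within-session slowing term is added to the nondecision component of every
# latency as session time accumulates.

#' Cohort generator configuration
#'
#' The defaults state the emulated experiment: 15 rats tested over five
#' 300-trial choice-learning sessions; two-thirds single-offer trials and
#' one-third dual-offer trials; high and low stimuli of 8 and 2 LEDs; a 5%
#' single-offer error rate; a decision threshold that declines across
#' sessions (2.3 to 1.9 evidence units) with drift coefficient (0.8) and
#' nondecision time (0.22 s) held constant — the generative learning
#' effect; and a gradual within-session slowing of 0.003 s of latency per
#' minute of session time. Per-rat heterogeneity is multiplicative
#' log-normal jitter (SD 0.12) on the drift coefficient, boundary
#' separation, nondecision time, and the ex-Gaussian mu and tau.
#'
#' @param n_rats number of simulated rats.
#' @param n_sessions number of choice-learning sessions per rat.
#' @param trials_per_session trials per session.
#' @param dual_fraction probability a trial is dual-offer, in (0, 1) (or 0
#'   for single-offer-only sessions).
#' @param luminance_high,luminance_low LED counts of the two stimuli
#'   (`luminance_high > luminance_low > 0`).
#' @param single_error_rate Bernoulli probability of an error on
#'   single-offer trials.
#' @param ddm_by_session list of length `n_sessions` of [ddm_params()]
#'   giving each session's generative DDM.
#' @param single_offer_exgauss list with elements `high` and `low`, each a
#'   numeric vector `c(mu, sigma, tau)` for the single-offer latency
#'   distribution of that value.
#' @param slowing_slope_s_per_min seconds of added latency per minute of
#'   elapsed session time.
#' @param rat_heterogeneity_sd SD of the per-rat log-normal parameter jitter.
#' @param iti_fixed_s,iti_exp_mean_s intertrial interval model: a fixed
#'   reward/consumption period plus an exponential self-paced component.
#' @param seed master seed; per-rat child seeds derive from it.
#' @return object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_rats = 15L,
                          n_sessions = 5L,
                          trials_per_session = 300L,
                          dual_fraction = 1 / 3,
                          luminance_high = 8,
                          luminance_low = 2,
                          single_error_rate = 0.05,
                          ddm_by_session = NULL,
                          single_offer_exgauss = list(
                            high = c(mu = 0.40, sigma = 0.05, tau = 0.11),
                            low = c(mu = 0.43, sigma = 0.06, tau = 0.12)),
                          slowing_slope_s_per_min = 0.003,
                          rat_heterogeneity_sd = 0.12,
                          iti_fixed_s = 2,
                          iti_exp_mean_s = 2,
                          seed = 42L) {
  if (is.null(ddm_by_session)) {
    a_decline <- seq(2.3, 1.9, length.out = n_sessions)
    ddm_by_session <- lapply(a_decline, function(a) ddm_params(0.8, a, 0.22))
  }
  cfg <- structure(list(
    n_rats = as.integer(n_rats),
    n_sessions = as.integer(n_sessions),
    trials_per_session = as.integer(trials_per_session),
    dual_fraction = dual_fraction,
    luminance_high = luminance_high,
    luminance_low = luminance_low,
    single_error_rate = single_error_rate,
    ddm_by_session = ddm_by_session,
    single_offer_exgauss = single_offer_exgauss,
    slowing_slope_s_per_min = slowing_slope_s_per_min,
    rat_heterogeneity_sd = rat_heterogeneity_sd,
    iti_fixed_s = iti_fixed_s,
    iti_exp_mean_s = iti_exp_mean_s,
    seed = as.integer(seed)
  ), class = "cohort_config")
  .check_cohort_config(cfg)
  cfg
}

#' Default cohort configuration
#'
#' @return the default [cohort_config()].
#' @export
default_config <- function() cohort_config()

.check_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_rats < 0L) stop("n_rats must be >= 0")
  if (cfg$n_sessions < 1L) stop("n_sessions must be >= 1")
  if (cfg$trials_per_session < 1L) stop("trials_per_session must be > 0")
  if (cfg$dual_fraction < 0 || cfg$dual_fraction >= 1) {
    stop("dual_fraction must be in [0, 1)")
  }
  if (!(cfg$luminance_high > cfg$luminance_low && cfg$luminance_low > 0)) {
    stop("need luminance_high > luminance_low > 0")
  }
  if (cfg$single_error_rate < 0 || cfg$single_error_rate >= 1) {
    stop("single_error_rate must be in [0, 1)")
  }
  if (length(cfg$ddm_by_session) != cfg$n_sessions) {
    stop("ddm_by_session must have one entry per session")
  }
  for (p in cfg$ddm_by_session) {
    if (!inherits(p, "ddm_params")) stop("ddm_by_session entries must be ddm_params")
  }
  for (v in c("high", "low")) {
    e <- cfg$single_offer_exgauss[[v]]
    if (is.null(e) || length(e) != 3L || !all(is.finite(e)) ||
        e[2L] <= 0 || e[3L] <= 0) {
      stop("single_offer_exgauss$", v, " must be c(mu, sigma > 0, tau > 0)")
    }
  }
  if (cfg$rat_heterogeneity_sd < 0) stop("rat_heterogeneity_sd must be >= 0")
  if (cfg$slowing_slope_s_per_min < 0) stop("slowing slope must be >= 0")
  if (cfg$iti_fixed_s < 0 || cfg$iti_exp_mean_s <= 0) stop("invalid intertrial interval")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  a <- vapply(x$ddm_by_session, function(p) p$boundary_sep, numeric(1L))
  cat(sprintf("Cohort config: %d rats x %d sessions x %d trials (dual fraction %.3g)\n",
              x$n_rats, x$n_sessions, x$trials_per_session, x$dual_fraction))
  cat(sprintf("  stimuli %g vs %g LEDs; error rate %.3g; slowing %.3g s/min; seed %d\n",
              x$luminance_high, x$luminance_low, x$single_error_rate,
              x$slowing_slope_s_per_min, x$seed))
  cat(sprintf("  threshold by session: %s (k = %.3g, t0 = %.3g s)\n",
              paste(sprintf("%.2f", a), collapse = ", "),
              x$ddm_by_session[[1L]]$drift_coef,
              x$ddm_by_session[[1L]]$nondecision_t))
  invisible(x)
}

# Deterministic 32-bit child seed from a parent seed and a string tag.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * (31^(seq_along(utf8ToInt(as.character(tag))) %% 7)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

# Per-rat parameter bundle: log-normal multiplicative jitter on the DDM free
# parameters and on the ex-Gaussian mu and tau (sigma kept); keeps all
# parameters positive.
rat_parameters <- function(cfg, rat_id) {
  sdj <- cfg$rat_heterogeneity_sd
  with_seed(child_seed(cfg$seed, paste0(rat_id, "/params")), {
    jit <- function() exp(stats::rnorm(1L, -sdj^2 / 2, sdj))
    j_k <- jit(); j_a <- jit(); j_t0 <- jit()
    ddm <- lapply(cfg$ddm_by_session, function(p) {
      ddm_params(p$drift_coef * j_k, p$boundary_sep * j_a,
                 p$nondecision_t * j_t0, noise = p$noise,
                 start_offset = p$start_offset, lapse_mix = p$lapse_mix,
                 lapse_rate = p$lapse_rate)
    })
    exg <- lapply(cfg$single_offer_exgauss, function(e) {
      c(mu = unname(e[1L]) * jit(), sigma = unname(e[2L]),
        tau = unname(e[3L]) * jit())
    })
    list(rat_id = rat_id, ddm_by_session = ddm, exgauss = exg)
  })
}

#' Generate one session of simulated trials
#'
#' Draws the trial mix (dual with probability `dual_fraction`, offered value
#' and side at random), dual-offer choices and latencies from the DDM
#' simulator under that session's parameters, single-offer latencies from
#' the per-value ex-Gaussian, and single-offer errors as Bernoulli. Trial
#' start times accumulate latency plus a fixed-plus-exponential intertrial
#' interval, and the within-session slowing term
#' `slowing_slope_s_per_min * trial_start / 60` is added to every latency.
#'
#' @param rat_params per-rat parameter bundle from `rat_parameters()`
#'   (exported for reproducibility of cohorts; most callers want
#'   [generate_cohort()]).
#' @param session_index session number, 1-based.
#' @param cfg a [cohort_config()].
#' @param seed integer seed for this session.
#' @return data.frame of canonical trial rows.
#' @export
generate_session <- function(rat_params, session_index, cfg, seed) {
  .check_cohort_config(cfg)
  if (session_index > cfg$n_sessions) stop("session_index exceeds cfg$n_sessions")
  n <- cfg$trials_per_session
  ddm <- rat_params$ddm_by_session[[session_index]]
  cond <- ddm_condition(cfg$luminance_high, cfg$luminance_low)
  slope_per_s <- cfg$slowing_slope_s_per_min / 60

  with_seed(seed, {
    is_dual <- stats::runif(n) < cfg$dual_fraction
    n_dual <- sum(is_dual)
    high_side <- ifelse(stats::runif(n) < 0.5, "left", "right")
    single_high <- stats::runif(n) < 0.5         # offered value on single trials
    single_err <- stats::runif(n) < cfg$single_error_rate
    iti <- cfg$iti_fixed_s + stats::rexp(n, rate = 1 / cfg$iti_exp_mean_s)
    exg_hi <- rat_params$exgauss$high
    exg_lo <- rat_params$exgauss$low
    lat_hi <- rexgauss(n, exg_hi[1L], exg_hi[2L], exg_hi[3L])
    lat_lo <- rexgauss(n, exg_lo[1L], exg_lo[2L], exg_lo[3L])
    dual <- if (n_dual > 0L) {
      simulate_ddm(ddm, cond, n_dual, dt = 0.001)
    } else {
      data.frame(choice = character(), latency_s = numeric())
    }

    trial_type <- ifelse(is_dual, "dual", "single")
    chosen <- character(n)
    base_lat <- numeric(n)
    chosen[is_dual] <- dual$choice
    base_lat[is_dual] <- dual$latency_s
    sh <- !is_dual & single_high
    sl <- !is_dual & !single_high
    chosen[sh] <- "high"; base_lat[sh] <- lat_hi[sh]
    chosen[sl] <- "low";  base_lat[sl] <- lat_lo[sl]
    is_error <- !is_dual & single_err
    chosen[is_error] <- "none"

    # sequential clock: slowing depends on each trial's start time
    trial_start <- numeric(n)
    latency <- numeric(n)
    t_clock <- 0
    for (i in seq_len(n)) {
      trial_start[i] <- t_clock
      latency[i] <- base_lat[i] + slope_per_s * trial_start[i]
      t_clock <- t_clock + latency[i] + iti[i]
    }

    data.frame(
      rat_id = rat_params$rat_id,
      phase = "choice_learning",
      session_index = as.integer(session_index),
      trial_index = seq_len(n),
      trial_type = trial_type,
      offered_high = is_dual | single_high,
      offered_low = is_dual | !single_high,
      high_side = high_side,
      chosen = chosen,
      is_error = is_error,
      latency_s = latency,
      trial_start_s = trial_start,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic cohort
#'
#' One dataset of `n_rats` rats by `n_sessions` choice-learning sessions.
#' Per-rat parameters are jittered once per rat (child seed derived
#' deterministically from `cfg$seed` and the rat id), then each session is
#' generated with its own child seed, so the output is reproducible
#' trial-for-trial under a fixed configuration.
#'
#' @param cfg a [cohort_config()].
#' @return a validated `trial_dataset`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_rats = 2, n_sessions = 2,
#'                                         trials_per_session = 50))
#' cohort
#' @export
generate_cohort <- function(cfg = default_config()) {
  .check_cohort_config(cfg)
  sessions <- list()
  for (i in seq_len(cfg$n_rats)) {
    rat_id <- sprintf("rat%02d", i)
    rp <- rat_parameters(cfg, rat_id)
    for (s in seq_len(cfg$n_sessions)) {
      sessions[[length(sessions) + 1L]] <-
        generate_session(rp, s, cfg, child_seed(cfg$seed, paste0(rat_id, "/s", s)))
    }
  }
  trials <- if (length(sessions) == 0L) {
    data.frame(rat_id = character(), phase = character(),
               session_index = integer(), trial_index = integer(),
               trial_type = character(), offered_high = logical(),
               offered_low = logical(), high_side = character(),
               chosen = character(), is_error = logical(),
               latency_s = numeric(), trial_start_s = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, sessions)
  }
  ds <- trial_dataset(trials, meta = list(source = "synthetic",
                                          seed = cfg$seed))
  v <- validate_dataset(ds)
  if (nrow(v) > 0L) stop("generated cohort failed validation: ", v$message[1L])
  ds
}
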