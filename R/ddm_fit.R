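# Maximum-likelihood fitting of the generalized DDM by differential
# evolution over (drift coefficient, boundary separation, nondecision time),
# with the lapse-mixture first-passage likelihood evaluated from the
# analytic series densities.

# Differential evolution (rand/1/bin) over a box. Deterministic under seed.
de_optimize <- function(fn, lower, upper, pop = NULL, generations = 120L,
                        tol = 1e-3, cr = 0.7, seed = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  np <- max(if (is.null(pop)) 0L else pop, 15L * d)
  with_seed(seed, {
    x <- matrix(stats::runif(np * d), np, d)
    x <- sweep(sweep(x, 2L, upper - lower, "*"), 2L, lower, "+")
    fv <- apply(x, 1L, fn)
    gen <- 0L
    spread <- diff(range(fv))
    while (gen < generations && spread >= tol) {
      gen <- gen + 1L
      Fg <- stats::runif(1L, 0.5, 1.0)     # dithered scale factor
      for (i in seq_len(np)) {
        r <- sample.int(np - 1L, 3L)
        r <- r + (r >= i)                  # three distinct indices != i
        mut <- x[r[1L], ] + Fg * (x[r[2L], ] - x[r[3L], ])
        mask <- stats::runif(d) < cr
        mask[sample.int(d, 1L)] <- TRUE    # forced crossover coordinate
        trial <- ifelse(mask, mut, x[i, ])
        trial <- pmin(pmax(trial, lower), upper)
        ft <- fn(trial)
        if (ft <= fv[i]) {
          x[i, ] <- trial
          fv[i] <- ft
        }
      }
      spread <- diff(range(fv))
    }
    best <- which.min(fv)
    list(par = x[best, ], value = fv[best], generations = gen,
         spread = spread, pop = np)
  })
}

#' Fit the generalized drift-diffusion model to dual-offer trials
#'
#' Maximizes the summed log lapse-mixture likelihood of (choice, latency)
#' observations over the three free parameters — drift coefficient,
#' boundary separation, nondecision time — by differential evolution
#' (rand/1/bin, population at least 15 times the dimension, crossover 0.7,
#' scale factor dithered in `[0.5, 1)`), followed by a Nelder-Mead polish
#' inside the box. The likelihood interpolates the analytic first-passage
#' series densities on a `dt` grid. The noise, start-offset, and lapse
#' constants are fixed (see [ddm_params()]).
#'
#' @param trials data.frame with columns `choice` ("high"/"low") and
#'   `latency_s` (seconds), dual-offer trials only.
#' @param cond the stimulus [ddm_condition()] shared by the trials.
#' @param bounds named list of `c(lower, upper)` boxes for `drift_coef`,
#'   `boundary_sep`, `nondecision_t`. The lower bound for `boundary_sep`
#'   is raised to `2|z0| + 0.05` so the start point stays inside the bounds.
#' @param de_config list: `pop`, `generations`, `tol` (stop when the
#'   population objective spread falls below), `seed`.
#' @param constants optional overrides for the fixed parameters (`noise`,
#'   `start_offset`, `lapse_mix`, `lapse_rate`).
#' @param trim_percentile if non-`NULL`, latencies above this empirical
#'   percentile are trimmed before fitting (see [trim_to_percentile()]).
#' @param dt,T_max likelihood time grid; `T_max` is extended to cover the
#'   largest observed latency.
#' @param min_trials minimum number of trials accepted for a fit.
#' @param scope,rat_id,session_index provenance labels carried on the fit.
#' @return An object of class `"ddm_fit"`: `params` (a full [ddm_params()]
#'   with the fitted free values), `loglik`, `n_trials`, `boundary_warning`,
#'   optimizer trace (`de`), and the provenance labels. Supports `coef()`,
#'   `logLik()`, `print()`, `simulate()`, and `predict()`.
#' @examples
#' \donttest{
#' truth <- ddm_params(1.5, 2.0, 0.3)
#' cond <- ddm_condition(8, 2)
#' sim <- simulate_ddm(truth, cond, 500, seed = 1)
#' fit <- fit_ddm(sim, cond, de_config = list(generations = 40, seed = 1))
#' coef(fit)
#' }
#' @export
fit_ddm <- function(trials, cond = ddm_condition(),
                    bounds = list(drift_coef = c(0.02, 6),
                                  boundary_sep = c(0.25, 6),
                                  nondecision_t = c(0, 1)),
                    de_config = list(),
                    constants = list(),
                    trim_percentile = NULL,
                    dt = 0.005, T_max = 4, min_trials = 50L,
                    scope = c("pooled", "per_rat"),
                    rat_id = NA_character_, session_index = NA_integer_) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(trials), all(c("choice", "latency_s") %in% names(trials)))
  if (!all(trials$choice %in% c("high", "low"))) {
    stop("trials$choice must be 'high' or 'low'")
  }
  lat <- trials$latency_s
  ch <- trials$choice
  trim_info <- NULL
  if (!is.null(trim_percentile)) {
    keep_lat <- trim_to_percentile(lat, trim_percentile)
    keep <- lat <= attr(keep_lat, "cut_point")
    trim_info <- list(percentile = trim_percentile,
                      cut_point = attr(keep_lat, "cut_point"),
                      n_removed = attr(keep_lat, "n_removed"))
    lat <- lat[keep]
    ch <- ch[keep]
  }
  if (length(lat) < min_trials) {
    stop("need at least ", min_trials, " trials to fit, got ", length(lat))
  }

  const <- utils::modifyList(
    list(noise = 1.5, start_offset = 0.1, lapse_mix = 0.2, lapse_rate = 1.0),
    constants)
  de <- utils::modifyList(
    list(pop = NULL, generations = 120L, tol = 1e-3, seed = 1L), de_config)

  bounds$boundary_sep[1L] <- max(bounds$boundary_sep[1L],
                                 2 * abs(const$start_offset) + 0.05)
  lower <- c(bounds$drift_coef[1L], bounds$boundary_sep[1L], bounds$nondecision_t[1L])
  upper <- c(bounds$drift_coef[2L], bounds$boundary_sep[2L], bounds$nondecision_t[2L])
  T_fit <- max(T_max, 3, max(lat) + dt)

  make_params <- function(par) {
    ddm_params(drift_coef = par[1L], boundary_sep = par[2L],
               nondecision_t = par[3L], noise = const$noise,
               start_offset = const$start_offset, lapse_mix = const$lapse_mix,
               lapse_rate = const$lapse_rate)
  }
  negll <- function(par) {
    par <- pmin(pmax(par, lower), upper)
    p <- make_params(par)
    sol <- fpt_solve(p, cond, dt = dt, T_max = T_fit, method = "series")
    val <- -sum(log(trial_likelihood(p, cond, ch, lat, sol)))
    if (!is.finite(val)) 1e10 else val
  }

  opt <- de_optimize(negll, lower, upper, pop = de$pop,
                     generations = de$generations, tol = de$tol,
                     seed = de$seed)
  polish <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                         control = list(maxit = 300L))
  par <- pmin(pmax(polish$par, lower), upper)
  value <- negll(par)
  if (value > opt$value) {                  # keep the DE optimum if better
    par <- opt$par
    value <- opt$value
  }
  edge <- (par - lower < 1e-3 * (upper - lower)) |
          (upper - par < 1e-3 * (upper - lower))

  structure(list(
    params = make_params(par),
    loglik = -value,
    n_trials = length(lat),
    scope = scope,
    rat_id = rat_id,
    session_index = session_index,
    cond = cond,
    bounds = list(lower = lower, upper = upper),
    de = list(pop = opt$pop, generations = opt$generations,
              spread = opt$spread, seed = de$seed),
    boundary_warning = any(edge),
    trim = trim_info,
    dt = dt, T_max = T_fit
  ), class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("DDM fit (%s%s%s, n = %d trials)\n", x$scope,
              if (!is.na(x$rat_id)) paste0(", rat ", x$rat_id) else "",
              if (!is.na(x$session_index)) paste0(", session ", x$session_index) else "",
              x$n_trials))
  cat(sprintf("  k = %.4f, a = %.4f, t0 = %.4f s; logLik = %.2f\n",
              x$params$drift_coef, x$params$boundary_sep,
              x$params$nondecision_t, x$loglik))
  if (x$boundary_warning) cat("  warning: estimate at box boundary\n")
  invisible(x)
}

#' @export
coef.ddm_fit <- function(object, ...) {
  c(drift_coef = object$params$drift_coef,
    boundary_sep = object$params$boundary_sep,
    nondecision_t = object$params$nondecision_t)
}

#' @export
logLik.ddm_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n_trials, class = "logLik")
}

#' @export
simulate.ddm_fit <- function(object, nsim = object$n_trials, seed = NULL, ...) {
  simulate_ddm(object$params, object$cond, nsim, seed = seed)
}

#' @export
predict.ddm_fit <- function(object, ...) {
  sol <- fpt_solve(object$params, object$cond, dt = object$dt,
                   T_max = object$T_max, method = "series")
  lam <- object$params$lapse_mix
  list(p_high = (1 - lam) * choice_prob_closed_form(object$params, object$cond) +
         lam / 2,
       solution = sol)
}
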