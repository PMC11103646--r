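# Ex-Gaussian model of response latencies: a Normal(mu, sigma) sensorimotor
# component convolved with an Exponential(mean tau) decision-tail component.
# Implied moments: mean mu + tau, variance sigma^2 + tau^2,
# skewness 2 tau^3 / (sigma^2 + tau^2)^(3/2).

.check_exgauss_params <- function(mu, sigma, tau) {
  if (!all(is.finite(c(mu, sigma, tau)))) stop("ex-Gaussian parameters must be finite")
  if (sigma <= 0) stop("sigma must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  invisible(NULL)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Used wherever the API promises determinism
# under an explicit seed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Ex-Gaussian density
#'
#' Density of the ex-Gaussian distribution, the sum of an independent
#' Normal(`mu`, `sigma`) and Exponential(mean `tau`) variate. Evaluated in
#' log space — the exponential factor
#' `exp((mu - t)/tau + sigma^2/(2 tau^2))` is combined with
#' `pnorm(..., log.p = TRUE)` before exponentiating — so the Gaussian limit
#' (`tau` much smaller than `sigma`) does not overflow.
#'
#' @param t quantiles (seconds).
#' @param mu Gaussian mean (seconds).
#' @param sigma Gaussian SD, > 0 (seconds).
#' @param tau exponential mean, > 0 (seconds).
#' @param log return log-density.
#' @return density values (1/seconds).
#' @export
dexgauss <- function(t, mu, sigma, tau, log = FALSE) {
  .check_exgauss_params(mu, sigma, tau)
  lf <- -base::log(tau) + (mu - t) / tau + sigma^2 / (2 * tau^2) +
    stats::pnorm((t - mu) / sigma - sigma / tau, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' Ex-Gaussian random draws
#'
#' @param n number of draws.
#' @param mu,sigma,tau distribution parameters (see [dexgauss()]).
#' @param seed optional integer; when given, draws are deterministic and the
#'   caller's RNG stream is left untouched.
#' @return numeric vector of `n` draws (seconds).
#' @export
rexgauss <- function(n, mu, sigma, tau, seed = NULL) {
  .check_exgauss_params(mu, sigma, tau)
  stopifnot(n >= 1)
  with_seed(seed, stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau))
}

# Moment-based starting values (skewness -> tau, then mu, sigma).
.exgauss_moment_init <- function(x) {
  m <- mean(x)
  v <- stats::var(x)
  s <- stats::sd(x)
  skew <- mean((x - m)^3) / s^3
  tau0 <- s * (max(skew, 0.01) / 2)^(1 / 3)
  tau0 <- min(tau0, 0.95 * s)
  sigma0 <- sqrt(max(v - tau0^2, 0.05 * v))
  c(mu = m - tau0, sigma = sigma0, tau = tau0)
}

#' Fit an ex-Gaussian model to response latencies by maximum likelihood
#'
#' Maximizes the ex-Gaussian log-likelihood with bounded quasi-Newton
#' (`optim` method `"L-BFGS-B"`) from a moment-based initializer: the
#' starting `tau` comes from the sample skewness
#' (`tau0 = sd * (skew/2)^(1/3)`), then `mu0 = mean - tau0` and
#' `sigma0^2 = max(var - tau0^2, eps)`. A single deterministic fit is
#' performed; no resampling is involved.
#'
#' @param latencies numeric vector of response latencies (seconds), finite
#'   and positive.
#' @param min_n minimum sample size accepted for a fit (default 40).
#' @return An object of class `"exgauss_fit"` with components `params`
#'   (named vector `mu`, `sigma`, `tau`), `loglik`, `n`, `converged`, and
#'   `validation` (empty until [validate_exgauss_fit()] is run). Supports
#'   `coef()`, `logLik()`, `print()`, and `simulate()`.
#' @examples
#' x <- rexgauss(500, mu = 0.45, sigma = 0.05, tau = 0.15, seed = 1)
#' fit <- fit_exgauss(x)
#' coef(fit)
#' @export
fit_exgauss <- function(latencies, min_n = 40) {
  x <- latencies
  if (length(x) < min_n) {
    stop("fit-size error: need at least ", min_n, " latencies, got ", length(x))
  }
  if (!all(is.finite(x)) || any(x <= 0)) {
    stop("latencies must be finite and positive")
  }
  if (stats::sd(x) < .Machine$double.eps^0.5 * max(1, mean(x))) {
    stop("degenerate-input error: latency sample has (near) zero variance")
  }
  start <- .exgauss_moment_init(x)
  s <- stats::sd(x)
  nll <- function(p) {
    val <- -sum(dexgauss(x, p[1L], p[2L], p[3L], log = TRUE))
    if (!is.finite(val)) 1e10 else val
  }
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(-Inf, 1e-4 * s, 1e-4 * s),
                      control = list(maxit = 500L))
  if (opt$convergence != 0L) {
    # line-search failures near the sigma/tau bounds: refit on log scale
    nll_log <- function(q) nll(c(q[1L], exp(q[2L]), exp(q[3L])))
    alt <- stats::optim(c(opt$par[1L], log(opt$par[2L]), log(opt$par[3L])),
                        nll_log, method = "Nelder-Mead",
                        control = list(maxit = 2000L, reltol = 1e-10))
    alt$par <- c(alt$par[1L], exp(alt$par[2L]), exp(alt$par[3L]))
    if (alt$value <= opt$value) opt <- alt
  }
  params <- c(mu = unname(opt$par[1L]), sigma = unname(opt$par[2L]),
              tau = unname(opt$par[3L]))
  structure(list(
    params = params,
    loglik = -opt$value,
    start = start,
    loglik_start = -nll(start),
    n = length(x),
    converged = opt$convergence == 0L,
    validation = NULL
  ), class = "exgauss_fit")
}

#' @export
print.exgauss_fit <- function(x, ...) {
  cat("Ex-Gaussian latency fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  mu = %.4f s, sigma = %.4f s, tau = %.4f s\n",
              x$params["mu"], x$params["sigma"], x$params["tau"]))
  cat(sprintf("  implied mean %.4f s, sd %.4f s; logLik %.2f%s\n",
              x$params["mu"] + x$params["tau"],
              sqrt(x$params["sigma"]^2 + x$params["tau"]^2),
              x$loglik, if (x$converged) "" else " (NOT converged)"))
  if (!is.null(x$validation)) {
    v <- x$validation
    cat(sprintf("  validation: KS D = %.3f (p = %.3f)%s -> %s\n",
                v$ks_stat, v$ks_p,
                if (!is.null(v$ranksum_p) && !is.na(v$ranksum_p)) {
                  sprintf(", rank-sum p = %.3f", v$ranksum_p)
                } else "",
                if (v$accepted) "accepted" else "rejected"))
  }
  invisible(x)
}

#' @export
coef.exgauss_fit <- function(object, ...) object$params

#' @export
logLik.exgauss_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n, class = "logLik")
}

#' @export
simulate.exgauss_fit <- function(object, nsim = object$n, seed = NULL, ...) {
  p <- object$params
  rexgauss(nsim, p["mu"], p["sigma"], p["tau"], seed = seed)
}

#' Validate an ex-Gaussian fit by simulating from the fitted parameters
#'
#' Generates a synthetic sample of the same size as the raw data from the
#' fitted parameters and compares it against the raw latencies with a
#' two-sample Kolmogorov-Smirnov test. If the KS test is significant at
#' 0.05, a Wilcoxon rank-sum test is run as a second opinion; the fit is
#' accepted when either test fails to distinguish the generated data from
#' the raw data.
#'
#' @param latencies the raw latencies the fit was estimated from.
#' @param fit an `exgauss_fit` (must have converged).
#' @param seed integer seed for the synthetic draws.
#' @return `fit` with `$validation` filled in: `ks_stat`, `ks_p`,
#'   `ranksum_p` (`NA` when not run), `accepted`.
#' @export
validate_exgauss_fit <- function(latencies, fit, seed = 1L) {
  stopifnot(inherits(fit, "exgauss_fit"))
  if (!fit$converged) stop("cannot validate a fit that did not converge")
  synth <- simulate(fit, nsim = length(latencies), seed = seed)
  ks <- ks_two_sample(latencies, synth)
  ranksum_p <- NA_real_
  if (ks$p_value < 0.05) {
    ranksum_p <- ranksum(latencies, synth)$p_value
  }
  fit$validation <- list(
    ks_stat = ks$statistic,
    ks_p = ks$p_value,
    ranksum_p = ranksum_p,
    accepted = (ks$p_value >= 0.05) || (!is.na(ranksum_p) && ranksum_p >= 0.05)
  )
  fit
}
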