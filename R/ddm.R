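# Generalized drift-diffusion model of dual-offer choices.
#
# Evidence accumulates on [0, a] from a start point z = a/2 + z0 (z0 > 0 is
# a bias toward the high-value boundary at a), with drift
# v = k * log(lum_high / lum_low) and diffusion noise s. Three parameters
# are free (drift coefficient k, boundary separation a, nondecision time
# t0); noise, start offset, and the lapse mixture are fixed constants
# (s = 1.5, z0 = 0.1, lambda = 0.2, lapse rate 1/s), so the model is
# identified despite diffusion scale invariance.

#' Drift-diffusion model parameters
#'
#' Bundles the three free parameters of the generalized DDM with its fixed
#' constants. The free parameters are the drift coefficient (evidence/s per
#' unit log-luminance contrast), the boundary separation (evidence units),
#' and the nondecision time (seconds). The constants are the diffusion
#' noise (1.5 evidence/sqrt(s)), the start-point offset toward the
#' high-value boundary (0.1 evidence units from the midpoint), and a lapse
#' mixture: with weight 0.2 a response arises from a stimulus-independent
#' exponential process (rate 1/s, choice at random).
#'
#' @param drift_coef drift per unit log-luminance contrast (free).
#' @param boundary_sep boundary separation `a` > 0 (free); must exceed
#'   `2 * |start_offset|`.
#' @param nondecision_t nondecision time `t0` >= 0 seconds (free).
#' @param noise diffusion SD `s` (fixed constant, default 1.5).
#' @param start_offset `z0`, start point offset from `a/2` (fixed, 0.1).
#' @param lapse_mix lapse mixture weight in [0, 1) (fixed, 0.2).
#' @param lapse_rate rate of the exponential lapse process (fixed, 1/s).
#' @return object of class `"ddm_params"`.
#' @export
ddm_params <- function(drift_coef, boundary_sep, nondecision_t,
                       noise = 1.5, start_offset = 0.1,
                       lapse_mix = 0.2, lapse_rate = 1.0) {
  p <- list(drift_coef = drift_coef, boundary_sep = boundary_sep,
            nondecision_t = nondecision_t, noise = noise,
            start_offset = start_offset, lapse_mix = lapse_mix,
            lapse_rate = lapse_rate)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1L)))) {
    stop("all DDM parameters must be finite scalars")
  }
  if (boundary_sep <= 0) stop("boundary separation must be > 0")
  if (abs(start_offset) >= boundary_sep / 2) {
    stop("|start_offset| must be < boundary_sep / 2 (start point inside the bounds)")
  }
  if (noise <= 0) stop("noise must be > 0")
  if (lapse_mix < 0 || lapse_mix >= 1) stop("lapse_mix must be in [0, 1)")
  if (lapse_rate <= 0) stop("lapse_rate must be > 0")
  if (nondecision_t < 0) stop("nondecision time must be >= 0")
  structure(p, class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: k = %.4g, a = %.4g, t0 = %.4g s",
              x$drift_coef, x$boundary_sep, x$nondecision_t))
  cat(sprintf(" (s = %.3g, z0 = %.3g, lapse %.2g @ rate %.2g)\n",
              x$noise, x$start_offset, x$lapse_mix, x$lapse_rate))
  invisible(x)
}

#' Stimulus condition (luminances of the two offers)
#'
#' @param lum_high,lum_low luminances (LED counts) of the high- and
#'   low-value stimuli; both must be > 0.
#' @return object of class `"ddm_condition"`.
#' @export
ddm_condition <- function(lum_high = 8, lum_low = 2) {
  if (lum_high <= 0 || lum_low <= 0) stop("luminances must be > 0")
  structure(list(lum_high = lum_high, lum_low = lum_low),
            class = "ddm_condition")
}

#' Drift rate from luminance contrast
#'
#' `v = k * (log(lum_high) - log(lum_low))`: drift is linear in the log
#' luminance contrast of the two stimuli, so doubling both luminances
#' leaves the drift unchanged and positive `v` drives the accumulator
#' toward the high-value boundary.
#'
#' @param k drift coefficient.
#' @param cond a [ddm_condition()].
#' @return drift rate (evidence/s).
#' @export
drift_from_condition <- function(k, cond) {
  stopifnot(inherits(cond, "ddm_condition"))
  k * (log(cond$lum_high) - log(cond$lum_low))
}

# Start point on the evidence axis.
.ddm_start <- function(params) params$boundary_sep / 2 + params$start_offset

#' Closed-form probability of choosing the high-value option (pre-lapse)
#'
#' Absorption probability at the upper boundary for a Wiener process with
#' drift `v`, noise `s`, bounds at 0 and `a`, starting at `z = a/2 + z0`:
#' `P = (1 - exp(-2 v z / s^2)) / (1 - exp(-2 v a / s^2))`, with the
#' continuous limit `P = z/a` at `v = 0`. The lapse mixture is not applied;
#' the observed choice fraction is `(1 - lambda) * P + lambda / 2`.
#'
#' @param params a [ddm_params()].
#' @param cond a [ddm_condition()].
#' @return probability of high-boundary absorption.
#' @export
choice_prob_closed_form <- function(params, cond) {
  stopifnot(inherits(params, "ddm_params"))
  v <- drift_from_condition(params$drift_coef, cond)
  a <- params$boundary_sep
  z <- .ddm_start(params)
  s2 <- params$noise^2
  if (abs(v) < 1e-12 * s2 / a) return(z / a)
  expm1(-2 * v * z / s2) / expm1(-2 * v * a / s2)
}

# ---------------------------------------------------------------------------
# First-passage densities
# ---------------------------------------------------------------------------

# Standardized zero-drift first-passage density at the LOWER boundary for a
# unit-variance Wiener process on [0, 1] started at relative position w,
# evaluated at standardized times u = t / a'^2. Truncation per the usual
# small-time (image sum) / large-time (Fourier sine series) error bounds,
# absolute error < eps per point.
.fpt_f0 <- function(u, w, eps = 1e-8) {
  out <- numeric(length(u))
  pos <- u > 0
  if (!any(pos)) return(out)
  u <- u[pos]
  # required terms for each expansion (Navarro-Fuss style bounds)
  ks <- ifelse(eps < 1 / (2 * sqrt(2 * pi * u)),
               2 + sqrt(pmax(-2 * u * log(2 * eps * sqrt(2 * pi * u)), 0)),
               2)
  kl <- ifelse(eps < 1 / (pi * sqrt(u)),
               sqrt(pmax(-2 * log(pi * u * eps), 0) / (pi^2 * u)),
               1 / (pi * sqrt(u)))
  use_small <- ks < kl
  val <- numeric(length(u))
  if (any(use_small)) {
    us <- u[use_small]
    K <- ceiling((max(ks[use_small]) - 1) / 2)
    j <- (-K):K
    # sum_j (w + 2j) exp(-(w + 2j)^2 / (2u)) / sqrt(2 pi u^3)
    wj <- w + 2 * j
    term <- outer(1 / (2 * us), wj^2)      # (w+2j)^2 / (2u)
    val[use_small] <- as.vector(exp(-term) %*% wj) / sqrt(2 * pi * us^3)
  }
  if (any(!use_small)) {
    ul <- u[!use_small]
    K <- max(3, ceiling(max(kl[!use_small])))
    k <- seq_len(K)
    term <- outer(ul, k^2 * pi^2 / 2)      # k^2 pi^2 u / 2
    val[!use_small] <- pi * as.vector(exp(-term) %*% (k * sin(k * pi * w)))
  }
  out[pos] <- pmax(val, 0)
  out
}

# Boundary-resolved first-passage densities by the analytic series, before
# nondecision shift and lapse mixing. Scale invariance: X/s is a Wiener
# process with drift v/s on [0, a/s].
.fpt_series <- function(params, cond, tg) {
  v <- drift_from_condition(params$drift_coef, cond) / params$noise
  a <- params$boundary_sep / params$noise
  w <- .ddm_start(params) / params$boundary_sep
  u <- tg / a^2
  drift_fac_low <- exp(-v * a * w - v^2 * tg / 2)
  drift_fac_high <- exp(v * a * (1 - w) - v^2 * tg / 2)
  dens_low <- drift_fac_low * .fpt_f0(u, w) / a^2
  dens_high <- drift_fac_high * .fpt_f0(u, 1 - w) / a^2
  list(dens_high = dens_high, dens_low = dens_low)
}

# Crank-Nicolson integration of the Fokker-Planck equation
#   dp/dt = -v dp/dx + (s^2/2) d^2p/dx^2
# on [0, a] with absorbing ends and a (linearly allocated) delta initial
# condition at z. Rannacher startup (4 implicit-Euler half steps) damps the
# spurious oscillations the delta would excite under plain CN. Boundary
# absorption is recorded with the discrete flux that exactly telescopes the
# scheme's interior mass, so absorbed + remaining mass is conserved to
# machine precision.
.fpt_pde <- function(params, cond, tg, dt, n_x = NULL, refine = 40L,
                     refine0 = 320L, t_switch = 0.5) {
  v <- drift_from_condition(params$drift_coef, cond)
  a <- params$boundary_sep
  D <- params$noise^2 / 2
  z <- .ddm_start(params)
  # the first-passage peak sharpens as (noise/a)^2, so space resolution
  # follows the diffusion-scaled boundary separation
  if (is.null(n_x)) n_x <- ceiling(384 * max(1, 1.5 * params$noise / a))
  M <- as.integer(max(n_x, 201L))          # intervals; >= 200 interior points
  dx <- a / M
  ni <- M - 1L

  # tridiagonal operator L on interior nodes
  lower <- rep(v / (2 * dx) + D / dx^2, ni - 1L)
  diagc <- rep(-2 * D / dx^2, ni)
  upper <- rep(-v / (2 * dx) + D / dx^2, ni - 1L)
  Lmat <- matrix(0, ni, ni)
  Lmat[cbind(seq_len(ni), seq_len(ni))] <- diagc
  Lmat[cbind(2:ni, 1:(ni - 1L))] <- lower
  Lmat[cbind(1:(ni - 1L), 2:ni)] <- upper

  I <- diag(ni)
  dt_f <- dt / refine                      # fine step for the early transient
  dt_0 <- dt / refine0                     # finest step, first grid interval
  step_cn <- solve(I - (dt / 2) * Lmat, I + (dt / 2) * Lmat)
  step_cn_f <- solve(I - (dt_f / 2) * Lmat, I + (dt_f / 2) * Lmat)
  step_cn_0 <- solve(I - (dt_0 / 2) * Lmat, I + (dt_0 / 2) * Lmat)
  step_ie_0 <- solve(I - (dt_0 / 2) * Lmat)  # implicit Euler, finest half step

  p <- numeric(ni)
  i0 <- min(max(floor(z / dx), 1L), ni - 1L)
  frac <- z / dx - i0
  p[i0] <- (1 - frac) / dx
  p[i0 + 1L] <- frac / dx

  flux <- function(p) {
    c(low = D * p[1L] / dx - v * p[1L] / 2,
      high = D * p[ni] / dx + v * p[ni] / 2)
  }

  nt <- length(tg)
  dens_low <- numeric(nt)
  dens_high <- numeric(nt)
  # The density rises steeply just after the (near-)delta start. The first
  # grid interval is integrated at dt/refine0 with Rannacher startup (4
  # implicit half steps), the transient up to t_switch at dt/refine, and the
  # remainder with plain CN at dt; fluxes are recorded at the grid times.
  n_coarse_fine <- min(nt - 1L, max(1L, ceiling(t_switch / dt)))
  absorbed <- c(low = 0, high = 0)         # trapezoid at stepping resolution
  f_prev <- c(low = 0, high = 0)
  take <- function(stepm, h) {
    p <<- stepm %*% p
    f <- flux(p)
    absorbed <<- absorbed + h * (f_prev + f) / 2
    f_prev <<- f
    f
  }
  for (r in 1:4) f <- take(step_ie_0, dt_0 / 2)
  for (r in seq_len(refine0 - 2L)) f <- take(step_cn_0, dt_0)
  dens_low[2L] <- f["low"]
  dens_high[2L] <- f["high"]
  if (n_coarse_fine >= 2L) {
    for (n in 3:(n_coarse_fine + 1L)) {
      for (r in seq_len(refine)) f <- take(step_cn_f, dt_f)
      dens_low[n] <- f["low"]
      dens_high[n] <- f["high"]
    }
  }
  if (n_coarse_fine + 2L <= nt) {
    for (n in (n_coarse_fine + 2L):nt) {
      f <- take(step_cn, dt)
      dens_low[n] <- f["low"]
      dens_high[n] <- f["high"]
    }
  }
  list(dens_high = pmax(dens_high, 0), dens_low = pmax(dens_low, 0),
       absorbed_high = unname(absorbed["high"]),
       absorbed_low = unname(absorbed["low"]),
       p_undecided = dx * sum(p))
}

#' Solve for the first-passage time densities of the DDM
#'
#' Boundary-resolved densities of the decision time on a uniform grid,
#' before the nondecision shift and lapse mixture are applied. Two
#' independent routes are provided: `"series"` evaluates the analytic
#' small-time/large-time expansions of the Wiener first-passage density
#' (truncated for absolute error below 1e-6), and `"pde"` integrates the
#' Fokker-Planck equation by Crank-Nicolson on at least 200 interior space
#' points with absorbing boundaries.
#'
#' @param params a [ddm_params()].
#' @param cond a [ddm_condition()].
#' @param dt time step, in (0, 0.01] seconds (default 0.005).
#' @param T_max time horizon, >= 3 seconds (default 4).
#' @param method `"series"` or `"pde"`.
#' @return object of class `"fpt_solution"`: `time_grid` (from 0 to
#'   `T_max`), `dens_high`, `dens_low`, `p_undecided`, `p_high` (absorbed
#'   mass at the high boundary within the horizon), plus the inputs.
#' @export
fpt_solve <- function(params, cond, dt = 0.005, T_max = 4,
                      method = c("series", "pde")) {
  stopifnot(inherits(params, "ddm_params"), inherits(cond, "ddm_condition"))
  method <- match.arg(method)
  if (dt <= 0 || dt > 0.01) stop("dt must be in (0, 0.01]")
  if (T_max < 3) stop("horizon T_max must be >= 3 s")
  tg <- seq(0, T_max, by = dt)
  if (method == "series") {
    dens <- .fpt_series(params, cond, tg)
    absorbed_high <- .trapz(tg, dens$dens_high)
    absorbed_low <- .trapz(tg, dens$dens_low)
    p_undecided <- max(0, 1 - absorbed_high - absorbed_low)
  } else {
    dens <- .fpt_pde(params, cond, tg, dt)
    absorbed_high <- dens$absorbed_high
    absorbed_low <- dens$absorbed_low
    p_undecided <- dens$p_undecided
    mass_err <- abs(absorbed_high + absorbed_low + p_undecided - 1)
    if (mass_err > 1e-3) {
      stop("numerical-accuracy error: PDE mass defect ", signif(mass_err, 3),
           " exceeds tolerance 1e-3")
    }
  }
  structure(list(
    time_grid = tg,
    dens_high = dens$dens_high,
    dens_low = dens$dens_low,
    p_undecided = p_undecided,
    p_high = absorbed_high,
    p_low = absorbed_low,
    dt = dt, T_max = T_max, method = method,
    params = params, cond = cond
  ), class = "fpt_solution")
}

.trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)])) / 2

#' @export
print.fpt_solution <- function(x, ...) {
  cat(sprintf("First-passage solution (%s, dt = %g s, horizon %g s)\n",
              x$method, x$dt, x$T_max))
  cat(sprintf("  P(high) = %.4f, P(low) = %.4f, undecided = %.2e\n",
              x$p_high, x$p_low, x$p_undecided))
  invisible(x)
}

#' Likelihood of one or more (choice, latency) observations
#'
#' Lapse-mixture likelihood: with weight `1 - lambda` the density is the
#' first-passage density at the chosen boundary interpolated from `sol` and
#' shifted by the nondecision time (zero below `t0`); with weight `lambda`
#' it is the lapse density, an exponential with the fixed lapse rate whose
#' mass is split evenly between the two choices. Values are floored at
#' 1e-12 so log-likelihoods stay finite in support gaps.
#'
#' @param params a [ddm_params()] (supplies `t0` and the lapse constants).
#' @param cond a [ddm_condition()] (must match `sol`).
#' @param choice character vector, `"high"` or `"low"`.
#' @param latency_s observed latencies (seconds, >= 0).
#' @param sol a `"fpt_solution"` for `params` without nondecision shift.
#' @return vector of density values (1/seconds).
#' @export
trial_likelihood <- function(params, cond, choice, latency_s, sol) {
  stopifnot(inherits(sol, "fpt_solution"), all(latency_s >= 0))
  if (length(choice) != length(latency_s)) stop("choice/latency length mismatch")
  lam <- params$lapse_mix
  r <- params$lapse_rate
  td <- latency_s - params$nondecision_t
  f <- numeric(length(td))
  ok <- td >= 0 & td <= sol$T_max
  if (any(ok)) {
    hi <- choice == "high"
    f[ok & hi] <- stats::approx(sol$time_grid, sol$dens_high,
                                xout = td[ok & hi], rule = 1)$y
    f[ok & !hi] <- stats::approx(sol$time_grid, sol$dens_low,
                                 xout = td[ok & !hi], rule = 1)$y
  }
  f[is.na(f)] <- 0
  g <- 0.5 * r * exp(-r * latency_s)
  pmax((1 - lam) * f + lam * g, 1e-12)
}

#' Simulate dual-offer choices and latencies from the DDM
#'
#' Euler-Maruyama paths with absorbing bounds at 0 and `a`, with the exact
#' Brownian-bridge within-step crossing correction (the probability that
#' the path crossed a boundary between grid points is
#' `exp(-2 d_old d_new / (s^2 dt))`), which removes the O(sqrt(dt))
#' boundary bias of the plain scheme. Lapse trials occur with the fixed
#' mixture weight: their choice is uniform and their latency an
#' exponential draw with the lapse rate (no nondecision shift). Non-lapse
#' latencies are decision time + `t0`.
#'
#' @param params a [ddm_params()].
#' @param cond a [ddm_condition()].
#' @param n number of trials.
#' @param dt Euler step (seconds, default 0.001).
#' @param seed optional integer seed (caller's RNG stream preserved).
#' @param max_time safety horizon (seconds); paths still alive are absorbed
#'   at the nearer boundary (probability negligible for sane parameters).
#' @return data.frame with columns `choice` ("high"/"low"), `latency_s`,
#'   `lapse` (logical).
#' @export
simulate_ddm <- function(params, cond, n, dt = 0.001, seed = NULL,
                         max_time = 30) {
  stopifnot(inherits(params, "ddm_params"), n >= 1)
  v <- drift_from_condition(params$drift_coef, cond)
  a <- params$boundary_sep
  s <- params$noise
  z <- .ddm_start(params)
  with_seed(seed, {
    lapse <- stats::runif(n) < params$lapse_mix
    n_lapse <- sum(lapse)
    choice <- character(n)
    lat <- numeric(n)
    if (n_lapse > 0L) {
      choice[lapse] <- ifelse(stats::runif(n_lapse) < 0.5, "high", "low")
      lat[lapse] <- stats::rexp(n_lapse, rate = params$lapse_rate)
    }
    n_dif <- n - n_lapse
    if (n_dif > 0L) {
      x <- rep(z, n_dif)
      dec_t <- rep(NA_real_, n_dif)
      dec_hi <- logical(n_dif)
      alive <- seq_len(n_dif)
      t_now <- 0
      sq <- s * sqrt(dt)
      while (length(alive) > 0L && t_now < max_time) {
        t_now <- t_now + dt
        xo <- x[alive]
        xn <- xo + v * dt + sq * stats::rnorm(length(alive))
        hit_hi <- xn >= a
        hit_lo <- xn <= 0
        inside <- !hit_hi & !hit_lo
        if (any(inside)) {
          # Brownian-bridge crossing probabilities within the step
          p_hi <- exp(-2 * (a - xo[inside]) * (a - xn[inside]) / (s^2 * dt))
          p_lo <- exp(-2 * xo[inside] * xn[inside] / (s^2 * dt))
          u <- stats::runif(sum(inside))
          br_hi <- u < p_hi
          br_lo <- !br_hi & (u < p_hi + p_lo)
          hit_hi[inside] <- br_hi
          hit_lo[inside] <- br_lo
        }
        done <- hit_hi | hit_lo
        if (any(done)) {
          idx <- alive[done]
          dec_t[idx] <- t_now
          dec_hi[idx] <- hit_hi[done]
          alive <- alive[!done]
          x[alive] <- xn[!done]
        } else {
          x[alive] <- xn
        }
      }
      if (length(alive) > 0L) {           # safety net, ~never reached
        dec_t[alive] <- max_time
        dec_hi[alive] <- x[alive] >= a / 2
      }
      choice[!lapse] <- ifelse(dec_hi, "high", "low")
      lat[!lapse] <- dec_t + params$nondecision_t
    }
    data.frame(choice = choice, latency_s = lat, lapse = lapse,
               stringsAsFactors = FALSE)
  })
}

#' Trim latencies at an upper empirical percentile
#'
#' Retains values at or below the pth empirical percentile (linear
#' interpolation definition, `quantile(..., type = 7)`), the screening used
#' before outlier-sensitive model fitting.
#'
#' @param latencies nonempty numeric vector.
#' @param percentile upper percentile in (50, 100].
#' @return the retained latencies, with attributes `cut_point` and
#'   `n_removed`.
#' @export
trim_to_percentile <- function(latencies, percentile = 95) {
  if (length(latencies) == 0L) stop("empty latency sample")
  if (percentile <= 50 || percentile > 100) {
    stop("configuration error: percentile must be in (50, 100]")
  }
  cut <- stats::quantile(latencies, percentile / 100, names = FALSE, type = 7)
  keep <- latencies <= cut
  structure(latencies[keep], cut_point = cut, n_removed = sum(!keep))
}
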