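# Descriptive behavioral measures: latency screening, per-group median
# latencies, choice and error percentages, the dual-minus-single offer
# effect, and robust (Huber) within-session slowing.

# Derived value label of a trial: the chosen stimulus for dual offers and
# correct single offers; error trials (chosen = none) return NA.
.trial_value <- function(trials) {
  ifelse(trials$chosen %in% c("high", "low"), trials$chosen, NA_character_)
}

#' Screen latencies for the latency-analysis view
#'
#' Removes trials with response latencies above `max_latency_s` (task
#' disengagement; default 3 s) and removes error trials, which carry no
#' latency to a chosen port. Counts of both removals are recorded in the
#' dataset metadata. Error *rates* must be computed from the unscreened
#' dataset (see [error_percentage()]).
#'
#' @param dataset a `trial_dataset`.
#' @param max_latency_s screening threshold in seconds (> 0).
#' @return the screened `trial_dataset`; `$meta$screen` holds
#'   `max_latency_s`, `n_latency_removed`, `n_error_removed`.
#' @export
screen_latencies <- function(dataset, max_latency_s = 3.0) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (max_latency_s <= 0) stop("configuration error: max_latency_s must be > 0")
  tr <- dataset$trials
  slow <- tr$latency_s > max_latency_s
  err <- tr$is_error %in% TRUE
  out <- dataset_subset(dataset, !slow & !err)
  out$meta$screen <- list(max_latency_s = max_latency_s,
                          n_latency_removed = sum(slow),
                          n_error_removed = sum(err & !slow))
  out
}

#' Per-group median response latencies
#'
#' Median latency (linear interpolation for even group sizes, as
#' [stats::median()]) per grouping cell. Groups smaller than `min_n` trials
#' yield a missing median; empty groups are absent from the table. Cohort
#' summaries should average the per-rat medians, mirroring an analysis in
#' which the rat is the experimental unit.
#'
#' @param dataset a screened `trial_dataset` (see [screen_latencies()]).
#' @param by grouping columns; `"value"` is accepted as a derived column
#'   (the chosen stimulus value).
#' @param min_n minimum trials for a median to be reported (default 5).
#' @return data.frame of grouping columns plus `median_latency_s`, `n_trials`.
#' @export
median_latency <- function(dataset,
                           by = c("rat_id", "session_index", "trial_type", "value"),
                           min_n = 5L) {
  stopifnot(inherits(dataset, "trial_dataset"))
  tr <- dataset$trials
  tr$value <- .trial_value(tr)
  bad <- setdiff(by, names(tr))
  if (length(bad) > 0L) stop("unknown grouping column(s): ", paste(bad, collapse = ", "))
  keep <- !is.na(tr$value) | !"value" %in% by
  tr <- tr[keep, , drop = FALSE]
  if (nrow(tr) == 0L) {
    out <- tr[, by, drop = FALSE]
    out$median_latency_s <- numeric()
    out$n_trials <- integer()
    return(out)
  }
  key <- interaction(tr[by], drop = TRUE, sep = "\r")
  med <- tapply(tr$latency_s, key, stats::median)
  n <- as.integer(tapply(tr$latency_s, key, length))
  parts <- strsplit(names(med), "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- by
  if ("session_index" %in% by) out$session_index <- as.integer(out$session_index)
  out$median_latency_s <- ifelse(n >= min_n, as.numeric(med), NA_real_)
  out$n_trials <- n
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' High-value choice percentage on dual-offer trials
#'
#' Percentage of dual-offer trials on which the high-value stimulus was
#' chosen, per rat and session: number of high choices divided by the
#' total number of dual-offer trials (after any screening applied to the
#' dataset). Rat-sessions without dual-offer trials get a missing value.
#'
#' @param dataset a `trial_dataset`.
#' @return data.frame `rat_id`, `session_index`, `choice_pct` (0-100),
#'   `n_dual`.
#' @export
choice_percentage <- function(dataset) {
  .rate_table(dataset, type = "dual",
              num = function(tr) tr$chosen == "high",
              rate_col = "choice_pct", n_col = "n_dual")
}

#' Error percentage on single-offer trials
#'
#' Percentage of single-offer trials on which the rat responded at the
#' non-illuminated port, per rat and session. Compute this from the
#' unscreened dataset: latency screening removes error trials.
#'
#' @param dataset a `trial_dataset`.
#' @return data.frame `rat_id`, `session_index`, `error_pct` (0-100),
#'   `n_single`.
#' @export
error_percentage <- function(dataset) {
  .rate_table(dataset, type = "single",
              num = function(tr) tr$is_error %in% TRUE,
              rate_col = "error_pct", n_col = "n_single")
}

# Shared per-rat/session rate computation over one trial type.
.rate_table <- function(dataset, type, num, rate_col, n_col) {
  stopifnot(inherits(dataset, "trial_dataset"))
  tr <- dataset$trials
  sessions <- unique(tr[c("rat_id", "session_index")])
  sub <- tr[tr$trial_type == type, , drop = FALSE]
  key <- paste(sub$rat_id, sub$session_index, sep = "\r")
  n <- tapply(rep(1L, nrow(sub)), key, sum)
  hits <- tapply(num(sub), key, sum)
  skey <- paste(sessions$rat_id, sessions$session_index, sep = "\r")
  out <- data.frame(
    rat_id = sessions$rat_id,
    session_index = sessions$session_index,
    rate = 100 * as.numeric(hits[skey]) / as.numeric(n[skey]),
    n = ifelse(is.na(n[skey]), 0L, as.integer(n[skey])),
    stringsAsFactors = FALSE)
  names(out)[3:4] <- c(rate_col, n_col)
  out <- out[order(out$rat_id, out$session_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dual-minus-single offer effect on median latencies
#'
#' Signed difference between the dual-offer and single-offer median
#' latencies for the same stimulus value, per rat, session, and value —
#' the deliberation measure. A missing median (group below `min_n`)
#' propagates to a missing difference. Cohort summaries are means of the
#' per-rat differences.
#'
#' @param dataset a screened `trial_dataset`.
#' @param min_n minimum trials per median (see [median_latency()]).
#' @return data.frame `rat_id`, `session_index`, `value`, `offer_effect_s`,
#'   `n_dual`, `n_single`.
#' @export
offer_effect <- function(dataset, min_n = 5L) {
  med <- median_latency(dataset, by = c("rat_id", "session_index",
                                        "trial_type", "value"),
                        min_n = min_n)
  dual <- med[med$trial_type == "dual", , drop = FALSE]
  single <- med[med$trial_type == "single", , drop = FALSE]
  out <- merge(single[c("rat_id", "session_index", "value",
                        "median_latency_s", "n_trials")],
               dual[c("rat_id", "session_index", "value",
                      "median_latency_s", "n_trials")],
               by = c("rat_id", "session_index", "value"),
               suffixes = c("_single", "_dual"), all = TRUE)
  out$offer_effect_s <- out$median_latency_s_dual - out$median_latency_s_single
  res <- out[c("rat_id", "session_index", "value", "offer_effect_s")]
  res$n_dual <- ifelse(is.na(out$n_trials_dual), 0L, out$n_trials_dual)
  res$n_single <- ifelse(is.na(out$n_trials_single), 0L, out$n_trials_single)
  res <- res[order(res$rat_id, res$session_index, res$value), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Within-session slowing by Huber robust regression
#'
#' Robust linear fit of response latency on within-session time by
#' iteratively reweighted least squares with Huber weights
#' (`w = min(1, k / |standardized residual|)`, tuning constant `k = 1.345`),
#' residual scale re-estimated each iteration by the normalized MAD.
#' Iterations stop when the relative coefficient change falls below `tol`
#' (default 1e-8) or after `max_iter` iterations; non-convergence is
#' flagged, not thrown. With no large residuals the fit coincides with
#' ordinary least squares.
#'
#' @param trials data.frame of one session's screened trials with columns
#'   `latency_s` and `trial_start_s` (at least 10 rows).
#' @param k Huber tuning constant in standardized residual units.
#' @param max_iter,tol iteration controls.
#' @return list: `slope` (seconds of latency per second of session time),
#'   `intercept`, `weighted_r2`, `f_stat`, `df`, `scale`, `converged`,
#'   `iterations`, `n`.
#' @export
within_session_slowing <- function(trials, k = 1.345, max_iter = 200L,
                                   tol = 1e-8) {
  stopifnot(is.data.frame(trials),
            all(c("latency_s", "trial_start_s") %in% names(trials)))
  y <- trials$latency_s
  x <- trials$trial_start_s
  n <- length(y)
  if (n < 10L) stop("need at least 10 trials for within-session regression")
  X <- cbind(1, x)
  beta <- stats::lm.fit(X, y)$coefficients
  converged <- FALSE
  iter <- 0L
  w <- rep(1, n)
  scale <- NA_real_
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- y - X %*% beta
    scale <- stats::mad(r, center = 0)
    if (scale < .Machine$double.eps * max(1, mean(abs(y)))) {
      converged <- TRUE                    # (near-)exact fit
      w <- rep(1, n)
      break
    }
    rs <- abs(r) / scale
    w <- pmin(1, k / pmax(rs, .Machine$double.eps))
    beta_new <- stats::lm.wfit(X, y, w)$coefficients
    delta <- max(abs(beta_new - beta)) / max(max(abs(beta)), .Machine$double.eps)
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  r <- as.vector(y - X %*% beta)
  ybar_w <- sum(w * y) / sum(w)
  ss_res <- sum(w * r^2)
  ss_tot <- sum(w * (y - ybar_w)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  fstat <- if (!is.na(r2) && r2 < 1) (r2 / 1) / ((1 - r2) / (n - 2L)) else Inf
  list(slope = unname(beta[2L]), intercept = unname(beta[1L]),
       weighted_r2 = r2, f_stat = fstat, df = c(1L, n - 2L),
       scale = scale, converged = converged, iterations = iter, n = n)
}
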