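# End-to-end orchestration: load or simulate a cohort, validate, screen,
# compute behavioral metrics, fit the ex-Gaussian and DDM models, run the
# resampling statistics, and assemble a reproducible report.

#' Pipeline configuration
#'
#' Exactly one of `input` (path to a canonical trial CSV) or `simulate`
#' (a [cohort_config()]) must be given.
#'
#' @param input path to a canonical trial table CSV, or `NULL`.
#' @param simulate a [cohort_config()], or `NULL`.
#' @param max_latency_s latency screening threshold (seconds).
#' @param trim_percentile optional upper-percentile latency trim applied to
#'   dual-offer latencies before DDM fitting (`NULL` to disable).
#' @param exgauss_min_n minimum trials per ex-Gaussian fit cell.
#' @param ddm list of DDM fitting settings: `bounds`, `de_config`,
#'   `per_rat` (fit each rat x session), `min_trials`.
#' @param bonferroni_m multiple-testing family size for the per-value
#'   offer-effect permutation tests (`NULL`: the number of sessions).
#' @param n_perm,n_boot resampling sizes for the permutation tests.
#' @param out_dir directory for CSV/JSON outputs (`NULL`: in-memory only).
#' @param seed master seed for every stochastic stage.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            max_latency_s = 3.0,
                            trim_percentile = NULL,
                            exgauss_min_n = 40L,
                            ddm = list(),
                            bonferroni_m = NULL,
                            n_perm = 5000L, n_boot = 5000L,
                            out_dir = NULL, seed = 1L) {
  if (is.null(input) == is.null(simulate)) {
    stop("exactly one of `input` or `simulate` must be given")
  }
  if (!is.null(simulate)) .check_cohort_config(simulate)
  ddm <- utils::modifyList(list(
    bounds = list(drift_coef = c(0.02, 6), boundary_sep = c(0.25, 6),
                  nondecision_t = c(0, 1)),
    de_config = list(generations = 40L, tol = 1e-2),
    per_rat = TRUE,
    min_trials = 50L
  ), ddm)
  structure(list(input = input, simulate = simulate,
                 max_latency_s = max_latency_s,
                 trim_percentile = trim_percentile,
                 exgauss_min_n = as.integer(exgauss_min_n),
                 ddm = ddm, bonferroni_m = bonferroni_m,
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# ---------------------------------------------------------------------------
# stages
# ---------------------------------------------------------------------------

.stage_exgauss <- function(screened, min_n, seed) {
  tr <- screened$trials
  tr$value <- .trial_value(tr)
  tr <- tr[!is.na(tr$value), , drop = FALSE]
  cells <- unique(tr[c("rat_id", "session_index", "trial_type", "value")])
  cells <- cells[order(cells$rat_id, cells$session_index, cells$trial_type,
                       cells$value), , drop = FALSE]
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ce <- cells[i, ]
    lat <- tr$latency_s[tr$rat_id == ce$rat_id &
                        tr$session_index == ce$session_index &
                        tr$trial_type == ce$trial_type &
                        tr$value == ce$value]
    row <- data.frame(ce, mu = NA_real_, sigma = NA_real_, tau = NA_real_,
                      loglik = NA_real_, n = length(lat), converged = NA,
                      ks_p = NA_real_, accepted = NA,
                      stringsAsFactors = FALSE)
    if (length(lat) >= min_n && stats::sd(lat) > 0) {
      fit <- fit_exgauss(lat, min_n = min_n)
      row$mu <- fit$params["mu"]; row$sigma <- fit$params["sigma"]
      row$tau <- fit$params["tau"]; row$loglik <- fit$loglik
      row$converged <- fit$converged
      if (fit$converged) {
        fit <- validate_exgauss_fit(lat, fit,
                                    seed = child_seed(seed, paste0("exg/", i)))
        row$ks_p <- fit$validation$ks_p
        row$accepted <- fit$validation$accepted
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.stage_ddm <- function(screened, cfgp, cond, seed) {
  tr <- screened$trials
  dual <- tr[tr$trial_type == "dual", , drop = FALSE]
  dual$choice <- dual$chosen
  fits <- list()
  fit_row <- function(fit) {
    data.frame(scope = fit$scope, rat_id = fit$rat_id,
               session_index = fit$session_index,
               drift_coef = fit$params$drift_coef,
               boundary_sep = fit$params$boundary_sep,
               nondecision_t = fit$params$nondecision_t,
               loglik = fit$loglik, n = fit$n_trials,
               boundary_warning = fit$boundary_warning,
               stringsAsFactors = FALSE)
  }
  sessions <- sort(unique(dual$session_index))
  for (s in sessions) {
    ds <- dual[dual$session_index == s, , drop = FALSE]
    if (nrow(ds) >= cfgp$ddm$min_trials) {
      fit <- fit_ddm(ds, cond, bounds = cfgp$ddm$bounds,
                     de_config = utils::modifyList(
                       cfgp$ddm$de_config,
                       list(seed = child_seed(seed, paste0("ddm/pool/", s)))),
                     trim_percentile = cfgp$trim_percentile,
                     min_trials = cfgp$ddm$min_trials,
                     scope = "pooled", session_index = s)
      fits[[length(fits) + 1L]] <- fit_row(fit)
    }
    if (isTRUE(cfgp$ddm$per_rat)) {
      for (r in sort(unique(ds$rat_id))) {
        dr <- ds[ds$rat_id == r, , drop = FALSE]
        if (nrow(dr) >= cfgp$ddm$min_trials) {
          fit <- fit_ddm(dr, cond, bounds = cfgp$ddm$bounds,
                         de_config = utils::modifyList(
                           cfgp$ddm$de_config,
                           list(seed = child_seed(seed, paste0("ddm/", r, "/", s)))),
                         trim_percentile = cfgp$trim_percentile,
                         min_trials = cfgp$ddm$min_trials,
                         scope = "per_rat", rat_id = r, session_index = s)
          fits[[length(fits) + 1L]] <- fit_row(fit)
        }
      }
    }
  }
  if (length(fits) == 0L) return(NULL)
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out
}

.stage_offer_tests <- function(medians, cfgp, seed) {
  res <- list()
  for (v in c("high", "low")) {
    sess <- sort(unique(medians$session_index))
    m <- if (is.null(cfgp$bonferroni_m)) length(sess) else cfgp$bonferroni_m
    for (s in sess) {
      cell <- medians[medians$session_index == s & medians$value == v, ]
      w <- merge(cell[cell$trial_type == "single", c("rat_id", "median_latency_s")],
                 cell[cell$trial_type == "dual", c("rat_id", "median_latency_s")],
                 by = "rat_id", suffixes = c("_single", "_dual"))
      w <- w[stats::complete.cases(w), , drop = FALSE]
      if (nrow(w) < 3L) next
      pt <- paired_permutation_test(w$median_latency_s_single,
                                    w$median_latency_s_dual,
                                    n_perm = cfgp$n_perm, n_boot = cfgp$n_boot,
                                    seed = child_seed(seed, paste0("perm/", v, "/", s)))
      res[[length(res) + 1L]] <- data.frame(
        value = v, session_index = s, n_rats = nrow(w),
        mean_diff_s = pt$mean_diff, ci_low = pt$ci_low, ci_high = pt$ci_high,
        p_raw = pt$p_value, m = m, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) return(NULL)
  out <- do.call(rbind, res)
  out$p_bonferroni <- NA_real_
  for (v in unique(out$value)) {
    sel <- out$value == v
    out$p_bonferroni[sel] <- bonferroni(out$p_raw[sel], m = out$m[sel][1L])
  }
  rownames(out) <- NULL
  out
}

# rmANOVA of per-rat medians (session x trial type), one per value, using
# only rats with a complete cell grid.
.stage_rm_anova <- function(medians) {
  out <- list()
  for (v in c("high", "low")) {
    mv <- medians[medians$value == v & !is.na(medians$median_latency_s), ]
    if (nrow(mv) == 0L) next
    n_cells <- length(unique(mv$session_index)) * length(unique(mv$trial_type))
    per_rat <- table(mv$rat_id)
    keep <- names(per_rat)[per_rat == n_cells]
    mv <- mv[mv$rat_id %in% keep, , drop = FALSE]
    if (length(keep) < 3L || length(unique(mv$session_index)) < 2L) next
    an <- rm_anova(mv, dv = "median_latency_s", subject = "rat_id",
                   within = c("session_index", "trial_type"))
    an$value <- v
    an$n_rats <- length(keep)
    out[[length(out) + 1L]] <- as.data.frame(an)
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# Repeated-measures correlations of per-rat/session DDM parameters against
# behavioral and ex-Gaussian measures.
.stage_rm_corr <- function(ddm_fits, choice_pct, exgauss_fits, medians) {
  if (is.null(ddm_fits)) return(NULL)
  per <- ddm_fits[ddm_fits$scope == "per_rat", , drop = FALSE]
  if (nrow(per) == 0L) return(NULL)
  tab <- merge(per[c("rat_id", "session_index", "drift_coef", "boundary_sep",
                     "nondecision_t")],
               choice_pct[c("rat_id", "session_index", "choice_pct")],
               by = c("rat_id", "session_index"), all.x = TRUE)
  exg <- exgauss_fits[exgauss_fits$trial_type == "dual" &
                      exgauss_fits$value == "high",
                      c("rat_id", "session_index", "mu", "tau")]
  names(exg)[3:4] <- c("exg_mu", "exg_tau")
  tab <- merge(tab, exg, by = c("rat_id", "session_index"), all.x = TRUE)

  pool <- medians[!is.na(medians$median_latency_s), , drop = FALSE]
  med_rv <- stats::aggregate(median_latency_s ~ rat_id + session_index + value,
                             pool, stats::median)
  wide_v <- stats::reshape(med_rv, idvar = c("rat_id", "session_index"),
                           timevar = "value", direction = "wide")
  wide_v$value_effect_s <- wide_v$median_latency_s.low - wide_v$median_latency_s.high
  tab <- merge(tab, wide_v[c("rat_id", "session_index", "value_effect_s")],
               by = c("rat_id", "session_index"), all.x = TRUE)
  oh <- medians[medians$value == "high", , drop = FALSE]
  wide_o <- merge(oh[oh$trial_type == "single",
                     c("rat_id", "session_index", "median_latency_s")],
                  oh[oh$trial_type == "dual",
                     c("rat_id", "session_index", "median_latency_s")],
                  by = c("rat_id", "session_index"),
                  suffixes = c("_single", "_dual"))
  wide_o$offer_effect_s <- wide_o$median_latency_s_dual - wide_o$median_latency_s_single
  tab <- merge(tab, wide_o[c("rat_id", "session_index", "offer_effect_s")],
               by = c("rat_id", "session_index"), all.x = TRUE)

  params <- c("drift_coef", "boundary_sep", "nondecision_t")
  measures <- c("choice_pct", "exg_mu", "exg_tau", "offer_effect_s",
                "value_effect_s")
  rows <- list()
  for (p in params) {
    for (m in measures) {
      sub <- tab[!is.na(tab[[p]]) & !is.na(tab[[m]]), c("rat_id", p, m)]
      enough <- table(sub$rat_id) >= 2L
      if (sum(enough) < 3L) next
      rc <- tryCatch(suppressWarnings(rm_corr(sub, "rat_id", m, p)),
                     error = function(e) NULL)
      if (is.null(rc)) next
      rows[[length(rows) + 1L]] <- data.frame(
        param = p, measure = m, r = rc$r, df = rc$df, p = rc$p,
        ci_low = rc$ci_low, ci_high = rc$ci_high, n_obs = rc$n_obs,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
  list(table = out, measures = tab)
}

.stage_slowing <- function(screened) {
  tr <- screened$trials
  key <- unique(tr[c("rat_id", "session_index")])
  rows <- list()
  for (i in seq_len(nrow(key))) {
    sub <- tr[tr$rat_id == key$rat_id[i] &
              tr$session_index == key$session_index[i], , drop = FALSE]
    if (nrow(sub) < 10L) next
    h <- within_session_slowing(sub)
    rows[[length(rows) + 1L]] <- data.frame(
      rat_id = key$rat_id[i], session_index = key$session_index[i],
      slope_s_per_s = h$slope, intercept_s = h$intercept,
      weighted_r2 = h$weighted_r2, converged = h$converged, n = h$n,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$rat_id, out$session_index), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# run
# ---------------------------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the cohort; validate; compute error
#' percentages (unscreened); screen latencies (3 s threshold, error trials
#' removed); per-cell median latencies, choice percentages, offer effects,
#' and within-session Huber slowing; ex-Gaussian fits per rat x session x
#' trial type x value with simulate-and-test validation; DDM fits on
#' dual-offer trials (pooled per session, and per rat when configured);
#' paired permutation tests of dual vs single medians per value x session
#' with Bonferroni correction; repeated-measures ANOVA of the medians; and
#' repeated-measures correlations of the per-rat DDM parameters with choice
#' percentage, ex-Gaussian mu/tau, and the offer- and value-effect
#' measures. Fully deterministic under `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `"analysis_report"`; when `config$out_dir` is
#'   set, tables are also written as CSV plus a `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  dataset <- if (!is.null(config$input)) {
    read_trial_table(config$input)
  } else {
    cfg <- config$simulate
    cfg$seed <- child_seed(seed, "simulate")
    generate_cohort(cfg)
  }
  v <- validate_dataset(dataset)
  if (nrow(v) > 0L) {
    stop("stage validate: dataset has ", nrow(v), " violation(s); first: ",
         v$message[1L], " [", v$address[1L], "]")
  }

  err_pct <- error_percentage(dataset)
  screened <- screen_latencies(dataset, config$max_latency_s)
  medians <- median_latency(screened)
  choice_pct <- choice_percentage(screened)
  offer <- offer_effect(screened)
  slowing <- .stage_slowing(screened)
  exg <- .stage_exgauss(screened, config$exgauss_min_n, seed)
  cond <- if (!is.null(config$simulate)) {
    ddm_condition(config$simulate$luminance_high, config$simulate$luminance_low)
  } else {
    ddm_condition()
  }
  ddm_fits <- .stage_ddm(screened, config, cond, seed)
  offer_tests <- .stage_offer_tests(medians, config, seed)
  anova_tab <- .stage_rm_anova(medians)
  rmc <- .stage_rm_corr(ddm_fits, choice_pct, exg, medians)

  report <- structure(list(
    metrics = list(medians = medians, choice_pct = choice_pct,
                   error_pct = err_pct, offer_effect = offer,
                   slowing = slowing),
    exgauss_fits = exg,
    ddm_fits = ddm_fits,
    stats = list(offer_tests = offer_tests, rm_anova = anova_tab,
                 rm_corr = rmc$table),
    rm_corr_measures = rmc$measures,
    provenance = list(
      seed = seed,
      screen_max_latency_s = config$max_latency_s,
      trim_percentile = config$trim_percentile,
      ddm_constants = list(noise = 1.5, start_offset = 0.1,
                           lapse_mix = 0.2, lapse_rate = 1.0),
      n_trials = nrow(dataset$trials),
      n_removed_latency = screened$meta$screen$n_latency_removed,
      n_removed_error = screened$meta$screen$n_error_removed,
      source = dataset$meta$source,
      package_version = as.character(utils::packageVersion("choicedyn"))
    ),
    dataset = dataset
  ), class = "analysis_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  %d trials from %s; %d medians cells, %d ex-Gaussian fits, %d DDM fits\n",
              x$provenance$n_trials, x$provenance$source,
              nrow(x$metrics$medians), nrow(x$exgauss_fits),
              if (is.null(x$ddm_fits)) 0L else nrow(x$ddm_fits)))
  if (!is.null(x$stats$offer_tests)) {
    sig <- sum(x$stats$offer_tests$p_bonferroni < 0.05)
    cat(sprintf("  offer-effect permutation tests: %d of %d significant after Bonferroni\n",
                sig, nrow(x$stats$offer_tests)))
  }
  if (!is.null(x$stats$rm_corr)) {
    top <- x$stats$rm_corr[which.max(abs(x$stats$rm_corr$r)), ]
    cat(sprintf("  strongest rm-correlation: %s ~ %s, r = %.3f\n",
                top$param, top$measure, top$r))
  }
  invisible(x)
}

#' Write the report tables of an analysis
#'
#' Writes `metrics.csv` (medians), `choice_pct.csv`, `error_pct.csv`,
#' `offer_effect.csv`, `slowing.csv`, `exgauss_fits.csv`, `ddm_fits.csv`
#' and a `report.json` holding the statistics block and provenance.
#'
#' @param report an `"analysis_report"`.
#' @param out_dir destination directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  wcsv(report$metrics$medians, "metrics.csv")
  wcsv(report$metrics$choice_pct, "choice_pct.csv")
  wcsv(report$metrics$error_pct, "error_pct.csv")
  wcsv(report$metrics$offer_effect, "offer_effect.csv")
  wcsv(report$metrics$slowing, "slowing.csv")
  wcsv(report$exgauss_fits, "exgauss_fits.csv")
  wcsv(report$ddm_fits, "ddm_fits.csv")
  jsonlite::write_json(
    list(stats = report$stats, provenance = report$provenance),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(out_dir)
}

#' Re-analyze a converted deposited dataset
#'
#' Runs the identical pipeline on a user-converted canonical trial CSV and
#' attaches a comparison of the cohort-level summaries against the
#' published reference values the pipeline was designed around (first-session
#' dual/single medians, high-choice percentage, per-value offer effects,
#' and the drift-vs-choice repeated-measures correlation). With fewer than
#' three rats the comparison is marked insufficient rather than computed.
#'
#' @param path canonical trial CSV (converted from the deposited session
#'   files by the user; raw MedPC parsing is out of scope).
#' @param ... further arguments passed to [pipeline_config()].
#' @return an `"analysis_report"` with an extra `$comparison` data.frame.
#' @export
replicate_from_deposited <- function(path, ...) {
  if (!file.exists(path)) {
    stop("deposited-data file not found: ", path,
         "\nConvert the deposited session files to the canonical CSV ",
         "(see ?read_trial_table) and pass its path.")
  }
  report <- run_pipeline(pipeline_config(input = path, ...))
  reference <- data.frame(
    quantity = c("median latency, dual offers, session 1 (ms)",
                 "median latency, single offers, session 1 (ms)",
                 "high-value choice percentage, session 1",
                 "offer effect, high value, session 1 (s)",
                 "offer effect, low value, session 1 (s)",
                 "rm-correlation drift vs high-choice %"),
    reference = c(625, 521, 72, 0.09, 0.12, 0.9222),
    stringsAsFactors = FALSE)
  n_rats <- length(unique(report$dataset$trials$rat_id))
  if (n_rats < 3L) {
    reference$measured <- NA_real_
    reference$note <- "insufficient n"
  } else {
    med1 <- report$metrics$medians
    med1 <- med1[med1$session_index == 1L & !is.na(med1$median_latency_s), ]
    rat_med <- function(tt) {
      m <- stats::aggregate(median_latency_s ~ rat_id,
                            med1[med1$trial_type == tt, ], stats::median)
      1000 * mean(m$median_latency_s)
    }
    cp <- report$metrics$choice_pct
    oe <- report$stats$offer_tests
    oe1 <- function(v) {
      r <- oe[oe$value == v & oe$session_index == 1L, "mean_diff_s"]
      if (length(r) == 1L) r else NA_real_
    }
    rc <- report$stats$rm_corr
    r_drift <- if (!is.null(rc)) {
      rr <- rc[rc$param == "drift_coef" & rc$measure == "choice_pct", "r"]
      if (length(rr) == 1L) rr else NA_real_
    } else NA_real_
    reference$measured <- c(
      rat_med("dual"), rat_med("single"),
      mean(cp$choice_pct[cp$session_index == 1L], na.rm = TRUE),
      oe1("high"), oe1("low"), r_drift)
    reference$note <- ""
  }
  report$comparison <- reference
  report
}
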