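# Canonical trial-table data model for 2AFC choice-learning experiments.
#
# A trial dataset is a list with two components:
#   $trials - data.frame, one row per trial, canonical columns (see below)
#   $meta   - list of provenance fields (source, screening applied, dialect)
# carrying S3 class "trial_dataset".

.CANONICAL_COLUMNS <- c(
  "rat_id", "phase", "session_index", "trial_index", "trial_type",
  "offered_high", "offered_low", "high_side", "chosen", "is_error",
  "latency_s", "trial_start_s"
)

.PHASES <- c("value_learning", "choice_learning")
.TRIAL_TYPES <- c("single", "dual")
.SIDES <- c("left", "right")
.CHOICES <- c("high", "low", "none")

.DIALECT_VERSION <- "canonical_csv/1"

#' Construct a trial dataset
#'
#' Bundles a trial table with provenance metadata. The table must carry the
#' canonical column set; rows are one behavioral trial each (identity, offer
#' configuration, choice, response latency in seconds, trial start time in
#' seconds from session start).
#'
#' @param trials data.frame with the canonical columns.
#' @param meta named list of provenance fields; `dialect` is filled in.
#' @param validate if `TRUE` (default) stop on any invariant violation.
#' @return An object of class `"trial_dataset"`.
#' @seealso [validate_dataset()], [read_trial_table()], [write_trial_table()]
#' @export
trial_dataset <- function(trials, meta = list(), validate = TRUE) {
  if (!is.data.frame(trials)) stop("`trials` must be a data.frame")
  missing_cols <- setdiff(.CANONICAL_COLUMNS, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trial table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  trials <- trials[, .CANONICAL_COLUMNS, drop = FALSE]
  rownames(trials) <- NULL
  trials$rat_id <- as.character(trials$rat_id)
  trials$phase <- as.character(trials$phase)
  trials$session_index <- as.integer(trials$session_index)
  trials$trial_index <- as.integer(trials$trial_index)
  trials$trial_type <- as.character(trials$trial_type)
  trials$offered_high <- as.logical(trials$offered_high)
  trials$offered_low <- as.logical(trials$offered_low)
  trials$high_side <- as.character(trials$high_side)
  trials$chosen <- as.character(trials$chosen)
  trials$is_error <- as.logical(trials$is_error)
  trials$latency_s <- as.numeric(trials$latency_s)
  trials$trial_start_s <- as.numeric(trials$trial_start_s)
  meta$dialect <- .DIALECT_VERSION
  obj <- structure(list(trials = trials, meta = meta), class = "trial_dataset")
  if (validate) {
    v <- validate_dataset(obj)
    if (nrow(v) > 0L) {
      stop("invalid trial dataset (", nrow(v), " violation(s)); first: ",
           v$message[1L], " [", v$address[1L], "]")
    }
  }
  obj
}

#' @export
print.trial_dataset <- function(x, ...) {
  tr <- x$trials
  cat("<trial_dataset> ", nrow(tr), " trials, ",
      length(unique(tr$rat_id)), " rat(s), ",
      length(unique(interaction(tr$rat_id, tr$phase, tr$session_index, drop = TRUE))),
      " session(s)\n", sep = "")
  if (nrow(tr) > 0L) {
    cat("  trial types: ",
        paste(sprintf("%s=%d", names(table(tr$trial_type)), table(tr$trial_type)),
              collapse = ", "), "\n", sep = "")
  }
  if (length(x$meta) > 0L) {
    cat("  meta: ", paste(names(x$meta), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.trial_dataset <- function(x, ...) x$trials

.violation <- function(address, field, message) {
  data.frame(address = address, field = field, message = message,
             stringsAsFactors = FALSE)
}

.no_violations <- function() {
  data.frame(address = character(), field = character(), message = character(),
             stringsAsFactors = FALSE)
}

#' Validate a trial dataset against its structural invariants
#'
#' Checks every trial-level and dataset-level invariant of the canonical
#' model: enum membership, offer/trial-type consistency (single offers light
#' exactly one port, dual offers both), errors restricted to single-offer
#' trials, a choice recorded on every dual-offer trial, nonnegative
#' latencies, strictly increasing trial start times within a session, and
#' uniqueness of the (rat, phase, session, trial) key.
#'
#' Violations are data, not exceptions: the return value has one row per
#' violation with a human-readable address (`rat/phase/session/trial`), the
#' offending field, and a message. An empty report means the dataset is valid.
#'
#' @param dataset a `trial_dataset`.
#' @return data.frame with columns `address`, `field`, `message`.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  tr <- dataset$trials
  out <- list()
  if (nrow(tr) == 0L) return(.no_violations())
  addr <- sprintf("%s/%s/s%d/t%d", tr$rat_id, tr$phase, tr$session_index,
                  tr$trial_index)
  add <- function(idx, field, msg) {
    if (any(idx, na.rm = TRUE)) {
      idx <- which(idx)
      out[[length(out) + 1L]] <<- .violation(addr[idx], field, msg)
    }
  }

  add(!(tr$phase %in% .PHASES), "phase", "phase not in {value_learning, choice_learning}")
  add(!(tr$trial_type %in% .TRIAL_TYPES), "trial_type", "trial_type not in {single, dual}")
  add(!(tr$high_side %in% .SIDES), "high_side", "high_side not in {left, right}")
  add(!(tr$chosen %in% .CHOICES), "chosen", "chosen not in {high, low, none}")
  add(is.na(tr$session_index) | tr$session_index < 1L, "session_index",
      "session_index must be a positive integer")
  add(is.na(tr$trial_index) | tr$trial_index < 1L, "trial_index",
      "trial_index must be a positive integer")
  add(is.na(tr$latency_s) | tr$latency_s < 0, "latency_s", "latency_s must be >= 0")
  add(is.na(tr$trial_start_s) | tr$trial_start_s < 0, "trial_start_s",
      "trial_start_s must be >= 0")
  add(is.na(tr$offered_high) | is.na(tr$offered_low), "offered_high",
      "offer flags must be non-missing")

  single <- tr$trial_type == "single"
  dual <- tr$trial_type == "dual"
  n_offered <- (tr$offered_high %in% TRUE) + (tr$offered_low %in% TRUE)
  add(single & n_offered != 1L, "offered_high",
      "single-offer trial must light exactly one port")
  add(dual & n_offered != 2L, "offered_high",
      "dual-offer trial must light both ports")
  add(dual & (tr$is_error %in% TRUE), "is_error",
      "is_error is defined only for single-offer trials")
  add(dual & !(tr$chosen %in% c("high", "low")), "chosen",
      "dual-offer trial must record a choice (high or low)")
  add(single & (tr$is_error %in% TRUE) & tr$chosen != "none", "chosen",
      "error trial must carry chosen = none")
  add(single & !(tr$is_error %in% TRUE) & tr$offered_high %in% TRUE & tr$chosen != "high",
      "chosen", "correct single-offer high trial must carry chosen = high")
  add(single & !(tr$is_error %in% TRUE) & tr$offered_low %in% TRUE & tr$chosen != "low",
      "chosen", "correct single-offer low trial must carry chosen = low")

  key <- interaction(tr$rat_id, tr$phase, tr$session_index, tr$trial_index,
                     drop = TRUE)
  add(duplicated(key), "trial_index", "(rat, phase, session, trial) key duplicated")

  sess <- interaction(tr$rat_id, tr$phase, tr$session_index, drop = TRUE)
  for (s in levels(sess)) {
    idx <- which(sess == s)
    idx <- idx[order(tr$trial_index[idx])]
    if (length(idx) > 1L) {
      bad <- idx[-1L][diff(tr$trial_start_s[idx]) <= 0]
      if (length(bad) > 0L) {
        out[[length(out) + 1L]] <- .violation(
          addr[bad], "trial_start_s",
          "trial_start_s must increase strictly with trial_index")
      }
    }
  }

  if (length(out) == 0L) .no_violations() else do.call(rbind, out)
}

#' Read a canonical trial table from CSV
#'
#' Reads the canonical comma-separated dialect (UTF-8, header row, booleans
#' as TRUE/FALSE, seconds as decimal floats). The full column set must be
#' present; rows are never silently dropped. Per-row field problems (bad
#' enum values, negative latencies, unparseable numbers) raise an error
#' naming the first offending data row.
#'
#' @param path file to read.
#' @param dialect only `"canonical_csv"` is defined.
#' @return a `trial_dataset`; `$meta$source` records `path`.
#' @export
read_trial_table <- function(path, dialect = "canonical_csv") {
  dialect <- match.arg(dialect, "canonical_csv")
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(.CANONICAL_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(raw), .CANONICAL_COLUMNS)
  if (length(unknown) > 0L) {
    stop("schema error: unknown column(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    empty <- raw
    for (cc in c("session_index", "trial_index")) empty[[cc]] <- integer()
    for (cc in c("offered_high", "offered_low", "is_error")) empty[[cc]] <- logical()
    for (cc in c("latency_s", "trial_start_s")) empty[[cc]] <- numeric()
    return(trial_dataset(empty, meta = list(source = path)))
  }

  parse_num <- function(col, check = NULL, what = "a number") {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(x) & !is.na(raw[[col]])
    if (!is.null(check)) bad <- bad | (!is.na(x) & !check(x))
    if (any(bad)) {
      stop(sprintf("parse error in column '%s' at row %d: '%s' is not %s",
                   col, which(bad)[1L], raw[[col]][which(bad)[1L]], what))
    }
    x
  }
  parse_bool <- function(col) {
    v <- toupper(trimws(raw[[col]]))
    x <- ifelse(v %in% c("TRUE", "T", "1"), TRUE,
                ifelse(v %in% c("FALSE", "F", "0"), FALSE, NA))
    if (anyNA(x)) {
      stop(sprintf("parse error in column '%s' at row %d: '%s' is not a boolean",
                   col, which(is.na(x))[1L], raw[[col]][which(is.na(x))[1L]]))
    }
    x
  }
  parse_enum <- function(col, levels) {
    v <- trimws(raw[[col]])
    bad <- !(v %in% levels)
    if (any(bad)) {
      stop(sprintf("parse error in column '%s' at row %d: '%s' not in {%s}",
                   col, which(bad)[1L], v[which(bad)[1L]],
                   paste(levels, collapse = ", ")))
    }
    v
  }

  trials <- data.frame(
    rat_id = raw$rat_id,
    phase = parse_enum("phase", .PHASES),
    session_index = as.integer(parse_num("session_index", function(x) x >= 1 & x == floor(x),
                                         "a positive integer")),
    trial_index = as.integer(parse_num("trial_index", function(x) x >= 1 & x == floor(x),
                                       "a positive integer")),
    trial_type = parse_enum("trial_type", .TRIAL_TYPES),
    offered_high = parse_bool("offered_high"),
    offered_low = parse_bool("offered_low"),
    high_side = parse_enum("high_side", .SIDES),
    chosen = parse_enum("chosen", .CHOICES),
    is_error = parse_bool("is_error"),
    latency_s = parse_num("latency_s", function(x) x >= 0, "a nonnegative number"),
    trial_start_s = parse_num("trial_start_s", function(x) x >= 0, "a nonnegative number"),
    stringsAsFactors = FALSE
  )
  trial_dataset(trials, meta = list(source = path))
}

#' Write a trial dataset as canonical CSV
#'
#' Inverse of [read_trial_table()]: numbers are printed with enough digits
#' (`%.17g`) that the written file reads back field-for-field identical, and
#' a written-read-written file is byte-identical. Refuses to write a dataset
#' that fails [validate_dataset()].
#'
#' @param dataset a valid `trial_dataset`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  v <- validate_dataset(dataset)
  if (nrow(v) > 0L) {
    stop("refusing to write invalid dataset (", nrow(v), " violation(s)); first: ",
         v$message[1L], " [", v$address[1L], "]")
  }
  tr <- dataset$trials
  fmt <- tr
  fmt$latency_s <- sprintf("%.17g", tr$latency_s)
  fmt$trial_start_s <- sprintf("%.17g", tr$trial_start_s)
  con <- try(file(path, open = "wb"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open path for writing: ", path)
  on.exit(close(con))
  lines <- c(paste(.CANONICAL_COLUMNS, collapse = ","),
             if (nrow(fmt) > 0L) do.call(paste, c(unname(as.list(fmt)), sep = ",")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# Subset a dataset by a logical row index, keeping meta.
dataset_subset <- function(dataset, keep, note = NULL) {
  meta <- dataset$meta
  if (!is.null(note)) meta[[names(note)]] <- note[[1L]]
  tr <- dataset$trials[keep, , drop = FALSE]
  rownames(tr) <- NULL
  structure(list(trials = tr, meta = meta), class = "trial_dataset")
}
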