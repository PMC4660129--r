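#' Construct an EHR event log
#'
#' An event log is the package's raw-data container: one row per timestamped
#' clinical event for one patient. Three kinds of event are distinguished:
#' `diagnosis` and `drug` events carry a clinical code (ICD-10 / ATC), while
#' `measurement` events carry a measurement name and a numeric value.
#' Timestamps are real-valued times in days from an arbitrary origin.
#'
#' Duplicate rows are permitted and preserved: occurrence counts (a patient
#' being prescribed the same drug repeatedly, a measurement taken many times)
#' are meaningful downstream.
#'
#' @param patient_id character vector of opaque patient identifiers.
#' @param timestamp finite numeric vector, days from an arbitrary origin.
#' @param kind character vector, each element one of `"diagnosis"`, `"drug"`,
#'   `"measurement"`.
#' @param code character vector; non-empty exactly for diagnosis/drug rows
#'   (use `NA` for measurement rows).
#' @param measurement_name character vector; non-empty exactly for
#'   measurement rows.
#' @param value numeric vector; finite exactly for measurement rows.
#' @param provenance free-text source tag stored as an attribute.
#'
#' @return An object of class `event_log`: a `data.frame` with columns
#'   `patient_id, timestamp, kind, code, measurement_name, value`.
#' @examples
#' log <- event_log(
#'   patient_id = c("P1", "P1", "P2"),
#'   timestamp  = c(0, 2.5, 1),
#'   kind       = c("drug", "measurement", "diagnosis"),
#'   code       = c("C10AA01", NA, "G444"),
#'   measurement_name = c(NA, "bodyweight", NA),
#'   value      = c(NA, 81.3, NA)
#' )
#' print(log)
#' @export
event_log <- function(patient_id = character(), timestamp = numeric(),
                      kind = character(), code = NA_character_,
                      measurement_name = NA_character_, value = NA_real_,
                      provenance = "in-memory") {
  n <- length(patient_id)
  df <- data.frame(
    patient_id = as.character(patient_id),
    timestamp = as.numeric(timestamp),
    kind = as.character(kind),
    code = rep_len(as.character(code), n),
    measurement_name = rep_len(as.character(measurement_name), n),
    value = rep_len(as.numeric(value), n),
    stringsAsFactors = FALSE
  )
  log <- structure(df, class = c("event_log", "data.frame"),
                   provenance = provenance)
  problems <- validate_event_log(log)
  if (length(problems))
    stop("invalid event log:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  log
}

EVENT_KINDS <- c("diagnosis", "drug", "measurement")
EVENT_COLUMNS <- c("patient_id", "timestamp", "kind", "code",
                   "measurement_name", "value")

#' Validate event-log rows
#'
#' Checks every row against the event-record invariants: a known `kind`, a
#' finite timestamp, and exactly one of (`code`) / (`measurement_name`,
#' `value`) populated, matching the kind. Problems are collected and reported
#' with row numbers, never silently dropped.
#'
#' @param log a data.frame with the event-log columns.
#' @return character vector of problem descriptions (empty when valid).
#' @export
validate_event_log <- function(log) {
  problems <- character()
  missing_cols <- setdiff(EVENT_COLUMNS, names(log))
  if (length(missing_cols))
    return(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  row_problem <- function(rows, what) {
    if (any(rows))
      sprintf("row %d: %s", which(rows), what)
    else character()
  }
  is_meas <- !is.na(log$kind) & log$kind == "measurement"
  is_code <- !is.na(log$kind) & log$kind %in% c("diagnosis", "drug")
  has_code <- !is.na(log$code) & nzchar(log$code)
  has_name <- !is.na(log$measurement_name) & nzchar(log$measurement_name)
  has_value <- is.finite(log$value)
  c(problems,
    row_problem(is.na(log$kind) | !(log$kind %in% EVENT_KINDS),
                "kind must be one of diagnosis/drug/measurement"),
    row_problem(!is.finite(log$timestamp), "timestamp must be finite"),
    row_problem(is.na(log$patient_id) | !nzchar(log$patient_id),
                "empty patient_id"),
    row_problem(is_code & !has_code, "diagnosis/drug row with empty code"),
    row_problem(is_code & (has_name | has_value),
                "diagnosis/drug row carries measurement fields"),
    row_problem(is_meas & !has_name, "measurement row with empty name"),
    row_problem(is_meas & !has_value,
                "measurement row with missing or non-finite value"),
    row_problem(is_meas & has_code, "measurement row carries a code"))
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d events, %d patients (source: %s)\n",
              nrow(x), length(unique(x$patient_id)),
              attr(x, "provenance") %||% "unknown"))
  tab <- table(factor(x$kind, levels = EVENT_KINDS))
  cat(sprintf("  diagnoses: %d  drugs: %d  measurements: %d\n",
              tab[["diagnosis"]], tab[["drug"]], tab[["measurement"]]))
  if (nrow(x)) {
    cat(sprintf("  time span: [%.3g, %.3g] days\n",
                min(x$timestamp), max(x$timestamp)))
  }
  invisible(x)
}

#' @export
summary.event_log <- function(object, ...) {
  kinds <- table(factor(object$kind, levels = EVENT_KINDS))
  structure(list(
    n_events = nrow(object),
    n_patients = length(unique(object$patient_id)),
    events_by_kind = kinds,
    n_distinct_codes = length(unique(stats::na.omit(object$code))),
    n_distinct_measurements =
      length(unique(stats::na.omit(object$measurement_name))),
    provenance = attr(object, "provenance")
  ), class = "summary.event_log")
}

#' @export
print.summary.event_log <- function(x, ...) {
  cat(sprintf("Event log (%s): %d events over %d patients\n",
              x$provenance, x$n_events, x$n_patients))
  print(x$events_by_kind)
  cat(sprintf("distinct codes: %d, distinct measurements: %d\n",
              x$n_distinct_codes, x$n_distinct_measurements))
  invisible(x)
}

# canonical stable order used by the writer: patient, time, then the
# remaining fields so exact duplicates stay adjacent and order is total
canonical_order <- function(log) {
  order(log$patient_id, log$timestamp, log$kind, log$code,
        log$measurement_name, log$value, method = "radix",
        na.last = TRUE)
}

#' Read an event log from a delimited text file
#'
#' The on-disk format is one event per row with header
#' `patient_id, timestamp, kind, code, measurement_name, value` (comma by
#' default, tab selectable). Malformed rows are reported with their line
#' numbers; by default any invalid row aborts the read.
#'
#' @param path path to the file.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @param on_invalid `"error"` (default) to abort on invalid rows, `"drop"`
#'   to drop them with a warning listing the offending lines.
#' @return an [event_log()].
#' @seealso [write_event_log()]
#' @export
read_event_log <- function(path, sep = ",", on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  missing_cols <- setdiff(EVENT_COLUMNS, header)
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c("character", "numeric", "character",
                                         "character", "character", "numeric"),
                          na.strings = "", quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "")
  missing_cols <- setdiff(EVENT_COLUMNS, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df <- df[EVENT_COLUMNS]
  log <- structure(df, class = c("event_log", "data.frame"),
                   provenance = path)
  problems <- validate_event_log(log)
  if (length(problems)) {
    # report as file line numbers (header is line 1)
    msg <- sub("^row (\\d+)", "line \\1", problems)
    msg <- vapply(strsplit(msg, ":"), function(parts) {
      ln <- as.integer(sub("line ", "", parts[[1]])) + 1L
      paste0("line ", ln, ":", paste(parts[-1], collapse = ":"))
    }, character(1))
    if (on_invalid == "error")
      stop(sprintf("%s: invalid rows:\n  %s", path,
                   paste(msg, collapse = "\n  ")), call. = FALSE)
    bad <- as.integer(sub("^row (\\d+):.*$", "\\1", problems))
    warning(sprintf("%s: dropped %d invalid row(s):\n  %s", path,
                    length(unique(bad)), paste(msg, collapse = "\n  ")),
            call. = FALSE)
    log <- log[-unique(bad), , drop = FALSE]
    rownames(log) <- NULL
    log <- structure(log, class = c("event_log", "data.frame"),
                     provenance = path)
  }
  log
}

#' Write an event log to a delimited text file
#'
#' Output is bit-stable for a given log: rows are emitted in a canonical
#' total order (patient, timestamp, remaining fields) with fixed numeric
#' formatting, so write -> read -> write is byte-identical. Duplicate rows
#' are preserved.
#'
#' @param log an [event_log()].
#' @param path destination path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path, sep = ",") {
  stopifnot(inherits(log, "event_log"))
  log <- log[canonical_order(log), , drop = FALSE]
  fmt_num <- function(x) ifelse(is.na(x), "", formatC(x, digits = 17,
                                                      format = "g"))
  fmt_chr <- function(x) ifelse(is.na(x), "", x)
  lines <- paste(fmt_chr(log$patient_id), fmt_num(log$timestamp),
                 fmt_chr(log$kind), fmt_chr(log$code),
                 fmt_chr(log$measurement_name), fmt_num(log$value),
                 sep = sep)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(EVENT_COLUMNS, collapse = sep), lines), con,
             sep = "\n", useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
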