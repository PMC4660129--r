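#' Build a labeled case/control cohort for one target ADE code
#'
#' Patients carrying the exact target diagnosis code are positives; patients
#' carrying a *similar* diagnosis code — same first `similarity_level`
#' hierarchy levels, but never the target itself — are negatives; everyone
#' else is excluded. A patient carrying both the target and a merely similar
#' code is a positive: the control definition excludes any target-code
#' bearer. Each retained patient is anchored at an index timestamp, the time
#' of their first qualifying event, and only history strictly before that
#' index may later feed features (see [prior_events()]).
#'
#' @param log an [event_log()].
#' @param target_code the ADE-defining ICD-10 code, as a string or a
#'   [parse_code()] result.
#' @param similarity_level hierarchy level shared by similar codes
#'   (default 3).
#' @return an object of class `labeled_cohort`: a data.frame with columns
#'   `patient_id`, `label` (1 positive / 0 negative), `index_timestamp`,
#'   plus attributes `target_code`, `similarity_level`, `excluded`
#'   (patient ids with neither target nor similar codes) and counts.
#' @examples
#' log <- event_log(
#'   patient_id = c("P1", "P2", "P3", "P4", "P4"),
#'   timestamp  = c(5, 3, 2, 9, 1),
#'   kind       = "diagnosis",
#'   code       = c("G444", "G440", "G514", "G444", "G441"))
#' build_cohort(log, "G444")
#' @export
build_cohort <- function(log, target_code, similarity_level = 3L) {
  stopifnot(inherits(log, "event_log"))
  if (is.character(target_code)) target_code <- parse_code(target_code, "ICD10")
  stopifnot(inherits(target_code, "clinical_code"))
  if (similarity_level < 1L || similarity_level > 4L)
    stop("similarity_level must be in 1..4", call. = FALSE)
  target <- target_code$normalized
  prefix <- truncate_code(target_code, similarity_level)

  dx <- log[log$kind == "diagnosis", , drop = FALSE]
  norm <- toupper(gsub("[^A-Za-z0-9]", "", dx$code))
  is_target <- norm == target
  # similar = shares the prefix at similarity_level but is not the target
  is_sim <- startsWith(norm, prefix) & !is_target

  first_time <- function(keep) {
    if (!any(keep)) return(numeric())
    tapply(dx$timestamp[keep], dx$patient_id[keep], min)
  }
  t_target <- first_time(is_target)
  t_sim <- first_time(is_sim)

  pos_ids <- names(t_target)
  neg_ids <- setdiff(names(t_sim), pos_ids)
  all_ids <- unique(log$patient_id)
  excluded <- setdiff(all_ids, c(pos_ids, neg_ids))
  if (!length(pos_ids) || !length(neg_ids))
    stop(sprintf(paste0("degenerate cohort for target %s: %d positives, ",
                        "%d negatives - unusable for binary classification"),
                 target, length(pos_ids), length(neg_ids)), call. = FALSE)

  cohort <- data.frame(
    patient_id = c(pos_ids, neg_ids),
    label = rep(c(1L, 0L), c(length(pos_ids), length(neg_ids))),
    index_timestamp = c(unname(t_target[pos_ids]), unname(t_sim[neg_ids])),
    stringsAsFactors = FALSE)
  cohort <- cohort[order(cohort$patient_id, method = "radix"), , drop = FALSE]
  rownames(cohort) <- NULL
  structure(cohort, class = c("labeled_cohort", "data.frame"),
            target_code = target, similarity_level = similarity_level,
            excluded = sort(excluded))
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf(
    "<labeled_cohort> target %s (similarity level %d): %d positives, %d negatives, %d excluded\n",
    attr(x, "target_code"), attr(x, "similarity_level"),
    sum(x$label == 1L), sum(x$label == 0L), length(attr(x, "excluded"))))
  invisible(x)
}

#' Restrict an event log to each patient's pre-index history
#'
#' Keeps, for every patient in the cohort, only the events with timestamp
#' strictly before that patient's index timestamp; the index event itself
#' (and anything simultaneous with it) is removed. This is the temporal
#' leakage guard: features may only describe what was on record before the
#' event of interest. Patients with no prior events are retained in the
#' cohort with empty histories. Events of patients outside the cohort are
#' dropped.
#'
#' @param log an [event_log()].
#' @param cohort a [build_cohort()] result.
#' @return an [event_log()] containing only pre-index events of cohort
#'   patients.
#' @export
prior_events <- function(log, cohort) {
  stopifnot(inherits(log, "event_log"), inherits(cohort, "labeled_cohort"))
  idx <- cohort$index_timestamp[match(log$patient_id, cohort$patient_id)]
  keep <- !is.na(idx) & log$timestamp < idx
  out <- log[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("event_log", "data.frame"),
            provenance = paste0(attr(log, "provenance") %||% "log",
                                " [pre-index]"))
}

#' Write / read a cohort table
#'
#' Plain three-column delimited text (`patient_id, label, index_timestamp`);
#' target code and similarity level travel in `#`-prefixed header comments.
#'
#' @param cohort a [build_cohort()] result.
#' @param path destination path.
#' @return `path` invisibly (writer); a `labeled_cohort` (reader).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("# target_code=%s similarity_level=%d",
            attr(cohort, "target_code"), attr(cohort, "similarity_level")),
    "patient_id,label,index_timestamp",
    paste(cohort$patient_id, cohort$label,
          formatC(cohort$index_timestamp, digits = 17, format = "g"),
          sep = ",")), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header,
                     regexec("target_code=(\\S+) similarity_level=(\\d+)",
                             header))[[1]]
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "numeric"))
  df <- df[order(df$patient_id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("labeled_cohort", "data.frame"),
            target_code = if (length(meta)) meta[[2]] else NA_character_,
            similarity_level = if (length(meta)) as.integer(meta[[3]]) else NA_integer_,
            excluded = character())
}
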