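#' Parse a clinical code into its concept-hierarchy levels
#'
#' ICD-10 diagnosis codes and ATC drug codes are hierarchical: each code sits
#' at the bottom of an ordered chain of increasingly specific prefixes.
#' `parse_code()` normalizes a raw code (uppercase, punctuation stripped) and
#' exposes four ordered hierarchy levels, most general first.
#'
#' Level prefix lengths default to 1, 2, 3, 4 characters for ICD-10 (so the
#' level-3 prefix of `"G44.4"` is `"G44"`) and 1, 3, 4 and the full code for
#' ATC (the anatomical main group, therapeutic subgroup, pharmacological
#' subgroup, and chemical substance, with ATC's two most specific official
#' levels collapsed into one). Codes shorter than a requested prefix length
#' truncate to themselves: real ICD-10 logs contain 3-character codes.
#'
#' @param raw non-empty code string, e.g. `"G44.4"` or `"C10AA01"`.
#' @param system `"ICD10"` or `"ATC"`.
#' @param level_lengths optional integer vector of 4 increasing prefix
#'   lengths overriding the per-system default (`NA` in the last position
#'   means "the full code").
#' @return an object of class `clinical_code` with fields `system`,
#'   `normalized` and `levels` (character vector of length 4, most general
#'   first).
#' @examples
#' parse_code("G44.4", "ICD10")$levels   # "G" "G4" "G44" "G444"
#' parse_code("C10AA01", "ATC")$levels   # "C" "C10" "C10A" "C10AA01"
#' @export
parse_code <- function(raw, system = c("ICD10", "ATC"),
                       level_lengths = NULL) {
  system <- match.arg(system)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("cannot parse empty clinical code", call. = FALSE)
  normalized <- toupper(gsub("[^A-Za-z0-9]", "", raw))
  pattern <- switch(system,
    ICD10 = "^[A-Z][0-9]{1,5}[A-Z]?$",
    ATC   = "^[A-Z]([0-9]{2}([A-Z]{1,2}([0-9]{2})?)?)?$")
  if (!grepl(pattern, normalized))
    stop(sprintf("not a valid %s code: '%s' (normalized '%s')",
                 system, raw, normalized), call. = FALSE)
  if (is.null(level_lengths))
    level_lengths <- switch(system, ICD10 = c(1L, 2L, 3L, 4L),
                            ATC = c(1L, 3L, 4L, NA_integer_))
  stopifnot(length(level_lengths) == 4L)
  lens <- ifelse(is.na(level_lengths), nchar(normalized),
                 pmin(level_lengths, nchar(normalized)))
  if (is.unsorted(lens)) stop("level lengths must be non-decreasing")
  structure(list(system = system, normalized = normalized,
                 levels = substr(rep(normalized, 4L), 1L, lens)),
            class = "clinical_code")
}

#' @export
print.clinical_code <- function(x, ...) {
  cat(sprintf("<clinical_code %s> %s  (levels: %s)\n", x$system,
              x$normalized, paste(x$levels, collapse = " < ")))
  invisible(x)
}

#' @export
format.clinical_code <- function(x, ...) x$normalized

#' Truncate a clinical code to a hierarchy level
#'
#' Aggregating codes to more general hierarchy levels is how sparse code
#' features are coarsened: level 4 is the full code, level 1 the most
#' general prefix.
#'
#' @param code a [parse_code()] result.
#' @param level integer in 1..4.
#' @return the level prefix string.
#' @examples
#' truncate_code(parse_code("G44.4", "ICD10"), 3)  # "G44"
#' @export
truncate_code <- function(code, level) {
  stopifnot(inherits(code, "clinical_code"))
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level < 1L || level > 4L || level != as.integer(level))
    stop("level must be an integer in 1..4", call. = FALSE)
  code$levels[[as.integer(level)]]
}

#' Decide whether two codes are similar
#'
#' Two codes are *similar* when they share the first three concept-hierarchy
#' levels; similarity drives control selection when cohorts are built (the
#' negative class for target G44.4 is "any code starting with G44, but not
#' G44.4"). Similarity is only defined within one coding system.
#'
#' @param a,b [parse_code()] results from the same coding system.
#' @param level hierarchy level that must be shared (default 3).
#' @return `TRUE` or `FALSE`.
#' @export
is_similar <- function(a, b, level = 3L) {
  stopifnot(inherits(a, "clinical_code"), inherits(b, "clinical_code"))
  if (a$system != b$system)
    stop("similarity is not defined across coding systems (",
         a$system, " vs ", b$system, ")", call. = FALSE)
  identical(truncate_code(a, level), truncate_code(b, level))
}

#' Expand a code into per-level feature names
#'
#' One feature name per requested hierarchy level, tagged with the coding
#' system and level so identical prefixes at different levels (or across
#' systems) remain distinct features, e.g. `"code:ICD10:L3:G44"`.
#'
#' @param code a [parse_code()] result.
#' @param levels subset of `1:4`, or `"all"`.
#' @return character vector of feature names, one per requested level.
#' @examples
#' expand_levels(parse_code("G444", "ICD10"))
#' @export
expand_levels <- function(code, levels = "all") {
  stopifnot(inherits(code, "clinical_code"))
  if (identical(levels, "all")) levels <- 1:4
  levels <- as.integer(levels)
  if (!length(levels) || anyNA(levels) || any(levels < 1L | levels > 4L))
    stop("levels must be a non-empty subset of 1..4 or \"all\"", call. = FALSE)
  levels <- sort(unique(levels))
  sprintf("code:%s:L%d:%s", code$system, levels, code$levels[levels])
}

#' The packaged ADE target diagnosis codes
#'
#' The 27 ICD-10 diagnosis codes whose presence defines an adverse drug
#' event in this pipeline, with their clinical descriptions. Each code
#' yields one binary classification dataset: patients carrying the code are
#' positives, patients carrying a similar code (same 3-level prefix) are
#' controls.
#'
#' @return a data.frame with columns `code` and `description`.
#' @examples
#' head(ade_target_codes())
#' @export
ade_target_codes <- function() {
  data.frame(code = c(
    "D642", "E273", "F110", "F112", "F130", "F132", "F150", "F151", "F152",
    "F190", "F192", "F199", "G240", "G251", "G444", "G620", "I427", "I952",
    "L270", "L271", "O355", "T782", "T783", "T784", "T808", "T886", "T887"),
    description = c(
      "Secondary sideroblastic anemia due to drugs and toxins",
      "Drug-induced adrenocortical insufficiency",
      "Mental and behavioural disorders (MBDs) due to use of opioids: acute intoxication",
      "MBDs due to use of opioids: dependence syndrome",
      "MBDs due to use of sedatives or hypnotics: acute intoxication",
      "MBDs due to use of sedatives or hypnotics: dependence syndrome",
      "MBDs due to use of other stimulants, including caffeine: acute intoxication",
      "MBDs due to use of other stimulants, including caffeine: harmful use",
      "MBDs due to use of other stimulants, including caffeine: dependence syndrome",
      "MBDs due to multiple drug use: acute intoxication",
      "MBDs due to multiple drug use: dependence syndrome",
      "MBDs due to multiple drug use: unspecified mental and behavioural disorder",
      "Drug-induced dystonia",
      "Drug-induced tremor",
      "Drug-induced headache, not elsewhere classified",
      "Drug-induced polyneuropathy",
      "Cardiomyopathy due to drugs and other external agents",
      "Hypotension due to drugs",
      "Generalized skin eruption due to drugs and medicaments",
      "Localized skin eruption due to drugs and medicaments",
      "Maternal care for (suspected) damage to fetus by drugs",
      "Adverse effects: anaphylactic shock, unspecified",
      "Adverse effects: angioneurotic oedema",
      "Adverse effects: allergy, unspecified",
      "Other complications following infusion, transfusion and therapeutic injection",
      "Anaphylactic shock due to correct drug or medicament properly administered",
      "Unspecified adverse effect of drug or medicament"),
    stringsAsFactors = FALSE)
}
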