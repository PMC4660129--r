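#' Representation configuration for feature building
#'
#' Controls how raw patient history becomes feature columns. Repeated
#' clinical measurements are summarized by up to five representations:
#' *mean* and *sd* of the observed values, *slope* (difference between the
#' temporally first and last observation divided by the time span, a rate
#' per day), *existence* (whether the measurement was ever taken) and
#' *count* (how many times). Clinical codes are aggregated at hierarchy
#' levels 1-4, valued either as occurrence counts (default; repeated
#' prescriptions are informative) or binary existence.
#'
#' @param measurement_reps subset of
#'   `c("mean","sd","slope","existence","count")` or `"all"`.
#' @param code_levels subset of `1:4` or `"all"`.
#' @param code_value `"count"` or `"existence"`.
#' @param slope_mode `"rate"` (difference over time span, default) or
#'   `"difference"` (last minus first value).
#' @param impute value imputed for mean/sd/slope when a patient never had
#'   the measurement (default 0; existence and count are exactly 0 there).
#' @return a list of class `representation_config`.
#' @export
representation_config <- function(measurement_reps = "all",
                                  code_levels = "all",
                                  code_value = c("count", "existence"),
                                  slope_mode = c("rate", "difference"),
                                  impute = 0) {
  all_reps <- c("mean", "sd", "slope", "existence", "count")
  if (identical(measurement_reps, "all")) measurement_reps <- all_reps
  if (identical(code_levels, "all")) code_levels <- 1:4
  if (length(measurement_reps))
    measurement_reps <- match.arg(measurement_reps, all_reps,
                                  several.ok = TRUE)
  code_levels <- sort(unique(as.integer(code_levels)))
  if ((!length(measurement_reps)) && !length(code_levels))
    stop("at least one representation must be selected", call. = FALSE)
  if (length(code_levels) && any(code_levels < 1L | code_levels > 4L))
    stop("code_levels must lie in 1..4", call. = FALSE)
  structure(list(measurement_reps = measurement_reps,
                 code_levels = code_levels,
                 code_value = match.arg(code_value),
                 slope_mode = match.arg(slope_mode),
                 impute = impute),
            class = "representation_config")
}

#' Summarize one patient's repeated measurements
#'
#' The five-component summary of a series of (timestamp, value)
#' observations of a single measurement. `sd` uses the sample (n-1)
#' denominator and is 0 for fewer than two observations; `slope` is
#' (last - first value) / (last - first time), and 0 when the time span is
#' zero or there are fewer than two observations. The empty series yields
#' existence 0, count 0 and imputed mean/sd/slope.
#'
#' @param timestamps,values numeric vectors of equal length (need not be
#'   pre-sorted; they are ordered by timestamp internally).
#' @param slope_mode see [representation_config()].
#' @param impute value for mean/sd/slope of an empty series.
#' @return named numeric vector `c(mean, sd, slope, existence, count)`.
#' @examples
#' summarize_measurement(c(0, 2), c(10, 14))
#' @export
summarize_measurement <- function(timestamps, values,
                                  slope_mode = c("rate", "difference"),
                                  impute = 0) {
  slope_mode <- match.arg(slope_mode)
  stopifnot(length(timestamps) == length(values))
  n <- length(values)
  if (n == 0L)
    return(c(mean = impute, sd = impute, slope = impute,
             existence = 0, count = 0))
  stopifnot(all(is.finite(timestamps)), all(is.finite(values)))
  ord <- order(timestamps)
  t <- timestamps[ord]; v <- values[ord]
  span <- t[n] - t[1L]
  diff_fl <- v[n] - v[1L]
  slope <- if (n < 2L || span == 0) 0 else
    switch(slope_mode, rate = diff_fl / span, difference = diff_fl)
  c(mean = mean(v),
    sd = if (n < 2L) 0 else stats::sd(v),
    slope = slope,
    existence = 1,
    count = n)
}

#' Build a patient-by-feature matrix from pre-index history
#'
#' Turns a (pre-filtered, see [prior_events()]) event log into the dense
#' feature matrix the classifiers consume: one column per
#' (measurement x selected representation) and one per distinct code
#' prefix at each selected hierarchy level. The feature universe is the
#' union over all patients of what actually occurs in the log; patients
#' with empty histories get all-zero (or imputed) rows.
#'
#' @param log an [event_log()] of pre-index events.
#' @param cohort a [build_cohort()] result; rows of the matrix follow
#'   cohort order.
#' @param config a [representation_config()].
#' @param code_systems named character vector mapping event kinds to coding
#'   systems.
#' @return an object of class `feature_matrix`: a numeric matrix (patients
#'   x features) with attributes `labels` (aligned 0/1 integer vector),
#'   `patient_id`, and `feature_info` (data.frame: `name`, `data_type`,
#'   `representation`, `level`).
#' @export
build_features <- function(log, cohort, config = representation_config(),
                           code_systems = c(diagnosis = "ICD10",
                                            drug = "ATC")) {
  stopifnot(inherits(log, "event_log"), inherits(cohort, "labeled_cohort"),
            inherits(config, "representation_config"))
  patients <- cohort$patient_id
  npat <- length(patients)

  blocks <- list()
  info <- list()

  ## measurement block
  meas <- log[log$kind == "measurement" & log$patient_id %in% patients, ,
              drop = FALSE]
  if (length(config$measurement_reps) && nrow(meas)) {
    meas_names <- sort(unique(meas$measurement_name))
    per <- split(meas[c("patient_id", "timestamp", "value")],
                 meas$measurement_name)
    for (m in meas_names) {
      dd <- per[[m]]
      by_pat <- split(dd[c("timestamp", "value")], dd$patient_id)
      summ <- matrix(rep(c(config$impute, config$impute, config$impute, 0, 0),
                         each = npat),
                     nrow = npat,
                     dimnames = list(patients,
                                     c("mean", "sd", "slope",
                                       "existence", "count")))
      hit <- intersect(patients, names(by_pat))
      if (length(hit))
        summ[hit, ] <- t(vapply(by_pat[hit], function(d)
          summarize_measurement(d$timestamp, d$value,
                                slope_mode = config$slope_mode,
                                impute = config$impute),
          numeric(5)))
      keep <- config$measurement_reps
      block <- summ[, keep, drop = FALSE]
      colnames(block) <- sprintf("meas:%s:%s", keep, m)
      blocks[[length(blocks) + 1L]] <- block
      info[[length(info) + 1L]] <- data.frame(
        name = colnames(block), data_type = "measurement",
        representation = keep, level = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }

  ## clinical-code block
  codes <- log[log$kind %in% names(code_systems) &
                 log$patient_id %in% patients, , drop = FALSE]
  if (length(config$code_levels) && nrow(codes)) {
    parsed_cache <- new.env(parent = emptyenv())
    expand <- function(kind, raw) {
      key <- paste0(kind, ":", raw)
      hit <- parsed_cache[[key]]
      if (!is.null(hit)) return(hit)
      val <- expand_levels(parse_code(raw, code_systems[[kind]]),
                           config$code_levels)
      assign(key, val, envir = parsed_cache)
      val
    }
    L <- length(config$code_levels)
    feat_per_event <- mapply(expand, codes$kind, codes$code,
                             SIMPLIFY = FALSE, USE.NAMES = FALSE)
    long <- data.frame(
      patient_id = rep(codes$patient_id, each = L),
      feature = unlist(feat_per_event, use.names = FALSE),
      stringsAsFactors = FALSE)
    tab <- table(factor(long$patient_id, levels = patients), long$feature)
    block <- matrix(as.numeric(tab), nrow = npat,
                    dimnames = list(patients, colnames(tab)))
    block <- block[, order(colnames(block)), drop = FALSE]
    if (config$code_value == "existence") block <- (block > 0) + 0
    blocks[[length(blocks) + 1L]] <- block
    cn <- colnames(block)
    info[[length(info) + 1L]] <- data.frame(
      name = cn, data_type = "code",
      representation = config$code_value,
      level = as.integer(sub("^code:[^:]+:L(\\d):.*$", "\\1", cn)),
      stringsAsFactors = FALSE)
  }

  if (!length(blocks))
    stop("empty feature universe: no usable events for this configuration",
         call. = FALSE)
  x <- do.call(cbind, blocks)
  new_feature_matrix(x, labels = cohort$label, patient_id = patients,
                     feature_info = do.call(rbind, info))
}

new_feature_matrix <- function(x, labels, patient_id, feature_info) {
  stopifnot(nrow(x) == length(labels), !anyDuplicated(colnames(x)))
  rownames(feature_info) <- NULL
  structure(x, class = c("feature_matrix", class(matrix())),
            labels = as.integer(labels), patient_id = patient_id,
            feature_info = feature_info)
}

#' @export
print.feature_matrix <- function(x, ...) {
  fi <- attr(x, "feature_info")
  lab <- attr(x, "labels")
  cat(sprintf("<feature_matrix> %d patients x %d features (%.1f%% positives, %.1f%% nonzero)\n",
              nrow(x), ncol(x), 100 * mean(lab == 1L),
              100 * mean(x != 0)))
  cat(sprintf("  code features: %d, measurement features: %d\n",
              sum(fi$data_type == "code"),
              sum(fi$data_type == "measurement")))
  invisible(x)
}

#' Column-wise fusion of two feature matrices
#'
#' Concatenates the code and measurement data types (or any two compatible
#' matrices) into one feature set, checking that the patients and labels
#' are identically aligned; per-feature metadata is preserved.
#'
#' @param a,b `feature_matrix` objects over the same patients.
#' @return a `feature_matrix` with `ncol(a) + ncol(b)` columns.
#' @export
fuse <- function(a, b) {
  stopifnot(inherits(a, "feature_matrix"), inherits(b, "feature_matrix"))
  if (!identical(attr(a, "patient_id"), attr(b, "patient_id")) ||
      !identical(attr(a, "labels"), attr(b, "labels")))
    stop("cannot fuse: patient rows or labels are not aligned",
         call. = FALSE)
  if (ncol(b) == 0L) return(a)
  if (ncol(a) == 0L) return(b)
  new_feature_matrix(cbind(unclass_matrix(a), unclass_matrix(b)),
                     labels = attr(a, "labels"),
                     patient_id = attr(a, "patient_id"),
                     feature_info = rbind(attr(a, "feature_info"),
                                          attr(b, "feature_info")))
}

unclass_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}

#' Subset the columns of a feature matrix
#'
#' @param x a `feature_matrix`.
#' @param features character vector of feature names to keep.
#' @return a `feature_matrix` restricted to `features`.
#' @export
select_features <- function(x, features) {
  stopifnot(inherits(x, "feature_matrix"))
  missing <- setdiff(features, colnames(x))
  if (length(missing))
    stop("unknown feature(s): ", paste(utils::head(missing, 5),
                                       collapse = ", "), call. = FALSE)
  fi <- attr(x, "feature_info")
  new_feature_matrix(unclass_matrix(x)[, features, drop = FALSE],
                     labels = attr(x, "labels"),
                     patient_id = attr(x, "patient_id"),
                     feature_info = fi[match(features, fi$name), ,
                                       drop = FALSE])
}

#' Restrict a feature matrix to one data type
#'
#' @param x a `feature_matrix`.
#' @param data_type `"code"` or `"measurement"`.
#' @return a `feature_matrix` with only that data type's columns.
#' @export
data_type_matrix <- function(x, data_type = c("code", "measurement")) {
  data_type <- match.arg(data_type)
  fi <- attr(x, "feature_info")
  select_features(x, fi$name[fi$data_type == data_type])
}

#' Write a feature matrix as sparse triplets
#'
#' Two delimited files: `<path>` holds the nonzero triplets
#' (`patient_id, feature, value`) and `<path>.features` the column metadata
#' sidecar (every feature, including all-zero columns, with its data type,
#' representation and level) plus patient labels in `<path>.labels`.
#'
#' @param x a `feature_matrix`.
#' @param path destination path for the triplet table.
#' @return `path` invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(inherits(x, "feature_matrix"))
  nz <- which(unclass_matrix(x) != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
  triplets <- data.frame(
    patient_id = attr(x, "patient_id")[nz[, 1L]],
    feature = colnames(x)[nz[, 2L]],
    value = formatC(unclass_matrix(x)[nz], digits = 17, format = "g"))
  utils::write.table(triplets, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(attr(x, "feature_info"), paste0(path, ".features"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(patient_id = attr(x, "patient_id"),
               label = attr(x, "labels")),
    paste0(path, ".labels"), sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path path of the triplet table.
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  triplets <- utils::read.table(path, header = TRUE, sep = ",",
                                stringsAsFactors = FALSE,
                                colClasses = c("character", "character",
                                               "numeric"))
  fi <- utils::read.table(paste0(path, ".features"), header = TRUE,
                          sep = ",", stringsAsFactors = FALSE)
  labs <- utils::read.table(paste0(path, ".labels"), header = TRUE,
                            sep = ",", stringsAsFactors = FALSE,
                            colClasses = c("character", "integer"))
  x <- matrix(0, nrow = nrow(labs), ncol = nrow(fi),
              dimnames = list(labs$patient_id, fi$name))
  if (nrow(triplets))
    x[cbind(match(triplets$patient_id, labs$patient_id),
            match(triplets$feature, fi$name))] <- triplets$value
  new_feature_matrix(x, labels = labs$label, patient_id = labs$patient_id,
                     feature_info = fi)
}
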