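#' Configuration for a full pipeline experiment
#'
#' Bundles everything one end-to-end run needs: the synthetic dataset
#' specs (or pre-generated datasets), the representation settings, the
#' feature-selection fraction grid, the classifiers to compare, and the
#' cross-validation protocol. The experiment mirrors a three-part design:
#' compare representations within each data type, compare data types and
#' their fusion (with feature selection over a 10%-step threshold grid),
#' and compare learning algorithms — all summarized across datasets by
#' rank statistics.
#'
#' @param specs list of [synthetic_spec()] objects, one per dataset.
#' @param representation a [representation_config()].
#' @param fractions selection-fraction grid (default [selection_grid()]).
#' @param classifiers character vector of [classifier_config()] names.
#' @param folds,repeats CV protocol.
#' @param seed master seed; all stage seeds derive from it.
#' @param compare_representations whether to run the within-data-type
#'   representation comparison (the most CV-heavy stage).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(specs, representation = representation_config(),
                            fractions = selection_grid(),
                            classifiers = "RF", folds = 10L, repeats = 2L,
                            seed = 1L, compare_representations = FALSE) {
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "synthetic_spec")),
            all(classifiers %in% CLASSIFIER_NAMES),
            all(fractions > 0 & fractions <= 1))
  structure(list(specs = specs, representation = representation,
                 fractions = fractions, classifiers = classifiers,
                 folds = folds, repeats = repeats, seed = seed,
                 compare_representations = compare_representations),
            class = "pipeline_config")
}

#' Run the full ADE-detection experiment
#'
#' For every dataset: generate the event log, build the case/control
#' cohort for its target code, restrict to pre-index history, build
#' measurement and code feature matrices, then evaluate the configured
#' classifiers on measurements (M), codes (C) and their fusion (M+C) at
#' every selection fraction. Optionally also compares the five measurement
#' representations and four code hierarchy levels. Across datasets, every
#' family of configurations is compared with Friedman ranks and
#' Bergmann-Hommel-adjusted pairwise p-values. All numeric outputs are
#' reproducible from the config seed; when `out_dir` is given they are
#' written as delimited text tables with a run manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for result tables.
#' @param verbose print stage-boundary progress with record counts.
#' @return list of class `ade_experiment` with elements
#'   `datatype_results` (long data.frame over dataset x data type x
#'   classifier x fraction), `datatype_comparison` (a
#'   [compare_configurations()] result for M / C / M+C at full feature
#'   set), `classifier_comparison` (across classifiers, when more than
#'   one), `representation_results` (when enabled), `selection_curves`,
#'   `feature_composition`, `informativeness`, and `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  n_data <- length(config$specs)
  datasets <- lapply(seq_len(n_data), function(i)
    generate_cohort(config$specs[[i]], seed = config$seed + 1000L * i))

  datatype_rows <- list()
  rep_rows <- list()
  comp_rows <- list()
  info_rows <- list()

  for (i in seq_len(n_data)) {
    ds <- datasets[[i]]
    dname <- sprintf("D%02d", i)
    cohort <- build_cohort(ds$log, ds$vocabulary$target_code)
    say("[%s] cohort: %d positives / %d negatives / %d excluded", dname,
        sum(cohort$label == 1L), sum(cohort$label == 0L),
        length(attr(cohort, "excluded")))
    pre <- prior_events(ds$log, cohort)
    say("[%s] pre-index events: %d of %d", dname, nrow(pre), nrow(ds$log))
    feats <- build_features(pre, cohort, config$representation)
    M <- data_type_matrix(feats, "measurement")
    C <- data_type_matrix(feats, "code")
    MC <- fuse(M, C)
    say("[%s] features: M=%d C=%d fused=%d", dname, ncol(M), ncol(C),
        ncol(MC))

    ## feature informativeness (full-matrix ranking)
    ranking <- rank_features(MC)
    info_rows[[dname]] <- informativeness_summary(ranking, dname)
    comp_rows[[dname]] <- composition_by_fraction(ranking, config$fractions,
                                                  dname)

    ## representation comparisons within each data type
    if (config$compare_representations) {
      rep_rows[[dname]] <- rbind(
        representation_sweep(pre, cohort, config, dname, "measurement"),
        representation_sweep(pre, cohort, config, dname, "code"))
    }

    ## data types x classifiers x fractions
    mats <- list(M = M, C = C, `M+C` = MC)
    for (cl in config$classifiers) {
      cfg <- classifier_config(cl)
      for (dt in names(mats)) {
        for (frac in config$fractions) {
          cv <- run_cv(mats[[dt]], cfg, folds = config$folds,
                       repeats = config$repeats,
                       seed = config$seed + 7L * i,
                       select_fraction = if (frac < 1) frac else NULL)
          datatype_rows[[length(datatype_rows) + 1L]] <- data.frame(
            dataset = dname, data_type = dt, classifier = cl,
            fraction = frac,
            accuracy = attr(cv, "mean_accuracy"),
            auc = attr(cv, "mean_auc"), stringsAsFactors = FALSE)
        }
      }
    }
  }

  datatype_results <- do.call(rbind, datatype_rows)
  rownames(datatype_results) <- NULL

  ## cross-dataset comparisons at the full feature set, first classifier
  base_cl <- config$classifiers[[1L]]
  full <- datatype_results[datatype_results$fraction == max(config$fractions) &
                             datatype_results$classifier == base_cl, ]
  datatype_comparison <- NULL
  if (n_data >= 2L) {
    perf <- stats::reshape(full[c("dataset", "data_type", "auc")],
                           direction = "wide", idvar = "dataset",
                           timevar = "data_type")
    m <- as.matrix(perf[-1]); rownames(m) <- perf$dataset
    colnames(m) <- sub("^auc\\.", "", colnames(m))
    datatype_comparison <- compare_configurations(m, metric = "AUC")
  }

  classifier_comparison <- NULL
  if (length(config$classifiers) >= 2L && n_data >= 2L) {
    sub <- datatype_results[datatype_results$fraction ==
                              max(config$fractions) &
                              datatype_results$data_type == "M+C", ]
    perf <- stats::reshape(sub[c("dataset", "classifier", "auc")],
                           direction = "wide", idvar = "dataset",
                           timevar = "classifier")
    m <- as.matrix(perf[-1]); rownames(m) <- perf$dataset
    colnames(m) <- sub("^auc\\.", "", colnames(m))
    classifier_comparison <- compare_configurations(m, metric = "AUC")
  }

  ## selection curves: mean over datasets per (data type, fraction)
  curves <- stats::aggregate(
    cbind(accuracy, auc) ~ data_type + fraction + classifier,
    data = datatype_results, FUN = mean)

  out <- structure(list(
    datatype_results = datatype_results,
    datatype_comparison = datatype_comparison,
    classifier_comparison = classifier_comparison,
    representation_results = if (length(rep_rows))
      do.call(rbind, c(rep_rows, make.row.names = FALSE)) else NULL,
    selection_curves = curves,
    feature_composition = do.call(rbind, c(comp_rows,
                                           make.row.names = FALSE)),
    informativeness = do.call(rbind, c(info_rows,
                                       make.row.names = FALSE)),
    config = config), class = "ade_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

# mean information gain per representation / hierarchy level
informativeness_summary <- function(ranking, dname) {
  key <- ifelse(ranking$data_type == "measurement",
                paste0("meas:", ranking$representation),
                paste0("code:L", ranking$level))
  agg <- stats::aggregate(ranking$gain_bits, list(representation = key),
                          mean)
  data.frame(dataset = dname, representation = agg$representation,
             mean_gain_bits = agg$x, stringsAsFactors = FALSE)
}

# proportion of each data type among the selected features per fraction
composition_by_fraction <- function(ranking, fractions, dname) {
  do.call(rbind, lapply(fractions, function(fr) {
    sel <- seq_len(ceiling(fr * nrow(ranking)))
    dt <- ranking$data_type[sel]
    data.frame(dataset = dname, fraction = fr, n_selected = length(sel),
               prop_code = mean(dt == "code"),
               prop_measurement = mean(dt == "measurement"),
               stringsAsFactors = FALSE)
  }))
}

# CV sweep over single representations plus their combination, one data type
representation_sweep <- function(pre, cohort, config, dname, data_type) {
  cfg <- classifier_config(config$classifiers[[1L]])
  if (data_type == "measurement") {
    variants <- c(as.list(c("mean", "sd", "slope", "existence", "count")),
                  list("all"))
    build <- function(v) build_features(
      pre, cohort, representation_config(measurement_reps = v,
                                         code_levels = integer()))
    vname <- function(v) if (identical(v, "all")) "All" else v
  } else {
    variants <- c(as.list(1:4), list("all"))
    build <- function(v) build_features(
      pre, cohort, representation_config(measurement_reps = character(),
                                         code_levels = v,
                                         code_value = config$representation$code_value))
    vname <- function(v) if (identical(v, "all")) "All" else paste0("L", v)
  }
  do.call(rbind, lapply(variants, function(v) {
    x <- tryCatch(build(v), error = function(e) NULL)
    if (is.null(x)) return(NULL)
    cv <- run_cv(x, cfg, folds = config$folds, repeats = config$repeats,
                 seed = config$seed)
    data.frame(dataset = dname, data_type = data_type,
               representation = vname(v),
               accuracy = attr(cv, "mean_accuracy"),
               auc = attr(cv, "mean_auc"), stringsAsFactors = FALSE)
  }))
}

#' @export
print.ade_experiment <- function(x, ...) {
  nd <- length(x$config$specs)
  cat(sprintf("<ade_experiment> %d dataset(s), classifiers: %s\n", nd,
              paste(x$config$classifiers, collapse = ", ")))
  full <- x$selection_curves[x$selection_curves$fraction ==
                               max(x$selection_curves$fraction), ]
  cat("Mean performance at the full feature set:\n")
  print(full, row.names = FALSE)
  if (!is.null(x$datatype_comparison)) {
    cat(sprintf("\nData-type Friedman chi-square = %.3f, p = %.4g\n",
                x$datatype_comparison$statistic,
                x$datatype_comparison$p_value))
  }
  invisible(x)
}

#' Write experiment result tables
#'
#' Plain delimited tables under `out_dir`, each with a provenance header
#' (`# seed=... config_hash=...`), plus a `manifest.json`.
#'
#' @param experiment an `ade_experiment`.
#' @param out_dir destination directory (created if absent).
#' @return `out_dir` invisibly.
#' @export
write_experiment <- function(experiment, out_dir) {
  stopifnot(inherits(experiment, "ade_experiment"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- experiment$config
  hash <- config_hash(cfg)
  header <- sprintf("# seed=%d config_hash=%s", cfg$seed, hash)
  emit <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    path <- file.path(out_dir, paste0(name, ".csv"))
    con <- file(path, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(header, con, useBytes = TRUE)
    utils::write.table(format(df, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       con, sep = ",", row.names = FALSE, quote = FALSE)
  }
  emit(experiment$datatype_results, "datatype_results")
  emit(experiment$selection_curves, "selection_curves")
  emit(experiment$feature_composition, "feature_composition")
  emit(experiment$informativeness, "informativeness")
  emit(experiment$representation_results, "representation_results")
  if (!is.null(experiment$datatype_comparison)) {
    emit(experiment$datatype_comparison$pairwise, "datatype_pairwise")
    emit(data.frame(configuration = names(experiment$datatype_comparison$avg_ranks),
                    avg_rank = experiment$datatype_comparison$avg_ranks,
                    statistic = experiment$datatype_comparison$statistic,
                    p_value = experiment$datatype_comparison$p_value),
         "datatype_ranks")
  }
  if (!is.null(experiment$classifier_comparison)) {
    emit(experiment$classifier_comparison$pairwise, "classifier_pairwise")
    emit(data.frame(configuration = names(experiment$classifier_comparison$avg_ranks),
                    avg_rank = experiment$classifier_comparison$avg_ranks,
                    statistic = experiment$classifier_comparison$statistic,
                    p_value = experiment$classifier_comparison$p_value),
         "classifier_ranks")
  }
  jsonlite::write_json(
    list(seed = cfg$seed, config_hash = hash,
         n_datasets = length(cfg$specs),
         classifiers = cfg$classifiers, fractions = cfg$fractions,
         folds = cfg$folds, repeats = cfg$repeats),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

config_hash <- function(config) {
  stripped <- unclass(config)
  txt <- paste(utils::capture.output(utils::str(stripped, digits.d = 10)),
               collapse = "\n")
  # small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
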