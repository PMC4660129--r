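#' Specification for a synthetic EHR dataset
#'
#' Describes one synthetic dataset with the statistical structure the
#' pipeline assumes: a hierarchical code vocabulary (ICD-like diagnoses,
#' ATC-like drugs), sparse long-tailed background code events, repeated
#' timestamped measurements with Gaussian baselines, a designated target
#' ADE code with a similar-code sibling (so controls exist), and a list of
#' planted effects that separate positives from negatives through a chosen
#' representation channel.
#'
#' Defaults emulate the kind of clinical datasets the pipeline targets:
#' hundreds of patients, positive-class proportions anywhere from a few
#' percent to a large majority (valid range 2.5%-87.5%), hundreds of
#' sparse code features and a few dozen measurements with repeated
#' observations per patient.
#'
#' @param n_patients number of patients (default 500).
#' @param prevalence target positive fraction in \[0.025, 0.875\]
#'   (default 0.2); realized prevalence is binomial.
#' @param diag_branching,drug_branching integer vectors of 4 branching
#'   factors for the diagnosis / drug vocabulary trees.
#' @param n_measurements number of distinct measurement types (default 20).
#' @param background_rate mean number of background code events per
#'   patient (Poisson; default 20).
#' @param measurement_rate mean number of observations per (patient,
#'   measurement) pair (Poisson; default 1.5).
#' @param zipf_exponent exponent of the Zipf-like long tail over the code
#'   vocabulary (default 1.2); larger = sparser tail.
#' @param signal list of planted effects, each a list with fields
#'   `feature` (a leaf code string, or a measurement name such as
#'   `"meas03"`), `channel` (one of `"count"`, `"presence"`, `"mean"`,
#'   `"slope"`) and `effect` (effect size: extra Poisson mean for `count`,
#'   occurrence probability for `presence`, shift in baseline-SD units for
#'   `mean`, drift in SD units per index-window for `slope`).
#' @param duplicate_prob probability that an event row is duplicated
#'   exactly (default 0.02).
#' @param index_window length in days of the pre-index observation window
#'   (index timestamps are drawn uniformly in
#'   `[index_window, 2 * index_window]`; default 30).
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients = 500L, prevalence = 0.2,
                           diag_branching = c(4L, 4L, 4L, 4L),
                           drug_branching = c(3L, 4L, 3L, 3L),
                           n_measurements = 20L, background_rate = 20,
                           measurement_rate = 1.5, zipf_exponent = 1.2,
                           signal = list(), duplicate_prob = 0.02,
                           index_window = 30) {
  stopifnot(n_patients > 0, prevalence > 0, prevalence < 1,
            length(diag_branching) == 4L, all(diag_branching >= 1L),
            length(drug_branching) == 4L, all(drug_branching >= 1L),
            n_measurements >= 1L, background_rate >= 0,
            measurement_rate >= 0, duplicate_prob >= 0,
            duplicate_prob < 1, index_window > 0)
  if (prevalence < 0.025 || prevalence > 0.875)
    stop("prevalence must lie in [0.025, 0.875]", call. = FALSE)
  for (s in signal) {
    stopifnot(is.list(s), all(c("feature", "channel", "effect") %in% names(s)),
              s$channel %in% c("count", "presence", "mean", "slope"),
              is.finite(s$effect))
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a hierarchical code vocabulary
#'
#' Builds ICD-like diagnosis codes (letter + 3 digits, so hierarchy levels
#' are the 1-4 character prefixes) and ATC-like drug codes (letter + 2
#' digits + 2 letters + 2 digits) as complete 4-level trees given
#' per-level branching factors. One diagnosis leaf is designated the
#' target ADE code; a sibling sharing its 3-level prefix is designated the
#' control code, so similar-code negatives always exist.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `diagnosis` and `drug` leaf code vectors,
#'   `target_code`, `sibling_code`, and `measurements` (names).
#' @export
generate_vocabulary <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  b <- spec$diag_branching
  if (b[1] > 26 || any(b[-1] > 10))
    stop("diagnosis branching limited to 26 roots and 10 children per digit level",
         call. = FALSE)
  l1 <- LETTERS[seq_len(b[1])]
  l2 <- as.vector(outer(l1, 0:(b[2] - 1), paste0))
  l3 <- as.vector(outer(l2, 0:(b[3] - 1), paste0))
  diag_leaves <- sort(as.vector(outer(l3, 0:(b[4] - 1), paste0)))

  d <- spec$drug_branching
  if (d[1] > 26 || d[2] > 10 || d[3] > 26 || d[4] > 10)
    stop("drug branching limited by the code alphabet", call. = FALSE)
  a1 <- LETTERS[seq_len(d[1])]
  a2 <- as.vector(outer(a1, sprintf("%02d", 0:(d[2] - 1)), paste0))
  a3 <- as.vector(outer(a2, LETTERS[seq_len(d[3])], paste0))
  drug_leaves <- sort(as.vector(outer(a3, sprintf("%02d", 0:(d[4] - 1)),
                                      paste0)))

  # target = last diagnosis leaf; sibling = its predecessor in the same
  # 3-level branch (requires diag_branching[4] >= 2)
  if (b[4] < 2L)
    stop("diag_branching[4] must be >= 2 so the target code has a similar sibling",
         call. = FALSE)
  target <- diag_leaves[length(diag_leaves)]
  sibling <- diag_leaves[length(diag_leaves) - 1L]
  list(diagnosis = diag_leaves, drug = drug_leaves,
       target_code = target, sibling_code = sibling,
       measurements = sprintf("meas%02d", seq_len(spec$n_measurements)))
}

#' Generate one synthetic labeled EHR dataset
#'
#' Each patient gets a true label (Bernoulli at the spec prevalence), an
#' index event at a random time (the target code for positives, the
#' similar sibling code for negatives), and a pre-index history: background
#' diagnosis/drug events drawn Zipf-long-tailed over the vocabulary at
#' uniform times, and per-measurement repeated (timestamp, value)
#' observations from Gaussian baselines. Planted effects act on positives
#' only, through their declared channel. A small fraction of rows is
#' duplicated exactly, mimicking the duplicated records of real EHR
#' extracts. Bit-reproducible given (spec, seed).
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return list of class `synthetic_dataset` with elements `log` (an
#'   [event_log()]), `truth` (per-patient `patient_id`, `label`, plus the
#'   planted feature names per channel), and `vocabulary`.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  vocab <- generate_vocabulary(spec)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed))
  set.seed(seed)

  for (s in spec$signal) {
    known <- c(vocab$diagnosis, vocab$drug, vocab$measurements)
    if (!(s$feature %in% known))
      stop("planted signal references an absent feature: ", s$feature,
           call. = FALSE)
  }

  n <- spec$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  label <- stats::rbinom(n, 1L, spec$prevalence)
  index_t <- stats::runif(n, spec$index_window, 2 * spec$index_window)

  # background pool excludes the target and sibling codes: those two are
  # reserved for the index event so labels stay clean by construction
  bg_codes <- c(setdiff(vocab$diagnosis,
                        c(vocab$target_code, vocab$sibling_code)),
                vocab$drug)
  bg_kind <- rep(c("diagnosis", "drug"),
                 c(length(vocab$diagnosis) - 2L, length(vocab$drug)))
  zipf_w <- (seq_along(bg_codes))^(-spec$zipf_exponent)
  # fixed permutation ties a code to its popularity rank, independent of
  # alphabetical order
  perm <- sample(seq_along(bg_codes))
  bg_codes <- bg_codes[perm]; bg_kind <- bg_kind[perm]

  # per-measurement Gaussian baselines
  mu0 <- stats::rnorm(spec$n_measurements, 50, 15)
  sd0 <- stats::runif(spec$n_measurements, 2, 8)
  names(mu0) <- names(sd0) <- vocab$measurements

  sig_by_channel <- function(ch)
    Filter(function(s) s$channel == ch, spec$signal)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- ids[i]; pos <- label[i] == 1L; t_idx <- index_t[i]
    ev <- list()

    # index event
    ev[[1]] <- data.frame(
      patient_id = pid, timestamp = t_idx, kind = "diagnosis",
      code = if (pos) vocab$target_code else vocab$sibling_code,
      measurement_name = NA_character_, value = NA_real_,
      stringsAsFactors = FALSE)

    # background codes, long-tailed
    n_bg <- stats::rpois(1L, spec$background_rate)
    if (n_bg > 0L) {
      pick <- sample(seq_along(bg_codes), n_bg, replace = TRUE,
                     prob = zipf_w)
      ev[[length(ev) + 1L]] <- data.frame(
        patient_id = pid, timestamp = stats::runif(n_bg, 0, t_idx),
        kind = bg_kind[pick], code = bg_codes[pick],
        measurement_name = NA_character_, value = NA_real_,
        stringsAsFactors = FALSE)
    }

    # planted code effects (positives only)
    if (pos) {
      for (s in sig_by_channel("count")) {
        extra <- stats::rpois(1L, s$effect)
        if (extra > 0L) ev[[length(ev) + 1L]] <- code_rows(
          pid, stats::runif(extra, 0, t_idx), s$feature, vocab)
      }
      for (s in sig_by_channel("presence")) {
        if (stats::runif(1L) < s$effect)
          ev[[length(ev) + 1L]] <- code_rows(
            pid, stats::runif(1L, 0, t_idx), s$feature, vocab)
      }
    }

    # measurements
    mean_shift <- stats::setNames(numeric(spec$n_measurements),
                                  vocab$measurements)
    slope_shift <- mean_shift
    if (pos) {
      for (s in sig_by_channel("mean"))
        mean_shift[s$feature] <- mean_shift[s$feature] +
          s$effect * sd0[s$feature]
      for (s in sig_by_channel("slope"))
        slope_shift[s$feature] <- slope_shift[s$feature] +
          s$effect * sd0[s$feature]
    }
    n_obs <- stats::rpois(spec$n_measurements, spec$measurement_rate)
    total <- sum(n_obs)
    if (total > 0L) {
      mnames <- rep(vocab$measurements, n_obs)
      tt <- stats::runif(total, 0, t_idx)
      vals <- stats::rnorm(total, mu0[mnames] + mean_shift[mnames],
                           sd0[mnames]) +
        slope_shift[mnames] * (tt / t_idx)
      ev[[length(ev) + 1L]] <- data.frame(
        patient_id = pid, timestamp = tt, kind = "measurement",
        code = NA_character_, measurement_name = mnames, value = vals,
        stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, ev)
  }
  df <- do.call(rbind, rows)

  # exact duplicate rows
  if (spec$duplicate_prob > 0 && nrow(df) > 0L) {
    dup <- which(stats::runif(nrow(df)) < spec$duplicate_prob)
    if (length(dup)) df <- rbind(df, df[dup, , drop = FALSE])
  }
  rownames(df) <- NULL
  log <- structure(df, class = c("event_log", "data.frame"),
                   provenance = sprintf("synthetic(seed=%d)", seed))

  planted <- lapply(spec$signal, function(s)
    data.frame(feature = s$feature, channel = s$channel,
               effect = s$effect, stringsAsFactors = FALSE))
  truth <- list(
    patient_id = ids, label = label, index_timestamp = index_t,
    target_code = vocab$target_code, sibling_code = vocab$sibling_code,
    planted = if (length(planted)) do.call(rbind, planted) else
      data.frame(feature = character(), channel = character(),
                 effect = numeric(), stringsAsFactors = FALSE))
  structure(list(log = log, truth = truth, vocabulary = vocab,
                 spec = spec, seed = seed),
            class = "synthetic_dataset")
}

code_rows <- function(pid, times, code, vocab) {
  kind <- if (code %in% vocab$diagnosis) "diagnosis" else "drug"
  data.frame(patient_id = pid, timestamp = times, kind = kind,
             code = code, measurement_name = NA_character_,
             value = NA_real_, stringsAsFactors = FALSE)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> seed %d: %d patients (%.1f%% positive), %d events\n",
    x$seed, length(x$truth$patient_id), 100 * mean(x$truth$label),
    nrow(x$log)))
  if (nrow(x$truth$planted)) {
    cat("  planted signal:\n")
    for (r in seq_len(nrow(x$truth$planted)))
      cat(sprintf("    %s via %s (effect %.3g)\n",
                  x$truth$planted$feature[r], x$truth$planted$channel[r],
                  x$truth$planted$effect[r]))
  } else cat("  no planted signal (null dataset)\n")
  invisible(x)
}

#' Generate a collection of independent synthetic datasets
#'
#' One dataset per spec, with seeds derived deterministically from
#' `base_seed`; stands in for a battery of per-ADE clinical datasets in
#' cross-dataset classifier comparisons.
#'
#' @param specs list of [synthetic_spec()] objects (at least 2).
#' @param base_seed integer; dataset i uses seed `base_seed + i - 1`.
#' @return list of `synthetic_dataset` objects.
#' @export
dataset_collection <- function(specs, base_seed = 1L) {
  stopifnot(length(specs) >= 2L)
  lapply(seq_along(specs), function(i)
    generate_cohort(specs[[i]], seed = base_seed + i - 1L))
}

#' Canonical planted-signal study conditions
#'
#' The reference synthetic scenario used throughout the package's
#' simulation studies: 500 patients at 20% prevalence with the default
#' vocabulary, carrying one count-channel drug-code effect (positives draw
#' on average 3 extra occurrences of one drug code) and one mean-channel
#' measurement effect (positives' baseline shifted by 1.5 within-patient
#' SDs). Either channel can be switched off to place the signal in a
#' single data type; with both off the spec is a matched null.
#'
#' @param n_patients,prevalence cohort size and positive fraction.
#' @param code_effect extra Poisson mean of the planted drug code for
#'   positives (0 disables the code channel).
#' @param mean_effect baseline shift of the planted measurement for
#'   positives, in units of its SD (0 disables the measurement channel).
#' @return a [synthetic_spec()].
#' @export
planted_signal_spec <- function(n_patients = 500L, prevalence = 0.2,
                                code_effect = 3, mean_effect = 1.5) {
  signal <- list()
  if (code_effect > 0)
    signal[[length(signal) + 1L]] <- list(feature = "A00A00",
                                          channel = "count",
                                          effect = code_effect)
  if (mean_effect > 0)
    signal[[length(signal) + 1L]] <- list(feature = "meas01",
                                          channel = "mean",
                                          effect = mean_effect)
  synthetic_spec(n_patients = n_patients, prevalence = prevalence,
                 signal = signal)
}

#' Expected feature names of a planted effect
#'
#' Maps a planted effect to the feature-matrix column that carries it:
#' a code effect appears as the level-4 code column; a measurement `mean`
#' effect as `meas:mean:<name>`, a `slope` effect as `meas:slope:<name>`,
#' a `presence` code effect as the level-4 column, a measurement count
#' effect as `meas:count:<name>`.
#'
#' @param dataset a [generate_cohort()] result.
#' @return character vector of planted column names (possibly empty).
#' @export
planted_feature_names <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  pl <- dataset$truth$planted
  if (!nrow(pl)) return(character())
  vocab <- dataset$vocabulary
  vapply(seq_len(nrow(pl)), function(r) {
    f <- pl$feature[r]; ch <- pl$channel[r]
    if (f %in% vocab$measurements) {
      rep_name <- switch(ch, mean = "mean", slope = "slope",
                         count = "count", presence = "existence")
      sprintf("meas:%s:%s", rep_name, f)
    } else {
      system <- if (f %in% vocab$diagnosis) "ICD10" else "ATC"
      sprintf("code:%s:L4:%s", system, f)
    }
  }, character(1))
}
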