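# Independent oracles and fixture generators. Every oracle here is a
# deliberately naive re-derivation (brute force, pair enumeration,
# subset search) kept separate from the package's implementation paths.

# -- entropy / information gain, evaluated directly from the formulas ----
entropy_oracle <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

ig_oracle <- function(feature, labels) {
  n <- length(labels)
  h_cond <- 0
  for (v in unique(feature)) {
    sel <- feature == v
    h_cond <- h_cond + sum(sel) / n * entropy_oracle(labels[sel])
  }
  entropy_oracle(labels) - h_cond
}

# -- AUC by exhaustive concordant-pair enumeration -----------------------
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# -- exhaustive hypothesis sets characterized graph-theoretically --------
# A pair set is exhaustive iff, viewed as an edge set on the k
# configurations, every connected component is a complete clique.
exhaustive_sets_oracle <- function(k) {
  pairs <- t(combn(k, 2))
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    adj <- matrix(FALSE, k, k)
    adj[pairs[idx, , drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    # connected components by repeated expansion
    comp <- seq_len(k)
    repeat {
      new_comp <- comp
      for (i in seq_len(k)) for (j in seq_len(k))
        if (adj[i, j]) new_comp[j] <- min(new_comp[j], new_comp[i])
      if (identical(new_comp, comp)) break
      comp <- new_comp
    }
    ok <- TRUE
    for (cc in unique(comp)) {
      members <- which(comp == cc)
      if (length(members) < 2) next
      need <- t(combn(members, 2))
      if (!all(adj[need])) { ok <- FALSE; break }
    }
    if (ok) out[[length(out) + 1L]] <- idx
  }
  out
}

bergman_hommel_oracle <- function(p_raw, k) {
  sets <- exhaustive_sets_oracle(k)
  vapply(seq_along(p_raw), function(h) {
    vals <- vapply(sets, function(I)
      if (h %in% I) length(I) * min(p_raw[I]) else NA_real_, numeric(1))
    min(1, max(vals, na.rm = TRUE))
  }, numeric(1))
}

# -- random well-formed event logs ---------------------------------------
random_event_log <- function(n_rows = 40L, n_patients = 6L) {
  kinds <- sample(c("diagnosis", "drug", "measurement"), n_rows,
                  replace = TRUE)
  is_meas <- kinds == "measurement"
  event_log(
    patient_id = sample(sprintf("P%02d", seq_len(n_patients)), n_rows,
                        replace = TRUE),
    timestamp = round(runif(n_rows, 0, 50), 3),
    kind = kinds,
    code = ifelse(is_meas, NA,
                  ifelse(kinds == "drug",
                         sample(c("A01AB01", "C10AA01", "B02BC99"), n_rows,
                                replace = TRUE),
                         sample(c("G444", "G440", "G514", "F251"), n_rows,
                                replace = TRUE))),
    measurement_name = ifelse(is_meas,
                              sample(c("hr", "bp", "weight"), n_rows,
                                     replace = TRUE), NA),
    value = ifelse(is_meas, round(rnorm(n_rows, 70, 10), 2), NA))
}

# canonical row order so logs can be compared as sets-with-multiplicity
sort_log <- function(log) {
  df <- data.frame(unclass(as.data.frame(log))[
    c("patient_id", "timestamp", "kind", "code", "measurement_name",
      "value")], stringsAsFactors = FALSE)
  df <- df[order(df$patient_id, df$timestamp, df$kind, df$code,
                 df$measurement_name, df$value, method = "radix",
                 na.last = TRUE), ]
  rownames(df) <- NULL
  df
}

# the four-patient toy log used in the cohort examples
toy_cohort_log <- function() {
  event_log(
    patient_id = c("P1", "P2", "P3", "P4", "P4"),
    timestamp = c(5, 3, 2, 9, 1),
    kind = "diagnosis",
    code = c("G444", "G440", "G514", "G444", "G441"))
}

# tiny feature matrix with separable signal for classifier smoke tests
toy_feature_matrix <- function(n = 60L, seed = 99L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(signal1 = rnorm(n, y * 2),
             signal2 = rnorm(n, y * 1.5),
             noise1 = rnorm(n), noise2 = rnorm(n),
             count1 = rpois(n, 2 + y))
  ehrade:::new_feature_matrix(
    x, labels = y, patient_id = sprintf("P%03d", seq_len(n)),
    feature_info = data.frame(
      name = colnames(x),
      data_type = c("measurement", "measurement", "measurement",
                    "measurement", "code"),
      representation = c("mean", "mean", "mean", "mean", "count"),
      level = c(NA, NA, NA, NA, 4L), stringsAsFactors = FALSE))
}
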