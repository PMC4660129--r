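#' Stratified fold assignment
#'
#' Assigns each example to one of `folds` test folds, separately within
#' each class so every fold sees both classes even at extreme class
#' imbalance. When the minority class has fewer members than `folds`, the
#' fold count is reduced to the minority size with a warning.
#'
#' @param labels binary label vector.
#' @param folds requested number of folds.
#' @return integer vector of fold ids in `1..folds` (possibly reduced).
#' @export
stratified_folds <- function(labels, folds = 10L) {
  y <- as_binary_labels(labels)
  n_min <- min(table(y))
  if (n_min < 2L)
    stop("degenerate class distribution: minority class has fewer than 2 members",
         call. = FALSE)
  if (n_min < folds) {
    warning(sprintf("minority class has %d members; reducing folds from %d to %d",
                    n_min, folds, n_min), call. = FALSE)
    folds <- n_min
  }
  assignment <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assignment
}

#' Repeated stratified cross-validation of one classifier configuration
#'
#' The evaluation protocol: `repeats` iterations of stratified `folds`-fold
#' cross-validation, recording accuracy (%) and AUC on each held-out fold.
#' When `select_fraction` is given, information-gain feature selection runs
#' inside each training fold (leakage-safe default) or once on the full
#' matrix (`selection_mode = "global"`, a simpler protocol), and only the
#' selected columns reach the classifier. Constant training columns are
#' dropped before fitting. Fully reproducible from `seed`.
#'
#' @param x a `feature_matrix` (or numeric matrix with a `labels`
#'   attribute or explicit `labels`).
#' @param config a [classifier_config()].
#' @param labels binary labels; defaults to the matrix's own.
#' @param folds,repeats CV protocol (default 10 x 10).
#' @param seed integer seed controlling folds and classifier randomness.
#' @param select_fraction optional fraction in (0, 1] of top
#'   information-gain features to keep.
#' @param selection_mode `"per_fold"` (default) or `"global"`.
#' @param bins discretization bins for the information-gain ranking.
#' @return an object of class `cv_result`: a data.frame with one row per
#'   (repeat, fold) and columns `repeat_`, `fold`, `accuracy`, `auc`,
#'   `n_features`; attributes `mean_accuracy`, `mean_auc`, `config`,
#'   `seed`.
#' @export
run_cv <- function(x, config, labels = attr(x, "labels"), folds = 10L,
                   repeats = 10L, seed = 1L, select_fraction = NULL,
                   selection_mode = c("per_fold", "global"), bins = 10L) {
  stopifnot(is.matrix(x), inherits(config, "classifier_config"),
            !is.null(labels), nrow(x) == length(labels))
  selection_mode <- match.arg(selection_mode)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  xm <- unclass_matrix(x)

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed))
  set.seed(seed)

  if (!is.null(select_fraction) && selection_mode == "global") {
    keep <- select_top_fraction(rank_features(x, y, bins = bins),
                                select_fraction)
    xm <- xm[, keep, drop = FALSE]
    select_fraction <- NULL
  }

  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(y, folds)
    k <- max(fold_id)
    res <- matrix(NA_real_, nrow = k, ncol = 3,
                  dimnames = list(NULL, c("accuracy", "auc", "n_features")))
    for (f in seq_len(k)) {
      test <- fold_id == f
      xtr <- xm[!test, , drop = FALSE]
      ytr <- y[!test]
      if (!is.null(select_fraction)) {
        ranking <- rank_features(xtr, ytr, bins = bins)
        keep <- select_top_fraction(ranking, select_fraction)
        xtr <- xtr[, keep, drop = FALSE]
      }
      # constant training columns carry no information for any learner
      keep_var <- matrixStats_colVar(xtr) > 0
      if (any(keep_var)) {
        xtr2 <- xtr[, keep_var, drop = FALSE]
        xte <- xm[test, colnames(xtr2), drop = FALSE]
        model <- config$fit(xtr2, ytr)
        scores <- config$score(model, xte)
      } else {
        scores <- rep(mean(ytr), sum(test))  # no usable signal: prior
      }
      yte <- y[test]
      res[f, "accuracy"] <- accuracy(scores > 0.5, yte)
      res[f, "auc"] <- if (length(unique(yte)) == 2L)
        auc(scores, yte) else NA_real_
      res[f, "n_features"] <- if (any(keep_var)) sum(keep_var) else 0
    }
    rows[[r]] <- data.frame(repeat_ = r, fold = seq_len(k), res)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("cv_result", "data.frame"),
            mean_accuracy = mean(out$accuracy),
            mean_auc = mean(out$auc, na.rm = TRUE),
            config = config$name, seed = seed,
            select_fraction = select_fraction %||% NA_real_,
            selection_mode = selection_mode)
}

matrixStats_colVar <- function(x) {
  if (nrow(x) < 2L) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  colSums((x - rep(mu, each = nrow(x)))^2) / (nrow(x) - 1L)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old_seed, envir = globalenv())
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s: %d repeats x %d folds | mean accuracy %.2f%%, mean AUC %.3f\n",
    attr(x, "config"), max(x$repeat_), max(x$fold),
    attr(x, "mean_accuracy"), attr(x, "mean_auc")))
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  c(mean_accuracy = attr(object, "mean_accuracy"),
    sd_accuracy = stats::sd(object$accuracy),
    mean_auc = attr(object, "mean_auc"),
    sd_auc = stats::sd(object$auc[!is.na(object$auc)]))
}
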