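#' Shannon entropy of a discrete vector, in bits
#'
#' \eqn{H(x) = -\sum_x p(x) \log_2 p(x)} with the convention
#' \eqn{0 \log 0 = 0}. Probabilities are the empirical frequencies of the
#' distinct values.
#'
#' @param x non-empty vector of discrete values (any type coercible to a
#'   grouping).
#' @return entropy in bits.
#' @examples
#' entropy(c(1, 1, 0, 0))  # 1 bit
#' entropy(c(1, 1, 1, 0))  # 0.8113 bits
#' @export
entropy <- function(x) {
  if (!length(x)) stop("entropy of an empty vector is undefined",
                       call. = FALSE)
  p <- tabulate(as.integer(factor(x)))
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a discrete feature for a class label
#'
#' The reduction in class entropy from splitting on the feature,
#' \eqn{I(f, Y) = H(Y) - H(Y|f)} with
#' \eqn{H(Y|f) = \sum_v p(f = v)\, H(Y \mid f = v)}, in bits. The feature
#' must already be discrete ([discretize()] continuous ones first). The
#' result is non-negative (up to floating-point rounding) and at most
#' \eqn{H(Y)}.
#'
#' @param feature discrete vector.
#' @param labels discrete class vector of the same length.
#' @return information gain in bits.
#' @examples
#' information_gain(c(1, 1, 0, 0, 0, 0), c(1, 1, 1, 0, 0, 0))  # 0.4591
#' @export
information_gain <- function(feature, labels) {
  if (length(feature) != length(labels))
    stop("feature and labels differ in length", call. = FALSE)
  n <- length(labels)
  h_y <- entropy(labels)
  groups <- split(labels, feature)
  h_cond <- sum(vapply(groups,
                       function(g) length(g) / n * entropy(g),
                       numeric(1)))
  h_y - h_cond
}

#' Equal-frequency discretization of a numeric feature
#'
#' Bins a continuous vector into at most `bins` categories at empirical
#' quantile boundaries, so bin occupancies are as equal as ties permit.
#' Boundary handling is deterministic (left-open intervals via
#' `findInterval`); a constant vector maps to a single bin. Vectors that
#' already take few distinct values (such as binary existence features or
#' small counts) are left as their own categories.
#'
#' @param x numeric vector.
#' @param bins target number of bins (>= 2).
#' @return integer vector of bin codes.
#' @export
discretize <- function(x, bins = 10L) {
  if (bins < 2L) stop("bins must be >= 2", call. = FALSE)
  ux <- unique(x)
  if (length(ux) <= bins)
    return(match(x, sort(ux)))
  qs <- stats::quantile(x, probs = seq_len(bins - 1L) / bins,
                        type = 1, names = FALSE)
  findInterval(x, unique(qs), left.open = TRUE) + 1L
}

#' Rank features by information gain
#'
#' Scores every column of a feature matrix by its information gain with
#' the class label (continuous columns are discretized first) and returns
#' the ranking, non-increasing in gain with ties broken by feature name so
#' the order is deterministic across runs.
#'
#' @param x a `feature_matrix` (or plain numeric matrix with column names).
#' @param labels class labels; defaults to the matrix's own labels.
#' @param bins discretization bins for continuous columns.
#' @return an object of class `feature_ranking`: a data.frame with columns
#'   `rank`, `feature`, `gain_bits`, plus `data_type`, `representation`,
#'   `level` when metadata is available; attribute `class_entropy`.
#' @export
rank_features <- function(x, labels = attr(x, "labels"), bins = 10L) {
  stopifnot(is.matrix(x), !is.null(colnames(x)), !is.null(labels),
            nrow(x) == length(labels))
  gains <- vapply(seq_len(ncol(x)), function(j)
    information_gain(discretize(x[, j], bins), labels), numeric(1))
  ord <- order(-gains, colnames(x), method = "radix")
  out <- data.frame(rank = seq_len(ncol(x)),
                    feature = colnames(x)[ord],
                    gain_bits = gains[ord],
                    stringsAsFactors = FALSE)
  fi <- attr(x, "feature_info")
  if (!is.null(fi)) {
    meta <- fi[match(out$feature, fi$name), c("data_type",
                                              "representation", "level")]
    rownames(meta) <- NULL
    out <- cbind(out, meta)
  }
  structure(out, class = c("feature_ranking", "data.frame"),
            class_entropy = entropy(labels))
}

#' @export
print.feature_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("<feature_ranking> %d features, class entropy %.4f bits\n",
              nrow(x), attr(x, "class_entropy")))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

#' Select the top fraction of ranked features
#'
#' Returns the names of the `ceiling(fraction * m)` top-ranked features;
#' the ceiling guarantees a 10% selection of a small feature set is never
#' empty. Selections are nested: a larger fraction is a superset of a
#' smaller one. The canonical threshold grid walks from the top 10% in 10%
#' steps until the full feature set is included.
#'
#' @param ranking a [rank_features()] result.
#' @param fraction real in (0, 1].
#' @return character vector of selected feature names, in rank order.
#' @export
select_top_fraction <- function(ranking, fraction) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (!nrow(ranking)) stop("empty ranking", call. = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  ranking$feature[seq_len(ceiling(fraction * nrow(ranking)))]
}

#' The canonical selection-threshold grid
#'
#' Top 10%, 20%, ..., 100% of features by information gain.
#' @return `seq(0.1, 1, by = 0.1)`.
#' @export
selection_grid <- function() seq(0.1, 1, by = 0.1)
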