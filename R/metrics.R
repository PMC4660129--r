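#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive example is scored above
#' a randomly chosen negative one, with ties counting one half. Computed
#' from midranks: \eqn{AUC = (R_1 - n_1(n_1+1)/2) / (n_1 n_0)} where
#' \eqn{R_1} is the rank sum of the positives.
#'
#' @param scores numeric vector, higher = more positive.
#' @param labels binary vector (0/1, logical, or a 2-level factor whose
#'   second level is positive).
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC is undefined when only one class is present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification accuracy, in percent
#'
#' @param predicted,actual binary vectors of equal length.
#' @return percentage of matching predictions in \[0, 100\].
#' @export
accuracy <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  100 * mean(as_binary_labels(predicted) == as_binary_labels(actual))
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    stopifnot(nlevels(labels) == 2L)
    return(as.integer(labels) - 1L)
  }
  y <- as.integer(as.logical(as.numeric(labels)))
  stopifnot(!anyNA(y))
  y
}
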