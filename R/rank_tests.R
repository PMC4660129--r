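#' Friedman test over a datasets-by-configurations performance matrix
#'
#' Ranks the k configurations within each of the N datasets (rank 1 =
#' best, i.e. highest performance; average ranks on ties), and computes
#' the Friedman chi-square statistic
#' \deqn{\chi^2_F = \frac{12}{N k (k+1)} \sum_j R_j^2 - 3 N (k+1)}
#' where \eqn{R_j} is the rank sum of configuration j, with a p-value from
#' the chi-square distribution on k-1 degrees of freedom.
#'
#' @param perf numeric N x k matrix, one row per dataset, one column per
#'   configuration; higher values are better.
#' @return list with `statistic`, `p_value`, `avg_ranks` (named, length
#'   k), `ranks` (N x k matrix), `n_datasets`, `k`.
#' @examples
#' perf <- rbind(c(3, 2, 1), c(3, 2, 1), c(3, 2, 1), c(3, 2, 1))
#' friedman_test(perf)$statistic  # 8
#' @export
friedman_test <- function(perf) {
  perf <- as.matrix(perf)
  n <- nrow(perf); k <- ncol(perf)
  if (n < 2L || k < 2L)
    stop("need at least 2 datasets and 2 configurations", call. = FALSE)
  ranks <- t(apply(perf, 1L, function(r) rank(-r, ties.method = "average")))
  r_sum <- colSums(ranks)
  statistic <- 12 / (n * k * (k + 1)) * sum(r_sum^2) - 3 * n * (k + 1)
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = k - 1L, lower.tail = FALSE),
       avg_ranks = colMeans(ranks), ranks = ranks, n_datasets = n, k = k)
}

#' Pairwise post-hoc p-values from average ranks
#'
#' For each pair of configurations, the standardized average-rank
#' difference \eqn{z = (\bar R_i - \bar R_j) / \sqrt{k(k+1)/(6N)}} is
#' referred to the standard normal distribution (two-sided).
#'
#' @param avg_ranks named numeric vector of k average ranks.
#' @param n_datasets N, the number of datasets ranked.
#' @return data.frame with one row per unordered pair: `i`, `j` (names),
#'   `z`, `p_raw`, in the canonical `combn` pair order.
#' @export
pairwise_rank_p <- function(avg_ranks, n_datasets) {
  k <- length(avg_ranks)
  stopifnot(k >= 2L, n_datasets >= 1L)
  nm <- names(avg_ranks) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2L)
  se <- sqrt(k * (k + 1) / (6 * n_datasets))
  z <- (avg_ranks[pairs[1L, ]] - avg_ranks[pairs[2L, ]]) / se
  data.frame(i = nm[pairs[1L, ]], j = nm[pairs[2L, ]], z = unname(z),
             p_raw = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

# All set partitions of 1..n (each partition a list of integer blocks).
set_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  smaller <- set_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p))
      out[[length(out) + 1L]] <- c(p[-b], list(c(p[[b]], n)))
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

#' Exhaustive sets of pairwise hypotheses over k configurations
#'
#' A set of pairwise equality hypotheses is *exhaustive* when exactly those
#' hypotheses could hold simultaneously — i.e. the set is the collection of
#' all within-group pairs of some partition of the k configurations.
#' Enumerated from all set partitions; pair indices follow the canonical
#' `combn(k, 2)` order.
#'
#' @param k number of configurations (2..9).
#' @return list of integer vectors of pair indices (distinct, non-empty).
#' @export
exhaustive_sets <- function(k) {
  stopifnot(k >= 2L, k <= 9L)
  pairs <- utils::combn(k, 2L)
  pair_index <- matrix(0L, k, k)
  pair_index[t(pairs)] <- seq_len(ncol(pairs))
  sets <- lapply(set_partitions(k), function(p) {
    idx <- unlist(lapply(p, function(block) {
      if (length(block) < 2L) return(integer())
      bp <- utils::combn(sort(block), 2L)
      pair_index[t(bp)]
    }))
    sort(idx)
  })
  sets <- unique(sets[lengths(sets) > 0L])
  sets
}

#' Bergmann-Hommel adjusted p-values
#'
#' Adjusts the k(k-1)/2 raw pairwise p-values by exhaustive enumeration of
#' the sets of hypotheses that could simultaneously be true: the adjusted
#' p-value of hypothesis h is
#' \eqn{\min(1, \max\{|I| \cdot \min_{j \in I} p_j : I \text{ exhaustive},
#' h \in I\})}. At least as powerful as Holm (adjusted values are never
#' larger). Enumeration cost grows with the Bell number of k, so k > 9
#' falls back to Holm with a warning.
#'
#' @param p_raw numeric vector of raw pairwise p-values in canonical
#'   `combn(k, 2)` order (length k(k-1)/2).
#' @param k number of configurations compared.
#' @return numeric vector of adjusted p-values, same order as `p_raw`.
#' @export
bergman_hommel <- function(p_raw, k) {
  m <- k * (k - 1L) / 2L
  if (length(p_raw) != m)
    stop(sprintf("expected %d p-values for k = %d, got %d", m, k,
                 length(p_raw)), call. = FALSE)
  stopifnot(all(p_raw >= 0 & p_raw <= 1))
  if (k > 9L) {
    warning("k > 9: exhaustive-set enumeration is infeasible, falling back to Holm",
            call. = FALSE)
    return(stats::p.adjust(p_raw, method = "holm"))
  }
  if (k == 2L) return(p_raw)
  sets <- exhaustive_sets(k)
  set_stat <- vapply(sets, function(I) length(I) * min(p_raw[I]),
                     numeric(1))
  adj <- vapply(seq_len(m), function(h) {
    max(set_stat[vapply(sets, function(I) h %in% I, logical(1))])
  }, numeric(1))
  pmin(adj, 1)
}

#' Compare k pipeline configurations across N datasets
#'
#' The full rank-based comparison: per-dataset ranks, average ranks,
#' Friedman statistic and p-value, and pairwise p-values adjusted by the
#' Bergmann-Hommel procedure.
#'
#' @param perf numeric N x k performance matrix (higher is better) with
#'   configuration names as column names.
#' @param metric label for printing (e.g. `"AUC"`).
#' @return an object of class `comparison_table`.
#' @export
compare_configurations <- function(perf, metric = "performance") {
  perf <- as.matrix(perf)
  if (is.null(colnames(perf)))
    colnames(perf) <- paste0("config", seq_len(ncol(perf)))
  ft <- friedman_test(perf)
  pw <- pairwise_rank_p(ft$avg_ranks, ft$n_datasets)
  pw$p_holm <- stats::p.adjust(pw$p_raw, method = "holm")
  pw$p_bergmann_hommel <- bergman_hommel(pw$p_raw, ft$k)
  structure(list(perf = perf, metric = metric, ranks = ft$ranks,
                 avg_ranks = ft$avg_ranks, statistic = ft$statistic,
                 p_value = ft$p_value, pairwise = pw,
                 n_datasets = ft$n_datasets, k = ft$k),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> %d configurations over %d datasets (%s)\n",
              x$k, x$n_datasets, x$metric))
  means <- colMeans(x$perf)
  tab <- data.frame(mean = round(means, 4),
                    avg_rank = round(x$avg_ranks, 2))
  print(tab[order(tab$avg_rank), ])
  cat(sprintf("Friedman chi-square = %.4f (df = %d), p = %.4g\n",
              x$statistic, x$k - 1L, x$p_value))
  cat("Pairwise (Bergmann-Hommel adjusted):\n")
  pw <- x$pairwise
  for (r in seq_len(nrow(pw)))
    cat(sprintf("  %s vs %s: p = %.4g\n", pw$i[r], pw$j[r],
                pw$p_bergmann_hommel[r]))
  invisible(x)
}

#' @export
plot.comparison_table <- function(x, ...) {
  ord <- order(x$avg_ranks)
  graphics::dotchart(x$avg_ranks[ord], labels = names(x$avg_ranks)[ord],
                     xlab = "average rank (1 = best)",
                     main = sprintf("%s over %d datasets", x$metric,
                                    x$n_datasets), ...)
  invisible(x)
}
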