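#' Classifier configurations
#'
#' The nine classifier families evaluated by the pipeline, each with its
#' fixed default settings:
#'
#' * `DT` — CART decision tree, minimum 1 instance per leaf.
#' * `SVM-Poly` — support vector machine, polynomial kernel of degree 3.
#' * `SVM-RBF` — support vector machine, RBF kernel, gamma = 1/m (the
#'   automatic convention; m = number of features).
#' * `LogReg` — logistic regression with L2 (ridge) regularization,
#'   lambda = 1/n.
#' * `kNN` — k nearest neighbors, k = 5.
#' * `AdaBoost` — adaptive boosting of decision stumps, 50 base estimators.
#' * `Bagging` — bagging of unpruned CART trees, 10 base estimators.
#' * `NB` — Gaussian naive Bayes.
#' * `RF` — random forest, 500 trees, `ceiling(sqrt(m))` features inspected
#'   per node.
#'
#' Every configuration is deterministic given the RNG state, and each
#' `fit`/`score` pair returns probability-like scores in \[0, 1\] for the
#' positive class (class prediction threshold: 0.5).
#'
#' @param name one of the nine names above.
#' @param ... overrides for the named hyperparameters (`ntree`, `mtry`,
#'   `k`, `degree`, `gamma`, `lambda`, `n_estimators`).
#' @return a list of class `classifier_config` with elements `name`,
#'   `params`, `fit(x, y)` and `score(model, x)`.
#' @examples
#' cfg <- classifier_config("RF", ntree = 100)
#' @export
classifier_config <- function(name = CLASSIFIER_NAMES, ...) {
  name <- match.arg(name)
  params <- utils::modifyList(default_params(name), list(...))
  structure(list(name = name, params = params,
                 fit = classifier_fit(name, params),
                 score = classifier_score(name, params)),
            class = "classifier_config")
}

#' @rdname classifier_config
#' @format NULL
#' @export
CLASSIFIER_NAMES <- c("RF", "DT", "SVM-Poly", "SVM-RBF", "LogReg", "kNN",
                      "AdaBoost", "Bagging", "NB")

#' @export
print.classifier_config <- function(x, ...) {
  ps <- paste(names(x$params), unlist(x$params), sep = "=",
              collapse = ", ")
  cat(sprintf("<classifier_config> %s (%s)\n", x$name,
              if (nzchar(ps)) ps else "defaults"))
  invisible(x)
}

default_params <- function(name) {
  switch(name,
    "RF" = list(ntree = 500L, mtry = NULL),   # NULL -> ceiling(sqrt(m))
    "DT" = list(minbucket = 1L),
    "SVM-Poly" = list(degree = 3L),
    "SVM-RBF" = list(gamma = NULL),           # NULL -> 1/m
    "LogReg" = list(lambda = NULL),           # NULL -> 1/n
    "kNN" = list(k = 5L),
    "AdaBoost" = list(n_estimators = 50L, maxdepth = 1L),
    "Bagging" = list(n_estimators = 10L),
    "NB" = list())
}

# unpruned CART with the configured leaf minimum; cp = 0 so the leaf
# minimum, not the complexity penalty, limits growth
fit_cart <- function(x, y, minbucket = 1L, maxdepth = 30L, weights = NULL) {
  df <- data.frame(.y = factor(y, levels = c(0L, 1L)), x,
                   check.names = FALSE)
  rpart::rpart(.y ~ ., data = df, method = "class", weights = weights,
               control = rpart::rpart.control(
                 minsplit = 2L, minbucket = minbucket, cp = 0,
                 maxdepth = maxdepth, xval = 0L))
}

score_cart <- function(model, x) {
  stats::predict(model, data.frame(x, check.names = FALSE),
                 type = "prob")[, "1"]
}

classifier_fit <- function(name, params) {
  switch(name,
    "RF" = function(x, y) {
      mtry <- params$mtry %||% max(1L, ceiling(sqrt(ncol(x))))
      df <- data.frame(.y = factor(y, levels = c(0L, 1L)), x,
                       check.names = FALSE)
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = params$ntree,
                     mtry = min(mtry, ncol(x)), probability = TRUE,
                     num.threads = 1L,
                     seed = sample.int(.Machine$integer.max, 1L))
    },
    "DT" = function(x, y) fit_cart(x, y, minbucket = params$minbucket),
    "SVM-Poly" = function(x, y)
      e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "polynomial",
                 degree = params$degree, probability = TRUE, scale = FALSE),
    "SVM-RBF" = function(x, y)
      e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "radial",
                 gamma = params$gamma %||% (1 / ncol(x)),
                 probability = TRUE, scale = FALSE),
    "LogReg" = function(x, y) {
      # glmnet requires >= 2 columns; pad with an all-zero dummy if needed
      if (ncol(x) < 2L) x <- cbind(x, .dummy = 0)
      glmnet::glmnet(x, factor(y, levels = c(0L, 1L)),
                     family = "binomial", alpha = 0,
                     lambda = params$lambda %||% (1 / nrow(x)),
                     standardize = FALSE)
    },
    "kNN" = function(x, y) list(train = x, y = factor(y, levels = c(0L, 1L)),
                                k = params$k),
    "AdaBoost" = function(x, y)
      fit_adaboost(x, y, n_estimators = params$n_estimators,
                   maxdepth = params$maxdepth),
    "Bagging" = function(x, y)
      fit_bagging(x, y, n_estimators = params$n_estimators),
    "NB" = function(x, y)
      e1071::naiveBayes(data.frame(x, check.names = FALSE),
                        factor(y, levels = c(0L, 1L))))
}

classifier_score <- function(name, params) {
  switch(name,
    "RF" = function(model, x)
      stats::predict(model, data.frame(x, check.names = FALSE),
                     num.threads = 1L)$predictions[, "1"],
    "DT" = score_cart,
    "SVM-Poly" = ,
    "SVM-RBF" = function(model, x) {
      pr <- attr(stats::predict(model, x, probability = TRUE),
                 "probabilities")
      pr[, "1"]
    },
    "LogReg" = function(model, x) {
      if (ncol(x) < 2L) x <- cbind(x, .dummy = 0)
      as.numeric(stats::predict(model, x, type = "response"))
    },
    "kNN" = function(model, x) {
      pred <- class::knn(model$train, x, model$y, k = model$k, prob = TRUE)
      votes <- attr(pred, "prob")  # vote share of the winning class
      ifelse(pred == "1", votes, 1 - votes)
    },
    "AdaBoost" = score_adaboost,
    "Bagging" = score_bagging,
    "NB" = function(model, x)
      stats::predict(model, data.frame(x, check.names = FALSE),
                     type = "raw", threshold = 1e-6)[, "1"])
}

# --- AdaBoost (SAMME voting on decision stumps) and bagging of CART ------
# No boosting/bagging ensemble implementation ships with the declared
# dependencies, so these two are small in-package loops over rpart trees.

fit_adaboost <- function(x, y, n_estimators = 50L, maxdepth = 1L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric()
  y01 <- as_binary_labels(y)
  for (b in seq_len(n_estimators)) {
    tree <- fit_cart(x, y01, minbucket = 1L, maxdepth = maxdepth,
                     weights = w * n)
    pred <- as.integer(score_cart(tree, x) > 0.5)
    err <- sum(w[pred != y01])
    if (err >= 0.5) break
    if (err <= 0) { stumps <- list(tree); alphas <- 1; break }
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y01, 1, -1))
    w <- w / sum(w)
  }
  if (!length(stumps)) {  # first stump already at chance: fall back to it
    stumps <- list(fit_cart(x, y01, minbucket = 1L, maxdepth = maxdepth))
    alphas <- 1
  }
  list(stumps = stumps, alphas = alphas)
}

score_adaboost <- function(model, x) {
  votes <- vapply(model$stumps,
                  function(tr) as.numeric(score_cart(tr, x) > 0.5),
                  numeric(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  as.numeric(votes %*% model$alphas) / sum(model$alphas)
}

fit_bagging <- function(x, y, n_estimators = 10L) {
  n <- nrow(x)
  trees <- lapply(seq_len(n_estimators), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_cart(x[idx, , drop = FALSE], y[idx], minbucket = 1L)
  })
  list(trees = trees)
}

score_bagging <- function(model, x) {
  probs <- vapply(model$trees, function(tr) score_cart(tr, x),
                  numeric(nrow(x)))
  rowMeans(matrix(probs, nrow = nrow(x)))
}
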