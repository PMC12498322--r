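# Tree-ensemble regressors assembled on the compiled CART fitter.
#
# No tree-ensemble package ships in the supported environment, so the
# three regressors are implemented here directly. Hyperparameters are
# frozen at the documented defaults of the reference implementations of
# these algorithms and recorded in every fitted object:
#   gradient_boost: 100 trees, learning rate 0.1, depth 3, squared error
#   random_forest:  100 trees, bootstrap, unlimited depth, all features
#   ada_boost:      AdaBoost.R2, 50 depth-3 trees, linear loss,
#                   weighted-bootstrap resampling, weighted-median predict

SUPPORTED_ALGORITHMS <- c("ada_boost", "gradient_boost", "random_forest")

default_hyperparameters <- function(algorithm) {
  switch(algorithm,
    gradient_boost = list(n_estimators = 100L, learning_rate = 0.1,
                          max_depth = 3L, min_samples_split = 2L,
                          min_samples_leaf = 1L),
    random_forest = list(n_estimators = 100L, max_depth = -1L,
                         min_samples_split = 2L, min_samples_leaf = 1L,
                         bootstrap = TRUE),
    ada_boost = list(n_estimators = 50L, learning_rate = 1,
                     max_depth = 3L, min_samples_split = 2L,
                     min_samples_leaf = 1L, loss = "linear"),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

fit_tree <- function(X, y, rows = seq_len(nrow(X)), max_depth = -1L,
                     min_samples_split = 2L, min_samples_leaf = 1L) {
  .fit_tree_cpp(X, y, as.integer(rows) - 1L, as.integer(max_depth),
                as.integer(min_samples_split), as.integer(min_samples_leaf))
}

predict_tree <- function(tree, X) .predict_tree_cpp(tree, X)

fit_gradient_boost <- function(X, y, hp) {
  f0 <- mean(y)
  pred <- rep(f0, length(y))
  trees <- vector("list", hp$n_estimators)
  for (m in seq_len(hp$n_estimators)) {
    tr <- fit_tree(X, y - pred, max_depth = hp$max_depth,
                   min_samples_split = hp$min_samples_split,
                   min_samples_leaf = hp$min_samples_leaf)
    trees[[m]] <- tr
    pred <- pred + hp$learning_rate * predict_tree(tr, X)
  }
  list(kind = "gradient_boost", init = f0, trees = trees,
       learning_rate = hp$learning_rate)
}

fit_random_forest <- function(X, y, hp, seed) {
  n <- nrow(X)
  trees <- with_seed(seed, lapply(seq_len(hp$n_estimators), function(b) {
    rows <- if (hp$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    fit_tree(X, y, rows = rows, max_depth = hp$max_depth,
             min_samples_split = hp$min_samples_split,
             min_samples_leaf = hp$min_samples_leaf)
  }))
  list(kind = "random_forest", trees = trees)
}

# AdaBoost.R2 (Drucker 1997): each round fits a depth-limited tree on a
# weighted bootstrap of the data, computes the weighted average loss, and
# down-weights well-predicted examples. Prediction is the weighted median
# of the rounds' outputs.
fit_ada_boost <- function(X, y, hp, seed) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  with_seed(seed, {
    for (m in seq_len(hp$n_estimators)) {
      rows <- sample.int(n, n, replace = TRUE, prob = w)
      tr <- fit_tree(X, y, rows = rows, max_depth = hp$max_depth,
                     min_samples_split = hp$min_samples_split,
                     min_samples_leaf = hp$min_samples_leaf)
      err <- abs(predict_tree(tr, X) - y)
      emax <- max(err)
      if (emax <= 0) {  # perfect fit: dominate and stop
        trees[[length(trees) + 1L]] <- tr
        alphas <- c(alphas, log(1 / 1e-10))
        break
      }
      loss <- err / emax  # linear loss
      avg_loss <- sum(w * loss)
      if (avg_loss >= 0.5) {
        if (!length(trees)) {  # keep at least one estimator
          trees[[1L]] <- tr
          alphas <- 1e-10
        }
        break
      }
      beta <- avg_loss / (1 - avg_loss)
      trees[[length(trees) + 1L]] <- tr
      alphas <- c(alphas, hp$learning_rate * log(1 / beta))
      w <- w * beta^(hp$learning_rate * (1 - loss))
      w <- w / sum(w)
    }
  })
  list(kind = "ada_boost", trees = trees, alphas = alphas)
}

weighted_median <- function(values, weights) {
  o <- order(values)
  cw <- cumsum(weights[o])
  values[o][which(cw >= 0.5 * sum(weights))[1L]]
}

fit_regressor <- function(X, y, algorithm, seed, hyper = list()) {
  algorithm <- match.arg(algorithm, SUPPORTED_ALGORITHMS)
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 2L)
  hp <- utils::modifyList(default_hyperparameters(algorithm), hyper)
  fit <- switch(algorithm,
    gradient_boost = fit_gradient_boost(X, y, hp),
    random_forest = fit_random_forest(X, y, hp, seed),
    ada_boost = fit_ada_boost(X, y, hp, seed))
  fit$hyperparameters <- hp
  fit
}

predict_regressor <- function(fit, X) {
  stopifnot(is.matrix(X))
  switch(fit$kind,
    gradient_boost = {
      pred <- rep(fit$init, nrow(X))
      for (tr in fit$trees) pred <- pred + fit$learning_rate * predict_tree(tr, X)
      pred
    },
    random_forest = {
      preds <- matrix(unlist(lapply(fit$trees, function(tr)
        predict_tree(tr, X))), nrow = nrow(X))
      rowMeans(preds)
    },
    ada_boost = {
      preds <- matrix(unlist(lapply(fit$trees, function(tr)
        predict_tree(tr, X))), nrow = nrow(X))
      apply(preds, 1L, weighted_median, weights = fit$alphas)
    },
    stop("unknown fitted regressor kind: ", fit$kind, call. = FALSE))
}
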