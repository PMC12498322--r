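# Training, cross-validation, evaluation, selection and persistence of
# completeness regressors over module-coverage features.

subset_dataset <- function(dataset, rows) {
  structure(list(features = dataset$features[rows, , drop = FALSE],
                 labels = dataset$labels[rows],
                 genome_ids = dataset$genome_ids[rows],
                 fractions = dataset$fractions[rows],
                 replicate = dataset$replicate[rows],
                 module_order = dataset$module_order,
                 provenance = dataset$provenance),
            class = "labeled_dataset")
}

#' Split a labeled dataset into train and test partitions by genome
#'
#' The split unit is the source genome: all simulated completeness levels
#' of one genome land on the same side, preventing leakage of a genome's
#' annotation idiosyncrasies from train to test.
#'
#' @param dataset a `labeled_dataset`.
#' @param train_fraction fraction of genomes assigned to training,
#'   strictly between 0 and 1 (default 0.9).
#' @param seed integer seed controlling the genome shuffle.
#' @return `list(train = , test = )` of `labeled_dataset`s.
#' @export
split_train_test <- function(dataset, train_fraction = 0.9, seed) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  genomes <- unique(dataset$genome_ids)
  if (length(genomes) < 2L) {
    stop("need at least 2 source genomes to split", call. = FALSE)
  }
  n_train <- round_half_away(train_fraction * length(genomes))
  n_train <- min(max(n_train, 1L), length(genomes) - 1L)
  shuffled <- with_seed(derive_seed(seed, "split"), sample(genomes))
  train_genomes <- shuffled[seq_len(n_train)]
  in_train <- dataset$genome_ids %in% train_genomes
  list(train = subset_dataset(dataset, which(in_train)),
       test = subset_dataset(dataset, which(!in_train)))
}

#' Train a completeness regressor with k-fold cross-validation
#'
#' Genomes are shuffled and dealt round-robin into `n_folds` folds; one
#' model is fitted per fold on the out-of-fold examples and evaluated on
#' the held-out fold, and a final model is refitted on all training data.
#'
#' @param train a `labeled_dataset`.
#' @param algorithm one of `"ada_boost"`, `"gradient_boost"`,
#'   `"random_forest"`.
#' @param n_folds number of cross-validation folds (default 5).
#' @param shuffle shuffle genomes before fold assignment (default TRUE).
#' @param seed integer seed.
#' @param hyper optional list of hyperparameter overrides.
#' @return a `completeness_model_cv`: `model` (the final
#'   `trained_completeness_model`), `fold_models`, `cv_summary`
#'   (per-fold data.frame) and `fold_assignment`.
#' @export
train_model <- function(train, algorithm, n_folds = 5L, shuffle = TRUE,
                        seed, hyper = list()) {
  stopifnot(inherits(train, "labeled_dataset"))
  algorithm <- match.arg(algorithm, SUPPORTED_ALGORITHMS)
  genomes <- unique(train$genome_ids)
  if (length(genomes) < n_folds) {
    stop(sprintf("need at least %d source genomes for %d-fold CV, have %d",
                 n_folds, n_folds, length(genomes)), call. = FALSE)
  }
  ord <- if (shuffle) {
    with_seed(derive_seed(seed, "folds"), sample(genomes))
  } else genomes
  fold_of_genome <- stats::setNames(rep_len(seq_len(n_folds), length(ord)), ord)
  fold <- unname(fold_of_genome[train$genome_ids])

  fold_models <- vector("list", n_folds)
  cv_rows <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    fit_rows <- which(fold != k)
    val_rows <- which(fold == k)
    fit <- fit_regressor(train$features[fit_rows, , drop = FALSE],
                         train$labels[fit_rows], algorithm,
                         seed = derive_seed(seed, "fold", k), hyper = hyper)
    model_k <- new_trained_model(fit, algorithm, train$module_order, seed)
    fold_models[[k]] <- model_k
    pred <- predict_completeness(model_k,
                                 train$features[val_rows, , drop = FALSE])
    expected <- train$labels[val_rows]
    cv_rows[[k]] <- data.frame(
      fold = k,
      n = length(val_rows),
      pearson_r = if (stats::sd(pred) > 0 && stats::sd(expected) > 0)
        stats::cor(pred, expected) else NA_real_,
      mse = mean((pred / 100 - expected / 100)^2),
      median_difference = stats::median(expected - pred))
  }
  final_fit <- fit_regressor(train$features, train$labels, algorithm,
                             seed = derive_seed(seed, "final"),
                             hyper = hyper)
  structure(list(model = new_trained_model(final_fit, algorithm,
                                           train$module_order, seed),
                 fold_models = fold_models,
                 cv_summary = do.call(rbind, cv_rows),
                 fold_assignment = fold_of_genome,
                 algorithm = algorithm),
            class = "completeness_model_cv")
}

new_trained_model <- function(fit, algorithm, feature_order, seed) {
  structure(list(algorithm = algorithm,
                 feature_order = feature_order,
                 fitted_state = fit,
                 seed = as.integer(seed),
                 version = as.character(utils::packageVersion("plastidr"))),
            class = "trained_completeness_model")
}

#' @export
print.trained_completeness_model <- function(x, ...) {
  cat(sprintf("<trained_completeness_model> %s, %d features, seed %d\n",
              x$algorithm, length(x$feature_order), x$seed))
  invisible(x)
}

#' @export
print.completeness_model_cv <- function(x, ...) {
  cat(sprintf("<completeness_model_cv> %s, %d folds\n", x$algorithm,
              nrow(x$cv_summary)))
  print(x$cv_summary)
  invisible(x)
}

as_feature_matrix <- function(features, feature_order) {
  if (inherits(features, "coverage_vector")) {
    if (!identical(features$module_order, feature_order)) {
      stop("feature order mismatch: coverage vector modules differ from ",
           "the model's training catalog (no silent reordering)",
           call. = FALSE)
    }
    return(matrix(features$values, nrow = 1,
                  dimnames = list(NULL, feature_order)))
  }
  if (is.matrix(features)) {
    if (!is.null(colnames(features)) &&
        !identical(colnames(features), feature_order)) {
      stop("feature order mismatch: matrix columns differ from the ",
           "model's training catalog (no silent reordering)", call. = FALSE)
    }
    if (ncol(features) != length(feature_order)) {
      stop("feature order mismatch: expected ", length(feature_order),
           " features, got ", ncol(features), call. = FALSE)
    }
    return(features)
  }
  stop("features must be a coverage_vector or a feature matrix",
       call. = FALSE)
}

#' Predict completeness percent from module-coverage features
#'
#' Raw regressor output clamped to \[0, 100\]. The feature order must
#' equal the model's training catalog order; mismatches are an error.
#'
#' @param model a `trained_completeness_model` (or a
#'   `completeness_model_cv`, whose final model is used).
#' @param features a `coverage_vector` or a feature matrix whose columns
#'   follow the model's `feature_order`.
#' @return numeric vector of percentages in \[0, 100\].
#' @export
predict_completeness <- function(model, features) {
  if (inherits(model, "completeness_model_cv")) model <- model$model
  stopifnot(inherits(model, "trained_completeness_model"))
  X <- as_feature_matrix(features, model$feature_order)
  pmin(100, pmax(0, predict_regressor(model$fitted_state, X)))
}

#' Evaluate a trained model on a labeled test grid
#'
#' Summarises predictions per expected completeness level (median and
#' population SD), fits ordinary least squares `predicted ~ expected`,
#' and reports Pearson correlation, mean squared error on the \[0, 1\]
#' label scale, and the median signed difference expected - predicted.
#'
#' @param model a `trained_completeness_model` or `completeness_model_cv`.
#' @param test a `labeled_dataset`.
#' @return an `evaluation_report`: `per_level` (data.frame level, median,
#'   sd, n), `linear_fit` (slope, intercept, adj_r_squared, p_value; NULL
#'   when undefined), `pearson_r`, `pearson_p`, `mse`,
#'   `median_difference`.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(test, "labeled_dataset"))
  if (!nrow(test$features)) stop("test dataset is empty", call. = FALSE)
  pred <- predict_completeness(model, test$features)
  expected <- test$labels

  levels <- sort(unique(expected))
  per_level <- do.call(rbind, lapply(levels, function(lv) {
    p <- pred[expected == lv]
    data.frame(level = lv, median = stats::median(p), sd = sd_pop(p),
               n = length(p))
  }))

  linear_fit <- NULL
  pearson_r <- NA_real_
  pearson_p <- NA_real_
  degenerate <- character(0)
  if (length(levels) < 2L) {
    degenerate <- c(degenerate, "single distinct expected level")
  } else {
    fit <- stats::lm(pred ~ expected)
    sm <- summary(fit)
    linear_fit <- list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      adj_r_squared = sm$adj.r.squared,
      p_value = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                 sm$fstatistic[3], lower.tail = FALSE)))
    if (stats::sd(pred) > 0) {
      ct <- stats::cor.test(pred, expected)
      pearson_r <- unname(ct$estimate)
      pearson_p <- ct$p.value
    } else {
      degenerate <- c(degenerate, "constant predictions (zero variance)")
    }
  }
  structure(list(per_level = per_level,
                 linear_fit = linear_fit,
                 pearson_r = pearson_r,
                 pearson_p = pearson_p,
                 mse = mean((pred / 100 - expected / 100)^2),
                 median_difference = stats::median(expected - pred),
                 degenerate = degenerate,
                 n = length(pred)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n=%d, pearson r=%.3f, mse=%.5f, median diff=%.2f\n",
              x$n, x$pearson_r, x$mse, x$median_difference))
  if (!is.null(x$linear_fit)) {
    cat(sprintf("  linear fit: y = %.3fx + %.3f (adj R^2 = %.3f)\n",
                x$linear_fit$slope, x$linear_fit$intercept,
                x$linear_fit$adj_r_squared))
  }
  print(x$per_level, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Per-level medians and SDs as TSV, scalar metrics as JSON.
#'
#' @param report an `evaluation_report`.
#' @param prefix output path prefix; writes `<prefix>_levels.tsv` and
#'   `<prefix>_metrics.json`.
#' @export
write_evaluation_report <- function(report, prefix) {
  stopifnot(inherits(report, "evaluation_report"))
  write_tsv_plain(report$per_level, paste0(prefix, "_levels.tsv"))
  metrics <- list(linear_fit = report$linear_fit,
                  pearson_r = report$pearson_r,
                  pearson_p = report$pearson_p,
                  mse = report$mse,
                  median_difference = report$median_difference,
                  n = report$n)
  jsonlite::write_json(metrics, paste0(prefix, "_metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' Select the best-performing algorithm from evaluation reports
#'
#' Chooses the algorithm whose median signed difference
#' (expected - predicted) is smallest in magnitude, i.e. the least
#' systematic over- or under-estimation. Ties break to the larger
#' Pearson correlation, then to fixed algorithm-name order.
#'
#' @param reports named list, algorithm -> `evaluation_report`.
#' @param verbose print the criterion trail (default FALSE).
#' @return the selected algorithm name.
#' @export
select_best_model <- function(reports, verbose = FALSE) {
  stopifnot(length(reports) >= 1L, !is.null(names(reports)))
  tab <- data.frame(
    algorithm = names(reports),
    median_difference = vapply(reports, function(r) r$median_difference,
                               numeric(1)),
    pearson_r = vapply(reports, function(r)
      if (is.na(r$pearson_r)) -Inf else r$pearson_r, numeric(1)))
  tab <- tab[order(abs(tab$median_difference), -tab$pearson_r,
                   tab$algorithm), ]
  if (verbose) {
    message("model selection (|median difference|, then pearson r):")
    for (i in seq_len(nrow(tab))) {
      message(sprintf("  %d. %s: median diff %+0.3f, r %.3f", i,
                      tab$algorithm[i], tab$median_difference[i],
                      tab$pearson_r[i]))
    }
  }
  tab$algorithm[1L]
}

#' Contrast model predictions on plastid-like vs mitochondria-like sets
#'
#' Predicts completeness for both labeled sets and reports the medians
#' and their discrimination margin. A wide margin indicates the model
#' does not mistake the reduced mitochondrial gene complement for a
#' partially complete plastid genome.
#'
#' @param model a `trained_completeness_model` or `completeness_model_cv`.
#' @param plastid_test,mito_test non-empty `labeled_dataset`s.
#' @return list with `plastid_median`, `mito_median`, `margin`.
#' @export
contrast_organelles <- function(model, plastid_test, mito_test) {
  stopifnot(inherits(plastid_test, "labeled_dataset"),
            inherits(mito_test, "labeled_dataset"))
  if (!nrow(plastid_test$features)) stop("plastid test set is empty",
                                         call. = FALSE)
  if (!nrow(mito_test$features)) stop("mitochondrial test set is empty",
                                      call. = FALSE)
  pm <- stats::median(predict_completeness(model, plastid_test$features))
  mm <- stats::median(predict_completeness(model, mito_test$features))
  list(plastid_median = pm, mito_median = mm, margin = pm - mm)
}

#' Persist / restore a trained completeness model
#'
#' The artifact is a single RDS file embedding the fitted state together
#' with metadata (algorithm, feature order, seed, package version).
#' Loading validates the artifact and, when a catalog is supplied,
#' checks that its module order matches the model's feature order.
#'
#' @param model a `trained_completeness_model` or `completeness_model_cv`.
#' @param path artifact path.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "completeness_model_cv")) model <- model$model
  stopifnot(inherits(model, "trained_completeness_model"))
  saveRDS(list(format = "plastidr_completeness_model", format_version = 1L,
               metadata = list(algorithm = model$algorithm,
                               feature_order = model$feature_order,
                               seed = model$seed,
                               package_version = model$version),
               model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @param catalog optional module catalog to validate against the
#'   artifact's feature order.
#' @export
load_model <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop("model artifact not found: ", path,
                               call. = FALSE)
  obj <- readRDS(path)
  if (!is.list(obj) ||
      !identical(obj$format, "plastidr_completeness_model")) {
    stop("not a completeness model artifact: ", path, call. = FALSE)
  }
  model <- obj$model
  if (!inherits(model, "trained_completeness_model")) {
    stop("incompatible model artifact (corrupt payload): ", path,
         call. = FALSE)
  }
  if (!is.null(catalog)) {
    ids <- check_catalog(catalog)
    if (!identical(ids, model$feature_order)) {
      stop("model/catalog mismatch: artifact was trained on a different ",
           "module catalog than the one supplied", call. = FALSE)
    }
  }
  model
}
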