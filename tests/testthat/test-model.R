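test_that("train/test split is genome-level, exhaustive and seeded", {
  catalog <- toy_catalog()
  profs <- lapply(1:10, function(i)
    ko_profile(sprintf("g%02d", i),
               stats::setNames(rep(2L, 3), c("K00001", "K00002", "K00003"))))
  ds <- make_training_grid(profs, fractions = c(0.5, 1), catalog = catalog,
                           seed = 2)
  parts <- split_train_test(ds, train_fraction = 0.9, seed = 2)
  expect_equal(length(unique(parts$train$genome_ids)), 9)
  expect_equal(length(unique(parts$test$genome_ids)), 1)
  expect_length(intersect(parts$train$genome_ids, parts$test$genome_ids), 0)
  expect_equal(nrow(parts$train$features) + nrow(parts$test$features),
               nrow(ds$features))

  again <- split_train_test(ds, train_fraction = 0.9, seed = 2)
  expect_identical(again$test$genome_ids, parts$test$genome_ids)

  expect_error(split_train_test(ds, train_fraction = 1, seed = 2),
               "strictly between")
  one <- subset_ds <- plastidr:::subset_dataset(ds, which(ds$genome_ids == "g01"))
  expect_error(split_train_test(one, seed = 2), "at least 2")
})

test_that("cross-validated training produces fold models and is seeded", {
  run <- small_model_run()
  cv <- run$cv
  expect_length(cv$fold_models, 5)
  expect_equal(nrow(cv$cv_summary), 5)
  expect_s3_class(cv$model, "trained_completeness_model")
  expect_equal(cv$model$algorithm, "gradient_boost")
  # every training genome sits in exactly one fold
  expect_setequal(names(cv$fold_assignment),
                  unique(run$parts$train$genome_ids))

  cv2 <- train_model(run$parts$train, "gradient_boost", seed = 401)
  expect_identical(cv2$fold_assignment, cv$fold_assignment)
  probe <- run$parts$test$features
  expect_identical(predict_completeness(cv2, probe),
                   predict_completeness(cv, probe))

  expect_error(train_model(run$parts$train, "neural_net", seed = 1))
  few <- plastidr:::subset_dataset(run$dataset,
                                   which(run$dataset$genome_ids %in%
                                           unique(run$dataset$genome_ids)[1:3]))
  expect_error(train_model(few, "gradient_boost", seed = 1), "5-fold")
})

test_that("predictions are clamped and reject reordered features", {
  run <- small_model_run()
  zero <- matrix(0, 1, ncol(run$dataset$features),
                 dimnames = list(NULL, run$dataset$module_order))
  one <- matrix(1, 1, ncol(run$dataset$features),
                dimnames = list(NULL, run$dataset$module_order))
  expect_lte(predict_completeness(run$cv, zero), 15)
  expect_gte(predict_completeness(run$cv, one), 90)
  preds <- predict_completeness(run$cv, run$parts$test$features)
  expect_true(all(preds >= 0 & preds <= 100))

  shuffled <- run$parts$test$features[, rev(run$dataset$module_order)]
  expect_error(predict_completeness(run$cv, shuffled), "feature order")

  # clamping: an artificial fit pushed far above 100 reports 100
  hot <- plastidr:::new_trained_model(
    list(kind = "gradient_boost", init = 250, learning_rate = 1,
         trees = list()),
    "gradient_boost", run$dataset$module_order, 0L)
  expect_equal(unname(predict_completeness(hot, zero)), 100)
})

test_that("evaluation reports per-level summaries and degenerate cases", {
  run <- small_model_run()
  probe <- run$parts$test

  perfect <- perfect_model_for(probe)
  rep_perfect <- evaluate_model(perfect, probe)
  expect_equal(rep_perfect$linear_fit$slope, 1, tolerance = 1e-8)
  expect_equal(rep_perfect$linear_fit$intercept, 0, tolerance = 1e-6)
  expect_equal(rep_perfect$pearson_r, 1, tolerance = 1e-8)
  expect_equal(rep_perfect$median_difference, 0)
  expect_equal(rep_perfect$mse, 0, tolerance = 1e-12)
  expect_equal(rep_perfect$per_level$level, sort(unique(probe$labels)))
  expect_equal(rep_perfect$per_level$sd[rep_perfect$per_level$n == 1],
               rep(0, sum(rep_perfect$per_level$n == 1)))

  const <- constant_model_for(probe)
  rep_const <- evaluate_model(const, probe)
  expect_true(is.na(rep_const$pearson_r))
  expect_match(rep_const$degenerate, "constant", all = FALSE)

  single <- plastidr:::subset_dataset(probe, which(probe$labels == 100))
  rep_single <- evaluate_model(perfect, single)
  expect_null(rep_single$linear_fit)
  expect_match(rep_single$degenerate, "single", all = FALSE)

  prefix <- file.path(withr::local_tempdir(), "eval")
  write_evaluation_report(rep_perfect, prefix)
  expect_true(file.exists(paste0(prefix, "_levels.tsv")))
  metrics <- jsonlite::fromJSON(paste0(prefix, "_metrics.json"))
  expect_equal(metrics$pearson_r, 1, tolerance = 1e-8)
})

test_that("model selection minimises |median difference| with tie rules", {
  reports <- list(ada_boost = stub_report(-2.12, 0.91),
                  gradient_boost = stub_report(0.37, 0.95),
                  random_forest = stub_report(-7.5, 0.91))
  expect_equal(select_best_model(reports), "gradient_boost")
  expect_equal(select_best_model(reports["random_forest"]), "random_forest")
  tie <- list(a = stub_report(2, 0.8), b = stub_report(-2, 0.9))
  expect_equal(select_best_model(tie), "b")
  tie2 <- list(b = stub_report(2, 0.9), a = stub_report(-2, 0.9))
  expect_equal(select_best_model(tie2), "a")
})

test_that("organelle contrast reports medians and margin", {
  run <- small_model_run()
  catalog <- run$catalog
  pl <- synthesize_reference_profiles(5, "plastid_like", catalog, seed = 77)
  mt <- synthesize_reference_profiles(5, "mito_like", catalog, seed = 77)
  full <- function(refs) make_training_grid(lapply(refs, `[[`, "profile"),
                                            fractions = 1, catalog = catalog,
                                            seed = 77)
  res <- contrast_organelles(run$cv, full(pl), full(mt))
  expect_equal(res$margin, res$plastid_median - res$mito_median)
  expect_gt(res$margin, 0)
  same <- contrast_organelles(run$cv, full(pl), full(pl))
  expect_equal(same$margin, 0)
  empty <- plastidr:::subset_dataset(full(mt), integer(0))
  expect_error(contrast_organelles(run$cv, full(pl), empty), "empty")
})

test_that("model artifacts round-trip bit-exactly and validate catalogs", {
  run <- small_model_run()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(run$cv, path)
  probe <- run$parts$test$features
  before <- predict_completeness(run$cv, probe)
  loaded <- load_model(path, catalog = run$catalog)
  expect_identical(predict_completeness(loaded, probe), before)
  expect_equal(loaded$algorithm, "gradient_boost")
  expect_equal(loaded$seed, 401L)

  expect_error(load_model(path, catalog = toy_catalog()), "mismatch")
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(load_model(junk), "not a completeness model")
  expect_error(load_model("no/such/file.rds"), "not found")
})
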