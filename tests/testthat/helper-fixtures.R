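# Shared fixtures and independent oracles for the test suite.

toy_catalog <- function() {
  list(parse_module_definition("M_toy1", "K00001 K00002"),
       parse_module_definition("M_toy2", "(K00001,K00003) K00002"),
       parse_module_definition("M_toy3", "K00001+K00002"))
}

# Independent module-completeness oracle: rewrites the DEFINITION string
# into an R logical expression per step and evaluates it with base R's
# parser. Shares no code with the package's recursive-descent evaluator.
oracle_module_completeness <- function(definition_text, present) {
  # split into steps at spaces outside parentheses
  chars <- strsplit(definition_text, "")[[1]]
  depth <- 0L
  breaks <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == " " && depth == 0L) breaks <- c(breaks, i)
  }
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks - 1L, length(chars))
  steps <- vapply(seq_along(starts), function(k)
    paste(chars[starts[k]:ends[k]], collapse = ""), character(1))
  steps <- steps[nzchar(steps)]

  eval_step <- function(step) {
    e <- gsub("-K[0-9]{5}", "#", step)             # optional members
    kos <- unique(regmatches(e, gregexpr("K[0-9]{5}", e))[[1]])
    for (ko in kos) {
      e <- gsub(ko, if (ko %in% present) "TRUE" else "FALSE", e,
                fixed = TRUE)
    }
    e <- gsub("\\+", "&", e)
    e <- gsub(" ", "&", e)
    e <- gsub(",", "|", e)
    e <- gsub("^#", "TRUE", e)                     # optional-only position
    e <- gsub("([(&|])#", "\\1TRUE", e)
    e <- gsub("#", "&TRUE", e)                     # optional after operand
    eval(parse(text = e))
  }
  mean(vapply(steps, eval_step, logical(1)))
}

definition_kos <- function(definition_text) {
  unique(regmatches(definition_text,
                    gregexpr("K[0-9]{5}", definition_text))[[1]])
}

bundled_catalog_table <- function() {
  utils::read.delim(system.file("extdata", "synthetic_module_catalog.tsv",
                                package = "plastidr"),
                    stringsAsFactors = FALSE)
}

# Small trained model + datasets shared by model tests (12 genomes keeps
# the default run fast); memoised per session.
.small_run <- new.env(parent = emptyenv())
small_model_run <- function() {
  if (!is.null(.small_run$res)) return(.small_run$res)
  catalog <- bundled_module_catalog()
  refs <- synthesize_reference_profiles(12, "plastid_like", catalog,
                                        seed = 401)
  ds <- make_training_grid(lapply(refs, `[[`, "profile"),
                           catalog = catalog, seed = 401)
  parts <- split_train_test(ds, seed = 401)
  cv <- train_model(parts$train, "gradient_boost", seed = 401)
  .small_run$res <- list(catalog = catalog, dataset = ds, parts = parts,
                         cv = cv)
  .small_run$res
}

# Stub evaluation report carrying just the fields the selector reads.
stub_report <- function(median_difference, pearson_r = 0.9) {
  structure(list(median_difference = median_difference,
                 pearson_r = pearson_r),
            class = "evaluation_report")
}

# A model whose predictions exactly reproduce a dataset's labels: one
# unshrunk full-depth tree fitted to the probe data (leaf means are exact
# when feature rows are distinct).
perfect_model_for <- function(dataset) {
  tree <- plastidr:::fit_tree(dataset$features, dataset$labels)
  fit <- list(kind = "gradient_boost", init = 0, learning_rate = 1,
              trees = list(tree),
              hyperparameters = list(n_estimators = 1L))
  plastidr:::new_trained_model(fit, "gradient_boost",
                               dataset$module_order, 0L)
}

constant_model_for <- function(dataset, value = 50) {
  fit <- list(kind = "gradient_boost", init = value, learning_rate = 1,
              trees = list(), hyperparameters = list(n_estimators = 0L))
  plastidr:::new_trained_model(fit, "gradient_boost",
                               dataset$module_order, 0L)
}
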