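# Simulation of partial genomes by annotation subsampling, and synthetic
# reference profiles for offline training and testing.
#
# The sampling unit is the annotation token (one gene's KO assignment):
# a KO with count c contributes c tokens. Subsampling tokens without
# replacement mirrors the loss of individual genes in an incomplete
# assembly, rather than the loss of whole pathways.

#' Subsample a KO profile without replacement
#'
#' Draws a uniformly random sub-multiset of the profile's annotation
#' tokens of size `round(fraction * total)` (half away from zero).
#' Deterministic for a fixed seed; the caller's RNG state is untouched.
#'
#' @param profile a `ko_profile`.
#' @param fraction retained fraction in \[0, 1\].
#' @param seed integer seed.
#' @return a `ko_profile` with the same `genome_id`.
#' @export
subsample_profile <- function(profile, fraction, seed) {
  stopifnot(inherits(profile, "ko_profile"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must be a single number in [0, 1]", call. = FALSE)
  }
  k <- min(round_half_away(fraction * profile$total), profile$total)
  if (k == profile$total) return(profile)
  if (k == 0L) return(ko_profile(profile$genome_id))
  tokens <- rep(names(profile$counts), profile$counts)
  kept <- with_seed(seed, sample(tokens, size = k, replace = FALSE))
  tab <- table(kept)
  ko_profile(profile$genome_id,
             stats::setNames(as.integer(tab), names(tab)))
}

#' Default training completeness grid
#'
#' 0 to 100 percent in 5-percent increments (21 levels). The companion
#' `test_grid_fractions()` is the coarser 10 to 100 percent grid used for
#' held-out validation.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
training_grid_fractions <- function() seq(0, 1, by = 0.05)

#' @rdname training_grid_fractions
#' @export
test_grid_fractions <- function() seq(0.1, 1, by = 0.1)

#' Build a labeled completeness dataset over a subsampling grid
#'
#' For every profile x fraction x replicate cell, subsamples the profile
#' with a seed derived from `(seed, genome_id, fraction, replicate)`,
#' featurizes it with [coverage_vector()], and labels it
#' `100 * fraction`. Cell seeds are stable under reordering or partial
#' re-runs of the grid.
#'
#' @param profiles list of `ko_profile`.
#' @param fractions completeness fractions; default the 5 percent increment grid.
#' @param replicates subsamples per (profile, fraction) cell; default 1.
#' @param catalog module catalog (list of `module_definition`).
#' @param seed master seed.
#' @return a `labeled_dataset`: `features` (matrix, rows = examples,
#'   columns = modules), `labels` (percent in \[0, 100\]), `genome_ids`,
#'   `fractions`, `replicate`, `module_order`, `provenance`.
#' @export
make_training_grid <- function(profiles,
                               fractions = training_grid_fractions(),
                               replicates = 1L,
                               catalog,
                               seed) {
  if (!length(profiles)) stop("no profiles supplied", call. = FALSE)
  stopifnot(all(fractions >= 0 & fractions <= 1), replicates >= 1L)
  module_order <- check_catalog(catalog)
  rows <- vector("list", length(profiles) * length(fractions) * replicates)
  gid <- character(length(rows)); lab <- numeric(length(rows))
  frc <- numeric(length(rows)); rep_i <- integer(length(rows))
  r <- 0L
  for (p in profiles) {
    stopifnot(inherits(p, "ko_profile"))
    for (f in fractions) {
      for (rep in seq_len(replicates)) {
        r <- r + 1L
        cell_seed <- derive_seed(seed, p$genome_id, f, rep)
        sub <- subsample_profile(p, f, cell_seed)
        rows[[r]] <- coverage_vector(sub, catalog)$values
        gid[r] <- p$genome_id
        lab[r] <- 100 * f
        frc[r] <- f
        rep_i[r] <- rep
      }
    }
  }
  features <- do.call(rbind, rows)
  colnames(features) <- module_order
  rownames(features) <- NULL
  structure(list(features = features,
                 labels = lab,
                 genome_ids = gid,
                 fractions = frc,
                 replicate = rep_i,
                 module_order = module_order,
                 provenance = list(seed = as.integer(seed),
                                   fractions = fractions,
                                   replicates = as.integer(replicates),
                                   n_profiles = length(profiles))),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "<labeled_dataset> %d examples (%d genomes x %d levels x %d rep), %d features\n",
    nrow(x$features), x$provenance$n_profiles,
    length(x$provenance$fractions), x$provenance$replicates,
    ncol(x$features)))
  invisible(x)
}

#' Serialize / read a labeled dataset as TSV
#'
#' One `#provenance` header line (JSON) followed by a TSV with columns
#' `genome_id`, `expected_completeness`, then one column per module.
#'
#' @param dataset a `labeled_dataset`.
#' @param path output path.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  prov <- jsonlite::toJSON(dataset$provenance, auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "wb")  # binary mode: byte-identical across runs
  on.exit(close(con))
  writeLines(paste0("#provenance\t", prov), con)
  header <- paste(c("genome_id", "expected_completeness",
                    dataset$module_order), collapse = "\t")
  writeLines(header, con)
  body <- apply(dataset$features, 1L, function(v)
    paste(sprintf("%.10g", v), collapse = "\t"))
  writeLines(paste(dataset$genome_ids,
                   sprintf("%.10g", dataset$labels),
                   body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#provenance\t")) {
    stop("not a dataset file (missing provenance header): ", path,
         call. = FALSE)
  }
  prov <- jsonlite::fromJSON(sub("^#provenance\t", "", lines[1]))
  df <- utils::read.delim(text = paste(lines[-1], collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  module_order <- setdiff(names(df), c("genome_id", "expected_completeness"))
  features <- as.matrix(df[, module_order, drop = FALSE])
  rownames(features) <- NULL
  structure(list(features = features,
                 labels = df$expected_completeness,
                 genome_ids = as.character(df$genome_id),
                 fractions = df$expected_completeness / 100,
                 replicate = rep(1L, nrow(df)),
                 module_order = module_order,
                 provenance = prov),
            class = "labeled_dataset")
}

#' Filter training references by genome span
#'
#' Removes reference genomes smaller than a minimum span. The default of
#' 94 kb is the median plastid genome size of protists and excludes
#' outlier reduced genomes from model training.
#'
#' @param profiles list of `ko_profile`.
#' @param spans named numeric vector, bp span per `genome_id`.
#' @param min_span_bp minimum span in bp (default 94000).
#' @return the retained profiles, order preserved.
#' @export
filter_training_references <- function(profiles, spans, min_span_bp = 94000) {
  ids <- vapply(profiles, function(p) p$genome_id, character(1))
  missing <- setdiff(ids, names(spans))
  if (length(missing)) {
    stop("no span recorded for genome(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  profiles[spans[ids] >= min_span_bp]
}

#' Synthesize reference annotation profiles
#'
#' Generates seed-deterministic stand-ins for reference organelle
#' annotation sets. `plastid_like` genomes carry most of the catalog's
#' KOs (independent retention per KO, Poisson-distributed extra copies)
#' and plastid-scale spans; `mito_like` genomes draw a handful of KOs
#' from a small fixed subpool of the catalog (the metabolic overlap
#' between organelles) and mitochondrion-scale spans.
#'
#' @param n_genomes number of profiles to generate.
#' @param role `"plastid_like"` or `"mito_like"`.
#' @param catalog module catalog; its distinct KOs form the annotation
#'   universe.
#' @param seed integer seed.
#' @param params list overriding defaults: `ko_retention` (plastid, 0.97),
#'   `count_lambda` (extra-copy Poisson mean, 1), `mito_pool_fraction`
#'   (0.05), `mito_ko_min`/`mito_ko_max` (3/8 KOs per genome),
#'   `plastid_span_range` (c(100000, 250000)), `mito_span_range`
#'   (c(15000, 70000)).
#' @return list of `list(profile = ko_profile, span_bp = integer)`.
#' @export
synthesize_reference_profiles <- function(n_genomes,
                                          role = c("plastid_like", "mito_like"),
                                          catalog, seed, params = list()) {
  role <- match.arg(role)
  stopifnot(n_genomes >= 1L)
  check_catalog(catalog)
  p <- utils::modifyList(list(
    ko_retention = 0.97,
    count_lambda = 1,
    mito_pool_fraction = 0.05,
    mito_ko_min = 3L,
    mito_ko_max = 8L,
    plastid_span_range = c(100000, 250000),
    mito_span_range = c(15000, 70000)
  ), params)
  universe <- sort(unique(unlist(lapply(catalog, function(m)
    c(m$kos, m$optional_leaves)))))
  with_seed(derive_seed(seed, "synthesize", role), {
    # fixed minority subpool shared by all mito-like genomes
    pool_n <- max(1L, floor(p$mito_pool_fraction * length(universe)))
    mito_pool <- sample(universe, pool_n)
    lapply(seq_len(n_genomes), function(i) {
      if (role == "plastid_like") {
        keep <- universe[stats::runif(length(universe)) < p$ko_retention]
        span_range <- p$plastid_span_range
      } else {
        n_ko <- sample(seq(min(p$mito_ko_min, pool_n),
                           min(p$mito_ko_max, pool_n)), 1L)
        keep <- sample(mito_pool, n_ko)
        span_range <- p$mito_span_range
      }
      counts <- 1L + stats::rpois(length(keep), p$count_lambda)
      span <- as.integer(round(stats::runif(1, span_range[1], span_range[2])))
      prof <- ko_profile(sprintf("%s_%03d", role, i),
                         stats::setNames(counts, keep))
      list(profile = prof, span_bp = span)
    })
  })
}
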