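# Synthetic fixture generation: every input the pipeline consumes can be
# produced offline with controlled ground truth. Fixture sequences are
# uniform-random nucleotides; contig classification is consumed from
# tables, never computed from sequence, so composition realism is not
# attempted.

#' Bundled synthetic module catalog
#'
#' A hand-authored test catalog of KEGG-style module definitions (36
#' modules, stable within a major version). The definitions are
#' syntactically faithful to KEGG DEFINITION grammar — multi-step
#' modules, alternatives, `+` complexes, `-` optional members, nesting —
#' but the module ids (M9xxxx) and KO assignments are synthetic stand-ins
#' so no KEGG download is needed at build or test time. User-supplied
#' DEFINITION dumps load through [load_module_catalog()].
#'
#' @return list of `module_definition`.
#' @export
bundled_module_catalog <- function() {
  path <- system.file("extdata", "synthetic_module_catalog.tsv",
                      package = "plastidr", mustWork = TRUE)
  load_module_catalog(path)
}

#' Write KO profiles as an annotation TSV
#'
#' Inverse of [load_ko_annotations()]: expands each profile's counts into
#' per-gene rows (`genome_id`, `gene_id`, `ko_id`).
#'
#' @param profiles list of `ko_profile`.
#' @param path output TSV path.
#' @export
write_ko_annotations <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "ko_profile"))
    kos <- rep(names(p$counts), p$counts)
    if (!length(kos)) {
      return(data.frame(genome_id = p$genome_id, gene_id = "gene_00001",
                        ko_id = "", stringsAsFactors = FALSE))
    }
    data.frame(genome_id = p$genome_id,
               gene_id = sprintf("gene_%05d", seq_along(kos)),
               ko_id = kos, stringsAsFactors = FALSE)
  })
  write_tsv_plain(do.call(rbind, rows), path)
}

#' Specify a toy metagenomic sample
#'
#' Describes a sample as a set of bins with controlled composition plus
#' an unbinned pool. When `bins` is NULL a random composition is drawn:
#' per-bin span 60-300 kb, plastid fraction uniform on \[0, 1\], 1-10
#' contigs, non-plastid span assigned to a random other class.
#'
#' @param n_bins number of bins.
#' @param seed integer seed (drives both composition and sequences).
#' @param bins optional list of per-bin specs, each
#'   `list(span_bp =, plastid_fraction =, n_contigs =, other_class =)`.
#' @param n_unbinned number of unbinned contigs (default 3).
#' @return a `fixture_spec`.
#' @export
toy_sample_spec <- function(n_bins = 3L, seed = 1L, bins = NULL,
                            n_unbinned = 3L) {
  if (is.null(bins) && n_bins > 0L) {
    bins <- with_seed(derive_seed(seed, "spec"), {
      lapply(seq_len(n_bins), function(i) {
        list(span_bp = as.integer(round(stats::runif(1, 6e4, 3e5))),
             plastid_fraction = stats::runif(1),
             n_contigs = sample(1:10, 1),
             other_class = sample(c("bacteria", "mitochondrion", "eukarya",
                                    "archaea"), 1))
      })
    })
  }
  structure(list(n_bins = as.integer(n_bins), bins = bins,
                 n_unbinned = as.integer(n_unbinned),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

split_length <- function(total, n) {
  # n positive integer parts summing to total (assumes total >= n)
  if (n == 1L) return(total)
  cuts <- sort(sample.int(total - 1L, n - 1L))
  diff(c(0L, cuts, total))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy sample on disk
#'
#' Writes an assembly FASTA, a contig-classification TSV, a bin-
#' membership TSV, a contig-level taxonomy TSV, and a ground-truth JSON
#' recording each bin's true plastid span fraction. Byte-identical given
#' the same spec (seeded).
#'
#' @param spec a `fixture_spec` from [toy_sample_spec()].
#' @param outdir output directory (created if needed).
#' @return manifest list: file paths plus `ground_truth`
#'   (per-bin `plastid_fraction`, `span_bp`, `plastid_span_bp`).
#' @export
generate_toy_sample <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) {
    stop("output directory not writable: ", outdir, call. = FALSE)
  }
  with_seed(derive_seed(spec$seed, "sample"), {
    contigs <- list()
    truth <- list()
    for (i in seq_along(spec$bins)) {
      b <- spec$bins[[i]]
      bin_id <- sprintf("bin.%d", i)
      plastid_bp <- as.integer(round(b$plastid_fraction * b$span_bp))
      other_bp <- b$span_bp - plastid_bp
      n <- max(b$n_contigs, (plastid_bp > 0) + (other_bp > 0))
      # allot contigs to the two classes proportionally to span
      n_p <- if (plastid_bp == 0L) 0L else
        max(1L, min(n - (other_bp > 0L),
                    as.integer(round(n * plastid_bp / b$span_bp))))
      n_o <- n - n_p
      if (other_bp > 0L && n_o == 0L) { n_o <- 1L; n_p <- n_p - 1L }
      lens_p <- if (n_p > 0L) split_length(plastid_bp, n_p) else integer(0)
      lens_o <- if (n_o > 0L) split_length(other_bp, n_o) else integer(0)
      classes <- c(rep("plastid", n_p), rep(b$other_class, n_o))
      lens <- c(lens_p, lens_o)
      for (k in seq_along(lens)) {
        contigs[[length(contigs) + 1L]] <- list(
          contig_id = sprintf("%s_ctg%02d", bin_id, k),
          bin_id = bin_id, class = classes[k], length = lens[k])
      }
      truth[[bin_id]] <- list(
        span_bp = as.integer(sum(lens)),
        plastid_span_bp = as.integer(sum(lens_p)),
        plastid_fraction = sum(lens_p) / sum(lens))
    }
    for (k in seq_len(spec$n_unbinned)) {
      contigs[[length(contigs) + 1L]] <- list(
        contig_id = sprintf("unbinned_ctg%02d", k), bin_id = NA_character_,
        class = sample(c("bacteria", "eukarya", "plastid"), 1),
        length = as.integer(round(stats::runif(1, 1e3, 2e4))))
    }

    ids <- vapply(contigs, `[[`, character(1), "contig_id")
    lens <- vapply(contigs, `[[`, integer(1), "length")
    classes <- vapply(contigs, `[[`, character(1), "class")
    bins_of <- vapply(contigs, `[[`, character(1), "bin_id")

    assembly <- Biostrings::DNAStringSet(vapply(lens, random_dna,
                                                character(1)))
    names(assembly) <- ids
    assembly_path <- file.path(outdir, "assembly.fasta")
    Biostrings::writeXStringSet(assembly, assembly_path)

    class_path <- file.path(outdir, "classifications.tsv")
    write_tsv_plain(data.frame(contig_id = ids, class_label = classes,
                               length_bp = lens, stringsAsFactors = FALSE),
                    class_path)

    membership_path <- file.path(outdir, "bins.tsv")
    binned <- !is.na(bins_of)
    write_tsv_plain(data.frame(contig_id = ids[binned],
                               bin_id = bins_of[binned],
                               stringsAsFactors = FALSE),
                    membership_path)

    # contig-level taxonomy consistent with the classes
    lineage_of <- c(
      plastid = "root;Eukaryota;Chlorophyta;Trebouxiophyceae;Trebouxia",
      bacteria = "root;Bacteria;Proteobacteria",
      mitochondrion = "root;Eukaryota;Fungi;Ascomycota",
      eukarya = "root;Eukaryota;Fungi;Ascomycota;Lecanoromycetes",
      archaea = "root;Archaea;Euryarchaeota")
    tax_path <- file.path(outdir, "taxonomy.tsv")
    write_tsv_plain(data.frame(contig_id = ids,
                               lineage = unname(lineage_of[classes]),
                               stringsAsFactors = FALSE),
                    tax_path)

    truth_path <- file.path(outdir, "ground_truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)

    list(assembly = assembly_path, classifications = class_path,
         membership = membership_path, taxonomy = tax_path,
         ground_truth_path = truth_path, ground_truth = truth,
         outdir = outdir)
  })
}
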