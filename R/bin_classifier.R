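# Per-bin plastid content and the probable-plastid-bin retention rule.
#
# Contig classifications come from an external deep-learning classifier
# (consumed as a table, never recomputed); bin membership comes from an
# external binner (per-bin FASTA files or a two-column table). A bin is a
# probable plastid bin when strictly more than `min_plastid_content` of
# its nucleotides sit on plastid-classified contigs.

CLASS_LABELS <- c("plastid", "mitochondrion", "bacteria", "archaea",
                  "eukarya", "prokarya", "unknown")

# case-insensitive synonym map applied by load_contig_classifications()
LABEL_SYNONYMS <- c(
  plastid = "plastid", chloroplast = "plastid", plast = "plastid",
  mitochondrion = "mitochondrion", mitochondria = "mitochondrion",
  mit = "mitochondrion",
  bacteria = "bacteria", bacterium = "bacteria",
  archaea = "archaea", archaeon = "archaea",
  eukarya = "eukarya", eukaryote = "eukarya", eukaryota = "eukarya",
  prokarya = "prokarya", prokaryote = "prokarya",
  unknown = "unknown", unk = "unknown")

normalize_class_label <- function(labels) {
  key <- tolower(trimws(labels))
  # "organelle" alone is ambiguous between the two organelles: unknown
  out <- unname(LABEL_SYNONYMS[key])
  unrecognised <- unique(labels[is.na(out)])
  if (length(unrecognised)) {
    warning("unrecognised class label(s) treated as unknown: ",
            paste(unrecognised, collapse = ", "), call. = FALSE)
    out[is.na(out)] <- "unknown"
  }
  out
}

#' Load contig classifications from a TSV table
#'
#' Accepts the tabular output of a contig classifier: a header row with a
#' contig id column (`contig_id`, `sequence_id` or `sequence id`) and a
#' class column (`class_label`, `class`, `classification` or
#' `class_fst_stage`). Labels are normalised case-insensitively with
#' documented synonyms (e.g. "chloroplast" -> "plastid"); unrecognised
#' labels become "unknown" with a warning. Contig lengths come from a
#' `length_bp`/`length` column or from `lengths`.
#'
#' @param path classification TSV.
#' @param lengths optional named numeric vector contig_id -> length in bp,
#'   used when the table has no length column (e.g. from
#'   [fasta_contig_lengths()]).
#' @return data.frame with columns `contig_id`, `class_label`,
#'   `length_bp`.
#' @export
load_contig_classifications <- function(path, lengths = NULL) {
  df <- read_tsv_strict(path)
  id_col <- intersect(c("contig_id", "sequence_id", "sequence id"),
                      names(df))[1]
  class_col <- intersect(c("class_label", "class", "classification",
                           "class_fst_stage"), names(df))[1]
  if (is.na(id_col) || is.na(class_col)) {
    stop(sprintf("file '%s' needs a contig id and a class column", path),
         call. = FALSE)
  }
  ids <- as.character(df[[id_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate contig id(s) in classification table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  len_col <- intersect(c("length_bp", "length"), names(df))[1]
  if (!is.na(len_col)) {
    len <- as.numeric(df[[len_col]])
  } else if (!is.null(lengths)) {
    len <- unname(lengths[ids])
    if (anyNA(len)) {
      stop("no length available for contig(s): ",
           paste(ids[is.na(len)], collapse = ", "), call. = FALSE)
    }
  } else {
    stop("classification table has no length column and no lengths were ",
         "supplied", call. = FALSE)
  }
  if (any(is.na(len) | len < 1)) {
    stop("contig lengths must be positive integers", call. = FALSE)
  }
  data.frame(contig_id = ids,
             class_label = normalize_class_label(df[[class_col]]),
             length_bp = as.integer(len),
             stringsAsFactors = FALSE)
}

#' Contig lengths from a FASTA file
#' @param path FASTA path.
#' @return named integer vector, contig id (first token of header) -> bp.
#' @export
fasta_contig_lengths <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  stats::setNames(Biostrings::width(seqs), ids)
}

#' Load bin membership
#'
#' Accepts either a directory of per-bin FASTA files (bin id = file stem,
#' extensions fa/fasta/fna) or a two-column TSV (`contig_id`, `bin_id`).
#' A contig assigned to two bins is a format error. Contigs absent from
#' every bin are simply not in the mapping; callers track them as the
#' unbinned pool.
#'
#' @param path_or_dir directory of FASTAs or a membership TSV.
#' @return named list bin_id -> character vector of contig ids.
#' @export
load_bin_membership <- function(path_or_dir) {
  if (dir.exists(path_or_dir)) {
    files <- sort(list.files(path_or_dir, pattern = "\\.(fa|fasta|fna)$",
                             full.names = TRUE))
    if (!length(files)) {
      warning("no FASTA files found in ", path_or_dir, call. = FALSE)
      return(stats::setNames(list(), character(0)))
    }
    membership <- lapply(files, function(f) {
      sub("\\s.*$", "", names(Biostrings::readDNAStringSet(f)))
    })
    names(membership) <- tools::file_path_sans_ext(basename(files))
  } else {
    df <- read_tsv_strict(path_or_dir, required = c("contig_id", "bin_id"))
    membership <- split(as.character(df$contig_id),
                        as.character(df$bin_id))
  }
  all_contigs <- unlist(membership, use.names = FALSE)
  dup <- unique(all_contigs[duplicated(all_contigs)])
  if (length(dup)) {
    stop("contig(s) assigned to more than one bin: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  membership[order(names(membership))]
}

#' Classify bins by plastid nucleotide content
#'
#' For each bin computes the span, plastid span and the plastid fraction
#' both by nucleotides and by contig count. A bin is retained as a
#' probable plastid bin when its nucleotide fraction strictly exceeds
#' `min_plastid_content` (a bin at exactly the threshold is not
#' retained). Bins below `min_bin_span_bp` are kept in the output but
#' flagged `sub_span`. Mitochondrial and all other non-plastid classes
#' count toward the denominator only.
#'
#' @param membership named list bin_id -> contig ids
#'   (see [load_bin_membership()]).
#' @param classifications data.frame from [load_contig_classifications()].
#' @param min_plastid_content retention threshold on the nucleotide
#'   fraction (default 0.90; user-adjustable stringency).
#' @param min_bin_span_bp span below which a bin is flagged sub-span
#'   (default 50000, the reduced bin size used at binning time).
#' @return data.frame ordered by `bin_id` with columns `bin_id`,
#'   `n_contigs`, `span_bp`, `plastid_contig_count`, `plastid_span_bp`,
#'   `plastid_fraction`, `plastid_contig_fraction`,
#'   `is_probable_plastid`, `sub_span`.
#' @export
classify_bins <- function(membership, classifications,
                          min_plastid_content = 0.90,
                          min_bin_span_bp = 50000) {
  stopifnot(is.list(membership),
            is.data.frame(classifications),
            min_plastid_content >= 0, min_plastid_content <= 1)
  if (!length(membership)) {
    return(data.frame(bin_id = character(0), n_contigs = integer(0),
                      span_bp = integer(0), plastid_contig_count = integer(0),
                      plastid_span_bp = integer(0),
                      plastid_fraction = numeric(0),
                      plastid_contig_fraction = numeric(0),
                      is_probable_plastid = logical(0),
                      sub_span = logical(0), stringsAsFactors = FALSE))
  }
  binned <- unlist(membership, use.names = FALSE)
  missing <- setdiff(binned, classifications$contig_id)
  if (length(missing)) {
    stop("binned contig(s) without classification: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(binned, classifications$contig_id)
  bin_ids <- rep(names(membership), lengths(membership))
  len <- classifications$length_bp[idx]
  is_plastid <- classifications$class_label[idx] == "plastid"

  ord <- sort(unique(bin_ids))
  rows <- lapply(ord, function(b) {
    sel <- bin_ids == b
    span <- sum(len[sel])
    pspan <- sum(len[sel & is_plastid])
    n <- sum(sel)
    np <- sum(sel & is_plastid)
    frac <- pspan / span
    data.frame(bin_id = b, n_contigs = n, span_bp = span,
               plastid_contig_count = np, plastid_span_bp = pspan,
               plastid_fraction = frac,
               plastid_contig_fraction = np / n,
               is_probable_plastid = frac > min_plastid_content,
               sub_span = span < min_bin_span_bp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unbinned contig pool
#'
#' Contigs in the classification table absent from every bin.
#'
#' @inheritParams classify_bins
#' @return data.frame subset of `classifications`.
#' @export
unbinned_contigs <- function(membership, classifications) {
  binned <- unlist(membership, use.names = FALSE)
  classifications[!(classifications$contig_id %in% binned), , drop = FALSE]
}
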