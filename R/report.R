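# Per-sample summary report: bin span, completeness estimate, taxonomy,
# and marker loci, joined from bin records, model predictions, and the
# tabular outputs of external taxonomy/marker tools.

#' Build the plastid bin summary report
#'
#' One row per probable plastid bin. Joins are by bin id; absent
#' predictions, taxonomy or markers leave fields empty and never fail.
#' Predictions for bin ids that are not probable plastid bins are dropped
#' with a warning.
#'
#' @param bins data.frame from [classify_bins()].
#' @param predictions named numeric vector bin_id -> completeness percent,
#'   or NULL.
#' @param taxonomy named character vector bin_id -> lineage (from
#'   [ingest_taxonomy()]), or NULL.
#' @param markers named list bin_id -> character vector of marker names
#'   (from [ingest_markers()]), or NULL.
#' @param sample_id sample identifier column value.
#' @return data.frame with columns `sample_id`, `bin_id`, `span_bp`,
#'   `n_contigs`, `n_plastid_contigs`, `completeness_percent`,
#'   `taxonomy`, `markers` (comma-joined).
#' @export
build_report <- function(bins, predictions = NULL, taxonomy = NULL,
                         markers = NULL, sample_id = "sample") {
  stopifnot(is.data.frame(bins))
  probable <- bins[bins$is_probable_plastid, , drop = FALSE]
  if (!is.null(predictions)) {
    stray <- setdiff(names(predictions), probable$bin_id)
    if (length(stray)) {
      warning("prediction(s) for non-probable or unknown bin(s) dropped: ",
              paste(stray, collapse = ", "), call. = FALSE)
    }
    bad <- predictions[!is.na(predictions) &
                         (predictions < 0 | predictions > 100)]
    if (length(bad)) {
      stop("completeness predictions outside [0, 100]", call. = FALSE)
    }
  }
  lookup <- function(map, id, default = NA_character_) {
    if (is.null(map) || !(id %in% names(map))) default else map[[id]]
  }
  rows <- lapply(seq_len(nrow(probable)), function(i) {
    b <- probable$bin_id[i]
    mk <- lookup(markers, b, default = character(0))
    data.frame(
      sample_id = sample_id,
      bin_id = b,
      span_bp = probable$span_bp[i],
      n_contigs = probable$n_contigs[i],
      n_plastid_contigs = probable$plastid_contig_count[i],
      completeness_percent = if (is.null(predictions)) NA_real_ else
        as.numeric(lookup(predictions, b, NA_real_)),
      taxonomy = lookup(taxonomy, b),
      markers = paste(sort(unique(mk)), collapse = ","),
      stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(sample_id = character(0), bin_id = character(0),
                      span_bp = integer(0), n_contigs = integer(0),
                      n_plastid_contigs = integer(0),
                      completeness_percent = numeric(0),
                      taxonomy = character(0), markers = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the summary report TSV
#' @param report data.frame from [build_report()].
#' @param path output path.
#' @export
write_report <- function(report, path) write_tsv_plain(report, path)

# ---- Taxonomy --------------------------------------------------------------

#' Derive bin-level lineages from contig-level taxonomy calls
#'
#' Consumes a contig-classification table in the style of contig
#' taxonomy tools: a contig id column (`contig_id` or `# contig`) and a
#' `lineage` column of semicolon-separated ranks (root first). The bin
#' lineage is built rank by rank: at each depth the span-weighted
#' majority taxon (> 50% of the bin's classified span) is accepted and
#' the walk continues inside it; the walk stops at the first depth with
#' no majority, so a 50/50 conflict reports the deepest common ancestor.
#' Rows whose lineage cannot be parsed are skipped with a warning.
#'
#' @param path taxonomy TSV.
#' @param membership named list bin_id -> contig ids.
#' @param classifications data.frame with `contig_id` and `length_bp`
#'   (for span weighting).
#' @return named character vector bin_id -> lineage (semicolon-joined);
#'   bins with no classified contigs are absent.
#' @export
ingest_taxonomy <- function(path, membership, classifications) {
  df <- read_tsv_strict(path)
  id_col <- intersect(c("contig_id", "# contig", "contig"), names(df))[1]
  if (is.na(id_col) || !("lineage" %in% names(df))) {
    stop(sprintf("file '%s' needs contig id and lineage columns", path),
         call. = FALSE)
  }
  ids <- as.character(df[[id_col]])
  lineages <- strsplit(as.character(df$lineage), ";", fixed = TRUE)
  lineages <- lapply(lineages, trimws)
  ok <- vapply(lineages, function(l) length(l) > 0 && all(nzchar(l)),
               logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with unparseable lineage skipped",
            call. = FALSE)
  }
  ids <- ids[ok]; lineages <- lineages[ok]
  span_of <- stats::setNames(as.numeric(classifications$length_bp),
                             classifications$contig_id)

  out <- character(0)
  for (b in names(membership)) {
    sel <- which(ids %in% membership[[b]])
    if (!length(sel)) next
    w <- span_of[ids[sel]]
    w[is.na(w)] <- 0
    total_w <- sum(w)  # majority is always over the bin's classified span
    lins <- lineages[sel]
    lineage <- character(0)
    depth <- 1L
    repeat {
      has <- vapply(lins, function(l) length(l) >= depth, logical(1))
      if (!any(has)) break
      taxa <- vapply(lins[has], `[[`, character(1), depth)
      wt <- tapply(w[has], taxa, sum)
      top <- names(wt)[which.max(wt)]
      if (total_w <= 0 || wt[top] <= 0.5 * total_w) break
      lineage <- c(lineage, top)
      keep <- vapply(lins, function(l)
        length(l) >= depth && l[[depth]] == top, logical(1))
      lins <- lins[keep]
      w <- w[keep]
      depth <- depth + 1L
    }
    if (length(lineage)) out[b] <- paste(lineage, collapse = ";")
  }
  out
}

# ---- Marker loci -----------------------------------------------------------

RRNA_MARKER_MAP <- c("16s" = "rRNA_16S-like", "23s" = "rRNA_23S-like",
                     "5s" = "rRNA_5S-like")

#' Ingest marker-gene search results
#'
#' Reads the per-domain table of a profile HMM search (whitespace-
#' delimited, `#` comments; target = contig in field 1, query = marker
#' name in field 4) and/or an rRNA-predictor GFF3 (seqid, start, end,
#' strand; `Name=` attribute such as `16S_rRNA`). Coordinates are GFF3
#' 1-based inclusive; loci on the minus strand are reverse-complemented
#' on extraction. Loci whose coordinates exceed the contig length are
#' skipped with a warning.
#'
#' @param hmm_table path to the HMM domain table, or NULL.
#' @param rrna_gff path to the rRNA GFF3, or NULL.
#' @param membership named list bin_id -> contig ids.
#' @param assembly optional `Biostrings::DNAStringSet` of the assembly
#'   for locus sequence extraction.
#' @return list with `markers` (named list bin_id -> marker names) and
#'   `loci` (data.frame contig_id, bin_id, marker, start, end, strand,
#'   sequence; sequence NA without an assembly).
#' @export
ingest_markers <- function(hmm_table = NULL, rrna_gff = NULL, membership,
                           assembly = NULL) {
  contig_to_bin <- stats::setNames(
    rep(names(membership), lengths(membership)),
    unlist(membership, use.names = FALSE))
  loci <- list()

  if (!is.null(hmm_table) && file.exists(hmm_table)) {
    lines <- readLines(hmm_table, warn = FALSE)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    for (ln in lines) {
      f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(f) < 4L) next
      loci[[length(loci) + 1L]] <- data.frame(
        contig_id = f[1], marker = f[4], start = NA_integer_,
        end = NA_integer_, strand = "+", stringsAsFactors = FALSE)
    }
  }

  if (!is.null(rrna_gff) && file.exists(rrna_gff)) {
    lines <- readLines(rrna_gff, warn = FALSE)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 9L) next
      name <- sub(".*Name=([^;]+).*", "\\1", f[9])
      key <- tolower(sub("_.*$", "", name))
      marker <- if (key %in% names(RRNA_MARKER_MAP))
        unname(RRNA_MARKER_MAP[key]) else name
      loci[[length(loci) + 1L]] <- data.frame(
        contig_id = f[1], marker = marker,
        start = as.integer(f[4]), end = as.integer(f[5]),
        strand = f[7], stringsAsFactors = FALSE)
    }
  }

  if (!length(loci)) {
    return(list(markers = stats::setNames(
      rep(list(character(0)), length(membership)), names(membership)),
      loci = data.frame(contig_id = character(0), bin_id = character(0),
                        marker = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        sequence = character(0), stringsAsFactors = FALSE)))
  }
  loci <- do.call(rbind, loci)
  loci$bin_id <- unname(contig_to_bin[loci$contig_id])
  loci <- loci[!is.na(loci$bin_id), , drop = FALSE]

  loci$sequence <- NA_character_
  if (!is.null(assembly)) {
    names(assembly) <- sub("\\s.*$", "", names(assembly))
    drop <- logical(nrow(loci))
    for (i in seq_len(nrow(loci))) {
      if (is.na(loci$start[i])) next
      ctg <- loci$contig_id[i]
      if (!(ctg %in% names(assembly))) next
      if (loci$end[i] > Biostrings::width(assembly[ctg]) ||
          loci$start[i] < 1L) {
        warning(sprintf("locus %s on %s exceeds contig length; skipped",
                        loci$marker[i], ctg), call. = FALSE)
        drop[i] <- TRUE
        next
      }
      s <- Biostrings::subseq(assembly[[ctg]], loci$start[i], loci$end[i])
      if (loci$strand[i] == "-") s <- Biostrings::reverseComplement(s)
      loci$sequence[i] <- as.character(s)
    }
    loci <- loci[!drop, , drop = FALSE]
  }
  rownames(loci) <- NULL

  markers <- lapply(stats::setNames(names(membership), names(membership)),
                    function(b) sort(unique(loci$marker[loci$bin_id == b])))
  list(markers = markers, loci = loci)
}

#' Write extracted marker loci as FASTA
#' @param loci data.frame from [ingest_markers()] (`loci` element).
#' @param path output FASTA path.
#' @export
write_marker_fasta <- function(loci, path) {
  keep <- !is.na(loci$sequence)
  seqs <- Biostrings::DNAStringSet(loci$sequence[keep])
  names(seqs) <- sprintf("%s|%s|%s:%d-%d(%s)", loci$bin_id[keep],
                         loci$marker[keep], loci$contig_id[keep],
                         loci$start[keep], loci$end[keep],
                         loci$strand[keep])
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
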