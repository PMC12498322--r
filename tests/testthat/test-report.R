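report_fixture <- function() {
  cls <- data.frame(
    contig_id = c("c1", "c2", "c3", "c4"),
    class_label = c("plastid", "plastid", "bacteria", "bacteria"),
    length_bp = c(90000L, 60000L, 4000L, 70000L),
    stringsAsFactors = FALSE)
  membership <- list(goodbin = c("c1", "c2", "c3"), badbin = "c4")
  list(cls = cls, membership = membership,
       bins = classify_bins(membership, cls))
}

test_that("the report carries one row per probable bin with joins", {
  fx <- report_fixture()
  expect_equal(sum(fx$bins$is_probable_plastid), 1)

  report <- build_report(fx$bins,
                         predictions = c(goodbin = 96.1),
                         taxonomy = c(goodbin = "root;Eukaryota;Trebouxia"),
                         markers = list(goodbin = c("rbcL")),
                         sample_id = "s1")
  expect_equal(nrow(report), 1)
  expect_equal(report$bin_id, "goodbin")
  expect_equal(report$completeness_percent, 96.1)
  expect_equal(report$span_bp, 154000)
  expect_equal(report$n_contigs, 3)
  expect_equal(report$n_plastid_contigs, 2)
  expect_equal(report$taxonomy, "root;Eukaryota;Trebouxia")
  expect_equal(report$markers, "rbcL")

  # absent joins leave fields empty, never fail
  bare <- build_report(fx$bins, predictions = c(goodbin = 50))
  expect_true(is.na(bare$taxonomy))
  expect_equal(bare$markers, "")
  noPred <- build_report(fx$bins)
  expect_true(is.na(noPred$completeness_percent))

  expect_warning(build_report(fx$bins, predictions = c(ghost = 10)),
                 "ghost")

  none <- fx$bins[fx$bins$bin_id == "badbin", ]
  empty <- build_report(none)
  expect_equal(nrow(empty), 0)
  expect_named(empty, names(report))

  # rerun on identical inputs is byte-identical on disk
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(report, f1)
  write_report(build_report(fx$bins,
                            predictions = c(goodbin = 96.1),
                            taxonomy = c(goodbin = "root;Eukaryota;Trebouxia"),
                            markers = list(goodbin = c("rbcL")),
                            sample_id = "s1"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("bin taxonomy is the span-weighted majority walk", {
  fx <- report_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig_id\tlineage",
               "c1\troot;Eukaryota;Chlorophyta;Trebouxia",
               "c2\troot;Eukaryota;Chlorophyta;Trebouxia",
               "c3\troot;Bacteria;Proteobacteria",
               "c4\troot;Bacteria;Cyanobacteria"), path)
  tax <- ingest_taxonomy(path, fx$membership, fx$cls)
  # c1+c2 (150 kb Trebouxia) dominate c3 (4 kb) in goodbin
  expect_equal(unname(tax["goodbin"]),
               "root;Eukaryota;Chlorophyta;Trebouxia")
  expect_equal(unname(tax["badbin"]), "root;Bacteria;Cyanobacteria")

  # 50/50 by span: deepest common ancestor only
  even <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig_id\tlineage",
               "d1\troot;Eukaryota;Chlorophyta",
               "d2\troot;Eukaryota;Fungi"), even)
  cls2 <- data.frame(contig_id = c("d1", "d2"),
                     class_label = c("plastid", "eukarya"),
                     length_bp = c(5000L, 5000L), stringsAsFactors = FALSE)
  tax2 <- ingest_taxonomy(even, list(b = c("d1", "d2")), cls2)
  expect_equal(unname(tax2["b"]), "root;Eukaryota")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig_id\tlineage", "d1\troot;Eukaryota", "d2\t;;"), bad)
  expect_warning(tax3 <- ingest_taxonomy(bad, list(b = c("d1", "d2")), cls2),
                 "unparseable")
  expect_equal(unname(tax3["b"]), "root;Eukaryota")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("contig_id\tlineage", empty)
  expect_length(ingest_taxonomy(empty, fx$membership, fx$cls), 0)
})

test_that("marker ingestion maps hits to bins and extracts stranded loci", {
  fx <- report_fixture()
  assembly <- Biostrings::DNAStringSet(c(
    c1 = "ATGCCGTTAACCGGTTAACCGGATCC",
    c4 = "TTTTACGTACGTACGTAAAA"))

  hmm <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# domtblout-style comment",
               "c1  -  rbcL_dom  rbcL  1e-50  400.0"), hmm)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("c1", "rrna_pred", "rRNA", "3", "10", "1e-10", "-",
                     ".", "Name=16S_rRNA;product=16S ribosomal RNA",
                     sep = "\t"),
               paste("c4", "rrna_pred", "rRNA", "2", "9", "1e-9", "+",
                     ".", "Name=23S_rRNA", sep = "\t"),
               paste("c4", "rrna_pred", "rRNA", "5", "99", "1e-9", "+",
                     ".", "Name=5S_rRNA", sep = "\t")), gff)

  expect_warning(
    mk <- ingest_markers(hmm, gff, fx$membership, assembly = assembly),
    "exceeds contig length")
  expect_setequal(mk$markers$goodbin, c("rbcL", "rRNA_16S-like"))
  expect_equal(mk$markers$badbin, "rRNA_23S-like")

  loci <- mk$loci
  rrna16 <- loci[loci$marker == "rRNA_16S-like", ]
  # GFF3 1-based inclusive: length end - start + 1, minus strand revcomp
  expect_equal(nchar(rrna16$sequence), 10 - 3 + 1)
  fwd <- substr("ATGCCGTTAACCGGTTAACCGGATCC", 3, 10)
  expect_equal(rrna16$sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(fwd))))
  rrna23 <- loci[loci$marker == "rRNA_23S-like", ]
  expect_equal(rrna23$sequence, substr("TTTTACGTACGTACGTAAAA", 2, 9))

  fasta <- withr::local_tempfile(fileext = ".fasta")
  write_marker_fasta(loci, fasta)
  seqs <- Biostrings::readDNAStringSet(fasta)
  expect_equal(unname(Biostrings::width(seqs)),
               nchar(loci$sequence[!is.na(loci$sequence)]))

  none <- ingest_markers(NULL, NULL, fx$membership)
  expect_equal(none$markers$goodbin, character(0))
  expect_equal(nrow(none$loci), 0)
})
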