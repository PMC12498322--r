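Package: plastidr
Title: Identification and Completeness Estimation of Plastid Bins from
    Metagenomic Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies probable plastid bins among metagenomic assembly
    bins from contig-level classifications, and estimates plastid genome
    completeness from KEGG module coverage. Plastid genomes lack the
    single-copy marker genes used by standard bin quality tools, so
    completeness is instead predicted by regression models (Ada boosting,
    gradient boosting, random forest) trained on module-coverage feature
    vectors of reference annotation profiles subsampled across a
    completeness grid. Includes a KEGG module DEFINITION parser and
    evaluator, an annotation subsampling simulator, bin classification by
    plastid nucleotide content, summary reporting with taxonomy and
    marker-locus integration, and fully synthetic fixture generators so
    the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
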