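test_that("DEFINITION parsing recovers step structure and round-trips", {
  m1 <- parse_module_definition("M_toy1", "K00001 K00002")
  expect_s3_class(m1, "module_definition")
  expect_equal(n_steps(m1), 2)
  expect_true(all(vapply(m1$steps, function(s) s$kind == "leaf",
                         logical(1))))

  m2 <- parse_module_definition("M_toy2", "(K00001,K00003) K00002")
  expect_equal(n_steps(m2), 2)
  expect_equal(m2$steps[[1]]$op, "ANY")
  expect_equal(m2$steps[[2]]$kind, "leaf")

  m3 <- parse_module_definition("M_toy3", "K00001+K00002")
  expect_equal(n_steps(m3), 1)
  expect_equal(m3$steps[[1]]$op, "ALL")

  # canonical serialization is a fixed point under reparsing
  for (row in seq_len(nrow(bundled_catalog_table()))) {
    tab <- bundled_catalog_table()
    m <- parse_module_definition(tab$module_id[row],
                                 tab$definition_text[row])
    txt <- format(m)
    m2 <- parse_module_definition(m$module_id, txt)
    expect_equal(format(m2), txt, info = tab$module_id[row])
    expect_equal(n_steps(m2), n_steps(m), info = tab$module_id[row])
  }
})

test_that("malformed definitions fail with positioned parse errors", {
  expect_error(parse_module_definition("Mx", ""), "empty")
  expect_error(parse_module_definition("Mx", "(K00001 K00002"),
               "unbalanced")
  expect_error(parse_module_definition("Mx", "K00001) K00002"),
               "position")
  expect_error(parse_module_definition("Mx", "K1 K00002"), "K-number")
})

test_that("module completeness follows the satisfied-steps fraction", {
  m1 <- parse_module_definition("M_toy1", "K00001 K00002")
  m2 <- parse_module_definition("M_toy2", "(K00001,K00003) K00002")
  expect_equal(module_completeness(m1, character(0)), 0)
  expect_equal(module_completeness(m1, c("K00001", "K00002")), 1)
  expect_equal(module_completeness(m1, "K00001"), 0.5)
  expect_equal(module_completeness(m2, c("K00003", "K00002")), 1)
})

test_that("completeness matches the truth-table oracle and is monotone", {
  tab <- bundled_catalog_table()
  set.seed(17)
  for (row in seq_len(nrow(tab))) {
    kos <- definition_kos(tab$definition_text[row])
    m <- parse_module_definition(tab$module_id[row],
                                 tab$definition_text[row])
    # random subsets: oracle agreement and superset monotonicity
    for (rep in 1:10) {
      a <- kos[runif(length(kos)) < 0.5]
      b <- union(a, kos[runif(length(kos)) < 0.3])
      expect_equal(module_completeness(m, a),
                   oracle_module_completeness(tab$definition_text[row], a),
                   info = tab$module_id[row])
      expect_gte(module_completeness(m, b), module_completeness(m, a))
    }
  }
})

test_that("optional components never affect the score", {
  tab <- bundled_catalog_table()
  with_opt <- tab[grepl("-", tab$definition_text, fixed = TRUE), ]
  expect_gte(nrow(with_opt), 3)
  set.seed(31)
  for (row in seq_len(nrow(with_opt))) {
    m <- parse_module_definition(with_opt$module_id[row],
                                 with_opt$definition_text[row])
    expect_gt(length(m$optional_leaves), 0)
    for (rep in 1:5) {
      kos <- definition_kos(with_opt$definition_text[row])
      s <- kos[runif(length(kos)) < 0.6]
      expect_equal(module_completeness(m, s),
                   module_completeness(m, setdiff(s, m$optional_leaves)))
    }
  }
})

test_that("coverage vectors follow catalog order and binary mode", {
  catalog <- toy_catalog()
  empty <- ko_profile("none")
  cv0 <- coverage_vector(empty, catalog)
  expect_equal(unname(cv0$values), c(0, 0, 0))
  expect_equal(cv0$module_order, c("M_toy1", "M_toy2", "M_toy3"))

  all_kos <- unique(unlist(lapply(catalog, `[[`, "kos")))
  full <- ko_profile("full", stats::setNames(rep(1L, length(all_kos)),
                                             all_kos))
  expect_equal(unname(coverage_vector(full, catalog)$values), c(1, 1, 1))

  p <- ko_profile("g1", c(K00001 = 3L))
  cv <- coverage_vector(p, catalog[c(1, 3)])
  expect_equal(unname(cv$values), c(0.5, 0))
  # counts beyond 1 do not raise completeness
  p1 <- ko_profile("g1", c(K00001 = 1L))
  expect_equal(coverage_vector(p, catalog)$values,
               coverage_vector(p1, catalog)$values)

  bin <- coverage_vector(p, catalog[c(1, 3)], mode = "binary")
  expect_equal(unname(bin$values), c(0, 0))

  expect_error(coverage_vector(p, c(catalog, catalog[1])), "duplicate")
  expect_error(coverage_vector(p, list()), "empty")
})

test_that("annotation tables load, aggregate and partition by genome", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tgene_id\tko_id",
               "g1\tgene1\tK00001",
               "g1\tgene2\tK00001",
               "g1\tgene3\t",
               "g2\tgene1\tK00002"), path)
  profs <- load_ko_annotations(path)
  expect_named(profs, c("g1", "g2"))
  expect_equal(profs$g1$counts, c(K00001 = 2L))
  expect_equal(profs$g2$total, 1L)

  empty_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tgene_id\tko_id", "g1\tgene1\t", "g1\tgene2\t"),
             empty_path)
  p <- load_ko_annotations(empty_path)$g1
  expect_equal(p$total, 0L)
  expect_length(p$counts, 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome\tko", "g1\tK00001"), bad)
  expect_error(load_ko_annotations(bad), "genome_id")
})

test_that("annotation round trip preserves profiles and row order is moot", {
  catalog <- bundled_module_catalog()
  refs <- synthesize_reference_profiles(2, "plastid_like", catalog,
                                        seed = 5)
  profs <- lapply(refs, `[[`, "profile")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ko_annotations(profs, path)
  back <- load_ko_annotations(path)
  expect_equal(back[[profs[[1]]$genome_id]]$counts, profs[[1]]$counts)

  # permuting table rows leaves every coverage vector unchanged
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  perm <- withr::local_tempfile(fileext = ".tsv")
  set.seed(9)
  utils::write.table(df[sample(nrow(df)), ], perm, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  back2 <- load_ko_annotations(perm)
  for (p in profs) {
    expect_equal(coverage_vector(back2[[p$genome_id]], catalog)$values,
                 coverage_vector(p, catalog)$values)
  }
})
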