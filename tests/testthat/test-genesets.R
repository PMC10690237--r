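test_that("membership counts enumerate set membership exactly", {
  cl <- gene_set_collection(list(gene_set("A", c("g1", "g2")),
                                 gene_set("B", "g2")))
  mc <- membership_counts(cl)
  expect_equal(mc$n_sets[match(c("g1", "g2"), mc$gene)], c(1L, 2L))

  disjoint <- gene_set_collection(lapply(1:9, function(i)
    gene_set(paste0("s", i), paste0("d", i, "_", 1:3))))
  expect_true(all(membership_counts(disjoint)$n_sets == 1L))

  mc9 <- membership_counts(toy_collection())
  expect_equal(mc9$n_sets[mc9$gene == "FIVE1"], 5L)
  # counts partition the universe
  expect_equal(sum(table(mc9$n_sets)), length(toy_collection()$universe))
  expect_error(gene_set_collection(list()), "at least one")
})

test_that("consensus curation applies the membership threshold and majority direction", {
  cl <- toy_collection()
  cons <- curate_consensus(cl, min_sets = 5)
  expect_setequal(cons$genes, c("CORE1", "CORE2", "FIVE1"))
  expect_false("FOUR1" %in% cons$genes)          # 4 of 9 < 5
  # CORE1 is inhibit in 5 sets, induce in 4 -> majority inhibit;
  # CORE2 induce in 8 sets; FIVE1 has no direction anywhere
  expect_equal(unname(cons$direction["CORE1"]), "inhibit")
  expect_equal(unname(cons$direction["CORE2"]), "induce")
  expect_false("FIVE1" %in% names(cons$direction))

  # monotone in min_sets
  for (k in 2:9) {
    expect_true(all(curate_consensus(cl, k)$genes %in%
                      curate_consensus(cl, k - 1)$genes))
  }
  expect_error(curate_consensus(cl, 10), "min_sets")
})

test_that("direction ties across sets resolve to unknown", {
  sets <- lapply(1:4, function(i)
    gene_set(paste0("s", i), "g",
             direction = c(g = if (i <= 2) "induce" else "inhibit")))
  cons <- curate_consensus(gene_set_collection(sets), min_sets = 2)
  expect_equal(unname(cons$direction["g"]), "unknown")
})

test_that("literature-record filtering applies both retention clauses", {
  rec <- tibble::tibble(
    gene = c("a", "b", "c", "d", "e"),
    n_publications = c(15L, 4L, 4L, 3L, 20L),
    n_induce = c(7L, 3L, 2L, 3L, 0L),
    n_inhibit = c(8L, 1L, 2L, 0L, 0L))
  gs <- filter_senequest(rec)
  expect_setequal(gs$genes, c("a", "b", "e"))    # c: 0.5 < 0.7; d: too few pubs
  expect_equal(unname(gs$direction["b"]), "induce")   # 3/4 = 0.75 >= 0.7
  expect_false("a" %in% names(gs$direction))     # first clause only
  # exactly 70% agreement is retained (>= convention)
  g70 <- filter_senequest(tibble::tibble(gene = "x", n_publications = 10L,
                                         n_induce = 7L, n_inhibit = 3L))
  expect_equal(g70$genes, "x")
  # zero directional reports fall back to the publication clause
  expect_equal(filter_senequest(tibble::tibble(
    gene = "y", n_publications = 14L, n_induce = 0L,
    n_inhibit = 0L))$genes, character(0))
})

test_that("Jaccard index follows the set formula and its symmetry", {
  a <- gene_set("a", c("x", "y")); b <- gene_set("b", c("y", "z"))
  expect_equal(jaccard_index(a, b), 1 / 3)
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(a, gene_set("c", c("p", "q"))), 0)
  expect_error(jaccard_index(gene_set("e", character(0)),
                             gene_set("f", character(0))), "undefined")
  set.seed(7)
  for (i in 1:20) {
    g1 <- gene_set("g1", sample(letters, sample(3:10, 1)))
    g2 <- gene_set("g2", sample(letters, sample(3:10, 1)))
    expect_equal(jaccard_index(g1, g2), jaccard_index(g2, g1))
    expect_equal(jaccard_index(g1, g2) == 1, setequal(g1$genes, g2$genes))
  }
  jm <- jaccard_matrix(toy_collection())
  expect_equal(jm, t(jm))
  expect_equal(unname(diag(jm)), rep(1, 9))
})

test_that("GMT and gene TSV round-trips preserve sets; symbols can be remapped", {
  cl <- toy_collection()
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(cl, path)
  back <- read_gmt(path)
  expect_equal(names(back$sets), names(cl$sets))
  for (nm in names(cl$sets))
    expect_equal(back$sets[[nm]]$genes, cl$sets[[nm]]$genes)

  # case normalization and symbol mapping
  gs <- gene_set("m", c("Cdkn1a", "Trp53"), uppercase = TRUE)
  expect_setequal(gs$genes, c("CDKN1A", "TRP53"))
  mapped <- map_symbols(gs, data.frame(from = c("TRP53"), to = c("TP53")))
  expect_equal(mapped$genes, "TP53")
})

test_that("the bundled default signature is a 39-gene directed set", {
  sig <- default_signature()
  expect_s3_class(sig, "gene_set")
  expect_length(sig$genes, 39)
  expect_true(all(c("CDKN1A", "CDKN2A") %in% sig$genes))
  expect_setequal(unique(sig$direction), c("induce", "inhibit"))
})
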