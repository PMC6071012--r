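test_that("edge lists are parsed, trimmed and deduplicated", {
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("m1\td1", "m1\td2", "m2\td1", "m1\td1"), f)
  es <- suppressMessages(read_edge_list(f, "miRNA", "disease"))
  expect_s3_class(es, "edge_set")
  expect_equal(length(es), 3L)  # duplicate collapsed
  expect_message(read_edge_list(f, "miRNA", "disease"), "1 duplicate")

  writeLines(c("# comment", "miRNA\tdisease"), f)  # header only
  expect_equal(length(read_edge_list(f, "miRNA", "disease")), 0L)

  writeLines(c("  m1 \t d1  "), f)  # whitespace trimmed, case preserved
  es <- read_edge_list(f, "miRNA", "disease")
  expect_identical(es$edges$left, "m1")
  expect_identical(es$edges$right, "d1")

  writeLines(c("m1\td1", "m1\t\t"), f)
  expect_error(read_edge_list(f, "miRNA", "disease"), "line 2.*empty")

  writeLines(c("m1\td1", "lonely"), f)
  expect_error(read_edge_list(f, "miRNA", "disease"), "line 2.*fewer than 2")
})

test_that("edge sets round-trip through write_edge_list/read_edge_list", {
  for (seed in 1:5) {
    rn <- rand_net(seed, gn2 = FALSE)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_edge_list(rn$net$mln, f)
    back <- read_edge_list(f, "miRNA", "lncRNA")
    expect_identical(back$edges[order(back$edges$left, back$edges$right), ],
                     rn$net$mln$edges[order(rn$net$mln$edges$left,
                                            rn$net$mln$edges$right), ],
                     ignore_attr = TRUE)
  }
})

test_that("GN1 assembly derives sorted union registries", {
  net <- toy_gn1()
  expect_identical(net$mode, "GN1")
  expect_identical(net$lncRNAs, c("l1", "l2"))
  expect_identical(net$diseases, c("d1", "d2"))
  expect_identical(net$miRNAs, "m1")
  expect_identical(net$genes, character())
  expect_equal(sum(net$Y), 1)  # |Mc| = 1

  # minimal network with no known associations
  tiny <- assemble_gn1(edge_set("m1", "d1", "miRNA", "disease"),
                       edge_set("m1", "l1", "miRNA", "lncRNA"),
                       edge_set(left_kind = "lncRNA", right_kind = "disease"))
  expect_equal(c(length(tiny$lncRNAs), length(tiny$diseases),
                 length(tiny$miRNAs), sum(tiny$Y)), c(1, 1, 1, 0))

  # an lncRNA only present in LDN still enters the registry
  extra <- assemble_gn1(edge_set("m1", "d1", "miRNA", "disease"),
                        edge_set("m1", "l1", "miRNA", "lncRNA"),
                        edge_set("lX", "d1", "lncRNA", "disease"))
  expect_true("lX" %in% extra$lncRNAs)

  expect_error(assemble_gn1(edge_set("d1", "m1", "disease", "miRNA"),
                            edge_set("m1", "l1", "miRNA", "lncRNA"),
                            edge_set("l1", "d1", "lncRNA", "disease")),
               "kinds")
})

test_that("GN2 assembly preserves GN1 content and grows registries", {
  net <- toy_gn2()
  expect_identical(net$mode, "GN2")
  expect_identical(net$genes, "g1")
  total_edges <- nrow(net$mdn$edges) + nrow(net$mln$edges) +
    nrow(net$ldn$edges) + nrow(net$gdn$edges) + nrow(net$gln$edges) +
    nrow(net$gmn$edges)
  expect_equal(total_edges, 8)
  expect_identical(net$mdn$edges, toy_gn1()$mdn$edges)

  # a disease seen only in GDN enlarges the disease registry
  wide <- assemble_gn2(toy_gn1(),
                       gdn = edge_set("g1", "dNew", "gene", "disease"),
                       gln = edge_set("g1", "l1", "gene", "lncRNA"),
                       gmn = edge_set(left_kind = "gene", right_kind = "miRNA"))
  expect_true("dNew" %in% wide$diseases)
  expect_gt(length(wide$diseases), length(toy_gn1()$diseases))

  expect_error(assemble_gn2(toy_gn1(),
                            gdn = edge_set("g1", "d1", "disease", "gene"),
                            gln = edge_set("g1", "l1", "gene", "lncRNA"),
                            gmn = edge_set("g1", "m1", "gene", "miRNA")),
               "kinds")
})

test_that("assembly is deterministic", {
  a <- rand_net(11)$net
  b <- rand_net(11)$net
  expect_identical(a[c("lncRNAs", "diseases", "miRNAs", "genes")],
                   b[c("lncRNAs", "diseases", "miRNAs", "genes")])
  expect_identical(a$Y, b$Y)
})

test_that("MeSH tables are parsed with set semantics", {
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("dA\tC04", "dB\tC04.123"), f)
  onto <- read_mesh_table(f)
  expect_identical(onto$tree_numbers$dA, "C04")
  expect_identical(onto$tree_numbers$dB, "C04.123")

  writeLines(c("dA\tC04", "dA\tC06.1", "dA\tC04"), f)
  onto <- read_mesh_table(f)
  expect_identical(onto$tree_numbers$dA, c("C04", "C06.1"))

  writeLines(character(), f)
  expect_equal(length(read_mesh_table(f)$tree_numbers), 0L)

  writeLines("dA\tC04..123", f)  # empty segment
  expect_error(read_mesh_table(f), "malformed")
})

test_that("write_scores emits ranked, tie-broken TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")

  m <- matrix(c(0.9, 0.1), 2, 1, dimnames = list(c("l1", "l2"), "d1"))
  write_scores(m, f)
  tab <- read.delim(f)
  expect_identical(names(tab), c("lncRNA", "disease", "score", "rank"))
  expect_equal(tab$rank, 1:2)
  expect_identical(tab$lncRNA, c("l1", "l2"))

  # lexicographic tie-break on equal scores
  m <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("l2", "l1"), "d1"))
  write_scores(m, f)
  expect_identical(read.delim(f)$lncRNA, c("l1", "l2"))

  m <- matrix(1:4 / 10, 2, 2, dimnames = list(c("l1", "l2"), c("d1", "d2")))
  write_scores(m, f)
  expect_equal(nrow(read.delim(f)), 4L)  # n x r rows
})
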