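test_that("prior odds follow the known-association count", {
  p <- prior_odds(toy_gn1())
  expect_equal(p$p1, 0.25)
  expect_equal(p$phi, 1 / 3)

  # no knowledge: p1 = 0, phi = 0
  empty <- assemble_gn1(edge_set("m1", "d1", "miRNA", "disease"),
                        edge_set("m1", "l1", "miRNA", "lncRNA"),
                        edge_set(left_kind = "lncRNA",
                                 right_kind = "disease"))
  expect_equal(prior_odds(empty)$phi, 0)

  # curated-corpus scale: 407 known pairs over 1089 x 373 registries
  expect_equal(407 / (1089 * 373), 407 / 406197)
  big <- toy_gn1()
  big$lncRNAs <- sprintf("l%04d", 1:1089)
  big$diseases <- sprintf("d%03d", 1:373)
  big$Y <- matrix(0, 1089, 373,
                  dimnames = list(big$lncRNAs, big$diseases))
  big$Y[seq_len(407)] <- 1
  expect_equal(prior_odds(big)$p1, 407 / 406197)
})

test_that("common neighbors partition into pairs and singletons", {
  fs <- common_neighbors(toy_gn1(), "l2", "d2")
  expect_length(fs$features, 1L)
  expect_identical(fs$features[[1L]],
                   feature("miRNA", "m1"))

  # interacting miRNA-gene common neighbors fuse into one pair feature,
  # leaving the non-interacting nodes as singletons
  fs <- common_neighbors(toy_pair_motif(), "l2", "d3")
  expect_setequal(vapply(fs$features, format, ""),
                  c("pair(m3,g4)", "miRNA(m1)", "gene(g1)"))

  # nodes covered by a pair never reappear as singletons
  nodes_in_pairs <- unlist(lapply(fs$features, function(f)
    if (f$kind == "pair") f$members))
  singles <- unlist(lapply(fs$features, function(f)
    if (f$kind != "pair") f$members))
  expect_length(intersect(nodes_in_pairs, singles), 0L)

  # no shared neighbors -> empty feature set
  isolated <- assemble_gn1(edge_set("m1", "d1", "miRNA", "disease"),
                           edge_set("m1", "l1", "miRNA", "lncRNA"),
                           edge_set("l2", "d1", "lncRNA", "disease"))
  expect_length(common_neighbors(isolated, "l2", "d1")$features, 0L)

  expect_error(common_neighbors(toy_gn1(), "nope", "d1"), "unknown lncRNA")
})

test_that("feature counts match exhaustive enumeration on the toys", {
  ct <- feature_counts(toy_gn1(), feature("miRNA", "m1"))
  expect_equal(unclass(ct)[c("n_l", "n_d", "n_plus", "n_minus")],
               list(n_l = 2, n_d = 2, n_plus = 1, n_minus = 3))

  ct <- feature_counts(toy_gn2(), feature("pair", c("m1", "g1")))
  expect_equal(unclass(ct)[c("n_l", "n_d", "n_plus", "n_minus")],
               list(n_l = 1, n_d = 1, n_plus = 0, n_minus = 1))

  # a feature adjacent to no lncRNA has all-zero counts
  net <- assemble_gn1(edge_set("mX", "d1", "miRNA", "disease"),
                      edge_set("m1", "l1", "miRNA", "lncRNA"),
                      edge_set("l1", "d1", "lncRNA", "disease"))
  ct <- feature_counts(net, feature("miRNA", "mX"))
  expect_equal(c(ct$n_l, ct$n_plus, ct$n_minus), c(0, 0, 0))
})

test_that("worked toys score exactly 0.5 at (l2, d2)", {
  expect_identical(score_pair(toy_gn1(), "l2", "d2"), 0.5)
  expect_identical(score_pair(toy_gn2(), "l2", "d2"), 0.5)

  # empty common-neighbor set: score reduces to the prior odds
  isolated <- assemble_gn1(edge_set("m1", "d1", "miRNA", "disease"),
                           edge_set("m1", "l1", "miRNA", "lncRNA"),
                           edge_set("l2", "d1", "lncRNA", "disease"))
  phi <- prior_odds(isolated)$phi
  expect_equal(score_pair(isolated, "l2", "d1"), phi)

  # no known associations anywhere: score 0 (documented limit)
  empty <- assemble_gn1(edge_set("m1", "d1", "miRNA", "disease"),
                        edge_set("m1", "l1", "miRNA", "lncRNA"),
                        edge_set(left_kind = "lncRNA",
                                 right_kind = "disease"))
  expect_equal(score_pair(empty, "l1", "d1"), 0)
  expect_true(all(score_all(empty) == 0))
})

test_that("GN2 with empty gene layers degenerates to GN1 scores", {
  gn1 <- rand_net(21, gn2 = FALSE)$net
  gn2 <- assemble_gn2(gn1,
                      edge_set(left_kind = "gene", right_kind = "disease"),
                      edge_set(left_kind = "gene", right_kind = "lncRNA"),
                      edge_set(left_kind = "gene", right_kind = "miRNA"))
  expect_equal(score_all(gn2), score_all(gn1), ignore_attr = TRUE)
})

test_that("vectorized score_all agrees with per-pair score_pair", {
  for (seed in 1:12) {
    rn <- rand_net(seed, gn2 = seed %% 2 == 0)
    s <- score_all(rn$net)
    prior <- prior_odds(rn$net)
    for (l in rn$net$lncRNAs) for (d in rn$net$diseases)
      expect_equal(s[l, d], score_pair(rn$net, l, d, prior = prior),
                   tolerance = 1e-12)
  }
})

test_that("held-out edges are removed from every count", {
  net <- toy_gn1()
  held <- c("l1", "d1")
  expect_equal(prior_odds(net, excluded = held)$phi, 0)
  ct <- feature_counts(net, feature("miRNA", "m1"), excluded = held)
  expect_equal(ct$n_plus, 0)
  expect_equal(ct$n_minus, 4)
})

test_that("a single-feature score is (N+ + 1)/(N- + 1), independent of the prior", {
  for (seed in 1:6) {
    rn <- rand_net(seed, gn2 = FALSE)
    prior <- prior_odds(rn$net)
    for (l in rn$net$lncRNAs) for (d in rn$net$diseases) {
      fs <- common_neighbors(rn$net, l, d)
      if (length(fs$features) != 1L) next
      ct <- feature_counts(rn$net, fs$features[[1L]])
      expect_equal(score_pair(rn$net, l, d),
                   (ct$n_plus + 1) / (ct$n_minus + 1), tolerance = 1e-12)
    }
  }
})

test_that("shifting one association from unknown to known raises the score", {
  # with all else fixed, (N+ + 1)/(N- + 1) is strictly increasing in N+
  n_plus <- 0:5; n_minus <- 8 - n_plus
  ratios <- (n_plus + 1) / (n_minus + 1)
  expect_true(all(diff(ratios) > 0))

  # and on a network: adding a known association carried by the feature
  # increases the score of other pairs sharing that feature
  base <- toy_gn1()
  more <- assemble_gn1(base$mdn, base$mln,
                       edge_set(c("l1", "l2"), c("d1", "d1"),
                                "lncRNA", "disease"))
  f <- feature("miRNA", "m1")
  expect_gt(feature_counts(more, f)$n_plus, feature_counts(base, f)$n_plus)
})

test_that("log normalization preserves ranking and maps zeros below", {
  expect_equal(as.vector(normalize_scores(matrix(0.5), lambda = 1)),
               log(0.5))

  rn <- rand_net(31)
  raw <- score_all(rn$net)
  auto <- normalize_scores(raw)
  expect_true(all(auto >= -1 & auto <= 1))
  expect_equal(attr(auto, "lambda"), max(abs(log(raw[raw > 0]))))

  n1 <- normalize_scores(raw, lambda = 1)
  n7 <- normalize_scores(raw, lambda = 7.5)
  expect_identical(order(n1, rownames(raw)[row(raw)], colnames(raw)[col(raw)]),
                   order(n7, rownames(raw)[row(raw)], colnames(raw)[col(raw)]))
  expect_identical(rank(as.vector(n1)), rank(as.vector(n7)))
  expect_identical(rank(as.vector(n1)), rank(as.vector(auto)))

  # zero raw scores are mapped strictly below every finite score
  z <- normalize_scores(matrix(c(0, 0.5, 2, 0), 2, 2), lambda = 1)
  expect_true(all(z[c(1, 4)] < min(z[c(2, 3)])))

  expect_error(normalize_scores(raw, lambda = -1), "positive")
  expect_error(normalize_scores(raw, lambda = 0), "positive")
})
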