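# Shared fixtures: random small networks (raw edge frames + assembled
# hetnet) and the worked toy with two interacting common neighbors.

# random bipartite edge frame over name pools
rand_edges <- function(a_pool, b_pool, p, a_name, b_name) {
  grid <- expand.grid(a = a_pool, b = b_pool, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
  stats::setNames(grid, c(a_name, b_name))
}

# draws a random small network; returns both the raw edge frames (for the
# oracle) and the assembled hetnet.  Guarantees at least one known
# association so the prior is defined.
rand_net <- function(seed, gn2 = TRUE, max_l = 6, max_d = 6, max_m = 5,
                     max_g = 4) {
  set.seed(seed)
  nl <- sample(2:max_l, 1); nd <- sample(2:max_d, 1)
  nm <- sample(1:max_m, 1); ng <- if (gn2) sample(1:max_g, 1) else 0
  ls <- sprintf("l%d", 1:nl); ds <- sprintf("d%d", 1:nd)
  ms <- sprintf("m%d", 1:nm); gs <- if (ng) sprintf("g%d", 1:ng)
  p <- stats::runif(1, 0.2, 0.6)
  edges <- list(mdn = rand_edges(ms, ds, p, "m", "d"),
                mln = rand_edges(ms, ls, p, "m", "l"),
                ldn = rand_edges(ls, ds, stats::runif(1, 0.1, 0.4), "l", "d"))
  if (!nrow(edges$ldn))
    edges$ldn <- data.frame(l = sample(ls, 1), d = sample(ds, 1))
  if (gn2) {
    edges$gdn <- rand_edges(gs, ds, p, "g", "d")
    edges$gln <- rand_edges(gs, ls, p, "g", "l")
    edges$gmn <- rand_edges(gs, ms, p, "g", "m")
    # an empty gene layer degenerates to GN1; keep at least one gene edge
    if (!nrow(edges$gdn) && !nrow(edges$gln) && !nrow(edges$gmn))
      edges$gdn <- data.frame(g = sample(gs, 1), d = sample(ds, 1))
  }
  gn1 <- assemble_gn1(edge_set(edges$mdn$m, edges$mdn$d, "miRNA", "disease"),
                      edge_set(edges$mln$m, edges$mln$l, "miRNA", "lncRNA"),
                      edge_set(edges$ldn$l, edges$ldn$d, "lncRNA", "disease"))
  net <- if (gn2)
    assemble_gn2(gn1,
                 edge_set(edges$gdn$g, edges$gdn$d, "gene", "disease"),
                 edge_set(edges$gln$g, edges$gln$l, "gene", "lncRNA"),
                 edge_set(edges$gmn$g, edges$gmn$m, "gene", "miRNA"))
  else gn1
  list(edges = edges, net = net)
}

# quadruple-network motif with four common neighbors of (l2, d3), two of
# which (m3, g4) interact: the expected feature partition is
# {pair(m3, g4), m1, g1}
toy_pair_motif <- function() {
  assemble_gn2(
    assemble_gn1(
      mdn = edge_set(c("m1", "m3"), c("d3", "d3"), "miRNA", "disease"),
      mln = edge_set(c("m1", "m3"), c("l2", "l2"), "miRNA", "lncRNA"),
      ldn = edge_set("l2", "d3", "lncRNA", "disease")),
    gdn = edge_set(c("g1", "g4"), c("d3", "d3"), "gene", "disease"),
    gln = edge_set(c("g1", "g4"), c("l2", "l2"), "gene", "lncRNA"),
    gmn = edge_set("g4", "m3", "gene", "miRNA"))
}

# tripartite toy for evaluation tests: two disjoint miRNA "channels", so
# each held-out association outranks every candidate negative
toy_separable <- function() {
  assemble_gn1(
    mdn = edge_set(c("m1", "m2"), c("d1", "d2"), "miRNA", "disease"),
    mln = edge_set(c("m1", "m2"), c("l1", "l2"), "miRNA", "lncRNA"),
    ldn = edge_set(c("l1", "l2"), c("d1", "d2"), "lncRNA", "disease"))
}

# no lncRNA-disease pair has any common neighbor (the miRNAs linking
# lncRNAs and those linking diseases are disjoint), so every score equals
# the prior odds and every LOOCV round is all ties
toy_flat <- function() {
  assemble_gn1(
    mdn = edge_set(c("m1", "m1"), c("d1", "d2"), "miRNA", "disease"),
    mln = edge_set(c("m2", "m2"), c("l1", "l2"), "miRNA", "lncRNA"),
    ldn = edge_set(c("l1", "l2"), c("d1", "d2"), "lncRNA", "disease"))
}
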