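# Brute-force scoring oracle, kept deliberately independent of the package
# internals: it works from raw edge data frames and computes every count by
# exhaustive enumeration of node and pair lists.  Used to cross-check
# score_pair/score_all.

# edges: list with data frames mdn(m,d), mln(m,l), ldn(l,d) and optionally
# gdn(g,d), gln(g,l), gmn(g,m)
oracle_registries <- function(edges) {
  list(
    l = sort(unique(c(edges$mln$l, edges$ldn$l,
                      if (!is.null(edges$gln)) edges$gln$l))),
    d = sort(unique(c(edges$mdn$d, edges$ldn$d,
                      if (!is.null(edges$gdn)) edges$gdn$d))),
    m = sort(unique(c(edges$mdn$m, edges$mln$m,
                      if (!is.null(edges$gmn)) edges$gmn$m))),
    g = sort(unique(c(edges$gdn$g, edges$gln$g, edges$gmn$g))))
}

oracle_has <- function(df, a, b) {
  if (is.null(df) || !nrow(df)) return(FALSE)
  any(df[[1L]] == a & df[[2L]] == b)
}

# all common-neighbor features of (l, d) as a list of
# list(kind=, m=, g=) entries, pair rule included
oracle_features <- function(edges, l, d, gn2) {
  cm <- Filter(function(m) oracle_has(edges$mln, m, l) &&
                 oracle_has(edges$mdn, m, d),
               sort(unique(c(edges$mdn$m, edges$mln$m,
                             if (gn2) edges$gmn$m))))
  feats <- list()
  if (!gn2) {
    for (m in cm) feats[[length(feats) + 1L]] <- list(kind = "m", m = m)
    return(feats)
  }
  cg <- Filter(function(g) oracle_has(edges$gln, g, l) &&
                 oracle_has(edges$gdn, g, d),
               sort(unique(c(edges$gdn$g, edges$gln$g, edges$gmn$g))))
  paired_m <- character(); paired_g <- character()
  for (m in cm) for (g in cg) if (oracle_has(edges$gmn, g, m)) {
    feats[[length(feats) + 1L]] <- list(kind = "pair", m = m, g = g)
    paired_m <- union(paired_m, m); paired_g <- union(paired_g, g)
  }
  for (m in setdiff(cm, paired_m))
    feats[[length(feats) + 1L]] <- list(kind = "m", m = m)
  for (g in setdiff(cg, paired_g))
    feats[[length(feats) + 1L]] <- list(kind = "g", g = g)
  feats
}

# is `feat` adjacent to lncRNA l / disease d?
oracle_adj_l <- function(edges, feat, l) {
  switch(feat$kind,
         m = oracle_has(edges$mln, feat$m, l),
         g = oracle_has(edges$gln, feat$g, l),
         pair = oracle_has(edges$mln, feat$m, l) &&
           oracle_has(edges$gln, feat$g, l))
}
oracle_adj_d <- function(edges, feat, d) {
  switch(feat$kind,
         m = oracle_has(edges$mdn, feat$m, d),
         g = oracle_has(edges$gdn, feat$g, d),
         pair = oracle_has(edges$mdn, feat$m, d) &&
           oracle_has(edges$gdn, feat$g, d))
}

# N+, N-, Nl, Nd of one feature by full enumeration of the l x d grid
oracle_counts <- function(edges, feat, known) {
  reg <- oracle_registries(edges)
  n_l <- 0L; n_d <- 0L; n_plus <- 0L; n_minus <- 0L
  for (l in reg$l) if (oracle_adj_l(edges, feat, l)) n_l <- n_l + 1L
  for (d in reg$d) if (oracle_adj_d(edges, feat, d)) n_d <- n_d + 1L
  for (l in reg$l) for (d in reg$d) {
    if (oracle_adj_l(edges, feat, l) && oracle_adj_d(edges, feat, d)) {
      if (oracle_has(known, l, d)) n_plus <- n_plus + 1L
      else n_minus <- n_minus + 1L
    }
  }
  list(n_plus = n_plus, n_minus = n_minus, n_l = n_l, n_d = n_d)
}

# raw posterior-odds score of (l, d), optionally with one known edge
# excluded; gn2 switches the pair-feature rule on
oracle_score <- function(edges, l, d, gn2 = !is.null(edges$gmn),
                         excluded = NULL) {
  reg <- oracle_registries(edges)
  known <- edges$ldn
  if (!is.null(excluded))
    known <- known[!(known$l == excluded[[1L]] & known$d == excluded[[2L]]), ,
                   drop = FALSE]
  mc <- nrow(known)
  p1 <- mc / (length(reg$l) * length(reg$d))
  if (p1 == 0) return(0)
  phi <- p1 / (1 - p1)
  s <- phi
  for (feat in oracle_features(edges, l, d, gn2)) {
    ct <- oracle_counts(edges, feat, known)
    s <- s * (1 / phi) * (ct$n_plus + 1) / (ct$n_minus + 1)
  }
  s
}

# exhaustive pairwise-counting AUC oracle
oracle_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
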