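## Naive Bayesian common-neighbor scoring.
##
## Each candidate lncRNA-disease pair is scored by its posterior odds of
## association given the pair's common neighbors in the heterogeneous
## network.  With prior odds phi = p1/(1-p1), p1 = |known| / (n*r), the raw
## score is
##
##   S = phi * prod over features f of [ phi^-1 * (Nf+ + 1) / (Nf- + 1) ]
##
## where Nf+ counts known lncRNA-disease associations having f among their
## common neighbors, Nf- = Nl*Nd - Nf+ counts the unknown ones (Nl, Nd the
## lncRNAs/diseases adjacent to f), and the +1 terms are the Laplace
## calibration that keeps every factor positive.  On GN1 the features are
## the common neighboring miRNAs; on GN2 common neighboring genes join
## them, and a common-neighbor miRNA and gene that interact (a GMN edge)
## fuse into a single miRNA-gene pair feature, with each node covered by at
## least one pair dropped from the singleton features.  Every feature class
## contributes one phi^-1 factor, so a pair with k features scores
## phi^(1-k) * prod (Nf+ + 1)/(Nf- + 1).

#' Prior odds of a random lncRNA--disease association
#'
#' The prior probability of association is the number of known
#' lncRNA--disease edges divided by the number of possible pairs
#' `n * r` over the full registries.
#'
#' @param network a [hetnet()].
#' @param excluded optional length-2 character vector `c(lncRNA, disease)`
#'   naming one known association to leave out before counting (used by
#'   cross-validation so that test labels never leak into the counts).
#' @return An object of class `prior_odds`: list with `p1`, `p0`,
#'   `phi = p1/p0`, `n_known` and `n_pairs`.
#' @examples
#' net <- toy_gn1()
#' prior_odds(net)  # p1 = 1/4, phi = 1/3
#' @export
prior_odds <- function(network, excluded = NULL) {
  stopifnot(inherits(network, "hetnet"))
  n <- length(network$lncRNAs); r <- length(network$diseases)
  if (n * r == 0) stop("prior_odds: empty lncRNA or disease registry",
                       call. = FALSE)
  mc <- sum(.known_matrix(network, excluded))
  p1 <- mc / (n * r)
  phi <- if (p1 < 1) p1 / (1 - p1) else Inf
  structure(list(p1 = p1, p0 = 1 - p1, phi = phi,
                 n_known = mc, n_pairs = n * r),
            class = "prior_odds")
}

#' @export
print.prior_odds <- function(x, ...) {
  cat(sprintf("<prior_odds> p1 = %d/%d = %.6g, phi = %.6g\n",
              x$n_known, x$n_pairs, x$p1, x$phi))
  invisible(x)
}

#' Construct a single scoring feature
#'
#' @param kind `"miRNA"`, `"gene"` or `"pair"`.
#' @param members one node name, or for `kind = "pair"` a length-2 vector
#'   `c(miRNA, gene)`.
#' @return An object of class `nbclda_feature`.
#' @export
feature <- function(kind = c("miRNA", "gene", "pair"), members) {
  kind <- match.arg(kind)
  members <- as.character(members)
  if (kind == "pair") {
    stopifnot(length(members) == 2L)
    names(members) <- c("miRNA", "gene")
  } else stopifnot(length(members) == 1L)
  structure(list(kind = kind, members = members), class = "nbclda_feature")
}

#' @export
format.nbclda_feature <- function(x, ...) {
  if (x$kind == "pair") paste0("pair(", x$members[["miRNA"]], ",",
                               x$members[["gene"]], ")")
  else paste0(x$kind, "(", x$members, ")")
}

#' @export
print.nbclda_feature <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Common-neighbor features of one lncRNA--disease pair
#'
#' On GN1 the features are all miRNAs adjacent to both the lncRNA (via
#' MLN) and the disease (via MDN).  On GN2, genes adjacent to both (via
#' GLN/GDN) join the set; every (miRNA, gene) combination within the
#' common-neighbor set joined by a GMN interaction edge becomes one pair
#' feature, and any node participating in at least one pair is removed
#' from the singleton features.
#'
#' @param network a [hetnet()].
#' @param l,d lncRNA and disease names (must be registered).
#' @return An object of class `feature_set`: list with `lncRNA`, `disease`
#'   and `features` (a list of [feature()] objects, ordered pairs first,
#'   then miRNA singletons, then gene singletons, each lexicographically).
#' @examples
#' fs <- common_neighbors(toy_gn1(), "l2", "d2")  # one miRNA feature
#' @export
common_neighbors <- function(network, l, d) {
  stopifnot(inherits(network, "hetnet"))
  i <- match(l, network$lncRNAs); j <- match(d, network$diseases)
  if (is.na(i)) stop("unknown lncRNA: ", l, call. = FALSE)
  if (is.na(j)) stop("unknown disease: ", d, call. = FALSE)
  cn <- .cell_features(network, i, j)
  feats <- c(
    lapply(cn$pairs, function(p)
      feature("pair", c(network$miRNAs[p[[1L]]], network$genes[p[[2L]]]))),
    lapply(network$miRNAs[cn$m_single], feature, kind = "miRNA"),
    lapply(network$genes[cn$g_single], feature, kind = "gene"))
  structure(list(lncRNA = l, disease = d, features = feats),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> (%s, %s): %d feature(s)\n",
              x$lncRNA, x$disease, length(x$features)))
  if (length(x$features))
    cat(" ", paste(vapply(x$features, format, ""), collapse = ", "), "\n")
  invisible(x)
}

## feature partition of cell (i, j) by registry index.
## Returns integer indices: m_single, g_single and a list of
## c(miRNA_idx, gene_idx) pairs (sorted for determinism).
.cell_features <- function(net, i, j) {
  cm <- which(net$A_ml[, i] > 0 & net$A_md[, j] > 0)
  if (net$mode != "GN2")
    return(list(m_single = cm, g_single = integer(), pairs = list()))
  cg <- which(net$A_gl[, i] > 0 & net$A_gd[, j] > 0)
  pairs <- list(); pm <- integer(); pg <- integer()
  if (length(cm) && length(cg)) {
    sub <- net$A_gm[cg, cm, drop = FALSE]
    hit <- which(sub > 0, arr.ind = TRUE)
    if (nrow(hit)) {
      ord <- order(cm[hit[, 2L]], cg[hit[, 1L]])
      pairs <- lapply(ord, function(k)
        c(cm[hit[k, 2L]], cg[hit[k, 1L]]))
      pm <- unique(cm[hit[, 2L]]); pg <- unique(cg[hit[, 1L]])
    }
  }
  list(m_single = setdiff(cm, pm), g_single = setdiff(cg, pg), pairs = pairs)
}

#' Count known and unknown associations carrying a feature
#'
#' For a singleton feature, `n_l`/`n_d` are the numbers of lncRNAs and
#' diseases adjacent to the node, `n_plus` the number of known
#' lncRNA--disease associations having the node as a common neighbor, and
#' `n_minus = n_l * n_d - n_plus` the unknown ones.  For a miRNA--gene
#' pair feature, adjacency means adjacency to both members.  The
#' conservation identity `n_plus + n_minus = n_l * n_d` is asserted.
#'
#' @param network a [hetnet()].
#' @param feat a [feature()].
#' @param excluded optional held-out known edge `c(lncRNA, disease)`.
#' @return An object of class `feature_counts`: list with `n_plus`,
#'   `n_minus`, `n_l`, `n_d`.
#' @examples
#' feature_counts(toy_gn1(), feature("miRNA", "m1"))  # N+ = 1, N- = 3
#' @export
feature_counts <- function(network, feat, excluded = NULL) {
  stopifnot(inherits(network, "hetnet"), inherits(feat, "nbclda_feature"))
  Y <- .known_matrix(network, excluded)
  if (feat$kind == "pair") {
    m <- match(feat$members[["miRNA"]], network$miRNAs)
    g <- match(feat$members[["gene"]], network$genes)
    if (is.na(m) || is.na(g)) stop("unknown pair member", call. = FALSE)
    vl <- network$A_ml[m, ] * network$A_gl[g, ]
    vd <- network$A_md[m, ] * network$A_gd[g, ]
  } else if (feat$kind == "miRNA") {
    m <- match(feat$members, network$miRNAs)
    if (is.na(m)) stop("unknown miRNA: ", feat$members, call. = FALSE)
    vl <- network$A_ml[m, ]; vd <- network$A_md[m, ]
  } else {
    g <- match(feat$members, network$genes)
    if (is.na(g)) stop("unknown gene: ", feat$members, call. = FALSE)
    vl <- network$A_gl[g, ]; vd <- network$A_gd[g, ]
  }
  n_l <- sum(vl); n_d <- sum(vd)
  n_plus <- as.numeric(vl %*% Y %*% vd)
  n_minus <- n_l * n_d - n_plus
  stopifnot(n_plus + n_minus == n_l * n_d, n_minus >= 0, n_plus >= 0)
  structure(list(n_plus = n_plus, n_minus = n_minus, n_l = n_l, n_d = n_d),
            class = "feature_counts")
}

#' @export
print.feature_counts <- function(x, ...) {
  cat(sprintf("<feature_counts> N+ = %g, N- = %g (Nl = %g, Nd = %g)\n",
              x$n_plus, x$n_minus, x$n_l, x$n_d))
  invisible(x)
}

#' Raw posterior-odds score of one lncRNA--disease pair
#'
#' `S = phi * prod_f phi^-1 (Nf+ + 1)/(Nf- + 1)` over the pair's
#' common-neighbor features; an empty feature set gives `S = phi`, and a
#' network without known associations (`phi = 0`) gives `S = 0`.
#'
#' @inheritParams common_neighbors
#' @param prior a [prior_odds()] computed on the same (possibly reduced)
#'   known set; computed from `network` and `excluded` when `NULL`.
#' @param excluded optional held-out known edge `c(lncRNA, disease)`.
#' @return The raw score, a single non-negative number.
#' @examples
#' score_pair(toy_gn1(), "l2", "d2")  # 0.5
#' @export
score_pair <- function(network, l, d, prior = NULL, excluded = NULL) {
  stopifnot(inherits(network, "hetnet"))
  if (is.null(prior)) prior <- prior_odds(network, excluded)
  if (prior$phi == 0) return(0)
  fs <- common_neighbors(network, l, d)
  log_s <- log(prior$phi)
  for (f in fs$features) {
    ct <- feature_counts(network, f, excluded)
    log_s <- log_s - log(prior$phi) + log((ct$n_plus + 1) / (ct$n_minus + 1))
  }
  exp(log_s)
}

## Per-feature singleton and pair count tables used by the vectorized
## scorer.  Conservation (N+ + N- = Nl*Nd) holds by construction; N- >= 0
## is asserted.
.count_tables <- function(net, Y) {
  t_m <- list(n_l = rowSums(net$A_ml), n_d = rowSums(net$A_md),
              n_plus = rowSums((net$A_ml %*% Y) * net$A_md))
  t_m$n_minus <- t_m$n_l * t_m$n_d - t_m$n_plus
  stopifnot(all(t_m$n_minus >= 0))
  out <- list(m = t_m)
  if (net$mode == "GN2") {
    t_g <- list(n_l = rowSums(net$A_gl), n_d = rowSums(net$A_gd),
                n_plus = rowSums((net$A_gl %*% Y) * net$A_gd))
    t_g$n_minus <- t_g$n_l * t_g$n_d - t_g$n_plus
    stopifnot(all(t_g$n_minus >= 0))
    ## one row per GMN interaction edge
    gm <- which(net$A_gm > 0, arr.ind = TRUE)
    pair <- NULL
    if (nrow(gm)) {
      vl <- net$A_ml[gm[, 2L], , drop = FALSE] *
        net$A_gl[gm[, 1L], , drop = FALSE]
      vd <- net$A_md[gm[, 2L], , drop = FALSE] *
        net$A_gd[gm[, 1L], , drop = FALSE]
      n_plus <- rowSums((vl %*% Y) * vd)
      pair <- list(gene = gm[, 1L], miRNA = gm[, 2L],
                   vl = vl, vd = vd,
                   n_l = rowSums(vl), n_d = rowSums(vd), n_plus = n_plus)
      pair$n_minus <- pair$n_l * pair$n_d - pair$n_plus
      stopifnot(all(pair$n_minus >= 0))
    }
    out$g <- t_g
    out$pair <- pair
  }
  out
}

## exact score of cell (i, j) from precomputed count tables (pair-aware)
.score_cell <- function(net, tab, phi, i, j) {
  cn <- .cell_features(net, i, j)
  lr <- function(tb, idx) sum(log((tb$n_plus[idx] + 1) / (tb$n_minus[idx] + 1)))
  k <- length(cn$m_single) + length(cn$g_single) + length(cn$pairs)
  log_s <- (1 - k) * log(phi) + lr(tab$m, cn$m_single)
  if (net$mode == "GN2") {
    log_s <- log_s + lr(tab$g, cn$g_single)
    for (p in cn$pairs) {
      row <- which(tab$pair$miRNA == p[[1L]] & tab$pair$gene == p[[2L]])
      log_s <- log_s + lr(tab$pair, row)
    }
  }
  exp(log_s)
}

#' Raw posterior-odds scores for every lncRNA--disease pair
#'
#' Vectorized scoring of the full lncRNA x disease grid.  On GN1 the score
#' matrix is computed in closed form by accumulating per-miRNA log odds
#' through the incidence matrices; on GN2 the all-singleton matrix is
#' corrected exactly at the cells where at least one miRNA--gene pair
#' feature is active.  Agrees with [score_pair()] cell by cell.
#'
#' @inheritParams score_pair
#' @return A numeric lncRNA x disease matrix of raw scores with attribute
#'   `mode`.
#' @export
score_all <- function(network, excluded = NULL) {
  stopifnot(inherits(network, "hetnet"))
  Y <- .known_matrix(network, excluded)
  n <- length(network$lncRNAs); r <- length(network$diseases)
  prior <- prior_odds(network, excluded)
  if (prior$phi == 0)
    return(structure(matrix(0, n, r,
                            dimnames = list(network$lncRNAs, network$diseases)),
                     mode = network$mode))
  tab <- .count_tables(network, Y)
  log_phi <- log(prior$phi)
  w_m <- -log_phi + log((tab$m$n_plus + 1) / (tab$m$n_minus + 1))
  log_s <- log_phi + crossprod(network$A_ml * w_m, network$A_md)
  if (network$mode == "GN2") {
    w_g <- -log_phi + log((tab$g$n_plus + 1) / (tab$g$n_minus + 1))
    log_s <- log_s + crossprod(network$A_gl * w_g, network$A_gd)
    if (!is.null(tab$pair)) {
      ## cells where some GMN edge joins two common neighbors need the
      ## pair-aware partition; recompute those exactly
      touched <- matrix(FALSE, n, r)
      for (e in seq_along(tab$pair$n_plus))
        touched <- touched | (outer(tab$pair$vl[e, ], tab$pair$vd[e, ]) > 0)
      idx <- which(touched, arr.ind = TRUE)
      for (k in seq_len(nrow(idx)))
        log_s[idx[k, 1L], idx[k, 2L]] <-
          log(.score_cell(network, tab, prior$phi, idx[k, 1L], idx[k, 2L]))
    }
  }
  s <- exp(log_s)
  dimnames(s) <- list(network$lncRNAs, network$diseases)
  attr(s, "mode") <- network$mode
  s
}

#' Log-normalize a raw score matrix
#'
#' Maps raw posterior odds `S` to `S' = ln(S) / lambda`.  With
#' `lambda = "auto"` the constant is the largest `|ln S|` over positive
#' entries (1 when that maximum is 0), so normalized scores lie in
#' `[-1, 1]`.  Zero raw scores (possible only when there are no known
#' associations) are mapped to one less than the smallest finite
#' normalized score, keeping them strictly rank-bottom.  Any positive
#' `lambda` yields the same ranking.
#'
#' @param raw non-negative score matrix from [score_all()].
#' @param lambda `"auto"` or a positive number.
#' @return Matrix of normalized scores with attribute `lambda`.
#' @examples
#' normalize_scores(matrix(0.5), lambda = 1)  # ln(0.5)
#' @export
normalize_scores <- function(raw, lambda = "auto") {
  stopifnot(is.matrix(raw), all(raw >= 0))
  pos <- raw > 0
  ln <- log(raw[pos])
  if (identical(lambda, "auto")) {
    lambda <- if (length(ln)) max(abs(ln)) else 0
    if (lambda == 0) lambda <- 1
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be \"auto\" or a single positive number", call. = FALSE)
  out <- raw
  out[pos] <- ln / lambda
  if (any(!pos))
    out[!pos] <- (if (length(ln)) min(out[pos]) else 0) - 1
  attr(out, "lambda") <- lambda
  attr(out, "mode") <- attr(raw, "mode")
  out
}
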