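## Heterogeneous network assembly.
##
## A `hetnet` is the global network the scorer operates on: node registries
## per kind (lncRNA, disease, miRNA, gene) plus the bipartite edge sets.
## mode "GN1" is the tripartite lncRNA-miRNA-disease network; mode "GN2"
## additionally carries the gene-disease, gene-lncRNA and gene-miRNA layers.
## Registries are the sorted union of all endpoint names of that kind, so
## matrix layouts and tie-breaks are reproducible.

.kind_check <- function(es, left, right, what) {
  if (!inherits(es, "edge_set"))
    stop(what, " must be an edge_set", call. = FALSE)
  if (!identical(es$left_kind, left) || !identical(es$right_kind, right))
    stop(sprintf("%s must have kinds (%s, %s), got (%s, %s)",
                 what, left, right, es$left_kind, es$right_kind),
         call. = FALSE)
  invisible(es)
}

## 0/1 incidence matrix of an edge_set on fixed row/column registries
.incidence <- function(es, rows, cols) {
  a <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  if (nrow(es$edges))
    a[cbind(match(es$edges$left, rows), match(es$edges$right, cols))] <- 1
  a
}

#' Assemble the global tripartite network GN1
#'
#' Combines the miRNA--disease (MDN), miRNA--lncRNA (MLN) and
#' lncRNA--disease (LDN) edge sets into one network.  Node registries are
#' the lexicographically sorted unions of endpoint names per kind, so a
#' lncRNA appearing only in LDN still enters the lncRNA registry.
#'
#' @param mdn [edge_set()] with kinds (miRNA, disease).
#' @param mln [edge_set()] with kinds (miRNA, lncRNA).
#' @param ldn [edge_set()] with kinds (lncRNA, disease); the known
#'   associations to be learned from.
#' @return An object of class `hetnet` with `mode = "GN1"`; registries
#'   `lncRNAs`, `diseases`, `miRNAs` (and empty `genes`), the edge sets,
#'   and 0/1 incidence matrices `A_ml` (miRNA x lncRNA), `A_md`
#'   (miRNA x disease) and `Y` (lncRNA x disease, the known LDN edges).
#' @examples
#' net <- assemble_gn1(
#'   edge_set(c("m1", "m1"), c("d1", "d2"), "miRNA", "disease"),
#'   edge_set(c("m1", "m1"), c("l1", "l2"), "miRNA", "lncRNA"),
#'   edge_set("l1", "d1", "lncRNA", "disease"))
#' net
#' @export
assemble_gn1 <- function(mdn, mln, ldn) {
  .kind_check(mdn, "miRNA", "disease", "mdn")
  .kind_check(mln, "miRNA", "lncRNA", "mln")
  .kind_check(ldn, "lncRNA", "disease", "ldn")
  lncRNAs <- sort(unique(c(mln$edges$right, ldn$edges$left)))
  diseases <- sort(unique(c(mdn$edges$right, ldn$edges$right)))
  miRNAs <- sort(unique(c(mdn$edges$left, mln$edges$left)))
  net <- list(mode = "GN1",
              lncRNAs = lncRNAs, diseases = diseases,
              miRNAs = miRNAs, genes = character(),
              mdn = mdn, mln = mln, ldn = ldn,
              gdn = NULL, gln = NULL, gmn = NULL,
              A_ml = .incidence(mln, miRNAs, lncRNAs),
              A_md = .incidence(mdn, miRNAs, diseases),
              Y = .incidence(ldn, lncRNAs, diseases))
  class(net) <- "hetnet"
  net
}

#' Extend a tripartite network to the quadruple network GN2
#'
#' Appends the gene--disease (GDN), gene--lncRNA (GLN) and gene--miRNA
#' (GMN) layers to a GN1 network.  Registries are re-derived as unions, so
#' a disease seen only in GDN enlarges the disease registry; all GN1 edges
#' are preserved unchanged.
#'
#' @param gn1 a `hetnet` with `mode = "GN1"`.
#' @param gdn [edge_set()] with kinds (gene, disease).
#' @param gln [edge_set()] with kinds (gene, lncRNA).
#' @param gmn [edge_set()] with kinds (gene, miRNA); these interaction
#'   edges define which miRNA--gene common neighbors fuse into pair
#'   features during scoring.
#' @return A `hetnet` with `mode = "GN2"` and additional incidence
#'   matrices `A_gl`, `A_gd`, `A_gm`.
#' @export
assemble_gn2 <- function(gn1, gdn, gln, gmn) {
  if (!inherits(gn1, "hetnet") || gn1$mode != "GN1")
    stop("gn1 must be a hetnet with mode GN1", call. = FALSE)
  .kind_check(gdn, "gene", "disease", "gdn")
  .kind_check(gln, "gene", "lncRNA", "gln")
  .kind_check(gmn, "gene", "miRNA", "gmn")
  lncRNAs <- sort(unique(c(gn1$lncRNAs, gln$edges$right)))
  diseases <- sort(unique(c(gn1$diseases, gdn$edges$right)))
  miRNAs <- sort(unique(c(gn1$miRNAs, gmn$edges$right)))
  genes <- sort(unique(c(gdn$edges$left, gln$edges$left, gmn$edges$left)))
  net <- list(mode = "GN2",
              lncRNAs = lncRNAs, diseases = diseases,
              miRNAs = miRNAs, genes = genes,
              mdn = gn1$mdn, mln = gn1$mln, ldn = gn1$ldn,
              gdn = gdn, gln = gln, gmn = gmn,
              A_ml = .incidence(gn1$mln, miRNAs, lncRNAs),
              A_md = .incidence(gn1$mdn, miRNAs, diseases),
              Y = .incidence(gn1$ldn, lncRNAs, diseases),
              A_gl = .incidence(gln, genes, lncRNAs),
              A_gd = .incidence(gdn, genes, diseases),
              A_gm = .incidence(gmn, genes, miRNAs))
  class(net) <- "hetnet"
  net
}

#' Assemble a heterogeneous network from edge sets
#'
#' Convenience wrapper: with three edge sets builds GN1, with six builds
#' GN2.
#'
#' @inheritParams assemble_gn1
#' @inheritParams assemble_gn2
#' @return A `hetnet`.
#' @export
hetnet <- function(mdn, mln, ldn, gdn = NULL, gln = NULL, gmn = NULL) {
  gn1 <- assemble_gn1(mdn, mln, ldn)
  if (is.null(gdn) && is.null(gln) && is.null(gmn)) return(gn1)
  if (is.null(gdn) || is.null(gln) || is.null(gmn))
    stop("GN2 requires all three gene layers (gdn, gln, gmn)", call. = FALSE)
  assemble_gn2(gn1, gdn, gln, gmn)
}

#' @export
print.hetnet <- function(x, ...) {
  cat(sprintf("<hetnet mode=%s> %d lncRNAs x %d diseases, %d miRNAs, %d genes\n",
              x$mode, length(x$lncRNAs), length(x$diseases),
              length(x$miRNAs), length(x$genes)))
  cat(sprintf("  known lncRNA-disease associations: %d\n", sum(x$Y)))
  n_e <- nrow(x$mdn$edges) + nrow(x$mln$edges) + nrow(x$ldn$edges)
  if (x$mode == "GN2")
    n_e <- n_e + nrow(x$gdn$edges) + nrow(x$gln$edges) + nrow(x$gmn$edges)
  cat(sprintf("  total edges: %d\n", n_e))
  invisible(x)
}

## known-association matrix with an optional held-out edge removed;
## excluded is c(lncRNA, disease)
.known_matrix <- function(net, excluded = NULL) {
  Y <- net$Y
  if (!is.null(excluded)) {
    i <- match(excluded[[1L]], net$lncRNAs)
    j <- match(excluded[[2L]], net$diseases)
    if (is.na(i) || is.na(j))
      stop("excluded edge endpoint not in registry", call. = FALSE)
    Y[i, j] <- 0
  }
  Y
}
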