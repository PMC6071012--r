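## MeSH-based disease semantic similarity (Wang-style DAG measure).
##
## Each disease maps to one or more MeSH tree numbers (dotted position
## codes); every dotted prefix of a tree number is an ancestor position.
## A disease's DAG is the union of its prefix chains; an ancestor at h
## hops contributes delta^h to the disease's semantics (max over paths
## when a position is reachable at several depths), the semantic value DV
## is the sum of contributions, and two diseases are similar in proportion
## to the contributions of the tree positions they share.

.mesh_pattern <- "^[^.]+(\\.[^.]+)*$"

#' Construct a disease ontology from tree numbers
#'
#' @param tree_numbers named list: disease name -> character vector of
#'   MeSH tree numbers (dot-separated position codes).  Duplicates are
#'   collapsed; a disease may have zero tree numbers (it is then treated
#'   as MeSH-missing downstream).
#' @return An object of class `disease_ontology`.
#' @export
disease_ontology <- function(tree_numbers = list()) {
  stopifnot(is.list(tree_numbers))
  tree_numbers <- lapply(tree_numbers, function(tn) {
    tn <- trimws(as.character(tn))
    bad <- !grepl(.mesh_pattern, tn)
    if (any(bad))
      stop("malformed MeSH tree number: ", tn[bad][1L], call. = FALSE)
    sort(unique(tn))
  })
  structure(list(tree_numbers = tree_numbers), class = "disease_ontology")
}

#' @export
print.disease_ontology <- function(x, ...) {
  n_missing <- sum(lengths(x$tree_numbers) == 0L)
  cat(sprintf("<disease_ontology> %d disease(s), %d tree number(s)%s\n",
              length(x$tree_numbers), sum(lengths(x$tree_numbers)),
              if (n_missing) sprintf(", %d without tree numbers", n_missing)
              else ""))
  invisible(x)
}

#' Read a disease -> MeSH tree-number table
#'
#' Expects tab-separated lines `disease<TAB>tree_number`, one tree number
#' per line (multiple lines per disease allowed).  `#` comments and an
#' optional `disease<TAB>...` header are skipped.
#'
#' @param path path to the TSV file.
#' @return A [disease_ontology()].
#' @export
read_mesh_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lineno <- seq_along(raw)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  raw <- raw[keep]; lineno <- lineno[keep]
  if (length(raw)) {
    first <- trimws(strsplit(raw[[1L]], "\t", fixed = TRUE)[[1L]])
    if (length(first) && tolower(first[[1L]]) == "disease") {
      raw <- raw[-1L]; lineno <- lineno[-1L]
    }
  }
  if (!length(raw)) return(disease_ontology())
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop(sprintf("parse error at line %d of %s: fewer than 2 fields",
                 lineno[which(nf < 2L)[1L]], path), call. = FALSE)
  disease <- trimws(vapply(parts, `[`, "", 1L))
  tn <- trimws(vapply(parts, `[`, "", 2L))
  bad <- !nzchar(disease) | !grepl(.mesh_pattern, tn)
  if (any(bad))
    stop(sprintf("parse error at line %d of %s: empty name or malformed tree number",
                 lineno[which(bad)[1L]], path), call. = FALSE)
  disease_ontology(split(tn, factor(disease, levels = unique(disease))))
}

#' Build the ancestor DAG of one disease
#'
#' Nodes are all dotted prefixes of the disease's tree numbers (each
#' prefix is one ancestor position, identified by its tree-number
#' string); the parent of `"A.B.C"` is `"A.B"`.
#'
#' @param ontology a [disease_ontology()].
#' @param disease disease name.
#' @return An object of class `disease_dag`: list with `disease`,
#'   `positions` (the disease's own tree numbers), `nodes` and `parents`
#'   (named character vector, `NA` for roots); or `NULL` (with a warning)
#'   when the disease has no tree numbers.
#' @examples
#' onto <- disease_ontology(list(dB = "C04.123"))
#' build_dag(onto, "dB")
#' @export
build_dag <- function(ontology, disease) {
  stopifnot(inherits(ontology, "disease_ontology"))
  tn <- ontology$tree_numbers[[disease]]
  if (is.null(tn) || !length(tn)) {
    warning("disease has no MeSH tree numbers: ", disease, call. = FALSE)
    return(NULL)
  }
  nodes <- unique(unlist(lapply(strsplit(tn, ".", fixed = TRUE), function(seg)
    vapply(seq_along(seg), function(k) paste(seg[1:k], collapse = "."), ""))))
  nodes <- sort(nodes)
  parents <- vapply(nodes, function(nd) {
    seg <- strsplit(nd, ".", fixed = TRUE)[[1L]]
    if (length(seg) == 1L) NA_character_
    else paste(seg[-length(seg)], collapse = ".")
  }, "")
  structure(list(disease = disease, positions = tn,
                 nodes = nodes, parents = parents),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("<disease_dag> %s: %d node(s), %d root(s)\n",
              x$disease, length(x$nodes), sum(is.na(x$parents))))
  invisible(x)
}

#' Semantic contribution of each DAG node
#'
#' The disease's own positions contribute 1; an ancestor contributes
#' `delta` times the largest contribution among its children, i.e.
#' `delta^h` for an ancestor at minimum hop distance `h`.  Computed by a
#' single sweep from the deepest positions outward.
#'
#' @param dag a [disease_dag()].
#' @param delta semantic decay factor per edge, in (0, 1].
#' @return Named numeric vector of contributions over `dag$nodes`.
#' @examples
#' dag <- build_dag(disease_ontology(list(d = "C04.111.222")), "d")
#' semantic_contribution(dag, 0.5)  # 1, 0.5, 0.25
#' @export
semantic_contribution <- function(dag, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"),
            is.numeric(delta), length(delta) == 1L, delta > 0, delta <= 1)
  contrib <- stats::setNames(rep(0, length(dag$nodes)), dag$nodes)
  contrib[dag$positions] <- 1
  depth <- lengths(strsplit(dag$nodes, ".", fixed = TRUE))
  for (nd in dag$nodes[order(depth, decreasing = TRUE)]) {
    p <- dag$parents[[nd]]
    if (!is.na(p))
      contrib[[p]] <- max(contrib[[p]], delta * contrib[[nd]])
  }
  contrib
}

#' Semantic value of a disease
#'
#' The sum of the semantic contributions of all nodes in the disease's
#' ancestor DAG.
#'
#' @param contribs named vector from [semantic_contribution()].
#' @return A single non-negative number.
#' @export
semantic_value <- function(contribs) sum(contribs)

#' Pairwise disease semantic similarity matrix
#'
#' `SD(di, dj)` is the summed contribution, from both diseases' DAGs, of
#' the tree positions they share, divided by the sum of their semantic
#' values.  Identical diseases score 1; diseases in disjoint MeSH
#' families score 0.  Diseases missing from the ontology get identity
#' rows/columns (similar only to themselves), so downstream re-weighting
#' degrades gracefully to the base score.
#'
#' @param ontology a [disease_ontology()].
#' @param diseases character vector of disease names (matrix order).
#' @param delta semantic decay factor per edge, in (0, 1].
#' @return Symmetric numeric matrix with unit diagonal, entries in [0, 1].
#' @examples
#' onto <- disease_ontology(list(dA = "C04", dB = "C04.123"))
#' similarity_matrix(onto, c("dA", "dB"), delta = 0.5)  # off-diagonal 0.6
#' @export
similarity_matrix <- function(ontology, diseases, delta = 0.5) {
  stopifnot(inherits(ontology, "disease_ontology"))
  diseases <- as.character(diseases)
  r <- length(diseases)
  sd_mat <- diag(1, r)
  dimnames(sd_mat) <- list(diseases, diseases)
  has <- vapply(diseases, function(d)
    length(ontology$tree_numbers[[d]]) > 0L, TRUE)
  info <- lapply(diseases[has], function(d) {
    dag <- build_dag(ontology, d)
    contribs <- semantic_contribution(dag, delta)
    list(contribs = contribs, dv = semantic_value(contribs))
  })
  names(info) <- diseases[has]
  idx <- which(has)
  if (length(idx) >= 2L) {
    for (a in seq_len(length(idx) - 1L)) for (b in (a + 1L):length(idx)) {
      ia <- info[[diseases[idx[a]]]]; ib <- info[[diseases[idx[b]]]]
      shared <- intersect(names(ia$contribs), names(ib$contribs))
      val <- if (length(shared))
        sum(ia$contribs[shared] + ib$contribs[shared]) / (ia$dv + ib$dv)
      else 0
      sd_mat[idx[a], idx[b]] <- sd_mat[idx[b], idx[a]] <- val
    }
  }
  sd_mat
}

#' Re-weight normalized scores by disease semantic similarity
#'
#' Disease-space matrix product `S = S' %*% SD`: each disease column of
#' the combined score is the similarity-weighted sum of the normalized
#' scores over all diseases, so evidence is smoothed across semantically
#' close diseases.  With an identity similarity matrix the input is
#' returned unchanged.
#'
#' @param scores lncRNA x disease matrix of normalized scores.
#' @param sim disease similarity matrix from [similarity_matrix()] whose
#'   row/column names cover the score columns.
#' @return Matrix of combined scores, same shape and dimnames as
#'   `scores`.
#' @export
combine_scores <- function(scores, sim) {
  stopifnot(is.matrix(scores), is.matrix(sim))
  dn <- colnames(scores)
  if (is.null(dn) || is.null(rownames(sim)) ||
      !all(dn %in% rownames(sim)) || nrow(sim) != ncol(sim))
    stop("similarity matrix must be square and cover all score columns",
         call. = FALSE)
  out <- scores %*% sim[dn, dn, drop = FALSE]
  dimnames(out) <- dimnames(scores)
  attr(out, "lambda") <- attr(scores, "lambda")
  attr(out, "mode") <- attr(scores, "mode")
  out
}

#' Write a disease similarity matrix as TSV
#'
#' Square matrix with a disease header row and a leading disease column.
#'
#' @param sim matrix from [similarity_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(is.matrix(sim))
  df <- data.frame(disease = rownames(sim), sim, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
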