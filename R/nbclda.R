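#' Fit the naive Bayesian lncRNA--disease association model
#'
#' Scores every lncRNA--disease pair of a heterogeneous network by
#' Laplace-calibrated naive Bayesian posterior odds over the pair's
#' common-neighbor features ([score_all()]), log-normalizes the raw odds
#' ([normalize_scores()]), and optionally re-weights the result by MeSH
#' disease semantic similarity ([combine_scores()]).
#'
#' @param network a [hetnet()] (GN1 or GN2 mode).
#' @param ontology optional [disease_ontology()]; required when
#'   `use_similarity = TRUE`.
#' @param use_similarity re-weight scores by disease semantic similarity
#'   (default: `TRUE` when `ontology` is supplied).
#' @param delta semantic decay factor per DAG edge, in (0, 1].
#' @param lambda `"auto"` or a positive normalization constant; any
#'   positive value yields the same ranking.
#' @param exclude optional held-out known edge `c(lncRNA, disease)`
#'   removed from every count before scoring (cross-validation support).
#' @return An object of class `nbclda`: list with elements `network`,
#'   `prior` ([prior_odds()]), `raw`, `normalized` and `scores` (the final
#'   matrix: combined when similarity is used, otherwise normalized),
#'   `similarity` (or `NULL`), `lambda`, `delta`, `use_similarity`, and
#'   `call`.  Methods: `print`, `summary`, `coef` (final score matrix),
#'   `predict` (ranked association table) and `plot`.
#' @examples
#' fit <- nbclda(toy_gn1())
#' coef(fit)
#' predict(fit, k = 3)
#' @seealso [loocv()] for evaluation, [simulate_hetnet()] for test data.
#' @export
nbclda <- function(network, ontology = NULL,
                   use_similarity = !is.null(ontology),
                   delta = 0.5, lambda = "auto", exclude = NULL) {
  stopifnot(inherits(network, "hetnet"))
  if (use_similarity && is.null(ontology))
    stop("use_similarity = TRUE requires a disease ontology", call. = FALSE)
  prior <- prior_odds(network, exclude)
  raw <- score_all(network, exclude)
  normalized <- normalize_scores(raw, lambda)
  sim <- NULL
  scores <- normalized
  if (use_similarity) {
    sim <- similarity_matrix(ontology, network$diseases, delta)
    scores <- combine_scores(normalized, sim)
  }
  structure(list(network = network, prior = prior,
                 raw = raw, normalized = normalized, scores = scores,
                 similarity = sim, lambda = attr(normalized, "lambda"),
                 delta = if (use_similarity) delta else NULL,
                 use_similarity = use_similarity,
                 call = match.call()),
            class = "nbclda")
}

#' @export
print.nbclda <- function(x, ...) {
  net <- x$network
  cat(sprintf("Naive Bayesian lncRNA-disease association model (%s%s)\n",
              net$mode, if (x$use_similarity) " + semantic similarity" else ""))
  cat(sprintf("  %d lncRNAs x %d diseases, %d known associations (p1 = %.4g)\n",
              length(net$lncRNAs), length(net$diseases),
              x$prior$n_known, x$prior$p1))
  cat(sprintf("  lambda = %.4g\n", x$lambda))
  invisible(x)
}

#' @export
summary.nbclda <- function(object, ...) {
  known <- object$network$Y > 0
  s <- object$scores
  out <- list(model = object,
              n_candidates = sum(!known),
              score_known = summary(s[known]),
              score_candidate = summary(s[!known]))
  class(out) <- "summary.nbclda"
  out
}

#' @export
print.summary.nbclda <- function(x, ...) {
  print(x$model)
  cat("\nFinal scores of known associations:\n")
  print(x$score_known)
  cat(sprintf("\nFinal scores of the %d candidate pairs:\n", x$n_candidates))
  print(x$score_candidate)
  invisible(x)
}

#' @export
coef.nbclda <- function(object, ...) object$scores

#' Ranked association predictions
#'
#' Flattens the final score matrix into a ranked table, by default
#' dropping the already-known associations so only novel candidates
#' remain.  Ties are broken by (lncRNA, disease) lexicographic order.
#'
#' @param object an [nbclda()] fit.
#' @param k optional cutoff: return only the top `k` rows.
#' @param include_known keep known associations in the table
#'   (default `FALSE`).
#' @param ... unused.
#' @return A data frame with columns `lncRNA`, `disease`, `score`,
#'   `known`, `rank`.
#' @export
predict.nbclda <- function(object, k = NULL, include_known = FALSE, ...) {
  df <- .rank_table(object$scores)
  df$known <- object$network$Y[cbind(match(df$lncRNA, object$network$lncRNAs),
                                     match(df$disease, object$network$diseases))] > 0
  if (!include_known) {
    df <- df[!df$known, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
  }
  if (!is.null(k)) df <- df[seq_len(min(k, nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
plot.nbclda <- function(x, ...) {
  known <- x$network$Y > 0
  s_known <- x$scores[known]
  s_cand <- x$scores[!known]
  graphics::boxplot(list(known = s_known, candidate = s_cand),
                    ylab = "final association score",
                    main = "Score separation of known vs candidate pairs", ...)
  invisible(x)
}

## score matrix -> sorted long table (score desc, lncRNA, disease)
.rank_table <- function(scores) {
  df <- data.frame(
    lncRNA = rep(rownames(scores), times = ncol(scores)),
    disease = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores),
    stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$lncRNA, df$disease), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Write a score matrix as a ranked TSV
#'
#' Columns `lncRNA`, `disease`, `score`, `rank`; rows sorted by score
#' descending with ties broken by (lncRNA, disease) lexicographic order;
#' `rank` is the 1-based position after sorting.
#'
#' @param scores numeric lncRNA x disease matrix (finite values), or an
#'   [nbclda()] fit (its final score matrix is written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  if (inherits(scores, "nbclda")) scores <- scores$scores
  stopifnot(is.matrix(scores), all(is.finite(scores)))
  utils::write.table(.rank_table(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
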