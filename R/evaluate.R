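## Evaluation protocols: leave-one-out cross-validation with ROC/AUC, and
## top-k precision/recall/F1 under sparse (20%) training.

#' Rank-based AUC from positive and negative scores
#'
#' Mann--Whitney statistic: the probability that a random positive
#' outscores a random negative, with half credit for ties.  Identical to
#' the trapezoidal area under the threshold-swept ROC curve.
#'
#' @param pos,neg numeric score vectors (both non-empty).
#' @return AUC in [0, 1].
#' @examples
#' auc_from_ranks(c(3, 1), c(2, 0))  # 0.75
#' @export
auc_from_ranks <- function(pos, neg) {
  if (!length(pos) || !length(neg))
    stop("auc_from_ranks: empty score vector", call. = FALSE)
  stopifnot(is.numeric(pos), is.numeric(neg),
            !anyNA(pos), !anyNA(neg))
  r <- rank(c(pos, neg), ties.method = "average")
  np <- length(pos)
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  u / (np * length(neg))
}

#' Leave-one-out cross-validation of the association scorer
#'
#' Each known lncRNA--disease association is held out in turn; the prior,
#' all feature counts, and all scores are recomputed on the remaining
#' associations (no label leakage), and the held-out pair is ranked
#' against the candidate pairs not in the training positives.  By default
#' the candidates are global (all lncRNA x disease cells minus training
#' positives); `per_disease = TRUE` restricts them to the held-out
#' disease's column.  The round AUC is the fraction of negatives scored
#' below the positive, ties half-credited; the report AUC is the mean
#' over rounds.
#'
#' @inheritParams nbclda
#' @param per_disease use per-disease candidate sets instead of global.
#' @param progress print a dot per 50 rounds (default FALSE).
#' @return An object of class `nbclda_cv`: list with `auc`, `rounds` (one
#'   row per held-out edge: `lncRNA`, `disease`, `rank`, `n_candidates`,
#'   `n_ties`, `auc`), `roc` (FPR/TPR step points), and the evaluation
#'   settings.
#' @examples
#' sim <- simulate_hetnet(n_l = 12, n_d = 10, n_m = 8, n_g = 0, seed = 1)
#' loocv(sim$network)$auc
#' @export
loocv <- function(network, ontology = NULL, use_similarity = !is.null(ontology),
                  delta = 0.5, lambda = "auto", per_disease = FALSE,
                  progress = FALSE) {
  stopifnot(inherits(network, "hetnet"))
  known <- which(network$Y > 0, arr.ind = TRUE)
  if (nrow(known) < 2L)
    stop("loocv requires at least 2 known associations", call. = FALSE)
  sim_mat <- if (use_similarity) {
    if (is.null(ontology))
      stop("use_similarity = TRUE requires a disease ontology", call. = FALSE)
    similarity_matrix(ontology, network$diseases, delta)
  } else NULL
  rounds <- data.frame(lncRNA = network$lncRNAs[known[, 1L]],
                       disease = network$diseases[known[, 2L]],
                       rank = NA_real_, n_candidates = NA_integer_,
                       n_ties = NA_integer_, auc = NA_real_,
                       stringsAsFactors = FALSE)
  for (e in seq_len(nrow(known))) {
    i <- known[e, 1L]; j <- known[e, 2L]
    held <- c(network$lncRNAs[i], network$diseases[j])
    raw <- score_all(network, excluded = held)
    final <- normalize_scores(raw, lambda)
    if (use_similarity) final <- combine_scores(final, sim_mat)
    train <- network$Y
    train[i, j] <- 0
    cand <- if (per_disease) {
      which_col <- rep(FALSE, ncol(train)); which_col[j] <- TRUE
      train == 0 & matrix(which_col, nrow(train), ncol(train), byrow = TRUE)
    } else train == 0
    cand[i, j] <- FALSE   # the held-out cell is the positive, not a negative
    pos <- final[i, j]
    neg <- final[cand]
    n_below <- sum(neg < pos); n_ties <- sum(neg == pos)
    rounds$rank[e] <- 1 + sum(neg > pos) + n_ties / 2
    rounds$n_candidates[e] <- length(neg) + 1L
    rounds$n_ties[e] <- n_ties
    rounds$auc[e] <- (n_below + n_ties / 2) / length(neg)
    if (progress && e %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  fpr <- 1 - rounds$auc
  xs <- sort(unique(fpr))
  roc <- data.frame(fpr = c(0, xs, 1),
                    tpr = c(0, vapply(xs, function(v) mean(fpr <= v), 0), 1))
  structure(list(auc = mean(rounds$auc), rounds = rounds, roc = roc,
                 mode = network$mode, use_similarity = use_similarity,
                 per_disease = per_disease, lambda = lambda,
                 delta = if (use_similarity) delta else NULL),
            class = "nbclda_cv")
}

#' @export
print.nbclda_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation (%s%s%s)\n", x$mode,
              if (x$use_similarity) " + semantic similarity" else "",
              if (x$per_disease) ", per-disease candidates" else ""))
  cat(sprintf("  rounds: %d   AUC: %.4f\n", nrow(x$rounds), x$auc))
  cat(sprintf("  median positive rank: %.1f of %d candidates\n",
              stats::median(x$rounds$rank),
              as.integer(stats::median(x$rounds$n_candidates))))
  invisible(x)
}

#' @export
plot.nbclda_cv <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "s",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("LOOCV ROC (AUC = %.4f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Write a cross-validation report
#'
#' Emits `<prefix>_report.json` (summary with `auc`), `<prefix>_rounds.tsv`
#' (per-round positive ranks) and `<prefix>_roc.tsv` (ROC step points).
#'
#' @param report an `nbclda_cv` object from [loocv()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, default `"loocv"`.
#' @return The report path, invisibly.
#' @export
write_cv_report <- function(report, dir, prefix = "loocv") {
  stopifnot(inherits(report, "nbclda_cv"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(dir, paste0(prefix, "_report.json"))
  jsonlite::write_json(
    list(auc = report$auc, rounds = nrow(report$rounds),
         mode = report$mode, use_similarity = report$use_similarity,
         per_disease = report$per_disease,
         lambda = if (identical(report$lambda, "auto")) "auto" else report$lambda,
         delta = report$delta),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(report$rounds, file.path(dir, paste0(prefix, "_rounds.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$roc, file.path(dir, paste0(prefix, "_roc.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary_path)
}

## evaluate expr with a temporary RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Top-k F1 under sparse training
#'
#' Randomly samples `ceiling(train_fraction * n_known)` known
#' associations (seeded) as the training set, scores all non-training
#' pairs on the reduced network, and takes the top `k` by score (ties
#' broken by lncRNA then disease name) as predictions.  The held-out
#' known associations are the positives: precision = TP/k, recall =
#' TP/#held-out, F1 their harmonic mean (0 when undefined).
#'
#' @inheritParams nbclda
#' @param k prediction-list cutoff (positive integer).
#' @param train_fraction fraction of known associations used for
#'   training, default 0.2.
#' @param seed integer seed for the training sample.
#' @return An object of class `nbclda_f1`: list with `k`, `precision`,
#'   `recall`, `f1`, `tp`, `n_train`, `n_test`, `train_fraction`, `seed`.
#' @examples
#' sim <- simulate_hetnet(n_l = 12, n_d = 10, n_m = 8, n_g = 0, seed = 1)
#' f1_at_k(sim$network, k = 10, seed = 1)
#' @export
f1_at_k <- function(network, k, train_fraction = 0.2, seed = 1,
                    ontology = NULL, use_similarity = !is.null(ontology),
                    delta = 0.5, lambda = "auto") {
  stopifnot(inherits(network, "hetnet"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("k must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  known <- which(network$Y > 0, arr.ind = TRUE)
  n_known <- nrow(known)
  n_train <- as.integer(ceiling(train_fraction * n_known))
  if (n_train < 1L)
    stop("training subset is empty after sampling", call. = FALSE)
  train_idx <- .with_seed(seed, sample.int(n_known, n_train))
  net2 <- network
  held <- known[-train_idx, , drop = FALSE]
  net2$Y[held] <- 0
  keep_edge <- paste(network$lncRNAs[known[train_idx, 1L]],
                     network$diseases[known[train_idx, 2L]], sep = "\r")
  all_edge <- paste(net2$ldn$edges$left, net2$ldn$edges$right, sep = "\r")
  net2$ldn$edges <- net2$ldn$edges[all_edge %in% keep_edge, , drop = FALSE]
  fit <- nbclda(net2, ontology = ontology, use_similarity = use_similarity,
                delta = delta, lambda = lambda)
  tab <- .rank_table(fit$scores)
  is_train <- paste(tab$lncRNA, tab$disease, sep = "\r") %in% keep_edge
  tab <- tab[!is_train, , drop = FALSE]
  top <- tab[seq_len(min(k, nrow(tab))), , drop = FALSE]
  held_key <- paste(network$lncRNAs[held[, 1L]],
                    network$diseases[held[, 2L]], sep = "\r")
  tp <- sum(paste(top$lncRNA, top$disease, sep = "\r") %in% held_key)
  precision <- tp / k
  recall <- if (nrow(held)) tp / nrow(held) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(k = k, precision = precision, recall = recall, f1 = f1,
                 tp = tp, n_train = n_train, n_test = nrow(held),
                 train_fraction = train_fraction, seed = seed),
            class = "nbclda_f1")
}

#' @export
print.nbclda_f1 <- function(x, ...) {
  cat(sprintf("Top-%d evaluation (%.0f%% training, seed %d)\n",
              x$k, 100 * x$train_fraction, x$seed))
  cat(sprintf("  TP: %d of %d held-out   precision: %.4f   recall: %.4f   F1: %.4f\n",
              x$tp, x$n_test, x$precision, x$recall, x$f1))
  invisible(x)
}
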