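#' Generate a synthetic heterogeneous network with planted associations
#'
#' Emulates the statistical structure the scorer assumes: bipartite
#' evidence layers drawn i.i.d. Bernoulli, and lncRNA--disease
#' associations planted preferentially where common miRNA/gene neighbors
#' exist.  Each cross-layer edge (miRNA--lncRNA, miRNA--disease,
#' gene--lncRNA, gene--disease, gene--miRNA) is drawn with probability
#' `layer_density`; each (lncRNA, disease) pair with `k` common miRNA or
#' gene neighbors becomes a known association with probability
#' `plogis(plant_intercept + plant_slope * k)`.  With `plant_slope = 0`
#' the associations are independent of the evidence layers (null model,
#' expected LOOCV AUC 0.5).  Diseases receive one 2-level MeSH-style tree
#' number under one of four root codes, so diseases sharing a root are
#' semantically similar.
#'
#' @param n_l,n_d,n_m,n_g node counts (lncRNAs, diseases, miRNAs, genes);
#'   `n_g = 0` generates a purely tripartite network.
#' @param layer_density Bernoulli edge probability of the evidence
#'   layers, in [0, 1].
#' @param plant_intercept,plant_slope logistic planting coefficients.
#' @param seed integer seed; the same parameters and seed reproduce the
#'   network exactly.
#' @return An object of class `nbclda_sim`: list with `network` (a
#'   [hetnet()], GN2 mode when `n_g > 0` else GN1), `ontology` (a
#'   [disease_ontology()]), `truth` (data frame of planted lncRNA--disease
#'   edges) and `params`.
#' @examples
#' sim <- simulate_hetnet(n_l = 12, n_d = 10, n_m = 8, n_g = 5, seed = 42)
#' sim$network
#' @export
simulate_hetnet <- function(n_l = 40, n_d = 30, n_m = 25, n_g = 15,
                            layer_density = 0.1,
                            plant_intercept = -3, plant_slope = 1.2,
                            seed = 1) {
  stopifnot(n_l >= 1, n_d >= 1, n_m >= 1, n_g >= 0,
            layer_density >= 0, layer_density <= 1,
            is.numeric(seed), length(seed) == 1L)
  pad <- function(prefix, n)
    sprintf("%s%0*d", prefix, max(2L, nchar(n)), seq_len(n))
  lnc <- pad("l", n_l); dis <- pad("d", n_d)
  mir <- pad("m", n_m); gen <- if (n_g > 0) pad("g", n_g) else character()
  .with_seed(seed, {
    bern <- function(nr, nc, p, rn, cn)
      matrix(stats::rbinom(nr * nc, 1L, p), nr, nc, dimnames = list(rn, cn))
    a_ml <- bern(n_m, n_l, layer_density, mir, lnc)
    a_md <- bern(n_m, n_d, layer_density, mir, dis)
    if (n_g > 0) {
      a_gl <- bern(n_g, n_l, layer_density, gen, lnc)
      a_gd <- bern(n_g, n_d, layer_density, gen, dis)
      a_gm <- bern(n_g, n_m, layer_density, gen, mir)
    }
    k <- crossprod(a_ml, a_md)
    if (n_g > 0) k <- k + crossprod(a_gl, a_gd)
    y <- matrix(stats::rbinom(n_l * n_d, 1L,
                              stats::plogis(plant_intercept + plant_slope * k)),
                n_l, n_d, dimnames = list(lnc, dis))
    roots <- c("C04", "C06", "C10", "C14")
    dis_root <- sample(roots, n_d, replace = TRUE)
    ## assigned after the draws so the planting RNG stream is unaffected
    tree <- paste0(dis_root, ".", sprintf("%03d", seq_len(n_d)))
  })
  as_es <- function(mat, lk, rk) {
    idx <- which(mat > 0, arr.ind = TRUE)
    edge_set(rownames(mat)[idx[, 1L]], colnames(mat)[idx[, 2L]], lk, rk)
  }
  mdn <- as_es(a_md, "miRNA", "disease")
  mln <- as_es(a_ml, "miRNA", "lncRNA")
  ldn <- as_es(y, "lncRNA", "disease")
  network <- if (n_g > 0)
    assemble_gn2(assemble_gn1(mdn, mln, ldn),
                 gdn = as_es(a_gd, "gene", "disease"),
                 gln = as_es(a_gl, "gene", "lncRNA"),
                 gmn = as_es(a_gm, "gene", "miRNA"))
  else assemble_gn1(mdn, mln, ldn)
  ontology <- disease_ontology(stats::setNames(as.list(tree), dis))
  structure(list(network = network, ontology = ontology,
                 truth = ldn$edges,
                 params = list(n_l = n_l, n_d = n_d, n_m = n_m, n_g = n_g,
                               layer_density = layer_density,
                               plant_intercept = plant_intercept,
                               plant_slope = plant_slope, seed = seed)),
            class = "nbclda_sim")
}

#' @export
print.nbclda_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<nbclda_sim> seed %s: %d lncRNAs, %d diseases, %d miRNAs, %d genes\n",
    format(p$seed), p$n_l, p$n_d, p$n_m, p$n_g))
  cat(sprintf("  planted associations: %d (logistic %g + %g * k)\n",
              nrow(x$truth), p$plant_intercept, p$plant_slope))
  invisible(x)
}

#' Write a simulated network as edge-list and MeSH TSV files
#'
#' Emits the same formats the readers consume: `mdn.tsv`, `mln.tsv`,
#' `ldn.tsv` (plus `gdn.tsv`, `gln.tsv`, `gmn.tsv` when genes are
#' present), `mesh.tsv`, and `truth.tsv` (the planted associations).
#'
#' @param sim an `nbclda_sim` from [simulate_hetnet()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_hetnet <- function(sim, dir) {
  stopifnot(inherits(sim, "nbclda_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- sim$network
  paths <- c(mdn = "mdn.tsv", mln = "mln.tsv", ldn = "ldn.tsv")
  if (net$mode == "GN2")
    paths <- c(paths, gdn = "gdn.tsv", gln = "gln.tsv", gmn = "gmn.tsv")
  for (nm in names(paths))
    write_edge_list(net[[nm]], file.path(dir, paths[[nm]]))
  tn <- sim$ontology$tree_numbers
  mesh_lines <- c("disease\ttree_number",
                  unlist(lapply(names(tn), function(d)
                    paste(d, tn[[d]], sep = "\t")), use.names = FALSE))
  writeLines(mesh_lines, file.path(dir, "mesh.tsv"), useBytes = TRUE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, mesh = "mesh.tsv", truth = "truth.tsv")
  invisible(stats::setNames(file.path(dir, paths), names(paths)))
}
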