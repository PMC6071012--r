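#' Worked toy networks
#'
#' Two tiny hand-checkable networks used throughout the documentation and
#' tests.  `toy_gn1()` is a tripartite network with two lncRNAs, two
#' diseases and one miRNA (one known association, so `p1 = 1/4` and
#' `phi = 1/3`); the pair (l2, d2) has the single common neighbor m1 and
#' raw score 0.5.  `toy_gn2()` appends one gene linked to l2, d2 and m1,
#' so (l2, d2) gains a miRNA--gene pair feature and again scores 0.5.
#'
#' @return A [hetnet()] in GN1 or GN2 mode.
#' @examples
#' score_pair(toy_gn1(), "l2", "d2")
#' score_pair(toy_gn2(), "l2", "d2")
#' @export
toy_gn1 <- function() {
  assemble_gn1(
    mdn = edge_set(c("m1", "m1"), c("d1", "d2"), "miRNA", "disease"),
    mln = edge_set(c("m1", "m1"), c("l1", "l2"), "miRNA", "lncRNA"),
    ldn = edge_set("l1", "d1", "lncRNA", "disease"))
}

#' @rdname toy_gn1
#' @export
toy_gn2 <- function() {
  assemble_gn2(
    toy_gn1(),
    gdn = edge_set("g1", "d2", "gene", "disease"),
    gln = edge_set("g1", "l2", "gene", "lncRNA"),
    gmn = edge_set("g1", "m1", "gene", "miRNA"))
}
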