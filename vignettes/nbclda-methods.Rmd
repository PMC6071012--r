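---
title: "Scoring lncRNA-disease associations by naive Bayesian common neighbors"
author: "nbclda authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring lncRNA-disease associations by naive Bayesian common neighbors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbclda)
```

## The inference problem

Known lncRNA-disease associations (the LDN layer) are few; the
surrounding evidence layers — miRNA-disease (MDN), miRNA-lncRNA (MLN)
and, in the quadruple network, gene-disease (GDN), gene-lncRNA (GLN) and
gene-miRNA (GMN) — are much denser.  The working hypothesis is that an
lncRNA and a disease that share many neighbors in these layers are
likely to be associated.  `nbclda` turns that hypothesis into a
calibrated probabilistic ranking.

## The model

Treat the existence of an edge between lncRNA $l_i$ and disease $d_j$ as
the class variable and the pair's common neighbors as features.  With
$|M_c|$ known associations among $n \times r$ possible pairs, the prior
is $p_1 = |M_c| / (nr)$ and the prior odds $\phi = p_1/(1-p_1)$.  Under
the naive conditional-independence assumption the posterior odds factor
over the common neighbors, and after expressing each conditional through
per-feature association counts the score has the closed form

$$S(l_i,d_j) \;=\; \phi \prod_{f \in CN(l_i,d_j)}
  \phi^{-1}\,\frac{N_f^+ + 1}{N_f^- + 1},$$

where $N_f^+$ counts the known associations that have $f$ as a common
neighbor, $N_f^- = N_l N_d - N_f^+$ the unknown ones ($N_l$, $N_d$ the
numbers of lncRNAs and diseases adjacent to $f$), and the $+1$ terms are
the Laplace calibration that keeps every factor positive even when
$N_f^+ = 0$.  The identity $N_f^+ + N_f^- = N_l N_d$ is asserted inside
the scorer on every evaluation.

On the tripartite network all features are miRNAs.  On the quadruple
network common-neighbor genes join the feature set, with one refinement:
a common-neighbor miRNA and gene that themselves interact (a GMN edge)
are clearly not conditionally independent, so they fuse into a single
miRNA-gene *pair* feature whose adjacency means adjacency to both
members.  Two choices here were genuinely open and are fixed as package
policy:

* **One $\phi^{-1}$ per feature.**  Each feature — miRNA, gene or pair —
  contributes exactly one $\phi^{-1}$ factor, so a pair (the cell's
  feature count) of $k$ features scores $\phi^{1-k}\prod_f
  (N_f^++1)/(N_f^-+1)$.  Any bookkeeping that ties the power of $\phi$
  to a product over feature *combinations* would make the score depend
  on how the product is indexed rather than on the evidence; the
  per-feature form is the one consistent with the derivation from the
  posterior-odds factorization.
* **All connected combinations become pairs.**  When one miRNA interacts
  with several common-neighbor genes (or vice versa), every connected
  (miRNA, gene) combination becomes a pair feature, and a node covered
  by at least one pair never re-appears as a singleton.  This rule is
  deterministic and order-independent, unlike a maximal matching, which
  would depend on tie-breaking.

Raw odds span orders of magnitude, so ranking and downstream combination
use $S' = \ln(S)/\lambda$.  The base of the logarithm and the value of
$\lambda > 0$ only rescale, never re-rank (a property the test suite
checks exactly), so the package uses the natural log and defaults to
`lambda = "auto"`, the largest $|\ln S|$ over positive entries, which
maps all scores into $[-1, 1]$.  A fixed $\lambda$ can be supplied to
reproduce external score scales.  $S = 0$ can occur only when there are
no known associations at all ($\phi = 0$); such entries are mapped one
unit below the smallest finite normalized score so they rank strictly
last.

## Disease semantic similarity

Each disease maps to MeSH tree numbers; every dotted prefix of a tree
number is an ancestor position, and the prefix chains form the disease's
DAG.  An ancestor at minimum hop distance $h$ contributes $\Delta^h$
(maximum over paths when several apply); the semantic value $DV$ is the
sum of contributions, and

$$SD(d_i,d_j) = \frac{\sum_{t \in T_i \cap T_j} (D_i(t) + D_j(t))}
  {DV(d_i) + DV(d_j)}.$$

$\Delta$ defaults to 0.5, the standard decay used with this family of
DAG measures; it is exposed as `delta` everywhere.  Two implementation
choices deserve note:

* **Node identity is the tree-number string.**  The same MeSH heading
  sitting at two tree positions counts as two nodes, because the input
  format supplies positions only, with no heading-merging table.  With a
  merged-heading table the similarity of multi-position diseases would
  change slightly.
* **Combination is a disease-space matrix product**, $S = S' \times SD$:
  each disease column of the final score is the similarity-weighted sum
  of normalized scores across all diseases, i.e. evidence is smoothed
  over semantically close diseases.  The alternative reading — an
  element-wise weight $S'(l,d)\,SD(d,\cdot)$ — needs a second disease
  argument that the combination rule does not have, and with an identity
  $SD$ the product is an exact no-op, which is the natural degenerate
  behavior.  Diseases missing from MeSH get identity rows, so their
  columns pass through unchanged.

## Evaluation protocols

**Leave-one-out cross-validation.**  Each known association is held out
in turn, and *every* quantity — the prior, all $N^+$/$N^-$ counts, the
normalization — is recomputed without it, so no test label leaks into
training.  The held-out pair is ranked against the candidate pairs not
in the training positives.  Candidates are global (all lncRNA x disease
cells) by default: with sparse LDN layers, per-disease candidate sets
leave many rounds with a handful of negatives and make the AUC
estimate noisy.  `per_disease = TRUE` switches to column-restricted
candidates for comparison with protocols defined that way.  Ties get
half credit (the Mann-Whitney convention), the round AUC is the
fraction of negatives ranked below the positive, and the report AUC is
the mean over rounds.  Because the AUC is rank-based it is exactly
invariant to $\lambda$ and to any strictly increasing transform of the
scores.

**Top-k F1.**  A seeded 20% sample of the known associations forms the
training set; all non-training pairs are scored and the top $k$ (ties
broken by lncRNA then disease name, the same deterministic order the
score writer uses) are the predictions; precision is TP$/k$ and recall
is TP over the held-out positives.

## The synthetic study conditions

`simulate_hetnet()` generates the conditions every stochastic test runs
under: each evidence layer is i.i.d. Bernoulli with `layer_density =
0.1` over 40 lncRNAs, 30 diseases, 25 miRNAs and 15 genes, and each
(lncRNA, disease) pair with $k$ common miRNA/gene neighbors becomes a
known association with probability $\mathrm{logit}^{-1}(-3 + 1.2k)$.
The logistic planting guarantees learnable signal that is a monotone
function of shared-neighbor evidence *without* encoding the scoring
formula itself, so a high AUC is not self-confirmation.  Setting
`plant_slope = 0` yields the chance control.  Each disease receives one
two-level tree number under one of four root codes (roots drawn
uniformly); four roots give non-trivial root-sharing groups at 30
diseases while keeping cross-family similarity zero.

What the generator does *not* emulate: the heavy-tailed degree
distributions of curated interaction databases, correlated evidence
layers, name-curation noise, and — importantly — an ontology that is
*informative* about the planted signal.  The generated tree numbers are
independent of the planted edges, so semantic-similarity re-weighting
adds smoothing noise on synthetic data and typically lowers the
synthetic AUC slightly; on curated data, where diseases with similar
MeSH ancestry really do share lncRNAs, the same smoothing is the step
that helps.  Passing tests therefore demonstrate correctness of the
machinery and recovery of neighbor-borne signal, not a performance
forecast for any particular curated corpus.

## Numerical and degenerate-input choices

* All score accumulation happens in log space; the vectorized scorer
  accumulates per-feature log odds through the incidence matrices and
  recomputes exactly (pair-aware) only the cells where a GMN edge joins
  two common neighbors.  It agrees with the per-pair scorer to within
  floating-point round-off, which the suite checks at $10^{-12}$
  relative tolerance against a brute-force enumeration oracle.
* Registries are lexicographically sorted unions of edge endpoints, so
  matrix layouts, tie-breaks and output files are reproducible
  byte-for-byte; all sampling funnels through one integer seed.
* A network with no known associations scores 0 everywhere (documented
  limit, not an error); a network with an empty lncRNA or disease
  registry is a domain error.
* Node identity is exact string match after trimming outer whitespace;
  no alias resolution is attempted, and a reversed edge in a kind-typed
  file is rejected rather than silently flipped, since silent flipping
  hides curation errors.
* $|M| = nr$ uses the full registries, including lncRNAs and diseases
  that appear only in the LDN layer.

## Problem sizes

The default test suite scores hundreds of random networks of up to 6
lncRNAs, 6 diseases, 5 miRNAs and 4 genes against the enumeration
oracle, and runs full LOOCV on 10 replicate generator networks (about
1,100 rounds) for the signal-recovery and null checks; the acceptance
script uses the same 10-replicate design.  These sizes give
Monte-Carlo standard errors below 0.01 AUC while keeping a full run in
well under a minute of CPU — they are the package's chosen study scale,
and all of them rise gracefully if larger networks are supplied.

## Known limitations

* The scorer uses dense incidence matrices; at curated-corpus scale
  (thousands of lncRNAs) memory grows as $n \times r$ matrices, which
  is still modest, but very large registries would warrant sparse
  algebra.
* Pair features are the only dependence correction; higher-order
  dependence among common neighbors (two interacting miRNAs, say) is
  ignored by construction of the naive model.
* Semantic similarity treats tree positions, not merged MeSH headings
  (see above), and diseases without tree numbers fall back to identity
  similarity.
* LOOCV recomputes all counts per round; the cost is linear in the
  number of known associations times the scoring cost, which is the
  honest price of leakage-free evaluation.
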