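---
title: "Graph regression for lncRNA-disease association prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph regression for lncRNA-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gruf)
```

## The problem

Most long non-coding RNAs have no experimentally established disease
association, and many diseases have no known lncRNA partner. Beyond the
usual binary question ("is this pair associated?") the association carries
structure worth predicting: how many RNA-binding proteins (and their coding
genes) mediate it (a *discrete* association) and how strong it is (a
*continued*, real-valued intensity). `gruf` implements a unified
graph-regression model that handles four scenarios at once:

* **T1** — new pairs among lncRNAs and diseases that both have other known
  associations;
* **T2** — a new lncRNA with no known disease association (cold start on
  rows);
* **T3** — a new disease with no known lncRNA association (cold start on
  columns);
* **T4** — both sides new (double cold start).

## The model

Three graphs enter: the association graph with m x n matrix $A$, the lncRNA
similarity graph with symmetric matrix $S_r$, and the disease similarity
graph with $S_d$. The objective couples three low-rank decompositions with
two regressions:

$$\min \|A - A_r A_d^T\|_F^2 + \|S_r - F_r F_r^T\|_F^2 +
      \|S_d - F_d F_d^T\|_F^2 + \|A_r - F_r B_r\|_F^2 +
      \|A_d - F_d B_d\|_F^2$$

The five terms are treated as independent and minimised in order:

1. $A_r$ (m x r) and $A_d$ (n x r) come from the truncated SVD
   $A = U\Sigma V^T$ as $U\sqrt\Sigma$ and $V\sqrt\Sigma$ — the
   *associating* embeddings.
2. $F_r$ (m x p) and $F_d$ (n x q) come from the symmetric
   eigendecomposition of $S_r$ and $S_d$, again as $U\sqrt{\Lambda^+}$ —
   the *latent feature* embeddings. Because $1/(1+\mathrm{dist})$
   similarity matrices are not guaranteed positive semi-definite, negative
   eigenvalues are clipped to zero before the square root.
3. $B_r$ (p x r) and $B_d$ (q x r) are multi-response partial least-squares
   regressions of the associating embeddings on the latent features. The
   predictors of step 4 have no intercept, so the PLS is run *uncentered*
   and unscaled (NIPALS, implemented in the package; convergence tolerance
   1e-12, early stop when the predictor matrix deflates to numerical zero).

With the bi-regression matrix $\Theta = B_r B_d^T$ the four predictors are

$$\tilde A_{T1} = F_r \Theta F_d^T,\quad
  \tilde A_{T2} = F_{r,x} \Theta F_d^T,\quad
  \tilde A_{T3} = F_r \Theta F_{d,y}^T,\quad
  \tilde A_{T4} = F_{r,x} \Theta F_{d,y}^T,$$

where $F_{r,x}$ and $F_{d,y}$ are latent vectors of *new* entities. The
model never states how these are obtained from similarities alone; we use
the Nyström out-of-sample projection $F_{r,x} = s_x U \Sigma^{-1/2}$ over
the retained spectrum, which has the exact property that projecting a
training entity's own similarity row reproduces its latent row.

Determinism across linear-algebra backends is enforced by a sign
convention: the largest-magnitude entry of each singular/eigen vector is
made non-negative (flipping the paired right vector along with it).

## Building the three association variants

From a binary lncRNA x protein interaction matrix $A_{rp}$ and a binary
gene x disease matrix $A_{gd}$ (gene and protein naming the same object;
the shared namespace is the intersection of the two id sets, everything
else dropped with a warning):

* binary: $a^b(i,j) = 1$ iff lncRNA i and disease j share at least one
  gene;
* discrete: $a^d(i,j)$ = number of shared genes; binarising it reproduces
  the binary matrix exactly;
* continued: $A^c = A_{rp} S_P A_{gd}$ with $S_P$ the protein similarity —
  every shared-gene path weighted by how similar the proteins are. With
  $S_P = I$ this degenerates exactly to the discrete count. The raw
  product is reported without rescaling; the product formula can in
  principle push pairs that share no gene above 1 when $S_P$ has large
  off-diagonal entries, so any thresholding is left to the caller.

## Similarity measurement

* **lncRNA**: the sequence is split left-to-right into 35 segments of
  near-equal length (the first `L mod 35` segments one residue longer),
  4-mer frequencies are computed per segment (overlapping windows, step 1,
  each block summing to 1) and concatenated: 35 x 4^4 = 8960 dimensions.
  Per-segment normalisation is an explicit choice; the alternative (global
  normalisation) is not what "calculating 4-mer features separately"
  suggests. Features are then z-scored per column (sample sd, zero-variance
  columns to zero rather than NaN), projected by PCA dropping components
  whose singular value is below 1e-10 of the largest (a relative reading of
  "dimensions that are zero within numerical accuracy"), and turned into
  similarities by $1/(1+\mathrm{dist})$.
* **protein**: residues are mapped onto 7 physico-chemical groups
  ({A,G,V}, {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W}, {R,K}, {D,E}, {C}), and 3-mer
  frequencies on the encoded sequence give 343 dimensions, then the same
  z-score / PCA / kernel pipeline.
* **disease**: each disease is a DAG — its MeSH descriptors plus all
  ancestors, with minimum-hop depths. A node at depth k contributes
  decay^k (decay = 0.5 by default, configurable; the decay form follows
  the standard semantic-similarity construction this model delegates to),
  and two diseases score the shared contribution relative to their total.
  When no explicit hierarchy is supplied, ancestry is derived from
  dot-prefix truncation of the tree numbers themselves
  (C04.588.180 → C04.588 → C04). Disjoint DAGs score exactly 0, so the
  disease similarity matrix lives in [0, 1] rather than (0, 1]; the ICD
  same-category fallback (1 if same category else 0) shares that range.

## Cross-validation protocol

`makeCvPlan()` partitions the task's unit — entries (T1), rows (T2),
columns (T3) — into K folds of sizes differing by at most one,
deterministically per seed. T4 crosses K row-folds with K column-folds
into K^2 fold pairs; within a pair only the test-row x test-column block
is tested, only the train x train block trains, and the two mixed blocks
are excluded from both, so no training entry shares a row or column with a
test entry. Standard K rounds are run (each fold tested once). For T1 the
test entries are set to 0 in the training matrix — the factorisation needs
a complete matrix and 0 encodes "no known association"; leave-one-out is
K = number of units.

Metrics: AUC as the midrank Mann-Whitney statistic (ties count one half);
AUPR by step-curve summation without interpolation, with equal-scored
items forming a single threshold block; and *Correlation* — Pearson by
default (Spearman behind a flag) — between predicted scores and the
association intensity. By default the correlation truth is the evaluated
matrix's own values; for comparing variants the `intensityTruth` argument
supplies a common truth (the shared-protein counts, or the continued
intensities), which is how the continued > discrete > binary ordering is
measured. Folds whose test labels are single-class are skipped with a
warning. Aggregation is fold-averaged by default, entry-pooled behind a
flag.

## The planted-data generator

`generatePlantedDataset()` emulates the premise the model exploits —
similar entities associate similarly — at an arbitrary scale, with every
artifact drawn from its own derived seed so outputs are bit-reproducible
and adding a stage never perturbs another:

* latent vectors for lncRNAs, genes and diseases (`latentDim`, standard
  normal);
* bipartite interactions by thresholding the bilinear scores $H_r H_g^T$
  and $H_g H_d^T$ at the `interactionDensity` quantile (default 0.02,
  matching the sparse regime of curated interaction sets, and yielding a
  binary association density near 3% at the reference scale m = 60,
  g = 40, n = 80 — real curated lncRNA-disease matrices sit at a few
  percent);
* similarities as $1/(1+\mathrm{dist})$ kernels on the latent vectors
  after adding isotropic Gaussian noise of sd `noiseSd` (0 = fully
  informative side information; at 10x the unit signal the similarities
  carry essentially no geometry);
* the three association variants built through the association-builder
  operations, so their mutual identities hold by construction;
* sequences drawn from family-specific composition profiles, so k-mer
  similarity separates families in expectation.

What the generator does *not* emulate: real lncRNA composition biases,
actual MeSH content, curation biases, or any dependence between sequence
families and the planted association structure — the sequences exercise
the featurisation code, they do not drive the planted associations. A
recovery experiment passing on planted data therefore shows the algebra
and the protocol are right, not that the biology of a particular dataset
will behave as well.

## Analysis configuration and numerical choices

The model never prescribes the ranks (r, p, q) or the PLS component count.
Defaults retain every singular/eigen value above 1e-10 of the largest and
use min(p, r) components. For the *recovery experiments* on planted data
(tests and the acceptance script) we fix r = 12, p = q = 16,
8 components at the reference scale: the associating rank about twice the
planted latent dimension (the thresholded construction adds overtones
beyond the planted rank), the feature ranks about three times it, and the
component count below r so that the similarity geometry — not the
zero-filled training matrix — regularises the regression.

That trade-off deserves a remark. The T1 predictor mixes two information
routes: smoothing through the similarity embeddings, and plain
reconstruction of the zero-filled training matrix through the regression
fit. At large p, q the second route dominates: held-out T1 AUC rises (the
model becomes a zero-fill SVD completer) but becomes insensitive to
similarity quality, so destroying the similarities no longer destroys T1
performance. At moderate p, q the similarity geometry carries the
prediction and noise degrades it monotonically, at the cost of a slightly
lower clean-data ceiling (about 0.95-0.99 AUC across generator seeds at
the reference scale). We use the similarity-dominant configuration because
it reflects what the method is for.

Other numerical choices: ridge shrinkage of $B_r$, $B_d$ is available as
an escape hatch for degenerate spectra but off by default (the objective
omits regularisation terms); RNA FASTA input maps T to U and uppercases;
zero-variance feature columns become zero, keeping distances finite;
problem sizes in the tests (m = 60, g = 40, n = 80 for recovery, smaller
for unit tests) keep the whole suite fast while leaving every code path
exercised.

## Known limitations

* The "simple solution" minimises the five objective terms independently;
  no joint or alternating optimisation is attempted, matching the model's
  own presentation.
* Continued intensities are raw products; their "entries >= 1 mark known
  associations" reading is emergent, not enforced.
* The Nyström projection assumes the similarity matrix restricted to
  training entities is well approximated by its retained spectrum; heavily
  indefinite similarity matrices lose the part of the geometry carried by
  clipped negative eigenvalues.
* MeSH semantic similarity implements the decay form only; information
  content variants (Resnik/Lin) are out of scope, as is parsing official
  MeSH XML.
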