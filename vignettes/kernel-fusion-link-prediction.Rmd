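---
title: "Multiple-kernel Kronecker RLS for miRNA-disease association prediction"
author: "kronMKL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-kernel Kronecker RLS for miRNA-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kronMKL)
```

## The problem

Experimentally confirmed miRNA-disease associations form a sparse bipartite
network: a binary matrix $A \in \{0,1\}^{n_m \times n_d}$ with rows indexed
by miRNAs and columns by diseases (this orientation is fixed package-wide).
The prediction task is to score every unobserved pair so that true but
unrecorded associations rank above non-associations. The working assumption
is the usual one in this field: functionally similar miRNAs tend to be
associated with phenotypically similar diseases, so similarity structure on
each side carries information about missing links.

Both sides come with *several* heterogeneous similarity sources — semantic
similarity derived from disease term hierarchies, a curated (and only
partially available) miRNA functional similarity matrix, and topology-driven
interaction-profile kernels — and none of them is uniformly best. The
package therefore learns a convex combination of base kernels on each side
jointly with the predictor.

## Base kernels

**DAG semantic similarity, contribution model 1.** Each disease $D$ is
described by the DAG of its ancestor terms (MeSH-descriptor style; a disease
listed under several tree positions contributes the union of its ancestor
paths — the semantic value below sums over the term *set*, so union is the
natural merge). The disease itself contributes 1 and a term $t$ contributes
$\Delta \cdot \max\{\text{contribution of its children}\}$, so contributions
decay geometrically with distance and terms in the same layer contribute
equally. With $DV(D)$ the sum of contributions over $T(D)$,

$$SS1(i,j) = \frac{\sum_{t \in T(i) \cap T(j)} \big(D1_i(t) + D1_j(t)\big)}
                 {DV1(i) + DV1(j)},$$

so diseases sharing a larger part of their DAGs score higher; the diagonal
is exactly 1. The contribution factor defaults to $\Delta = 0.5$ (the
convention of the established disease-similarity literature; it is
configurable and was not revisited).

**Contribution model 2.** Specific terms should matter more than ubiquitous
ones: a term present in $DAG_t$ of the $n_d$ disease DAGs contributes
$-\log(DAG_t / n_d)$, identically for every disease containing it. The
logarithm is natural; only ratios of contributions enter the similarity, so
the base is a global constant that must simply be fixed once for
reproducibility. The per-disease semantic value under model 2 is defined by
analogy as the sum of its model-2 contributions. A disease all of whose
terms are ubiquitous has semantic value 0; its diagonal entry is set to 1 by
convention with a warning.

**Gaussian interaction-profile kernels.** The profile of a disease is its
column of $A$, that of a miRNA its row, and

$$GD(i,j) = \exp(-\gamma_d \, \lVert IP(i) - IP(j)\rVert^2), \qquad
\gamma_d = \gamma'_d \Big/ \frac{1}{n_d}\sum_i \lVert IP(i)\rVert^2 ,$$

i.e. the raw bandwidth is normalized by the mean number of known
associations per entity (profiles are binary, so squared norms count
associations). $\gamma'_d = \gamma'_m = 1$ by default, the value established
for interaction-profile kernels in prior link-prediction work. Entities with
an all-zero profile are legal inputs (new diseases or miRNAs); only an
entirely empty $A$ leaves the bandwidth undefined and errors.

**Partial functional similarity.** A curated miRNA functional similarity
matrix typically covers only a subset of the miRNAs in the association
table. `integrateMirnaSimilarity()` fills the uncovered entries with the
Gaussian profile kernel value, yielding one full-size kernel.

**Kernel hygiene.** The solver requires positive semidefinite side kernels.
Semantic and functional matrices carry no such guarantee, so
`repairKernel()` clips negative eigenvalues (default) or shifts the diagonal
by $|\lambda_{\min}| + 10^{-8}$, then cosine-normalizes
$K_{ij}/\sqrt{K_{ii}K_{jj}}$ back to a unit diagonal, recording
$\lambda_{\min}$ before repair. Gaussian kernels are PSD by construction and
skip repair. Similarity denominators (the $DV$ terms) always use the raw,
unrepaired contributions; repair applies to the assembled matrix afterwards.

## The single-kernel solver

With side kernels $K_D$ and $K_M$, every (miRNA, disease) pair is a training
example with label $A_{ij}$ and the pairwise kernel is the Kronecker product
$K = K_D \otimes K_M$. Regularized least squares solves
$(K + \lambda I)\,\alpha = \mathrm{vec}(Y)$, but materializing $K$ costs
$O((n_m n_d)^2)$ memory and $O((n_m n_d)^3)$ time. Using the
eigendecompositions $K_M = Q_M \Lambda_M Q_M^\top$,
$K_D = Q_D \Lambda_D Q_D^\top$ and the fact that eigenvalues and
eigenvectors of a Kronecker product are Kronecker products of the factors',

$$F = Q_M \big[ H \circ (Q_M^\top Y Q_D) \big] Q_D^\top, \qquad
H_{ab} = \frac{\lambda^M_a \lambda^D_b}{\lambda^M_a \lambda^D_b + \lambda},$$

which costs two small eigendecompositions and a few dense products.
`fitKronRLS()` implements this route; `fitKronRLSDirect()` materializes the
Kronecker system (guarded to $n_m n_d \le 2000$) and exists purely as the
independent oracle — the test suite pins the fast route to it entrywise at
$10^{-8}$ on random instances, which also settles any transposition
ambiguity in the factored formula once and for all.

Numerical choices: eigenvalues are returned ascending; downstream results
are invariant to eigenvector sign (tested). A denominator
$\lambda^M_a \lambda^D_b + \lambda \le 10^{-12}$ is an *error* directing the
user to `repairKernel()`, never a silent clamp — clamping would mask an
unrepaired indefinite kernel. Decompositions are cached under a content hash
of the kernel matrix, so sweeping $\lambda$ or iterating the optimizer never
recomputes them.

## Learning the kernel weights

Each side's kernel is a convex combination
$K_D^* = \sum_i \beta_D^i K_D^i$, $K_M^* = \sum_j \beta_M^j K_M^j$ with
simplex weights. Optimization alternates, starting from the mean kernel
(uniform weights) on both sides: solve the dual on the current combination;
update $\beta_D$ with $K_M^*$ fixed; re-solve; update $\beta_M$; re-solve.
A proposed weight update that would increase the regularized objective

$$J = \tfrac{1}{2n}\lVert \mathrm{vec}(Y) - \mathrm{vec}(F)\rVert^2
    + \tfrac{\lambda}{2}\,\langle \alpha, F\rangle$$

is rejected and that side is frozen for the remainder, so the recorded
objective trace is non-increasing by construction (asserted on every fit).
The loop stops on a relative objective decrease below `relTol` ($10^{-4}$),
when both sides freeze, or after `maxOuterIters` (50) cycles — values chosen
so toy problems converge within a handful of cycles.

**The weight update.** For each base kernel on the active side a response
matrix is formed by pushing the current dual coefficients through that
kernel alone ($U_i = K_M^i \,\alpha\, K_D^*$ on the miRNA side, analogously
for diseases), and the weights solve the small ridge system
$\min_\beta \lVert \mathrm{vec}(Y) - \sum_i \beta_i\, \mathrm{vec}(U_i)
\rVert^2 + \sigma \lVert \beta \rVert^2$, followed by clipping at zero and
renormalization to the simplex (if everything clips, the incoming weights
are kept; identical response matrices also keep the incoming weights, since
the objective is then flat in $\beta$). The update is isolated in
`updateKernelWeights()` so an alternative rule can be swapped in.

Two design findings are worth recording, because the obvious alternatives
fail in instructive ways:

* *Exact coordinate descent degenerates.* With $\alpha$ fixed the RKHS
  penalty $\frac{\lambda}{2}\alpha^\top K(\beta)\alpha$ is linear in
  $\beta$, so the true objective can be minimized over the simplex exactly.
  Doing so drives all weight onto the kernel *least* aligned with the
  labels whenever $\lambda$ is moderate — shrinking the kernel is the
  cheapest way to cut the penalty. Risk minimization over the kernel itself
  is not a sound kernel-selection criterion here, which is exactly why the
  label-regression surrogate above is used.
* *The penalty center matters because of the renormalization.* After
  clip-and-renormalize, the large-$\sigma$ limit of the origin-centered
  ridge is the label-correlation direction, not the uniform vector; global
  shrinkage is undone by the normalization, and what survives is the
  *differential* shrinkage that suppresses weak response matrices. That
  differential shrinkage is precisely the mechanism that separates
  informative from noise kernels when $\lambda$ is small (where the data
  term alone is flat, because any simplex combination near-interpolates
  $Y$). The origin-centered penalty is therefore the default. A
  `penaltyCenter = "uniform"` variant is provided for the complementary
  behavior — its large-$\sigma$ limit is the mean-kernel combination — and
  both limits are asserted in the test suite.

**Weight identifiability and $\lambda$.** The grids follow the method's
convention: $\lambda \in \{2^{-15}, 2^{-10}, \ldots, 2^{30}\}$ and
$\sigma \in \{0, 0.25, 0.5, 0.75, 1\}$; defaults when no selection is
requested are the mid-grid $\lambda = 1$ and $\sigma = 0.25$.
`selectHyperparameters()` runs an inner cross-validation on training folds
only (never test entries), scoring by AUC. Two caveats, both visible in the
planted-data studies below: AUC is nearly scale-invariant in $\lambda$, so
ranking-based selection cannot pin $\lambda$ down; and at large $\lambda$
the regularizer dominates the training loss, so the monotone-objective gate
structurally rejects moves toward informative kernels and the weights stay
near uniform. Weight *interpretation* therefore requires the data term to
dominate: all planted-bundle analyses in this package (tests and the
acceptance script) use $\lambda = 2^{-5}$ from the grid's data-dominated
regime, with $\sigma = 0.25$. $\sigma = 0$ is permitted but errors on a
singular weight system rather than regularizing silently. The penalty is
applied to each side separately, and the dual is re-solved after each
side's update.

## Cross-validation protocols

* **Global leave-one-out**: every known association is zeroed in turn in a
  training copy and ranked against *all* unknown pairs of the original
  matrix. All leave-outs share that candidate set, so the pooled
  rank-threshold sweep equals the mean of the per-leave-out Mann-Whitney
  values, which is what `globalLoocv()` reports.
* **Local leave-one-out**: per disease, each known miRNA is left out and
  ranked only among that disease's candidate miRNAs; `localLoocv()` reports
  per-disease AUCs and their mean. Diseases with no known miRNA cannot be
  evaluated and are skipped with a warning.
* **Repeated k-fold** (`kfoldCv()`): the known associations are partitioned
  into $k$ near-equal groups (default $k = 5$), each masked in turn; the
  per-repeat AUC pools one full partition, and mean and SD over repeats are
  reported. The default is 5 repeats to keep routine runs fast; pass
  `repeats = 100` to average the partition noise down the way large-scale
  studies do.

Ties in ranking always receive average rank (0.5 credit), the standard
Mann-Whitney treatment. `rocAuc()` computes AUC by pair counting, which is
identical to trapezoidal integration of the returned ROC curve; the test
suite verifies both against a brute-force all-pairs oracle and against
pROC.

**Leakage.** Gaussian profile kernels are functions of $A$, so computing
them once on the full matrix leaks the held-out labels through the
interaction profiles. By default every fold rebuilds them from the masked
training matrix (`refold = TRUE` in the `KernelRecipe`); the cheaper leaky
variant is available as `refold = FALSE` for comparison, since published
protocols often do not say which was done. Fixed kernels (semantic,
functional) do not depend on $A$ and are shared across folds.

## The synthetic planted-structure generator

`makeLatentBundle()` draws latent factors $U$ ($n_m \times r$) and $V$
($n_d \times r$) from a standard normal stream, sets the true score matrix
$UV^\top$, and places the observed 1s at its top
$\lceil \text{density} \cdot n_m n_d \rceil$ entries (ties broken by
row-major index for determinism; the ceiling is computed with a $10^{-9}$
slack so an exactly integer product never rounds up). The informative
kernels are the cosine-normalized Gram matrices $UU^\top$ and $VV^\top$,
optionally corrupted by a convex mixture with a random PSD matrix
(`corruptKernel()`, mixing weight $\text{noise}/(1+\text{noise})$, followed
by clip repair); noise kernels are Gram matrices of independent factors.
Draws are namespaced — each component re-seeds from the bundle seed plus a
fixed offset — so adding a component can never silently shift existing
fixtures.

The default bundle (30 miRNAs x 20 diseases, rank 3, density 0.1, noiseless
informative kernels, one noise kernel per side) is the planted instance
used across the test suite and the acceptance script. These sizes keep a
full global leave-one-out run (one optimizer fit per known association)
around ten seconds, so the complete evaluation battery runs in minutes.
What the generator emulates is the *statistical* structure the method
relies on — low-rank association structure whose side similarities are
informative about missing links, contaminated by irrelevant kernels. What
it does not emulate: the degree distribution of curated association
databases (which is heavy-tailed), miRNA family/cluster structure,
correlated noise between kernels, or biased missingness (clinically
popular diseases are better annotated). Passing the planted-data checks
therefore demonstrates correctness of the machinery and recoverability of
planted signal, not real-data performance.

`makeToyDagCollection()` builds a shared random term tree and hangs each
disease under a random leaf, giving small DAG collections with exactly
known semantic similarities (e.g. two diseases under a common parent at
$\Delta = 0.5$ score exactly $1/3$).

## Degenerate inputs and edge cases

* A dataset whose matrix is all zeros: Gaussian bandwidth undefined, error.
* One known association: leave-one-out is meaningless, error.
* $\lambda = 0$ is allowed only when every eigenvalue product exceeds
  $10^{-12}$ (full-rank interpolation); otherwise the solver errors.
* A single base kernel per side reduces `fitMKL()` to `fitKronRLS()`
  within $10^{-12}$ (tested bitwise-level).
* Duplicate association rows collapse to one with a reported count;
  identifiers are matched case-insensitively after trimming, keeping the
  first-seen spelling.

## Limitations

The dense eigendecomposition solver scales as the cube of each side's size,
comfortable for curated association databases (hundreds of entities per
side) but not for tens of thousands; no sparse or low-rank approximations
are provided. The weight update is a surrogate, not exact coordinate
descent — convergence is guaranteed monotone by the reject-and-freeze rule
rather than by the update itself. Leave-one-out at database scale refits
the optimizer once per known association and is accordingly expensive;
k-fold with repeats is the practical protocol there. Verification of
predictions against external literature databases is out of scope.
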