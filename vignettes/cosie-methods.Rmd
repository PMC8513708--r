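---
title: "Joint spectral embedding of multiple networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint spectral embedding of multiple networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosie)
```

## The model

This package works with samples of undirected graphs $A^{(1)}, \dots,
A^{(m)}$ observed on the *same* set of $n$ labelled vertices — repeated
brain-connectivity scans registered to a common atlas, replicate
interaction networks, time slices of a contact network.  Each adjacency
matrix is binary, symmetric and hollow, with conditionally independent
edges: $A^{(i)}_{uv} \sim \mathrm{Bernoulli}(P^{(i)}_{uv})$.

The common subspace independent-edge (COSIE) model assumes the expected
adjacency matrices share a low-dimensional invariant subspace but are
otherwise free to differ:
$$ P^{(i)} = V R^{(i)} V^\top, \qquad i = 1, \dots, m, $$
where $V \in \mathbb{R}^{n \times d}$ has orthonormal columns and each
*score matrix* $R^{(i)} \in \mathbb{R}^{d \times d}$ is symmetric, with
every entry of $V R^{(i)} V^\top$ in $[0,1]$.  The rows of $V$ are joint
latent positions of the vertices; the score matrices encode how each graph
wires those positions together.  The parameter count is $O(nd + md^2)$
rather than $O(mn^2)$.

Two special cases anchor intuition.  An Erdős–Rényi graph $G(n, p)$ is the
rank-one model $V = n^{-1/2}\mathbf{1}$, $R = pn$.  A multilayer stochastic
blockmodel — a fixed partition of vertices into $K$ communities with
graph-specific $K \times K$ block connectivities $B^{(i)}$ — is a COSIE
model of dimension $d \le K$ (`sbm_to_cosie()` gives the explicit
construction; see below).  Importantly, $d$ can exceed the rank of any
individual graph: two rank-2 block matrices on three communities can
jointly span a rank-3 model, so communities invisible in any single graph
become identifiable from the collection.

**Identifiability.**  For any orthogonal $W$, $(VW,\, W^\top R^{(i)} W)$
induces the same $P^{(i)}$; $V$ is at best identifiable up to rotation
(and is, when the concatenation $(R^{(1)}, \dots, R^{(m)})$ has full
rank).  Pairwise distances $\|R^{(i)} - R^{(j)}\|_F$ *are* identifiable,
which is why downstream analyses here (testing, classification, scaling)
are built on them.  All comparisons with a ground truth first resolve the
rotation with `procrustes_align()`, or use the basis-free
`subspace_distance()` (norms of the difference of projection matrices).

## The estimator

`mase()` (multiple adjacency spectral embedding) estimates the model in
four steps:

1. embed each graph separately: the adjacency spectral embedding
   $\hat V^{(i)}$ is the matrix of the $d_i$ leading eigenvectors of
   $A^{(i)}$ by eigenvalue magnitude (`ase()`); optionally scaled by
   $|\hat D^{(i)}|^{1/2}$;
2. concatenate: $\hat U = (\hat V^{(1)} \cdots \hat V^{(m)})$, an
   $n \times \sum_i d_i$ matrix;
3. the estimate $\hat V$ is the $d$ leading left singular vectors of
   $\hat U$ — the SVD aligns the per-graph embeddings, each of which
   estimates the subspace only in its own rotated basis;
4. score matrices by least squares: $\hat R^{(i)} = \hat V^\top A^{(i)}
   \hat V$, the closed-form minimizer of $\|A^{(i)} - \hat V R \hat
   V^\top\|_F$ over symmetric $R$.

The crucial property, and the reason to prefer this over embedding the
mean adjacency matrix, is that the subspace error decreases with $m$ even
when every graph has a *different* score matrix.  Averaging adjacency
matrices instead estimates the subspace of the population-mean $P$, which
in a heterogeneous population can lose the block structure entirely; the
test suite reproduces this contrast (homogeneous vs heterogeneous
three-block populations at $n = 243$, $m \in \{1, 4, 16, 64\}$, 25
replicates, median spectral projection distance).

The error scale of the per-graph embeddings is summarized by
$\varepsilon = \tfrac1m \sum_i \delta(P^{(i)}) / \lambda_{\min}^2(R^{(i)})$
(`epsilon_stat()`), where $\delta(\cdot)$ is the maximum expected degree
(`delta_max_row_sum()`): dense graphs with well-conditioned score matrices
embed accurately, and the joint estimate inherits an averaged version of
this scale.

## Tunable parameters

* **`d` (joint dimension).**  The rank of the model; dimensionless, no
  default.  When omitted it is chosen by the profile-likelihood elbow of
  the singular values of $\hat U$ (`select_dim_elbow()`): candidate split
  points of the ordered values are scored by a two-mean, pooled-variance
  Gaussian likelihood, and the maximizing split is the elbow.  With
  `n_elbows > 1` the search recurses past the previous elbow; the deepest
  elbow is used by default, which in noisy spectra steps past the dominant
  gap to secondary structure.  Automatic selection is a heuristic — for
  scientific use inspect `plot(fit, "scree")`.
* **`d_i` (per-graph dimensions).**  Default: equal to `d` when `d` is
  given, otherwise per-graph elbows of the eigenvalue magnitudes.  Setting
  $d_i < d$ is legitimate: individual score matrices need not be full
  rank.
* **`scaled`.**  Unscaled embeddings (eigenvectors only) are the variant
  with supporting consistency theory and the default.  Scaling by
  $|\hat D|^{1/2}$ down-weights poorly estimated directions and can help
  when some $R^{(i)}$ are nearly singular; it is exposed as an option.
* **`diag_aug`.**  A hollow adjacency matrix underestimates its
  expectation on the diagonal, which propagates into the plug-in scores as
  a bias of roughly $-V^\top \mathrm{diag}(P)\, V$ — order
  $\mathrm{mean}(\mathrm{diag}(P))$, *constant in* $m$.  Degree-based
  diagonal augmentation ($A_{ss} \leftarrow \mathrm{deg}(s)/(n-1)$ before
  embedding and scoring) removes most of it; what remains is the gap
  between a vertex's mean connection probability and $P_{ss}$.  Off by
  default to keep the estimator exactly as defined; the eigenvalue-bias
  study in the tests turns it on, since without it the bias of eigenvalue
  estimates converges to the diagonal offset (about $0.4$ in the two-block
  $B = 0.3I + 0.1$ model at any $m$) rather than shrinking with the
  sample.

## Samplers and simulation scenarios

`simulate()` methods on model objects draw Bernoulli graphs from
$P^{(i)}$, upper triangle only, mirrored, zero diagonal.  Reproducibility
contract: one root seed; per-graph substream seeds are derived from it by
a counter, so graph $i$ is identical no matter how many other graphs are
drawn.  `sample_mmsbm()` draws mixed-membership models (Dirichlet rows on
the simplex; `Dir(0.1)` concentrates vertices near single communities
while retaining mixing).

`make_scenario()` packages the study designs used across the
documentation and tests, with their standard values built in: the
homogeneous and heterogeneous three-block populations ($n = 729$ by
default, balanced communities; fixed connectivity
$\bigl(\begin{smallmatrix}.4&.1&.1\\ .1&.4&.2\\ .1&.2&.3\end{smallmatrix}\bigr)$
or per-graph $\mathrm{U}(0,1)$ entries), the four-class two-block
population ($n = 256$, $m = 40$, ten graphs per class, class
connectivities $0.25 + \alpha C^{(k)}$ with $C^{(1)} = \mathrm{diag}(.1,
.1)$, $C^{(2)} = -\mathrm{diag}(.1,.1)$, $C^{(3)} = \mathrm{diag}(.1,0)$,
$C^{(4)} = \mathrm{diag}(0,.1)$ — $\alpha$ controls both class separation
and the smallest eigenvalue), and the two mixed-membership two-sample
testing scenarios (shared memberships with a shifted $B_{11}$; or equal
connectivity with the first $t$ memberships redrawn).  The testing
scenarios default to $n = 150$, the size at which the calibration and
power studies in the tests are run.

What the generator emulates: independent-edge noise around a low-rank
expectation, heterogeneity across graphs, community structure, mixed
membership.  What it does not: edge dependence (transitivity beyond the
latent positions), degree heterogeneity within communities, weighted
edges, directedness, vertex misalignment across graphs.  Tests passing on
these samplers therefore validate the estimator under the model's own
assumptions; they do not certify behaviour on real networks where those
assumptions fail.

## Community detection

In a multilayer blockmodel the rows of $V$ take only $K$ distinct values,
so clustering the rows of $\hat V$ recovers the partition.
`cluster_subspace()` minimizes the K-means objective $\|\tilde Z \tilde C -
\hat V\|_F$ over one-hot memberships (Lloyd iterations, 20 seeded restarts
with initial centres drawn from distinct rows, best objective kept — the
objective is global, restarts approximate it reproducibly), or fits a
full-covariance Gaussian mixture (`method = "gmm"`, assignment by maximum
responsibility).  K-means is the default because the misclustering theory
is stated for it; the mixture is often preferable in practice when
clusters are elliptical.  $K$ is user-supplied; the elbow of the spectrum
is only a heuristic for it.

`misclustering_error()` reports the minimum over label permutations of
the number of disagreeing vertices (equivalently $\|\hat Z - ZQ\|_F =
\sqrt{2 \cdot \mathrm{count}}$).  The optimal permutation is found by a
minimum-cost assignment (Hungarian algorithm) on the confusion matrix —
identical to enumerating all $K!$ permutations (the tests verify this
against full enumeration for $K \le 4$) but polynomial in $K$; differing
label counts are handled by padding.

## Two-sample testing

`cosie_test()` tests $H_0: P^{(1)} = P^{(2)}$ for a pair of graphs.  Both
are embedded jointly, reducing the null to $R^{(1)} = R^{(2)}$, and the
statistic is $T = \|\hat R^{(1)} - \hat R^{(2)}\|_F^2$ — identifiable,
rotation-invariant, zero iff the fitted scores agree.  Large $T$ is
evidence against $H_0$; p-values are upper-tailed with the add-one
correction $(1 + \#\{T_b \ge T\})/(B + 1)$, so the smallest attainable
p-value with $B$ null replicates is $1/(B+1)$.

* **Parametric bootstrap.**  Plug-in matrices $\tilde P^{(k)}$ are built
  from the *scaled* single-graph embedding of each observed graph
  ($\hat X \hat X^\top$ with eigenvalue signs restored, entries clamped to
  $[0,1]$).  Half the null replicates draw an independent pair from
  $\tilde P^{(1)}$, half from $\tilde P^{(2)}$; each pair is refit at the
  same $d$ and $d_i$ as the observed fit, so the null statistic carries
  the same estimation noise as the observed one.
* **Asymptotic (generalized chi-square).**  As $n$ grows the
  half-vectorized score estimate is approximately Gaussian with
  covariance $\Sigma$ given by the explicit edge-variance sum
  (`score_covariance()`):
  $\Sigma_{(k,l),(k',l')} = \sum_{s<t} P_{st}(1-P_{st})
  (V_{sk}V_{tl} + V_{tk}V_{sl})(V_{sk'}V_{tl'} + V_{tk'}V_{sl'})$.
  Under $H_0$ the difference is $N(0, 2\Sigma)$, and
  $T = \|\mathrm{unvec}(y)\|_F^2$ (off-diagonal coordinates counted
  twice) is sampled by Monte Carlo, half the draws from the plug-in
  $\hat\Sigma$ of each graph — an equal-weight mixture.  The plug-in
  formula is validated in the tests against the empirical covariance of
  $\mathrm{vec}(V^\top A V)$ over $10^5$ simulated graphs.  This null is
  cheap but relies on full-rank score matrices and on the subspace bias
  being negligible; with only two graphs the bias need not be small, and
  when $d$ exceeds the per-graph ranks (as in the membership-perturbation
  scenario) the asymptotic p-values can be anticonservative.  The
  bootstrap is the safer default.

Plug-in covariances can be slightly indefinite in finite samples; negative
eigenvalues are floored at zero (with a warning beyond tolerance) before
sampling.  For screening many pairs, `pairwise_score_distances()` gives
the identifiable distance matrix; p-values for all pairs are reported raw
— apply `p.adjust(..., "BH")` if a false-discovery guarantee is needed.

## Numerical choices

* Eigenpairs are ordered by decreasing magnitude, ties broken by signed
  value then original index; each eigenvector's largest-magnitude entry is
  made positive (first index on ties).  Outputs are therefore
  deterministic, and permutation-conjugation of the input permutes the
  embedding rows exactly.
* Dense symmetric eigensolvers are used up to $n = 2000$; above that an
  implicitly restarted Lanczos iteration extracts the top-$d$ pairs by
  magnitude (the two branches agree to solver tolerance; a test pins
  this).
* Rank decisions (in `sbm_to_cosie()` and the rank warning in `mase()`)
  use a relative singular-value threshold
  $\max(\mathrm{dim}) \cdot \epsilon_{\mathrm{mach}} \cdot \sigma_1$,
  overridable; the blockmodel conversion computes the orthonormal factor
  $W$ from the SVD of the concatenated $\Xi^{1/2} B^{(i)} \Xi^{1/2}$
  blocks and sets $V = Z \Xi^{-1/2} W$, which reconstructs $Z B^{(i)}
  Z^\top$ exactly and keeps $V^\top V = I$ even with unbalanced
  communities.
* Score matrices are symmetrized as $(\hat R + \hat R^\top)/2$ to absorb
  floating-point asymmetry.
* `validate_cosie()` reports defects (orthonormality, symmetry,
  probability range) instead of raising; constructors raise.  The
  probability-range check uses a $10^{-12}$ floor so that genuine modelling
  errors are not masked by roundoff slack.
* Degenerate inputs: the zero matrix embeds with a `degenerate` flag (any
  orthonormal basis is as good as another); constant scree sequences
  return dimension 1 with a warning; empty communities and out-of-range
  probabilities are errors at construction.

## Problem sizes in the shipped studies

The test suite and `scripts/acceptance.R` run their simulation studies at
$n = 243$ (subspace consistency and community recovery, 15–25 replicates),
$n = 300$ (score normality and eigenvalue bias, 150–200 replicates per
sample size), $n = 150$ with 100-replicate bootstrap nulls (test
calibration and power), and $10^5$ Monte Carlo draws at $n = 8$ for the
covariance oracle.  These sizes were chosen so that the asymptotic
regimes are visibly entered while a full run stays a desk-scale
computation; the qualitative conclusions (error decreasing in $m$,
calibrated type-I error, near-perfect recovery) are stable across seeds at
these sizes.

## Known limitations

* Laplacian and regularized-Laplacian embeddings are not provided; for
  very sparse graphs the adjacency embedding is known to be inferior.
* The finite-sample bias of the subspace estimate (the term that shrinks
  like $d/m$) is not estimable from data and is neither estimated nor
  corrected; it is visible as the residual eigenvalue bias at small $m$
  and as anticonservatism of the asymptotic null for $m = 2$.
* Weighted and directed graphs are handled only in the trivial sense that
  `read_graphs(weighted = TRUE)` preserves weights; the samplers and
  theory are Bernoulli-undirected.
* Perfect-recovery guarantees for community detection at fixed small $m$
  are not available; the recovery study is explicitly a large-$m$ result.
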