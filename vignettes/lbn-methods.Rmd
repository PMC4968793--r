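---
title: "Local Bayesian networks for directed GRN inference: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local Bayesian networks for directed GRN inference: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbnet)
```

## The model and its assumptions

`lbnet` treats a genes-by-samples expression matrix as i.i.d. draws from a
multivariate Gaussian whose conditional-independence structure reflects the
regulatory network. Two consequences of Gaussianity are used throughout:

* Differential entropy reduces to a covariance determinant,
  $H(X) = \tfrac12 \log\big((2\pi e)^d\,\lvert C\rvert\big)$, so mutual
  information and conditional mutual information become determinant ratios:
  $$\mathrm{MI}(X;Y) = \tfrac12 \log\frac{\lvert C(X)\rvert\,\lvert C(Y)\rvert}
  {\lvert C(X,Y)\rvert}, \qquad
  \mathrm{CMI}(X;Y\mid Z) = \tfrac12 \log\frac{\lvert C(X,Z)\rvert\,\lvert C(Y,Z)\rvert}
  {\lvert C(Z)\rvert\,\lvert C(X,Y,Z)\rvert}.$$
  For a pair this is $-\tfrac12\log(1-r^2)$ with $r$ the sample Pearson
  correlation, and for one conditioning gene it is the same function of the
  partial correlation — identities the test suite asserts to $10^{-10}$.
  A kernel-density estimate of the same quantities is *not* implemented:
  everything the pipeline needs follows from the covariance form, and the
  determinant route is exact under the stated model.
* A directed acyclic structure factorises the joint density into node-given-
  parents families, $P(X_1,\dots,X_n) = \prod_i P(X_i \mid \mathrm{Pa}(X_i))$,
  so a decomposable score turns structure search into per-family bookkeeping.

All information values are in **nats** (natural logarithm); the thresholds
$\alpha$ and $\beta$ are interpreted on the same scale. Raw MI/CMI estimates
that fall below zero through round-off are clamped to 0, since the population
quantities are nonnegative.

The linearity of regulation implied by the Gaussian model is an
approximation. What the method needs in practice is that dependence is
monotone enough for correlation-based MI to rank pairs usefully; strongly
non-monotone regulation is outside its reach.

## The pipeline

`lbn()` (or `run_lbn()` with an `lbn_config()`) executes:

1. **Screening.** All $O(n^2)$ pairwise MIs (`pairwise_mi_matrix()`), then
   edges with $\mathrm{MI} \ge \alpha$ form the undirected network `G_MI`
   (`build_initial_network()`). All genes stay in the node set even when
   isolated so that evaluation over all ordered pairs is well defined.
2. **Decomposition.** One local subnetwork per gene: the gene plus its
   neighbours within shortest-path distance $\le k$ (`decompose_network()`).
   The cumulative $\le k$ convention is deliberate — the $k=2$ neighbourhood
   contains the $k=1$ one and approximately covers the gene's Markov blanket
   (parents, children and co-parents), which is the smallest set that shields
   a gene from the rest of the network. Distances ignore direction and
   weights.
3. **Local structure search.** `learn_local_bn()` scores structures with the
   Gaussian BIC family score: the maximised log-likelihood of the linear
   regression of a child on its parents minus $\tfrac12(|\mathrm{Pa}|+2)\log N$.
   BIC was chosen because it is decomposable, consistent, hyperparameter-free
   and matches the Gaussian treatment of the data; the score interface is a
   single function (`family_score()`), so a marginal-likelihood score could
   be slotted in later. No discretisation is performed. Subnetworks of at
   most `exhaustive_node_limit` (default 5) members are solved *exactly*: a
   dynamic program over sink orderings that provably attains the same optimum
   as enumerating every DAG (`enumerate_dags()` provides that enumeration,
   and the test suite asserts the equivalence on every small subnetwork).
   Larger subnetworks fall back to exhaustively scoring all parent sets of
   the centre gene of size $\le$ `max_parents` (default 3) drawn from the
   other members — the $O(2^m)$ search — and only edges into the centre are
   proposed; sibling–sibling edges belong to the subnetworks centred at those
   siblings.
4. **Integration.** Local DAG edges are united into the directed candidate
   network `G_B` (`integrate_local_dags()`); each edge carries its
   family-score improvement (score with the edge minus score without).
   Antiparallel conflicts keep the better-supported direction, with exact
   ties (within $10^{-9}$) broken toward the lexicographically smaller
   source, so the result never contains a 2-cycle. Global acyclicity is *not*
   enforced — directed cycles through longer paths are recorded in the
   iteration history but left alone.
5. **Pruning.** `prune_by_cmi()` deletes an edge as soon as *any* tested
   conditioning set renders its endpoints conditionally independent
   (CMI $< \beta$): all single common neighbours first, then, if the edge
   survives, all pairs (second-order CMI). Candidates are the genes adjacent
   to both endpoints (direction ignored), capped at the 10 with the highest
   combined MI to the endpoints for tractability. An edge with no common
   neighbours is tested against its order-0 MI. Surviving edges keep their
   direction and carry the minimum information value observed as confidence.
6. **Iteration.** Steps 2–5 repeat at $k = 2$ (`k_schedule` defaults to
   `c(1, 2)`, last value recycled) until two successive tentative networks
   have identical directed edge sets, or `max_iterations` (default 20) is
   reached.

### Why the candidate network is restricted to the current skeleton

Step 4 keeps only directed edges whose unordered pair is present in the
network being refined. The decomposition's premise is that a gene's candidate
regulators are its current neighbours; letting the local searches introduce
brand-new pairs each round contradicts that premise and, empirically, makes
the iteration oscillate: re-proposed pairs and re-derived orientations change
the neighbourhood structure, which changes the next round's proposals, and
the edge set never settles. Restricting each round to selecting, orienting
and deleting among existing adjacencies makes the skeleton weakly decreasing
across iterations, so the iteration provably reaches a fixpoint; on the
simulated benchmarks it also restores the expected ordering of the ablation
modes (the full pipeline leaves the fewest false positives, the single
CMI pass next, the BN-only variant the most — the comparison
`scripts/acceptance.R` recomputes). The $k = 2$ rounds still see distance-2
genes: they enter the local searches as context (mediators, co-parents), they
just cannot become direct edges unless already adjacent.

### Ablation modes

`ablation = "mi_bn"` stops after the first integration (no CMI pruning);
`"mi_bn_cmi"` stops after the first pruning pass; `"full"` iterates. These
isolate the contribution of the pruning and of the iterated decomposition.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `alpha` | 0.03 | nats | MI threshold of the screening stage |
| `beta` | 0.03 | nats | CMI deletion threshold of the pruning stage |
| `max_parents` | 3 | — | in-degree cap in local BNs |
| `exhaustive_node_limit` | 5 | — | largest subnetwork solved by exact search |
| `k_schedule` | 1, 2, 2, … | — | neighbourhood radius per round |
| `max_iterations` | 20 | — | iteration cap |
| `max_prune_order` | 2 | — | highest CMI order tested |

The defaults for $\alpha$ and $\beta$ (0.03 nats $\approx$ pairwise
$|r| \ge 0.24$) suit sample sizes of a few hundred; they are configuration,
not constants, because the appropriate threshold depends on $N$ and the
noise level. `permutation_threshold()` offers a data-driven alternative: it
builds a null MI distribution from random sample-order permutations and
returns the $1-\text{significance}$ quantile. It is a permutation substitute
for parametric MI significance tests; on independent Gaussian data it agrees
with the analytic null law of the squared correlation
($r^2 \sim \mathrm{Beta}(\tfrac12, \tfrac{N-2}{2})$), which the tests check.

## Numerical choices

* **Covariance estimation.** Unbiased ($N-1$) empirical covariance when
  $N >$ subset size; otherwise the off-diagonal entries are shrunk toward
  zero with an intensity estimated from the sampling variance of the entries
  (clamped to $[0,1]$), with a fixed $10^{-6}$ ridge fallback if the shrunk
  matrix is still not positive definite. `mode = "auto"` picks between the
  two; the subsets the pipeline uses are at most 4 genes, so the empirical
  path is the common one.
* **Degeneracy guards.** A determinant below $10^{-12}$ relative to the
  product of the diagonal raises a degenerate-data error (collinear
  expression) instead of returning $\pm\infty$; zero-variance genes and
  zero-residual-variance regression families are rejected the same way.
* **Determinants.** Explicit formulas for $1\times1$ and $2\times2$
  covariances keep MI bit-symmetric in its arguments and exactly zero at
  sample correlation zero; larger blocks use LU decomposition.
* **Tie-breaking.** Score ties in the structure search (routine, because
  Markov-equivalent DAGs score identically) are resolved toward fewer edges,
  then by a fixed deterministic search order; the globally smallest edge
  list among exact ties is not sought. What matters downstream is
  determinism — two runs on the same input produce byte-identical edge
  lists — and that is guaranteed.
* **Sentinels.** Metric denominators that vanish yield defined values
  (PPV = FDR = F = MCC = 0) so threshold sweeps are total functions.

## The synthetic generator

`simulate_expression()` draws i.i.d. samples from a linear-Gaussian
structural equation model over a random DAG: each gene is the sum of signed
coefficients (magnitudes uniform in `coeff_range`, default 0.5–1.0, signs
random) times its parents plus $\mathcal N(0, \texttt{noise\_sd}^2)$ noise
(default sd 0.5). The defaults keep edges bounded away from undetectable
strength at $N = 200$, the sample size the bundled fixtures use. The
population covariance is available in closed form,
$\Sigma = (I-B)^{-\top} D (I-B)^{-1}$, and is attached to the simulated
matrix, so estimator tests can compare against analytic ground truth.

What the generator deliberately does **not** emulate: kinetic/ODE dynamics,
saturating or combinatorial regulation, time courses, measurement-specific
noise, and non-Gaussian marginals. Passing tests on these fixtures therefore
show correctness of the machinery under the model's own assumptions — an
upper bound on, not a guarantee of, performance on biological data, where
the Gaussian linearity is only an approximation.

Fixture shapes: `tiny_chain` (3 genes, a chain), `vstructure` (3 genes, a
collider — the structure that makes directions identifiable), `sos_like`
(9 genes / 24 edges, the size of the experimentally verified SOS DNA-repair
network in *E. coli*) and `dream10_like` (10 genes / 10 edges, the size of
the smallest DREAM3 benchmark).

## Evaluation conventions

Evaluation is over **all ordered pairs** $(i, j)$, $i \ne j$ — $n(n-1)$
pairs, self-pairs excluded; this convention is forced by the arithmetic of
the published worked examples the tests reproduce (e.g. FPR $= 10/48$
requires 72 ordered pairs for 9 genes). Directed evaluation is the default;
an undirected mode collapses pairs for comparison against undirected
baselines. ROC curves sweep the edge-confidence threshold from large to
small over distinct values, with tied confidences as a single step and
trapezoidal integration, which makes the AUC identical to the rank-sum
(Mann–Whitney) normalisation — asserted in the tests. Per-gene AUC summaries
restrict the pair universe to one gene in the regulator or target role and
skip genes with no in-role gold positives or negatives.

## Problem sizes in the test and acceptance runs

The bundled checks use 10-gene/10-edge benchmarks at $N = 200$ over
20 simulation seeds for recovery and ablation comparisons, 2000-sample
fixtures for conditional-independence and consistency properties, 50 000
samples for the SEM covariance identity, and sparse 25- vs 100-gene networks
for the runtime-scaling check. These sizes were chosen so that population
effects dominate sampling noise while the whole suite stays comfortably
interactive.

## Known limitations

* Directions are identifiable only up to Markov equivalence from
  observational Gaussian data: an isolated chain or pairwise link can be
  oriented either way at identical score, and the deterministic tie-break
  then decides. Colliders (v-structures) are what anchor true directions.
* The integrated network may contain directed cycles through paths longer
  than two; only 2-cycles are resolved. Downstream consumers that need a DAG
  must post-process.
* Second-order pruning caps its candidate pool at 10 common neighbours per
  edge; in very dense networks a relevant conditioning pair could be missed.
* The Gaussian MI estimator sees only (partial) correlation; purely
  non-monotone dependencies are invisible to the screen and hence to the
  whole pipeline.
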