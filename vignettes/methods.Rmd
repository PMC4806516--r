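---
title: "Exhaustive time-reversible model testing: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive time-reversible model testing: models, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtrspace)
```

# The question

Maximum-likelihood phylogenetics conventionally models DNA substitution with
a time-reversible Markov process. Reversibility constrains the instantaneous
rate matrix to

$$ q_{ij} = r_{ij}\,\pi_j, \qquad r_{ij} = r_{ji}, $$

leaving at most six distinct exchangeability rates
$(r_{AC}, r_{AG}, r_{AT}, r_{CG}, r_{CT}, r_{GT})$ over the stationary
frequencies $\pi$. Between the one-rate Jukes–Cantor model and the six-rate
GTR model lies every way of tying the six rates into equality classes — a
set partition of six objects, of which there are exactly $B_6 = 203$ (the
Bell number; $S(6,k)$ of them for each number $k$ of distinct rates:
1, 31, 90, 65, 15, 1). `gtrspace` scores all 203 models on an alignment,
selects the best under five information-criterion variants, runs a tree
search under each winner, and measures whether the choice of model changed
the resulting topology.

# Model strings and their canonical form

A model is encoded as six digits over $\{1,\dots,6\}$ in the fixed position
order (AC, AG, AT, CG, CT, GT); positions sharing a digit share a rate.
`121121` is the transition/transversion (HKY-type) tie structure, `123456`
is GTR. Many strings denote the same partition (`121121` ≡ `212212`), so a
canonical — *normalized* — representative is defined: at the first occurrence
of each digit value $v$, the preceding characters must be exactly
$\{1,\dots,v-1\}$. Normalized strings are restricted-growth strings: they
start with 1, and the $n$-th character is at most $n$.

Two independent generators produce the space:

* **Exhaustive enumeration** (`enumerate_brute_force()`): count `111111` to
  `666666` in base 6 (46656 strings), normalize each, keep first
  occurrences. The optimized variant only places digits $\{1..n\}$ at
  position $n$, enumerating $6! = 720$ candidates (517 redundant).
* **Inductive derivation** (`generate_inductive()`): from `111111`, each
  $k$-model spawns $(k{+}1)$-models by replacing occurrences of digit $k$
  outside the protected *$k$-prefix* (the shortest prefix containing all $k$
  digits) with $k{+}1$ — one replacement per unprotected occurrence, then a
  recursion that only moves rightward, which makes the derived sets disjoint
  across source models.

The test suite asserts that both generators return the identical set of 203
strings and that the per-$k$ counts equal the Stirling numbers computed by
an independent set-partition enumerator. One definitional subtlety: the
$k$-prefix is defined for any string whose digit set is $\{1..k\}$, not only
for normalized ones (`124311` has 4-prefix `1243` although it is not
normalized).

# The likelihood engine

`log_likelihood()` implements Felsenstein pruning over compressed site
patterns with the standard ingredients:

* **Rate matrix.** $Q$ is assembled from the tied rates (the class containing
  the GT position is the relative-rate reference, fixed at 1) and normalized
  to one expected substitution per unit branch length, so branch lengths are
  comparable across models. The source never states its scaling convention;
  this is the package's choice, recorded here.
* **Eigendecomposition.** $P(t) = e^{Qrt}$ is computed from the
  eigendecomposition of the $\pi$-symmetrized matrix
  $\mathrm{diag}(\sqrt\pi)\, Q\, \mathrm{diag}(1/\sqrt\pi)$, which is real
  symmetric for a reversible $Q$; one decomposition serves all branches and
  rate categories. Tiny negative entries from roundoff are clipped to zero.
* **Γ rate heterogeneity.** Four equal-probability categories, each
  represented by its conditional mean of $\Gamma(\alpha,\alpha)$ computed in
  closed form from the incomplete-gamma identity and renormalized to mean 1.
  Means rather than medians, matching the convention of the rate-heterogeneity
  literature and of the likelihood libraries this design follows.
* **Ambiguity.** IUPAC codes become 0/1 indicator vectors at the tips; `-`,
  `?`, `.`, `N` are all-ones. Site patterns are compressed with
  multiplicities.
* **Scaling.** Per-node rescaling (threshold $10^{-240}$) with per-pattern
  log-scalers; categories with unequal scalers are combined by log-sum-exp,
  and the common equal-scaler case takes a cheaper single-log path.

Reversibility makes the likelihood independent of virtual-root placement;
the suite asserts this to $10^{-8}$, checks the engine against an exhaustive
sum over internal-state assignments on 4-taxon trees, against the
Jukes–Cantor closed form on pairs, and verifies that the likelihoods of all
$4^T$ site patterns sum to one.

# Parameter optimization

`optimize_on_fixed_tree()` runs coordinate ascent: branch lengths by Brent's
method per branch, then exchangeabilities, the Γ shape and (optionally) the
base frequencies jointly by Nelder–Mead on log/softmax-transformed
parameters; rounds repeat until the lnL gain drops below `tol` (default
$10^{-4}$, at most 25 rounds, warning and best-so-far on non-convergence).
lnL is non-decreasing across rounds by construction: every proposal is
accepted only if it improves the exact recomputed lnL.

Branch optimization uses cached directional partials: one postorder pass
stores each edge's child contribution, one preorder pass derives, for every
edge at once, the likelihood of the data *outside* the edge's subtree
(reversibility lets the same $P$ propagate both ways). Each branch is then a
cheap univariate problem. Within a smoothing sweep all branches are updated
against the sweep-start partials (simultaneous smoothing); a sweep is kept
only if the exact lnL improved, which preserves monotonicity while avoiding
a full partial refresh per branch.

Free parameters are counted as $(k-1)$ rates $+$ 3 frequencies (only when
ML-estimated) $+$ 1 shape $+$ $(2T-3)$ branch lengths. Whether branch
lengths belong in the "degrees of freedom" of an information criterion is a
convention the source leaves open; both are supported
(`include_branch_lengths`, default `TRUE`), and the run report records which
was used.

# Model scan and selection

`evaluate_all_models()` fits all 203 models on a fixed tree — in practice
the randomized stepwise-addition parsimony tree of `parsimony_start_tree()`
— and scores five criteria: AIC, AICc and BIC, the latter two with sample
size defined as sites (S) or sites × taxa (M):

$$ \mathrm{AIC} = 2k - 2\ln L,\quad
   \mathrm{AICc} = \mathrm{AIC} + \tfrac{2k(k+1)}{n-k-1},\quad
   \mathrm{BIC} = k\ln n - 2\ln L. $$

AICc is undefined when $n \le k+1$; such models are excluded from that
criterion's minimization only. Results accumulate in a mergeable
minimum-keeping list — merging is associative and commutative with ties
broken toward the lexicographically smaller model string — so the outcome is
identical for any evaluation order or worker partition (the in-process
analogue of a master/worker reduction).

Two implementation choices matter for speed and are deliberate:

* The GTR fit is computed first, always at full convergence settings, and
  seeds every other model (tied classes start at the mean of the GTR rates
  they pool, branch lengths and shape carry over). Since every nested
  parameterization is a GTR parameterization, the converged anchor also
  bounds all other fits — the nesting property
  $\ln L_{GTR} \ge \ln L_m$ is asserted over the full score table.
* The per-model fits accept a capped optimizer budget. The acceptance suite
  scans with `max_sweeps = 2`, `tol = 10^{-2}`, `branch_sweeps = 3`,
  `brent_tol = 10^{-3}`, keeping the whole suite inside a sensible compute
  budget. The suite itself bounds the budget's cost: the capped fits must
  stay below the fully converged GTR anchor (nesting), and the recovery
  criteria pass at the capped budget, so the winner identities those tests
  assert are computed, not assumed.

# Tree search and topological comparison

`ml_search()` hill-climbs over nearest-neighbour interchanges: all
neighbors are evaluated with branch-length re-optimization under the current
parameters, the best improving one is accepted and fully re-optimized, until
no neighbor improves by more than `nni_tol`. The search is deterministic,
monotone in lnL, and ends NNI-locally optimal; at 4–5 taxa it provably finds
the global optimum (checked against exhaustive topology enumeration). The
source treats the tree search as a black box provided by its likelihood
library (an SPR-based search); NNI was chosen here for desk-scale
determinism and testability, isolated behind the `move_set`-style control so
an SPR upgrade stays local.

Topologies are compared by Robinson–Foulds distance on canonicalized
nontrivial bipartitions, reported relative to the maximum $2(T-3)$
(a fixed denominator regardless of resolution). `significance_analysis()`
reproduces the significance procedure: the mean rRF across
(best-fit, GTR) tree pairs is compared with the *random expectation*, the
mean rRF among within-GTR pairs, the source's proxy for search-replicate
noise. The source states only "$p<0.01$", not a test; the package uses a
two-sided permutation test (default 1000 seeded label shuffles of the pooled
trees, recomputing the mean cross-set rRF), classifying outcomes as
`higher` / `lower` / `indistinguishable` at $\alpha = 0.01$. Identical tree
sets are classified `indistinguishable` with $p = 1$ — the outcome class
that covered 11 of 41 empirical datasets in the source's analysis.

# The simulator and what a green test establishes

`simulate_alignment()` draws root states from $\pi$, assigns each site one
of the four Γ category rates (once, shared across the tree — standard
mixture semantics), and evolves states edge by edge from the transition
matrices. It deliberately omits indels (alignments are gap-free): the
model-selection question concerns substitutions, and the original
simulation study's indel capability was incidental. Byte-identical output
given (spec, seed).

The recovery harness (`recovery_experiment()`) mirrors the accuracy
experiment's design: simulate, run the full pipeline, compare winners and
searched topologies to the truth (TTR, mean rRF, branch-score difference,
TMR). The original study's exact accuracy numbers depend on best-fit
parameters of two empirical datasets that were never published, so those
numbers are not reproduction targets; the harness reproduces the design at
a stated, scaled-down world.

**The stated world of the acceptance recovery tests.** One fixed 10-taxon
generating tree with exponential branch lengths of mean 0.08 substitutions
per site (typical of the empirical alignments the source surveys, where most
branches are short); 5000 sites; 10 simulation seeds; HKY-structured truth
`121121` with rates $(1,4)$ (a transition/transversion ratio in the common
empirical range), frequencies $(0.35, 0.15, 0.20, 0.30)$, and $\alpha=0.8$
(moderate heterogeneity); and a Jukes–Cantor truth with equal frequencies
and the same $\alpha$. Empirical base frequencies are used in the fits, as
the source's default configuration does. What a green run establishes: under
clean, model-conforming, gap-free data of this size, BIC with sites as
sample size recovers the generating tie structure (majority of replicates)
and does not over-parameterize Jukes–Cantor data ($k \le 2$ in at least
9/10). It does not establish robustness to model violation, alignment
error, or indels — real data contain all three.

# Numerical choices and degenerate inputs

* Branch lengths are optimized in $[10^{-8}, 6]$; candidate windows around
  the current length fall back to the full range when the window boundary
  binds. Brent tolerance $10^{-4}$ (relative) by default.
* Nelder–Mead works on $\log$ rates (clamped to $\pm 12$), $\log \alpha$
  (clamped to $[-7, 9]$) and a 3-parameter softmax for frequencies.
* Empirical frequencies add a $+1/4$ pseudo-count per base so no frequency
  is zero; fully ambiguous columns contribute nothing to the counts.
* A $k=6$ input to the inductive derivation step is an error (not an empty
  set), to catch driver mistakes; `derive_models` requires normalized input.
* Ties in stepwise addition and NNI are broken first-encountered in a fixed
  traversal order; all randomness flows through explicit integer seeds.

# Known limitations

* NNI search can in principle stall on multi-move ridges where SPR would
  escape; acceptable at desk scale and behind a config boundary.
* No invariant-sites (+I) mixtures, no partitioned models, no
  ascertainment-bias correction — all out of scope.
* The `workers` argument partitions the scan and merges local results; on
  one CPU it is a correctness contract (order invariance), not a speedup.
* Criterion scores at the capped scan budget are accurate to roughly
  $10^{-2}$ lnL; if two models ever scored within that margin the reported
  winner could flip — not observed in any tested configuration, and the
  full-budget defaults are available by passing an empty `control`.
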