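---
title: "Consensus ranking for docking-based virtual screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ranking for docking-based virtual screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dra)
```

## The problem

Docking scoring functions are weakly and *differently* correlated with
measured binding affinity: each one captures a partial view of the
receptor–ligand interaction (shape complementarity, hydrogen bonding,
desolvation, entropy). A virtual screen that ranks a compound library by any
single scoring function inherits that single view's blind spots. `dra`
implements the alternative used in consensus screening pipelines for nuclear
receptors such as PXR: dock with several scoring functions, convert each
score vector to a ranked list, and fuse the lists into one consensus ranking
that is as close as possible to all of them. The fused ranking is evaluated
against an activity reference (e.g. an EC50-sorted ligand list) with
normalised discounted cumulative gain, and validated by the detection rate
of known positives near the top of the list. Upstream of docking, a generic
3D pharmacophore engine prunes the library to candidates that can present
the required interaction features.

## Rank distances and the aggregation objective

For ranked lists \(L_i, L_j\) over a common item universe with rank
functions \(r_{L}(t)\) (1 = best), the Spearman footrule distance is

\[ S(L_i, L_j) = \sum_{t \in L_i \cup L_j} | r_{L_i}(t) - r_{L_j}(t) | , \]

and the weighted footrule scales each term by the difference in positional
importance,

\[ WS(L_i, L_j) = \sum_{t} \big| M(r_{L_i}(t)) - M(r_{L_j}(t)) \big| \cdot
   | r_{L_i}(t) - r_{L_j}(t) | . \]

The importance function \(M\) is not standardised across the consensus-
ranking literature, so it is configurable:

* `linear_rank` (default): \(M(r) = (n - r + 1)/n\). Parameter-free,
  monotone, 1 at the top of the list. This makes disagreement among the top
  ranks — the part of a screen anyone acts on — dominate the distance.
* `normalized_score`: the min–max-normalised raw score of the item in its
  list. This uses the actual energy gaps (two compounds separated by
  0.1 kcal/mol matter less than two separated by 3 kcal/mol) but requires
  the lists to carry scores. When a scoreless candidate is compared against
  a scored list inside the aggregation objective, the list's own importance
  curve is applied to both rank arguments; a candidate permutation has no
  scores of its own to normalise, and borrowing the reference curve keeps
  the distance well-defined and zero for identical orders.

Missing items (top-k lists) follow the standard convention: an item absent
from a list of length \(k\) is treated as sitting at rank \(k+1\) with zero
importance weight; `strict` mode rejects mismatched universes instead.

The consensus list \(\delta^*\) minimises the weighted total distance to the
ensemble \(\{(L_i, w_i)\}\):

\[ \Phi(\delta) = \sum_i w_i \, d(\delta, L_i), \qquad
   \delta^* = \arg\min_\delta \Phi(\delta). \]

## Cross-entropy search

Minimising \(\Phi\) over permutations is combinatorial, so the package uses
the cross-entropy Monte Carlo method standard in rank aggregation. The
search state is an \(n \times n\) item-by-position probability matrix `P`,
initially near-uniform. Each iteration:

1. sample `n_samples` permutations by filling positions left to right,
   drawing each item from the current column of `P` renormalised over
   unused items;
2. evaluate \(\Phi\) for every sample;
3. refit `P` towards the empirical item-position frequencies of the elite
   (best `ceiling(elite_fraction * n_samples)` samples) with smoothing
   weight `smoothing`;
4. stop at `max_iterations`, or once the elite-mean \(\Phi\) has gone
   `stagnation_limit` iterations without improving.

Defaults (`ce_params()`): `n_samples = max(200, 10 n)`,
`elite_fraction = 0.1`, `smoothing = 0.5`, `max_iterations = 100`,
`stagnation_limit = 15`, and a mandatory seed. Three design choices deserve
comment, because the design here was genuinely open:

* **Warm start.** The input lists themselves, plus the weighted mean-rank
  (Borda) ordering, are evaluated as candidates before the first iteration
  and seed `P` as an iteration-0 elite set. The returned consensus is the
  best permutation ever evaluated, so it is never worse (in \(\Phi\)) than
  the best input list or the Borda heuristic. Without this, the sampler
  needs most of its iteration budget just to rediscover input-list quality
  at realistic list lengths (n ≈ 100).
* **Stopping rule.** Stagnation is monitored on the *elite-mean* objective
  rather than the single best sample. The best sample is a noisy extreme
  statistic: at n ≈ 100 it can plateau for long stretches early in the
  search while the distribution is still concentrating, which makes it stop
  the search prematurely; the elite mean declines almost monotonically until
  convergence and flattens exactly when `P` has frozen.
* **Smoothing 0.5.** At 0.25 the refit is too timid: convergence at n ≥ 40
  needs more than the default iteration budget. At 0.5 the search converges
  both faster and to slightly lower \(\Phi\) in our experiments, while
  small-universe optima are still found essentially always (the exhaustive
  oracle check agrees in ≥ 99% of random ensembles and the sampler never
  reports a value below the true optimum).

A probability floor of \(10^{-12}\) per cell prevents absorbing states.
`aggregate_brute_force()` provides the exact minimiser for universes of at
most 8 items (40320 candidates) and is used throughout the tests as the
oracle; its ties resolve to the lexicographically smallest optimal
permutation.

## Evaluating a ranking: nDCG

Given graded relevances \(rel_i \ge 0\) in candidate order,

\[ DCG_p = rel_1 + \sum_{i=2}^{p} \frac{rel_i}{\log_2 i}, \qquad
   nDCG_p = \frac{DCG_p}{IDCG_p}, \]

with \(IDCG_p\) the DCG of the relevance-descending ordering (base-2
logarithm, position 1 undiscounted). The package's headline scalar is the
arithmetic mean of \(nDCG_p\) over all cutoffs \(p = 1..n\): a single
position would be arbitrary, and the mean over cutoffs rewards agreement at
every depth while still weighting the head most (early positions enter every
cutoff). A fixed-cutoff evaluation is available through `ndcg(..., p =)`.

The relevance convention is a real degree of freedom — published nDCG values
cannot be reproduced without knowing it — so three schemes are exposed:
`linear` (default, `rel = n - r_ref + 1`, parameter-free), `exponential`
(`2^(n-r)`, top-heavy), and `binary` with an activity threshold (e.g. EC50
at or below 10 µM = active). The replication harness `replicate_table1()`
sweeps conventions and, when published values are supplied, reports which
convention tracks them best; it never silently asserts a match.

`detection_rate()` is the validation statistic for a screen with known
positives: the fraction of the top `max(1, floor(top_fraction * n))` items
that are positive. The floor makes "top 10 percent" of a 305-item list
inspect exactly 30 items.

## The synthetic ensemble generator

Tests and the acceptance experiments need scorer ensembles with *known*
ground truth. `generate_ensemble()` draws, per item, a latent true affinity
\(u_t \sim N(0,1)\), and per scorer

\[ s_k(t) = -\alpha_k u_t + \beta_{g(k)} g_{g(k)}(t) + \varepsilon_{kt}, \]

lower = better, with per-scorer signal weight \(\alpha_k\), private Gaussian
noise of sd \(\sigma_k\), and an optional shared noise field per redundancy
group (weight \(\beta_g\)). Scorers with independent noise are
*complementary* views of \(u\); scorers sharing a strong group field are
*redundant* near-duplicates. The reference ranks items by \(u\), with
EC50-like stored activities \(10 e^{-u}\) µM.

The headline design `complementary_redundant_spec()` uses three
complementary scorers (\(\alpha = 0.5\), independent unit noise) plus a
near-duplicate of the third (shared noise \(\beta = 1\), private sd 0.15).
Defaults were fixed once: \(\sigma = 1\) puts each single scorer at a rank
correlation of about 0.45 with the truth — "weakly correlated with measured
affinity", which is the regime consensus ranking is for — and
`n_items = 107` matches the scale of the published EC50 benchmark this
design emulates. List length matters scientifically here: the mean-nDCG
statistic is head-weighted, so at small n (a few dozen items) the luck of a
single scorer's top ranks has variance comparable to the genuine aggregation
gain, and the best-of-four selection can mask it; at n ≈ 100 the gain is
cleanly visible. The subset-sweep experiment (all \(2^4 - 1\) scorer
subsets, the larger ones each requiring a full CE run) uses 40-item
replicates to keep 25 replicates inside a few minutes of CPU time; the
subset *ordering* it checks is robust to that choice.

What the generator does **not** emulate: the numeric distributions of real
docking scores, score ties, partial docking failures, or chemical series
structure (correlated activity among analogues). Passing these experiments
therefore shows that the machinery recovers planted structure of this
additive-Gaussian kind, not that any particular real screen will enjoy the
same gain.

## The pharmacophore engine

The screening stage is a generic ligand-based 3D pharmacophore matcher.
A model (`pharmacophore_model()`, JSON on disk) is a set of typed feature
spheres — centre in Å, tolerance radius, allowed types among hydrophobe
(`Hyd`), H-bond acceptor/donor (`Acc`/`Don`) with projected variants
(`Acc2`/`Don2`), aromatic ring (`ARO`) — plus excluded-volume spheres and a
partial-match threshold `min_features_required` (default: all features, the
behaviour of template models that every training ligand fits; minimum 3 for
a meaningful rigid 3D match).

Matching searches injective assignments of detected feature points to model
features with compatible types (`Acc2`/`Don2` collapse onto `Acc`/`Don` on
the chemistry side; they remain distinct model-side labels). Partial
assignments are pruned when any assigned pair's point distance differs from
the model distance by more than the sum of the two tolerances — a necessary
condition for any rigid superposition, so pruning is an efficiency choice
that cannot change decisions, which the tests confirm against an unpruned
exhaustive oracle. Each surviving assignment is superposed onto the model
centres by least-squares rigid fit (Kabsch, SVD with determinant
correction); it is accepted when every assigned point lies inside its
feature's tolerance sphere after superposition and no heavy atom of the
aligned conformer penetrates an excluded volume (heavy atoms only, since SDF
inputs often omit hydrogens). Among accepting assignments, most features
wins, then lowest RMSD.

Feature perception on SDF conformers uses deliberately simple shipped rules
(every N/O is an acceptor; N/O with an explicit hydrogen or unfilled valence
donates; aromatic-ring centroids from ring perception; centroids of
connected carbon fragments with no heteroatom neighbour are hydrophobes).
Abstract pre-typed point sets (`feature_molecule()`) bypass chemistry
entirely and are the primary fixture type, keeping the matching mathematics
testable without conformer noise. SMILES input is converted to a single 3D
conformer through the Open Babel command line when available.

The shipped template model carries the published five-feature type signature
for PXR agonist screening (Hyd|Acc, Acc|Acc2|Don2, Hyd|Acc2, Hyd|Acc,
ARO|Hyd, eight excluded volumes) but **synthetic placeholder geometry**:
the real model's coordinates are unpublished, so the file exists to exercise
the engine and document the format, not to reproduce the published screen.
Its centres are deliberately asymmetric — near-symmetric geometries admit
spurious matches under permuted assignments, which is also why fixture
generation refuses models whose tolerance spheres overlap.

Fixture libraries (`generate_screen_fixtures()`) plant hits by placing one
type-compatible point inside each feature sphere and applying a random
rigid motion. The jitter radius is bounded by \(0.9/\sqrt{k}\) of the
tolerance so that the least-squares pose — whose total squared deviation
cannot exceed the planted pose's — keeps every point inside its sphere,
guaranteeing recall 1.0 by construction. Decoys violate the model in one
recorded way (incompatible type, displaced point, or an atom planted at an
excluded-volume centre on an otherwise exact pose, so the violation survives
superposition exactly).

## Numerical choices and degenerate inputs

* Ranks are 1-based; 1 = best (most potent, lowest energy). Docking
  energies and EC50 both default to lower-is-better.
* Score-to-rank ties break by ascending item id in C-locale byte order:
  aggregation needs total orders, and the tie rule must be reproducible
  across platforms. The tie ordering of activity references is likewise a
  convention, since measured EC50 ties carry no ordering information.
* Distances are sums of products of small integers and ratios in double
  precision; no tolerances are needed there. Superposition acceptance uses
  a 1e-9 Å slack so that exact-coincidence fixtures are not rejected by
  floating-point jitter.
* All stochastic entry points require an explicit integer seed and are
  bitwise reproducible given it; sweeps derive per-subset seeds from the
  base seed.
* Degenerate inputs fail loudly and early: empty score maps, non-finite
  scores (named by item), duplicate ids, non-permutation rank columns
  (named by row), universes that mismatch in strict mode (listing the
  symmetric difference), all-zero relevance vectors.

## Problem sizes used by the tests

The shipped experiments run on one CPU in a few minutes total: the oracle
comparison uses 200 random ensembles of 3–7 items; the metric property suite
uses 1000 random permutation triples up to n = 12; the aggregation-gain
experiment uses 25 replicates of the 107-item four-scorer design; the subset
sweep uses 25 replicates at 40 items; the scale check aggregates four
107-item lists (about a second); pharmacophore fixtures use a 20-hit /
80-decoy library.

## Known limitations

* The consensus is a heuristic optimum: cross-entropy search carries no
  optimality certificate beyond the small-universe oracle checks.
* mean nDCG depends on the relevance convention; comparisons across studies
  are only meaningful with the convention fixed.
* The pharmacophore engine matches rigid conformers; conformational
  flexibility must come from supplying multiple conformers per molecule.
* Shipped feature-typing rules are intentionally minimal and are not a
  substitute for a curated chemistry perception stack.
* The generative model behind the synthetic experiments is additive
  Gaussian; real scorer error structure is heavier-tailed and
  compound-class dependent.
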