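---
title: "Methods and modeling choices in amyhex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in amyhex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyhex)
```

`amyhex` classifies six-residue peptide windows (hexmers) as amyloidogenic
or not, using only sequence-derived features. This vignette documents the
model, its tunable parameters, the numerical conventions, and the design
decisions taken where the architecture left genuine freedom — together with
what the synthetic-data tests do and do not establish.

## The unit of prediction

Experimental work on fibril formation shows that hexapeptides suffice to
form amyloid-like fibrils, so the window size is fixed at `w = 6`.
`sliding_hexmers()` cuts every offset (step 1; `L − 5` windows from a clean
length-`L` chain), uses 0-based origins and half-open `[start, end)`
regions (BED semantics), and labels a window positive only when it lies
entirely inside a positive region. Windows containing residues outside the
standard 20-letter alphabet are skipped and counted, never imputed: no
property table covers B/Z/X/U/O/J reliably, and six residues leave no room
for a missing value.

## Feature encoding

Three blocks, assembled in the fixed order BPC, AC, ATOM:

**BPC (per-property window mean).** Each amino-acid index contributes one
feature: the arithmetic mean of its raw per-residue values over the six
positions. The aggregation rule is deliberately order-free — the
autocorrelation block exists precisely to add order sensitivity, so the
mean is the natural complement. Raw (unstandardized) values are used here
because the downstream min-max step rescales every feature anyway.

**AC (Moreau-Broto autocorrelation).** For per-position property values
$p_1,\dots,p_w$,
$$F_v = \frac{1}{w-v} \sum_{i=1}^{w-v} p_i\,p_{i+v}, \qquad v = 1,\dots,5.$$
Two conventions needed fixing:

* *Lag normalization.* The lag-normalized form above (the PROFEAT
  convention for Moreau-Broto descriptors) is the default; the raw sum
  $\sum p_i p_{i+v}$ is available via
  `encoding_config(lag_normalized = FALSE)`. The normalized form keeps the
  five lags on a comparable scale as the number of summands shrinks from 5
  to 1.
* *Index pre-conditioning.* Indices are standardized to mean 0 and
  population sd 1 over the 20 residues before autocorrelation
  (`standardize_ac = TRUE`), again following the usual Moreau-Broto
  convention; without centering, an index with a large offset makes every
  $F_v$ dominated by the squared mean rather than by sequence order. The
  switch exists because the choice is a convention, not a theorem.

A shuffled window generally changes $F_v$ (empirically for ≥ 95% of random
non-homopolymer hexmers under a non-constant index, with at most five
distinct products rearranged, exact coincidences do occur) — this is the
sequence-order effect the block is designed to carry.

**ATOM (atomic composition).** The element-wise sum of C/H/N/O/S counts
over the six residues, using dehydrated in-chain residue formulas (free
amino acid minus one water; e.g. Gly = C2H3NO, Met = C5H9NOS). No terminal
water is added: a window is a fragment of a chain, and either convention
leaves the block exactly permutation-invariant, which is its defining
property. Counts are exact small integers.

**Min-max normalization.** Every feature is mapped by
$v' = \frac{v - \min_P}{\max_P - \min_P}(\mathit{new\_max} -
\mathit{new\_min}) + \mathit{new\_min}$, default target range $[0, 1]$ (the
target interval is configurable; nothing downstream assumes a particular
range). Parameters are fitted on the *training partition only* and reused
unchanged on validation and test data — out-of-range values are transformed
by the same affine map and may leave the target interval, which is the
honest behavior for unseen data. Degenerate features
($\min_P = \max_P$) map to $\mathit{new\_min}$: deterministic and bounded.
The affine map is exactly invertible for non-degenerate features
(`invert_minmax()`), which the tests exploit.

## Two-stage feature optimization

**Stage 1 — embedded pre-selection.** A single linear-kernel SVM is fitted
on all candidate per-property mean features; properties are ranked by the
absolute primal weight $|w_j| = |\sum_i \alpha_i y_i x_{ij}|$ and the top
`k` (186 in the canonical setting) survive. "Embedded based on an SVM
classifier" admits several readings; single-shot weight-magnitude ranking
is the simplest and is deterministic (ties break by accession order).
Recursive elimination would be a drop-in refinement but adds quadratic
cost for little benefit at these pool sizes.

**Stage 2 — memetic algorithm.** Fixed-cardinality subsets (default
`subset_size = 40`) evolve for up to 100 generations in a population of 10:

* *Fitness* is mean accuracy of an RBF-kernel SVM over stratified 5-fold
  cross-validation. Folds are assigned once per run from the run seed and
  reused for every evaluation: fitness comparisons are then exact, and the
  whole run is a pure function of its seed. (Re-randomizing folds each
  generation would add noise to the strict-improvement acceptance rule.)
* *SVM parameters as genes.* How "the corresponding SVM parameter values"
  are determined is unspecified, so each individual carries its own
  $(C, \gamma)$, log-uniform initialized over $[2^{-5}, 2^{15}] \times
  [2^{-15}, 2^{3}]$ (the customary libsvm grid span), inherited from a
  random parent at recombination and perturbed log-normally
  (σ = 0.3) at mutation — evolutionary parameter tuning inside the same
  loop that tunes the subset.
* *Recombination* builds a shared pool from the shuffled multiset of the
  best-half parents' properties; each offspring keeps first occurrences of
  sequential draws until it holds 40 distinct properties. Properties common
  among fit parents therefore enter offspring with elevated probability.
* *Mutation schedule.* The number of swaps per offspring decays
  exponentially with generation:
  $$N_M(n_G) = \max\{1,\ \mathrm{round}(s\,m\,e^{-\lambda n_G/N_G})\},
  \qquad \lambda = \ln(s\,m),$$
  so $N_M(0) = \mathrm{round}(s\,m) = 8$ at the canonical $s = 40$,
  $m = 0.2$, and $N_M(N_G) = 1$: big steps early, fine steps near
  convergence, never zero while the run lasts. The decay law is injectable
  (`mutation_count_fn`) for alternative readings of "exponential".
* *Local search.* Selected (S) and excluded (E) sets are ranked by the
  two-class F-score
  $$F = \frac{(\bar x_+ - \bar x)^2 + (\bar x_- - \bar x)^2}
  {s_+^2 + s_-^2}.$$
  Each step simultaneously Adds the top-ranked member of E and Deletes the
  bottom-ranked member of S — the merge of the Add and Delete operators
  that keeps cardinality at exactly 40 by construction — evaluates the
  candidate, and accepts only strict fitness improvements; the climb stops
  at the first rejection or after `local_search_length = 8` steps. A
  zero-denominator F-score with separated means returns `Inf` (a
  constant-within-class, between-class-separated feature is maximally
  discriminative); ties fall back to accession order.
* *Replacement and elitism.* The best half survives unchanged, so the best
  fitness is non-decreasing by construction — an invariant the tests
  assert. Early stopping after 15 generations without improvement
  (configurable) reflects the plateau behavior such runs show in practice.

All stochastic steps derive their seeds from the run seed, and all
tie-breaks are stable (lexical accession order), so `run_memetic()` is
bit-reproducible.

## Prediction models

`pm_config()` freezes the five canonical block combinations: PM1 (40 BPC),
PM2 (5 ATOM), PM3 (65 = BPC + AC), PM4 (45 = BPC + ATOM), PM5 (70 = all).
The five AC properties default to the top 5 of the *pre-selection* ranking
rather than of the final 40-subset: the forward reference in the
architecture points at pre-optimization, and the pre-selection ranking
exists even when the memetic stage is skipped. This is switchable by
passing any 5 accessions.

The classifier is a two-layer feed-forward network — one hidden layer of 23
sigmoid units (a trial-and-error choice frozen as the default, not
re-searched), one sigmoid output, target 1 for amyloidogenic. It is written
in-package as plain full-batch backpropagation on the cross-entropy loss
with momentum (0.9) and a geometrically decaying learning rate (0.1,
×0.999/epoch), because the contracts here demand validation-based early
stopping with best-weight restoration, a complete per-epoch loss history,
and bit-for-bit seed determinism. Weights initialize uniformly in
[−0.5, 0.5] from the seed. Training stops after `patience = 100` epochs
without validation-loss improvement (max 2000 epochs). Data are split
60/20/20 (train/validation/test), stratified by class with a seeded
shuffle; a non-empty validation partition is required, which is why a
(1, 0, 0) split is rejected. Decision threshold 0.5 with score ≥ threshold
called positive — the tie goes to the positive class, matching the target
coding.

## Evaluation conventions

Sn, Sp, BACC = (Sn + Sp)/2 and MCC follow their standard confusion-matrix
definitions; an empty class yields `NA` (never a silent 0), and a zero
factor in the MCC denominator yields MCC = 0, the standard convention. ROC
curves sweep the distinct score values as thresholds (ties collapse to one
operating point), so the trapezoidal AUC equals the Mann-Whitney
concordance probability with ties counted ½ — the tests verify this
identity against an $O(n^2)$ oracle. The quadrant classification splits ROC
space at (FPR, TPR) = (0.5, 0.5); boundary points are assigned to the
*lower* quadrant (a method exactly on a split line gets no credit for the
better half), so (0.5, 0.5) itself is quadrant IV.

## Synthetic data: what it emulates and what it does not

`synthesize_hexmers()` draws residues i.i.d. per position: positives from a
profile concentrated on β/aggregation-prone residues (V, I, F, Y, L, T),
negatives on aggregation breakers (P, G, D, E, K, R) — a modeling choice
informed by the amyloid literature's enrichment patterns, not a claim about
any particular dataset, and fully configurable. `effect` interpolates both
profiles toward uniform: classes are identical at 0 and have disjoint
residue supports at 1. Default sizes (1232 positive / 1280 negative) mirror
the scale of the curated hexmer benchmark this architecture targets, so
runtime profiles are comparable.

`synthesize_indices()` emits standard-normal per-residue values (rejecting
population sd < 0.2, so no near-constant index) with accessions
`SYN0001...`. `synthesize_planted()` builds feature matrices in which only
the planted columns carry a class mean shift. Its default `shift = 1`
noise-sd per feature was chosen on signal-to-noise grounds: one feature
alone is weakly informative (Bayes accuracy ≈ 0.69), while ten planted
features jointly give a Mahalanobis separation of $\sqrt{10} \approx 3.2$
(Bayes accuracy ≈ 0.94) — exactly the regime wrapper-based subset selection
exists for. Larger shifts (e.g. 3) make single features individually
decisive, which is the right fixture for filter-ranking tests but removes
the selection pressure a wrapper test needs.

Passing tests on these generators establishes that the machinery is
correct: encodings match their formulas, the search recovers planted
signal, the networks separate separable classes, and the pipeline is
leakage-free and seed-reproducible. It does *not* establish real-data
performance: i.i.d. per-position draws have no positional structure, no
homology between windows, no label noise, and far cleaner class structure
than experimentally assayed hexmer sets.

## Problem sizes and runtime choices

The test and acceptance runs use reduced problem sizes chosen as sensible
working points for a single CPU: planted-recovery runs use a pool of 60
properties (10 planted) with 100 samples per class, population 10 and 30
generations; the end-to-end runs keep the full 1232/1280 benchmark scale
but give the memetic stage a stratified fitness subsample of 500 training
hexmers, an 8-generation budget, and a pool of 60 properties pre-selected
from 80 synthetic indices. The canonical full-scale defaults (pool 186,
100 generations, full-data fitness) remain the module defaults; only the
pipeline wrapper passes the reduced budgets explicitly.

## Known limitations

* The MCC = 0 and quadrant-boundary conventions are conventions; reports
  carry raw confusion counts so downstream users can apply their own.
* The embedded pre-selection fits one linear SVM at fixed cost 1; features
  whose relevance is purely non-linear can be under-ranked at this stage
  (the memetic stage can still recover them only if they enter the pool).
* The network is a single-hidden-layer sigmoid classifier by design;
  no attempt is made to match any particular historical training
  implementation beyond the stated architecture.
* Fitness caching is limited to carrying parent fitness across
  generations; identical subsets reached twice via different paths are
  re-evaluated.
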