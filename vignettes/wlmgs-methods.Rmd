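---
title: "Weight local modularity for gene subset selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight local modularity for gene subset selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wlmgs)
```

## The model

`wlmgs` treats feature selection as a network question. Given an
`m × n` expression matrix (samples × genes) with class labels drawn from
`C ≥ 2` classes, any gene subset induces a geometry on the samples; the
package summarizes that geometry as a **weighted sample graph** and asks
how cleanly the known classes appear as communities in it.

The graph on a subset `gs` has one node per sample and an undirected edge
between samples `i` and `j` whenever `i ∈ kNN(j)` **or** `j ∈ kNN(i)`
(the *union* rule), weighted by the heat-kernel-like decay

$$A(i,j) = \exp(-d(i,j)), \qquad d(i,j) = \lVert x_i - x_j \rVert_2
\text{ restricted to } gs .$$

There are no self-loops: a self-weight of `exp(0) = 1` would inflate every
class identically and carry no information.

With the classes as fixed communities (never inferred), three scores are
defined from per-class aggregates — internal edge weight $w_k$, boundary
weight $w_{k,out}$ (each boundary edge counted once in *each* adjacent
class, so node strength satisfies $s_k = 2w_k + w_{k,out}$), and
$W_k = w_k + w_{k,out}$:

* **LM**, the unweighted local modularity
  $\sum_k [\, m_k/M_k - (d_k/2M_k)^2 \,]$ over internal edge counts,
  degrees and $M_k = m_k + b_k$;
* **WLM**, its weighted analogue
  $\sum_k [\, w_k/W_k - (s_k/2W_k)^2 \,]$;
* **WLM**$^s$ $= \sum_k w_k / W_k$, the fraction of each class's incident
  weight that stays internal, summed over classes.

`WLM^s` is the selection objective; `LM` and `WLM` are kept for
diagnostics. `WLM^s` is bounded by `[0, C]`, reaches `C` exactly when no
between-class edge survives, and is insensitive to distant outlier
samples, whose incident weights are exponentially small. A class whose
denominator vanishes (no incident edges at all, e.g. a singleton class in
a degenerate fold) contributes 0 rather than `NaN`; this is a deliberate
robustness rule.

For `LM`/`WLM` the denominators $M_k$/$W_k$ count the community's own
internal edges plus its boundary edges only — not the internal edges of
neighbouring communities. This choice keeps the three scores on one
consistent bookkeeping (`community_weights()` is shared by all three) and
makes $W_k = w_k + w_{k,out}$ an exact identity rather than an
approximation.

## The search

`wlmgs_select()` is sequential forward greedy search:

1. start from the single gene maximizing `WLM^s`;
2. at each step score every remaining candidate on the current subset plus
   that candidate, and take the best;
3. stop when the best candidate's score gain is below `theta`, when
   `lambda_max` genes are selected, or when candidates run out.

Squared distances are additive over genes, so the search keeps a running
squared-distance matrix and adds $\;(x_{ig}-x_{jg})^2$ per candidate; only
the `exp`/`sqrt`/k-NN step is recomputed per candidate. A full run costs
$O(\lambda n m^2)$, comfortable at tens of samples and thousands of genes.

Three decisions here were genuinely open:

* **The `theta` rule is applied online and rejects the sub-threshold
  candidate.** When the best remaining gain falls below `theta`, that
  candidate is *not* added, so a reported subset never ends on a gene that
  contributed less than the threshold. The alternative reading (accept,
  then stop) yields subsets one gene longer; it can be emulated with
  `stop_rule = "cap-only"` and post-hoc truncation.
* **Ties break to the smallest gene index**, in the first-gene argmax, in
  every greedy step, and with exact floating-point comparison (no
  tolerance window). With a fixed arithmetic order this makes runs
  bit-for-bit reproducible; cross-platform drift in the last ulp is
  accepted rather than masked.
* **Negative gains are legal** (the score is not monotone in the subset)
  and simply trip the `theta` rule, since any negative gain is below any
  non-negative threshold. `stop_rule = "cap-only"` disables the `theta`
  rule for fixed-length ranking curves.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 7 | neighbours per sample in the WSG; effective range is small (≈3–11) and `k` should stay below the smallest class size; values ≥ m are clamped to m−1 with a warning |
| `theta` | 0.02 | minimum `WLM^s` gain (unitless, on the `[0, C]` score scale) to keep growing the subset |
| `lambda_max` | 15 | hard cap on subset size |
| `stop_rule` | `"increment"` | `"cap-only"` ignores `theta` |

Distances are always computed on the normalized matrix the caller
provides; the package never rescales distances by subset size by default,
so absolute weights shrink as genes accumulate and score gains naturally
taper — this is what makes the `theta` rule an effective automatic
subset-size choice.

## Normalization and the evaluation protocol

`zscore_normalize()` maps each gene to mean 0 and sample (m−1 denominator)
standard deviation 1; constant genes map to all-zero columns and are
reported, never fatal. During cross-validation
(`cross_validated_selection()`) the statistics are fit on the training 90%
only and applied to the held-out 10%: normalizing globally would leak
test-fold information into the training geometry, so the global option
exists only as an explicit `normalize = "global"` escape hatch.

Folds are stratified by class. Plain random folds can leave a small class
absent from a training fold — with a 6-sample class and 10 folds this is
the rule, not the exception — so stratification is the default, with an
automatic, warned fallback to shuffled folds when a class has fewer
samples than folds. Repeated CV (`repeats`) re-draws folds with
consecutive seeds and pools all fold runs.

Held-out accuracy uses two deliberately different classifiers: 1-NN with
Euclidean distance (ties to the smallest training index) and a one-vs-one
soft-margin SVM with RBF kernel at `C = 100`. The RBF bandwidth is
`gamma = 1/(n_genes · var(train))`, the common variance-scaled heuristic;
only cost and kernel family are considered fixed, and a single-class
training fold degrades to majority prediction with a warning rather than
an error.

The consensus subset ranks genes by the number of fold runs that selected
them (ties: mean selection rank, then index) and takes the top genes at
the most common fold-subset size. Both the mean fold-subset size and the
consensus size are reported, since either is a defensible notion of "the"
subset size.

## Why the objective is sensible: the k-means connection

With class-conditional means as fixed centres, the within-class k-means
objective $J(C,\mu) = \sum_i \lVert x_i - \mu_{c(i)} \rVert^2$ measures
exactly what a good subset should shrink. Gene subsets that compress
classes (small within-class distances, large $w_k$) and separate them
(large between-class distances, small $w_{k,out}$) drive `WLM^s` up and
`J` down together. The package does not assert the strict equivalence of
the two optimizations — the k-NN truncation and the exponential weighting
break any exact correspondence — but it does test the directional claim:
across single-gene subsets spanning effect sizes 0–3 SD, the Spearman
correlation between `WLM^s` and `−J` is required to exceed 0.5 (observed
≈ 0.8 in the acceptance run). `kmeans_objective()` uses squared distances,
the standard k-means form; `squared = FALSE` is available for sensitivity
checks.

## The synthetic generator

`generate_dataset()` emulates class-structured continuous expression data
at the scale where this method is meant to operate: tens of samples,
10²–10⁴ genes, 2–5 classes, optional imbalance.

* **Informative genes**: class-conditional Gaussians with unit SD. Class
  centroids sit on a regular simplex with unit pairwise distance, cycled
  across the informative-gene axes and scaled by `effect_size`, so every
  pair of classes is equally separated and no gene accidentally favours
  one pair. `effect_size` is therefore the between-class mean separation
  in within-class SD units; it may be a vector (one value per informative
  gene), which the k-means-direction harness uses to span a range of
  signal strengths in one dataset.
* **Noise genes**: standard normal, independent of class.
* **Redundant genes**: copies of informative genes plus `N(0, 0.1)`
  jitter — near-duplicates without exact ties, to exercise redundancy
  handling.
* **Outlier samples**: redrawn at `N(0, 5)` on every gene while keeping
  their true label, to exercise the outlier-attenuation property of the
  exponential weights.
* **Within-class sub-clusters** (optional): ±1 mean shifts inside a
  class, emulating local cluster structure that the local (rather than
  global) modularity is designed to reward.

Everything is reproducible from `seed`. What the generator does *not*
emulate: intensity-dependent variance, batch effects, gene–gene
correlation beyond the planted redundancy, or heavy-tailed platform
noise. Passing tests on this generator therefore demonstrate the
machinery and its contracts, not performance on any real platform.

## Numerical choices and degenerate inputs

* Squared-distance matrices are symmetrized exactly
  (`(D + t(D))/2`, negatives from cancellation clipped at 0) so the k-NN
  step never sees asymmetric rounding.
* k-NN ties break by ascending sample index (stable order), making graph
  construction independent of input shuffling once sample order is fixed.
* Constant genes: zero distance contribution everywhere; they are
  reported by normalization and are harmless to selection.
* Reading rejects any non-numeric cell (including `NA`) with its row and
  column named; duplicate identifiers are errors, not silently
  uniquified. Written matrices round-trip at full precision (17
  significant digits).

## Problem sizes used by the test suite

The suite and the acceptance script run entirely on generated data: score
oracles on 50 random graphs of up to 15 nodes; selection panels of 20
seeds at 60 samples × 100 genes (the default design: 5 informative genes
at 2 SD separation, 95 noise); pure-noise panels at 40 × 100; the k-means
direction on 200 single-gene subsets at 40 × 200; and one 10-fold CV per
protocol check. These sizes keep a full run in a few minutes while staying
in the method's intended small-m regime.

## Known limitations

* **Score saturation makes the selector parsimonious, not exhaustive.**
  `WLM^s` is capped at `C`; once the classes are locally separated the
  remaining headroom is small, gains collapse, and the `theta` rule stops
  after a handful of genes. The test suite's recovery panels show the
  consequence directly: at 2 SD effect size the median run recovers 4 of
  5 planted informative genes, and *stronger* signal yields *smaller*
  subsets (separation is achieved sooner), not fuller recovery. If the
  goal is to enumerate all relevant genes rather than find a small
  sufficient panel, run with `stop_rule = "cap-only"` and read the full
  trajectory.
* **Near saturation the greedy argmax is an extreme-value draw.** When
  genuine gains shrink to the order of `theta`, the best of ~100
  chance-aligned noise genes can out-score the last true informative
  gene on a given draw; occasional noise picks in the final steps are
  expected behaviour at desk-scale sample sizes, not a defect.
* Exact k-NN is used throughout; no approximate graph construction is
  provided, which is the right trade-off at tens of samples but not at
  thousands.
* The method assumes classes form (possibly multi-cluster) compact
  regions in some gene subspace; label noise and strongly non-metric
  class structure are out of scope, as are missing values and raw
  platform formats.
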