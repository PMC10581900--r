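---
title: "Methods: disparity, morphospaces and complexity in morphodisp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disparity, morphospaces and complexity in morphodisp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Quantifying phenotypic disparity — the variety of bodyplans within and
between clades — over deep time requires stitching together several
pieces of machinery: a discrete morphological character matrix scored
for living and fossil taxa, a dated phylogeny, a dissimilarity measure
that tolerates missing and inapplicable scores, a low-dimensional
morphospace, and statistics that summarise how that space is occupied
by clades and through time. Fossils make this hard in a specific way:
a macrofossil rarely preserves the whole organism, so fossil taxa
carry large, *non-random* blocks of missing data (whole organ systems
at a time), and naive ordination clusters them by what they fail to
preserve rather than by what they were. `morphodisp` implements the
full workflow, with probabilistic phylogenetic imputation of the
missing scores as the step that removes that artefact, and ships a
synthetic-data generator with recorded truth so every stage can be
validated end to end without any external data.

# Character matrices

A `character_matrix` is taxa x characters with cells in 0..9, missing
(`?`) or inapplicable (`-`). The two non-states are semantically
different: missing means "not observed", inapplicable means "cannot
logically be scored" (a petal character for an alga). Polymorphic
cells such as `{01}` are collapsed to missing with a logged count —
the downstream unordered Mk machinery has no polymorphism concept, and
losing a handful of ambiguous scores is preferable to inventing a
resolution rule. Characters belong to named, possibly overlapping
categories (sporophyte, gametophyte, reproductive organ systems, ...)
used to build trait-subset morphospaces via `subset_characters()`.

For complexity analyses, `recode_presence()` converts characters to
presence/absence. Inapplicable recodes to absent: an organ that cannot
exist is not present. This is a modelling choice with a visible
alternative — `applicable_proportion()` scores each taxon by the
fraction of characters that are applicable at all, and serves as the
robustness check on the recode. `applicable_proportion()` excludes
missing cells from its denominator by default so that poorly known
taxa are not penalised twice (once for ignorance, once for absence);
`include_missing = TRUE` flips that.

# The Mk model and imputation

Each character evolves independently under the equal-rates k-state
Markov (Mk) model: every transition has rate `q`, giving the closed
form `P(same) = 1/k + (k-1)/k * exp(-kqt)`. Equal rates is the
standard regime for matrices of unordered multistate characters with
no prior asymmetry information; asymmetric or ordered models are out
of scope. Likelihoods use Felsenstein pruning; `fit_rate()` maximises
over `q` on a log scale by bounded 1-D optimisation, per character and
per tree. Invariant characters (and characters with a single scored
tip) carry no rate information and get a floor rate of 1e-8/Myr,
flagged.

`stochastic_map()` samples complete character histories: node states
root-down from the pruning conditionals, then each branch conditional
on its endpoints. For the equal-rates model the uniformization chain
with rate `kq` has a uniform jump matrix, so the endpoint-conditioned
jump count is Poisson (zero-truncated when the endpoints differ, mixed
with a point mass at zero when they agree) and intermediate states are
i.i.d. uniform — endpoint conditioning is exact, with no rejection
loop needed in practice.

`impute_matrix()` is the centrepiece: for every character and every
tree in a (posterior) sample, fit the rate, fix observed tips with
probability 1, give missing tips a uniform prior over that character's
*observed* states (states never observed for a character cannot be
assigned meaningfully), draw `n_sims` maps, and record the modal
sampled state per missing tip and per node. The consensus across
trees is the modal per-tree state; ties break deterministically to the
lowest state code and are flagged. Internal nodes are reported on the
first tree's topology, with nodes of other trees contributing through
exact clade (tip-set) matches only — nodes with no identical clade in
a sample tree simply contribute nothing for that tree. Inapplicable
cells pass through untouched. The modal state stabilises quickly in
`n_sims` (it estimates an argmax, not a density), which is why the
packaged analyses use 100 maps per character per tree rather than
1000; the parameter is exposed.

# Dissimilarities

`gower_distance()` computes, per pair, the fraction of *comparable*
characters on which the taxa differ, all characters unordered (any
difference scores 1). A character is comparable when both cells hold a
coded state; under the default `ignore_matching_zeros` mode a shared
zero is also discarded, so shared absence — including inapplicability
recoded to absence — carries no signal and does not draw organ-poor
taxa together. Whether *all* matching zeros or only
inapplicability-induced ones should be discarded is genuinely
ambiguous for matrices like these, so both modes are first-class and
the tests exercise both. Pairs with no comparable characters have no
defined distance; they are imputed to the maximum observed distance
and flagged rather than aborting (the flag propagates to NMDS as a
zero weight). `euclidean_distance()` is the metric counterpart,
rescaled by `sqrt(total/comparable)` to offset missingness.

# Ordination

`nmds()` is Kruskal-style non-metric MDS fitted by majorization
(SMACOF): each iteration fits monotone disparities to the current
configuration distances by weighted pool-adjacent-violators (primary
tie handling — tied observed dissimilarities are free to take
different fitted values), then applies the Guttman transform. Three
numerical choices matter:

* a backtracking safeguard halves any update that would increase
  stress-1, so the recorded stress sequence is non-increasing by
  construction;
* because stress-1 is scale-invariant, the configuration is
  re-anchored to the data scale after every accepted update (a joint
  rescaling that leaves stress-1 unchanged) — without this the
  configuration can drift towards collapse with stress unchanged;
* flagged (undefined) pairs get zero weight in both the isotonic fit
  and the Guttman transform.

Defaults: `k = 2`, 20 starts (one classical-scaling start, the rest
random), tolerance 1e-7 on the stress change, 500 iterations. Axes
are centred and sign-standardised so runs are comparable. `pcoa()`
delegates to classical scaling (double-centred squared distances,
eigendecomposition); negative eigenvalues are reported uncorrected,
matching common practice when PCoA is used only as a metricity check
against the NMDS (via `ordination_concordance()`, a Mantel test
between the two embeddings' distance matrices).

`phylomorphospace()` ordinates tips and reconstructed nodes *jointly*,
so node positions are informed by their imputed character distances to
living taxa, and returns the tree's edges as unit-label pairs for
drawing branches in morphospace. `convex_hull()` (monotone chain,
counterclockwise) outlines each clade's occupied envelope.

# Disparity

`mean_disparity()` is the mean pairwise distance within each group;
`partial_disparity()` is the Foote-style contribution of each group to
total disparity: the sum of squared distances to the grand centroid
divided by `n - 1` with `n` the total unit count. Squared distances
are the default because they make partial disparities over a partition
sum *exactly* to the total sum of variances (the additivity identity,
asserted to 1e-10 in the tests); the unsquared reading of "mean
distance to the overall centroid" is available as a flag. Bootstrap
envelopes (2.5/25/50/75/97.5 percentiles, 1000 replicates by default)
resample the units of the statistic being computed — group members for
the group indices, slice points for the time curve — which is the only
resampling unit that is well-defined for every statistic here.

`dtt()` slices the dated tree every 50 Myr (plus one slice at the root
age) and, at each slice, lets every crossing branch contribute one
morphospace point: linear interpolation between parent-node and child
coordinates in proportion to elapsed time (gradual model), or the
parent's or child's coordinates chosen uniformly at random,
re-randomised per bootstrap replicate so model uncertainty enters the
envelopes (punctuated model). A slice exactly at a branch's child
endpoint always takes the child's coordinates under both models, which
pins the present-day slice to the static disparity of the extant tips.
Slice membership is closed at the child (`parent age > t >= child
age`), so extinct tips drop out of slices younger than their age. The
statistic per slice is the sum of variances of the slice points;
slices with fewer than two lineages report 0, flagged. DTT operates on
ordination coordinates (tips plus reconstructed nodes), not on raw
distances; distance-space slicing is out of scope.

# Complexity and ploidy

`complexity_scores()` counts present-coded characters per taxon.
`ancestral_complexity()` reconstructs every binary character with the
same stochastic-mapping consensus machinery and reports both a modal
score (integer) and an expected score (the sum of per-character
presence frequencies across trees, fractional) — the expected score is
the better summary when reconstructions are uncertain, and is why
reconstructed node values need not be integers.
`ploidy_complexity_correlation()` takes whole-genome-duplication
events as per-branch counts (no inference of WGD placement is
attempted), accumulates them along root-to-tip paths, and correlates
them with complexity either by phylogenetically independent contrasts
(through-origin Pearson on the contrasts, t-based p on `n - 2` degrees
of freedom — the headline method) or by a rank correlation of raw tip
values.

# The synthetic generator

`synthetic_scenario()` fixes the study conditions; all generators are
bit-reproducible from its seed. The defaults describe a desk-scale
analogue of a kingdom-level analysis:

* 64 extant + 16 fossil tips on a birth-death tree rescaled to a
  500-Ma root — deep enough that 50-Myr time slices produce a real
  curve, small enough that the full pipeline runs in minutes;
* 200 unordered characters, state counts 2-4 (60/30/10%), per-Myr
  rates log-normal around 0.001 with sdlog 0.75 — a slow,
  morphology-like regime giving of the order of a handful of state
  changes per character across the whole tree;
* 20% of extant cells missing independently; fossil tips instead lose
  *entire categories* (gametophytic, sperm-cell and root characters by
  default — the organ systems plant macrofossils essentially never
  preserve). The block structure is the point: it reproduces the
  shared-missingness clustering artefact, and `missingness_distance()`
  plus `group_silhouette()` quantify that artefact before and after
  imputation (fossils sit at silhouette ~1 on their missingness
  patterns before, ~0 after);
* ploidy events Poisson with 0.004 events/Myr of branch, so root-to-tip
  cumulative counts span roughly 0-5 — the range over which mean
  complexity is expected to climb — with an optional coupling that
  raises per-character presence probability by 0.5 logits per
  inherited event, creating a known true ploidy-complexity correlation
  for recovery tests;
* a `stem_multiplier` on the root's two child branches creates
  two-regime scenarios whose basal clades form separated morphospace
  clusters.

A posterior tree sample is emulated by multiplicative log-normal
jitter (sd 0.1) of the true tree's branch lengths with the topology
fixed; dated trees are required input throughout, and the package does
not time-scale trees itself.

What the generator does *not* emulate: correlated characters and
morphological integration, ordered characters, taxon-sampling biases
beyond the fossil block mask, topological uncertainty in the tree
sample, and polymorphism. Passing tests therefore demonstrate the
machinery is correct under the stated model, not that real matrices
satisfy that model.

# Determinism and problem sizes

Every stochastic routine takes a seed; `impute_matrix()` derives a
deterministic stream per (tree, character) from one master seed, and
`run_pipeline()` fans a master seed out into named per-stage streams
recorded in `manifest.json`, so a config plus seed reproduces every
output byte for byte (this is asserted in the tests by hashing two
independent runs). The test suite and the acceptance script run the
scenario at its default size (80 tips x 200 characters, 1-3 trees,
100 maps per character per tree, 500-1000 bootstrap replicates),
chosen so the whole validation completes in a few minutes on one core;
all sizes scale up through the exposed parameters.

# Known limitations

* Node matching across tree samples is by exact clade identity, so
  topologically diverse samples contribute little node information off
  the reference topology; a majority-rule or MRCA-based matcher would
  be the natural extension.
* The equal-rates Mk model is fitted per character per tree by ML; no
  rate variation across branches, no correlated evolution, no
  gamma-over-characters.
* Gower's unordered semantics ignore `ordered_flags`; ordered
  (morphocline) range scaling is not implemented.
* NMDS stress targets Kruskal stress-1 only; other stress variants and
  3-D+ visualisation are out of scope.
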