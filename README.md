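# morphodisp

Morphospaces, disparity through time and phenotypic complexity from
discrete morphological character matrices and dated phylogenies.

## The problem

Phenotypic **disparity** — how much morphological variety a set of
organisms spans — is measured from a taxa × characters matrix of
discrete scores, ordinated into a low-dimensional morphospace and
summarised per clade and per time slice. Doing this across deep time
forces three technical problems that this package solves together:

1. **Fossils are mostly missing data, and not at random.** A
   macrofossil preserves some organ systems and none of the others, so
   raw ordinations cluster fossil taxa by their shared *missingness*
   rather than their morphology. `morphodisp` removes this artefact by
   probabilistic imputation: each character is modelled with the
   equal-rates k-state Markov (Mk) model, whose transition probability
   is `P(i→i; t) = 1/k + (k−1)/k·e^(−kqt)`, the rate `q` fitted by
   maximum likelihood per character per tree; missing tip states and
   all ancestral node states are then sampled by stochastic character
   mapping (node states root-down from the pruning conditionals,
   branch histories by exact endpoint-conditioned uniformization), and
   the modal sampled state per tree, then across a posterior tree
   sample, fills the matrix.
2. **Discrete characters need a missing/inapplicable-aware
   dissimilarity.** Gower's coefficient is computed over the
   characters *comparable* for each pair (both scored; optionally also
   discarding matching zeros so shared absence carries no signal),
   then embedded by non-metric multidimensional scaling (Kruskal
   stress-1, SMACOF majorization with a monotone safeguard) with a
   PCoA cross-check of metricity.
3. **Disparity statistics need phylogenetic context.** Clade
   disparity is the mean pairwise distance and the Foote partial
   disparity Σ‖x−centroid‖²/(n−1) (which sum, over a partition, to the
   total sum of variances); disparity through time slices the dated
   tree every 50 Myr and lets every branch alive at a slice contribute
   an interpolated (gradual) or endpoint (punctuated) morphospace
   point; complexity is the count of present-coded characters, tested
   against cumulative whole-genome-duplication counts with
   phylogenetically independent contrasts.

A synthetic-data generator with recorded truth (clade-structured
birth–death time trees with fossil tips, Mk characters, i.i.d. extant
and block-structured fossil missingness, Poisson ploidy events) makes
the entire pipeline testable end to end.

## Worked example

```r
library(morphodisp)

sc  <- synthetic_scenario(seed = 42, n_extant = 32, n_fossil = 8,
                          n_characters = 120)
b   <- simulate_scenario(sc, n_trees = 2)
b$matrix
#> character_matrix: 40 taxa x 120 characters
#>   missing: 1142  inapplicable: 0
#>   partitions: sporophyte, gametophyte, branching_appendages, ...

imp <- impute_matrix(b$matrix, b$trees, n_sims = 100, seed = 1)
acc <- imputation_accuracy(imp, b$truth$matrix, b$mask)
sprintf("accuracy %.3f vs chance %.3f on %d masked cells",
        acc$accuracy, acc$chance, acc$n_scored)
#> "accuracy 0.780 vs chance 0.665 on 1142 masked cells"
```

The imputed focal matrix (tips plus 39 reconstructed ancestors) feeds
the morphospace and the downstream statistics:

```r
g   <- gower_distance(imp$combined)
ord <- nmds(g, k = 2, n_starts = 10, seed = 1)
ord
#> NMDS ordination: 79 units in 2 dimension(s); stress = 0.2056

curve <- dtt(ord, b$tree, model = "gradual", bin_Myr = 100,
             n_boot = 500, seed = 3)
curve[, c("time_Ma", "n_lineages", "estimate")]
#>   time_Ma n_lineages estimate
#> 1     500          2  0.00000
#> 2     400          2  0.00261
#> 3     300          7  0.00295
#> 4     200         14  0.03970
#> 5     100         20  0.10479
#> 6       0         32  0.17575
```

Read: the imputation recovered 78% of deliberately masked cells
(against a 66.5% best-naive-guess rate); the 79-unit morphospace has
Kruskal stress 0.21 in two dimensions; and disparity (sum of
variances among the lineages crossing each 100-Myr slice) rises from
zero at the 500-Ma root to 0.176 among the 32 extant tips — the
expanding-variance signature built into this scenario. Clade
summaries (`mean_disparity()`, `partial_disparity()` with bootstrap
envelopes), convex hulls, complexity scores and the
ploidy–complexity contrast correlation follow the same pattern; or run
everything at once:

```r
res <- run_pipeline(pipeline_config("out/", seed = 1))
```

which writes one CSV/JSON artifact per stage plus a `manifest.json`
recording parameters and per-stage seeds (identical config + seed
gives byte-identical outputs).

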