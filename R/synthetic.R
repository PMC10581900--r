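# Synthetic data with known truth: clade-structured dated birth-death
# trees with fossil tips, unordered multistate characters evolved
# under the equal-rates Mk model, random extant missingness plus
# block-structured ("fossil-like") missingness, and Poisson-placed
# genome-duplication events. Every generator is reproducible under the
# scenario seed.

.category_names <- c("sporophyte", "gametophyte", "branching_appendages",
                     "shoot_anatomy", "roots_symbionts",
                     "zoospores_spermatozoids", "spores_pollen_embryology",
                     "sporophylls_sporangia")

#' Define a synthetic study scenario
#'
#' The scenario fixes every generator parameter: tree size and
#' timescale, character count and state-number distribution, per-Myr
#' Mk rates, the missingness regime (i.i.d. on extant tips,
#' whole-category blocks on fossil tips, mimicking what macrofossils
#' cannot preserve) and the ploidy process. Defaults describe a
#' desk-scale analogue of a kingdom-level supermatrix: 64 extant plus
#' 16 fossil tips on a deep (500 Ma) time tree scored for 200
#' unordered characters in eight overlapping morphological categories,
#' 20% of extant cells missing at random and gametophytic,
#' sperm-cell and root characters unobservable in fossils.
#'
#' @param seed Master seed; all derived simulations consume streams
#'   seeded from it.
#' @param n_extant,n_fossil Extant and fossil (extinct) tip counts.
#' @param birth,death Birth-death rates used for topology simulation
#'   (the tree is subsequently rescaled to `root_age_Ma`).
#' @param root_age_Ma Root age of the rescaled tree.
#' @param n_characters Number of characters.
#' @param state_probs Named probabilities for the per-character state
#'   count k (names "2", "3", ...).
#' @param q_mean,q_sdlog Log-normal distribution of per-character Mk
#'   rates (per Myr). The default gives of the order of a handful of
#'   state changes per character across the whole tree, the slow
#'   regime typical of conserved morphological traits.
#' @param stem_multiplier Rate multiplier applied to the root's two
#'   child branches; values well above 1 make the two basal clades
#'   diverge into separate morphospace clusters (two-regime scenario).
#' @param clade_multipliers Length-2 numeric: rate multipliers for all
#'   branches inside the root's first and second child clades.
#' @param extant_missing Fraction of extant cells masked i.i.d.
#' @param fossil_block Character-category names wholly unobservable in
#'   fossil tips.
#' @param ploidy_rate Whole-genome-duplication events per Myr of
#'   branch.
#' @param ploidy_effect Logit shift in per-character presence
#'   probability per inherited duplication event (couples complexity
#'   to ploidy history with a known true effect).
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed = 1L, n_extant = 64, n_fossil = 16,
                               birth = 1, death = 0.3, root_age_Ma = 500,
                               n_characters = 200,
                               state_probs = c("2" = 0.6, "3" = 0.3,
                                               "4" = 0.1),
                               q_mean = 0.001, q_sdlog = 0.75,
                               stem_multiplier = 1,
                               clade_multipliers = c(1, 1),
                               extant_missing = 0.2,
                               fossil_block = c("gametophyte",
                                                "zoospores_spermatozoids",
                                                "roots_symbionts"),
                               ploidy_rate = 0.004,
                               ploidy_effect = 0.5) {
  stopifnot(extant_missing >= 0, extant_missing <= 1,
            birth > 0, death >= 0, q_mean > 0, ploidy_rate >= 0,
            n_extant >= 2, n_fossil >= 0)
  if (n_fossil > 0 && death == 0) {
    stop("fossil tips require a positive death rate")
  }
  stopifnot(all(fossil_block %in% .category_names))
  structure(list(seed = as.integer(seed), n_extant = n_extant,
                 n_fossil = n_fossil, birth = birth, death = death,
                 root_age_Ma = root_age_Ma, n_characters = n_characters,
                 state_probs = state_probs, q_mean = q_mean,
                 q_sdlog = q_sdlog, stem_multiplier = stem_multiplier,
                 clade_multipliers = clade_multipliers,
                 extant_missing = extant_missing,
                 fossil_block = fossil_block, ploidy_rate = ploidy_rate,
                 ploidy_effect = ploidy_effect),
            class = "synthetic_scenario")
}

#' Simulate the scenario's dated tree
#'
#' Birth-death tree conditioned on the extant tip count (retrying
#' until at least `n_fossil` extinct lineages were produced, then
#' down-sampling the extinct tips to exactly `n_fossil`), rescaled so
#' the root sits at `root_age_Ma`. Extant tips are labelled `sp_*`,
#' fossil tips `fos_*`.
#'
#' @param scenario A [synthetic_scenario()].
#' @param max_tries Retry budget for the conditioning.
#' @return A rooted, dated `phylo`.
#' @export
simulate_tree <- function(scenario, max_tries = 200) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  for (i in seq_len(max_tries)) {
    tr <- phytools::pbtree(b = scenario$birth, d = scenario$death,
                           n = scenario$n_extant, extant.only = FALSE,
                           quiet = TRUE)
    if (is.null(tr) || !inherits(tr, "phylo")) next
    ages <- node_ages(tr)[seq_len(ape::Ntip(tr))]
    extinct <- which(ages > 1e-8)
    extant <- which(ages <= 1e-8)
    if (length(extant) != scenario$n_extant) next
    if (length(extinct) < scenario$n_fossil) next
    if (length(extinct) > scenario$n_fossil) {
      drop <- sample(extinct, length(extinct) - scenario$n_fossil)
      tr <- ape::drop.tip(tr, tr$tip.label[drop])
    }
    tr$edge.length <- tr$edge.length * scenario$root_age_Ma / root_age(tr)
    # snap numerically-extant tips (simulator rounding) to age exactly 0
    ages <- node_ages(tr)[seq_len(ape::Ntip(tr))]
    tol <- scenario$root_age_Ma * 1e-6
    snap <- which(ages > 0 & ages < tol)
    for (ti in snap) {
      e <- which(tr$edge[, 2] == ti)
      tr$edge.length[e] <- tr$edge.length[e] + ages[ti]
    }
    ages <- node_ages(tr)[seq_len(ape::Ntip(tr))]
    extinct <- ages > tol
    lab <- character(ape::Ntip(tr))
    lab[!extinct] <- sprintf("sp_%03d", seq_len(sum(!extinct)))
    lab[extinct] <- sprintf("fos_%03d", seq_len(sum(extinct)))
    tr$tip.label <- lab
    return(tr)
  }
  stop("could not condition the birth-death tree after ", max_tries,
       " tries")
}

# Per-edge rate multipliers: clade multipliers inside the root's two
# child clades plus the stem multiplier on the two stem branches.
.edge_multipliers <- function(tree, scenario) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  mult <- rep(1, nrow(tree$edge))
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  for (ci in seq_along(kids)) {
    cm <- scenario$clade_multipliers[min(ci,
                                         length(scenario$clade_multipliers))]
    desc <- if (kids[ci] <= ntip) kids[ci] else
      c(kids[ci], phangorn_free_descendants(tree, kids[ci]))
    inside <- tree$edge[, 1] %in% desc
    mult[inside] <- cm
    stem <- which(tree$edge[, 1] == root & tree$edge[, 2] == kids[ci])
    mult[stem] <- scenario$stem_multiplier
  }
  mult
}

# All descendants (internal + tips) of a node, without extra deps.
phangorn_free_descendants <- function(tree, node) {
  out <- integer(0)
  todo <- node
  while (length(todo)) {
    ch <- tree$edge[tree$edge[, 1] %in% todo, 2]
    out <- c(out, ch)
    todo <- ch[ch > ape::Ntip(tree)]
  }
  out
}

#' Simulate the scenario's character matrix (with truth)
#'
#' Each character evolves under the equal-rates Mk model with its own
#' log-normal rate (times per-edge clade/stem multipliers), a uniform
#' root state, and a state count drawn from the scenario's
#' distribution. Characters are assigned to eight overlapping
#' morphological categories. The complete matrix and the true node
#' states are returned as truth records.
#'
#' @param tree Dated `phylo` from [simulate_tree()].
#' @param scenario A [synthetic_scenario()].
#' @return List: `matrix` (complete [character_matrix()] with category
#'   partitions), `node_states` (internal-node truth, nodes x
#'   characters), `rates` (per-character q), `k` (per-character state
#'   count).
#' @export
simulate_characters <- function(tree, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed + 1L)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  nc <- scenario$n_characters
  ks <- as.integer(sample(names(scenario$state_probs), nc, replace = TRUE,
                          prob = scenario$state_probs))
  qs <- stats::rlnorm(nc, meanlog = log(scenario$q_mean),
                      sdlog = scenario$q_sdlog)
  mult <- .edge_multipliers(tree, scenario)
  co <- ape::reorder.phylo(tree, "cladewise")
  states <- matrix(0L, ntip + nnode, nc)
  root <- ntip + 1L
  for (ci in seq_len(nc)) {
    k <- ks[ci]
    states[root, ci] <- sample.int(k, 1) - 1L
    for (e in seq_len(nrow(co$edge))) {
      par <- co$edge[e, 1]; ch <- co$edge[e, 2]
      P <- mk_transition(k, qs[ci] * mult[e], co$edge.length[e])
      states[ch, ci] <- sample.int(k, 1,
                                   prob = P[states[par, ci] + 1L, ]) - 1L
    }
  }
  char_ids <- sprintf("c%03d", seq_len(nc))
  cells <- states[seq_len(ntip), , drop = FALSE]
  dimnames(cells) <- list(tree$tip.label, char_ids)
  primary <- rep(.category_names, length.out = nc)
  partitions <- lapply(.category_names, function(g) char_ids[primary == g])
  names(partitions) <- .category_names
  # overlap: every sporophyte character also belongs to shoot_anatomy
  # for a non-mutually-exclusive category structure
  overlap <- char_ids[primary == "sporophyte"][c(TRUE, FALSE)]
  partitions$shoot_anatomy <- sort(union(partitions$shoot_anatomy, overlap))
  node_states <- states[(ntip + 1L):(ntip + nnode), , drop = FALSE]
  dimnames(node_states) <- list(paste0("node_", (ntip + 1L):(ntip + nnode)),
                                char_ids)
  list(matrix = character_matrix(cells, partitions = partitions),
       node_states = node_states, rates = qs, k = ks)
}

#' Mask cells according to the scenario's missingness regime
#'
#' Extant-tip cells are masked independently at the scenario fraction;
#' fossil tips lose every character of the blocked categories in one
#' block (the non-random, organ-level missingness typical of plant
#' macrofossils). The mask is returned for recovery scoring.
#'
#' @param m Complete [character_matrix()].
#' @param scenario A [synthetic_scenario()].
#' @param tree The scenario tree (identifies fossil tips by positive
#'   age).
#' @return List: `matrix` (masked), `mask` (logical matrix, TRUE =
#'   masked).
#' @export
apply_missingness <- function(m, scenario, tree) {
  stopifnot(inherits(m, "character_matrix"),
            inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed + 2L)
  cells <- m$cells
  mask <- matrix(FALSE, nrow(cells), ncol(cells),
                 dimnames = dimnames(cells))
  extinct <- is_extinct_tip(tree)
  extant_rows <- rownames(cells)[!extinct[rownames(cells)]]
  if (scenario$extant_missing > 0 && length(extant_rows)) {
    sub <- matrix(stats::runif(length(extant_rows) * ncol(cells)) <
                    scenario$extant_missing,
                  length(extant_rows), ncol(cells))
    mask[extant_rows, ] <- sub
  }
  fossil_rows <- rownames(cells)[extinct[rownames(cells)]]
  block_chars <- unique(unlist(m$partitions[scenario$fossil_block]))
  if (length(fossil_rows) && length(block_chars)) {
    mask[fossil_rows, block_chars] <- TRUE
  }
  cells[mask] <- NA_integer_
  list(matrix = character_matrix(cells, partitions = m$partitions,
                                 ordered = m$ordered),
       mask = mask)
}

#' Place ploidy events and optionally couple them to complexity
#'
#' Whole-genome-duplication events fall on each branch as a Poisson
#' draw with mean `ploidy_rate * branch length`; tips accumulate the
#' events on their root-to-tip path. When `n_presence_characters > 0`
#' a presence/absence matrix is also generated whose per-character
#' presence probability increases by `ploidy_effect` logits per
#' inherited event, giving a known true ploidy-complexity coupling.
#'
#' @param tree Dated `phylo`.
#' @param scenario A [synthetic_scenario()].
#' @param n_presence_characters Characters in the coupled presence
#'   matrix (0 = skip).
#' @param base_presence Baseline presence probability per character.
#' @return List: `ploidy` (a [ploidy_annotation()]) and, when
#'   requested, `presence` (a `presence_matrix`).
#' @export
assign_ploidy <- function(tree, scenario, n_presence_characters = 0,
                          base_presence = 0.3) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed + 3L)
  events <- stats::rpois(nrow(tree$edge),
                         scenario$ploidy_rate * tree$edge.length)
  ann <- ploidy_annotation(tree, events)
  out <- list(ploidy = ann)
  if (n_presence_characters > 0) {
    ntip <- ape::Ntip(tree)
    shift <- scenario$ploidy_effect * ann$tip_events[tree$tip.label]
    p <- stats::plogis(stats::qlogis(base_presence) + shift)
    cells <- matrix(as.integer(stats::runif(ntip *
                                              n_presence_characters) <
                                 rep(p, n_presence_characters)),
                    ntip, n_presence_characters,
                    dimnames = list(tree$tip.label,
                                    sprintf("p%03d",
                                            seq_len(n_presence_characters))))
    out$presence <- structure(list(cells = cells),
                              class = "presence_matrix")
  }
  out
}

#' Generate a complete scenario bundle
#'
#' Convenience wrapper running [simulate_tree()],
#' [simulate_characters()], [apply_missingness()] and
#' [assign_ploidy()], plus a perturbed tree sample standing in for a
#' posterior sample (branch lengths jittered multiplicatively around
#' the true tree, topology fixed).
#'
#' @param scenario A [synthetic_scenario()].
#' @param n_trees Size of the perturbed tree sample (the first tree is
#'   the true tree).
#' @param bl_jitter_sd Log-normal standard deviation of the branch
#'   length jitter.
#' @return List: `scenario`, `tree`, `trees` (a [tree_sample()]),
#'   `truth` (complete matrix + node states), `matrix` (masked),
#'   `mask`, `ploidy`.
#' @export
simulate_scenario <- function(scenario, n_trees = 1, bl_jitter_sd = 0.1) {
  tree <- simulate_tree(scenario)
  chars <- simulate_characters(tree, scenario)
  masked <- apply_missingness(chars$matrix, scenario, tree)
  pl <- assign_ploidy(tree, scenario)
  set.seed(scenario$seed + 4L)
  trees <- list(tree)
  if (n_trees > 1) {
    for (i in seq_len(n_trees - 1)) {
      tr <- tree
      tr$edge.length <- tr$edge.length *
        stats::rlnorm(length(tr$edge.length), 0, bl_jitter_sd)
      trees[[i + 1]] <- tr
    }
  }
  list(scenario = scenario, tree = tree, trees = tree_sample(trees),
       truth = chars, matrix = masked$matrix, mask = masked$mask,
       ploidy = pl$ploidy)
}

#' Score imputation recovery against the generator's truth
#'
#' Accuracy of the imputed focal matrix on the masked cells, against
#' the chance rate of a frequency guesser that always predicts each
#' character's most common observed (unmasked) state.
#'
#' @param imp An `imputation` from [impute_matrix()].
#' @param truth Complete [character_matrix()] (pre-masking).
#' @param mask Logical matrix from [apply_missingness()].
#' @return List: `accuracy`, `chance`, `n_scored`.
#' @export
imputation_accuracy <- function(imp, truth, mask) {
  focal <- imp$focal$cells
  tc <- truth$cells[rownames(focal), colnames(focal)]
  msk <- mask[rownames(focal), colnames(focal)]
  scored <- msk & !is.na(focal) & !is.na(tc) & tc != INAPPLICABLE
  acc <- mean(focal[scored] == tc[scored])
  # per-character modal observed state among unmasked cells
  hits <- 0; tot <- 0
  for (j in seq_len(ncol(tc))) {
    cells_j <- tc[, j]
    obs <- cells_j[!msk[, j] & !is.na(cells_j) & cells_j != INAPPLICABLE]
    sc <- which(scored[, j])
    if (!length(sc)) next
    if (!length(obs)) next
    counts <- table(obs)
    guess <- as.integer(names(counts)[which.max(counts)])
    hits <- hits + sum(tc[sc, j] == guess)
    tot <- tot + length(sc)
  }
  list(accuracy = acc, chance = if (tot > 0) hits / tot else NA_real_,
       n_scored = sum(scored))
}

#' Distance between missingness patterns
#'
#' Pairwise proportion of characters on which two taxa disagree about
#' being missing (the Hamming distance between their is-missing
#' indicator vectors). Fossil taxa that share organ-level blocks of
#' missing data sit at distance ~0 from one another here, which is the
#' mechanism behind their artefactual clustering in raw-data
#' ordinations.
#'
#' @param m A [character_matrix()].
#' @return A [dissimilarity()] over the taxa.
#' @export
missingness_distance <- function(m) {
  stopifnot(inherits(m, "character_matrix"))
  ind <- matrix(as.numeric(is.na(m$cells)), nrow(m$cells))
  n <- nrow(ind); p <- ncol(ind)
  agree11 <- tcrossprod(ind)
  agree00 <- tcrossprod(1 - ind)
  vals <- (p - agree11 - agree00) / p
  diag(vals) <- 0
  dimnames(vals) <- list(rownames(m$cells), rownames(m$cells))
  dissimilarity((vals + t(vals)) / 2)
}

#' Silhouette of a group on a dissimilarity
#'
#' Mean silhouette width of the units of `group` against all other
#' units, treating the grouping as a two-cluster assignment. Used to
#' quantify the artefactual clustering of fossil taxa by shared
#' missing data before imputation.
#'
#' @param d A [dissimilarity()].
#' @param members Labels of the focal group.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
group_silhouette <- function(d, members) {
  stopifnot(inherits(d, "morpho_dissimilarity"))
  members <- intersect(members, d$labels)
  others <- setdiff(d$labels, members)
  if (length(members) < 2 || length(others) < 1) {
    stop("need >= 2 group members and >= 1 outsider")
  }
  s <- vapply(members, function(u) {
    a <- mean(d$values[u, setdiff(members, u)])
    b <- mean(d$values[u, others])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
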