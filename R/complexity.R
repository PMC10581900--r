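# Phenotypic complexity: presence-sum scores per taxon, reconstructed
# ancestral complexity, and correlation against ploidy (whole-genome
# duplication) history with phylogenetic correction.

#' Presence-sum complexity scores
#'
#' Per taxon, the number of characters coded present (1) in a
#' presence/absence matrix. Missing cells contribute nothing to the
#' score and are counted separately.
#'
#' @param p A `presence_matrix` (see [recode_presence()]).
#' @return Data frame: taxon, score, n_missing.
#' @export
complexity_scores <- function(p) {
  stopifnot(inherits(p, "presence_matrix"))
  data.frame(taxon = rownames(p$cells),
             score = as.integer(rowSums(p$cells == 1L, na.rm = TRUE)),
             n_missing = as.integer(rowSums(is.na(p$cells))),
             row.names = NULL)
}

#' Ancestral complexity along a phylogeny
#'
#' Reconstructs every binary character over the tree sample with the
#' stochastic-mapping consensus machinery of [impute_matrix()] (missing
#' tip cells are imputed by the same pass), then scores each internal
#' node of the reference tree. Two scores are reported: `score` counts
#' characters whose modal consensus is "present", and `score_expected`
#' sums the per-character presence frequencies across trees, which can
#' be fractional and is the better summary when reconstructions are
#' uncertain.
#'
#' @param p A `presence_matrix` covering the tree tips.
#' @param trees A [tree_sample()] (or single `phylo`).
#' @param n_sims Stochastic maps per character per tree.
#' @param seed Master seed.
#' @return A `complexity_profile` data frame: unit, is_node, score,
#'   score_expected; plus the underlying `imputation` as attribute
#'   `imputation`.
#' @export
ancestral_complexity <- function(p, trees, n_sims = 100, seed = 1L) {
  stopifnot(inherits(p, "presence_matrix"))
  m <- character_matrix(p$cells)
  imp <- impute_matrix(m, trees, n_sims = n_sims, seed = seed)
  cells <- imp$combined$cells
  score <- rowSums(cells == 1L, na.rm = TRUE)
  # expected score: sum of per-character presence frequencies; for a
  # binary character the consensus frequency determines both.
  expected <- score
  det <- imp$details
  if (nrow(det)) {
    p_present <- ifelse(det$state == 1L, det$frequency, 1 - det$frequency)
    adj <- p_present - (det$state == 1L)   # replace the 0/1 modal call
    agg <- tapply(adj, det$unit, sum)
    expected[names(agg)] <- expected[names(agg)] + agg
  }
  ntip <- nrow(imp$focal$cells)
  out <- data.frame(unit = rownames(cells),
                    is_node = rownames(cells) %in% imp$node_labels,
                    score = as.numeric(score),
                    score_expected = as.numeric(expected),
                    row.names = NULL)
  structure(out, imputation = imp,
            class = c("complexity_profile", "data.frame"))
}

#' Per-branch ploidy events and cumulative tip counts
#'
#' Whole-genome-duplication events are consumed as per-branch counts;
#' each tip's ploidy history is the sum of events along its
#' root-to-tip path.
#'
#' @param tree Rooted `phylo`.
#' @param branch_events Integer vector of event counts, one per row of
#'   `tree$edge`.
#' @return A `ploidy_annotation`: list with `branch_events` and named
#'   `tip_events`.
#' @export
ploidy_annotation <- function(tree, branch_events) {
  stopifnot(length(branch_events) == nrow(tree$edge),
            all(branch_events >= 0))
  ntip <- ape::Ntip(tree)
  cum <- numeric(ntip + tree$Nnode)
  co <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(paste(co$edge[, 1], co$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  for (e in seq_len(nrow(co$edge))) {
    par <- co$edge[e, 1]; ch <- co$edge[e, 2]
    cum[ch] <- cum[par] + branch_events[ord[e]]
  }
  structure(list(branch_events = as.integer(branch_events),
                 tip_events = stats::setNames(as.integer(
                   cum[seq_len(ntip)]), tree$tip.label)),
            class = "ploidy_annotation")
}

#' Correlation between complexity and ploidy history
#'
#' `"pic_pearson"` (the headline method) computes phylogenetically
#' independent contrasts for both variables on the tree and the
#' through-origin Pearson correlation of the contrasts, with a t-based
#' p-value; `"spearman"` rank-correlates the raw tip values.
#'
#' @param complexity Named numeric vector of per-tip complexity scores.
#' @param ploidy A `ploidy_annotation` or named numeric vector of
#'   per-tip cumulative event counts.
#' @param tree Rooted `phylo` (needed for `"pic_pearson"`).
#' @param method `"pic_pearson"` or `"spearman"`.
#' @return A `correlation_report`.
#' @export
ploidy_complexity_correlation <- function(complexity, ploidy, tree = NULL,
                                          method = c("pic_pearson",
                                                     "spearman")) {
  method <- match.arg(method)
  tipp <- if (inherits(ploidy, "ploidy_annotation")) ploidy$tip_events else
    ploidy
  shared <- intersect(names(complexity), names(tipp))
  if (length(shared) < 3) stop("need at least 3 tips with both values")
  x <- complexity[shared]; y <- tipp[shared]
  if (method == "spearman") return(correlate(x, y, method = "spearman"))
  if (is.null(tree)) stop("pic_pearson needs a tree")
  missing <- setdiff(tree$tip.label, shared)
  if (length(missing)) {
    stop("tips without both values: ", paste(missing, collapse = ", "))
  }
  tr <- tree
  if (!ape::is.binary(tr)) tr <- ape::multi2di(tr)
  if (any(tr$edge.length <= 0)) {
    tr$edge.length[tr$edge.length <= 0] <- 1e-8
  }
  px <- ape::pic(x[tr$tip.label], tr)
  py <- ape::pic(y[tr$tip.label], tr)
  sx <- sum(px^2); sy <- sum(py^2)
  if (sx == 0 || sy == 0) stop("zero-variance contrasts")
  r <- sum(px * py) / sqrt(sx * sy)
  n <- length(px)
  p <- if (abs(r) >= 1) .Machine$double.xmin else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    max(2 * stats::pt(-abs(tt), df = n - 2), .Machine$double.xmin)
  }
  structure(list(method = "pic_pearson", coefficient = r, p = p, n = n),
            class = "correlation_report")
}
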