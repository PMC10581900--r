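# Clade disparity indices with bootstrap envelopes, and time-sliced
# disparity-through-time curves over a phylomorphospace.

.boot_quantiles <- function(x) {
  stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE,
                  na.rm = TRUE)
}

#' Mean pairwise disparity within groups
#'
#' Per group, the mean Gower (or other) distance over unordered
#' within-group pairs, with a bootstrap distribution obtained by
#' resampling group members with replacement. Singleton groups have no
#' defined value and are flagged.
#'
#' @param d A [dissimilarity()].
#' @param groups Named character vector mapping unit labels to group
#'   names; every name must be a label of `d`.
#' @param n_boot Bootstrap replicates (0 skips the bootstrap).
#' @param seed Optional integer seed.
#' @return A `disparity_summary` data frame: group, n, estimate,
#'   p2.5/p25/median/p75/p97.5 (NA when `n_boot == 0`), flagged.
#' @export
mean_disparity <- function(d, groups, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(d, "morpho_dissimilarity"))
  unknown <- setdiff(names(groups), d$labels)
  if (length(unknown)) {
    stop("grouped units absent from distances: ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(unique(groups), function(g) {
    members <- names(groups)[groups == g]
    n <- length(members)
    if (n < 2L) {
      return(data.frame(group = g, n = n, estimate = NA_real_,
                        p2.5 = NA_real_, p25 = NA_real_, median = NA_real_,
                        p75 = NA_real_, p97.5 = NA_real_, flagged = TRUE))
    }
    sub <- d$values[members, members]
    est <- mean(sub[upper.tri(sub)])
    if (n_boot > 0) {
      reps <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        s <- sub[idx, idx]
        mean(s[upper.tri(s)])
      }, numeric(1))
      q <- .boot_quantiles(reps)
    } else q <- rep(NA_real_, 5)
    data.frame(group = g, n = n, estimate = est, p2.5 = q[1], p25 = q[2],
               median = q[3], p75 = q[4], p97.5 = q[5], flagged = FALSE)
  })
  structure(do.call(rbind, out), metric = "mean_pairwise",
            class = c("disparity_summary", "data.frame"))
}

#' Partial disparity of groups within a morphospace
#'
#' Foote-style partial disparity: each group's summed (squared, by
#' default) distance to the grand centroid of all embedded units,
#' divided by `n - 1` with `n` the total unit count. In squared mode
#' partial disparities over a partition of the units sum exactly to the
#' total sum of variances.
#'
#' @param coords An [ordination_result()] or coordinate matrix with row
#'   names.
#' @param groups Named character vector unit -> group.
#' @param squared Use squared distances (default; required for the
#'   additivity identity).
#' @param n_boot,seed Bootstrap settings (members resampled with
#'   replacement; centroid and `n` stay fixed).
#' @return A `disparity_summary` data frame.
#' @export
partial_disparity <- function(coords, groups, squared = TRUE,
                              n_boot = 1000, seed = NULL) {
  X <- if (inherits(coords, "ordination_result")) coords$coordinates else
    as.matrix(coords)
  unknown <- setdiff(names(groups), rownames(X))
  if (length(unknown)) {
    stop("grouped units absent from coordinates: ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  centroid <- colMeans(X)
  n_total <- nrow(X)
  dev2 <- rowSums(sweep(X, 2, centroid)^2)
  contrib <- if (squared) dev2 else sqrt(dev2)
  out <- lapply(unique(groups), function(g) {
    members <- names(groups)[groups == g]
    n <- length(members)
    if (n == 0L) {
      return(data.frame(group = g, n = 0L, estimate = 0,
                        p2.5 = NA_real_, p25 = NA_real_, median = NA_real_,
                        p75 = NA_real_, p97.5 = NA_real_, flagged = TRUE))
    }
    vals <- contrib[members]
    est <- sum(vals) / (n_total - 1)
    if (n_boot > 0) {
      reps <- vapply(seq_len(n_boot), function(b) {
        sum(vals[sample.int(n, n, replace = TRUE)]) / (n_total - 1)
      }, numeric(1))
      q <- .boot_quantiles(reps)
    } else q <- rep(NA_real_, 5)
    data.frame(group = g, n = n, estimate = est, p2.5 = q[1], p25 = q[2],
               median = q[3], p75 = q[4], p97.5 = q[5], flagged = FALSE)
  })
  structure(do.call(rbind, out), metric = "partial", squared = squared,
            class = c("disparity_summary", "data.frame"))
}

#' Sum of variances of a coordinate set
#'
#' The disparity statistic used through time: the sum over axes of the
#' sample variance (denominator `n - 1`). Fewer than two units give 0
#' with a `flagged` attribute.
#'
#' @param coords Coordinate matrix (or [ordination_result()]).
#' @return Scalar; attribute `flagged` is `TRUE` for degenerate input.
#' @export
sum_of_variances <- function(coords) {
  X <- if (inherits(coords, "ordination_result")) coords$coordinates else
    as.matrix(coords)
  if (nrow(X) < 2L) {
    return(structure(0, flagged = TRUE))
  }
  structure(sum(apply(X, 2, stats::var)), flagged = FALSE)
}

# Coordinates of the points carried by the branches crossing a slice.
# gradual: linear interpolation between parent-node and child
# coordinates, proportional to elapsed time; punctuated: the parent or
# child coordinates, chosen by `pick` (logical per branch, TRUE =
# parent).
.slice_points <- function(X, slice, model, pick = NULL) {
  m <- nrow(slice)
  if (m == 0L) return(X[0, , drop = FALSE])
  Xp <- X[slice$parent_unit, , drop = FALSE]
  Xc <- X[slice$child_unit, , drop = FALSE]
  if (model == "gradual") {
    span <- slice$parent_age - slice$child_age
    frac <- ifelse(span > 0, (slice$parent_age - slice$time) / span, 1)
    Xp + (Xc - Xp) * frac
  } else {
    if (is.null(pick)) pick <- stats::runif(m) < 0.5
    # a slice exactly at the child endpoint is that endpoint: never
    # substitute the ancestor there (keeps the present-day slice equal
    # to the static extant disparity)
    at_child <- abs(slice$time - slice$child_age) <=
      1e-9 * pmax(1, slice$parent_age)
    pick[at_child] <- FALSE
    out <- Xc
    out[pick, ] <- Xp[pick, ]
    out
  }
}

#' Disparity through time by time-slicing
#'
#' At each slice age the branches alive at that time each contribute
#' one morphospace point: under the gradual model the point is
#' interpolated linearly along the branch between the parent node's and
#' the child's coordinates in proportion to elapsed time; under the
#' punctuated model it is the parent's or the child's coordinates,
#' chosen uniformly at random (re-randomized per bootstrap replicate so
#' model uncertainty enters the envelopes). The statistic per slice is
#' the sum of variances of the slice points; envelopes come from
#' bootstrap resampling of the slice points.
#'
#' Slices run every `bin_Myr` back from the present (0, 50, 100, ...)
#' plus one at the root age; slices crossed by fewer than two lineages
#' report 0 and are flagged.
#'
#' @param coords [ordination_result()] (or coordinate matrix) covering
#'   every tip and internal node of `tree` (node rows named by
#'   `tree$node.label` or `node_<ape number>`).
#' @param tree Rooted, dated `phylo`.
#' @param model `"gradual"` or `"punctuated"`.
#' @param bin_Myr Slice spacing in Myr.
#' @param n_boot Bootstrap replicates.
#' @param seed Optional integer seed.
#' @return A `dtt_curve` data frame (oldest slice first): time_Ma,
#'   n_lineages, estimate, p2.5/p25/median/p75/p97.5, flagged; the
#'   model is stored as an attribute.
#' @export
dtt <- function(coords, tree, model = c("gradual", "punctuated"),
                bin_Myr = 50, n_boot = 1000, seed = NULL) {
  model <- match.arg(model)
  X <- if (inherits(coords, "ordination_result")) coords$coordinates else
    as.matrix(coords)
  ntip <- ape::Ntip(tree)
  node_labels <- if (!is.null(tree$node.label) &&
                     all(nzchar(tree$node.label)))
    tree$node.label else paste0("node_", (ntip + 1L):(ntip + tree$Nnode))
  unit_of <- c(tree$tip.label, node_labels)
  missing <- setdiff(unit_of, rownames(X))
  if (length(missing)) {
    stop("coordinates lack tree units (impute node states first): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  }
  if (!is.null(seed)) set.seed(seed)
  ra <- root_age(tree)
  times <- sort(unique(c(seq(0, ra, by = bin_Myr), ra)))
  times <- times[c(TRUE, diff(times) > ra * 1e-9)]  # fp-safe dedupe
  times <- rev(times)
  rows <- lapply(times, function(tm) {
    ln <- lineages_at(tree, tm)
    slice <- data.frame(parent_unit = unit_of[ln$parent],
                        child_unit = unit_of[ln$child],
                        parent_age = ln$parent_age,
                        child_age = ln$child_age,
                        time = tm)
    m <- nrow(slice)
    if (m < 2L) {
      return(data.frame(time_Ma = tm, n_lineages = m, estimate = 0,
                        p2.5 = NA_real_, p25 = NA_real_, median = NA_real_,
                        p75 = NA_real_, p97.5 = NA_real_, flagged = TRUE))
    }
    pts <- .slice_points(X, slice, model)
    est <- as.numeric(sum_of_variances(pts))
    if (n_boot > 0) {
      reps <- vapply(seq_len(n_boot), function(b) {
        p <- if (model == "punctuated")
          .slice_points(X, slice, model) else pts
        idx <- sample.int(m, m, replace = TRUE)
        as.numeric(sum_of_variances(p[idx, , drop = FALSE]))
      }, numeric(1))
      q <- .boot_quantiles(reps)
    } else q <- rep(NA_real_, 5)
    data.frame(time_Ma = tm, n_lineages = m, estimate = est, p2.5 = q[1],
               p25 = q[2], median = q[3], p75 = q[4], p97.5 = q[5],
               flagged = FALSE)
  })
  structure(do.call(rbind, rows), model = model, bin_Myr = bin_Myr,
            class = c("dtt_curve", "data.frame"))
}

#' Correlations of disparity with diversity and clade age
#'
#' Spearman rank correlation of group disparity against species
#' diversity and Pearson correlation against clade age, on matched
#' group names.
#'
#' @param disparity Named numeric vector of group disparities.
#' @param diversity Named numeric vector of species counts (optional).
#' @param ages Named numeric vector of clade ages in Ma (optional).
#' @return List with elements `diversity` and/or `age`, each a
#'   `correlation_report`.
#' @export
disparity_diversity_tests <- function(disparity, diversity = NULL,
                                      ages = NULL) {
  out <- list()
  if (!is.null(diversity)) {
    shared <- intersect(names(disparity), names(diversity))
    if (length(shared) < 3) stop("need at least 3 groups with diversity")
    out$diversity <- correlate(disparity[shared], diversity[shared],
                               method = "spearman")
  }
  if (!is.null(ages)) {
    shared <- intersect(names(disparity), names(ages))
    if (length(shared) < 3) stop("need at least 3 groups with ages")
    out$age <- correlate(disparity[shared], ages[shared],
                         method = "pearson")
  }
  if (!length(out)) stop("provide diversity and/or ages")
  out
}
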