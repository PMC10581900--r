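# Morphospace construction: non-metric multidimensional scaling by
# majorization (SMACOF) with Kruskal primary tie handling, principal
# coordinates analysis, joint tip+node phylomorphospaces and convex
# hulls.

#' Construct an ordination result
#'
#' @param labels Unit labels (tips and optionally internal nodes).
#' @param coordinates Numeric matrix, one row per unit.
#' @param method `"nmds"` or `"pcoa"`.
#' @param stress Kruskal stress-1 (NMDS) or `NA`.
#' @param eigenvalues Full eigenvalue spectrum (PCoA) or `NULL`.
#' @param shepard Data frame pairing observed dissimilarity with
#'   ordination distance (and fitted disparities for NMDS).
#' @param ... Further fields stored verbatim (e.g. `converged`,
#'   `stress_trace`).
#' @return An `ordination_result`.
#' @export
ordination_result <- function(labels, coordinates, method, stress = NA_real_,
                              eigenvalues = NULL, shepard = NULL, ...) {
  coordinates <- as.matrix(coordinates)
  stopifnot(length(labels) == nrow(coordinates))
  rownames(coordinates) <- labels
  structure(list(labels = labels, coordinates = coordinates,
                 method = method, stress = stress,
                 eigenvalues = eigenvalues, shepard = shepard, ...),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(toupper(x$method), "ordination:", nrow(x$coordinates), "units in",
      ncol(x$coordinates), "dimension(s)")
  if (!is.na(x$stress)) cat("; stress =", signif(x$stress, 4))
  cat("\n")
  invisible(x)
}

# Flip axis signs so the first unit has nonnegative coordinates, and
# centre the configuration; makes runs comparable across seeds.
.standardize_axes <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  for (j in seq_len(ncol(X))) {
    piv <- which(abs(X[, j]) > 1e-12)[1]
    if (!is.na(piv) && X[piv, j] < 0) X[, j] <- -X[, j]
  }
  X
}

# Weighted pool-adjacent-violators: nondecreasing fit to y minimising
# sum w (f - y)^2. Returns fitted values in input order.
.pava <- function(y, w) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  val <- numeric(n); wt <- numeric(n); size <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; size[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      tw <- wt[top - 1L] + wt[top]
      val[top - 1L] <- if (tw > 0) (wt[top - 1L] * val[top - 1L] +
                                      wt[top] * val[top]) / tw else
        (val[top - 1L] + val[top]) / 2
      wt[top - 1L] <- tw
      size[top - 1L] <- size[top - 1L] + size[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], size[seq_len(top)])
}

# Monotone (isotonic) disparities for the current configuration, with
# Kruskal's primary approach to ties in the observed dissimilarities:
# tied delta blocks are ordered by the current distances, so tied
# observations may receive different fitted values.
.disparities <- function(delta, d, w) {
  ord <- order(delta, d)
  dhat <- numeric(length(d))
  active <- w[ord] > 0
  fit <- .pava(d[ord][active], w[ord][active])
  dhat[ord[active]] <- fit
  dhat[ord[!active]] <- d[ord[!active]]   # zero-weight pairs: no residual
  # rescale so sum w dhat^2 = sum w d^2 (fixes the scale of the fit)
  s2 <- sum(w * d^2); f2 <- sum(w * dhat^2)
  if (f2 > 0) dhat <- dhat * sqrt(s2 / f2)
  dhat
}

.stress1 <- function(d, dhat, w) {
  denom <- sum(w * d^2)
  if (denom == 0) return(0)
  sqrt(sum(w * (dhat - d)^2) / denom)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal-style NMDS fitted by iterative majorization (SMACOF):
#' each iteration fits monotone disparities to the configuration
#' distances by weighted isotonic regression (primary tie handling),
#' then updates the configuration by the Guttman transform, with a
#' backtracking safeguard so the recorded stress-1 sequence is
#' non-increasing. Pairs flagged as undefined in the input
#' dissimilarity get zero weight and thus no influence on the fit.
#' The best of `n_starts` starts (one classical-scaling start plus
#' random starts) is returned.
#'
#' @param d A [dissimilarity()] (or symmetric matrix).
#' @param k Number of dimensions.
#' @param n_starts Number of starts.
#' @param max_iter Maximum majorization iterations per start.
#' @param tol Convergence tolerance on the change in stress-1.
#' @param seed Optional integer seed (fixed seed gives identical
#'   output).
#' @return An [ordination_result()] with `stress`, `shepard`,
#'   `converged` and the best start's `stress_trace`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 500, tol = 1e-7,
                 seed = NULL) {
  stopifnot(k >= 1)
  D <- if (inherits(d, "morpho_dissimilarity")) d$values else as.matrix(d)
  flagged <- if (inherits(d, "morpho_dissimilarity")) d$flagged else
    matrix(FALSE, nrow(D), ncol(D))
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("u", seq_len(n))
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(D)
  delta <- D[ut]
  w <- as.numeric(!flagged[ut])
  if (n == 1L) {
    return(ordination_result(labels, matrix(0, 1, k), "nmds", stress = 0,
                             converged = TRUE, stress_trace = 0))
  }
  # Moore-Penrose inverse of V for the (possibly weighted) Guttman
  # transform, via the rank-completion identity.
  W <- matrix(0, n, n); W[ut] <- w; W <- W + t(W)
  V <- diag(rowSums(W)) - W
  Vp <- solve(V + 1 / n) - 1 / n
  pair_i <- row(D)[ut]; pair_j <- col(D)[ut]
  eval_config <- function(X) {
    dm <- as.matrix(stats::dist(X))
    dv <- dm[ut]
    dhat <- .disparities(delta, dv, w)
    list(d = dv, dhat = dhat, stress = .stress1(dv, dhat, w))
  }
  guttman <- function(X, dv, dhat) {
    ratio <- ifelse(dv > 0, dhat / dv, 0) * w
    B <- matrix(0, n, n); B[ut] <- ratio; B <- B + t(B)
    B <- diag(rowSums(B)) - B
    Vp %*% B %*% X
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    X <- if (s == 1L) {
      cs <- suppressWarnings(stats::cmdscale(D, k = min(k, n - 1)))
      if (ncol(cs) < k) cbind(cs, matrix(0, n, k - ncol(cs))) else cs
    } else {
      matrix(stats::rnorm(n * k), n, k) * max(delta)
    }
    st <- eval_config(X)
    trace <- st$stress
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Xc <- guttman(X, st$d, st$dhat)
      stc <- eval_config(Xc)
      tries <- 0
      while (stc$stress > st$stress + 1e-13 && tries < 12) {
        Xc <- (X + Xc) / 2
        stc <- eval_config(Xc)
        tries <- tries + 1
      }
      if (stc$stress > st$stress + 1e-13) { converged <- TRUE; break }
      improvement <- st$stress - stc$stress
      X <- Xc; st <- stc
      # re-anchor the configuration scale to the data scale; stress-1
      # is invariant under this joint rescaling (PAVA is
      # scale-equivariant), so monotonicity is untouched, but it stops
      # the configuration drifting towards collapse
      s2 <- sum(w * st$d^2)
      if (s2 > 0) {
        sc <- sqrt(sum(w * delta^2) / s2)
        X <- X * sc; st$d <- st$d * sc; st$dhat <- st$dhat * sc
      }
      trace <- c(trace, st$stress)
      if (improvement < tol) { converged <- TRUE; break }
    }
    if (is.null(best) || st$stress < best$stress) {
      best <- list(X = X, stress = st$stress, d = st$d, dhat = st$dhat,
                   trace = trace, converged = converged)
    }
    if (best$stress < tol) break
  }
  X <- .standardize_axes(best$X)
  shepard <- data.frame(dissimilarity = delta,
                        distance = best$d,
                        fitted = best$dhat)
  ordination_result(labels, X, "nmds", stress = best$stress,
                    shepard = shepard, converged = best$converged,
                    stress_trace = best$trace)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: double-centred Gower transform of the
#' squared distances, eigendecomposition, coordinates scaled by the
#' square roots of the positive eigenvalues. Negative eigenvalues are
#' reported uncorrected.
#'
#' @param d A [dissimilarity()] (or symmetric matrix).
#' @param k Number of axes to keep (default: all positive-eigenvalue
#'   axes).
#' @return An [ordination_result()] with the full eigenvalue spectrum.
#' @export
pcoa <- function(d, k = NULL) {
  D <- if (inherits(d, "morpho_dissimilarity")) d$values else as.matrix(d)
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("u", seq_len(n))
  cs <- suppressWarnings(stats::cmdscale(D, k = n - 1, eig = TRUE))
  eig <- sort(cs$eig, decreasing = TRUE)
  pts <- cs$points
  if (is.null(pts) || ncol(pts) == 0L) pts <- matrix(0, n, 1)
  if (!is.null(k)) {
    if (ncol(pts) < k) pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
    pts <- pts[, seq_len(k), drop = FALSE]
  }
  pts <- .standardize_axes(pts)
  dm <- as.matrix(stats::dist(pts))
  shepard <- data.frame(dissimilarity = D[upper.tri(D)],
                        distance = dm[upper.tri(dm)])
  ordination_result(labels, pts, "pcoa", eigenvalues = eig,
                    shepard = shepard)
}

#' Pairwise distances between ordination coordinates
#'
#' @param o An [ordination_result()].
#' @return A [dissimilarity()] over the ordination's units.
#' @export
ordination_distances <- function(o) {
  stopifnot(inherits(o, "ordination_result"))
  dissimilarity(as.matrix(stats::dist(o$coordinates)))
}

#' Concordance between two ordinations of the same units
#'
#' Mantel correlation between the pairwise distance matrices of the
#' two embeddings; used to check that an NMDS morphospace approximates
#' its metric (PCoA) counterpart.
#'
#' @param a,b [ordination_result()] objects over identical labels.
#' @param n_perm,seed Passed to [mantel_test()].
#' @return A `correlation_report`.
#' @export
ordination_concordance <- function(a, b, n_perm = 999, seed = NULL) {
  if (!identical(a$labels, b$labels)) stop("ordination label mismatch")
  mantel_test(ordination_distances(a), ordination_distances(b),
              n_perm = n_perm, seed = seed)
}

#' Joint tip + ancestor morphospace over a phylogeny
#'
#' Ordinate tips and reconstructed internal nodes together (so node
#' positions are informed by their distances to living taxa) and pair
#' each internal node with its children for drawing branches in
#' morphospace.
#'
#' @param m A [character_matrix()] whose rows are the tree's tips plus
#'   one row per internal node (e.g. the `combined` element of
#'   [impute_matrix()]).
#' @param tree Rooted `phylo`; internal node rows are matched by
#'   `tree$node.label` when present, else `node_<ape number>`.
#' @param distance_fun Function mapping a character matrix to a
#'   [dissimilarity()].
#' @param ordination_fun Function mapping a dissimilarity to an
#'   [ordination_result()].
#' @return List with `ordination` and `edges` (data frame
#'   `parent`/`child` of unit labels, one row per tree branch).
#' @export
phylomorphospace <- function(m, tree, distance_fun = gower_distance,
                             ordination_fun = function(d) nmds(d, seed = 1)) {
  stopifnot(inherits(m, "character_matrix"))
  ntip <- ape::Ntip(tree)
  node_labels <- if (!is.null(tree$node.label) &&
                     all(nzchar(tree$node.label)))
    tree$node.label else paste0("node_", (ntip + 1L):(ntip + tree$Nnode))
  needed <- c(tree$tip.label, node_labels)
  missing <- setdiff(needed, taxa(m))
  if (length(missing)) {
    stop("matrix lacks rows for tree units (did you impute node states?): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  }
  keep <- character_matrix(m$cells[needed, , drop = FALSE],
                           partitions = m$partitions, ordered = m$ordered)
  ord <- ordination_fun(distance_fun(keep))
  unit_of <- function(node) {
    if (node <= ntip) tree$tip.label[node] else node_labels[node - ntip]
  }
  edges <- data.frame(
    parent = vapply(tree$edge[, 1], unit_of, character(1)),
    child = vapply(tree$edge[, 2], unit_of, character(1)))
  list(ordination = ord, edges = edges)
}

#' Convex hull of a 2-D point set
#'
#' Andrew monotone-chain hull, vertices returned in counterclockwise
#' order. Collinear point sets return the two extreme points; a single
#' point returns itself.
#'
#' @param points Two-column numeric matrix.
#' @return Matrix of hull vertices (rows, counterclockwise) with an
#'   `indices` attribute giving their rows in `points`.
#' @export
convex_hull <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 1)
  uniq <- !duplicated(points)
  idx <- which(uniq)
  P <- points[uniq, , drop = FALSE]
  n <- nrow(P)
  if (n == 1L) {
    out <- P
    attr(out, "indices") <- idx
    return(out)
  }
  ord <- order(P[, 1], P[, 2])
  P <- P[ord, , drop = FALSE]; idx <- idx[ord]
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(seqi) {
    hull <- integer(0)
    for (i in seqi) {
      while (length(hull) >= 2 &&
             cross(P[hull[length(hull) - 1L], ], P[hull[length(hull)], ],
                   P[i, ]) <= 1e-12) {
        hull <- hull[-length(hull)]
      }
      hull <- c(hull, i)
    }
    hull
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  h <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(h) == 0L) h <- c(1L, n)
  out <- P[h, , drop = FALSE]
  attr(out, "indices") <- idx[h]
  out
}

#' Area of a 2-D convex hull
#'
#' Shoelace area of [convex_hull()] of the points (0 for degenerate
#' sets).
#'
#' @param points Two-column numeric matrix.
#' @return Nonnegative scalar area.
#' @export
hull_area <- function(points) {
  h <- convex_hull(points)
  if (nrow(h) < 3) return(0)
  x <- h[, 1]; y <- h[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
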