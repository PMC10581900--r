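# Tree handling: samples of rooted, dated phylogenies, node ages,
# patristic distances and time slices. Trees are ape "phylo" objects;
# branch lengths are in Myr and ages in Ma before present, with the
# deepest tip taken to sit at the present (age 0) unless tip ages say
# otherwise.

#' Read one or more rooted trees as a tree sample
#'
#' Reads Newick or NEXUS (translate tables honoured via
#' [ape::read.nexus()]). All trees must be rooted, have unique tip
#' labels and share an identical tip set; a single-tree file yields a
#' sample of size one.
#'
#' @param path File path.
#' @param format `"newick"`, `"nexus"` or `"auto"` (extension-based).
#' @return A `tree_sample`: list of `phylo` objects.
#' @export
read_tree_sample <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nexus|nxs|trees)$", path,
                        ignore.case = TRUE)) "nexus" else "newick"
  }
  trees <- if (format == "nexus") ape::read.nexus(path) else
    ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  tree_sample(trees)
}

#' Bundle trees into a validated sample
#'
#' @param trees List of `phylo` objects over one shared tip set.
#' @return A `tree_sample`.
#' @export
tree_sample <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1L)
  for (i in seq_along(trees)) {
    t <- trees[[i]]
    if (!inherits(t, "phylo")) stop("element ", i, " is not a phylo tree")
    if (!ape::is.rooted(t)) stop("tree ", i, " is unrooted; a root is required")
    if (anyDuplicated(t$tip.label)) {
      stop("tree ", i, " has duplicated tip labels: ",
           paste(unique(t$tip.label[duplicated(t$tip.label)]),
                 collapse = ", "))
    }
    if (is.null(t$edge.length)) stop("tree ", i, " has no branch lengths")
    if (any(t$edge.length < 0)) stop("tree ", i, " has negative branch lengths")
    if (any(t$edge.length == 0)) {
      message("tree ", i, " has ", sum(t$edge.length == 0),
              " zero-length branch(es)")
    }
  }
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)[-1]) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stop("tree ", i, " has a different tip set from tree 1")
    }
  }
  structure(trees, class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("tree_sample of", length(x), "tree(s),", length(x[[1]]$tip.label),
      "tips\n")
  invisible(x)
}

#' Node ages of a dated tree
#'
#' Ages in Ma before present for every node (tips then internal nodes,
#' ape numbering). The deepest tip anchors the present.
#'
#' @param tree A rooted, dated `phylo`.
#' @return Numeric vector of length `Ntip + Nnode`.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' @rdname node_ages
#' @export
root_age <- function(tree) {
  node_ages(tree)[ape::Ntip(tree) + 1L]
}

#' Extinct (positive-age) tips of a dated tree
#'
#' @param tree A rooted, dated `phylo`.
#' @param tol Ages below `tol` count as the present; defaults to a
#'   relative tolerance of 1e-6 of the root age.
#' @return Named logical vector over tips.
#' @export
is_extinct_tip <- function(tree, tol = NULL) {
  if (is.null(tol)) tol <- root_age(tree) * 1e-6
  ages <- node_ages(tree)[seq_len(ape::Ntip(tree))]
  stats::setNames(ages > tol, tree$tip.label)
}

#' Patristic distances between tips
#'
#' Sum of branch lengths along the tree path between each pair of tips.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return Symmetric numeric matrix with zero diagonal, tip labels as
#'   dimnames.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    stop("branch ", which(is.na(tree$edge.length))[1],
         " has a missing length")
  }
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Branches crossing a time slice
#'
#' Returns the branches alive at `time` Ma: those whose parent node is
#' older than the slice and whose child node is at or below it (the
#' slice is closed at the child, so the present-day slice returns
#' exactly the extant tips and a branch ending in an extinct tip drops
#' out after the tip's age). At `time == root_age` the root's child
#' branches are returned.
#'
#' @param tree A rooted, dated `phylo`.
#' @param time Slice age in Ma, within `[0, root_age(tree)]`.
#' @param tol Numerical tolerance on age comparisons.
#' @return Data frame with columns `edge` (row of `tree$edge`),
#'   `parent`, `child`, `parent_age`, `child_age`.
#' @export
lineages_at <- function(tree, time, tol = 1e-8) {
  ages <- node_ages(tree)
  ra <- root_age(tree)
  if (time < -tol || time > ra + tol) {
    stop("time ", time, " outside [0, ", signif(ra, 6), "]")
  }
  time <- min(max(time, 0), ra)
  pa <- ages[tree$edge[, 1]]
  ca <- ages[tree$edge[, 2]]
  root <- ape::Ntip(tree) + 1L
  cross <- (pa > time + tol | (tree$edge[, 1] == root & time >= ra - tol)) &
    ca <= time + tol
  data.frame(edge = which(cross),
             parent = tree$edge[cross, 1],
             child = tree$edge[cross, 2],
             parent_age = pa[cross],
             child_age = ca[cross])
}

#' Check that a tree's tips are covered by a matrix
#'
#' @param tree A `phylo`.
#' @param m A `character_matrix` or `presence_matrix`.
#' @return Invisibly `TRUE`; errors listing any tips absent from the
#'   matrix.
#' @export
check_tree_matrix <- function(tree, m) {
  missing <- setdiff(tree$tip.label, taxa(m))
  if (length(missing)) {
    stop("tree tips absent from matrix: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
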