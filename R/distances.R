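# Pairwise dissimilarities between rows of a character matrix, aware
# of missing and inapplicable cells. A character enters a pair's
# comparison only when both taxa carry a coded state for it; Gower
# optionally also discards matching zeros so shared absence (and
# shared inapplicability recoded as absence) carries no signal.

#' Construct a dissimilarity object
#'
#' @param values Symmetric numeric matrix, zero diagonal, with labels
#'   as dimnames.
#' @param comparable Optional symmetric integer matrix of per-pair
#'   comparable-character counts.
#' @param flagged Optional symmetric logical matrix marking pairs whose
#'   value was imputed (no comparable characters).
#' @return A `dissimilarity` object (list with `values`, `comparable`,
#'   `flagged`, `labels`).
#' @export
dissimilarity <- function(values, comparable = NULL, flagged = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) stop("values must carry labels")
  if (max(abs(values - t(values))) > 1e-12) stop("values must be symmetric")
  if (any(diag(values) != 0)) stop("diagonal must be zero")
  if (any(values < 0)) stop("dissimilarities must be nonnegative")
  if (is.null(flagged)) {
    flagged <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  }
  structure(list(values = values, comparable = comparable,
                 flagged = flagged, labels = rownames(values)),
            class = "morpho_dissimilarity")
}

#' @export
print.morpho_dissimilarity <- function(x, ...) {
  cat("dissimilarity over", length(x$labels), "units; range [",
      signif(min(x$values), 4), ",", signif(max(x$values), 4), "]")
  nf <- sum(x$flagged[upper.tri(x$flagged)])
  if (nf > 0) cat(";", nf, "flagged pair(s)")
  cat("\n")
  invisible(x)
}

#' @export
as.dist.morpho_dissimilarity <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

# Coded-state indicator and per-state indicators for cross products.
.coded_mask <- function(cells) {
  (!is.na(cells)) & cells != INAPPLICABLE
}

#' Gower dissimilarity for unordered discrete characters
#'
#' For each pair of taxa, the proportion of comparable characters on
#' which the two differ: `d = mismatches / comparable`, any state
#' difference scoring 1 (unordered semantics). A character is
#' comparable for a pair when both cells hold a coded state — missing
#' and inapplicable cells never contribute — and, under the default
#' `zero_mode = "ignore_matching_zeros"`, when the two states are not
#' both zero; shared absence is then uninformative, so taxa that merely
#' lack the same organs are not drawn together. `"count_zeros"` treats
#' matching zeros like any other match.
#'
#' Pairs with no comparable characters have no defined distance; they
#' are imputed to the maximum observed distance and flagged rather than
#' aborting the analysis (the flag propagates to ordination weights).
#'
#' @param m A [character_matrix()].
#' @param zero_mode `"ignore_matching_zeros"` (default) or
#'   `"count_zeros"`.
#' @return A [dissimilarity()] with values in \[0, 1\].
#' @export
gower_distance <- function(m, zero_mode = c("ignore_matching_zeros",
                                            "count_zeros")) {
  stopifnot(inherits(m, "character_matrix"))
  zero_mode <- match.arg(zero_mode)
  cells <- m$cells
  if (nrow(cells) < 2L) stop("need at least two taxa")
  coded <- .coded_mask(cells)
  M <- matrix(as.numeric(coded), nrow(cells))
  comparable <- tcrossprod(M)
  states <- sort(unique(cells[coded]))
  matches <- matrix(0, nrow(cells), nrow(cells))
  for (s in states) {
    E <- matrix(as.numeric(coded & !is.na(cells) & cells == s), nrow(cells))
    matches <- matches + tcrossprod(E)
  }
  mismatches <- comparable - matches
  if (zero_mode == "ignore_matching_zeros") {
    E0 <- matrix(as.numeric(coded & !is.na(cells) & cells == 0L), nrow(cells))
    comparable <- comparable - tcrossprod(E0)
  }
  vals <- mismatches / comparable
  undef <- !is.finite(vals)
  diag(undef) <- FALSE
  vals[!is.finite(vals)] <- 0
  diag(vals) <- 0
  if (any(undef)) {
    if (all(undef[upper.tri(undef)])) {
      stop("no pair of taxa shares a comparable character")
    }
    vals[undef] <- max(vals)
  }
  dimnames(vals) <- list(rownames(cells), rownames(cells))
  storage.mode(comparable) <- "integer"
  dimnames(comparable) <- dimnames(vals)
  dimnames(undef) <- dimnames(vals)
  dissimilarity(vals, comparable = comparable, flagged = undef)
}

#' Euclidean distance with missing-data rescaling
#'
#' Square root of summed squared state differences over the characters
#' comparable for each pair, rescaled by `sqrt(total / comparable)` so
#' pairs compared on fewer characters are not biased towards zero.
#' Used as the metric counterpart to [gower_distance()] when checking
#' that an NMDS morphospace is approximately metric.
#'
#' @param m A [character_matrix()].
#' @return A [dissimilarity()].
#' @export
euclidean_distance <- function(m) {
  stopifnot(inherits(m, "character_matrix"))
  cells <- m$cells
  if (nrow(cells) < 2L) stop("need at least two taxa")
  coded <- .coded_mask(cells)
  M <- matrix(as.numeric(coded), nrow(cells))
  X <- matrix(ifelse(coded, as.numeric(cells), 0), nrow(cells))
  S <- X^2
  comparable <- tcrossprod(M)
  ss <- tcrossprod(S, M) + tcrossprod(M, S) - 2 * tcrossprod(X)
  ss[ss < 0] <- 0  # numerical noise
  p <- ncol(cells)
  vals <- sqrt(ss * (p / comparable))
  undef <- comparable == 0
  diag(undef) <- FALSE
  vals[comparable == 0] <- 0
  diag(vals) <- 0
  if (any(undef)) {
    if (all(undef[upper.tri(undef)])) {
      stop("no pair of taxa shares a comparable character")
    }
    vals[undef] <- max(vals)
  }
  vals <- (vals + t(vals)) / 2
  dimnames(vals) <- list(rownames(cells), rownames(cells))
  storage.mode(comparable) <- "integer"
  dimnames(comparable) <- dimnames(vals)
  dimnames(undef) <- dimnames(vals)
  dissimilarity(vals, comparable = comparable, flagged = undef)
}

#' Write / read a square distance matrix as CSV
#'
#' @param d A [dissimilarity()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dissimilarity <- function(d, path) {
  df <- data.frame(label = d$labels, d$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  dissimilarity(vals)
}
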