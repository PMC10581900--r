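# Correlation and permutation machinery shared by the ordination,
# disparity and complexity analyses.

.upper_vec <- function(m) m[upper.tri(m)]

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with a null
#' distribution built by simultaneously permuting the rows and columns
#' of the second matrix. The p-value uses the add-one rule
#' `p = (#[r_perm >= r_obs] + 1) / (n_perm + 1)` and is one-tailed
#' (greater) by default, matching the directional hypotheses it is used
#' for here (morphological vs patristic distance, NMDS vs PCoA
#' distance); `tail = "two"` doubles the smaller tail.
#'
#' @param a,b [dissimilarity()] objects (or plain symmetric matrices)
#'   over the same labels in the same order.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @param tail `"greater"` or `"two"`.
#' @return A `correlation_report`: list with `method`, `coefficient`,
#'   `p`, `n_perm`, `n`, `seed`.
#' @export
mantel_test <- function(a, b, n_perm = 999, seed = NULL,
                        tail = c("greater", "two")) {
  tail <- match.arg(tail)
  A <- if (inherits(a, "morpho_dissimilarity")) a$values else as.matrix(a)
  B <- if (inherits(b, "morpho_dissimilarity")) b$values else as.matrix(b)
  if (!identical(dim(A), dim(B))) stop("dimension mismatch")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B))) {
    stop("label mismatch between distance matrices")
  }
  va <- .upper_vec(A)
  if (stats::sd(va) == 0 || stats::sd(.upper_vec(B)) == 0) {
    stop("constant distance matrix; Mantel correlation undefined")
  }
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(va, .upper_vec(B))
  n <- nrow(A)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(va, .upper_vec(B[p, p]))
  }, numeric(1))
  p_greater <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  p <- if (tail == "greater") p_greater else {
    p_less <- (sum(r_perm <= r_obs) + 1) / (n_perm + 1)
    min(1, 2 * min(p_greater, p_less))
  }
  structure(list(method = "mantel", coefficient = r_obs, p = p,
                 n_perm = n_perm, n = n, seed = seed, tail = tail),
            class = "correlation_report")
}

#' Pearson or Spearman correlation with t-based p-value
#'
#' The coefficient is the standard product-moment (or rank, ties
#' mid-ranked) correlation; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-sided (for Spearman this is the usual large-sample t
#' approximation applied to the rank correlation).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `correlation_report`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; correlation undefined")
  }
  r <- stats::cor(x, y, method = method)
  p <- if (abs(r) >= 1) .Machine$double.xmin else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    max(2 * stats::pt(-abs(tt), df = n - 2), .Machine$double.xmin)
  }
  structure(list(method = method, coefficient = unname(r), p = p, n = n),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(x$method, ": r = ", signif(x$coefficient, 4), ", p = ",
      signif(x$p, 4), sep = "")
  if (!is.null(x$n_perm)) cat(" (", x$n_perm, " permutations)", sep = "")
  cat("\n")
  invisible(x)
}

#' Serialise a correlation report to JSON
#'
#' @param x A `correlation_report`.
#' @param path Optional output path; when omitted the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "correlation_report"))
  out <- jsonlite::toJSON(unclass(x)[!vapply(unclass(x), is.null,
                                             logical(1))],
                          auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
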