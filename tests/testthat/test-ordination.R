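# NMDS, PCoA, concordance, phylomorphospace and convex hulls.

dist_obj <- function(P, labels = NULL) {
  D <- as.matrix(stats::dist(P))
  if (is.null(labels)) labels <- paste0("u", seq_len(nrow(D)))
  dimnames(D) <- list(labels, labels)
  dissimilarity(D)
}

test_that("pcoa reproduces known planar coordinates up to rigid motion", {
  set.seed(2)
  for (rep in 1:3) {
    P <- matrix(stats::rnorm(2 * 12), 12, 2)
    o <- pcoa(dist_obj(P), k = 2)
    expect_lt(procrustes_rms(P, o$coordinates), 1e-8)
    expect_true(all(diff(o$eigenvalues) <= 1e-9))   # sorted descending
  }
  # 3 known points, exact recovery
  tri <- rbind(c(0, 0), c(3, 0), c(0, 4))
  o3 <- pcoa(dist_obj(tri), k = 2)
  expect_lt(procrustes_rms(tri, o3$coordinates), 1e-8)
})

test_that("pcoa of an equidistant simplex has n-1 equal eigenvalues", {
  n <- 6
  D <- matrix(1, n, n) - diag(n)
  dimnames(D) <- list(paste0("u", 1:n), paste0("u", 1:n))
  o <- pcoa(dissimilarity(D))
  pos <- o$eigenvalues[o$eigenvalues > 1e-10]
  expect_length(pos, n - 1)
  expect_lt(diff(range(pos)), 1e-10)
})

test_that("pcoa of identical units is all-zero", {
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  o <- pcoa(dissimilarity(D))
  expect_true(all(abs(o$coordinates) < 1e-12))
})

test_that("nmds embeds exact geometries with near-zero stress", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  o <- nmds(dist_obj(sq), k = 2, n_starts = 10, seed = 1)
  expect_lt(o$stress, 1e-3)
  dd <- sort(as.vector(stats::dist(o$coordinates)))
  expect_equal(dd[6] / dd[1], sqrt(2), tolerance = 1e-2)
  # 1-D structure embedded in 2-D: exact monotone embedding exists
  line <- matrix(c(0, 1, 2, 3.5, 7), ncol = 1)
  ol <- nmds(dist_obj(line), k = 2, n_starts = 10, seed = 2)
  expect_lt(ol$stress, 1e-6)
  # two units are always perfectly embeddable
  o2 <- nmds(dist_obj(matrix(c(0, 3), ncol = 1)), k = 2, seed = 3,
             n_starts = 2)
  expect_equal(o2$stress, 0, tolerance = 1e-12)
})

test_that("nmds stress is non-increasing within and across dimensions", {
  set.seed(17)
  P <- matrix(stats::rnorm(3 * 15), 15, 3)
  d <- dist_obj(P)
  o2 <- nmds(d, k = 2, n_starts = 6, seed = 4)
  expect_true(all(diff(o2$stress_trace) <= 1e-12))
  o3 <- nmds(d, k = 3, n_starts = 6, seed = 4)
  expect_true(all(diff(o3$stress_trace) <= 1e-12))
  expect_lte(o3$stress, o2$stress + 1e-6)
})

test_that("nmds agrees with an independent engine on stress", {
  skip_if_not_installed("vegan")
  set.seed(27)
  cells <- matrix(sample(0:2, 30 * 50, replace = TRUE), 30, 50,
                  dimnames = list(paste0("t", 1:30), paste0("c", 1:50)))
  g <- gower_distance(character_matrix(cells), "count_zeros")
  mine <- nmds(g, k = 2, n_starts = 10, seed = 5)
  ref <- vegan::monoMDS(stats::as.dist(g$values), k = 2)
  # same data, comparable stress (both Kruskal stress-1)
  expect_lt(abs(mine$stress - ref$stress), 0.03)
})

test_that("ordination concordance is invariant to axis permutation and sign", {
  set.seed(7)
  P <- matrix(stats::rnorm(2 * 20), 20, 2)
  a <- ordination_result(paste0("u", 1:20), P, "nmds")
  b <- ordination_result(paste0("u", 1:20), cbind(-P[, 2], P[, 1]), "pcoa")
  r <- ordination_concordance(a, b, n_perm = 99, seed = 1)
  expect_equal(r$coefficient, 1, tolerance = 1e-12)
  expect_equal(r$p, 1 / 100)
  # self-concordance
  rs <- ordination_concordance(a, a, n_perm = 99, seed = 2)
  expect_equal(rs$coefficient, 1, tolerance = 1e-12)
  # independent embeddings: small correlation, large p (typically)
  set.seed(8)
  c2 <- ordination_result(paste0("u", 1:20),
                          matrix(stats::rnorm(40), 20, 2), "nmds")
  ri <- ordination_concordance(a, c2, n_perm = 199, seed = 3)
  expect_lt(abs(ri$coefficient), 0.5)
  # label mismatch errors
  bad <- ordination_result(paste0("v", 1:20), P, "nmds")
  expect_error(ordination_concordance(a, bad), "mismatch")
})

test_that("phylomorphospace requires node rows and pairs edges correctly", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  cells <- matrix(sample(0:1, 7 * 12, replace = TRUE), 7, 12,
                  dimnames = list(c("A", "B", "C", "D",
                                    "node_5", "node_6", "node_7"),
                                  paste0("c", 1:12)))
  m <- character_matrix(cells)
  pm <- phylomorphospace(m, tr,
                         distance_fun = function(x)
                           gower_distance(x, "count_zeros"),
                         ordination_fun = function(d)
                           nmds(d, n_starts = 3, seed = 1))
  expect_identical(nrow(pm$edges), nrow(tr$edge))
  expect_setequal(unique(pm$edges$parent),
                  c("node_5", "node_6", "node_7"))
  expect_identical(sort(pm$ordination$labels),
                   sort(rownames(cells)))
  # tips-only matrix errors
  tips_only <- character_matrix(cells[1:4, ])
  expect_error(phylomorphospace(tips_only, tr), "impute")
})

test_that("star-tree phylomorphospace with identical tips collapses", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1);")
  cells <- matrix(1L, 4, 6,
                  dimnames = list(c("A", "B", "C", "node_4"),
                                  paste0("c", 1:6)))
  m <- character_matrix(cells)
  pm <- phylomorphospace(m, tr,
                         distance_fun = function(x)
                           gower_distance(x, "count_zeros"),
                         ordination_fun = function(d)
                           nmds(d, n_starts = 2, seed = 1))
  sp <- apply(pm$ordination$coordinates, 2, function(v) diff(range(v)))
  expect_true(all(sp < 1e-8))
})

test_that("convex hulls match orientation, degeneracy and area oracles", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  h <- convex_hull(sq)
  expect_identical(nrow(h), 4L)
  # counterclockwise: shoelace signed area positive
  signed <- sum(h[, 1] * c(h[-1, 2], h[1, 2]) -
                  c(h[-1, 1], h[1, 1]) * h[, 2]) / 2
  expect_gt(signed, 0)
  # collinear set: the extreme segment
  col3 <- cbind(c(0, 1, 2), c(0, 1, 2))
  expect_identical(nrow(convex_hull(col3)), 2L)
  expect_equal(hull_area(col3), 0)
  # area equals grDevices::chull oracle on random clouds
  set.seed(19)
  for (rep in 1:3) {
    pts <- matrix(stats::rnorm(200), 100, 2)
    ch <- grDevices::chull(pts)
    v <- pts[ch, ]
    oracle <- abs(sum(v[, 1] * c(v[-1, 2], v[1, 2]) -
                        c(v[-1, 1], v[1, 1]) * v[, 2]) / 2)
    expect_equal(hull_area(pts), oracle, tolerance = 1e-10)
  }
  # brute-force vertex oracle: a point is interior iff it lies inside a
  # triangle of three other points
  set.seed(29)
  pts <- matrix(stats::runif(50), 25, 2)
  in_tri <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 >= -1e-12 & s2 >= -1e-12 & s3 >= -1e-12) |
      (s1 <= 1e-12 & s2 <= 1e-12 & s3 <= 1e-12)
  }
  interior <- vapply(seq_len(25), function(i) {
    others <- setdiff(seq_len(25), i)
    combs <- utils::combn(others, 3)
    any(vapply(seq_len(ncol(combs)), function(ci) {
      in_tri(pts[i, ], pts[combs[1, ci], ], pts[combs[2, ci], ],
             pts[combs[3, ci], ])
    }, logical(1)))
  }, logical(1))
  hull_idx <- sort(attr(convex_hull(pts), "indices"))
  expect_identical(hull_idx, which(!interior))
})
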