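# Mk likelihoods, rate fitting, stochastic mapping and imputation.

test_that("transition probability rows sum to 1 across the parameter grid", {
  for (k in 2:5) for (q in c(0, 1e-4, 0.1, 3)) for (t in c(0, 0.5, 50)) {
    P <- mk_transition(k, q, t)
    expect_equal(rowSums(P), rep(1, k), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
})

test_that("likelihood matches closed-form hand calculations", {
  # zero branch lengths: only the root prior contributes
  tr <- ape::read.tree(text = "(A:0,B:0);")
  ll <- mk_likelihood(tr, c(A = 0L, B = 0L), mk_model(2, 0.7))
  expect_equal(exp(ll), 0.5, tolerance = 1e-12)
  # two-tip tree, explicit sum over the root state
  t1 <- 0.8; t2 <- 1.7; q <- 0.3; k <- 2
  tr2 <- ape::read.tree(text = sprintf("(A:%f,B:%f);", t1, t2))
  P1 <- mk_transition(k, q, t1); P2 <- mk_transition(k, q, t2)
  hand <- sum(0.5 * P1[, 1] * P2[, 1])
  ll2 <- mk_likelihood(tr2, c(A = 0L, B = 0L), mk_model(k, q))
  expect_equal(exp(ll2), hand, tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on random small trees", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    k <- sample(2:4, 1)
    q <- stats::runif(1, 0.02, 1.5)
    tr <- rand_tree(n)
    states <- sample(0:(k - 1), n, replace = TRUE)
    ts <- as.list(stats::setNames(states, tr$tip.label))
    ts[[sample(n, 1)]] <- NA   # one unknown tip
    ll <- mk_likelihood(tr, ts, mk_model(k, q))
    expect_equal(ll, log(enum_mk_likelihood(tr, ts, k, q)),
                 tolerance = 1e-10)
  }
})

test_that("invariant and single-tip characters get the floor rate", {
  tr <- rand_tree(8)
  inv <- stats::setNames(rep(0L, 8), tr$tip.label)
  fit <- fit_rate(tr, inv, k = 2)
  expect_true(fit$at_floor)
  expect_equal(fit$q, 1e-8)
  one <- stats::setNames(c(1L, rep(NA, 7)), tr$tip.label)
  expect_true(fit_rate(tr, one, k = 2)$at_floor)
})

test_that("rate fitting recovers a simulated rate", {
  set.seed(31)
  tr <- rand_tree(64)
  q_true <- 0.05
  qs <- replicate(200, {
    sim <- sim_mk_character(tr, k = 2, q = q_true)
    fit_rate(tr, sim$tips, k = 2)$q
  })
  expect_gt(stats::median(qs), 0.03)
  expect_lt(stats::median(qs), 0.08)
})

test_that("stochastic maps honour fixed tips and zero-rate degeneracy", {
  tr <- rand_tree(6)
  ts <- stats::setNames(rep(1L, 6), tr$tip.label)
  sm0 <- stochastic_map(tr, ts, mk_model(3, 0), n_sims = 20, seed = 1)
  # q = 0: no changes anywhere, everything stuck at the uniform tip state
  expect_true(all(sm0$node_states == 1L))
  expect_true(all(vapply(sm0$histories[[1]], nrow, integer(1)) == 1L))

  ts2 <- stats::setNames(c(0L, 1L, NA, 1L, 0L, NA), tr$tip.label)
  sm <- stochastic_map(tr, ts2, mk_model(2, 0.4), n_sims = 200, seed = 2)
  observed <- which(!is.na(ts2[tr$tip.label]))
  for (i in observed) {
    expect_true(all(sm$node_states[i, ] == ts2[[tr$tip.label[i]]]))
  }
})

test_that("branch histories are consistent segment decompositions", {
  set.seed(5)
  tr <- rand_tree(5)
  ts <- stats::setNames(c(0L, 1L, 2L, 1L, 0L), tr$tip.label)
  sm <- stochastic_map(tr, ts, mk_model(3, 0.6), n_sims = 10, seed = 3)
  for (s in 1:10) {
    h <- sm$histories[[s]]
    for (e in seq_along(h)) {
      expect_equal(sum(h[[e]]$dwell), tr$edge.length[e], tolerance = 1e-12)
      if (nrow(h[[e]]) > 1) expect_true(all(diff(h[[e]]$state) != 0))
      expect_identical(h[[e]]$state[1],
                       sm$node_states[tr$edge[e, 1], s])
      expect_identical(h[[e]]$state[nrow(h[[e]])],
                       sm$node_states[tr$edge[e, 2], s])
    }
  }
})

test_that("sampled node-state frequencies converge to exact marginals", {
  tr <- ape::read.tree(text = "((A:0.6,B:1.1):0.5,(C:0.9,D:0.4):0.8);")
  k <- 2; q <- 0.5
  ts <- list(A = 0L, B = 0L, C = 1L, D = NA)
  n_sims <- 4000
  sm <- stochastic_map(tr, ts, mk_model(k, q), n_sims = n_sims, seed = 9,
                       record_history = FALSE)
  for (node in 5:7) {
    marg <- enum_mk_marginal(tr, ts, k, q, node)
    freq <- tabulate(sm$node_states[node, ] + 1L, k) / n_sims
    se <- sqrt(marg * (1 - marg) / n_sims)
    expect_true(all(abs(freq - marg) <= 4 * se + 1e-9))
  }
})

test_that("imputation is the identity on complete matrices", {
  set.seed(41)
  tr <- rand_tree(8)
  cells <- matrix(sample(0:1, 8 * 5, replace = TRUE), 8, 5,
                  dimnames = list(tr$tip.label, paste0("c", 1:5)))
  m <- character_matrix(cells)
  imp <- impute_matrix(m, tr, n_sims = 20, seed = 2)
  expect_identical(imp$focal$cells, m$cells)
  expect_identical(nrow(imp$nodes$cells), tr$Nnode)
})

test_that("a masked tip inside a uniform clade is imputed to the clade state", {
  tr <- ape::read.tree(text =
    "(((A:1,B:1):1,(C:1,D:1):1):8,((E:1,F:1):1,(G:1,H:1):1):8);")
  # clade ABCD all state 1, clade EFGH all 0; C masked
  cells <- matrix(rep(c(1L, 1L, NA, 1L, 0L, 0L, 0L, 0L), 3), 8, 3,
                  dimnames = list(c("A", "B", "C", "D", "E", "F", "G", "H"),
                                  paste0("c", 1:3)))
  m <- character_matrix(cells)
  imp <- impute_matrix(m, tr, n_sims = 200, seed = 5)
  expect_identical(unname(imp$focal$cells["C", ]), rep(1L, 3))
  det <- imp$details[imp$details$unit == "C", ]
  expect_true(all(det$frequency == 1))   # single tree: one-hot consensus
})

test_that("single-tree consensus equals the per-tree modal state", {
  set.seed(51)
  tr <- rand_tree(10)
  cells <- matrix(sample(0:2, 10 * 6, replace = TRUE), 10, 6,
                  dimnames = list(tr$tip.label, paste0("c", 1:6)))
  cells[sample(60, 12)] <- NA
  m <- character_matrix(cells)
  imp <- impute_matrix(m, tr, n_sims = 50, seed = 3)
  # with one tree every consensus frequency is 1 (one-hot tally)
  expect_true(all(imp$details$frequency == 1))
})

test_that("inapplicable cells pass through and zero-scored characters warn", {
  tr <- rand_tree(4)
  cells <- matrix(c(0L, 1L, -1L, NA,
                    NA, NA, NA, NA), 4, 2,
                  dimnames = list(tr$tip.label, c("c1", "c2")))
  m <- character_matrix(cells)
  expect_warning(imp <- impute_matrix(m, tr, n_sims = 20, seed = 1),
                 "zero scored")
  expect_identical(imp$focal$cells[3, "c1"], -1L)
  expect_true(all(is.na(imp$focal$cells[, "c2"])))
})

test_that("imputation accuracy beats chance and degrades with rate", {
  set.seed(61)
  tr <- rand_tree(32)
  tr$edge.length <- tr$edge.length * 5
  accs <- vapply(c(0.02, 1.0), function(q) {
    set.seed(71)
    cells <- t(replicate(40, sim_mk_character(tr, 2, q)$tips))
    cells <- t(cells)
    storage.mode(cells) <- "integer"
    dimnames(cells) <- list(tr$tip.label, paste0("c", 1:40))
    truth <- character_matrix(cells)
    mask <- matrix(stats::runif(length(cells)) < 0.2, nrow(cells),
                   ncol(cells), dimnames = dimnames(cells))
    masked <- cells; masked[mask] <- NA
    keep <- colSums(!is.na(masked)) > 0
    m <- character_matrix(masked[, keep, drop = FALSE])
    imp <- impute_matrix(m, tr, n_sims = 60, seed = 8)
    imputation_accuracy(imp, subset_characters(truth, characters(m)),
                        mask[, keep, drop = FALSE])$accuracy
  }, numeric(1))
  expect_gt(accs[1], accs[2])   # slower characters impute better
})
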