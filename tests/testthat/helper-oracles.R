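# Shared fixtures and independent oracles for the test suite.

# Build a character_matrix from cell strings ("0","1","?","-","2",...).
cm <- function(rows, taxa = NULL, chars = NULL, partitions = list()) {
  mat <- do.call(rbind, lapply(rows, function(r) {
    vapply(r, function(tok) {
      if (tok == "?") NA_integer_
      else if (tok == "-") -1L
      else as.integer(tok)
    }, integer(1))
  }))
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(mat)))
  if (is.null(chars)) chars <- paste0("c", seq_len(ncol(mat)))
  dimnames(mat) <- list(taxa, chars)
  character_matrix(mat, partitions = partitions)
}

# Exhaustive-enumeration Mk likelihood: sum over all internal-node
# state assignments of prior x product of closed-form transition
# probabilities. Independent of the pruning implementation.
enum_mk_likelihood <- function(tree, tip_states, k, q,
                               root_prior = rep(1 / k, k)) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  tipL <- lapply(tree$tip.label, function(lb) {
    s <- tip_states[[lb]]
    if (is.null(s) || anyNA(s)) seq_len(k) else s + 1L
  })
  combs <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
    mk_transition(k, q, tree$edge.length[e])
  })
  total <- 0
  tip_combs <- as.matrix(expand.grid(tipL))
  for (ri in seq_len(nrow(combs))) {
    for (ti in seq_len(nrow(tip_combs))) {
      st <- c(tip_combs[ti, ], combs[ri, ])
      p <- root_prior[st[ntip + 1L]]
      for (e in seq_len(nrow(tree$edge))) {
        p <- p * Ps[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      }
      total <- total + p
    }
  }
  total
}

# Exhaustive marginal posterior of a node's state.
enum_mk_marginal <- function(tree, tip_states, k, q, node,
                             root_prior = rep(1 / k, k)) {
  vapply(seq_len(k), function(s) {
    ntip <- ape::Ntip(tree)
    nn <- tree$Nnode
    tipL <- lapply(tree$tip.label, function(lb) {
      st <- tip_states[[lb]]
      if (is.null(st) || anyNA(st)) seq_len(k) else st + 1L
    })
    combs <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
    combs <- combs[combs[, node - ntip] == s, , drop = FALSE]
    tip_combs <- as.matrix(expand.grid(tipL))
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
      mk_transition(k, q, tree$edge.length[e])
    })
    total <- 0
    for (ri in seq_len(nrow(combs))) {
      for (ti in seq_len(nrow(tip_combs))) {
        stv <- c(tip_combs[ti, ], combs[ri, ])
        p <- root_prior[stv[ntip + 1L]]
        for (e in seq_len(nrow(tree$edge))) {
          p <- p * Ps[[e]][stv[tree$edge[e, 1]], stv[tree$edge[e, 2]]]
        }
        total <- total + p
      }
    }
    total
  }, numeric(1)) -> w
  w / sum(w)
}

# RMS after optimal rigid alignment (translation + rotation/reflection,
# no scaling) of B onto A.
procrustes_rms <- function(A, B) {
  A <- scale(A, scale = FALSE)
  B <- scale(B, scale = FALSE)
  s <- svd(crossprod(A, B))
  R <- s$v %*% t(s$u)
  sqrt(mean((A - B %*% R)^2))
}

# Forward-simulate one ER Mk character on a tree; returns 0-based tip
# states (named) and node states.
sim_mk_character <- function(tree, k, q) {
  ntip <- ape::Ntip(tree)
  co <- ape::reorder.phylo(tree, "cladewise")
  st <- integer(ntip + tree$Nnode)
  st[ntip + 1L] <- sample.int(k, 1)
  for (e in seq_len(nrow(co$edge))) {
    P <- mk_transition(k, q, co$edge.length[e])
    st[co$edge[e, 2]] <- sample.int(k, 1, prob = P[st[co$edge[e, 1]], ])
  }
  list(tips = stats::setNames(st[seq_len(ntip)] - 1L, tree$tip.label),
       nodes = st[(ntip + 1L):length(st)] - 1L)
}

# Random rooted tree with given tip count and exp(1)-ish branch
# lengths, deterministic under the current RNG state.
rand_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

# Hex digest of a file's bytes (md5 via tools, no extra deps).
digest_file <- function(path) unname(tools::md5sum(path))
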