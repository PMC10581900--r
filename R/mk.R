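# Equal-rates Mk machinery: closed-form transition probabilities,
# Felsenstein pruning, ML rate fitting, stochastic character mapping
# and cross-tree imputation of missing tip states.
#
# States are coded 0..k-1 externally and map to columns 1..k
# internally. For the equal-rates model (all off-diagonal rates q),
#   P(same state) = 1/k + (k-1)/k * exp(-k q t)
#   P(different)  = 1/k -   1/k * exp(-k q t).

#' Equal-rates Mk model for one character
#'
#' @param k Number of states (>= 2).
#' @param q Per-state substitution rate (per Myr); every off-diagonal
#'   rate-matrix entry equals `q`.
#' @param root_prior Probability vector over the k states at the root;
#'   uniform by default.
#' @return An `mk_model` object.
#' @export
mk_model <- function(k, q, root_prior = NULL) {
  stopifnot(k >= 2, q >= 0)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  stopifnot(length(root_prior) == k, all(root_prior >= 0))
  if (abs(sum(root_prior) - 1) > 1e-8) stop("root_prior must sum to 1")
  structure(list(k = as.integer(k), q = q, root_prior = root_prior),
            class = "mk_model")
}

#' Transition probability matrix of the equal-rates Mk model
#'
#' @param k Number of states.
#' @param q Per-state rate.
#' @param t Elapsed time (branch length, Myr).
#' @return k x k stochastic matrix, rows = ancestral state.
#' @export
mk_transition <- function(k, q, t) {
  if (t < 0) stop("negative branch length")
  if (q < 0) stop("q must be nonnegative")
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) / k * e
  P
}

# Normalise tip state input to an Ntip x k 0/1 likelihood matrix.
# `tip_states` may be a named integer vector (NA = all states allowed)
# or a named list of integer state vectors (ambiguity sets).
.tip_likelihoods <- function(tree, tip_states, k) {
  ntip <- ape::Ntip(tree)
  L <- matrix(0, ntip, k)
  if (is.list(tip_states)) {
    states <- tip_states[tree$tip.label]
    if (any(vapply(states, is.null, logical(1)))) {
      stop("tip(s) without state assignment: ",
           paste(setdiff(tree$tip.label, names(tip_states)), collapse = ", "))
    }
    for (i in seq_len(ntip)) {
      s <- states[[i]]
      if (length(s) == 0L || anyNA(s)) L[i, ] <- 1
      else {
        if (any(s < 0L | s >= k)) stop("tip state outside 0..k-1")
        L[i, s + 1L] <- 1
      }
    }
  } else {
    s <- tip_states[tree$tip.label]
    if (length(s) != ntip) stop("tip_states must cover every tip")
    for (i in seq_len(ntip)) {
      if (is.na(s[i])) L[i, ] <- 1
      else {
        if (s[i] < 0L || s[i] >= k) stop("tip state outside 0..k-1")
        L[i, s[i] + 1L] <- 1
      }
    }
  }
  L
}

# Felsenstein pruning. Returns scaled partial likelihoods for every
# node plus the total log-likelihood. Postorder guarantees children
# are complete before their parent accumulates them.
.mk_pruning <- function(tree, tipL, k, q, root_prior) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  partial <- matrix(1, ntip + nnode, k)
  partial[seq_len(ntip), ] <- tipL
  logscale <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]; t <- po$edge.length[e]
    P <- mk_transition(k, q, t)
    partial[par, ] <- partial[par, ] * as.vector(P %*% partial[ch, ])
    mx <- max(partial[par, ])
    if (mx > 0 && mx < 1e-150) {
      partial[par, ] <- partial[par, ] / mx
      logscale <- logscale + log(mx)
    }
  }
  lik <- sum(root_prior * partial[ntip + 1L, ])
  list(partial = partial, loglik = if (lik > 0) log(lik) + logscale else -Inf)
}

#' Mk log-likelihood of one character on a tree
#'
#' Felsenstein-pruning log-likelihood of a discrete character under the
#' equal-rates Mk model. Missing tips (`NA`) are integrated over all k
#' states; ambiguity sets are supported via a list of allowed states.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param tip_states Named integer vector of states 0..k-1 (`NA` =
#'   unknown) or named list of allowed-state vectors, covering every
#'   tip.
#' @param model An [mk_model()].
#' @return Log-likelihood (scalar).
#' @export
mk_likelihood <- function(tree, tip_states, model) {
  stopifnot(inherits(model, "mk_model"))
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tipL <- .tip_likelihoods(tree, tip_states, model$k)
  .mk_pruning(tree, tipL, model$k, model$q, model$root_prior)$loglik
}

#' Fit the equal-rates Mk rate by maximum likelihood
#'
#' One-dimensional bounded optimisation of [mk_likelihood()] over the
#' rate `q` on a log scale. Characters with fewer than two observed
#' states (invariant, or a single scored tip) carry no rate signal;
#' they get the floor rate and are flagged.
#'
#' @param tree Rooted `phylo`.
#' @param tip_states As in [mk_likelihood()].
#' @param k Number of states.
#' @param q_floor,q_ceiling Search bounds (per Myr).
#' @param root_prior Optional root prior.
#' @return An [mk_model()] with extra fields `loglik`, `at_floor`.
#' @export
fit_rate <- function(tree, tip_states, k, q_floor = 1e-8, q_ceiling = 10,
                     root_prior = NULL) {
  tipL <- .tip_likelihoods(tree, tip_states, k)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  fixed <- which(rowSums(tipL) == 1L)
  obs_states <- unique(apply(tipL[fixed, , drop = FALSE], 1, which.max))
  if (length(obs_states) < 2L) {
    m <- mk_model(k, q_floor, root_prior)
    m$loglik <- .mk_pruning(tree, tipL, k, q_floor, root_prior)$loglik
    m$at_floor <- TRUE
    return(m)
  }
  f <- function(lq) {
    -.mk_pruning(tree, tipL, k, 10^lq, root_prior)$loglik
  }
  opt <- stats::optimize(f, c(log10(q_floor), log10(q_ceiling)), tol = 1e-6)
  if (!is.finite(opt$objective)) stop("rate optimisation failed to converge")
  q_hat <- 10^opt$minimum
  at_floor <- opt$minimum <= log10(q_floor) + 1e-3
  if (at_floor) q_hat <- q_floor
  m <- mk_model(k, q_hat, root_prior)
  m$loglik <- -opt$objective
  m$at_floor <- at_floor
  m
}

# Sample node states (tips with free states included) for n_sims
# replicate histories, root-down from the pruning partials. Returns an
# (Ntip + Nnode) x n_sims integer matrix of states 1..k.
.sample_node_states <- function(tree, tipL, k, q, root_prior, n_sims) {
  pr <- .mk_pruning(tree, tipL, k, q, root_prior)
  partial <- pr$partial
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  states <- matrix(0L, ntip + nnode, n_sims)
  root <- ntip + 1L
  w <- root_prior * partial[root, ]
  if (sum(w) <= 0) stop("data have zero likelihood under this model")
  states[root, ] <- sample.int(k, n_sims, replace = TRUE, prob = w)
  co <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(co$edge))) {
    par <- co$edge[e, 1]; ch <- co$edge[e, 2]; t <- co$edge.length[e]
    P <- mk_transition(k, q, t)
    B <- P * rep(partial[ch, ], each = k)   # B[j, i] = P_ji(t) L_ch(i)
    pstates <- states[par, ]
    for (j in unique(pstates)) {
      idx <- which(pstates == j)
      wj <- B[j, ]
      if (sum(wj) <= 0) stop("zero-probability branch endpoint at edge ", e)
      states[ch, idx] <- sample.int(k, length(idx), replace = TRUE, prob = wj)
    }
  }
  states
}

# Endpoint-conditioned ER path on one branch by uniformization. With
# uniformization rate k*q the auxiliary jump chain is the uniform
# matrix, so intermediate states are iid uniform and the jump count is
# Poisson mixed with a point mass at zero when the endpoints agree.
# Returns data.frame(state (0-based), dwell).
.branch_history <- function(a, b, t, k, q) {
  if (q == 0 || t == 0) {
    if (a != b) stop("state change on a zero-rate or zero-length branch")
    return(data.frame(state = a - 1L, dwell = t))
  }
  lam <- k * q * t
  p0 <- stats::dpois(0, lam)
  if (a == b) {
    w0 <- p0 / (p0 + (1 - p0) / k)
    n <- if (stats::runif(1) < w0) 0L else
      stats::qpois(stats::runif(1, p0, 1), lam)
  } else {
    n <- stats::qpois(stats::runif(1, p0, 1), lam)
  }
  if (n == 0L) return(data.frame(state = a - 1L, dwell = t))
  times <- sort(stats::runif(n, 0, t))
  virt <- c(if (n > 1L) sample.int(k, n - 1L, replace = TRUE), b)
  seq_states <- c(a, virt)
  bounds <- c(0, times, t)
  keep <- c(TRUE, diff(seq_states) != 0)
  # collapse virtual (self) jumps into dwell segments
  st <- seq_states[keep]
  starts <- bounds[-length(bounds)][keep]
  ends <- c(starts[-1], t)
  data.frame(state = st - 1L, dwell = ends - starts)
}

#' Stochastic character mapping under the equal-rates Mk model
#'
#' Samples complete character histories consistent with the tip data:
#' node states are drawn root-down from their conditional distributions
#' (computed by pruning), then each branch history is simulated
#' conditional on its endpoint states by uniformization. Observed tips
#' keep their state with probability 1; missing tips are free and
#' sampled like nodes.
#'
#' @param tree Rooted `phylo`.
#' @param tip_states As in [mk_likelihood()].
#' @param model An [mk_model()].
#' @param n_sims Number of simulated histories.
#' @param seed Optional integer seed.
#' @param record_history If `FALSE`, only node/tip states are returned
#'   (much faster; sufficient for imputation).
#' @return A `stochastic_map` object: list with `node_states` (matrix,
#'   rows = tips then internal nodes in ape numbering, columns = sims,
#'   values 0..k-1) and, when recorded, `histories` (per sim, per edge,
#'   a data.frame of `state`/`dwell` segments ordered rootwards to
#'   tipwards).
#' @export
stochastic_map <- function(tree, tip_states, model, n_sims = 100,
                           seed = NULL, record_history = TRUE) {
  stopifnot(inherits(model, "mk_model"), n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- model$k
  tipL <- .tip_likelihoods(tree, tip_states, k)
  states <- .sample_node_states(tree, tipL, k, model$q, model$root_prior,
                                n_sims)
  out <- list(node_states = states - 1L, k = k, tree = tree)
  if (record_history) {
    out$histories <- lapply(seq_len(n_sims), function(s) {
      lapply(seq_len(nrow(tree$edge)), function(e) {
        a <- states[tree$edge[e, 1], s]
        b <- states[tree$edge[e, 2], s]
        .branch_history(a, b, tree$edge.length[e], k, model$q)
      })
    })
  }
  class(out) <- "stochastic_map"
  out
}

#' @export
print.stochastic_map <- function(x, ...) {
  cat("stochastic_map:", ncol(x$node_states), "simulation(s),",
      x$k, "states\n")
  invisible(x)
}

# Modal value with deterministic lowest-code tie-breaking.
# x: integer vector of sampled states (0-based). Returns c(mode, tied).
.modal_state <- function(counts) {
  mx <- max(counts)
  winners <- which(counts == mx)
  c(mode = winners[1] - 1L, tie = as.integer(length(winners) > 1L))
}

# Clade keys (sorted tip-label strings) for internal-node matching
# across trees that share a tip set.
.clade_keys <- function(tree) {
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  vapply((ntip + 1L):(ntip + tree$Nnode),
         function(n) paste(sort(sets[[n]]), collapse = "|"), character(1))
}

#' Impute missing tip states and reconstruct node states
#'
#' The imputation procedure behind the "focal matrix": for every
#' character and every tree in the sample, an equal-rates Mk rate is
#' fitted by maximum likelihood, `n_sims` stochastic maps are drawn
#' with observed tips fixed and missing tips given a uniform prior over
#' that character's observed states, and the per-tree modal sampled
#' state is recorded for each missing tip and each internal node. The
#' consensus across trees is the modal per-tree state; ties break to
#' the lowest state code and are flagged. Inapplicable cells pass
#' through unchanged (they are treated as unknown during mapping).
#' Internal nodes are reported on the first tree's topology; nodes of
#' other trees contribute through exact clade matches only.
#'
#' @param m A [character_matrix()] covering all tree tips.
#' @param trees A [tree_sample()] (tips must be taxa of `m`).
#' @param n_sims Stochastic maps per character per tree.
#' @param seed Master seed; per-(tree, character) streams are derived
#'   deterministically from it.
#' @param q_floor Floor rate for invariant characters.
#' @return A list of class `imputation`: `focal` (tip rows, missing
#'   cells filled where possible), `nodes` (a [character_matrix()] of
#'   reference-tree internal nodes), `combined` (tips + nodes),
#'   `details` (data.frame: unit, character, state, frequency, tie,
#'   is_node), `reference_tree`.
#' @export
impute_matrix <- function(m, trees, n_sims = 1000, seed = 1L,
                          q_floor = 1e-8) {
  stopifnot(inherits(m, "character_matrix"))
  if (inherits(trees, "phylo")) trees <- tree_sample(list(trees))
  if (!inherits(trees, "tree_sample")) trees <- tree_sample(trees)
  ref <- trees[[1]]
  check_tree_matrix(ref, m)
  ntip <- ape::Ntip(ref)
  nnode <- ref$Nnode
  node_labels <- if (!is.null(ref$node.label) && all(nzchar(ref$node.label)))
    ref$node.label else paste0("node_", (ntip + 1L):(ntip + nnode))
  ref_keys <- .clade_keys(ref)
  chars <- characters(m)
  cells <- m$cells[ref$tip.label, , drop = FALSE]
  n_states_max <- 10L
  # per-unit per-character tally of per-tree modal states
  units <- c(ref$tip.label, node_labels)
  tip_is_missing <- is.na(cells) | cells == INAPPLICABLE
  tally <- array(0L, dim = c(length(units), length(chars), n_states_max))
  zero_scored <- logical(length(chars))
  for (ci in seq_along(chars)) {
    col <- cells[, ci]
    coded <- !is.na(col) & col != INAPPLICABLE
    obs <- sort(unique(col[coded]))
    if (length(obs) == 0L) { zero_scored[ci] <- TRUE; next }
    if (length(obs) == 1L) {
      # invariant: every free unit takes the single observed state
      s <- obs + 1L
      free_units <- c(which(tip_is_missing[, ci]), ntip + seq_len(nnode))
      tally[free_units, ci, s] <- tally[free_units, ci, s] +
        length(trees)
      next
    }
    k <- length(obs)
    code_of <- function(idx) obs[idx]          # 1..k -> original code
    state_of <- match(col, obs) - 1L           # original -> 0..k-1, NA free
    for (ti in seq_along(trees)) {
      tr <- trees[[ti]]
      sub_seed <- (as.numeric(seed) * 1000003 + ti * 10007 + ci) %% 2147483647
      set.seed(as.integer(sub_seed))
      ts <- stats::setNames(state_of[match(tr$tip.label, ref$tip.label)],
                            tr$tip.label)
      fit <- fit_rate(tr, ts, k, q_floor = q_floor)
      sm <- stochastic_map(tr, ts, fit, n_sims = n_sims,
                           record_history = FALSE)
      st <- sm$node_states + 1L   # 1..k
      # per-unit modal state over sims for this tree
      free_tips <- which(is.na(ts[tr$tip.label]))
      for (u in free_tips) {
        counts <- tabulate(st[u, ], nbins = k)
        md <- .modal_state(counts)
        lab <- tr$tip.label[u]
        ui <- match(lab, units)
        sc <- code_of(md[["mode"]] + 1L) + 1L
        tally[ui, ci, sc] <- tally[ui, ci, sc] + 1L
      }
      keys <- if (ti == 1L) ref_keys else .clade_keys(tr)
      node_map <- match(keys, ref_keys)  # sample-tree node -> ref node
      ntip_t <- ape::Ntip(tr)
      for (ni in seq_len(tr$Nnode)) {
        ri <- node_map[ni]
        if (is.na(ri)) next
        counts <- tabulate(st[ntip_t + ni, ], nbins = k)
        md <- .modal_state(counts)
        ui <- ntip + ri
        sc <- code_of(md[["mode"]] + 1L) + 1L
        tally[ui, ci, sc] <- tally[ui, ci, sc] + 1L
      }
    }
  }
  if (any(zero_scored)) {
    warning(sum(zero_scored), " character(s) with zero scored tips left ",
            "missing: ", paste(chars[zero_scored], collapse = ", "))
  }
  # consensus
  focal_cells <- m$cells
  node_cells <- matrix(NA_integer_, nnode, length(chars),
                       dimnames = list(node_labels, chars))
  details <- list()
  for (ci in seq_along(chars)) {
    for (ui in seq_along(units)) {
      counts <- tally[ui, ci, ]
      tot <- sum(counts)
      if (tot == 0L) next
      md <- .modal_state(counts)
      state <- md[["mode"]]
      tie <- md[["tie"]]
      is_node <- ui > ntip
      if (is_node) {
        node_cells[ui - ntip, ci] <- state
      } else {
        lab <- units[ui]
        if (is.na(m$cells[lab, chars[ci]])) {
          focal_cells[lab, chars[ci]] <- state
        }
        # inapplicable cells pass through unchanged
      }
      details[[length(details) + 1L]] <- data.frame(
        unit = units[ui], character = chars[ci], state = state,
        frequency = counts[state + 1L] / tot, tie = tie == 1L,
        is_node = is_node)
    }
  }
  details <- if (length(details)) do.call(rbind, details) else
    data.frame(unit = character(), character = character(),
               state = integer(), frequency = numeric(),
               tie = logical(), is_node = logical())
  focal <- character_matrix(focal_cells, partitions = m$partitions,
                            ordered = m$ordered)
  nodes <- character_matrix(node_cells, partitions = m$partitions)
  combined <- character_matrix(
    rbind(focal_cells[ref$tip.label, , drop = FALSE], node_cells),
    partitions = m$partitions)
  structure(list(focal = focal, nodes = nodes, combined = combined,
                 details = details, reference_tree = ref,
                 node_labels = node_labels),
            class = "imputation")
}

#' @export
print.imputation <- function(x, ...) {
  cat("imputation:", nrow(x$focal$cells), "tips,", nrow(x$nodes$cells),
      "reference nodes,", ncol(x$focal$cells), "characters\n")
  invisible(x)
}
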