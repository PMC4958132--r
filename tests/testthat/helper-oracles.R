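# Independent brute-force oracles. Everything here enumerates explicitly
# (ancestral labelings, tree topologies) and never calls the package's
# pruning / Fitch / search code paths, so agreement is a real check.

# All nodes whose state is free to vary: internal nodes plus unscored tips.
.free_nodes <- function(tree, states) {
  ntip <- length(tree$tip.label)
  internals <- (ntip + 1):(ntip + tree$Nnode)
  nas <- which(is.na(states[tree$tip.label]))
  c(internals, nas)
}

# Minimum number of changes over all full labelings (binary character).
brute_fitch <- function(tree, states) {
  ntip <- length(tree$tip.label)
  x <- states[tree$tip.label]
  free <- .free_nodes(tree, states)
  fixed <- rep(NA_integer_, ntip + tree$Nnode)
  fixed[seq_len(ntip)] <- x
  best <- Inf
  for (mask in 0:(2^length(free) - 1)) {
    lab <- fixed
    lab[free] <- bitwAnd(bitwShiftR(mask, seq_along(free) - 1), 1L)
    cost <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, cost)
  }
  best
}

# States each node takes in at least one minimum-change labeling.
brute_mpr_sets <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  x <- states[tree$tip.label]
  free <- .free_nodes(tree, states)
  fixed <- rep(NA_integer_, nn)
  fixed[seq_len(ntip)] <- x
  best <- Inf
  sets <- vector("list", nn)
  for (mask in 0:(2^length(free) - 1)) {
    lab <- fixed
    lab[free] <- bitwAnd(bitwShiftR(mask, seq_along(free) - 1), 1L)
    cost <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    if (cost < best) {
      best <- cost
      sets <- lapply(seq_len(nn), function(v) lab[v])
    } else if (cost == best) {
      sets <- lapply(seq_len(nn), function(v) union(sets[[v]], lab[v]))
    }
  }
  list(steps = best, sets = lapply(sets, sort))
}

# Exact two-state transition matrix via numerical matrix exponential.
expm_2state <- function(t, q01, q10) {
  Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE)
  as.matrix(Matrix::expm(Q * t))
}

# Likelihood by explicit summation over all ancestral labelings (k states).
brute_ctmc_loglik <- function(tree, tipL, Q, prior) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  k <- ncol(tipL)
  internals <- (ntip + 1):nn
  el <- tree$edge.length
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) as.matrix(Matrix::expm(Q * el[e])))
  total <- 0
  grid <- do.call(expand.grid, rep(list(seq_len(k)), length(internals)))
  for (g in seq_len(nrow(grid))) {
    lab <- rep(NA_integer_, nn)
    lab[internals] <- as.integer(grid[g, ])
    lik <- prior[lab[ntip + 1]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      if (v <= ntip) {
        lik <- lik * sum(P[[e]][lab[p], ] * tipL[v, ])
      } else {
        lik <- lik * P[[e]][lab[p], lab[v]]
      }
    }
    total <- total + lik
  }
  log(total)
}

brute_mk_loglik <- function(tree, states, q01, q10, prior = c(0.5, 0.5)) {
  tipL <- matrix(0, length(tree$tip.label), 2)
  x <- states[tree$tip.label]
  for (i in seq_along(x)) {
    tipL[i, ] <- if (is.na(x[i])) c(1, 1) else as.numeric(0:1 == x[i])
  }
  Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE)
  brute_ctmc_loglik(tree, tipL, Q, prior)
}

# Marginal state probabilities at every node by explicit summation.
brute_marginals <- function(tree, states, q01, q10, prior = c(0.5, 0.5)) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  x <- states[tree$tip.label]
  free <- .free_nodes(tree, states)
  fixed <- rep(NA_integer_, nn)
  fixed[seq_len(ntip)] <- x
  el <- tree$edge.length
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) expm_2state(el[e], q01, q10))
  lik_sum <- matrix(0, nn, 2)
  for (mask in 0:(2^length(free) - 1)) {
    lab <- fixed
    lab[free] <- bitwAnd(bitwShiftR(mask, seq_along(free) - 1), 1L)
    lik <- prior[lab[ntip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      lik <- lik * P[[e]][lab[tree$edge[e, 1]] + 1, lab[tree$edge[e, 2]] + 1]
    }
    for (v in seq_len(nn)) {
      lik_sum[v, lab[v] + 1] <- lik_sum[v, lab[v] + 1] + lik
    }
  }
  lik_sum / rowSums(lik_sum)
}

# Pagel joint-chain generator from an 8-rate named vector (test-local copy).
oracle_dep_Q <- function(r) {
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- r[["q12"]]; Q[1, 3] <- r[["q13"]]
  Q[2, 1] <- r[["q21"]]; Q[2, 4] <- r[["q24"]]
  Q[3, 1] <- r[["q31"]]; Q[3, 4] <- r[["q34"]]
  Q[4, 2] <- r[["q42"]]; Q[4, 3] <- r[["q43"]]
  diag(Q) <- -rowSums(Q)
  Q
}

brute_pagel_loglik <- function(tree, xa, xb, rates, prior = rep(0.25, 4)) {
  a <- xa[tree$tip.label]; b <- xb[tree$tip.label]
  tipL <- t(vapply(seq_along(a), function(i) {
    la <- if (is.na(a[i])) c(1, 1) else as.numeric(0:1 == a[i])
    lb <- if (is.na(b[i])) c(1, 1) else as.numeric(0:1 == b[i])
    c(la[1] * lb[1], la[1] * lb[2], la[2] * lb[1], la[2] * lb[2])
  }, numeric(4)))
  brute_ctmc_loglik(tree, tipL, oracle_dep_Q(rates), prior)
}

# All unrooted binary topologies on a taxon set, by recursive insertion of
# each taxon into every edge of every partial tree.
enumerate_unrooted <- function(taxa) {
  start <- ape::read.tree(
    text = paste0("(", paste(taxa[1:3], collapse = ","), ");"))
  trees <- list(start)
  for (tx in taxa[-(1:3)]) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edge)), function(e) {
        n <- length(tr$tip.label)
        edge <- tr$edge
        edge[edge > n] <- edge[edge > n] + 1L
        new_tip <- n + 1L
        new_node <- n + 1L + tr$Nnode + 1L
        u <- edge[e, 1]; v <- edge[e, 2]
        edge[e, ] <- c(u, new_node)
        edge <- rbind(edge, c(new_node, v), c(new_node, new_tip))
        out <- structure(list(edge = edge,
                              tip.label = c(tr$tip.label, tx),
                              Nnode = tr$Nnode + 1L), class = "phylo")
        ape::reorder.phylo(out, "cladewise")
      })
    }), recursive = FALSE)
  }
  trees
}

# A random ultrametric tree with unique labels, for property-style loops.
random_ultra_tree <- function(n, depth = 10) {
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length * depth / max(ape::node.depth.edgelength(tr))
  tr
}

named_states <- function(tree, values) setNames(values, tree$tip.label)
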