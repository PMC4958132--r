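# Matrix representation with parsimony (MRP): Baum-Ragan coding of source
# trees, semi-rooted outgroup handling, weighted Fitch scoring, a heuristic
# search (random addition + NNI hill-climbing + a parsimony ratchet), and the
# semi-strict (combinable-component) consensus.

#' Encode source trees as an MRP matrix
#'
#' Baum-Ragan matrix representation: every non-root internal node of every
#' source tree contributes one binary character scoring its descendant taxa
#' 1, the source's remaining taxa 0, and taxa absent from that source `?`
#' (`NA`). Semi-rooted coding adds a hypothetical all-zero outgroup row which
#' is scored 0 for characters from rooted sources and `?` for characters
#' from unrooted ones, so rooted sources carry their rooting information into
#' the search while unrooted sources stay agnostic. Characters from the
#' scaffold (a tree, or a ready-made 0/1/`?` grouping matrix) are up-weighted
#' by `scaffold_weight` so that they act as a topological constraint.
#'
#' @param sources A list of `phylo` objects (or a `multiPhylo`).
#' @param rooted Logical vector (recycled) marking each source as rooted.
#' @param scaffold Optional `phylo`, or a data frame / matrix of 0/1/`NA`
#'   grouping characters with a `taxon` column or taxon rownames.
#' @param scaffold_weight Weight for scaffold characters (the study used
#'   100); other characters have weight 1.
#' @param outgroup Label of the hypothetical all-zero outgroup row.
#' @return An object of class `mrp_matrix`: list with `X` (taxa x characters
#'   integer matrix with `NA` as `?`), `weights`, `source`, `outgroup`.
#' @export
encode_mrp <- function(sources, rooted = TRUE, scaffold = NULL,
                       scaffold_weight = 100, outgroup = "Outgroup") {
  if (inherits(sources, "phylo")) sources <- list(sources)
  if (length(sources) == 0) abort("At least one source tree is required.")
  if (scaffold_weight < 1) abort("`scaffold_weight` must be >= 1.")
  rooted <- rep_len(rooted, length(sources))
  purrr::walk(sources, check_phylo)

  taxa <- sort(unique(unlist(purrr::map(sources, "tip.label"))))
  if (!is.null(scaffold) && inherits(scaffold, "phylo")) {
    taxa <- sort(union(taxa, scaffold$tip.label))
  }
  if (outgroup %in% taxa) {
    abort(sprintf("Outgroup label `%s` collides with a source taxon.",
                  outgroup))
  }
  all_taxa <- c(taxa, outgroup)

  encode_tree <- function(tr, is_rooted, src) {
    ntip <- length(tr$tip.label)
    internal <- setdiff(unique(tr$edge[, 1]), root_node(tr))
    cols <- purrr::map(internal, function(v) {
      clade <- tr$tip.label[unlist(phangorn::Descendants(tr, v, "tips"))]
      col <- rep(NA_integer_, length(all_taxa))
      names(col) <- all_taxa
      col[tr$tip.label] <- 0L
      col[clade] <- 1L
      col[outgroup] <- if (is_rooted) 0L else NA_integer_
      col
    })
    if (length(cols) == 0) return(NULL)
    m <- do.call(cbind, cols)
    colnames(m) <- paste0(src, "_n", internal)
    m
  }

  blocks <- purrr::imap(sources, function(tr, i) {
    encode_tree(tr, rooted[i], paste0("source", i))
  })
  blocks <- blocks[!purrr::map_lgl(blocks, is.null)]
  if (length(blocks)) {
    X <- do.call(cbind, blocks)
  } else {
    X <- matrix(NA_integer_, length(all_taxa), 0,
                dimnames = list(all_taxa, NULL))
  }
  weights <- rep(1, ncol(X))
  src <- sub("_n[0-9]+$", "", colnames(X) %||% character(0))

  if (!is.null(scaffold)) {
    if (inherits(scaffold, "phylo")) {
      S <- encode_tree(scaffold, TRUE, "scaffold")
    } else {
      S <- scaffold
      if (is.data.frame(S)) {
        if ("taxon" %in% names(S)) {
          rn <- S$taxon
          S <- as.matrix(S[setdiff(names(S), "taxon")])
          rownames(S) <- rn
        } else {
          S <- as.matrix(S)
        }
      }
      storage.mode(S) <- "integer"
      full <- matrix(NA_integer_, length(all_taxa), ncol(S),
                     dimnames = list(all_taxa, colnames(S)))
      keep <- intersect(rownames(S), all_taxa)
      full[keep, ] <- S[keep, ]
      full[outgroup, ] <- 0L
      S <- full
      colnames(S) <- paste0("scaffold_c", seq_len(ncol(S)))
    }
    if (!is.null(S)) {
      X <- cbind(X, S[rownames(X) %||% all_taxa, , drop = FALSE])
      weights <- c(weights, rep(scaffold_weight, ncol(S)))
      src <- c(src, rep("scaffold", ncol(S)))
    }
  }
  rownames(X) <- all_taxa
  structure(list(X = X, weights = weights, source = src, outgroup = outgroup),
            class = "mrp_matrix")
}

#' @export
print.mrp_matrix <- function(x, ...) {
  cat(sprintf("MRP matrix: %d taxa (incl. outgroup `%s`), %d characters\n",
              nrow(x$X), x$outgroup, ncol(x$X)))
  w <- table(x$weights)
  cat("  weights:", paste(sprintf("%s x%s", names(w), w), collapse = ", "), "\n")
  invisible(x)
}

#' Weighted Fitch length of a tree on an MRP matrix
#'
#' Minimum number of state changes (Fitch counting with `?` as missing and
#' all changes equal and unordered) summed over characters with their
#' weights. Branch lengths are ignored; the length depends on topology only,
#' so rooted and unrooted versions of the same tree score identically.
#'
#' @param tree A `phylo` whose tips include all matrix taxa.
#' @param mrp An `mrp_matrix` (or a plain 0/1/`NA` matrix with taxon
#'   rownames, in which case unit weights are used).
#' @return The weighted step count (single number).
#' @export
fitch_length <- function(tree, mrp) {
  check_phylo(tree)
  if (inherits(mrp, "mrp_matrix")) {
    X <- mrp$X; w <- mrp$weights
  } else {
    X <- mrp; w <- rep(1, ncol(X))
  }
  if (!all(rownames(X) %in% tree$tip.label)) {
    abort("All MRP taxa must be tips of `tree`.")
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  sum(w * fitch_steps_matrix(tree, X))
}

# --- tree surgery -----------------------------------------------------------

# Insert a new tip along edge `e` (row index of tree$edge) of an unrooted
# binary tree, keeping ape's id conventions (tips first, root = ntip + 1).
insert_tip <- function(tree, label, e) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  edge[edge > n] <- edge[edge > n] + 1L
  new_tip <- n + 1L
  new_node <- n + 1L + tree$Nnode + 1L
  u <- edge[e, 1]; v <- edge[e, 2]
  edge[e, ] <- c(u, new_node)
  edge <- rbind(edge, c(new_node, v), c(new_node, new_tip))
  out <- structure(list(edge = edge, tip.label = c(tree$tip.label, label),
                        Nnode = tree$Nnode + 1L), class = "phylo")
  ape::reorder.phylo(out, "cladewise")
}

# Canonical topology fingerprint (rooting-invariant).
topo_key <- function(tree) {
  tr <- ape::unroot(tree)
  anchor <- sort(tr$tip.label)[1]
  tr <- ape::root(tr, outgroup = anchor, resolve.root = TRUE)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  sets <- purrr::map_chr(pp, function(p) paste(sort(labs[p]), collapse = ","))
  paste(sort(unique(sets)), collapse = "|")
}

# One greedy random-addition tree for a taxon order.
random_addition_tree <- function(taxa, score_fn) {
  tr <- ape::read.tree(text = paste0("(", paste(taxa[1:3], collapse = ","), ");"))
  for (tx in taxa[-(1:3)]) {
    cands <- purrr::map(seq_len(nrow(tr$edge)), function(e) insert_tip(tr, tx, e))
    sc <- purrr::map_dbl(cands, score_fn)
    ord <- sample.int(length(sc)) # seeded by caller: random tie-breaking
    best <- ord[which.min(sc[ord])]
    tr <- cands[[best]]
  }
  tr
}

# First-improvement NNI hill-climbing; returns the local optimum plus any
# equally parsimonious distinct topologies met at the final score.
nni_climb <- function(tree, score_fn, max_rounds = 100) {
  cur <- tree
  cur_sc <- score_fn(cur)
  ties <- list()
  for (i in seq_len(max_rounds)) {
    nb <- phangorn::nni(cur)
    ord <- sample.int(length(nb))
    moved <- FALSE
    for (j in ord) {
      sc <- score_fn(nb[[j]])
      if (sc < cur_sc - 1e-9) {
        cur <- nb[[j]]; cur_sc <- sc; moved <- TRUE
        ties <- list()
        break
      } else if (abs(sc - cur_sc) < 1e-9) {
        ties <- c(ties, list(nb[[j]]))
      }
    }
    if (!moved) break
  }
  list(tree = cur, score = cur_sc, ties = ties)
}

#' Heuristic maximum-parsimony search on an MRP matrix
#'
#' Random-addition starting trees followed by first-improvement NNI
#' hill-climbing and a parsimony-ratchet perturbation cycle (iteratively
#' re-weighting a random quarter of the characters, re-climbing, and
#' restoring the original weights). All distinct topologies found at the
#' best weighted Fitch length are returned. Deterministic given `seed`.
#'
#' @param mrp An `mrp_matrix` from [encode_mrp()].
#' @param n_replicates Number of random-addition replicates (>= 1).
#' @param seed Integer seed controlling addition orders, tie-breaking, and
#'   ratchet perturbations.
#' @param ratchet_iter Ratchet cycles per replicate.
#' @return An object of class `parsimony_search`: list with `trees` (a
#'   `multiPhylo` of best unrooted topologies), `score`, and `log` (tibble of
#'   per-replicate best scores).
#' @export
parsimony_search <- function(mrp, n_replicates = 10, seed = 1,
                             ratchet_iter = 3) {
  if (!inherits(mrp, "mrp_matrix")) abort("`mrp` must be an `mrp_matrix`.")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  taxa <- rownames(mrp$X)
  if (length(taxa) < 4) abort("Need at least 4 taxa to search.")
  score_fn <- function(tr) sum(mrp$weights * fitch_steps_matrix(tr, mrp$X))
  nch <- ncol(mrp$X)

  with_seed(seed, {
    best_sc <- Inf
    best <- list(); best_keys <- character(0)
    log <- vector("list", n_replicates)
    offer <- function(tr, sc) {
      if (sc < best_sc - 1e-9) {
        best_sc <<- sc
        best <<- list(); best_keys <<- character(0)
      }
      if (abs(sc - best_sc) < 1e-9) {
        k <- topo_key(tr)
        if (!k %in% best_keys) {
          best_keys <<- c(best_keys, k)
          best <<- c(best, list(tr))
        }
      }
    }
    for (r in seq_len(n_replicates)) {
      ord <- sample(taxa)
      tr <- random_addition_tree(ord, score_fn)
      cl <- nni_climb(tr, score_fn)
      offer(cl$tree, cl$score)
      for (t2 in cl$ties) offer(t2, cl$score)
      # ratchet: perturb weights, climb, then climb again on the original
      for (k in seq_len(ratchet_iter)) {
        wpert <- mrp$weights
        idx <- sample.int(nch, max(1L, nch %/% 4L))
        wpert[idx] <- wpert[idx] * 2
        pert_fn <- function(t) sum(wpert * fitch_steps_matrix(t, mrp$X))
        pt <- nni_climb(cl$tree, pert_fn)$tree
        cl <- nni_climb(pt, score_fn)
        offer(cl$tree, cl$score)
        for (t2 in cl$ties) offer(t2, cl$score)
      }
      log[[r]] <- tibble::tibble(replicate = r, best_score = best_sc)
    }
    structure(list(trees = structure(best, class = "multiPhylo"),
                   score = best_sc, log = dplyr::bind_rows(log)),
              class = "parsimony_search")
  })
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat(sprintf("Parsimony search: best weighted length %.6g, %d tree(s)\n",
              x$score, length(x$trees)))
  invisible(x)
}

#' Semi-strict (combinable-component) consensus
#'
#' Returns the tree containing every clade that is present in at least one
#' input tree and contradicted by none: a clade is kept if it is compatible
#' (nested or disjoint) with every clade of every input tree. All inputs
#' must be rooted and share a leaf set.
#'
#' @param trees A list of rooted `phylo` objects (or `multiPhylo`).
#' @return A rooted `phylo` (possibly with polytomies); branch lengths are
#'   not carried over.
#' @export
semi_strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  purrr::walk(trees, check_phylo)
  leaves <- sort(trees[[1]]$tip.label)
  for (tr in trees[-1]) {
    if (!setequal(tr$tip.label, leaves)) {
      abort("All trees must share the same leaf set.")
    }
  }
  clade_sets <- purrr::map(trees, function(tr) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    purrr::map(pp, function(p) sort(labs[p]))
  })
  all_clades <- unique(purrr::flatten(clade_sets))
  compatible <- function(a, b) {
    i <- length(intersect(a, b))
    i == 0 || i == length(a) || i == length(b)
  }
  keep <- purrr::keep(all_clades, function(cl) {
    all(purrr::map_lgl(purrr::flatten(clade_sets),
                       function(other) compatible(cl, other)))
  })
  keep <- keep[order(-lengths(keep))]
  nest <- function(set, pool) {
    pool <- purrr::keep(pool, function(cl) {
      length(cl) < length(set) && all(cl %in% set)
    })
    parts <- list()
    covered <- character(0)
    for (cl in pool) {
      if (!length(intersect(cl, covered))) {
        parts <- c(parts, list(cl))
        covered <- c(covered, cl)
      }
    }
    kids <- purrr::map_chr(parts, function(cl) nest(cl, pool))
    singles <- setdiff(set, covered)
    paste0("(", paste(c(kids, singles), collapse = ","), ")")
  }
  txt <- paste0(nest(leaves, keep), ";")
  ape::read.tree(text = txt)
}

#' Prune a supertree to a taxon subset
#'
#' Induced subtree on `keep`: other tips are dropped, degree-2 nodes are
#' suppressed, and branch lengths are summed through suppressed nodes.
#'
#' @param tree A `phylo`.
#' @param keep Character vector of tip labels to retain (subset of the
#'   tree's tips).
#' @return The induced `phylo`.
#' @export
prune_supertree <- function(tree, keep) {
  check_phylo(tree)
  extra <- setdiff(keep, tree$tip.label)
  if (length(extra)) {
    abort(paste0("`keep` contains non-tips: ", paste(extra, collapse = ", ")))
  }
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Root a tree at its outgroup
#'
#' @param tree A `phylo` containing `outgroup` among its tips.
#' @param outgroup Outgroup tip label.
#' @return A rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup = "Outgroup") {
  check_phylo(tree)
  if (!outgroup %in% tree$tip.label) {
    abort(sprintf("Outgroup `%s` is not a tip of the tree.", outgroup))
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
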