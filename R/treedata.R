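#' Parse a Newick string into a phylogenetic tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Trees are the standard
#' `phylo` objects used throughout the package; branch lengths, when present,
#' are interpreted as time in thousands of years (kya).
#'
#' @param text A single Newick string (terminating `;` optional in ape but
#'   recommended).
#' @return A `phylo` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' write_newick(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      abort(sprintf("Malformed Newick: unbalanced ')' at offset %d.", i))
    }
  }
  if (depth != 0L) {
    abort(sprintf(
      "Malformed Newick: %d unclosed '(' at end of string (length %d).",
      depth, length(chars)))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) abort("Malformed Newick: ape could not parse the string.")
  check_phylo(tree)
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  check_phylo(tree)
  ape::write.tree(tree, digits = digits)
}

#' Read / write trees in NEXUS format
#'
#' Wrappers over [ape::read.nexus()] and [ape::write.nexus()] covering the
#' TREES block of a NEXUS file.
#'
#' @param file Path to a NEXUS file.
#' @return `read_trees_nexus()` returns a `multiPhylo` (or single `phylo`).
#' @export
read_trees_nexus <- function(file) ape::read.nexus(file)

#' @param trees A `phylo` or `multiPhylo`.
#' @rdname read_trees_nexus
#' @export
write_trees_nexus <- function(trees, file) {
  ape::write.nexus(trees, file = file, translate = TRUE)
  invisible(file)
}

#' Node ages of a tree
#'
#' Ages are measured backwards from the most distant tip (age 0 at that tip),
#' in the units of the branch lengths (kya for calibrated trees).
#'
#' @param tree A `phylo` with branch lengths.
#' @return A numeric vector of length `ntip + Nnode`, indexed by node id.
#' @export
node_ages <- function(tree) {
  check_phylo(tree)
  if (is.null(tree$edge.length)) abort("`tree` has no branch lengths.")
  d <- ape::node.depth.edgelength(tree)
  max(d[seq_along(tree$tip.label)]) - d
}

#' Build a minimum node-age constraint table
#'
#' Each constraint pins the most recent common ancestor (MRCA) of `leaves` to
#' an age of at least `min_age_kya`. Constraint clades must be monophyletic on
#' the target tree when applied.
#'
#' @param clade_id Character vector of constraint names.
#' @param leaves List of character vectors of leaf labels (one per constraint).
#' @param min_age_kya Numeric minimum ages, in kya; must be positive.
#' @param date_set Label distinguishing alternative calibration sets, e.g.
#'   `"deep"` or `"shallow"`.
#' @return A tibble with columns `clade_id`, `leaves` (list-column),
#'   `min_age_kya`, `date_set`.
#' @export
age_constraints <- function(clade_id, leaves, min_age_kya,
                            date_set = "default") {
  if (!is.list(leaves)) leaves <- list(leaves)
  stopifnot(length(clade_id) == length(leaves),
            length(min_age_kya) == length(leaves))
  if (any(min_age_kya <= 0)) abort("Constraint ages must be > 0.")
  tibble::tibble(clade_id = as.character(clade_id), leaves = leaves,
                 min_age_kya = as.numeric(min_age_kya),
                 date_set = rep_len(as.character(date_set), length(clade_id)))
}

#' Read age constraints from a TSV file
#'
#' Expected columns: `clade_id`, `leaf_set` (leaf labels separated by `;`),
#' `min_age_kya`, and `date_set`.
#'
#' @param file Path to a tab-separated file.
#' @param date_set Optional filter; keep only rows of this date set.
#' @return A constraint tibble as produced by [age_constraints()].
#' @export
read_age_constraints <- function(file, date_set = NULL) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("clade_id", "leaf_set", "min_age_kya", "date_set")
  if (!all(need %in% names(df))) {
    abort(paste0("Constraint file must have columns: ",
                 paste(need, collapse = ", ")))
  }
  out <- age_constraints(df$clade_id,
                         strsplit(df$leaf_set, ";", fixed = TRUE),
                         df$min_age_kya, df$date_set)
  if (!is.null(date_set)) {
    out <- dplyr::filter(out, .data$date_set == !!date_set)
    if (nrow(out) == 0) abort(sprintf("No constraints in date set `%s`.",
                                      date_set))
  }
  out
}

# Resolve each constraint to a node id, insisting on monophyly.
resolve_constraint_nodes <- function(tree, constraints) {
  ntip <- length(tree$tip.label)
  purrr::map_int(seq_len(nrow(constraints)), function(i) {
    lv <- constraints$leaves[[i]]
    missing <- setdiff(lv, tree$tip.label)
    if (length(missing)) {
      abort(sprintf("Constraint `%s`: leaves not in tree: %s",
                    constraints$clade_id[i], paste(missing, collapse = ", ")))
    }
    if (length(lv) == 1) {
      abort(sprintf(
        "Constraint `%s` names a single leaf; leaves are fixed at age 0.",
        constraints$clade_id[i]))
    }
    node <- ape::getMRCA(tree, lv)
    desc <- tree$tip.label[unlist(phangorn::Descendants(tree, node, "tips"))]
    if (!setequal(desc, lv)) {
      abort(sprintf(
        "Constraint `%s` is not monophyletic on the tree (MRCA spans: %s).",
        constraints$clade_id[i], paste(sort(desc), collapse = ", ")))
    }
    as.integer(node)
  })
}

#' Enforce minimum node-age constraints
#'
#' Pins each constrained node at (at least) its minimum age and propagates
#' ages rootwards so that no parent is younger than any of its children.
#' Constrained nodes become *fixed anchors* for [ultrametricize()]. If the
#' input tree is already ultrametric, its existing node ages are kept where
#' they satisfy the constraints.
#'
#' @param tree A rooted `phylo`.
#' @param constraints A tibble from [age_constraints()] (use one date set).
#' @return The tree with attributes `node_age` (numeric per node, `NA` for
#'   unanchored nodes) and `fixed_nodes` (integer node ids), ready for
#'   [ultrametricize()].
#' @export
enforce_min_node_ages <- function(tree, constraints) {
  check_phylo(tree)
  if (!ape::is.rooted(tree)) abort("`tree` must be rooted.")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  ages <- rep(NA_real_, nn)
  ages[seq_len(ntip)] <- 0
  if (!is.null(tree$edge.length) &&
      isTRUE(ape::is.ultrametric(tree, option = 2))) {
    ages <- node_ages(tree)
    ages[seq_len(ntip)] <- 0
  }
  nodes <- resolve_constraint_nodes(tree, constraints)
  fixed <- integer(0)
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    ages[v] <- max(ages[v], constraints$min_age_kya[i], na.rm = TRUE)
    fixed <- union(fixed, v)
  }
  # rootward propagation: a parent can never be younger than a fixed child
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1]; v <- po[e, 2]
    if (!is.na(ages[v]) && (v %in% fixed || v <= ntip)) {
      if (is.na(ages[p]) || ages[p] < ages[v]) {
        if (p %in% fixed && !is.na(ages[p]) && ages[p] < ages[v]) {
          # a raised minimum is still a minimum: lift the ancestor too
          ages[p] <- ages[v]
        } else {
          ages[p] <- max(ages[p], ages[v], na.rm = TRUE)
        }
        if (v %in% fixed) fixed <- union(fixed, p)
      }
    }
  }
  attr(tree, "node_age") <- ages
  attr(tree, "fixed_nodes") <- sort(fixed)
  tree
}

#' Arbitrarily ultrametricize a tree between fixed age anchors
#'
#' Every leaf is placed at age 0 and every fixed node keeps its age; each
#' remaining internal node is placed strictly between its nearest fixed
#' ancestor and the oldest fixed (or leaf) descendant. The default rule
#' spaces the nodes of each intervening chain evenly; `method =
#' "proportional"` instead preserves the proportions of the original branch
#' lengths along the chain.
#'
#' @param tree A rooted `phylo`, normally the output of
#'   [enforce_min_node_ages()]. Alternatively supply `fixed_ages` directly.
#' @param fixed_ages Optional named numeric vector (names = node ids) of
#'   anchored ages, overriding the `node_age`/`fixed_nodes` attributes.
#' @param method Interpolation rule for unanchored nodes.
#' @return An ultrametric `phylo` whose branch lengths are age differences;
#'   the age attributes are consumed and dropped.
#' @export
ultrametricize <- function(tree, fixed_ages = NULL,
                           method = c("even", "proportional")) {
  check_phylo(tree)
  method <- match.arg(method)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- root_node(tree)

  if (is.null(fixed_ages)) {
    ages_in <- attr(tree, "node_age")
    fixed <- attr(tree, "fixed_nodes") %||% integer(0)
    if (is.null(ages_in)) ages_in <- rep(NA_real_, nn)
  } else {
    ages_in <- rep(NA_real_, nn)
    fixed <- as.integer(names(fixed_ages))
    ages_in[fixed] <- as.numeric(fixed_ages)
  }
  ages <- rep(NA_real_, nn)
  ages[seq_len(ntip)] <- 0
  ages[fixed] <- ages_in[fixed]
  if (is.na(ages[root])) {
    if (!is.na(ages_in[root])) ages[root] <- ages_in[root]
    else abort("Root age is unknown; fix the root (or constrain a clade spanning it) first.")
  }
  fixed <- union(fixed, c(seq_len(ntip), root))

  kids <- child_list(tree)
  orig_el <- tree$edge.length
  el_of <- rep(NA_real_, nn) # original length of the edge above each node
  if (!is.null(orig_el)) el_of[tree$edge[, 2]] <- orig_el

  # postorder: lower anchor B (oldest fixed/leaf age below), chain length m
  # (longest run of free nodes below, inclusive) and original path length D
  # to the anchor realising B.
  B <- rep(NA_real_, nn); m <- rep(0, nn); D <- rep(0, nn)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  post_nodes <- c(unique(po[, 2][po[, 2] > ntip]), root)
  for (v in post_nodes) {
    bb <- -Inf; dd <- 0; mm <- 0
    for (c in kids[[v]]) {
      if (c %in% fixed) {
        bc <- ages[c]; dc <- el_of[c] %||% 1
        if (is.na(dc)) dc <- 1
        mc <- 0
      } else {
        bc <- B[c]
        dc <- (if (is.na(el_of[c])) 1 else el_of[c]) + D[c]
        mc <- m[c]
      }
      if (bc > bb || (bc == bb && dc > dd)) { bb <- bc; dd <- dc }
      mm <- max(mm, mc)
    }
    B[v] <- bb; D[v] <- dd; m[v] <- mm + 1
  }

  # preorder assignment
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(pre))) {
    p <- pre[e, 1]; v <- pre[e, 2]
    if (v %in% fixed) {
      if (!is.na(ages[p]) && ages[p] < ages[v] - 1e-12) {
        abort(sprintf(
          "Impossible interleaving: node %d (age %.6g) is older than its ancestor (age %.6g).",
          v, ages[v], ages[p]))
      }
      next
    }
    A <- ages[p]
    lower <- B[v]
    if (lower > A + 1e-12) {
      abort(sprintf(
        "Impossible interleaving below node %d: fixed descendant age %.6g exceeds ancestor age %.6g.",
        v, lower, A))
    }
    frac <- if (method == "even") {
      m[v] / (m[v] + 1)
    } else {
      len_up <- if (is.na(el_of[v])) 1 else el_of[v]
      D[v] / (D[v] + len_up)
    }
    ages[v] <- lower + (A - lower) * frac
  }

  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  if (any(tree$edge.length < -1e-9)) {
    abort("Internal error: negative branch length after ultrametricization.")
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "node_age") <- NULL
  attr(tree, "fixed_nodes") <- NULL
  tree
}

#' Time-calibrate a tree from minimum node-age constraints
#'
#' Convenience composition of [enforce_min_node_ages()] and
#' [ultrametricize()], the two steps used to turn a topology plus a table of
#' divergence-date minima into an ultrametric, time-calibrated tree.
#'
#' @inheritParams enforce_min_node_ages
#' @inheritParams ultrametricize
#' @return An ultrametric `phylo` with branch lengths in kya.
#' @export
calibrate_tree <- function(tree, constraints,
                           method = c("even", "proportional")) {
  ultrametricize(enforce_min_node_ages(tree, constraints),
                 method = match.arg(method))
}
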