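# Fitch parsimony: step counts, most-parsimonious ancestral state sets, and
# the Kluge-Farris consistency / retention indices.

# Vectorised Fitch step counting over the columns of a 0/1/NA matrix `X`
# (rows = taxa). Taxa on the tree but absent from `X` are treated as
# all-missing. Returns per-character minimum change counts.
fitch_steps_matrix <- function(tree, X) {
  pe <- postorder_edges(tree)
  ntip <- pe$ntip
  nch <- ncol(X)
  nn <- ntip + tree$Nnode
  # bitmask encoding: 1 = {0}, 2 = {1}, 3 = {0,1} (missing)
  sets <- matrix(0L, nn, nch)
  idx <- match(pe$labels, rownames(X))
  for (i in seq_len(ntip)) {
    if (is.na(idx[i])) {
      sets[i, ] <- 3L
    } else {
      x <- X[idx[i], ]
      sets[i, ] <- ifelse(is.na(x), 3L, ifelse(x == 1, 2L, 1L))
    }
  }
  steps <- numeric(nch)
  for (e in seq_len(nrow(pe$edge))) {
    p <- pe$edge[e, 1]; v <- pe$edge[e, 2]
    acc <- sets[p, ]; chi <- sets[v, ]
    first <- acc == 0L
    inter <- bitwAnd(acc, chi)
    hit <- !first & inter == 0L
    steps <- steps + hit
    sets[p, ] <- ifelse(first, chi, ifelse(hit, bitwOr(acc, chi), inter))
  }
  steps
}

# Matrix of 0/1/NA states from a character tibble, rownames = taxa.
char_state_matrix <- function(mat, traits = NULL) {
  mat <- as_char_tibble(mat)
  traits <- traits %||% trait_columns(mat)
  X <- as.matrix(mat[traits])
  storage.mode(X) <- "integer"
  rownames(X) <- mat$taxon
  X
}

#' Fitch parsimony ancestral state reconstruction
#'
#' Computes the minimum number of state changes for one binary character on a
#' rooted tree, and the exact set of states each internal node takes in at
#' least one most-parsimonious reconstruction (MPR). The computation is a
#' unit-cost dynamic program over the tree (a down-pass conditioning each
#' node on each state, plus an up-pass adding the cost contributed from the
#' rest of the tree), so the reported sets are complete: a state is in a
#' node's set if and only if some globally optimal labelling uses it there.
#'
#' @param tree A rooted `phylo`; tips must cover the scored taxa.
#' @param mat A character-matrix tibble with a `taxon` column.
#' @param trait Name of the binary character to reconstruct.
#' @return An object of class `fitch_asr`: a list with `trait`, `steps` (s),
#'   `min_steps` (m), `max_steps` (g), and `node_states`, a tibble with one
#'   row per node (`node`, `type`, `states` e.g. `"0"`, `"1"` or `"0/1"`,
#'   and `equivocal`).
#' @export
fitch_asr <- function(tree, mat, trait) {
  check_phylo(tree)
  states <- trait_states(mat, trait)
  bad <- !is.na(states) & !(states %in% 0:1)
  if (any(bad)) abort(sprintf("Character `%s` is not binary.", trait))

  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  INF <- .Machine$integer.max / 4
  # down-pass: C[v, s+1] = min changes in subtree of v given state s at v
  C <- matrix(0, nn, 2)
  x <- states[tree$tip.label]
  for (i in seq_len(ntip)) {
    if (is.na(x[i])) next
    C[i, ] <- c(if (x[i] == 0) 0 else INF, if (x[i] == 1) 0 else INF)
  }
  pe <- postorder_edges(tree)
  kids <- child_list(tree)
  post_nodes <- c(unique(pe$edge[, 2][pe$edge[, 2] > ntip]), root_node(tree))
  for (v in post_nodes) {
    for (s in 1:2) {
      C[v, s] <- sum(purrr::map_dbl(kids[[v]], function(cn) {
        min(C[cn, s], min(C[cn, ]) + 1)
      }))
    }
  }
  root <- root_node(tree)
  s_total <- min(C[root, ])

  # up-pass: U[v, s+1] = min changes outside the subtree of v given v = s
  U <- matrix(0, nn, 2)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(pre))) {
    p <- pre[e, 1]; v <- pre[e, 2]
    sib <- setdiff(kids[[p]], v)
    sib_cost <- function(sp) {
      sum(purrr::map_dbl(sib, function(b) min(C[b, sp], min(C[b, ]) + 1)))
    }
    for (s in 1:2) {
      U[v, s] <- min(purrr::map_dbl(1:2, function(sp) {
        U[p, sp] + (if (sp != s) 1 else 0) + sib_cost(sp)
      }))
    }
  }
  total <- C + U
  in_set <- total <= s_total + 1e-9

  types <- c(rep("tip", ntip), rep("internal", tree$Nnode))
  types[root] <- "root"
  node_states <- tibble::tibble(
    node = seq_len(nn),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    type = types,
    states = purrr::map_chr(seq_len(nn), function(v) {
      paste(c("0", "1")[in_set[v, ]], collapse = "/")
    }),
    equivocal = rowSums(in_set) > 1
  )

  scored <- x[!is.na(x)]
  n0 <- sum(scored == 0); n1 <- sum(scored == 1)
  m <- as.integer(n0 > 0 && n1 > 0)
  g <- as.integer(min(n0, n1))
  s_total <- as.integer(round(s_total))
  structure(list(trait = trait, steps = s_total, min_steps = m,
                 max_steps = g, node_states = node_states, tree = tree),
            class = "fitch_asr")
}

#' @export
print.fitch_asr <- function(x, ...) {
  cat(sprintf("Fitch parsimony reconstruction of `%s`: s = %d (m = %d, g = %d)\n",
              x$trait, x$steps, x$min_steps, x$max_steps))
  eq <- sum(x$node_states$equivocal & x$node_states$type != "tip")
  cat(sprintf("  %d of %d internal nodes equivocal\n",
              eq, sum(x$node_states$type != "tip")))
  invisible(x)
}

#' @export
tidy.fitch_asr <- function(x, ...) x$node_states

#' @export
glance.fitch_asr <- function(x, ...) {
  s <- x$steps; m <- x$min_steps; g <- x$max_steps
  tibble::tibble(trait = x$trait, steps = s, min_steps = m, max_steps = g,
                 ci = ifelse(s > 0, m / s, NA_real_),
                 ri = ifelse(g > m, (g - s) / (g - m), NA_real_))
}

#' Consistency and retention indices
#'
#' Per-character and ensemble homoplasy indices under Fitch parsimony, using
#' the standard Kluge-Farris definitions: CI = m/s and RI = (g - s)/(g - m),
#' where s is the observed minimum number of changes on the tree, m the
#' minimum conceivable on any tree (1 for a variable binary character) and g
#' the maximum needed on any tree (the minority-state count). Ensemble
#' values sum m, s and g over characters. Constant characters carry no
#' homoplasy signal and are excluded from the ensemble sums; their CI/RI are
#' reported as `NA`.
#'
#' @param tree A rooted `phylo`.
#' @param mat A character-matrix tibble of binary characters.
#' @param traits Characters to include (default all).
#' @param include_outgroup If `FALSE`, the taxon recorded in the matrix's
#'   `outgroup` attribute (or `outgroup` argument) is dropped from both tree
#'   and matrix before computing.
#' @param outgroup Outgroup label, for `include_outgroup = FALSE`.
#' @return A tibble with one row per character (`trait`, `steps`, `min_steps`,
#'   `max_steps`, `ci`, `ri`) and an `ensemble` attribute holding a one-row
#'   tibble of the ensemble CI and RI; see [ensemble_homoplasy()].
#' @export
homoplasy_indices <- function(tree, mat, traits = NULL,
                              include_outgroup = TRUE,
                              outgroup = attr(mat, "outgroup")) {
  check_phylo(tree)
  mat <- as_char_tibble(mat)
  if (!include_outgroup && !is.null(outgroup)) {
    mat <- dplyr::filter(mat, .data$taxon != !!outgroup)
    if (outgroup %in% tree$tip.label) {
      tree <- ape::keep.tip(tree, setdiff(tree$tip.label, outgroup))
    }
  }
  traits <- traits %||% trait_columns(mat)
  X <- char_state_matrix(mat, traits)
  if (!all(rownames(X) %in% tree$tip.label)) {
    abort("All matrix taxa must be tips of the tree.")
  }
  s <- unname(fitch_steps_matrix(tree, X))
  n1 <- unname(colSums(X == 1, na.rm = TRUE))
  n0 <- unname(colSums(X == 0, na.rm = TRUE))
  m <- as.numeric(n0 > 0 & n1 > 0)
  g <- pmin(n0, n1)
  per <- tibble::tibble(
    trait = traits, steps = s, min_steps = m, max_steps = g,
    ci = ifelse(m > 0, m / s, NA_real_),
    ri = ifelse(g > m, (g - s) / (g - m), NA_real_)
  )
  variable <- m > 0
  ens <- tibble::tibble(
    n_characters = sum(variable),
    sum_steps = sum(s[variable]), sum_min = sum(m[variable]),
    sum_max = sum(g[variable]),
    ci = sum(m[variable]) / sum(s[variable]),
    ri = (sum(g[variable]) - sum(s[variable])) /
      (sum(g[variable]) - sum(m[variable]))
  )
  attr(per, "ensemble") <- ens
  per
}

#' @describeIn homoplasy_indices Return just the one-row ensemble tibble.
#' @export
ensemble_homoplasy <- function(tree, mat, traits = NULL,
                               include_outgroup = TRUE,
                               outgroup = attr(mat, "outgroup")) {
  attr(homoplasy_indices(tree, mat, traits, include_outgroup, outgroup),
       "ensemble")
}
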