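# Internal helpers shared across modules. Not exported.

check_phylo <- function(tree, arg = "tree") {
  if (!inherits(tree, "phylo")) {
    abort(sprintf("`%s` must be a `phylo` object.", arg))
  }
  if (anyDuplicated(tree$tip.label)) {
    abort(sprintf("`%s` has duplicated tip labels.", arg))
  }
  invisible(tree)
}

# Postorder edge representation used by the C++ pruning routines.
postorder_edges <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  el <- po$edge.length
  if (is.null(el)) el <- rep(1, nrow(po$edge))
  list(edge = po$edge, el = el, ntip = length(po$tip.label),
       labels = po$tip.label)
}

# Convert a named 0/1/NA state vector into a tip partial-likelihood matrix
# in the tree's tip order. Missing (NA) tips get likelihood 1 in each state.
tip_partials <- function(tree, states, k = 2) {
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, names(states))
  if (length(missing_tips)) {
    abort(paste0("No state supplied for tip(s): ",
                 paste(missing_tips, collapse = ", ")))
  }
  x <- states[tips]
  L <- matrix(0, length(tips), k)
  na <- is.na(x)
  L[na, ] <- 1
  bad <- !na & !(x %in% 0:(k - 1))
  if (any(bad)) {
    abort(sprintf("States must be in 0..%d or NA; offending tips: %s",
                  k - 1, paste(tips[bad], collapse = ", ")))
  }
  L[cbind(which(!na), x[!na] + 1L)] <- 1
  L
}

# Extract one trait as a named 0/1/NA vector from a character-matrix tibble.
trait_states <- function(mat, trait) {
  mat <- as_char_tibble(mat)
  if (!trait %in% names(mat)) {
    abort(sprintf("Unknown character `%s`.", trait))
  }
  setNames(as.integer(mat[[trait]]), mat$taxon)
}

as_char_tibble <- function(mat) {
  mat <- tibble::as_tibble(mat)
  if (!"taxon" %in% names(mat)) {
    abort("A character matrix needs a `taxon` column.")
  }
  if (anyDuplicated(mat$taxon)) abort("Taxon labels must be unique.")
  mat
}

trait_columns <- function(mat) setdiff(names(mat), "taxon")

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (is.null(seed)) abort("A `seed` is required for stochastic operations.")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Children lists indexed by node id.
child_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    out[[p]] <- c(out[[p]], tree$edge[i, 2])
  }
  out
}

root_node <- function(tree) length(tree$tip.label) + 1L

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

rate_bounds <- function() c(lower = 1e-8, upper = 1e3)
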