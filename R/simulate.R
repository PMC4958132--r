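# Generators for ultrametric trees and binary characters with the
# statistical structure the analyses assume, plus the packaged synthetic
# study fixture (33 hunter-gatherer societies, 7 religiosity characters).

#' Simulate an ultrametric tree
#'
#' A pure-birth (Yule) tree rescaled to a chosen root depth, emulating a
#' clade of extant societies with a known time depth.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param depth Root age in kya (> 0).
#' @param birth Birth rate of the Yule process (shape parameter only; the
#'   depth is rescaled afterwards).
#' @param seed Integer seed (required).
#' @return An ultrametric `phylo` with root age `depth` and tip labels
#'   `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, depth = 70, birth = 1, seed = 1) {
  if (n_taxa < 3) abort("`n_taxa` must be >= 3.")
  if (depth <= 0) abort("`depth` must be > 0.")
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = birth, death = 0))
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / d
  tr
}

#' Simulate one binary character on a tree
#'
#' Continuous-time two-state Markov simulation with exponential waiting
#' times along each branch.
#'
#' @param tree A `phylo` with branch lengths.
#' @param q01,q10 Gain and loss rates per unit branch length.
#' @param root_prior `"stationary"` (default), `"uniform"`, or numeric(2).
#' @param seed Integer seed (required).
#' @return A named 0/1 vector over the tips.
#' @export
simulate_binary <- function(tree, q01, q10, root_prior = "stationary",
                            seed = 1) {
  check_phylo(tree)
  Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE)
  prior <- mk_root_prior(root_prior, q01, q10)
  states <- with_seed(seed, sim_markov_states(tree, Q, prior))
  ntip <- length(tree$tip.label)
  setNames(states[seq_len(ntip)] - 1L, tree$tip.label)
}

# Total transition rate used when none is requested: about 1.5 expected
# state flips per root-to-tip lineage, a moderately labile cultural trait.
default_rate_scale <- function(tree) {
  1.5 / max(node_ages(tree))
}

#' Calibrate two-state rates to a target prevalence
#'
#' Chooses gain/loss rates whose stationary frequency of the present state
#' equals the target prevalence: `q01 = r * p`, `q10 = r * (1 - p)` with
#' total rate `r`. With the root state drawn from the same stationary
#' distribution the expected tip prevalence equals the target exactly.
#'
#' @param prevalence Target prevalence in (0, 1).
#' @param rate_scale Total rate `r = q01 + q10` per unit branch length.
#' @return Named vector `c(q01, q10)`.
#' @export
calibrate_rates <- function(prevalence, rate_scale) {
  if (prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must be strictly inside (0, 1).")
  }
  c(q01 = rate_scale * prevalence, q10 = rate_scale * (1 - prevalence))
}

#' Simulate a binary character matrix on a tree
#'
#' Each requested character evolves independently under a two-state Markov
#' model calibrated so its stationary prevalence matches the target, except
#' for characters covered by a `dependent` specification, which evolve as a
#' correlated pair under an 8-rate dependent model (see [simulate_joint()]).
#' Prevalences of exactly 0 or 1 yield constant columns.
#'
#' @param tree A `phylo` with branch lengths.
#' @param prevalences Named numeric vector of target prevalences in `[0,
#'   1]`; names become the character columns.
#' @param rate_scale Total rate per character (default:
#'   1.5 expected changes per root-to-tip path).
#' @param dependent Optional list of specs `list(traits = c(a, b), rates =
#'   <named 8-vector>)` for correlated pairs.
#' @param seed Integer seed (required).
#' @return A character-matrix tibble (`taxon` + one 0/1 column per
#'   character).
#' @export
simulate_traits <- function(tree, prevalences, rate_scale = NULL,
                            dependent = NULL, seed = 1) {
  check_phylo(tree)
  if (is.null(names(prevalences)) || any(!nzchar(names(prevalences)))) {
    abort("`prevalences` must be a named vector.")
  }
  r <- rate_scale %||% default_rate_scale(tree)
  out <- tibble::tibble(taxon = tree$tip.label)
  dep_traits <- unlist(purrr::map(dependent, "traits"))
  if (anyDuplicated(dep_traits)) {
    abort("A trait may appear in at most one dependent pair.")
  }
  k <- 0L
  for (tr in names(prevalences)) {
    k <- k + 1L
    if (tr %in% dep_traits) next
    p <- prevalences[[tr]]
    if (p <= 0 || p >= 1) {
      out[[tr]] <- rep(as.integer(p >= 1), nrow(out))
      next
    }
    qs <- calibrate_rates(p, r)
    out[[tr]] <- unname(simulate_binary(tree, qs[["q01"]], qs[["q10"]],
                                        seed = seed + 31L * k))
  }
  for (i in seq_along(dependent)) {
    spec <- dependent[[i]]
    sim <- simulate_joint(tree, spec$rates, model = "dependent",
                          root_prior = spec$root_prior %||% "uniform",
                          seed = seed + 977L * i)
    out[[spec$traits[1]]] <- sim$A
    out[[spec$traits[2]]] <- sim$B
  }
  out
}

fixture_file <- function(name) {
  system.file("extdata", name, package = "cultphy", mustWork = TRUE)
}

# md5 checksums of the packaged synthetic fixture files
fixture_checksums <- c(
  hg_societies_tree_synthetic.nwk = "002e65d5f9a2502e267fcae72a5e81e2",
  hg_religiosity_matrix_synthetic.csv = "b29150d4728d2c588d18e89bf6c9e548",
  hg_age_constraints_synthetic.tsv = "0ccf5bdbf2ee18554bf3230bbfbe258d"
)

#' Load the synthetic hunter-gatherer study fixture
#'
#' A packaged, fully synthetic stand-in for the study data: a fully resolved
#' supertree topology over 33 named hunter-gatherer societies plus an
#' all-absent hypothetical outgroup, a 33 x 7 religiosity character matrix,
#' and two alternative divergence-date sets ("deep", mostly molecular-scale
#' ages, and "shallow", minimum estimates). The fixture reproduces the
#' aggregate structure of the study sample — the seven trait prevalences
#' (100/79/79/45/24/39/15 %), the nesting of the active traits, the deep
#' African/non-African split with the Vedda as deepest non-African lineage,
#' and the Paleo-Asiatic/Beringian clades — but is *not* the original
#' dataset, whose per-society codings and branch lengths are not
#' redistributed here.
#'
#' @param dates Which divergence-date set to calibrate with.
#' @param method Interpolation rule passed to [ultrametricize()].
#' @return A list with `tree` (ultrametric, 34 tips incl. `Outgroup`),
#'   `traits` (33 x 7 binary tibble), `raw` (matrix with the two 4-state
#'   columns before recoding), `constraints` (the chosen date set), and
#'   `outgroup`.
#' @export
load_study_fixture <- function(dates = c("shallow", "deep"),
                               method = "even") {
  dates <- match.arg(dates)
  for (f in names(fixture_checksums)) {
    path <- fixture_file(f)
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, unname(fixture_checksums[[f]]))) {
      abort(sprintf("Fixture integrity hash mismatch for %s.", f))
    }
  }
  topo <- parse_newick(readLines(fixture_file("hg_societies_tree_synthetic.nwk")))
  raw <- read_char_csv(fixture_file("hg_religiosity_matrix_synthetic.csv"))
  cons <- read_age_constraints(fixture_file("hg_age_constraints_synthetic.tsv"),
                               date_set = dates)
  tree <- calibrate_tree(topo, cons, method = method)
  traits <- derive_binary_traits(raw)
  list(tree = tree, traits = traits, raw = raw, constraints = cons,
       outgroup = "Outgroup")
}
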