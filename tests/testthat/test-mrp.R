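test_that("Baum-Ragan coding with semi-rooted outgroup handling", {
  # rooted triplet: one informative character
  src <- parse_newick("((A,B),C);")
  m <- encode_mrp(src, rooted = TRUE)
  expect_equal(ncol(m$X), 1)
  expect_equal(m$X[c("A", "B", "C", "Outgroup"), 1], c(A = 1, B = 1, C = 0,
                                                       Outgroup = 0))
  # unrooted quartet: outgroup scored missing
  q <- parse_newick("((A,B),(C,D));")
  mu <- encode_mrp(q, rooted = FALSE)
  og <- mu$X["Outgroup", ]
  expect_true(all(is.na(og)))
  ab <- apply(mu$X[c("A", "B", "C", "D"), , drop = FALSE], 2,
              paste, collapse = "")
  expect_true("1100" %in% ab || "0011" %in% ab)

  # taxa absent from a source are missing for its characters
  two <- list(parse_newick("((A,B),C);"), parse_newick("((C,D),E);"))
  m2 <- encode_mrp(two)
  expect_true(all(is.na(m2$X[c("D", "E"), m2$source == "source1"])))

  # scaffold characters carry the scaffold weight
  sc <- parse_newick("((A,B),(C,D));")
  m3 <- encode_mrp(list(parse_newick("((A,C),B);")), scaffold = sc,
                   scaffold_weight = 100)
  expect_true(all(m3$weights[m3$source == "scaffold"] == 100))
  expect_true(all(m3$weights[m3$source != "scaffold"] == 1))

  expect_error(encode_mrp(list()), "At least one")
})

test_that("weighted Fitch length matches direct expectations and brute force", {
  tr <- parse_newick("((A,B),(C,D));")
  X <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(c("A", "B", "C", "D")))
  expect_equal(fitch_length(tr, X), 1)
  Xc <- matrix(1, 4, 1, dimnames = list(c("A", "B", "C", "D")))
  expect_equal(fitch_length(tr, Xc), 0)

  set.seed(11)
  for (i in 1:40) {
    tr <- ape::rtree(6)
    X <- matrix(sample(c(0L, 1L, NA), 6 * 10, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2)),
                6, 10, dimnames = list(tr$tip.label))
    got <- fitch_length(tr, X)
    want <- sum(vapply(seq_len(ncol(X)), function(j) {
      brute_fitch(tr, setNames(X[, j], rownames(X)))
    }, numeric(1)))
    expect_equal(got, want)
  }
})

test_that("the search recovers a perfectly encoded tree", {
  truth <- parse_newick("(((A,B),C),((D,E),F));")
  m <- encode_mrp(truth, rooted = TRUE)
  res <- parsimony_search(m, n_replicates = 3, seed = 1)
  # every best tree, rooted at the outgroup and pruned of it, displays truth
  for (tr in res$trees) {
    rt <- root_at_outgroup(tr)
    rt <- prune_supertree(rt, setdiff(rt$tip.label, "Outgroup"))
    expect_true(ape::all.equal.phylo(ape::unroot(rt), ape::unroot(truth),
                                     use.edge.length = FALSE))
  }
  # perfectly compatible characters need exactly one step each
  expect_equal(res$score, ncol(m$X))
})

test_that("a heavily weighted character overrides a conflicting one", {
  X <- cbind(c(A = 1, B = 1, C = 0, D = 0, Outgroup = 0),
             c(A = 1, B = 0, C = 1, D = 0, Outgroup = 0))
  mrp <- structure(list(X = X, weights = c(100, 1),
                        source = c("scaffold", "source1"),
                        outgroup = "Outgroup"),
                   class = "mrp_matrix")
  res <- parsimony_search(mrp, n_replicates = 5, seed = 2)
  best <- root_at_outgroup(res$trees[[1]])
  ab <- ape::getMRCA(best, c("A", "B"))
  desc <- best$tip.label[unlist(phangorn::Descendants(best, ab, "tips"))]
  expect_setequal(desc, c("A", "B"))
})

test_that("search is deterministic given a seed", {
  set.seed(99)
  X <- matrix(sample(0:1, 7 * 12, replace = TRUE), 7, 12,
              dimnames = list(paste0("t", 1:7)))
  mrp <- structure(list(X = X, weights = rep(1, 12),
                        source = rep("s", 12), outgroup = "t7"),
                   class = "mrp_matrix")
  r1 <- parsimony_search(mrp, n_replicates = 4, seed = 5)
  r2 <- parsimony_search(mrp, n_replicates = 4, seed = 5)
  expect_equal(r1$score, r2$score)
  expect_equal(sort(sapply(r1$trees, write_newick)),
               sort(sapply(r2$trees, write_newick)))
})

test_that("semi-strict consensus keeps uncontradicted clades", {
  t1 <- parse_newick("((A,B),C,D);")
  t2 <- parse_newick("(A,B,(C,D));")
  cons <- semi_strict_consensus(list(t1, t2))
  key <- sort(sapply(ape::prop.part(cons), function(p) {
    paste(sort(attr(ape::prop.part(cons), "labels")[p]), collapse = ",")
  }))
  expect_true("A,B" %in% key && "C,D" %in% key)

  # identical inputs return the same tree
  t3 <- parse_newick("((A,B),(C,D));")
  out <- semi_strict_consensus(list(t3, t3))
  expect_true(ape::all.equal.phylo(out, t3, use.edge.length = FALSE))

  # direct contradiction collapses to a star
  c1 <- parse_newick("((A,B),C);")
  c2 <- parse_newick("((A,C),B);")
  star <- semi_strict_consensus(list(c1, c2))
  expect_equal(star$Nnode, 1)

  expect_error(semi_strict_consensus(list(c1, parse_newick("((A,B),D);"))),
               "leaf set")
})

test_that("pruning gives the induced subtree with summed branch lengths", {
  tr <- parse_newick("(((A:1,B:1):2,C:3):1,(D:2,E:2):2);")
  out <- prune_supertree(tr, c("A", "C", "D"))
  expect_setequal(out$tip.label, c("A", "C", "D"))
  # path A..C keeps total length 1 + 2 + 3 = 6
  d <- ape::cophenetic.phylo(out)
  expect_equal(d["A", "C"], 6)
  expect_true(ape::all.equal.phylo(prune_supertree(tr, tr$tip.label), tr))
  expect_error(prune_supertree(tr, c("A", "Z")), "non-tips")
})

test_that("compatible sources are all displayed by the best supertree", {
  s1 <- parse_newick("((A,B),(C,D));")
  s2 <- parse_newick("((C,D),E);")
  s3 <- parse_newick("(((A,B),C),F);")
  m <- encode_mrp(list(s1, s2, s3), rooted = TRUE)
  res <- parsimony_search(m, n_replicates = 5, seed = 3)
  best <- root_at_outgroup(res$trees[[1]])
  # a source clade is displayed if it appears on the subtree induced by the
  # taxa that source actually scores (other taxa may nest inside it)
  displays <- function(tree, clade, source_taxa) {
    sub <- prune_supertree(tree, c(source_taxa, "Outgroup"))
    anc <- ape::getMRCA(sub, clade)
    desc <- sub$tip.label[unlist(phangorn::Descendants(sub, anc, "tips"))]
    setequal(desc, clade)
  }
  expect_true(displays(best, c("A", "B"), s1$tip.label))
  expect_true(displays(best, c("C", "D"), s1$tip.label))
  expect_true(displays(best, c("C", "D"), s2$tip.label))
  expect_true(displays(best, c("A", "B"), s3$tip.label))
  expect_true(displays(best, c("A", "B", "C"), s3$tip.label))
})
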