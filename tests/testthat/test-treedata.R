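test_that("parse_newick reads simple trees and rejects malformed input", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(tr$Nnode, 2)

  tr2 <- parse_newick("(A,B);")
  expect_equal(length(tr2$tip.label), 2)
  expect_null(tr2$edge.length)

  expect_error(parse_newick("((A,B);"), "unclosed")
  expect_error(parse_newick("(A,B));"), "offset")
})

test_that("write/parse round-trips random trees", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:25, 1)
    tr <- ape::rtree(n)
    txt <- write_newick(tr)
    back <- parse_newick(txt)
    expect_equal(write_newick(back), txt)
    expect_true(ape::all.equal.phylo(tr, back))
  }
})

test_that("minimum node-age constraints raise and propagate ages", {
  tr <- parse_newick("((A,B),C);")
  cons <- age_constraints("ab", list(c("A", "B")), 10)
  out <- enforce_min_node_ages(tr, cons)
  ages <- attr(out, "node_age")
  ab <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(ages[ab], 10)
  expect_gte(ages[4], 10) # root propagated

  # chained constraints: the shallower outer clade is lifted to the inner one
  cons2 <- age_constraints(c("ab", "abc"),
                           list(c("A", "B"), c("A", "B", "C")), c(10, 5))
  ages2 <- attr(enforce_min_node_ages(tr, cons2), "node_age")
  expect_equal(ages2[ab], 10)
  expect_gte(ages2[4], 10)

  expect_error(enforce_min_node_ages(tr,
    age_constraints("x", list("A"), 5)), "single leaf")
  tr2 <- parse_newick("((A,C),B);")
  expect_error(enforce_min_node_ages(tr2, cons), "not monophyletic")
})

test_that("even-spacing ultrametricization matches hand computation", {
  # caterpillar with only the root fixed at 12: internals at 8 and 4
  tr <- parse_newick("(((A,B),C),D);")
  out <- ultrametricize(tr, fixed_ages = c(`5` = 12))
  ages <- node_ages(out)
  expect_equal(unname(ages[5:7]), c(12, 8, 4))
  expect_true(ape::is.ultrametric(out, tol = 1e-9))

  # an already-ultrametric tree with every node fixed is returned unchanged
  tr2 <- ape::rcoal(6)
  ages2 <- node_ages(tr2)
  fixed <- setNames(ages2[7:11], 7:11)
  out2 <- ultrametricize(tr2, fixed_ages = fixed)
  expect_equal(node_ages(out2), ages2, tolerance = 1e-9)

  # fixed descendant older than its fixed ancestor is impossible
  tr3 <- parse_newick("(((A,B),C),D);")
  expect_error(ultrametricize(tr3, fixed_ages = c(`5` = 5, `7` = 9)),
               "interleaving")
})

test_that("calibration satisfies random solvable constraint sets", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(6:15, 1)
    ref <- random_ultra_tree(n, depth = 100)
    topo <- ref
    topo$edge.length <- NULL
    ages <- node_ages(ref)
    internal <- (n + 1):(n + ref$Nnode)
    picks <- sample(internal, sample(2:4, 1))
    cons <- age_constraints(
      paste0("c", seq_along(picks)),
      lapply(picks, function(v) {
        ref$tip.label[unlist(phangorn::Descendants(ref, v, "tips"))]
      }),
      # ask for slightly less than the true age: always satisfiable
      pmax(ages[picks] * runif(length(picks), 0.5, 1), 1e-3))
    out <- calibrate_tree(topo, cons)
    expect_true(ape::is.ultrametric(out, tol = 1e-9))
    out_ages <- node_ages(out)
    for (j in seq_along(picks)) {
      node <- ape::getMRCA(out, cons$leaves[[j]])
      expect_gte(out_ages[node], cons$min_age_kya[j] - 1e-9)
    }
  }
})

test_that("proportional interpolation preserves branch-length ratios", {
  tr <- parse_newick("(((A:1,B:1):3,C:2):1,D:5);")
  out <- ultrametricize(tr, fixed_ages = c(`5` = 12), method = "proportional")
  ages <- node_ages(out)
  # chain root(12) -> n6 -> n7 -> A(0); original path lengths 1, 3, 1,
  # so the nodes sit at 4/5 and 1/5 of the root age
  expect_equal(unname(ages[6]), 12 * 4 / 5)
  expect_equal(unname(ages[7]), 12 * 1 / 5)
  expect_true(ape::is.ultrametric(out, tol = 1e-9))
})

test_that("constraint tables read from TSV and filter by date set", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clade_id\tleaf_set\tmin_age_kya\tdate_set",
               "ab\tA;B\t10\tdeep",
               "ab\tA;B\t5\tshallow"), f)
  cons <- read_age_constraints(f, date_set = "deep")
  expect_equal(nrow(cons), 1)
  expect_equal(cons$leaves[[1]], c("A", "B"))
  expect_equal(cons$min_age_kya, 10)
  expect_error(read_age_constraints(f, date_set = "nope"), "No constraints")
})

test_that("NEXUS tree round-trip preserves topology and lengths", {
  f <- withr::local_tempfile(fileext = ".nex")
  tr <- ape::rtree(8)
  write_trees_nexus(tr, f)
  back <- read_trees_nexus(f)
  expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE))
})
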