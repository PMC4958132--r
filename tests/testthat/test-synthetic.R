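test_that("simulated trees are ultrametric, scaled, and reproducible", {
  tr <- simulate_tree(33, depth = 100, seed = 1)
  expect_equal(length(tr$tip.label), 33)
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  expect_equal(max(node_ages(tr)), 100)
  expect_identical(write_newick(simulate_tree(10, 50, seed = 9)),
                   write_newick(simulate_tree(10, 50, seed = 9)))
  expect_error(simulate_tree(2, 10, seed = 1), ">= 3")
})

test_that("rate calibration hits target prevalences on average", {
  targets <- c(afterlife = 0.79, shamanism = 0.79, ancestor_worship = 0.45,
               active_ancestor_worship = 0.24, high_gods = 0.39,
               active_high_gods = 0.15)
  tr <- simulate_tree(33, depth = 70, seed = 11)
  reps <- 500
  acc <- matrix(0, reps, length(targets))
  for (r in seq_len(reps)) {
    m <- simulate_traits(tr, prevalences = targets, seed = 1000 + r)
    acc[r, ] <- colMeans(as.matrix(m[names(targets)]))
  }
  got <- colMeans(acc)
  expect_true(all(abs(got - targets) < 0.05))
})

test_that("extreme prevalences give constant columns", {
  tr <- simulate_tree(10, depth = 70, seed = 13)
  m <- simulate_traits(tr, prevalences = c(always = 1, never = 0), seed = 14)
  expect_true(all(m$always == 1))
  expect_true(all(m$never == 0))
})

test_that("dependent pairs are more associated than independent ones", {
  tr <- simulate_tree(60, depth = 70, seed = 15)
  dep_rates <- c(q12 = 0.005, q13 = 0.02, q21 = 0.02, q24 = 0.02,
                 q31 = 0.01, q34 = 0.1, q42 = 0.01, q43 = 0.02)
  phi <- function(a, b) {
    if (length(unique(a)) < 2 || length(unique(b)) < 2) return(0)
    abs(suppressWarnings(stats::cor(a, b)))
  }
  phi_dep <- phi_ind <- numeric(20)
  for (r in 1:20) {
    md <- simulate_traits(tr, prevalences = c(a = 0.5, b = 0.5),
                          dependent = list(list(traits = c("a", "b"),
                                                rates = dep_rates)),
                          seed = 2000 + r)
    mi <- simulate_traits(tr, prevalences = c(a = 0.5, b = 0.5),
                          seed = 3000 + r)
    phi_dep[r] <- phi(md$a, md$b)
    phi_ind[r] <- phi(mi$a, mi$b)
  }
  expect_gt(mean(phi_dep), mean(phi_ind))
})

test_that("the packaged fixture has the documented structure", {
  fx <- load_study_fixture("shallow")
  expect_equal(length(fx$tree$tip.label), 34)
  expect_true("Outgroup" %in% fx$tree$tip.label)
  expect_equal(nrow(fx$traits), 33)
  expect_equal(setdiff(names(fx$traits), "taxon"), study_characters)
  expect_true(ape::is.ultrametric(fx$tree, tol = 1e-8))

  # the African societies are the sister group of all non-Africans
  africans <- c("Hadza", "Sandawe", "Kung", "Gwi", "Mbuti", "Aka")
  mrca <- ape::getMRCA(fx$tree, africans)
  desc <- fx$tree$tip.label[unlist(phangorn::Descendants(fx$tree, mrca, "tips"))]
  expect_setequal(desc, africans)
  ing <- ingroup_root(fx$tree)
  kids <- fx$tree$edge[fx$tree$edge[, 1] == ing, 2]
  expect_true(mrca %in% kids)

  # the Vedda is the deepest-rooting non-African lineage
  non_af <- setdiff(fx$traits$taxon, africans)
  na_mrca <- ape::getMRCA(fx$tree, non_af)
  na_kids <- fx$tree$edge[fx$tree$edge[, 1] == na_mrca, 2]
  vedda <- which(fx$tree$tip.label == "Vedda")
  expect_true(vedda %in% na_kids)

  # both date sets calibrate; deep is older
  deep <- load_study_fixture("deep")
  expect_gt(max(node_ages(deep$tree)), max(node_ages(fx$tree)))

  # all minimum-age constraints hold on the calibrated tree
  ages <- node_ages(fx$tree)
  for (i in seq_len(nrow(fx$constraints))) {
    node <- ape::getMRCA(fx$tree, fx$constraints$leaves[[i]])
    expect_gte(ages[node], fx$constraints$min_age_kya[i] - 1e-9)
  }
})

test_that("simulated matrices feed the downstream analyses directly", {
  tr <- simulate_tree(12, depth = 70, seed = 21)
  m <- simulate_traits(tr, prevalences = c(x = 0.6, y = 0.4, z = 0.5),
                       seed = 22)
  expect_s3_class(fitch_asr(tr, m, "x"), "fitch_asr")
  expect_s3_class(fit_pagel_models(tr, m, pair = c("x", "y"), n_starts = 1),
                  "pagel_fit")
  st <- setNames(m$z, m$taxon)
  tab <- asr_marginal(tr, st, threshold = 2)
  expect_equal(nrow(tab), 12 + tr$Nnode)
})
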