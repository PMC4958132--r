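test_that("closed-form transition probabilities are exact", {
  expect_equal(mk_transition_matrix(0, 0.7, 0.2),
               diag(2), ignore_attr = TRUE)
  # q = 0.5, t = 1: P(diff) = (1 - exp(-1)) / 2
  P <- mk_transition_matrix(1, 0.5)
  expect_equal(P[1, 2], (1 - exp(-1)) / 2, tolerance = 1e-12)
  # long branches converge to the stationary distribution
  P2 <- mk_transition_matrix(1e6, 0.3, 0.1)
  expect_equal(unname(P2[1, ]), c(0.25, 0.75), tolerance = 1e-9)
  expect_equal(unname(P2[2, ]), c(0.25, 0.75), tolerance = 1e-9)
  expect_error(mk_transition_matrix(-1, 0.5), ">= 0")
})

test_that("closed form agrees with the matrix exponential across a grid", {
  for (q in c(1e-6, 1e-3, 0.05, 0.5, 2, 10)) {
    for (t in c(0, 0.01, 0.5, 1, 10, 100)) {
      expect_lt(max(abs(mk_transition_matrix(t, q) - expm_2state(t, q, q))),
                1e-12)
      expect_lt(max(abs(mk_transition_matrix(t, q, q / 3) -
                          expm_2state(t, q, q / 3))), 1e-12)
    }
  }
})

test_that("pruning log-likelihood equals brute-force enumeration", {
  set.seed(19)
  for (i in 1:25) {
    n <- sample(4:6, 1)
    tr <- random_ultra_tree(n, depth = sample(2:20, 1))
    states <- sample(c(0L, 1L, NA), n, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1))
    st <- named_states(tr, states)
    q01 <- runif(1, 0.01, 1); q10 <- runif(1, 0.01, 1)
    got <- mk_loglik(tr, st, q01, q10)
    want <- brute_mk_loglik(tr, st, q01, q10)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("degenerate limits behave analytically", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  # all tips present, rate ~ 0: likelihood -> prior of state 1
  ll <- mk_loglik(tr, c(A = 1, B = 1, C = 1), 1e-12)
  expect_equal(ll, log(0.5), tolerance = 1e-6)
  # rate fit on a constant character collapses to the lower bound
  fit <- fit_mk(tr, c(A = 0, B = 0, C = 0), "mk1")
  expect_equal(fit$q01, 1e-8)
})

test_that("the Mk1 optimum matches a dense grid search on the fixture", {
  fx <- load_study_fixture("shallow")
  m <- attach_outgroup(fx$traits)
  st <- setNames(m$afterlife, m$taxon)
  fit <- fit_mk(fx$tree, st, "mk1")
  grid <- exp(seq(log(1e-6), log(1), length.out = 4000))
  gl <- vapply(grid, function(q) mk_loglik(fx$tree, st, q), numeric(1))
  qg <- grid[which.max(gl)]
  expect_equal(log(fit$q01), log(qg), tolerance = 1e-2)
  expect_gte(fit$loglik, max(gl) - 1e-6)
})

test_that("marginal reconstructions are proper and match enumeration", {
  set.seed(29)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    tr <- random_ultra_tree(n, depth = 10)
    states <- sample(0:1, n, replace = TRUE)
    st <- named_states(tr, states)
    q <- runif(1, 0.02, 0.5)
    fit <- structure(list(model = "mk1", q01 = q, q10 = q, loglik = NA,
                          root_prior = "uniform", convergence = 0L),
                     class = "mk_fit")
    tab <- asr_marginal(tr, st, fit)
    expect_equal(tab$p0 + tab$p1, rep(1, nrow(tab)), tolerance = 1e-9)
    # scored tips are reconstructed as themselves
    expect_equal(tab$p1[seq_len(n)], as.numeric(states), tolerance = 1e-12)
    want <- brute_marginals(tr, st, q, q)
    expect_equal(tab$p1, want[, 2], tolerance = 1e-8)
  }
})

test_that("Mk1 marginals mirror under global state exchange", {
  tr <- random_ultra_tree(8, depth = 10)
  states <- c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L)
  st <- named_states(tr, states)
  fit <- fit_mk(tr, st, "mk1")
  a <- asr_marginal(tr, st, fit)
  b <- asr_marginal(tr, named_states(tr, 1L - states), fit)
  expect_equal(a$p1, b$p0, tolerance = 1e-9)
})

test_that("marginals agree with an independent implementation", {
  fx <- load_study_fixture("shallow")
  m <- attach_outgroup(fx$traits)
  st <- setNames(m$shamanism, m$taxon)
  fit <- fit_mk(fx$tree, st, "mk1")
  tab <- asr_marginal(fx$tree, st, fit)
  ntip <- length(fx$tree$tip.label)
  ac <- ape::ace(st[fx$tree$tip.label], fx$tree, type = "discrete",
                 model = "ER")
  # same fitted rate and same root-state probabilities
  expect_equal(unname(ac$rates), fit$q01, tolerance = 1e-3)
  expect_equal(unname(tab$p1[ntip + 1]),
               unname(ac$lik.anc[1, 2]), tolerance = 0.02)
})

test_that("simulated Mk1 rates are recovered within 25% (median)", {
  tr <- simulate_tree(200, depth = 70, seed = 77)
  err <- vapply(1:20, function(r) {
    st <- simulate_binary(tr, 0.02, 0.02, root_prior = "uniform",
                          seed = 78 + r)
    abs(fit_mk(tr, st, "mk1")$q01 - 0.02) / 0.02
  }, numeric(1))
  expect_lt(median(err), 0.25)
})

test_that("the asymmetry test is calibrated and has power", {
  tr <- simulate_tree(60, depth = 70, seed = 101)
  # balanced data on a symmetric question: LR stays near zero
  st <- simulate_binary(tr, 0.02, 0.02, seed = 102)
  out <- asymmetry_test(tr, st, seed = 103)
  expect_gte(out$statistic, 0)
  expect_equal(out$logl_ard >= out$logl_mk1 - 1e-6, TRUE)

  # strongly asymmetric generating process is detected
  tr2 <- simulate_tree(200, depth = 70, seed = 104)
  st2 <- simulate_binary(tr2, 0.1, 0.01, seed = 105)
  out2 <- asymmetry_test(tr2, st2, seed = 106)
  expect_true(out2$asymmetric)
})
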