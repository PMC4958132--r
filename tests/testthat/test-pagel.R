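test_that("the independent joint likelihood factorises over characters", {
  set.seed(53)
  tr <- random_ultra_tree(10, depth = 10)
  xa <- named_states(tr, sample(0:1, 10, TRUE))
  xb <- named_states(tr, sample(0:1, 10, TRUE))
  rates <- c(aG = 0.12, aL = 0.07, bG = 0.3, bL = 0.05)
  joint <- pagel_loglik(tr, xa, xb, rates, model = "independent")
  sep <- mk_loglik(tr, xa, rates[["aG"]], rates[["aL"]]) +
    mk_loglik(tr, xb, rates[["bG"]], rates[["bL"]])
  expect_equal(joint, sep, tolerance = 1e-9)
})

test_that("4-state pruning equals brute-force enumeration", {
  set.seed(59)
  for (i in 1:10) {
    n <- sample(4:5, 1)
    tr <- random_ultra_tree(n, depth = sample(3:15, 1))
    xa <- named_states(tr, sample(c(0L, 1L, NA), n, TRUE, c(.45, .45, .1)))
    xb <- named_states(tr, sample(0:1, n, TRUE))
    rates <- setNames(runif(8, 0.01, 0.6), cultphy:::pagel_rate_names)
    got <- pagel_loglik(tr, xa, xb, rates)
    want <- brute_pagel_loglik(tr, xa, xb, rates)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("the dependent model never scores below the independent one", {
  set.seed(61)
  for (i in 1:6) {
    tr <- simulate_tree(25, depth = 70, seed = 400 + i)
    m <- simulate_traits(tr, prevalences = c(a = 0.6, b = 0.4),
                         seed = 500 + i)
    if (length(unique(m$a)) < 2 || length(unique(m$b)) < 2) next
    fit <- fit_pagel_models(tr, m, pair = c("a", "b"), n_starts = 1,
                            seed = 600 + i)
    expect_gte(fit$logl_d_raw, fit$logl_i - 1e-6)
    expect_gte(fit$lr, 0)
  }
})

test_that("identical characters produce a strongly positive LR", {
  tr <- simulate_tree(30, depth = 70, seed = 71)
  x <- simulate_binary(tr, 0.02, 0.02, seed = 72)
  m <- tibble::tibble(taxon = names(x), a = unname(x), b = unname(x))
  fit <- fit_pagel_models(tr, m, pair = c("a", "b"), n_starts = 2)
  expect_gt(fit$lr, 2)
})

test_that("joint simulation respects degenerate and stationary regimes", {
  tr <- simulate_tree(15, depth = 50, seed = 81)
  zero <- setNames(rep(0, 8), cultphy:::pagel_rate_names)
  sim <- simulate_joint(tr, zero, seed = 82)
  # with no change allowed, all tips share the root state
  expect_equal(length(unique(paste(sim$A, sim$B))), 1)

  # determinism under a fixed seed
  r <- setNames(runif(8, 0.01, 0.1), cultphy:::pagel_rate_names)
  s1 <- simulate_joint(tr, r, seed = 83)
  s2 <- simulate_joint(tr, r, seed = 83)
  expect_identical(s1, s2)

  # high symmetric rates on long branches approach the uniform stationary
  # distribution of the symmetric chain
  tr2 <- simulate_tree(400, depth = 50, seed = 84)
  hot <- setNames(rep(0.5, 8), cultphy:::pagel_rate_names)
  sim2 <- simulate_joint(tr2, hot, seed = 85)
  counts <- table(factor(paste0(sim2$A, sim2$B),
                         levels = c("00", "01", "10", "11")))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("Monte Carlo p-values are proper", {
  tr <- simulate_tree(15, depth = 70, seed = 91)
  m <- simulate_traits(tr, prevalences = c(a = 0.5, b = 0.5), seed = 92)
  fit <- fit_pagel_models(tr, m, pair = c("a", "b"), n_starts = 1)
  out <- pagel_mc_test(fit, n_sim = 19, seed = 93)
  expect_true(out$p_value >= 1 / 20 && out$p_value <= 1)
  expect_equal(length(out$null_lr), 19)
  # a zero observed LR can never be beaten by the +1-corrected null
  fit0 <- fit
  fit0$lr <- 0
  out0 <- pagel_mc_test(fit0, n_sim = 19, seed = 93)
  expect_equal(out0$p_value, 1)
  # p is monotone nonincreasing in the observed LR
  fit_hi <- fit
  fit_hi$lr <- fit$lr + 10
  out_hi <- pagel_mc_test(fit_hi, n_sim = 19, seed = 93)
  expect_lte(out_hi$p_value, out$p_value)
})

test_that("transition flow tables expose the eight dependent rates", {
  tr <- simulate_tree(20, depth = 70, seed = 95)
  m <- simulate_traits(tr, prevalences = c(a = 0.5, b = 0.5), seed = 96)
  fit <- fit_pagel_models(tr, m, pair = c("a", "b"), n_starts = 1)
  flow <- transition_flow(fit)
  expect_equal(nrow(flow), 8)
  expect_setequal(flow$term, cultphy:::pagel_rate_names)
  expect_true(all(flow$rate >= 0))
  expect_false(any(attr(flow, "degenerate")))

  m2 <- m
  m2$a <- 1L
  fit2 <- fit_pagel_models(tr, m2, pair = c("a", "b"), n_starts = 1)
  expect_true(attr(transition_flow(fit2), "degenerate")[["a"]])
})
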