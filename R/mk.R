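# Maximum-likelihood ancestral state reconstruction for a binary character
# under the Mk1 (single-rate) and asymmetric two-rate continuous-time Markov
# models, with marginal ("proportional") node likelihoods and the
# likelihood-decision-threshold significance rule.

#' Transition probability matrix of a two-state Markov model
#'
#' Closed form: with gain rate `q01`, loss rate `q10` and `r = q01 + q10`,
#' `P(0 -> 1; t) = q01/r * (1 - exp(-r t))` and similarly for loss. For the
#' Mk1 model (`q01 = q10 = q`) this reduces to
#' `P(same) = 1/2 + exp(-2qt)/2`, `P(diff) = 1/2 - exp(-2qt)/2`.
#'
#' @param t Branch length (time, >= 0).
#' @param q01 Gain rate (0 to 1), per unit time.
#' @param q10 Loss rate (1 to 0); defaults to `q01` (Mk1).
#' @return A 2x2 row-stochastic matrix, rows = source state (0, 1).
#' @export
mk_transition_matrix <- function(t, q01, q10 = q01) {
  if (t < 0) abort("Branch length `t` must be >= 0.")
  if (q01 < 0 || q10 < 0) abort("Rates must be >= 0.")
  r <- q01 + q10
  if (r == 0) {
    p01 <- 0; p10 <- 0
  } else {
    ex <- exp(-r * t)
    p01 <- q01 / r * (1 - ex)
    p10 <- q10 / r * (1 - ex)
  }
  matrix(c(1 - p01, p01, p10, 1 - p10), 2, 2, byrow = TRUE,
         dimnames = list(c("0", "1"), c("0", "1")))
}

mk_root_prior <- function(root_prior, q01, q10) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == 2, all(root_prior >= 0))
    return(root_prior / sum(root_prior))
  }
  switch(root_prior,
         uniform = c(0.5, 0.5),
         stationary = {
           r <- q01 + q10
           if (r == 0) c(0.5, 0.5) else c(q10, q01) / r
         },
         abort("`root_prior` must be 'uniform', 'stationary' or numeric(2)."))
}

#' Log-likelihood of a binary character on a tree
#'
#' Felsenstein pruning under a two-state Markov model. Tips scored `NA`
#' contribute a partial likelihood of 1 for both states.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param states Named 0/1/`NA` vector (names = tip labels), or a
#'   character-matrix tibble together with `trait`.
#' @param q01,q10 Gain and loss rates.
#' @param root_prior `"uniform"` (default), `"stationary"`, or numeric(2).
#' @param trait Character name when `states` is a matrix tibble.
#' @return The log-likelihood.
#' @export
mk_loglik <- function(tree, states, q01, q10 = q01, root_prior = "uniform",
                      trait = NULL) {
  check_phylo(tree)
  if (!is.null(trait)) states <- trait_states(states, trait)
  pe <- postorder_edges(tree)
  L <- tip_partials(tree, states)
  prior <- mk_root_prior(root_prior, q01, q10)
  cpp_loglik_2state(pe$edge, pe$el, pe$ntip, L, q01, q10, prior)
}

#' Fit a two-state Markov model by maximum likelihood
#'
#' The Mk1 model has one free rate, optimised on the log scale by
#' one-dimensional bounded search; the asymmetric (`"ard"`) model has
#' separate gain and loss rates, optimised by quasi-Newton search with
#' multiple seeded starting points to avoid boundary traps. Rates are
#' bounded below at 1e-8.
#'
#' @inheritParams mk_loglik
#' @param model `"mk1"` (equal rates) or `"ard"` (all rates different).
#' @param n_starts Number of starting points for the `"ard"` optimisation.
#' @param seed Seed for the extra starting points.
#' @param factr,pgtol Convergence controls passed to [stats::optim()]'s
#'   L-BFGS-B (see there); loosened by Monte Carlo drivers for speed.
#' @return An object of class `mk_fit`: list with `model`, `q01`, `q10`,
#'   `loglik`, `root_prior`, `convergence` (0 = converged).
#' @export
fit_mk <- function(tree, states, model = c("mk1", "ard"),
                   root_prior = "uniform", trait = NULL,
                   n_starts = 3, seed = 1, factr = 1e7, pgtol = 0) {
  check_phylo(tree)
  model <- match.arg(model)
  if (!is.null(trait)) states <- trait_states(states, trait)
  pe <- postorder_edges(tree)
  L <- tip_partials(tree, states)
  b <- rate_bounds()
  ll <- function(q01, q10) {
    prior <- mk_root_prior(root_prior, q01, q10)
    cpp_loglik_2state(pe$edge, pe$el, pe$ntip, L, q01, q10, prior)
  }
  if (model == "mk1") {
    opt <- optimize(function(lq) -ll(exp(lq), exp(lq)),
                    interval = log(b), tol = 1e-10)
    q <- exp(opt$minimum)
    # a constant character drives the rate to the lower bound
    if (-opt$objective < ll(b["lower"], b["lower"]) + 1e-12 &&
        opt$minimum < log(b["lower"]) + 1e-6) {
      q <- unname(b["lower"])
    }
    fit <- list(model = "mk1", q01 = q, q10 = q, loglik = -opt$objective,
                root_prior = root_prior, convergence = 0L)
  } else {
    obj <- function(lp) -ll(exp(lp[1]), exp(lp[2]))
    starts <- with_seed(seed, {
      base <- log(c(0.5, 0.5) / max(sum(pe$el), 1))
      extra <- purrr::map(seq_len(max(0, n_starts - 1)), function(i) {
        base + stats::rnorm(2, 0, 2)
      })
      c(list(base), extra)
    })
    fits <- purrr::map(starts, function(s) {
      tryCatch(optim(s, obj, method = "L-BFGS-B",
                     lower = log(b["lower"]), upper = log(b["upper"]),
                     control = list(maxit = 500, factr = factr,
                                    pgtol = pgtol)),
               error = function(e) NULL)
    })
    fits <- fits[!purrr::map_lgl(fits, is.null)]
    if (!length(fits)) abort("Optimisation failed for all starting points.")
    bestf <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
    fit <- list(model = "ard", q01 = exp(bestf$par[1]), q10 = exp(bestf$par[2]),
                loglik = -bestf$value, root_prior = root_prior,
                convergence = bestf$convergence)
    if (bestf$convergence != 0) {
      warn("ARD optimisation did not formally converge; best value returned.")
    }
  }
  structure(fit, class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Two-state Markov fit (%s): q01 = %.6g, q10 = %.6g, logL = %.4f\n",
              x$model, x$q01, x$q10, x$loglik))
  invisible(x)
}

#' @export
tidy.mk_fit <- function(x, ...) {
  tibble::tibble(term = c("q01", "q10"), estimate = c(x$q01, x$q10))
}

#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(model = x$model, q01 = x$q01, q10 = x$q10,
                 logLik = x$loglik,
                 df = if (x$model == "mk1") 1L else 2L)
}

#' Asymmetric likelihood-ratio test for a binary character
#'
#' Compares the one-rate Mk1 model against the asymmetric two-rate model by
#' a likelihood-ratio test (statistic `2 * (logL_ard - logL_mk1)`, chi-square
#' with 1 df). A non-significant result validates the simpler Mk1 model for
#' ancestral state reconstruction.
#'
#' @inheritParams fit_mk
#' @param alpha Significance level for the verdict.
#' @return A one-row tibble: `logl_mk1`, `logl_ard`, `statistic`, `df`,
#'   `p_value`, `asymmetric` (logical verdict).
#' @export
asymmetry_test <- function(tree, states, root_prior = "uniform",
                           trait = NULL, n_starts = 3, seed = 1,
                           alpha = 0.05) {
  f1 <- fit_mk(tree, states, "mk1", root_prior, trait)
  f2 <- fit_mk(tree, states, "ard", root_prior, trait, n_starts, seed)
  stat <- max(2 * (f2$loglik - f1$loglik), 0)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  tibble::tibble(logl_mk1 = f1$loglik, logl_ard = f2$loglik,
                 statistic = stat, df = 1L, p_value = p,
                 asymmetric = p < alpha)
}

#' Marginal ancestral state reconstruction
#'
#' Marginal ("proportional") likelihoods of each state at every node under a
#' fitted two-state model, computed by the up-down algorithm: the pruning
#' pass supplies each node's below-partials, a preorder pass supplies the
#' likelihood of the rest of the tree, and their normalised product is the
#' marginal probability. A node's reconstruction is flagged significant when
#' the log-likelihoods of the two states differ by at least `threshold`
#' (T = 2 corresponds to one state being supported e^2 = 7.39 times more
#' strongly than the other); otherwise it is *equivocal*.
#'
#' @inheritParams mk_loglik
#' @param fit An `mk_fit` (from [fit_mk()]); fitted on the fly under Mk1 if
#'   omitted.
#' @param threshold Likelihood decision threshold T on the log scale.
#' @return An object of class `asr_table`: a tibble with one row per node
#'   (`node`, `label`, `type`, `p0`, `p1`, `state`, `significant`), with the
#'   fit and threshold stored in attributes.
#' @export
asr_marginal <- function(tree, states, fit = NULL, threshold = 2,
                         root_prior = NULL, trait = NULL) {
  check_phylo(tree)
  if (!is.null(trait)) states <- trait_states(states, trait)
  if (is.null(fit)) fit <- fit_mk(tree, states, "mk1")
  q01 <- fit$q01; q10 <- fit$q10
  prior <- mk_root_prior(root_prior %||% fit$root_prior, q01, q10)

  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- root_node(tree)
  pe <- postorder_edges(tree)
  tipL <- tip_partials(tree, states)

  el_of <- rep(NA_real_, nn)
  el_of[tree$edge[, 2]] <- tree$edge.length %||% rep(1, nrow(tree$edge))
  P_of <- vector("list", nn)
  for (v in tree$edge[, 2]) P_of[[v]] <- mk_transition_matrix(el_of[v], q01, q10)

  # downward partials F[v, ], renormalised per node (scale factors cancel
  # in the normalised marginals)
  F <- matrix(1, nn, 2)
  F[seq_len(ntip), ] <- tipL
  for (e in seq_len(nrow(pe$edge))) {
    p <- pe$edge[e, 1]; v <- pe$edge[e, 2]
    F[p, ] <- F[p, ] * as.vector(P_of[[v]] %*% F[v, ])
    if (max(F[p, ]) > 0) F[p, ] <- F[p, ] / max(F[p, ])
  }

  kids <- child_list(tree)
  # above-likelihoods G[v, ]
  G <- matrix(NA_real_, nn, 2)
  G[root, ] <- prior
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(pre))) {
    p <- pre[e, 1]; v <- pre[e, 2]
    sib <- setdiff(kids[[p]], v)
    above <- G[p, ]
    for (b in sib) above <- above * as.vector(P_of[[b]] %*% F[b, ])
    G[v, ] <- as.vector(t(P_of[[v]]) %*% above)
    if (max(G[v, ]) > 0) G[v, ] <- G[v, ] / max(G[v, ])
  }

  marg <- F * G
  marg <- marg / rowSums(marg)

  types <- c(rep("tip", ntip), rep("internal", tree$Nnode))
  types[root] <- "root"
  lp <- log(marg)
  out <- tibble::tibble(
    node = seq_len(nn),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    type = types,
    p0 = marg[, 1], p1 = marg[, 2],
    state = ifelse(marg[, 2] >= marg[, 1], 1L, 0L),
    significant = abs(lp[, 2] - lp[, 1]) >= threshold
  )
  structure(out, class = c("asr_table", class(out)),
            fit = fit, threshold = threshold, tree = tree)
}

#' Last common ancestor of the ingroup
#'
#' The node id of the most recent common ancestor of all tips except the
#' outgroup: on an outgroup-rooted tree this is the child of the global root
#' subtending every study taxon.
#'
#' @param tree A rooted `phylo`.
#' @param outgroup Outgroup tip label.
#' @return An integer node id.
#' @export
ingroup_root <- function(tree, outgroup = "Outgroup") {
  check_phylo(tree)
  ingroup <- setdiff(tree$tip.label, outgroup)
  if (length(ingroup) < 2) abort("Fewer than two ingroup tips.")
  as.integer(ape::getMRCA(tree, ingroup))
}
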