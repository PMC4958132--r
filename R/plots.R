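# ggplot2 visualisations: trait reconstructions on the tree and the
# dependent-model transition flow.

# Rectangular layout coordinates for a rooted tree: x = -age (time flows
# left to right), y = tip order with internal nodes centred on their
# children.
tree_layout <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  ages <- node_ages(tree)
  y <- rep(NA_real_, nn)
  tips_order <- ape::reorder.phylo(tree, "cladewise")$edge[, 2]
  tips_order <- tips_order[tips_order <= ntip]
  y[tips_order] <- seq_along(tips_order)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  kids <- child_list(tree)
  for (v in c(unique(po[, 2][po[, 2] > ntip]), root_node(tree))) {
    y[v] <- mean(y[kids[[v]]])
  }
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tibble::tibble(node = seq_len(nn), x = -ages, y = y,
                 parent = parent,
                 label = c(tree$tip.label, rep(NA_character_, tree$Nnode)))
}

#' Plot a marginal ancestral state reconstruction
#'
#' Time-calibrated tree with internal nodes coloured by the marginal
#' probability of the present state; significant reconstructions (the
#' likelihood-threshold rule) are drawn as filled circles, equivocal ones as
#' open circles.
#'
#' @param object An `asr_table` from [asr_marginal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asr_table <- function(object, ...) {
  tree <- attr(object, "tree")
  lay <- tree_layout(tree)
  seg <- dplyr::filter(lay, !is.na(.data$parent))
  seg <- dplyr::mutate(seg,
                       xpar = lay$x[.data$parent],
                       ypar = lay$y[.data$parent])
  nodes <- dplyr::left_join(lay, tibble::as_tibble(object)[
    c("node", "p1", "significant")], by = "node")
  ntip <- length(tree$tip.label)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$xpar, xend = .data$x,
                                       y = .data$y, yend = .data$y),
                          linewidth = 0.3) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$xpar, xend = .data$xpar,
                                       y = .data$ypar, yend = .data$y),
                          linewidth = 0.3) +
    ggplot2::geom_point(data = dplyr::filter(nodes, .data$node > ntip),
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$p1,
                                     shape = .data$significant),
                        size = 2.5) +
    ggplot2::geom_text(data = dplyr::filter(nodes, .data$node <= ntip),
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = 0, nudge_x = 0.01 * diff(range(lay$x)),
                       size = 2.8) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 21, `FALSE` = 1),
                                name = "significant") +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1), name = "P(present)") +
    ggplot2::scale_x_continuous(labels = function(v) -v, name = "age (kya)",
                                expand = ggplot2::expansion(mult = c(0.02, 0.18))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.title.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
}

#' Plot the dependent-model transition flow
#'
#' The four joint states at the corners of a square, with arrows whose
#' width is proportional to the fitted dependent-model transition rates —
#' the standard rendering of a correlated-evolution fit.
#'
#' @param object A fitted `pagel_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pagel_fit <- function(object, ...) {
  flow <- transition_flow(object)
  pos <- tibble::tibble(
    state = c("A0B0", "A0B1", "A1B0", "A1B1"),
    x = c(0, 0, 1, 1), y = c(0, 1, 0, 1))
  lab <- c(A0B0 = sprintf("%s -, %s -", object$pair[1], object$pair[2]),
           A0B1 = sprintf("%s -, %s +", object$pair[1], object$pair[2]),
           A1B0 = sprintf("%s +, %s -", object$pair[1], object$pair[2]),
           A1B1 = sprintf("%s +, %s +", object$pair[1], object$pair[2]))
  edges <- dplyr::left_join(flow, pos, by = c("from" = "state"))
  edges <- dplyr::left_join(edges, pos, by = c("to" = "state"),
                            suffix = c("", "_to"))
  # offset opposing arrows so they do not overlap
  edges <- dplyr::mutate(edges,
    dx = .data$x_to - .data$x, dy = .data$y_to - .data$y,
    ox = -.data$dy * 0.04, oy = .data$dx * 0.04,
    x0 = .data$x + .data$dx * 0.18 + .data$ox,
    y0 = .data$y + .data$dy * 0.18 + .data$oy,
    x1 = .data$x + .data$dx * 0.82 + .data$ox,
    y1 = .data$y + .data$dy * 0.82 + .data$oy)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$rate),
      arrow = ggplot2::arrow(length = ggplot2::unit(6, "pt"),
                             type = "closed")) +
    ggplot2::geom_label(data = pos,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = lab[.data$state])) +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 2.5),
                                        name = "rate (/kya)") +
    ggplot2::coord_equal(xlim = c(-0.25, 1.25), ylim = c(-0.2, 1.2)) +
    ggplot2::theme_void()
}

#' Bar chart of trait prevalences
#'
#' @param mat A character-matrix tibble.
#' @param ... Passed to [trait_prevalence()].
#' @return A ggplot object.
#' @export
plot_prevalence <- function(mat, ...) {
  pv <- trait_prevalence(mat, ...)
  pv$trait <- factor(pv$trait, levels = pv$trait)
  ggplot2::ggplot(pv, ggplot2::aes(x = .data$trait, y = .data$prevalence)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$prevalence_pct, "%")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "prevalence (%)") +
    ggplot2::ylim(0, 105) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
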