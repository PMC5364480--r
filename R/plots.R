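# ggplot2 methods for the main result types.

#' Plot a protein interaction network
#'
#' Fruchterman-Reingold layout with homodimer loops drawn as point rings.
#'
#' @param object A [pin()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pin <- function(object, ...) {
  g <- pin_igraph(object)
  set.seed(1L)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(node = igraph::V(g)$name, x = lay[, 1], y = lay[, 2])
  edges <- object$edges %>%
    left_join(nodes, by = c(node_a = "node")) %>%
    rename(xa = "x", ya = "y") %>%
    left_join(nodes, by = c(node_b = "node")) %>%
    rename(xb = "x", yb = "y")
  loops <- edges %>% filter(.data$node_a == .data$node_b)
  lines <- edges %>% filter(.data$node_a != .data$node_b)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = lines,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          colour = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 3) +
    ggplot2::geom_point(data = loops,
                        ggplot2::aes(x = .data$xa, y = .data$ya),
                        shape = 21, size = 6, stroke = 1.2, fill = NA) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$node),
                       vjust = -1, size = 3) +
    ggplot2::labs(title = sprintf("%s (%g mya), density %.3f",
                                  object$epoch_label, object$time_mya,
                                  network_density(object))) +
    ggplot2::theme_void()
}

#' Plot a network comparison
#'
#' Bar chart of conserved, gained and lost interaction counts.
#'
#' @param object A `pin_comparison` from [compare_networks()].
#' @param ... Ignored.
#' @export
autoplot.pin_comparison <- function(object, ...) {
  df <- tibble(
    category = factor(c("conserved", "gained", "lost"),
                      levels = c("conserved", "gained", "lost")),
    count = c(nrow(object$conserved), nrow(object$gained),
              nrow(object$lost))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$count,
                                   fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      title = sprintf("%s to %s (%g mya)", object$epoch_a, object$epoch_b,
                      object$divergence_mya),
      subtitle = sprintf("gain %.2g, loss %.2g per potential edge per mya",
                         object$gain_rate, object$loss_rate),
      x = NULL, y = "interactions") +
    ggplot2::theme_minimal()
}

#' Plot a trajectory RMSD series
#'
#' @param object A `trajectory_rmsd` tibble from [trajectory_rmsd()].
#' @param ... Ignored.
#' @export
autoplot.trajectory_rmsd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns, y = .data$rmsd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "RMSD (\u00c5)") +
    ggplot2::theme_minimal()
}

#' Plot Boltzmann probabilities of an ensemble
#'
#' Conformer probabilities ranked by energy; the flatter the profile, the
#' higher the conformational entropy.
#'
#' @param object A [conformer_ensemble()].
#' @param ... Ignored.
#' @export
autoplot.conformer_ensemble <- function(object, ...) {
  p <- boltzmann_probabilities(object)
  df <- tibble(rank = rank(object$energies, ties.method = "first"),
               probability = p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = object$label, x = "conformer (by energy rank)",
                  y = "Boltzmann probability") +
    ggplot2::theme_minimal()
}
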