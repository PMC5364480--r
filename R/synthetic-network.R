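# Generative model for an evolving interaction network: an initial
# Erdos-Renyi network (self-pairs allowed) evolves toward the present under
# per-mya Bernoulli edge gain/loss, punctuated by polyploidy events that copy
# every node and let copies inherit all parent edges all-versus-all, with
# optional subfunctionalization partitioning a parent's edge set among copies.

#' Parameters of a simulated network history
#'
#' @param n0 Initial node count (>= 1).
#' @param p0 Initial edge probability over all unordered pairs including
#'   self-pairs, in `[0, 1]`.
#' @param events Polyploidy events: a data frame with columns `time_mya`,
#'   `multiplicity`, or `NULL` for none.
#' @param gain_rate Probability per absent potential edge per mya of gaining
#'   that edge.
#' @param loss_rate Probability per existing edge per mya of losing it.
#' @param subfunc_prob Probability, at a polyploidy event, that a duplicated
#'   node's inherited edge set is partitioned among its copies (union of the
#'   copies' mapped edge sets equals the parent's; pairwise disjoint).
#' @param epochs Snapshot times in mya, strictly decreasing toward the
#'   present (e.g. `c(120, 109)`).
#' @param seed Integer seed for the history.
#' @return A list of class `evolution_params`.
#' @export
evolution_params <- function(n0 = 30, p0 = 0.1, events = NULL,
                             gain_rate = 0.002, loss_rate = 0.002,
                             subfunc_prob = 0, epochs = c(120, 109),
                             seed = 1L) {
  stop_if_not(n0 >= 1, "n0 must be >= 1")
  stop_if_not(p0 >= 0 && p0 <= 1, "p0 must be in [0, 1]")
  stop_if_not(subfunc_prob >= 0 && subfunc_prob <= 1,
              "subfunc_prob must be in [0, 1]")
  stop_if_not(gain_rate >= 0 && loss_rate >= 0, "rates must be >= 0")
  stop_if_not(length(epochs) >= 1 && all(diff(epochs) < 0),
              "epoch times must be strictly decreasing toward the present")
  if (!is.null(events)) {
    events <- as_tibble(events)
    stop_if_not(all(c("time_mya", "multiplicity") %in% names(events)),
                "events need columns time_mya, multiplicity")
    stop_if_not(all(events$multiplicity >= 2),
                "event multiplicities must be >= 2")
    events <- arrange(events, dplyr::desc(.data$time_mya))
  } else {
    events <- tibble(time_mya = double(), multiplicity = integer())
  }
  structure(
    list(n0 = n0, p0 = p0, events = events, gain_rate = gain_rate,
         loss_rate = loss_rate, subfunc_prob = subfunc_prob,
         epochs = round(epochs), seed = as.integer(seed)),
    class = "evolution_params"
  )
}

all_pairs <- function(nodes) {
  nodes <- sort(nodes)
  n <- length(nodes)
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  tibble(node_a = nodes[idx[, 1]], node_b = nodes[idx[, 2]])
}

#' Simulate a network history with known ground truth
#'
#' Runs the generative model of [evolution_params()] from the oldest epoch to
#' the most recent, in 1-mya steps. Polyploidy events copy every node
#' `multiplicity` times (copy ids `<parent>.<k>`) with all-versus-all edge
#' inheritance before optional subfunctionalization; between events each
#' absent pair is gained with probability `gain_rate` per mya and each present
#' edge lost with probability `loss_rate` per mya.
#'
#' @param params An [evolution_params()].
#' @return A list of class `evolution_truth` with `snapshots` (one [pin()]
#'   per epoch), `ortholog_maps` (one [ortholog_map()] per consecutive
#'   snapshot pair), realized `true_gain_rate` / `true_loss_rate` (event
#'   counts per potential edge per mya over the whole history, the same scale
#'   as [gain_loss_rates()]), the configured `params`, and `seed`.
#' @export
simulate_pin_evolution <- function(params) {
  stopifnot(inherits(params, "evolution_params"))
  seed_rng(params$seed)

  epochs <- params$epochs
  t_now <- epochs[1]
  nodes <- sprintf("p%02d", seq_len(params$n0))
  pairs <- all_pairs(nodes)
  present <- runif(nrow(pairs)) < params$p0
  edges <- pairs[present, ]

  snapshots <- list()
  maps <- list()
  # identity-so-far map between consecutive snapshots
  interval_map <- identity_map(nodes)
  gain_events <- 0; loss_events <- 0; exposure <- 0

  record <- function(t) {
    if (t %in% epochs) {
      snapshots[[length(snapshots) + 1]] <<- pin(
        edges = edges, nodes = nodes,
        epoch_label = sprintf("t%d", t), time_mya = t)
      if (length(snapshots) > 1) {
        maps[[length(maps) + 1]] <<- interval_map
      }
      interval_map <<- identity_map(nodes)
    }
  }
  record(t_now)

  events <- params$events
  while (t_now > epochs[length(epochs)]) {
    # polyploidy events scheduled within (t_now, t_now - 1]
    ev <- events[events$time_mya < t_now - 1e-9 &
                   events$time_mya >= t_now - 1 - 1e-9, , drop = FALSE]
    # one mya of gain/loss, then any event at the end of the step
    pairs <- all_pairs(nodes)
    keys <- edge_key(pairs)
    have <- keys %in% edge_key(edges)
    gain <- !have & runif(nrow(pairs)) < params$gain_rate
    lose <- have & runif(nrow(pairs)) < params$loss_rate
    gain_events <- gain_events + sum(gain)
    loss_events <- loss_events + sum(lose)
    exposure <- exposure + nrow(pairs)
    edges <- pairs[(have & !lose) | gain, ]
    t_now <- t_now - 1

    for (i in seq_len(nrow(ev))) {
      dup <- duplicate_network(nodes, edges, ev$multiplicity[i],
                               params$subfunc_prob)
      nodes <- dup$nodes
      edges <- dup$edges
      interval_map <- compose_maps(interval_map, dup$map)
    }
    record(t_now)
  }

  structure(
    list(
      snapshots = snapshots,
      ortholog_maps = maps,
      true_gain_rate = if (exposure > 0) gain_events / exposure else 0,
      true_loss_rate = if (exposure > 0) loss_events / exposure else 0,
      params = params,
      seed = params$seed
    ),
    class = "evolution_truth"
  )
}

# Copy every node `m` times with all-versus-all inheritance; with probability
# subfunc_prob a parent's edges are partitioned among its copies: each
# ancestral edge is assigned to exactly one copy of each subfunctionalizing
# endpoint, so the union of the copies' mapped edge sets equals the parent's
# edge set and pairwise intersections are empty.
duplicate_network <- function(nodes, edges, m, subfunc_prob) {
  copies <- lapply(setNames(nodes, nodes),
                   function(v) paste(v, seq_len(m), sep = "."))
  new_nodes <- unlist(copies, use.names = FALSE)
  subfunc <- setNames(runif(length(nodes)) < subfunc_prob, nodes)

  rows <- purrr::pmap(list(edges$node_a, edges$node_b), function(a, b) {
    ca <- copies[[a]]; cb <- copies[[b]]
    keep_a <- if (subfunc[[a]]) sample(ca, 1) else ca
    keep_b <- if (subfunc[[b]]) sample(cb, 1) else cb
    if (a == b) {
      kc <- if (subfunc[[a]]) keep_a else ca
      idx <- which(upper.tri(diag(length(kc)), diag = TRUE), arr.ind = TRUE)
      tibble(node_a = kc[idx[, 1]], node_b = kc[idx[, 2]])
    } else {
      g <- expand.grid(node_a = keep_a, node_b = keep_b,
                       stringsAsFactors = FALSE)
      as_tibble(g)
    }
  })
  list(
    nodes = sort(new_nodes),
    edges = canonical_edges(dplyr::bind_rows(rows)),
    map = ortholog_map(tibble(ancestor = rep(nodes, each = m),
                              descendant = unlist(copies, use.names = FALSE)))
  )
}

seed_rng <- function(seed) set.seed(as.integer(seed) %% .Machine$integer.max)

#' @export
print.evolution_truth <- function(x, ...) {
  cat(sprintf(
    "<evolution_truth> %d snapshots (%s mya); realized gain %.3g, loss %.3g per potential edge per mya\n",
    length(x$snapshots),
    paste(vapply(x$snapshots, function(s) s$time_mya, 0), collapse = ", "),
    x$true_gain_rate, x$true_loss_rate))
  invisible(x)
}
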