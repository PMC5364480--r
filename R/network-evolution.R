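#' Construct an ortholog map between two network epochs
#'
#' Relates the proteins of an ancestral network to their descendant copies.
#' Across a whole-genome duplication a single ancestor maps to several
#' descendants; every mapped descendant has exactly one ancestor.
#'
#' @param pairs Data frame with columns `ancestor`, `descendant`.
#' @return An object of class `ortholog_map` (a tibble).
#' @export
ortholog_map <- function(pairs) {
  out <- as_tibble(pairs[, c("ancestor", "descendant")])
  out$ancestor <- as.character(out$ancestor)
  out$descendant <- as.character(out$descendant)
  out <- distinct(out)
  dup <- out$descendant[duplicated(out$descendant)]
  stop_if_not(length(dup) == 0,
              "descendant(s) with more than one ancestor: %s",
              paste(unique(dup), collapse = ", "))
  class(out) <- c("ortholog_map", class(out))
  out
}

#' Identity ortholog map over a node set
#' @param nodes Character vector of protein ids.
#' @export
identity_map <- function(nodes) {
  ortholog_map(tibble(ancestor = nodes, descendant = nodes))
}

# Compose two ortholog maps (ancestor -> mid -> descendant).
compose_maps <- function(m1, m2) {
  j <- dplyr::inner_join(as_tibble(m1), as_tibble(m2),
                         by = c(descendant = "ancestor"))
  ortholog_map(tibble(ancestor = j$ancestor, descendant = j$descendant.y))
}

#' Rescale a network across a polyploidy event
#'
#' Every node is copied `multiplicity` times and the copies inherit all parent
#' interactions all-versus-all: an ancestral edge (a, b) yields edges between
#' every copy of a and every copy of b, and an ancestral homodimer loop (a, a)
#' yields all pairs among the copies of a, loops included. Redundant copies
#' are then removed down to `keep` (an explicit node subset) or `target_size`
#' (deterministic selection: lowest copy index first across ancestors in
#' sorted order), so that e.g. a triplicated ancestral network can be compared
#' against a descendant network of the same size.
#'
#' @param pin A [pin()].
#' @param multiplicity Integer >= 2; copies per node (3 for a triplication).
#' @param keep Optional character vector of copied node ids to retain.
#' @param target_size Optional integer; retained node count.
#' @return A [pin()] with `attr(, "map")`: the [ortholog_map()] from ancestral
#'   ids to retained copies. Copies are named `<ancestor>.<k>`.
#' @export
rescale_by_polyploidy <- function(pin, multiplicity, keep = NULL,
                                  target_size = NULL) {
  stop_if_not(multiplicity >= 2 && multiplicity == round(multiplicity),
              "`multiplicity` must be an integer >= 2")
  n0 <- length(pin$nodes)
  copies <- lapply(setNames(pin$nodes, pin$nodes),
                   function(v) paste(v, seq_len(multiplicity), sep = "."))
  all_copies <- unlist(copies, use.names = FALSE)

  if (!is.null(keep)) {
    bad <- setdiff(keep, all_copies)
    stop_if_not(length(bad) == 0, "keep contains non-copy nodes: %s",
                paste(bad, collapse = ", "))
  } else if (!is.null(target_size)) {
    stop_if_not(n0 * multiplicity >= target_size,
                "target_size %d exceeds copied node count %d",
                target_size, n0 * multiplicity)
    # lowest copy index first, ancestors in sorted order
    ordered <- unlist(lapply(seq_len(multiplicity), function(k)
      paste(sort(pin$nodes), k, sep = ".")))
    keep <- ordered[seq_len(target_size)]
  } else {
    keep <- all_copies
  }

  edges <- expand_edges(pin$edges, copies)
  keep_set <- keep
  edges <- edges %>%
    filter(.data$node_a %in% keep_set, .data$node_b %in% keep_set)

  out <- pin(edges = edges, nodes = keep,
             epoch_label = paste0(pin$epoch_label, " x", multiplicity),
             time_mya = pin$time_mya)
  map <- ortholog_map(tibble(
    ancestor = rep(pin$nodes, each = multiplicity),
    descendant = all_copies
  ) %>% filter(.data$descendant %in% keep_set))
  attr(out, "map") <- map
  out
}

# All-versus-all expansion of an ancestral edge set given copies per node.
expand_edges <- function(edges, copies) {
  if (nrow(edges) == 0) {
    return(tibble(node_a = character(), node_b = character()))
  }
  rows <- purrr::pmap(list(edges$node_a, edges$node_b), function(a, b) {
    ca <- copies[[a]]; cb <- copies[[b]]
    if (a == b) {
      idx <- which(upper.tri(diag(length(ca)), diag = TRUE), arr.ind = TRUE)
      tibble(node_a = ca[idx[, 1]], node_b = ca[idx[, 2]])
    } else {
      g <- expand.grid(node_a = ca, node_b = cb, stringsAsFactors = FALSE)
      as_tibble(g)
    }
  })
  canonical_edges(dplyr::bind_rows(rows))
}

#' Compare two network epochs through an ortholog map
#'
#' Classifies the descendant network's edges as conserved (some ancestral edge
#' maps onto the pair) or gained, and the ancestral network's edges as lost
#' when none of their descendant-pair images survive. Edges touching unmapped
#' descendant nodes count as gained; ancestral edges with no surviving
#' descendant pair count as lost. Densities and the potential-edge count of
#' the descendant frame are recorded, and per-potential-edge per-mya gain and
#' loss rates are attached via [gain_loss_rates()].
#'
#' @param a Ancestral [pin()] (`a$time_mya > b$time_mya`).
#' @param b Descendant [pin()].
#' @param map [ortholog_map()] from `a`'s nodes to `b`'s nodes.
#' @param count_loops Include self-pairs in the potential-edge denominator
#'   (`n(n+1)/2`, the default) or not (`n(n-1)/2`).
#' @return An object of class `pin_comparison`.
#' @export
compare_networks <- function(a, b, map, count_loops = TRUE) {
  divergence <- a$time_mya - b$time_mya
  stop_if_not(divergence > 0,
              "divergence time must be positive (a older than b); got %g",
              divergence)
  anc_of <- setNames(map$ancestor, map$descendant)
  anc_edges <- edge_key(a$edges)

  b_edges <- b$edges
  conserved_flag <- logical(nrow(b_edges))
  if (nrow(b_edges) > 0) {
    pa <- unname(anc_of[b_edges$node_a])
    pb <- unname(anc_of[b_edges$node_b])
    mapped <- !is.na(pa) & !is.na(pb)
    key <- edge_key(canonical_pairs(pa, pb))
    conserved_flag <- mapped & key %in% anc_edges
  }
  conserved <- b_edges[conserved_flag, c("node_a", "node_b")]
  gained <- b_edges[!conserved_flag, c("node_a", "node_b")]

  desc_of <- split(map$descendant, map$ancestor)
  b_keys <- edge_key(b$edges)
  lost_flag <- purrr::map_lgl(seq_len(nrow(a$edges)), function(i) {
    da <- desc_of[[a$edges$node_a[i]]]
    db <- desc_of[[a$edges$node_b[i]]]
    if (is.null(da) || is.null(db)) return(TRUE)
    g <- expand.grid(x = da, y = db, stringsAsFactors = FALSE)
    imgs <- edge_key(canonical_pairs(g$x, g$y))
    !any(imgs %in% b_keys)
  })
  lost <- a$edges[lost_flag, c("node_a", "node_b")]

  n_b <- length(b$nodes)
  potential <- if (count_loops) n_b * (n_b + 1) / 2 else n_b * (n_b - 1) / 2
  cmp <- structure(
    list(
      conserved = as_tibble(conserved), gained = as_tibble(gained),
      lost = as_tibble(lost),
      potential_edges = potential, divergence_mya = divergence,
      density_a = network_density(a, loops = count_loops),
      density_b = network_density(b, loops = count_loops),
      epoch_a = a$epoch_label, epoch_b = b$epoch_label,
      count_loops = count_loops
    ),
    class = "pin_comparison"
  )
  rates <- gain_loss_rates(cmp)
  cmp$gain_rate <- rates$gain_rate
  cmp$loss_rate <- rates$loss_rate
  cmp
}

canonical_pairs <- function(a, b) {
  swap <- a > b
  tibble(node_a = ifelse(swap, b, a), node_b = ifelse(swap, a, b))
}

#' Gain and loss rates between two network epochs
#'
#' The gain (loss) rate is the number of gained (lost) interactions divided by
#' the number of potential interactions in the comparison frame times the
#' divergence time, i.e. per potential edge per million years.
#'
#' @param cmp A `pin_comparison` from [compare_networks()].
#' @return A one-row tibble with `gain_rate` and `loss_rate`.
#' @export
gain_loss_rates <- function(cmp) {
  stop_if_not(cmp$potential_edges > 0, "potential_edges must be positive")
  stop_if_not(cmp$divergence_mya > 0, "divergence_mya must be positive")
  denom <- cmp$potential_edges * cmp$divergence_mya
  tibble(gain_rate = nrow(cmp$gained) / denom,
         loss_rate = nrow(cmp$lost) / denom)
}

#' @export
print.pin_comparison <- function(x, ...) {
  cat(sprintf(
    "<pin_comparison> %s -> %s over %g mya\n  conserved %d, gained %d, lost %d (potential %d)\n  densities %.3f -> %.3f; gain rate %.3g, loss rate %.3g per potential edge per mya\n",
    x$epoch_a, x$epoch_b, x$divergence_mya, nrow(x$conserved),
    nrow(x$gained), nrow(x$lost), x$potential_edges, x$density_a, x$density_b,
    x$gain_rate, x$loss_rate))
  invisible(x)
}

#' @export
tidy.pin_comparison <- function(x, ...) {
  dplyr::bind_rows(
    mutate(x$conserved, category = "conserved"),
    mutate(x$gained, category = "gained"),
    mutate(x$lost, category = "lost")
  )
}

#' @export
glance.pin_comparison <- function(x, ...) {
  tibble(
    epoch_a = x$epoch_a, epoch_b = x$epoch_b,
    n_conserved = nrow(x$conserved), n_gained = nrow(x$gained),
    n_lost = nrow(x$lost), potential_edges = x$potential_edges,
    divergence_mya = x$divergence_mya,
    density_a = x$density_a, density_b = x$density_b,
    gain_rate = x$gain_rate, loss_rate = x$loss_rate
  )
}
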