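#' Construct a protein interaction network (PIN)
#'
#' A PIN is an undirected network of proteins observed at one evolutionary
#' epoch. Homodimers are represented as self-pair loop edges, and edges may
#' carry Miller-unit interaction strengths as weights.
#'
#' @param edges Data frame of edges with columns `node_a`, `node_b` and
#'   optionally `weight`. Orientation does not matter; duplicates collapse.
#' @param nodes Character vector of protein ids. Defaults to the nodes seen in
#'   `edges`; isolated proteins must be listed explicitly.
#' @param epoch_label Label for the epoch, e.g. `"pre-PIN"` or `"Ara-PIN"`.
#' @param time_mya Age of the network snapshot in million years ago (>= 0).
#' @return An object of class `pin`.
#' @examples
#' pin(data.frame(node_a = c("SEP3", "AP1"), node_b = c("AP1", "AP1")),
#'     epoch_label = "Ara-PIN", time_mya = 0)
#' @export
pin <- function(edges = NULL, nodes = NULL, epoch_label = "PIN",
                time_mya = 0) {
  edges <- canonical_edges(edges %||% tibble(node_a = character(),
                                             node_b = character()))
  nodes <- sort(unique(c(as.character(nodes %||% character()),
                         edges$node_a, edges$node_b)))
  stop_if_not(is.numeric(time_mya) && length(time_mya) == 1 && time_mya >= 0,
              "`time_mya` must be a single non-negative number")
  structure(
    list(nodes = nodes, edges = edges, epoch_label = as.character(epoch_label),
         time_mya = as.double(time_mya)),
    class = "pin"
  )
}

#' @export
print.pin <- function(x, ...) {
  cat(sprintf("<pin> %s at %g mya: %d nodes, %d edges (%d loops), density %.3f\n",
              x$epoch_label, x$time_mya, length(x$nodes), nrow(x$edges),
              sum(x$edges$node_a == x$edges$node_b),
              if (length(x$nodes)) network_density(x) else NA_real_))
  invisible(x)
}

#' @export
tidy.pin <- function(x, ...) {
  dplyr::mutate(x$edges, epoch = x$epoch_label, time_mya = x$time_mya)
}

#' @export
glance.pin <- function(x, ...) {
  n <- length(x$nodes)
  tibble(
    epoch = x$epoch_label, time_mya = x$time_mya, n_nodes = n,
    n_edges = nrow(x$edges),
    n_loops = sum(x$edges$node_a == x$edges$node_b),
    potential_edges = n * (n + 1) / 2,
    density = if (n > 0) network_density(x) else NA_real_
  )
}

#' Network density with homodimer loops
#'
#' The ratio of observed to potential interactions. Because homodimers are
#' bona-fide network edges here, the default potential-edge count is
#' `n(n+1)/2` (all unordered pairs including self-pairs). Set
#' `loops = FALSE` for the loop-free convention `n(n-1)/2`, in which case loop
#' edges are also dropped from the numerator.
#'
#' Under `convention = "pairs"` the count is over unordered pairs; note that
#' all-versus-all polyploid edge inheritance then changes density slightly
#' (loops expand by `m(m+1)/2`, non-loops by `m^2`, the denominator by
#' neither factor). The `"matrix"` convention — occupied adjacency-matrix
#' entries (diagonal included) over `n^2` — is preserved exactly by such
#' expansions and is used where exact invariance matters.
#'
#' @param pin A [pin()] object.
#' @param loops Count self-pairs in numerator and denominator? Default
#'   `TRUE` (ignored for `"matrix"`, which always counts the diagonal).
#' @param convention `"pairs"` (unordered pairs, the default) or `"matrix"`
#'   (symmetric adjacency-matrix occupancy).
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(pin, loops = TRUE,
                            convention = c("pairs", "matrix")) {
  convention <- match.arg(convention)
  n <- length(pin$nodes)
  stop_if_not(n >= 1, "density needs at least one node")
  n_loop <- sum(pin$edges$node_a == pin$edges$node_b)
  n_pair <- nrow(pin$edges) - n_loop
  if (convention == "matrix") {
    return((2 * n_pair + n_loop) / n^2)
  }
  if (loops) {
    nrow(pin$edges) / (n * (n + 1) / 2)
  } else {
    if (n < 2) return(0)
    n_pair / (n * (n - 1) / 2)
  }
}

#' @rdname network_density
#' @param x A [pin()] object.
#' @param ... Passed on.
#' @export
density.pin <- function(x, ...) network_density(x, ...)

#' Build a network from interaction calls
#'
#' Nodes are all proteins appearing in the calls (so a fully negative assay
#' still defines the tested node set); edges are the positive calls passing
#' the mode filter. Pairs excluded for bait auto-activation are omitted from
#' the network and returned in the `"excluded"` attribute.
#'
#' @param calls Interaction-call tibble from [call_dimeric_interactions()] or
#'   [call_mediated_interactions()].
#' @param epoch_label,time_mya Epoch metadata for the resulting network.
#' @param mode_filter One of `"dimeric"`, `"mediated"`, `"both"`.
#' @return A [pin()]; `attr(, "excluded")` lists auto-active-excluded pairs.
#' @export
build_network <- function(calls, epoch_label = "PIN", time_mya = 0,
                          mode_filter = c("both", "dimeric", "mediated")) {
  mode_filter <- match.arg(mode_filter)
  stop_if_not(nrow(calls) > 0, "`calls` must be non-empty")
  keep_mode <- if (mode_filter == "both") unique(calls$mode) else mode_filter
  nodes <- unique(c(calls$protein_a, calls$protein_b))
  pos <- calls %>%
    filter(.data$status == "positive", .data$mode %in% keep_mode)
  excluded <- calls %>%
    filter(.data$status == "autoactive_excluded", .data$mode %in% keep_mode) %>%
    distinct(.data$protein_a, .data$protein_b)
  out <- pin(
    edges = tibble(node_a = pos$protein_a, node_b = pos$protein_b,
                   weight = pos$delta),
    nodes = nodes, epoch_label = epoch_label, time_mya = time_mya
  )
  attr(out, "excluded") <- excluded
  out
}

#' Per-node degree, hub class and promiscuity index
#'
#' Degree counts each distinct partner once, with a self-loop contributing a
#' single unit (the protein is its own partner). The promiscuity index is the
#' fraction of possible partners (including itself) the protein binds:
#' `degree / n`. Nodes are classed `hub` (degree >= `hub_min`), `island`
#' (degree <= `island_max`) or `intermediate`.
#'
#' @param pin A [pin()].
#' @param hub_min Minimum degree for a hub. Must exceed `island_max`.
#' @param island_max Maximum degree for an island.
#' @return A tibble with `node`, `degree`, `class`, `promiscuity`.
#' @export
degree_and_hub_profile <- function(pin, hub_min = 5, island_max = 2) {
  stop_if_not(hub_min > island_max && island_max >= 0,
              "need hub_min > island_max >= 0")
  n <- length(pin$nodes)
  deg <- setNames(integer(n), pin$nodes)
  for (i in seq_len(nrow(pin$edges))) {
    a <- pin$edges$node_a[i]; b <- pin$edges$node_b[i]
    deg[a] <- deg[a] + 1L
    if (b != a) deg[b] <- deg[b] + 1L
  }
  tibble(node = pin$nodes, degree = as.integer(deg)) %>%
    mutate(
      class = case_when(
        .data$degree >= hub_min ~ "hub",
        .data$degree <= island_max ~ "island",
        TRUE ~ "intermediate"
      ),
      promiscuity = .data$degree / n
    )
}

#' Evaluate a swapped-in foreign protein against a host network
#'
#' Mirrors the reciprocal swapping experiments in which an ancestral or extant
#' protein is tested against the proteins of a network of a different age: the
#' foreign protein's degree and promiscuity in the host network are reported,
#' optionally against its host-native counterpart.
#'
#' @param host The host [pin()].
#' @param foreign_id Id of the swapped-in protein; must not collide with a
#'   host node id.
#' @param foreign_calls Interaction calls of the foreign protein against host
#'   nodes (tibble with `protein_a`, `protein_b`, `status`); every tested
#'   partner must be a host node.
#' @param counterpart Optional host node id the foreign protein is orthologous
#'   to; its native degree is included for comparison.
#' @return A one-row tibble: `foreign_id`, `host_epoch`, `degree`,
#'   `promiscuity`, and counterpart degree when supplied.
#' @export
swap_protein <- function(host, foreign_id, foreign_calls, counterpart = NULL) {
  stop_if_not(!(foreign_id %in% host$nodes),
              "foreign id '%s' collides with a host node id", foreign_id)
  partners <- unique(c(foreign_calls$protein_a, foreign_calls$protein_b))
  partners <- setdiff(partners, foreign_id)
  bad <- setdiff(partners, host$nodes)
  stop_if_not(length(bad) == 0,
              "foreign calls reference non-host proteins: %s",
              paste(bad, collapse = ", "))
  pos <- foreign_calls %>% filter(.data$status == "positive")
  pos_partners <- unique(ifelse(pos$protein_a == foreign_id,
                                pos$protein_b, pos$protein_a))
  degree <- length(pos_partners)
  n_host <- length(host$nodes)
  out <- tibble(
    foreign_id = foreign_id,
    host_epoch = host$epoch_label,
    n_host = n_host,
    degree = degree,
    promiscuity = degree / n_host
  )
  if (!is.null(counterpart)) {
    prof <- degree_and_hub_profile(host, hub_min = 2, island_max = 0)
    out$counterpart <- counterpart
    out$counterpart_degree <-
      prof$degree[match(counterpart, prof$node)]
  }
  out
}

#' Additivity check for subfunctionalized duplicates
#'
#' After duplication, an ancestral hub's interaction partners may be
#' partitioned among its descendant copies. If partitioning is perfectly
#' additive, the descendants' degrees sum to the ancestor's degree; a positive
#' deficit means interactions were lost relative to additive partitioning,
#' a negative one that interactions were gained.
#'
#' @param ancestor_degree Degree of the ancestral protein in its network.
#' @param descendant_degrees Integer degrees of the descendant copies.
#' @return A one-row tibble with `combined` (sum of descendant degrees) and
#'   `deficit` (`ancestor_degree - combined`).
#' @examples
#' subfunctionalization_check(9, c(6, 3))   # perfectly additive
#' subfunctionalization_check(17, c(8, 4, 2, 0))
#' @export
subfunctionalization_check <- function(ancestor_degree, descendant_degrees) {
  stop_if_not(ancestor_degree >= 0 && all(descendant_degrees >= 0),
              "degrees must be non-negative")
  combined <- as.integer(sum(descendant_degrees))
  tibble(ancestor_degree = as.integer(ancestor_degree),
         combined = combined,
         deficit = as.integer(ancestor_degree) - combined)
}

# igraph view of a pin; loops kept.
pin_igraph <- function(pin) {
  igraph::graph_from_data_frame(
    d = pin$edges[, c("node_a", "node_b")],
    directed = FALSE,
    vertices = data.frame(name = pin$nodes)
  )
}
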