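test_that("density counts self-pairs in numerator and denominator", {
  # complete network on 3 nodes including all loops
  nodes <- c("a", "b", "c")
  full <- pin(pinflex:::all_pairs(nodes))
  expect_equal(network_density(full), 1)
  expect_equal(network_density(full, convention = "matrix"), 1)
  expect_equal(network_density(pin(nodes = nodes)), 0)
  # 4 nodes, 5 edges -> 5 / (4*5/2)
  p4 <- pin(data.frame(node_a = c("a", "a", "a", "b", "c"),
                       node_b = c("a", "b", "c", "c", "d")))
  expect_equal(network_density(p4), 0.5)
  expect_error(network_density(pin()), "node")
})

test_that("build_network filters by mode and drops excluded pairs", {
  calls <- tibble::tibble(
    protein_a = c("A", "A", "B", "C"),
    protein_b = c("B", "C", "B", "D"),
    mode = c("dimeric", "mediated", "dimeric", "mediated"),
    mediator = c(NA, "M", NA, "M"),
    mean_signal = c(40, 35, 38, 6),
    delta = c(35, 30, 33, 1),
    p_value = c(.001, .002, .001, NA),
    status = c("positive", "positive", "positive", "autoactive_excluded")
  )
  net_med <- build_network(calls, mode_filter = "mediated")
  expect_equal(nrow(net_med$edges), 1)
  expect_setequal(net_med$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(attr(net_med, "excluded")), 1)
  net_dim <- build_network(calls, mode_filter = "dimeric")
  expect_equal(nrow(net_dim$edges), 2)
  # loop edge from a positive self-pair
  loopy <- build_network(tibble::tibble(
    protein_a = "A", protein_b = "A", mode = "dimeric",
    mediator = NA_character_, mean_signal = 50, delta = 45,
    p_value = .001, status = "positive"))
  expect_equal(nrow(loopy$edges), 1)
  expect_true(all(loopy$edges$node_a == loopy$edges$node_b))
  # all-negative calls give an edgeless network over the tested nodes
  negs <- dplyr::mutate(calls, status = "negative")
  empty <- build_network(negs)
  expect_equal(nrow(empty$edges), 0)
  expect_setequal(empty$nodes, c("A", "B", "C", "D"))
})

test_that("polyploid rescaling copies nodes and inherits edges all-vs-all", {
  p <- pin(data.frame(node_a = c("a", "b"), node_b = c("b", "b")),
           nodes = c("a", "b", "c", "d", "e"))
  r <- rescale_by_polyploidy(p, 3)
  expect_equal(length(r$nodes), 15)
  # keep one copy of each endpoint: exactly one descendant edge
  r1 <- rescale_by_polyploidy(pin(data.frame(node_a = "a", node_b = "b")),
                              3, keep = c("a.1", "b.2"))
  expect_equal(nrow(r1$edges), 1)
  expect_setequal(r1$nodes, c("a.1", "b.2"))
  # ancestral loop triplicated, keep 2 copies: 2 loops + 1 pair
  r2 <- rescale_by_polyploidy(pin(data.frame(node_a = "a", node_b = "a")),
                              3, keep = c("a.1", "a.2"))
  expect_equal(nrow(r2$edges), 3)
  expect_equal(sum(r2$edges$node_a == r2$edges$node_b), 2)
  expect_error(rescale_by_polyploidy(p, 3, keep = "zz.9"), "non-copy")
  expect_error(rescale_by_polyploidy(p, 3, target_size = 99), "target_size")
  # deterministic redundant-node removal by target size
  r3 <- rescale_by_polyploidy(p, 3, target_size = 5)
  expect_setequal(r3$nodes, paste0(c("a", "b", "c", "d", "e"), ".1"))
})

test_that("matrix-convention density is exactly preserved by all-copy rescaling", {
  set.seed(5)
  for (i in 1:5) {
    nodes <- letters[1:6]
    ap <- pinflex:::all_pairs(nodes)
    p <- pin(ap[runif(nrow(ap)) < 0.4, ], nodes = nodes)
    r <- rescale_by_polyploidy(p, 3)
    expect_identical(network_density(p, convention = "matrix"),
                     network_density(r, convention = "matrix"))
    # pairs convention agrees to O(1/n)
    expect_lt(abs(network_density(p) - network_density(r)),
              1 / length(p$nodes))
  }
})

test_that("network comparison classifies conserved/gained/lost edges", {
  a <- pin(data.frame(node_a = c("x", "y"), node_b = c("y", "z")),
           nodes = c("x", "y", "z"), time_mya = 120)
  b_same <- pin(a$edges, nodes = a$nodes, time_mya = 109)
  idm <- identity_map(a$nodes)
  cmp <- compare_networks(a, b_same, idm)
  expect_equal(nrow(cmp$conserved), 2)
  expect_equal(nrow(cmp$gained), 0)
  expect_equal(nrow(cmp$lost), 0)

  b_plus <- pin(rbind(a$edges[, 1:2],
                      data.frame(node_a = "x", node_b = "z")),
                nodes = a$nodes, time_mya = 109)
  cmp2 <- compare_networks(a, b_plus, idm)
  expect_equal(nrow(cmp2$gained), 1)
  expect_equal(cmp2$gain_rate, 1 / (6 * 11))

  expect_error(compare_networks(b_same, b_same, idm), "divergence")
})

test_that("comparison against a triplication map matches planted rewiring", {
  set.seed(31)
  nodes <- letters[1:8]
  ap <- pinflex:::all_pairs(nodes)
  a <- pin(ap[runif(nrow(ap)) < 0.3, ], nodes = nodes, time_mya = 120)
  r <- rescale_by_polyploidy(a, 3)
  map <- attr(r, "map")
  # plant known rewiring in descendant coordinates
  all_desc <- pinflex:::all_pairs(r$nodes)
  have <- pinflex:::edge_key(all_desc) %in% pinflex:::edge_key(r$edges)
  add <- all_desc[!have, ][sample(sum(!have), 7), ]
  drop_idx <- sample(nrow(r$edges), 5)
  dropped <- r$edges[drop_idx, ]
  b_edges <- rbind(r$edges[-drop_idx, c("node_a", "node_b")],
                   add[, c("node_a", "node_b")])
  b <- pin(b_edges, nodes = r$nodes, time_mya = 109)
  cmp <- compare_networks(a, b, map)
  expect_equal(nrow(cmp$gained), 7)
  # a dropped copy-pair edge is only lost if no other image survives
  lost_expected <- sum(vapply(seq_len(nrow(a$edges)), function(i) {
    ca <- map$descendant[map$ancestor == a$edges$node_a[i]]
    cb <- map$descendant[map$ancestor == a$edges$node_b[i]]
    imgs <- pinflex:::edge_key(pinflex:::canonical_edges(
      expand.grid(node_a = ca, node_b = cb, stringsAsFactors = FALSE)))
    !any(imgs %in% pinflex:::edge_key(b$edges))
  }, TRUE))
  expect_equal(nrow(cmp$lost), lost_expected)
  # conserved + gained partitions the descendant edge set
  expect_equal(nrow(cmp$conserved) + nrow(cmp$gained), nrow(b$edges))
  both <- intersect(pinflex:::edge_key(cmp$conserved),
                    pinflex:::edge_key(cmp$gained))
  expect_length(both, 0)
})

test_that("reconstructing the descendant from conserved+gained is exact", {
  set.seed(77)
  for (i in 1:20) {
    nodes <- letters[1:7]
    ap <- pinflex:::all_pairs(nodes)
    a <- pin(ap[runif(nrow(ap)) < 0.35, ], nodes = nodes, time_mya = 50)
    b <- pin(ap[runif(nrow(ap)) < 0.35, ], nodes = nodes, time_mya = 40)
    cmp <- compare_networks(a, b, identity_map(nodes))
    rebuilt <- dplyr::bind_rows(cmp$conserved, cmp$gained)
    expect_setequal(pinflex:::edge_key(pinflex:::canonical_edges(rebuilt)),
                    pinflex:::edge_key(b$edges))
    # under the identity map, lost = a-edges absent from b
    expect_setequal(
      pinflex:::edge_key(cmp$lost),
      setdiff(pinflex:::edge_key(a$edges), pinflex:::edge_key(b$edges)))
  }
})

test_that("gain_loss_rates divides by potential edges times divergence", {
  a <- pin(nodes = letters[1:4], time_mya = 21)
  b <- pin(data.frame(node_a = c("a", "b"), node_b = c("b", "c")),
           nodes = letters[1:4], time_mya = 10)
  cmp <- compare_networks(a, b, identity_map(letters[1:4]))
  r <- gain_loss_rates(cmp)
  expect_equal(r$gain_rate, 2 / (10 * 11))
  expect_equal(r$loss_rate, 0)
})

test_that("degree, hub class and promiscuity follow the definitions", {
  # star: center connected to k leaves
  k <- 6
  star <- pin(data.frame(node_a = "hub", node_b = paste0("l", 1:k)))
  prof <- degree_and_hub_profile(star, hub_min = 5, island_max = 2)
  expect_equal(prof$degree[prof$node == "hub"], k)
  expect_equal(prof$class[prof$node == "hub"], "hub")
  expect_true(all(prof$class[prof$node != "hub"] == "island"))
  # promiscuity 1.0 for a node bound to everything including itself
  nodes <- c("e", "f", "g")
  anc <- pin(data.frame(node_a = "e", node_b = nodes), nodes = nodes)
  p2 <- degree_and_hub_profile(anc, hub_min = 3, island_max = 0)
  expect_equal(p2$promiscuity[p2$node == "e"], 1)
  # isolated node: degree 0, island
  iso <- degree_and_hub_profile(pin(nodes = "solo"), hub_min = 1,
                                island_max = 0)
  expect_equal(iso$degree, 0L)
  expect_equal(iso$class, "island")
  expect_error(degree_and_hub_profile(star, hub_min = 1, island_max = 2),
               "hub_min")
  # degrees agree with igraph (which counts loops twice)
  g <- igraph::graph_from_data_frame(toy_pin()$edges[, 1:2],
                                     directed = FALSE,
                                     vertices = toy_pin()$nodes)
  ig_deg <- igraph::degree(g, loops = TRUE)
  loops <- toy_pin()$edges$node_a[toy_pin()$edges$node_a ==
                                    toy_pin()$edges$node_b]
  ig_deg[loops] <- ig_deg[loops] - 1
  ours <- degree_and_hub_profile(toy_pin(), hub_min = 3, island_max = 0)
  expect_equal(ours$degree, unname(ig_deg[ours$node]))
})

test_that("swap reports foreign degree and promiscuity in the host frame", {
  host <- toy_pin()
  foreign_calls <- tibble::tibble(
    protein_a = "ancE", protein_b = host$nodes,
    status = "positive")
  rep <- swap_protein(host, "ancE", foreign_calls, counterpart = "SEP3")
  expect_equal(rep$degree, length(host$nodes))
  expect_equal(rep$promiscuity, 1)
  expect_equal(rep$counterpart_degree,
               degree_and_hub_profile(host, 2, 0)$degree[
                 match("SEP3", sort(host$nodes))])
  none <- swap_protein(host, "pAP3",
                       dplyr::mutate(foreign_calls, protein_a = "pAP3",
                                     status = "negative"))
  expect_equal(none$degree, 0)
  expect_error(swap_protein(host, "SEP3", foreign_calls), "collides")
  expect_error(swap_protein(host, "zz",
                            tibble::tibble(protein_a = "zz",
                                           protein_b = "nothost",
                                           status = "positive")),
               "non-host")
})

test_that("subfunctionalization additivity reproduces the worked examples", {
  pre <- subfunctionalization_check(9, c(6, 3))
  expect_equal(pre$combined, 9L)
  expect_equal(pre$deficit, 0L)
  ara <- subfunctionalization_check(17, c(8, 4, 2, 0))
  expect_equal(ara$combined, 14L)
  expect_equal(ara$deficit, 3L)
  none <- subfunctionalization_check(5, integer())
  expect_equal(none$combined, 0L)
  expect_equal(none$deficit, 5L)
})
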