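test_that("zero-noise assay tables reproduce configured means exactly", {
  net <- toy_pin()
  tab <- simulate_assay_table(net, signal_mu = 40, background_mu = 5,
                              noise_cv = 0, n_reps = 3, seed = 1)
  expect_true(all(tab$miller %in% c(40, 5)))
  # edges at signal level, non-edges at background
  planted <- pinflex:::edge_key(net$edges)
  tested <- tab %>% dplyr::filter(!is_control)
  key <- pinflex:::edge_key(pinflex:::canonical_pairs(tested$bait,
                                                      tested$prey))
  expect_true(all(tested$miller[key %in% planted] == 40))
  expect_true(all(tested$miller[!key %in% planted] == 5))
  # reproducible given seed and parameters
  tab2 <- simulate_assay_table(net, signal_mu = 40, background_mu = 5,
                               noise_cv = 0, n_reps = 3, seed = 1)
  expect_identical(tab, tab2)
})

test_that("edgeless networks without autoactivators stay at background", {
  net <- pin(nodes = LETTERS[1:4])
  tab <- simulate_assay_table(net, noise_cv = 0, seed = 1)
  expect_true(all(tab$miller[!tab$is_control] == 5))
})

test_that("simulator rejects too few replicates", {
  expect_error(simulate_assay_table(toy_pin(), n_reps = 1), "n_reps")
  expect_error(simulate_assay_table(toy_pin(), signal_mu = 3,
                                    background_mu = 5), "signal_mu")
})

test_that("wide and long assay formats read identically", {
  wide <- data.frame(bait = c("A", "B"), prey = c("B", "C"),
                     rep1 = c(10, 20), rep2 = c(11, 21), rep3 = c(9, 19))
  fw <- tempfile(fileext = ".csv")
  write.csv(wide, fw, row.names = FALSE)
  long <- data.frame(bait = rep(c("A", "B"), each = 3),
                     prey = rep(c("B", "C"), each = 3),
                     replicate = rep(1:3, 2),
                     miller = c(10, 11, 9, 20, 21, 19))
  fl <- tempfile(fileext = ".tsv")
  write.table(long, fl, row.names = FALSE, sep = "\t", quote = FALSE)
  a <- read_assay_table(fw)
  b <- read_assay_table(fl)
  key <- function(x) dplyr::arrange(x, bait, prey, replicate)
  expect_equal(key(a)$miller, key(b)$miller)
  expect_equal(key(a)$bait, key(b)$bait)
})

test_that("non-positive Miller values are rejected naming the row", {
  bad <- data.frame(bait = c("A", "B"), prey = c("B", "C"),
                    miller = c(10, 0))
  f <- tempfile(fileext = ".csv")
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_assay_table(f), "row")
  nob <- data.frame(prey = "B", miller = 3)
  f2 <- tempfile(fileext = ".csv")
  write.csv(nob, f2, row.names = FALSE)
  expect_error(read_assay_table(f2), "bait")
})

test_that("dimeric caller needs background and respects control logic", {
  net <- toy_pin()
  tab <- simulate_assay_table(net, noise_cv = 0.15, seed = 5)
  no_bg <- tab %>% dplyr::filter(control_kind != "empty_vector")
  expect_error(call_dimeric_interactions(no_bg), "background")

  # replicates identical to background level -> negative
  tab0 <- simulate_assay_table(pin(nodes = c("A", "B")), noise_cv = 0,
                               seed = 1)
  calls0 <- call_dimeric_interactions(tab0)
  expect_true(all(calls0$status == "negative"))
})

test_that("auto-active baits are excluded from calling", {
  net <- toy_pin()
  tab <- simulate_assay_table(net, noise_cv = 0.15, n_reps = 3,
                              autoactive_baits = "SVP", seed = 9)
  calls <- call_dimeric_interactions(tab)
  sv <- calls %>%
    dplyr::filter(protein_a == "SVP" | protein_b == "SVP")
  expect_true(all(sv$status == "autoactive_excluded"))
  expect_true(all(is.na(sv$p_value)))
  expect_identical(attr(calls, "autoactive_baits"), "SVP")
})

test_that("planted edges are recovered against an independent caller", {
  # 200-edge network, signal 8x background, CV 0.15, 3 reps
  set.seed(42)
  nodes <- sprintf("n%02d", 1:25)
  ap <- pinflex:::all_pairs(nodes)
  planted <- ap[sample(nrow(ap), 200), ]
  net <- pin(planted, nodes = nodes)
  tab <- simulate_assay_table(net, signal_mu = 40, background_mu = 5,
                              noise_cv = 0.15, n_reps = 3, seed = 13)
  calls <- call_dimeric_interactions(tab, alpha = 0.05, min_fold = 2)
  pos <- calls %>% dplyr::filter(status == "positive")
  truth <- pinflex:::edge_key(net$edges)
  called <- pinflex:::edge_key(
    pinflex:::canonical_pairs(pos$protein_a, pos$protein_b))
  recall <- mean(truth %in% called)
  expect_gte(recall, 0.95)

  # independent re-implementation of the per-orientation test: plain
  # t.test + fold filter over the raw table
  bg <- tab$miller[tab$control_kind == "empty_vector"]
  ref_pos <- tab %>%
    dplyr::filter(!is_control) %>%
    dplyr::group_by(bait, prey) %>%
    dplyr::summarise(p = stats::t.test(miller, bg,
                                       alternative = "greater")$p.value,
                     m = mean(miller), .groups = "drop") %>%
    dplyr::filter(p < 0.05, m > 2 * mean(bg))
  ref_keys <- unique(pinflex:::edge_key(
    pinflex:::canonical_pairs(ref_pos$bait, ref_pos$prey)))
  expect_setequal(called, ref_keys)
})

test_that("calling is invariant to orientation swap and replicate order", {
  net <- toy_pin()
  tab <- simulate_assay_table(net, noise_cv = 0.2, seed = 3)
  base <- call_dimeric_interactions(tab)
  # swap orientations and shuffle replicate order
  swapped <- tab
  nc <- !swapped$is_control
  tmp <- swapped$bait[nc]
  swapped$bait[nc] <- swapped$prey[nc]
  swapped$prey[nc] <- tmp
  swapped <- swapped[sample(nrow(swapped)), ]
  again <- call_dimeric_interactions(swapped)
  key <- function(x) dplyr::arrange(as_tibble(x), protein_a, protein_b)
  expect_equal(key(base)$status, key(again)$status)
  expect_equal(key(base)$p_value, key(again)$p_value, tolerance = 1e-12)
})

test_that("calls are invariant under common scaling of all Miller values", {
  net <- toy_pin()
  tab <- simulate_assay_table(net, noise_cv = 0.2, seed = 8)
  c1 <- call_dimeric_interactions(tab)
  tab2 <- tab; tab2$miller <- tab2$miller * 37.5
  c2 <- call_dimeric_interactions(tab2)
  expect_equal(c1$status, c2$status)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-9)
})

test_that("mediated calling implements the subtraction definition", {
  nodes <- c("A", "B", "C", "D")
  y2h_net <- pin(data.frame(node_a = "A", node_b = "B"), nodes = nodes)
  mediated <- data.frame(node_a = c("A", "C"), node_b = c("B", "D"))
  tab <- simulate_assay_table(
    y2h_net, signal_mu = 40, background_mu = 5, noise_cv = 0.1, n_reps = 3,
    mediator = list(id = "SEP3", enhancement = 4, mediated_pairs = mediated),
    seed = 21)
  y2h <- call_dimeric_interactions(tab)
  med <- call_mediated_interactions(tab, y2h)
  pos <- med %>% dplyr::filter(status == "positive")
  expect_setequal(
    pinflex:::edge_key(pinflex:::canonical_pairs(pos$protein_a,
                                                 pos$protein_b)),
    pinflex:::edge_key(pinflex:::canonical_edges(mediated)))
  # enhanced dimeric pair has positive delta against its dimeric baseline
  ab <- med %>% dplyr::filter(protein_a == "A", protein_b == "B")
  expect_gt(ab$delta, 0)
  # positives always have positive delta
  expect_true(all(pos$delta > 0))

  # Y3H replicates equal to Y2H level -> delta ~ 0, negative
  tab_flat <- simulate_assay_table(
    y2h_net, signal_mu = 40, background_mu = 5, noise_cv = 0, n_reps = 3,
    mediator = list(id = "SEP3", enhancement = 1,
                    mediated_pairs = mediated[0, ]),
    seed = 4)
  med_flat <- call_mediated_interactions(tab_flat,
                                         call_dimeric_interactions(tab_flat))
  expect_true(all(med_flat$status == "negative"))
  expect_equal(max(abs(med_flat$delta)), 0)
})

test_that("mediated calling requires mediator controls", {
  nodes <- c("A", "B")
  tab <- simulate_assay_table(
    pin(nodes = nodes), mediator = list(id = "M", mediated_pairs =
                                          data.frame(node_a = "A",
                                                     node_b = "B")),
    seed = 2)
  y2h <- call_dimeric_interactions(tab)
  no_ctrl <- tab %>%
    dplyr::filter(!(assay_mode == "Y3H" & control_kind == "autoactivation"))
  expect_error(call_mediated_interactions(no_ctrl, y2h), "auto-activation")
})

test_that("three-hybrid monotonicity: boosting a pair never flips it negative", {
  nodes <- c("A", "B", "C")
  tab <- simulate_assay_table(
    pin(data.frame(node_a = "A", node_b = "B"), nodes = nodes),
    noise_cv = 0.15,
    mediator = list(id = "M", enhancement = 3,
                    mediated_pairs = data.frame(node_a = "A", node_b = "B")),
    seed = 6)
  y2h <- call_dimeric_interactions(tab)
  base <- call_mediated_interactions(tab, y2h)
  ab0 <- base %>% dplyr::filter(protein_a == "A", protein_b == "B")
  boost <- tab
  sel <- boost$assay_mode == "Y3H" & !boost$is_control &
    pinflex:::edge_key(pinflex:::canonical_pairs(boost$bait, boost$prey)) ==
    "A\rB"
  boost$miller[sel] <- boost$miller[sel] * 5
  ab1 <- call_mediated_interactions(boost, y2h) %>%
    dplyr::filter(protein_a == "A", protein_b == "B")
  expect_false(ab0$status == "positive" && ab1$status != "positive")
  expect_gt(ab1$delta, ab0$delta)
})

test_that("caller type-I error on pure background stays at or below alpha", {
  # >= 1000 background-only pairs, 3 replicates
  nodes <- sprintf("x%02d", 1:46)   # 46*47/2 = 1081 pairs
  tab <- simulate_assay_table(pin(nodes = nodes), signal_mu = 40,
                              background_mu = 5, noise_cv = 0.15,
                              n_reps = 3, seed = 17)
  calls <- call_dimeric_interactions(tab, alpha = 0.05)
  n_pairs <- nrow(calls)
  expect_gte(n_pairs, 1000)
  fpr <- mean(calls$status == "positive")
  # binomial error bound on the empirical rate
  expect_lte(fpr, 0.05 + 2 * sqrt(0.05 * 0.95 / n_pairs))
})
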