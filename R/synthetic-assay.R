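#' Simulate a quantitative yeast-hybrid assay table
#'
#' Emulates a beta-galactosidase (Miller unit) interaction screen over the
#' node set of a network: interacting pairs report at signal level,
#' non-interacting pairs at reporter-leakiness background, auto-active baits
#' at signal level regardless of prey, and every value carries multiplicative
#' log-normal replicate noise. Empty-vector background controls and per-bait
#' auto-activation controls are included. When a mediator is supplied, a
#' matching set of three-hybrid rows is added in which the mediator enhances
#' its planted pairs.
#'
#' @param pin A [pin()]; its edges are the true dimeric interactions.
#' @param signal_mu Mean Miller units of a true interaction (> background).
#' @param background_mu Mean Miller units of reporter background (> 0).
#' @param noise_cv Coefficient of variation of replicate noise (log-normal);
#'   0 gives exact means.
#' @param n_reps Replicates per combination (>= 2).
#' @param autoactive_baits Node ids whose bait constructs auto-activate.
#' @param mediator Optional list describing the three-hybrid mediator:
#'   `list(id =, enhancement =, mediated_pairs =)` where `mediated_pairs` is a
#'   data frame of pairs the mediator enables or enhances. Enhanced pairs that
#'   are already dimeric interactions report `enhancement` times the dimeric
#'   level; mediator-enabled non-dimeric pairs report at signal level.
#' @param seed Integer seed.
#' @return A long-format tibble (one row per replicate) with columns `bait`,
#'   `prey`, `mediator`, `assay_mode`, `replicate`, `miller`, `is_control`,
#'   `control_kind`. `attr(, "truth")` records the planted dimeric edges and
#'   mediated pairs.
#' @export
simulate_assay_table <- function(pin, signal_mu = 40, background_mu = 5,
                                 noise_cv = 0.15, n_reps = 3,
                                 autoactive_baits = character(),
                                 mediator = NULL, seed = 1L) {
  stop_if_not(signal_mu > background_mu && background_mu > 0,
              "need signal_mu > background_mu > 0")
  stop_if_not(n_reps >= 2, "interaction calling needs n_reps >= 2 replicates")
  seed_rng(seed)

  nodes <- pin$nodes
  edges <- edge_key(pin$edges)
  is_edge <- function(a, b) edge_key(canonical_pairs(a, b)) %in% edges

  # ordered bait-prey combinations: both orientations for non-self pairs
  combos <- expand.grid(bait = nodes, prey = nodes,
                        stringsAsFactors = FALSE) %>%
    as_tibble()
  y2h_mean <- function(bait, prey) {
    ifelse(bait %in% autoactive_baits, signal_mu,
           ifelse(is_edge(bait, prey), signal_mu, background_mu))
  }
  combos$mu <- y2h_mean(combos$bait, combos$prey)

  n_bg <- max(6L, 2L * n_reps)
  rows <- list(
    mutate(combos, mediator = NA_character_, assay_mode = "Y2H",
           is_control = FALSE, control_kind = "none"),
    # per-bait auto-activation controls (bait + empty AD vector)
    tibble(bait = nodes, prey = "EMPTY_AD",
           mu = ifelse(nodes %in% autoactive_baits, signal_mu, background_mu),
           mediator = NA_character_, assay_mode = "Y2H",
           is_control = TRUE, control_kind = "autoactivation"),
    # empty-vector reporter-leakiness background
    tibble(bait = "EMPTY_BD", prey = "EMPTY_AD", mu = background_mu,
           mediator = NA_character_, assay_mode = "Y2H",
           is_control = TRUE, control_kind = "empty_vector")
  )

  med_pairs_key <- character()
  if (!is.null(mediator)) {
    stop_if_not(all(c("id", "mediated_pairs") %in% names(mediator)),
                "mediator needs fields id and mediated_pairs")
    enh <- mediator$enhancement %||% 4
    med_pairs_key <- edge_key(canonical_edges(mediator$mediated_pairs))
    mediated <- function(a, b) edge_key(canonical_pairs(a, b)) %in%
      med_pairs_key
    y3h <- combos %>%
      mutate(
        mu = ifelse(mediated(.data$bait, .data$prey),
                    ifelse(is_edge(.data$bait, .data$prey) |
                             .data$bait %in% autoactive_baits,
                           .data$mu * enh, signal_mu),
                    .data$mu),
        mediator = mediator$id, assay_mode = "Y3H",
        is_control = FALSE, control_kind = "none"
      )
    rows <- c(rows, list(
      y3h,
      tibble(bait = nodes, prey = "EMPTY_AD",
             mu = ifelse(nodes %in% autoactive_baits, signal_mu,
                         background_mu),
             mediator = mediator$id, assay_mode = "Y3H",
             is_control = TRUE, control_kind = "autoactivation"),
      tibble(bait = "EMPTY_BD", prey = "EMPTY_AD", mu = background_mu,
             mediator = mediator$id, assay_mode = "Y3H",
             is_control = TRUE, control_kind = "empty_vector")
    ))
  }

  tab <- dplyr::bind_rows(rows)
  # background controls get extra replicates so the pooled baseline is stable
  reps_of <- ifelse(tab$control_kind == "empty_vector", n_bg, n_reps)
  long <- tab[rep(seq_len(nrow(tab)), reps_of), ]
  long$replicate <- unlist(lapply(reps_of, seq_len))
  long$miller <- rlnorm_cv(long$mu, noise_cv)
  out <- long %>%
    select("bait", "prey", "mediator", "assay_mode", "replicate",
           "miller", "is_control", "control_kind") %>%
    as_tibble()
  attr(out, "truth") <- list(
    edges = pin$edges[, c("node_a", "node_b")],
    mediated_pairs = if (is.null(mediator)) NULL else
      canonical_edges(mediator$mediated_pairs)[, c("node_a", "node_b")],
    autoactive_baits = autoactive_baits
  )
  out
}

# Log-normal draws with exact mean mu and coefficient of variation cv;
# cv = 0 returns mu itself (zero-noise limit).
rlnorm_cv <- function(mu, cv) {
  if (cv == 0) return(mu)
  s2 <- log(1 + cv^2)
  rlnorm(length(mu), meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
}
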