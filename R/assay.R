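#' Read a quantitative assay table from CSV/TSV
#'
#' Accepts long format (one replicate per row) or wide format (one
#' combination per row with several replicate columns). Column names are
#' mapped through `dialect`, so tables from different plate layouts can be
#' ingested without renaming files.
#'
#' @param source Path to a CSV or TSV file (delimiter inferred from the
#'   extension; override with `delim`).
#' @param dialect Named list mapping canonical fields to file column names.
#'   Recognised fields: `bait`, `prey`, `mediator`, `assay_mode`,
#'   `replicate`, `miller`, `is_control`, `control_kind`, and for wide tables
#'   `replicate_cols` (character vector of Miller-unit columns). Defaults to
#'   identity naming.
#' @param delim Field delimiter; `NULL` to infer.
#' @return A validated long-format tibble as produced by
#'   [simulate_assay_table()]. Non-positive or non-numeric Miller values are
#'   a hard error naming the offending row.
#' @export
read_assay_table <- function(source, dialect = list(), delim = NULL) {
  delim <- delim %||%
    (if (grepl("\\.tsv$|\\.tab$|\\.txt$", source)) "\t" else ",")
  raw <- readr::read_delim(source, delim = delim, show_col_types = FALSE,
                           comment = "#")
  get_col <- function(field, default = field) {
    nm <- dialect[[field]] %||% default
    if (nm %in% names(raw)) raw[[nm]] else NULL
  }
  bait <- get_col("bait")
  prey <- get_col("prey")
  stop_if_not(!is.null(bait) && !is.null(prey),
              "assay table must have bait and prey columns")

  wide_cols <- dialect$replicate_cols
  if (is.null(wide_cols)) {
    auto <- grep("^(rep|miller_)[0-9]+$", names(raw), value = TRUE)
    if (length(auto) > 0 && is.null(get_col("miller"))) wide_cols <- auto
  }

  base <- tibble(
    bait = as.character(bait),
    prey = as.character(prey),
    mediator = {
      m <- get_col("mediator")
      if (is.null(m)) NA_character_ else as.character(m)
    },
    assay_mode = {
      m <- get_col("assay_mode")
      if (is.null(m)) "Y2H" else as.character(m)
    },
    is_control = {
      m <- get_col("is_control")
      if (is.null(m)) FALSE else as.logical(m)
    },
    control_kind = {
      m <- get_col("control_kind")
      if (is.null(m)) "none" else as.character(m)
    },
    .row = seq_len(nrow(raw))
  )

  if (!is.null(wide_cols)) {
    vals <- raw[, wide_cols, drop = FALSE]
    long <- tidyr::pivot_longer(
      dplyr::bind_cols(base, vals), cols = dplyr::all_of(wide_cols),
      names_to = "replicate", values_to = "miller")
    long$replicate <- match(long$replicate, wide_cols)
  } else {
    miller <- get_col("miller")
    stop_if_not(!is.null(miller),
                "no miller column and no replicate columns found")
    long <- base
    long$miller <- suppressWarnings(as.numeric(miller))
    rep_col <- get_col("replicate")
    long$replicate <- if (is.null(rep_col)) {
      stats::ave(seq_len(nrow(long)),
                 paste(long$bait, long$prey, long$mediator, long$assay_mode),
                 FUN = seq_along)
    } else as.integer(rep_col)
  }

  bad <- which(!is.finite(long$miller) | long$miller <= 0)
  stop_if_not(length(bad) == 0,
              "non-positive or non-numeric Miller value(s) at source row(s): %s",
              paste(unique(long$.row[bad]), collapse = ", "))
  mism <- which(xor(long$assay_mode == "Y3H", !is.na(long$mediator)))
  stop_if_not(length(mism) == 0,
              "mediator must be present iff assay_mode is Y3H (source row(s) %s)",
              paste(unique(long$.row[mism]), collapse = ", "))
  long %>%
    select("bait", "prey", "mediator", "assay_mode", "replicate", "miller",
           "is_control", "control_kind") %>%
    as_tibble()
}

# One-sided Welch p-value for mean(x) > mean(y); degenerate (zero-variance)
# inputs fall back to the deterministic comparison of means, with exact ties
# counted negative (conservative).
welch_greater_p <- function(x, y) {
  out <- tryCatch(stats::t.test(x, y, alternative = "greater")$p.value,
                  error = function(e) NA_real_)
  if (is.na(out)) out <- if (mean(x) > mean(y)) 0 else 1
  out
}

# One-sample one-sided p-value for mean(x) > mu0, with the same degenerate
# fallback.
t_greater_p <- function(x, mu0) {
  out <- tryCatch(stats::t.test(x, mu = mu0,
                                alternative = "greater")$p.value,
                  error = function(e) NA_real_)
  if (is.na(out)) out <- if (mean(x) > mu0) 0 else 1
  out
}

pooled_background <- function(measurements, mode) {
  bg <- measurements %>%
    filter(.data$assay_mode == mode, .data$control_kind == "empty_vector")
  stop_if_not(nrow(bg) > 0,
              "no empty-vector background controls for mode %s", mode)
  bg$miller
}

# A bait auto-activates when its bait + empty-AD control is significantly
# above background AND reaches the fold threshold used for positives (the
# fold gate keeps marginal test flukes from excluding whole baits).
autoactive_bait_set <- function(measurements, mode, background, alpha,
                                min_fold = 2) {
  aa <- measurements %>%
    filter(.data$assay_mode == mode, .data$control_kind == "autoactivation")
  if (nrow(aa) == 0) return(character())
  aa %>%
    group_by(.data$bait) %>%
    summarise(p = welch_greater_p(.data$miller, background),
              m = mean(.data$miller), .groups = "drop") %>%
    filter(.data$p < alpha, .data$m > min_fold * mean(background)) %>%
    pull("bait")
}

#' Call dimeric (two-hybrid) interactions
#'
#' A pair is positive when a one-sided Welch test of its replicates against
#' the pooled empty-vector background rejects at `alpha` and its mean exceeds
#' `min_fold` times the background mean. Pairs whose bait auto-activates
#' (bait + empty AD significantly above background) are excluded from
#' calling. Calls are symmetric: a pair is positive if either bait/prey
#' orientation is.
#'
#' @param measurements Long-format assay tibble (see [read_assay_table()]).
#' @param alpha Significance level in (0, 1).
#' @param min_fold Required fold-change of the pair mean over the background
#'   mean (>= 1).
#' @return A tibble of class `interaction_calls` with one row per unordered
#'   pair: `protein_a`, `protein_b`, `mode`, `mediator`, `mean_signal`,
#'   `delta` (mean minus background mean), `p_value`, `status`.
#' @export
call_dimeric_interactions <- function(measurements, alpha = 0.05,
                                      min_fold = 2) {
  stop_if_not(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  stop_if_not(min_fold >= 1, "min_fold must be >= 1")
  m <- measurements %>% filter(.data$assay_mode == "Y2H")
  bg <- pooled_background(m, "Y2H")
  bg_mean <- mean(bg)
  autoactive <- autoactive_bait_set(m, "Y2H", bg, alpha, min_fold)

  per_orientation <- m %>%
    filter(!.data$is_control) %>%
    group_by(.data$bait, .data$prey) %>%
    summarise(mean_o = mean(.data$miller),
              p_o = welch_greater_p(.data$miller, bg),
              n_rep = dplyr::n(), .groups = "drop") %>%
    mutate(pos_o = .data$p_o < alpha & .data$mean_o > min_fold * bg_mean,
           auto_o = .data$bait %in% autoactive)

  calls <- per_orientation %>%
    mutate(canonical_pairs(.data$bait, .data$prey)) %>%
    group_by(.data$node_a, .data$node_b) %>%
    summarise(
      mean_signal = mean(.data$mean_o),
      p_value = min(.data$p_o),
      positive = any(.data$pos_o),
      autoactive = any(.data$auto_o),
      .groups = "drop"
    ) %>%
    transmute(
      protein_a = .data$node_a, protein_b = .data$node_b,
      mode = "dimeric", mediator = NA_character_,
      mean_signal = .data$mean_signal,
      delta = .data$mean_signal - bg_mean,
      p_value = ifelse(.data$autoactive, NA_real_, .data$p_value),
      status = case_when(
        .data$autoactive ~ "autoactive_excluded",
        .data$positive ~ "positive",
        TRUE ~ "negative"
      )
    )
  attr(calls, "background_mean") <- bg_mean
  attr(calls, "autoactive_baits") <- autoactive
  class(calls) <- c("interaction_calls", class(calls))
  calls
}

#' Call mediator-enhanced (three-hybrid) interactions
#'
#' Implements the subtraction-based definition of a positive ternary
#' interaction: for each pair, `delta` is the three-hybrid mean minus the
#' two-hybrid baseline, where the baseline is the pair's dimeric mean when it
#' is dimerically positive and the pooled empty-vector background mean
#' otherwise. A pair is positive when it is dimerically negative but clearly
#' active in the three-hybrid assay (Welch test against background at
#' `alpha` and `min_fold` over background), or when it is enhanced beyond its
#' dimeric baseline (`delta > min_delta` with a one-sided test at `alpha`).
#' Negative deltas are called negative (lost / false-positive ternary
#' signal). Auto-active baits (bait + empty AD + mediator above background)
#' are excluded.
#'
#' @param y3h_measurements Long-format assay tibble with `assay_mode "Y3H"`
#'   rows, including empty-vector and mediator auto-activation controls
#'   (their absence is a hard error).
#' @param y2h_calls Dimeric calls from [call_dimeric_interactions()].
#' @param alpha Significance level.
#' @param min_delta Minimum Miller-unit enhancement over the dimeric
#'   baseline.
#' @param min_fold Fold over background required for a dimerically negative
#'   pair to count as three-hybrid active.
#' @return A tibble of class `interaction_calls`, `mode = "mediated"`.
#' @export
call_mediated_interactions <- function(y3h_measurements, y2h_calls,
                                       alpha = 0.05, min_delta = 0,
                                       min_fold = 2) {
  stop_if_not(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  m <- y3h_measurements %>% filter(.data$assay_mode == "Y3H")
  stop_if_not(nrow(m) > 0, "no Y3H measurements supplied")
  bg <- pooled_background(m, "Y3H")
  bg_mean <- mean(bg)
  has_med_control <- any(m$control_kind == "autoactivation")
  stop_if_not(has_med_control,
              "mediator auto-activation controls (bait + empty AD + mediator) are required")
  autoactive <- autoactive_bait_set(m, "Y3H", bg, alpha, min_fold)
  mediator_id <- unique(m$mediator[!is.na(m$mediator)])[1]

  y2h <- as_tibble(y2h_calls) %>%
    select(protein_a = "protein_a", protein_b = "protein_b",
           y2h_status = "status", y2h_mean = "mean_signal")

  pair_stats <- m %>%
    filter(!.data$is_control) %>%
    group_by(.data$bait, .data$prey) %>%
    summarise(reps = list(.data$miller), .groups = "drop") %>%
    mutate(canonical_pairs(.data$bait, .data$prey),
           auto_o = .data$bait %in% autoactive)

  calls <- pair_stats %>%
    left_join(y2h, by = c(node_a = "protein_a", node_b = "protein_b")) %>%
    mutate(
      y2h_status = dplyr::coalesce(.data$y2h_status, "negative"),
      baseline = ifelse(.data$y2h_status == "positive", .data$y2h_mean,
                        bg_mean)
    ) %>%
    group_by(.data$node_a, .data$node_b) %>%
    summarise(
      mean_signal = mean(unlist(.data$reps)),
      baseline = .data$baseline[1],
      y2h_positive = .data$y2h_status[1] == "positive",
      y2h_excluded = .data$y2h_status[1] == "autoactive_excluded",
      p_new = min(purrr::map_dbl(.data$reps, welch_greater_p, y = bg)),
      p_enh = min(purrr::map_dbl(.data$reps, t_greater_p,
                                 mu0 = .data$baseline[1])),
      mean_max = max(purrr::map_dbl(.data$reps, mean)),
      autoactive = any(.data$auto_o),
      .groups = "drop"
    ) %>%
    mutate(
      delta = .data$mean_signal - .data$baseline,
      new_pos = !.data$y2h_positive & !.data$y2h_excluded &
        .data$delta > 0 &
        .data$p_new < alpha & .data$mean_max > min_fold * bg_mean,
      enh_pos = .data$delta > min_delta & .data$p_enh < alpha
    ) %>%
    transmute(
      protein_a = .data$node_a, protein_b = .data$node_b,
      mode = "mediated", mediator = mediator_id,
      mean_signal = .data$mean_signal, delta = .data$delta,
      p_value = ifelse(.data$autoactive, NA_real_,
                       pmin(.data$p_new, .data$p_enh)),
      status = case_when(
        .data$autoactive ~ "autoactive_excluded",
        .data$delta <= 0 & !(.data$new_pos) ~ "negative",
        .data$new_pos | .data$enh_pos ~ "positive",
        TRUE ~ "negative"
      )
    )
  attr(calls, "background_mean") <- bg_mean
  attr(calls, "autoactive_baits") <- autoactive
  class(calls) <- c("interaction_calls", class(calls))
  calls
}
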