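# Configuration and staged pipeline driver tying the modules together.

#' Validated pipeline configuration
#'
#' All analysis knobs in one declarative object. Unknown keys are rejected
#' with the offending name. Defaults carry the standard epoch anchors (ePIN
#' 180, pre-PIN 120, post-PIN 109 mya) and calling thresholds; every one is
#' a plain config value.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    alpha = 0.05,            # significance level for interaction calling
    min_fold = 2,            # dimeric fold-change over background
    min_delta = 0,           # mediated Miller-unit enhancement threshold
    count_loops = TRUE,      # density convention: include homodimer loops
    epoch_times = c("ePIN" = 180, "pre-PIN" = 120, "post-PIN" = 109),
    entropy_temperature = 298.15,  # K
    minima_window = 5,       # kcal/mol above the global minimum
    sasa_probe = 1.4,        # Angstrom
    sasa_points = 960,       # quadrature points per atom
    turn_tolerance = 30,     # degrees
    hub_min = 5, island_max = 2,
    seed = 1L
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  stop_if_not(length(bad) == 0, "unknown config key(s): %s",
              paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  # small stable fingerprint of the configuration for output metadata
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e8
}

#' Run one pipeline stage
#'
#' A thin driver over the package functions: each command maps to one stage
#' of the analysis and returns its artifact; with `out_dir` set, artifacts
#' are also written to disk (JSON/TSV) with the tool version and config hash
#' in their metadata. Outputs are deterministic given `config` (which
#' includes the seed).
#'
#' @param command One of `"simulate-network"`, `"simulate-assay"`, `"call"`,
#'   `"build-net"`, `"compare"`, `"rates"`, `"swap"`, `"flexibility"`,
#'   `"structure-metrics"`, `"report"`.
#' @param config A [pipeline_config()].
#' @param inputs Named list of stage inputs (see each underlying function).
#' @param out_dir Optional output directory.
#' @return The stage artifact, invisibly when written to disk.
#' @export
run_stage <- function(command, config = pipeline_config(),
                      inputs = list(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  commands <- c("simulate-network", "simulate-assay", "call", "build-net",
                "compare", "rates", "swap", "flexibility",
                "structure-metrics", "report")
  stop_if_not(command %in% commands, "unknown command '%s'", command)

  artifact <- switch(
    command,
    "simulate-network" = {
      params <- inputs$params %||% evolution_params(seed = config$seed)
      simulate_pin_evolution(params)
    },
    "simulate-assay" = {
      stop_if_not(!is.null(inputs$pin), "simulate-assay needs inputs$pin")
      do.call(simulate_assay_table,
              c(list(pin = inputs$pin, seed = config$seed),
                inputs$assay_args %||% list()))
    },
    "call" = {
      stop_if_not(!is.null(inputs$measurements),
                  "call needs inputs$measurements")
      calls <- call_dimeric_interactions(inputs$measurements,
                                         alpha = config$alpha,
                                         min_fold = config$min_fold)
      if (any(inputs$measurements$assay_mode == "Y3H")) {
        med <- call_mediated_interactions(inputs$measurements, calls,
                                          alpha = config$alpha,
                                          min_delta = config$min_delta,
                                          min_fold = config$min_fold)
        calls <- dplyr::bind_rows(as_tibble(calls), as_tibble(med))
        class(calls) <- c("interaction_calls", class(calls))
      }
      calls
    },
    "build-net" = {
      do.call(build_network, c(list(calls = inputs$calls),
                               inputs$build_args %||% list()))
    },
    "compare" = {
      compare_networks(inputs$a, inputs$b, inputs$map,
                       count_loops = config$count_loops)
    },
    "rates" = gain_loss_rates(inputs$cmp),
    "swap" = do.call(swap_protein, inputs),
    "flexibility" = {
      compare_flexibility(inputs$a, inputs$b,
                          window = config$minima_window)
    },
    "structure-metrics" = {
      stop_if_not(!is.null(inputs$traj) || !is.null(inputs$structure),
                  "structure-metrics needs inputs$traj or inputs$structure")
      res <- list()
      if (!is.null(inputs$traj)) {
        res$rmsd <- trajectory_rmsd(inputs$traj,
                                    selection = inputs$selection)
      }
      s <- inputs$structure %||% inputs$traj$topology
      res$sasa <- glance(sasa(s, probe_radius = config$sasa_probe,
                              n_points = config$sasa_points))
      res$turns <- classify_turns(s, tolerance = config$turn_tolerance)
      res$contacts <- detect_polar_contacts(s)
      res
    },
    "report" = pipeline_report(inputs, config)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stage_artifact(artifact, command, config, out_dir)
  }
  artifact
}

write_stage_artifact <- function(artifact, command, config, out_dir) {
  path <- file.path(out_dir, paste0(gsub("-", "_", command), ".json"))
  payload <- list(
    meta = list(tool = "pinflex",
                version = as.character(utils::packageVersion("pinflex")),
                command = command,
                config_hash = config_hash(config),
                seed = config$seed),
    result = artifact_to_json(artifact)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

artifact_to_json <- function(x) {
  if (inherits(x, "evolution_truth")) {
    list(snapshots = lapply(x$snapshots, glance),
         true_gain_rate = x$true_gain_rate,
         true_loss_rate = x$true_loss_rate)
  } else if (inherits(x, "pin_comparison")) {
    glance(x)
  } else if (inherits(x, "pin")) {
    glance(x)
  } else if (is.data.frame(x)) {
    as_tibble(x)
  } else if (is.list(x)) {
    lapply(x, artifact_to_json)
  } else x
}

#' Aggregate stage outputs into a single report
#'
#' Collects per-epoch densities, conserved/gained/lost counts and rates,
#' swap degrees and flexibility comparisons into one tibble-backed summary
#' (and, through [run_stage()], one JSON file).
#'
#' @param inputs Named list with any of `networks` (list of [pin()]),
#'   `comparisons` (list of `pin_comparison`), `swaps` (tibbles from
#'   [swap_protein()]), `flexibility` (tibbles from
#'   [compare_flexibility()]).
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report`.
#' @export
pipeline_report <- function(inputs, config = pipeline_config()) {
  out <- list(
    densities = if (!is.null(inputs$networks))
      purrr::map(inputs$networks, glance) %>% dplyr::bind_rows(),
    comparisons = if (!is.null(inputs$comparisons))
      purrr::map(inputs$comparisons, glance) %>% dplyr::bind_rows(),
    swaps = if (!is.null(inputs$swaps))
      dplyr::bind_rows(inputs$swaps),
    flexibility = if (!is.null(inputs$flexibility))
      dplyr::bind_rows(lapply(inputs$flexibility, as_tibble))
  )
  out <- out[!vapply(out, is.null, TRUE)]
  class(out) <- "pipeline_report"
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    print(as.data.frame(x[[nm]]))
  }
  invisible(x)
}
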