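# Readers and writers for edge lists, ortholog maps, interaction calls and
# reports. All text writers round-trip through the matching readers.

meta_header <- function(extra = NULL) {
  c(sprintf("# pinflex %s",
            as.character(utils::packageVersion("pinflex"))),
    extra)
}

#' Write / read a network as a TSV edge list
#'
#' Columns `node_a`, `node_b`, `weight`, `epoch`, `time_mya`; a `# pinflex`
#' metadata comment line leads the file. Isolated nodes are preserved
#' through companion rows with an empty `node_b`.
#'
#' @param pin A [pin()].
#' @param file Output path.
#' @return `file` invisibly (writer); a [pin()] (reader).
#' @export
write_network_tsv <- function(pin, file) {
  iso <- setdiff(pin$nodes, c(pin$edges$node_a, pin$edges$node_b))
  df <- dplyr::bind_rows(
    mutate(pin$edges, epoch = pin$epoch_label, time_mya = pin$time_mya),
    if (length(iso)) tibble(node_a = iso, node_b = NA_character_,
                            weight = NA_real_, epoch = pin$epoch_label,
                            time_mya = pin$time_mya)
  )
  writeLines(meta_header(), file)
  readr::write_tsv(df, file, append = TRUE, col_names = TRUE, na = "")
  invisible(file)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(file) {
  df <- readr::read_tsv(file, comment = "#", show_col_types = FALSE,
                        na = "")
  iso <- df$node_a[is.na(df$node_b) | df$node_b == ""]
  edges <- df[!(is.na(df$node_b) | df$node_b == ""), , drop = FALSE]
  pin(edges = edges[, intersect(c("node_a", "node_b", "weight"),
                                names(edges))],
      nodes = unique(c(edges$node_a, edges$node_b, iso)),
      epoch_label = df$epoch[1] %||% "PIN",
      time_mya = df$time_mya[1] %||% 0)
}

#' Export a network as GraphML
#'
#' @param pin A [pin()].
#' @param file Output path.
#' @export
write_network_graphml <- function(pin, file) {
  igraph::write_graph(pin_igraph(pin), file, format = "graphml")
  invisible(file)
}

#' Write / read an ortholog map as two-column TSV
#' @param map An [ortholog_map()].
#' @param file Path.
#' @export
write_ortholog_map_tsv <- function(map, file) {
  writeLines(meta_header(), file)
  readr::write_tsv(as_tibble(map), file, append = TRUE, col_names = TRUE)
  invisible(file)
}

#' @rdname write_ortholog_map_tsv
#' @export
read_ortholog_map_tsv <- function(file) {
  ortholog_map(readr::read_tsv(file, comment = "#", show_col_types = FALSE))
}

#' Write interaction calls as TSV or JSON
#' @param calls An `interaction_calls` tibble.
#' @param file Path ending in `.tsv` or `.json`.
#' @export
write_calls <- function(calls, file) {
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(
      list(meta = list(tool = "pinflex",
                       version = as.character(
                         utils::packageVersion("pinflex"))),
           calls = as_tibble(calls)),
      file, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  } else {
    writeLines(meta_header(), file)
    readr::write_tsv(as_tibble(calls), file, append = TRUE,
                     col_names = TRUE, na = "")
  }
  invisible(file)
}

#' Write an assay table as CSV
#' @param table Long-format assay tibble.
#' @param file Path.
#' @export
write_assay_csv <- function(table, file) {
  writeLines(meta_header(), file)
  readr::write_csv(as_tibble(table), file, append = TRUE, col_names = TRUE,
                   na = "")
  invisible(file)
}
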