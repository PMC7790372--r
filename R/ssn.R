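#' Build a sequence similarity network from pairwise hits
#'
#' An edge is kept iff `evalue <= evalue_max` **and**
#' `edge_score >= score_min`, where the edge score is the alignment score
#' in the EFI-EST sense, `-log10(evalue)` (floored at E = 1e-180 to avoid
#' infinities). Edge weight is percent identity. The convergence ratio
#' (edges / possible pairs) is stored as a global divergence measure.
#'
#' @param hits Hit tibble from [all_vs_all()].
#' @param evalue_max Maximum E-value for an edge.
#' @param score_min Minimum edge score (`-log10` E-value units).
#' @param records Optional sequence-record tibble; supplies isolated nodes
#'   and node metadata. Defaults to the ids seen in `hits`.
#' @return An `ssn` object: list with `graph` (igraph, weighted by
#'   `pct_identity`), `nodes`, `edges` tibbles, `thresholds` and
#'   `convergence_ratio`.
#' @export
build_ssn <- function(hits, evalue_max = 1e-15, score_min = 30,
                      records = NULL) {
  edges <- hits %>%
    mutate(edge_score = -log10(pmax(.data$evalue, 1e-180))) %>%
    filter(.data$evalue <= evalue_max, .data$edge_score >= score_min,
           .data$query_id != .data$subject_id) %>%
    distinct(pair_key = paste(pmin(.data$query_id, .data$subject_id),
                              pmax(.data$query_id, .data$subject_id)),
             .keep_all = TRUE) %>%
    select("query_id", "subject_id", "pct_identity", "evalue", "edge_score")

  if (is.null(records)) {
    nodes <- tibble(id = sort(unique(c(hits$query_id, hits$subject_id))),
                    status = "unreviewed", taxon = "unknown", label = "unknown")
  } else {
    nodes <- as_records(records) %>% select(-"residues") %>% arrange(.data$id)
  }
  g <- igraph::graph_from_data_frame(
    d = edges %>% rename(from = "query_id", to = "subject_id") %>%
      mutate(weight = .data$pct_identity),
    directed = FALSE,
    vertices = as.data.frame(nodes)
  )
  n <- nrow(nodes)
  structure(
    list(graph = g, nodes = nodes, edges = edges,
         thresholds = c(evalue_max = evalue_max, score_min = score_min),
         convergence_ratio = if (n >= 2) nrow(edges) / (n * (n - 1) / 2) else 0),
    class = "ssn"
  )
}

#' @export
print.ssn <- function(x, ...) {
  cat(sprintf(
    "Sequence similarity network: %d nodes, %d edges (E <= %g, score >= %g)\nconvergence ratio: %.4g\n",
    nrow(x$nodes), nrow(x$edges),
    x$thresholds["evalue_max"], x$thresholds["score_min"],
    x$convergence_ratio
  ))
  invisible(x)
}

#' Connected components of an SSN
#'
#' @param ssn An `ssn` object (or igraph).
#' @return Tibble `id`, `component_id`, components numbered by decreasing
#'   size (ties by smallest member id).
#' @export
ssn_components <- function(ssn) {
  g <- if (inherits(ssn, "ssn")) ssn$graph else ssn
  comp <- igraph::components(g)
  members <- split(igraph::V(g)$name, comp$membership)
  ord <- order(-lengths(members), vapply(members, min, character(1)))
  tibble(
    id = unlist(members[ord], use.names = FALSE),
    component_id = rep(seq_along(ord), lengths(members[ord]))
  )
}

#' Write an SSN as a TSV edge list and node table
#'
#' @param ssn An `ssn` object.
#' @param edge_path TSV path for `id1, id2, pct_identity, evalue,
#'   edge_score`.
#' @param node_path Optional TSV path for the node attribute table.
#' @return `edge_path`, invisibly.
#' @export
write_ssn_tsv <- function(ssn, edge_path, node_path = NULL) {
  edges <- ssn$edges %>% rename(id1 = "query_id", id2 = "subject_id")
  write.table(edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(node_path)) {
    write.table(ssn$nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(edge_path)
}

#' Write a network as GraphML
#'
#' @param x An `ssn`, `pivot_network` or igraph object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(x, path) {
  g <- if (inherits(x, c("ssn", "pivot_network"))) x$graph else x
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
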