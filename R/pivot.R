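#' Contract a clustered SSN into the pivot network
#'
#' One pivot node per cluster; an (unweighted, undirected) pivot edge is
#' present iff at least one SSN edge joins a member of one cluster to a
#' member of the other, or the two clusters share a member (overlapping
#' clusters). SSN nodes assigned to no cluster are ignored.
#'
#' @param ssn An `ssn` object.
#' @param clustering A `nat_clustering` on (a subset of) the SSN nodes.
#' @return A `pivot_network`: `graph` (igraph on cluster ids), `nodes`
#'   tibble (`cluster_id`, `size`, `label`) and `edges` tibble.
#' @export
contract <- function(ssn, clustering) {
  if (!all(clustering$membership$id %in% ssn$nodes$id)) {
    abort("clustering nodes must be a subset of SSN nodes")
  }
  clusters <- clustering$clusters
  mem <- clustering$membership
  # map each ssn node to the (possibly several) clusters containing it
  by_node <- split(mem$cluster_id, mem$id)

  pair_set <- new.env(hash = TRUE)
  add_pair <- function(a, b) {
    if (a == b) return(invisible())
    key <- paste(min(a, b), max(a, b))
    assign(key, TRUE, envir = pair_set)
  }
  # inter-cluster SSN edges
  ed <- ssn$edges
  for (k in seq_len(nrow(ed))) {
    ca <- by_node[[ed$query_id[k]]]
    cb <- by_node[[ed$subject_id[k]]]
    if (is.null(ca) || is.null(cb)) next
    for (a in ca) for (b in cb) add_pair(a, b)
  }
  # shared members between overlapping clusters
  for (cl_ids in by_node) {
    if (length(cl_ids) > 1) {
      prs <- combn(sort(cl_ids), 2)
      for (k in seq_len(ncol(prs))) add_pair(prs[1, k], prs[2, k])
    }
  }
  keys <- ls(pair_set)
  edges <- if (length(keys)) {
    parts <- strsplit(keys, " ")
    tibble(from = as.integer(vapply(parts, `[`, character(1), 1)),
           to = as.integer(vapply(parts, `[`, character(1), 2))) %>%
      arrange(.data$from, .data$to)
  } else {
    tibble(from = integer(), to = integer())
  }
  nodes <- clusters %>% select("cluster_id", "size", "label")
  g <- igraph::graph_from_data_frame(
    d = edges %>% mutate(from = as.character(.data$from),
                         to = as.character(.data$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$cluster_id),
                          size = nodes$size, label = nodes$label)
  )
  structure(list(graph = g, nodes = nodes, edges = edges),
            class = "pivot_network")
}

#' @export
print.pivot_network <- function(x, ...) {
  cat(sprintf("Pivot network: %d cluster node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Topology statistics of an (unweighted, undirected) graph
#'
#' Degree, Brandes betweenness centrality normalised by
#' `(n-1)(n-2)/2` (disconnected pairs contribute nothing), and connected
#' components numbered by decreasing size.
#'
#' @param graph A `pivot_network`, `ssn`, or igraph.
#' @return Tibble: `node`, `degree`, `betweenness`, `component_id`.
#' @export
analyze_topology <- function(graph) {
  g <- if (inherits(graph, c("pivot_network", "ssn"))) graph$graph else graph
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  n <- igraph::vcount(g)
  btw <- if (n > 2) {
    igraph::betweenness(g, directed = FALSE, weights = NA) / ((n - 1) * (n - 2) / 2)
  } else {
    setNames(rep(0, n), igraph::V(g)$name)
  }
  comp <- igraph::components(g)
  members <- split(igraph::V(g)$name, comp$membership)
  ord <- order(-lengths(members), vapply(members, min, character(1)))
  comp_id <- setNames(rep(seq_along(ord), lengths(members[ord])),
                      unlist(members[ord], use.names = FALSE))
  tibble(
    node = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    betweenness = as.numeric(btw[igraph::V(g)$name]),
    component_id = as.integer(comp_id[igraph::V(g)$name])
  )
}

#' Write the pivot topology report
#'
#' TSV columns: `cluster_id`, `size`, `degree`, `betweenness`,
#' `component_id`.
#'
#' @param pivot A `pivot_network`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pivot_report <- function(pivot, path) {
  topo <- analyze_topology(pivot) %>%
    mutate(cluster_id = as.integer(.data$node)) %>%
    left_join(pivot$nodes, by = "cluster_id") %>%
    select("cluster_id", "size", "degree", "betweenness", "component_id")
  write.table(topo, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network in XGMML (Cytoscape-compatible)
#'
#' Minimal XGMML with node labels and edges, for interoperability with
#' Cytoscape sessions.
#'
#' @param x A `pivot_network`, `ssn` or igraph.
#' @param path Output path.
#' @param label Graph label attribute.
#' @return `path`, invisibly.
#' @export
write_network_xgmml <- function(x, path, label = "ssnat network") {
  g <- if (inherits(x, c("pivot_network", "ssn"))) x$graph else x
  nodes <- igraph::V(g)$name
  idx <- setNames(seq_along(nodes), nodes)
  ends <- igraph::as_edgelist(g, names = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    sprintf('<graph label="%s" directed="0" xmlns="http://www.cs.rpi.edu/XGMML">',
            label)
  ), con)
  writeLines(sprintf('  <node label="%s" id="%d"/>', nodes, idx[nodes]), con)
  if (nrow(ends)) {
    writeLines(sprintf('  <edge source="%d" target="%d"/>',
                       idx[ends[, 1]], idx[ends[, 2]]), con)
  }
  writeLines("</graph>", con)
  invisible(path)
}
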