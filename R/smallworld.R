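#' Small-worldness of a connected graph
#'
#' Computes the Watts-Strogatz small-world coefficient
#' `sigma = (C / C_rand) / (L / L_rand)` where `C` is the average local
#' clustering coefficient, `L` the average shortest path length, and the
#' reference values are means over `n_ref` degree-preserving rewired
#' versions of the graph (double-edge swaps, 10 x |E| attempted swaps
#' each). A graph is called small-world when `sigma > 1`.
#'
#' @param graph An `ssn` or igraph; must be connected with >= 4 nodes.
#' @param n_ref Number of rewired reference graphs.
#' @param seed Integer seed for the rewiring.
#' @return A `smallworld_stats` list: `C`, `L`, `C_rand`, `L_rand`,
#'   `sigma`, `is_smallworld`, `n_ref`, `seed`.
#' @export
smallworldness <- function(graph, n_ref = 10, seed = 1) {
  g <- if (inherits(graph, "ssn")) graph$graph else graph
  if (igraph::vcount(g) < 4) abort("need at least 4 nodes")
  if (!igraph::is_connected(g)) {
    abort("graph must be connected; pass the largest component")
  }
  g <- igraph::simplify(igraph::as_undirected(g))
  C <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  L <- igraph::mean_distance(g, directed = FALSE)
  stats <- with_seed_(seed, {
    vapply(seq_len(n_ref), function(i) {
      r <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
      c(igraph::transitivity(r, type = "localaverage", isolates = "zero"),
        igraph::mean_distance(r, directed = FALSE))
    }, numeric(2))
  })
  C_rand <- mean(stats[1, ]); L_rand <- mean(stats[2, ])
  sigma <- if (C_rand > 0 && L > 0) (C / C_rand) / (L / L_rand) else NA_real_
  structure(
    list(C = C, L = L, C_rand = C_rand, L_rand = L_rand,
         sigma = sigma, is_smallworld = isTRUE(sigma > 1),
         n_ref = n_ref, seed = as.integer(seed)),
    class = "smallworld_stats"
  )
}

#' @export
print.smallworld_stats <- function(x, ...) {
  cat(sprintf("C = %.4f (rand %.4f), L = %.3f (rand %.3f), sigma = %.3f%s\n",
              x$C, x$C_rand, x$L, x$L_rand, x$sigma,
              if (x$is_smallworld) " [small-world]" else ""))
  invisible(x)
}

#' Scan an SSN threshold grid for small-world components
#'
#' Builds one SSN per grid point from a single all-vs-all hit table
#' (computed at the loosest E-value) and measures the small-worldness of
#' each largest connected component.
#'
#' @param hits Hit tibble from [all_vs_all()] at the loosest E-value.
#' @param grid Tibble/data.frame with columns `evalue_max`, `score_min`.
#' @param records Optional records (isolated nodes / metadata).
#' @param n_ref,seed Passed to [smallworldness()].
#' @return Tibble: grid columns plus `n_nodes`, `n_edges`,
#'   `largest_component_size`, `sigma`, `is_smallworld`, and a `component`
#'   list-column holding the largest component's node ids.
#' @export
grid_scan <- function(hits, grid, records = NULL, n_ref = 10, seed = 1) {
  grid <- as_tibble(grid)
  stopifnot(all(c("evalue_max", "score_min") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    net <- build_ssn(hits, grid$evalue_max[i], grid$score_min[i], records)
    comp <- ssn_components(net)
    largest <- comp$id[comp$component_id == 1]
    sw <- if (length(largest) >= 4) {
      sub <- igraph::induced_subgraph(net$graph, largest)
      smallworldness(sub, n_ref = n_ref, seed = seed + i)
    } else {
      NULL
    }
    tibble(
      evalue_max = grid$evalue_max[i], score_min = grid$score_min[i],
      n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
      largest_component_size = length(largest),
      sigma = if (is.null(sw)) NA_real_ else sw$sigma,
      is_smallworld = if (is.null(sw)) FALSE else sw$is_smallworld,
      component = list(sort(largest))
    )
  })
  bind_rows(rows)
}

#' Choose the component for phylogeny from a grid scan
#'
#' Among grid rows whose largest component is small-world, picks the one
#' with the largest component (ties: stricter E-value, then higher minimum
#' score). If no row qualifies, returns the maximum-sigma row and sets a
#' warning flag.
#'
#' @param scan_table Output of [grid_scan()].
#' @return One-row tibble with the chosen parameters and `component`
#'   list-column, plus a logical `fallback` column.
#' @export
select_phylogeny_component <- function(scan_table) {
  if (!nrow(scan_table)) abort("`scan_table` must be non-empty")
  ok <- filter(scan_table, .data$is_smallworld)
  if (nrow(ok)) {
    chosen <- ok %>%
      arrange(desc(.data$largest_component_size), .data$evalue_max,
              desc(.data$score_min)) %>%
      slice(1) %>%
      mutate(fallback = FALSE)
  } else {
    warn("no grid point exhibits small-world properties; falling back to max sigma")
    chosen <- scan_table %>%
      arrange(desc(.data$sigma)) %>%
      slice(1) %>%
      mutate(fallback = TRUE)
  }
  chosen
}

#' Select per-cluster representative sequences for phylogeny
#'
#' For every cluster intersecting the chosen component: curated members
#' first (when more than `k` exist, the `k` lexicographically smallest
#' ids); remaining slots filled by seeded uniform sampling of unreviewed
#' members. Clusters with fewer than `k` members contribute all members.
#'
#' @param clustering A `nat_clustering`.
#' @param component Character vector of sequence ids (the chosen
#'   component), or a one-row tibble from [select_phylogeny_component()].
#' @param records Record tibble supplying curation status.
#' @param k Representatives per cluster (default 3).
#' @param seed Integer seed for the random fill.
#' @return Tibble `cluster_id`, `seq_id`, `status`.
#' @export
select_representatives <- function(clustering, component, records,
                                   k = 3, seed = 1) {
  stopifnot(k >= 1)
  if (is.data.frame(component)) component <- component$component[[1]]
  records <- as_records(records)
  status <- setNames(records$status, records$id)
  picks <- with_seed_(seed, {
    lapply(seq_len(nrow(clustering$clusters)), function(i) {
      cl <- clustering$clusters$members[[i]]
      inside <- sort(intersect(cl, component))
      if (!length(inside)) return(NULL)
      cur <- inside[status[inside] == "curated"]
      unr <- inside[status[inside] != "curated"]
      chosen <- head(sort(cur), k)
      need <- k - length(chosen)
      if (need > 0 && length(unr)) {
        chosen <- c(chosen, sort(sample(unr, min(need, length(unr)))))
      }
      tibble(cluster_id = clustering$clusters$cluster_id[i], seq_id = chosen)
    })
  })
  out <- bind_rows(picks)
  if (!nrow(out)) return(tibble(cluster_id = integer(), seq_id = character(),
                                status = character()))
  mutate(out, status = unname(status[.data$seq_id]))
}
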