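#' Clustering parameters for cohesiveness-based cluster detection
#'
#' Defaults follow the published defaults of the cohesiveness-based
#' overlapping clustering algorithm this module reimplements: size penalty
#' `penalty = 2`, overlap merge threshold `overlap_omega = 0.8`, and the
#' configuration used for SSNs: minimum cluster size 10 and
#' `min_density = "auto"` (resolved to 0.3 on weights normalised to
#' \[0, 1\]).
#'
#' @param min_size Minimum member count for a reported cluster.
#' @param penalty Non-negative cohesiveness size penalty.
#' @param overlap_omega Merge threshold on the overlap score
#'   `|A∩B|^2 / (|A|·|B|)`.
#' @param min_density Minimum cluster density, or `"auto"` for 0.3.
#' @return A `clustering_params` list.
#' @export
clustering_params <- function(min_size = 10, penalty = 2.0,
                              overlap_omega = 0.8, min_density = "auto") {
  stopifnot(min_size >= 1, penalty >= 0,
            overlap_omega >= 0, overlap_omega <= 1)
  structure(list(min_size = as.integer(min_size), penalty = penalty,
                 overlap_omega = overlap_omega, min_density = min_density),
            class = "clustering_params")
}

# Internal weighted adjacency view of an igraph / ssn: named list mapping
# each node to a named numeric vector of neighbour weights.
graph_adjacency <- function(graph) {
  g <- if (inherits(graph, "ssn")) graph$graph else graph
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  ends <- igraph::as_edgelist(g, names = TRUE)
  nodes <- igraph::V(g)$name
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- numeric(0)
  if (nrow(ends)) {
    for (k in seq_len(nrow(ends))) {
      a <- ends[k, 1]; b <- ends[k, 2]
      if (a == b) next
      adj[[a]][b] <- (if (is.na(adj[[a]][b])) 0 else adj[[a]][b]) + w[k]
      adj[[b]][a] <- (if (is.na(adj[[b]][a])) 0 else adj[[b]][a]) + w[k]
    }
  }
  adj
}

adj_strength <- function(adj) vapply(adj, sum, numeric(1))

# Weight scale used to normalise densities to [0, 1]: percent-identity
# weighted graphs (any weight > 1) are on a 0-100 scale, unit-weight test
# graphs on a 0-1 scale.
adj_weight_scale <- function(adj) {
  mx <- suppressWarnings(max(unlist(adj, use.names = FALSE), 0))
  if (mx > 1) 100 else 1
}

subset_weights <- function(adj, members) {
  inside <- unlist(lapply(adj[members], function(nb) nb[names(nb) %in% members]))
  w_in <- sum(inside) / 2
  all_inc <- sum(vapply(adj[members], sum, numeric(1)))
  w_bound <- all_inc - 2 * w_in
  c(w_in = w_in, w_bound = w_bound)
}

#' Cohesiveness of a node subset
#'
#' The objective of the greedy cluster search:
#' `f(V) = w_in / (w_in + w_bound + p * |V|)`, with `w_in` the total
#' weight of edges inside the subset and `w_bound` the total weight of
#' edges crossing its boundary.
#'
#' @param graph An `ssn`, igraph, or anything [build_ssn()] produces.
#' @param subset Character vector of node ids (non-empty).
#' @param penalty Non-negative size penalty `p`.
#' @return Cohesiveness in \[0, 1\].
#' @export
cohesiveness <- function(graph, subset, penalty = 2.0) {
  adj <- graph_adjacency(graph)
  subset <- as.character(subset)
  if (length(subset) == 0) abort("`subset` must be non-empty")
  if (!all(subset %in% names(adj))) abort("subset nodes must exist in the graph")
  w <- subset_weights(adj, subset)
  denom <- w[["w_in"]] + w[["w_bound"]] + penalty * length(subset)
  if (denom == 0) 0 else w[["w_in"]] / denom
}

new_cluster <- function(members, cohesiveness, density,
                        cluster_id = NA_integer_, label = "uncharacterized") {
  structure(list(cluster_id = cluster_id,
                 members = sort(members),
                 cohesiveness = cohesiveness,
                 density = density,
                 label = label),
            class = "nat_cluster")
}

#' @export
print.nat_cluster <- function(x, ...) {
  cat(sprintf("Cluster%s: %d members, cohesiveness %.3f, density %.3f, label %s\n",
              if (is.na(x$cluster_id)) "" else paste0(" ", x$cluster_id),
              length(x$members), x$cohesiveness, x$density, x$label))
  invisible(x)
}

cluster_density <- function(adj, members, scale = adj_weight_scale(adj)) {
  k <- length(members)
  if (k < 2) return(0)
  w_in <- subset_weights(adj, members)[["w_in"]]
  2 * (w_in / scale) / (k * (k - 1))
}

# One greedy growth from a seed over a prebuilt adjacency (workhorse shared
# by grow_cluster and detect_clusters).
grow_from_seed <- function(adj, strength, seed_node, penalty) {
  members <- seed_node
  w_in <- 0
  w_bound <- strength[[seed_node]]
  # wS[v]: total weight between v and the current member set
  wS <- adj[[seed_node]]
  f <- function(win, wbd, k) {
    d <- win + wbd + penalty * k
    if (d == 0) 0 else win / d
  }
  current <- f(w_in, w_bound, 1)
  repeat {
    k <- length(members)
    cand <- list()
    ext <- setdiff(names(wS)[wS > 0], members)
    for (v in ext) {
      new_in <- w_in + wS[[v]]
      new_bd <- w_bound - wS[[v]] + (strength[[v]] - wS[[v]])
      cand[[length(cand) + 1]] <- list(node = v, action = "add",
                                       f = f(new_in, new_bd, k + 1))
    }
    if (k > 1) {
      for (u in members) {
        nb <- adj[[u]]
        in_u <- sum(nb[names(nb) %in% members])
        out_u <- strength[[u]] - in_u
        if (out_u <= 0) next  # interior node, not a boundary member
        new_in <- w_in - in_u
        new_bd <- w_bound + in_u - out_u
        cand[[length(cand) + 1]] <- list(node = u, action = "remove",
                                         f = f(new_in, new_bd, k - 1))
      }
    }
    if (!length(cand)) break
    fs <- vapply(cand, `[[`, numeric(1), "f")
    best <- max(fs)
    if (best <= current + 1e-12) break
    top <- cand[abs(fs - best) < 1e-12]
    pick <- top[[order(vapply(top, `[[`, character(1), "node"))[1]]]
    if (pick$action == "add") {
      members <- c(members, pick$node)
      w_in <- w_in + wS[[pick$node]]
      w_bound <- w_bound - wS[[pick$node]] + (strength[[pick$node]] - wS[[pick$node]])
      for (nb in names(adj[[pick$node]])) {
        wS[nb] <- (if (is.na(wS[nb])) 0 else wS[nb]) + adj[[pick$node]][[nb]]
      }
    } else {
      members <- setdiff(members, pick$node)
      nb <- adj[[pick$node]]
      in_u <- sum(nb[names(nb) %in% members])
      w_in <- w_in - in_u
      w_bound <- w_bound + in_u - (strength[[pick$node]] - in_u)
      for (nbv in names(nb)) wS[nbv] <- wS[nbv] - nb[[nbv]]
    }
    current <- best
  }
  new_cluster(members, current, cluster_density(adj, members))
}

#' Greedy cohesiveness-maximising cluster growth
#'
#' Starting from the seed node, repeatedly applies the single
#' add-external-neighbour or remove-boundary-member step that maximally
#' increases cohesiveness, stopping at a local maximum. Tie-breaks are
#' deterministic (lexicographically smallest node id).
#'
#' @param graph An `ssn` or igraph.
#' @param seed_node Node id present in the graph.
#' @param params [clustering_params()]; only `penalty` is used here.
#' @return A `nat_cluster` (members, cohesiveness, density).
#' @export
grow_cluster <- function(graph, seed_node, params = clustering_params()) {
  adj <- graph_adjacency(graph)
  seed_node <- as.character(seed_node)
  if (!seed_node %in% names(adj)) abort("`seed_node` must exist in the graph")
  grow_from_seed(adj, adj_strength(adj), seed_node, params$penalty)
}

#' Detect dense, possibly overlapping clusters
#'
#' Seeds are taken in decreasing weighted-degree order over nodes not yet
#' claimed by a grown cluster. Grown clusters with pairwise overlap
#' `|A∩B|^2 / (|A|·|B|) >= overlap_omega` are merged (union) until a
#' fixpoint; clusters failing `min_size` or `min_density` are discarded;
#' survivors are numbered from 1 in decreasing size order (ties by
#' smallest member id).
#'
#' @param graph An `ssn` or igraph weighted by percent identity.
#' @param params [clustering_params()].
#' @return A `nat_clustering`: `clusters` tibble (`cluster_id`, `size`,
#'   `cohesiveness`, `density`, `label`, `members` list-column),
#'   `membership` tibble (`id`, `cluster_id`; overlapping nodes appear
#'   once per cluster) and `unassigned` node ids.
#' @export
detect_clusters <- function(graph, params = clustering_params()) {
  adj <- graph_adjacency(graph)
  if (!length(adj)) {
    return(new_clustering(list(), character(0), params))
  }
  strength <- adj_strength(adj)
  min_density <- if (identical(params$min_density, "auto")) 0.3 else params$min_density
  seeds <- names(sort(strength, decreasing = TRUE))
  seeds <- seeds[order(-strength[seeds], seeds)]
  claimed <- character(0)
  grown <- list()
  for (s in seeds) {
    if (s %in% claimed) next
    cl <- grow_from_seed(adj, strength, s, params$penalty)
    grown[[length(grown) + 1]] <- cl
    claimed <- union(claimed, cl$members)
  }
  # merge highly overlapping clusters (union) until fixpoint
  repeat {
    merged <- FALSE
    for (i in seq_along(grown)) {
      if (merged) break
      for (j in seq_along(grown)) {
        if (j <= i) next
        A <- grown[[i]]$members; B <- grown[[j]]$members
        ov <- length(intersect(A, B))^2 / (length(A) * length(B))
        if (ov >= params$overlap_omega) {
          u <- union(A, B)
          grown[[i]] <- new_cluster(u, cohesiveness_adj(adj, u, params$penalty),
                                    cluster_density(adj, u))
          grown[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  keep <- vapply(grown, function(cl) {
    length(cl$members) >= params$min_size && cl$density >= min_density
  }, logical(1))
  survivors <- grown[keep]
  ord <- order(-vapply(survivors, function(cl) length(cl$members), numeric(1)),
               vapply(survivors, function(cl) min(cl$members), character(1)))
  survivors <- survivors[ord]
  for (i in seq_along(survivors)) survivors[[i]]$cluster_id <- i
  new_clustering(survivors, names(adj), params)
}

cohesiveness_adj <- function(adj, members, penalty) {
  w <- subset_weights(adj, members)
  denom <- w[["w_in"]] + w[["w_bound"]] + penalty * length(members)
  if (denom == 0) 0 else w[["w_in"]] / denom
}

new_clustering <- function(clusters, all_nodes, params) {
  clusters_tbl <- tibble(
    cluster_id = vapply(clusters, `[[`, integer(1), "cluster_id"),
    size = vapply(clusters, function(cl) length(cl$members), integer(1)),
    cohesiveness = vapply(clusters, `[[`, numeric(1), "cohesiveness"),
    density = vapply(clusters, `[[`, numeric(1), "density"),
    label = vapply(clusters, `[[`, character(1), "label"),
    members = lapply(clusters, `[[`, "members")
  )
  membership <- if (nrow(clusters_tbl)) {
    tidyr::unnest(clusters_tbl %>% select("cluster_id", "members"),
                  cols = "members") %>%
      rename(id = "members") %>% select("id", "cluster_id")
  } else {
    tibble(id = character(), cluster_id = integer())
  }
  structure(
    list(clusters = clusters_tbl,
         membership = membership,
         unassigned = setdiff(all_nodes, membership$id),
         params = params),
    class = "nat_clustering"
  )
}

#' @export
print.nat_clustering <- function(x, ...) {
  cat(sprintf("Clustering: %d cluster(s), %d unassigned node(s)\n",
              nrow(x$clusters), length(x$unassigned)))
  if (nrow(x$clusters)) print(x$clusters %>% select(-"members"))
  invisible(x)
}

#' Exhaustive best-cohesiveness cluster (oracle)
#'
#' Enumerates every non-empty connected subset of a small graph (at most
#' 15 nodes) and returns the global cohesiveness maximum; on ties, the
#' lexicographically smallest member set. Intended as an independent check
#' of [grow_cluster()].
#'
#' @param graph An `ssn` or igraph with at most 15 nodes.
#' @param penalty Cohesiveness size penalty.
#' @return A `nat_cluster`.
#' @export
brute_force_best_cluster <- function(graph, penalty = 2.0) {
  adj <- graph_adjacency(graph)
  nodes <- sort(names(adj))
  n <- length(nodes)
  if (n > 15) abort("brute-force search refuses graphs larger than 15 nodes")
  best <- NULL; best_f <- -Inf
  for (mask in seq_len(2^n - 1)) {
    members <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (!subset_connected(adj, members)) next
    f <- cohesiveness_adj(adj, members, penalty)
    if (f > best_f + 1e-12 ||
        (abs(f - best_f) <= 1e-12 && !is.null(best) &&
         paste(members, collapse = "\r") < paste(best, collapse = "\r"))) {
      best <- members; best_f <- f
    }
  }
  new_cluster(best, best_f, cluster_density(adj, best))
}

subset_connected <- function(adj, members) {
  if (length(members) <= 1) return(TRUE)
  seen <- members[1]
  frontier <- members[1]
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(adj[frontier], names)))
    nxt <- setdiff(intersect(nxt, members), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(members)
}

#' Size-weighted clustering F1 against a ground-truth partition
#'
#' For each truth family, the F1 score against its best-matching predicted
#' cluster; families are combined by a size-weighted mean. An empty
#' predicted clustering scores 0.
#'
#' @param predicted A `nat_clustering`.
#' @param truth Named character vector (id -> family) or tibble with
#'   columns `seq_id`, `family_id`.
#' @return F1 in \[0, 1\].
#' @export
clustering_f1 <- function(predicted, truth) {
  if (is.data.frame(truth)) {
    truth <- setNames(truth$family_id, truth$seq_id)
  }
  fams <- split(names(truth), truth)
  if (!nrow(predicted$clusters)) return(0)
  clusters <- predicted$clusters$members
  f1s <- vapply(fams, function(fam) {
    max(vapply(clusters, function(cl) {
      tp <- length(intersect(fam, cl))
      if (tp == 0) return(0)
      prec <- tp / length(cl); rec <- tp / length(fam)
      2 * prec * rec / (prec + rec)
    }, numeric(1)))
  }, numeric(1))
  sum(f1s * lengths(fams)) / sum(lengths(fams))
}

#' Write cluster membership and summary tables
#'
#' Membership TSV columns: `seq_id`, `cluster_id`, `status`, `label`;
#' summary TSV columns: `cluster_id`, `size`, `cohesiveness`, `density`,
#' `label`.
#'
#' @param clustering A `nat_clustering`.
#' @param membership_path,summary_path Output TSV paths (`NULL` to skip).
#' @param records Optional record tibble supplying `status` per sequence.
#' @return `membership_path`, invisibly.
#' @export
write_clustering_tsv <- function(clustering, membership_path,
                                 summary_path = NULL, records = NULL) {
  mem <- clustering$membership %>% rename(seq_id = "id") %>%
    left_join(clustering$clusters %>% select("cluster_id", "label"),
              by = "cluster_id")
  if (!is.null(records)) {
    mem <- left_join(mem, as_records(records) %>%
                       select(seq_id = "id", "status"), by = "seq_id")
  } else {
    mem$status <- NA_character_
  }
  write.table(mem %>% select("seq_id", "cluster_id", "status", "label"),
              membership_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    write.table(clustering$clusters %>% select(-"members"),
                summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(membership_path)
}
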