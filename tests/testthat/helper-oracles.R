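# Independent oracles used to cross-check the package implementations.
# These are deliberately written from definitions, not from the package's
# algorithms.

# Optimal local alignment score by recursion over matched-column traces:
# a local alignment is a strictly increasing sequence of aligned column
# pairs; between consecutive pairs the unaligned residues sit in two gap
# runs whose affine cost is open + ext * len each. Memoised over the
# (i, j) start pair.
oracle_local_score <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  gapcost <- function(L) ifelse(L > 0, gap_open + gap_extend * L, 0)
  memo <- matrix(NA_real_, n, m)
  f <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    best_tail <- 0
    if (i < n && j < m) {
      for (i2 in (i + 1):n) for (j2 in (j + 1):m) {
        tail <- -gapcost(i2 - i - 1) - gapcost(j2 - j - 1) + f(i2, j2)
        if (tail > best_tail) best_tail <- tail
      }
    }
    val <- submat[A[i], B[j]] + best_tail
    memo[i, j] <<- val
    val
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) best <- max(best, f(i, j))
  best
}

# Normalised betweenness by explicit enumeration of all shortest paths
# (graphs up to ~6 nodes). Paths are enumerated by depth-first search and
# filtered to geodesic length.
oracle_betweenness <- function(g) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  score <- setNames(rep(0, n), nodes)
  if (n < 3) return(score)
  adj <- lapply(setNames(nodes, nodes), function(v) {
    igraph::neighbors(g, v)$name
  })
  all_paths <- function(from, to) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (nb in adj[[last]]) if (!nb %in% path) walk(c(path, nb))
    }
    walk(from)
    out
  }
  prs <- combn(nodes, 2)
  for (k in seq_len(ncol(prs))) {
    s <- prs[1, k]; t <- prs[2, k]
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- lengths(paths)
    geo <- paths[lens == min(lens)]
    for (p in geo) {
      inner <- setdiff(p, c(s, t))
      score[inner] <- score[inner] + 1 / length(geo)
    }
  }
  score / ((n - 1) * (n - 2) / 2)
}

# Exact position p-value of an integer PWM by full enumeration of the
# |alphabet|^w words.
oracle_position_pvalue <- function(M, background, score) {
  w <- ncol(M)
  A <- nrow(M)
  words <- as.matrix(expand.grid(rep(list(seq_len(A)), w)))
  tot <- 0
  for (r in seq_len(nrow(words))) {
    s <- sum(M[cbind(words[r, ], seq_len(w))])
    if (s >= score) tot <- tot + prod(background[words[r, ]])
  }
  tot
}

# Random connected weighted graph on `n` nodes (edge prob p, weights
# uniform), retried until connected.
random_connected_graph <- function(n, p = 0.5, weight_range = c(0.2, 1)) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  igraph::E(g)$weight <- round(runif(igraph::ecount(g), weight_range[1],
                                     weight_range[2]), 3)
  g
}

# Tiny deterministic graph builder from an edge list.
graph_from_edges <- function(edges, weights = NULL, isolated = character(0)) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)]),
    directed = FALSE,
    vertices = data.frame(name = unique(c(edges, isolated)))
  )
  igraph::E(g)$weight <- if (is.null(weights)) 1 else weights
  g
}
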