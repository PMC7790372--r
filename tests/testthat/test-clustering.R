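test_that("cohesiveness matches its closed form on small subsets", {
  tri <- graph_from_edges(c("a", "b", "b", "c", "a", "c"))
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 0), 1.0)

  path <- graph_from_edges(c("a", "b", "b", "c"))
  expect_equal(cohesiveness(path, c("a", "b"), penalty = 0), 0.5)

  single <- cohesiveness(path, "a", penalty = 2)
  expect_equal(single, 0)  # w_in = 0
  expect_error(cohesiveness(path, character(0)), "non-empty")
  expect_error(cohesiveness(path, "zz"), "exist")
})

test_that("greedy growth finds the planted dense region", {
  g <- fixture_two_triangles()
  params <- clustering_params(min_size = 1, penalty = 0.5)
  cl <- grow_cluster(g, "a", params)
  expect_setequal(cl$members, c("a", "b", "c"))
  # the triangle is a strict local optimum: every single move hurts
  for (v in c("d", "e", "f")) {
    expect_lt(cohesiveness(g, c(cl$members, v), 0.5), cl$cohesiveness)
  }
  for (v in cl$members) {
    expect_lt(cohesiveness(g, setdiff(cl$members, v), 0.5), cl$cohesiveness)
  }
  # the exhaustive optimum dominates the local one
  oracle <- brute_force_best_cluster(g, penalty = 0.5)
  expect_gte(oracle$cohesiveness, cl$cohesiveness)

  k5 <- graph_from_edges(as.vector(combn(letters[1:5], 2)))
  expect_setequal(grow_cluster(k5, "c", clustering_params(penalty = 0))$members,
                  letters[1:5])

  iso <- graph_from_edges(c("a", "b"), isolated = "z")
  expect_identical(grow_cluster(iso, "z")$members, "z")
})

test_that("detect_clusters sizes, numbering, merging and density filters", {
  two_k10 <- igraph::disjoint_union(
    igraph::make_full_graph(10), igraph::make_full_graph(10))
  igraph::V(two_k10)$name <- c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))
  igraph::E(two_k10)$weight <- 1
  cl <- detect_clusters(two_k10, clustering_params(min_size = 10))
  expect_equal(nrow(cl$clusters), 2)
  expect_equal(cl$clusters$size, c(10, 10))
  expect_equal(cl$clusters$cluster_id, c(1, 2))
  # ties by smallest member id: the "a" clique is cluster 1
  expect_true("a01" %in% cl$clusters$members[[1]])
  expect_length(cl$unassigned, 0)

  k9 <- igraph::make_full_graph(9)
  igraph::V(k9)$name <- sprintf("n%d", 1:9)
  igraph::E(k9)$weight <- 1
  cl9 <- detect_clusters(k9, clustering_params(min_size = 10))
  expect_equal(nrow(cl9$clusters), 0)
  expect_length(cl9$unassigned, 9)
})

test_that("growth trajectory is monotone and members stay connected inward", {
  set.seed(71)
  for (k in 1:10) {
    g <- random_connected_graph(sample(5:9, 1))
    seedv <- sample(igraph::V(g)$name, 1)
    cl <- grow_cluster(g, seedv, clustering_params(penalty = 1))
    # every member has an edge into the cluster (or is a singleton)
    if (length(cl$members) > 1) {
      for (m in cl$members) {
        nb <- igraph::neighbors(g, m)$name
        expect_true(length(intersect(nb, setdiff(cl$members, m))) > 0)
      }
    }
    # accepted result is a local optimum: no single move improves it
    f0 <- cohesiveness(g, cl$members, penalty = 1)
    ext <- setdiff(igraph::V(g)$name, cl$members)
    for (v in ext) {
      expect_lte(cohesiveness(g, c(cl$members, v), penalty = 1), f0 + 1e-9)
    }
  }
})

test_that("detect_clusters is invariant to node relabelling order", {
  set.seed(81)
  g <- random_connected_graph(8)
  cl1 <- detect_clusters(g, clustering_params(min_size = 2, min_density = 0))
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  cl2 <- detect_clusters(g2, clustering_params(min_size = 2, min_density = 0))
  sets1 <- lapply(cl1$clusters$members, sort)
  sets2 <- lapply(cl2$clusters$members, sort)
  expect_setequal(vapply(sets1, paste, character(1), collapse = ","),
                  vapply(sets2, paste, character(1), collapse = ","))
})

test_that("the exhaustive oracle dominates greedy growth", {
  # including a pendant removes its boundary weight, so the exhaustive
  # optimum of triangle + pendant is the whole component (cohesiveness 1
  # at zero penalty), strictly above the bare triangle
  tri_pendant <- graph_from_edges(c("a", "b", "b", "c", "a", "c", "c", "d"))
  o <- brute_force_best_cluster(tri_pendant, penalty = 0)
  expect_setequal(o$members, c("a", "b", "c", "d"))
  expect_equal(o$cohesiveness, 1)
  expect_gt(o$cohesiveness, cohesiveness(tri_pendant, c("a", "b", "c"), 0))

  edge <- graph_from_edges(c("a", "b"))
  oe <- brute_force_best_cluster(edge, penalty = 0)
  expect_setequal(oe$members, c("a", "b"))
  expect_equal(oe$cohesiveness, 1)

  set.seed(91)
  eq <- 0
  n_graphs <- 30
  for (k in seq_len(n_graphs)) {
    g <- random_connected_graph(sample(5:10, 1))
    o <- brute_force_best_cluster(g, penalty = 1)
    strength <- igraph::strength(g)[o$members]
    seedv <- names(sort(strength, decreasing = TRUE))[1]
    gr <- grow_cluster(g, seedv, clustering_params(penalty = 1))
    expect_gte(o$cohesiveness, gr$cohesiveness - 1e-12)
    if (abs(o$cohesiveness - gr$cohesiveness) < 1e-9) eq <- eq + 1
  }
  expect_gte(eq / n_graphs, 0.8)

  big <- igraph::make_full_graph(16)
  igraph::V(big)$name <- sprintf("v%02d", 1:16)
  expect_error(brute_force_best_cluster(big), "refuses")
})

test_that("clustering F1 behaves at its reference points", {
  fx <- fixture_superfamily()
  truth <- fx$sim$truth$membership
  expect_equal(clustering_f1(fx$clustering, truth), 1.0)

  # one giant cluster over two equal families -> 2/3
  half <- setNames(rep(c("A", "B"), each = 10), sprintf("s%02d", 1:20))
  giant <- ssnat:::new_clustering(
    list(ssnat:::new_cluster(names(half), 0.5, 0.5, cluster_id = 1L)),
    names(half), clustering_params(min_size = 1))
  expect_equal(clustering_f1(giant, half), 2 / 3)

  none <- ssnat:::new_clustering(list(), names(half), clustering_params())
  expect_equal(clustering_f1(none, half), 0)
})
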