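test_that("a complete graph has sigma exactly 1", {
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- letters[1:6]
  sw <- smallworldness(k6, n_ref = 3, seed = 5)
  expect_equal(sw$C, 1); expect_equal(sw$L, 1)
  expect_equal(sw$sigma, 1)
  expect_false(sw$is_smallworld)

  disc <- igraph::disjoint_union(igraph::make_full_graph(4),
                                 igraph::make_full_graph(4))
  igraph::V(disc)$name <- letters[1:8]
  expect_error(smallworldness(disc), "connected")
})

test_that("rewired references preserve every node's degree", {
  set.seed(121)
  g <- igraph::sample_gnp(40, 0.15)
  while (!igraph::is_connected(g)) g <- igraph::sample_gnp(40, 0.15)
  igraph::V(g)$name <- sprintf("n%02d", 1:40)
  r <- withr::with_seed(9, igraph::rewire(
    g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g))))
  expect_equal(igraph::degree(r), igraph::degree(g))
})

test_that("a rewired ring lattice is detected as small-world", {
  ws <- withr::with_seed(7, igraph::sample_smallworld(1, 200, 4, 0.05))
  igraph::V(ws)$name <- sprintf("w%03d", 1:200)
  sw <- smallworldness(ws, n_ref = 5, seed = 11)
  expect_gt(sw$sigma, 1)
  expect_true(sw$is_smallworld)
  # isomorphic relabelling: same graph, same seeds -> same sigma
  perm <- withr::with_seed(1, sample(200))
  ws2 <- igraph::permute(ws, perm)
  sw2 <- smallworldness(ws2, n_ref = 5, seed = 11)
  expect_equal(sw2$C, sw$C)
  expect_equal(sw2$L, sw$L)
  expect_lt(abs(sw2$sigma - sw$sigma), 0.3)
})

test_that("grid scan shrinks components monotonically and feeds selection", {
  fx <- fixture_superfamily()
  grid <- tibble::tibble(evalue_max = c(1e-5, 1e-5, 1e-15),
                         score_min = c(5, 20, 40))
  scan <- grid_scan(fx$hits, grid, fx$sim$records, n_ref = 3, seed = 3)
  expect_equal(nrow(scan), 3)
  expect_true(all(diff(scan$largest_component_size) <= 0))
  expect_true(all(scan$n_edges <= nrow(fx$hits)))

  chosen <- suppressWarnings(select_phylogeny_component(scan))
  if (any(scan$is_smallworld)) {
    expect_false(chosen$fallback)
    expect_equal(chosen$largest_component_size,
                 max(scan$largest_component_size[scan$is_smallworld]))
  } else {
    expect_true(chosen$fallback)
  }

  # explicit tie-breaking contract on a synthetic table
  tab <- tibble::tibble(
    evalue_max = c(1e-5, 1e-10), score_min = c(15, 20),
    n_nodes = 100, n_edges = 200,
    largest_component_size = c(50, 80),
    sigma = c(1.4, 1.2), is_smallworld = c(TRUE, TRUE),
    component = list(sprintf("a%d", 1:50), sprintf("b%d", 1:80))
  )
  expect_equal(select_phylogeny_component(tab)$largest_component_size, 80)
  tab$is_smallworld <- FALSE
  expect_warning(pick <- select_phylogeny_component(tab), "falling back")
  expect_equal(pick$sigma, 1.4)
  expect_true(pick$fallback)
})

test_that("representative selection prefers curated members deterministically", {
  recs <- sequence_records(
    sprintf("s%02d", 1:9), strrep("ACDEFGHIKL", 4),
    status = c("curated", "curated", rep("unreviewed", 5), "curated", "curated")
  )
  cl <- ssnat:::new_clustering(
    list(ssnat:::new_cluster(sprintf("s%02d", 1:7), 0.9, 0.9, cluster_id = 1L),
         ssnat:::new_cluster(sprintf("s%02d", 8:9), 0.9, 0.9, cluster_id = 2L)),
    recs$id, clustering_params(min_size = 1))

  reps <- select_representatives(cl, recs$id, recs, k = 3, seed = 5)
  r1 <- reps[reps$cluster_id == 1, ]
  expect_equal(sum(r1$status == "curated"), 2)  # both curated + 1 sampled
  expect_equal(nrow(r1), 3)
  r2 <- reps[reps$cluster_id == 2, ]
  expect_equal(nrow(r2), 2)  # capped at cluster size

  expect_identical(reps, select_representatives(cl, recs$id, recs, 3, seed = 5))

  # more curated members than k: lexicographically smallest ids win
  recs2 <- sequence_records(sprintf("c%d", 1:4), strrep("ACDEFGHIKL", 4),
                            status = "curated")
  cl2 <- ssnat:::new_clustering(
    list(ssnat:::new_cluster(recs2$id, 0.9, 0.9, cluster_id = 1L)),
    recs2$id, clustering_params(min_size = 1))
  expect_equal(select_representatives(cl2, recs2$id, recs2, 3, 1)$seq_id,
               c("c1", "c2", "c3"))
})
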