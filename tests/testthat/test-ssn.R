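toy_hits <- function(evalues, ids = NULL) {
  n <- (1 + sqrt(1 + 8 * length(evalues))) / 2
  prs <- combn(ids %||% sprintf("s%d", seq_len(n)), 2)
  tibble::tibble(
    query_id = prs[1, ], subject_id = prs[2, ],
    raw_score = 100, bit_score = 40, evalue = evalues,
    pct_identity = 50, aln_length = 100L
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("edge filtering, the E-value floor and the convergence ratio", {
  # E = 0 hits floor at edge score 180 and survive score_min 30
  h <- toy_hits(rep(0, 6))
  net <- build_ssn(h, evalue_max = 1e-15, score_min = 30)
  expect_equal(nrow(net$edges), 6)
  expect_true(all(net$edges$edge_score == 180))
  expect_equal(net$convergence_ratio, 1)  # complete K4

  # an edgeless network
  empty <- build_ssn(toy_hits(rep(1e-3, 6)), 1e-15, 30)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(empty$convergence_ratio, 0)

  # both thresholds must hold
  # score_min 30 removes the 1e-20 hit even though it passes the E cutoff
  mixed <- build_ssn(toy_hits(c(1e-40, 1e-20, 1e-10, 1e-40, 1e-5, 1)),
                     evalue_max = 1e-15, score_min = 30)
  expect_equal(nrow(mixed$edges), 2)
})

test_that("tightening thresholds never adds edges", {
  set.seed(61)
  h <- toy_hits(10^runif(45, -60, 0))
  grid <- expand.grid(e = c(1e-5, 1e-15, 1e-25), s = c(5, 15, 30))
  nets <- lapply(seq_len(nrow(grid)), function(i) {
    build_ssn(h, grid$e[i], grid$s[i])
  })
  key <- function(net) paste(net$edges$query_id, net$edges$subject_id)
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    if (grid$e[j] <= grid$e[i] && grid$s[j] >= grid$s[i]) {
      expect_true(all(key(nets[[j]]) %in% key(nets[[i]])))
    }
  }
  # convergence ratio bounded
  for (net in nets) {
    expect_gte(net$convergence_ratio, 0)
    expect_lte(net$convergence_ratio, 1)
  }
})

test_that("synthetic superfamily SSN components recover the planted families", {
  fx <- fixture_superfamily()
  comp <- ssn_components(fx$ssn)
  expect_equal(max(comp$component_id), 3)
  joined <- merge(comp, fx$sim$truth$membership,
                  by.x = "id", by.y = "seq_id")
  # each component is exactly one family
  expect_equal(adjusted_rand_index(joined$component_id, joined$family_id), 1)
})

test_that("records supply isolated nodes and exports round-trip", {
  recs <- sequence_records(sprintf("s%d", 1:5), strrep("ACDEFGHIKL", 4))
  net <- build_ssn(toy_hits(c(0, 0, 1), ids = c("s1", "s2", "s3")),
                   1e-15, 30, records = recs)
  expect_equal(nrow(net$nodes), 5)
  expect_equal(glance(net)$n_components, 3)  # connected triple + 2 isolated

  ep <- tempfile(fileext = ".tsv"); np <- tempfile(fileext = ".tsv")
  write_ssn_tsv(net, ep, np)
  expect_equal(nrow(read.table(ep, header = TRUE)), nrow(net$edges))
  gp <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gp)
  g2 <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::vcount(g2), 5)
  expect_equal(igraph::ecount(g2), nrow(net$edges))
})
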