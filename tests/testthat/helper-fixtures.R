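# Lazily built, cached fixtures shared across test files (built once per
# test run; everything is generated in code, nothing stored on disk).

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Three planted families x 10 sequences, plus hits and the SSN at the
# permissive validation thresholds.
fixture_superfamily <- function() {
  cache_fixture("superfamily", function() {
    specs <- lapply(1:3, function(i) {
      family_spec(sprintf("FAM%d", i), 10, target_within_identity = 0.75)
    })
    sim <- generate_superfamily(specs, seed = 7)
    hits <- all_vs_all(sim$records, evalue_cutoff = 1e-5)
    ssn <- build_ssn(hits, 1e-5, 5, sim$records)
    list(sim = sim, hits = hits, ssn = ssn,
         clustering = detect_clusters(ssn, clustering_params(min_size = 10)))
  })
}

# Two unit-weight triangles joined by one bridge edge.
fixture_two_triangles <- function() {
  graph_from_edges(c("a", "b", "b", "c", "a", "c",
                     "d", "e", "e", "f", "d", "f",
                     "c", "d"))
}

# Reference fingerprints, built once.
fixture_fingerprints <- function() {
  cache_fixture("fingerprints", nat_reference_fingerprints)
}

# Random-background sequences with one exact word planted per sequence.
planted_set <- function(word, n = 20, len = 150, seed = 5) {
  bg <- default_background()
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    s <- sample(amino_acids(), len, TRUE, prob = bg)
    off <- sample(seq_len(len - nchar(word)), 1)
    s[off:(off + nchar(word) - 1)] <- strsplit(word, "")[[1]]
    paste(s, collapse = "")
  }, character(1)))
}

# Hand-built SSN from an edge vector (pairs flattened) over given nodes.
manual_ssn <- function(edges, nodes) {
  hits <- tibble::tibble(
    query_id = edges[c(TRUE, FALSE)], subject_id = edges[c(FALSE, TRUE)],
    raw_score = 100, bit_score = 40, evalue = 1e-30,
    pct_identity = 80, aln_length = 100L
  )
  recs <- sequence_records(nodes, strrep("ACDEFGHIKL", 4))
  build_ssn(hits, 1e-5, 5, recs)
}

# Hand-built clustering from a list of member sets.
manual_clustering <- function(member_sets, all_nodes) {
  cls <- lapply(seq_along(member_sets), function(i) {
    ssnat:::new_cluster(member_sets[[i]], 0.9, 0.9, cluster_id = i)
  })
  ssnat:::new_clustering(cls, all_nodes, clustering_params(min_size = 1))
}

# Adjusted Rand index between two label vectors (closed form from the
# pair-counting contingency table).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# A 4-letter toy scoring alphabet (subset of BLOSUM62) for the alignment
# and scanning oracles.
toy_alphabet <- c("A", "C", "D", "E")

toy_submatrix <- function() {
  m <- ssnat::align_params()$matrix
  m[toy_alphabet, toy_alphabet]
}

random_toy_sequence <- function(len) {
  paste(sample(toy_alphabet, len, replace = TRUE), collapse = "")
}

# Random toy PWM over the 4-letter alphabet (pseudocounted, no zeros).
random_toy_motif <- function(w = 3, conc = 0.5) {
  ppm <- matrix(0, 4, w, dimnames = list(toy_alphabet, NULL))
  for (c in seq_len(w)) {
    p <- runif(4) + c(conc, 0, 0, 0)[sample.int(4)]
    ppm[, c] <- p / sum(p)
  }
  bg <- setNames(rep(0.25, 4), toy_alphabet)
  new_motif(ppm, bg, name = "toy")
}
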