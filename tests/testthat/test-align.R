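test_that("self-alignment and hand-computed scores are exact", {
  hit <- align_pair("MDELWKVAQ", "MDELWKVAQ")
  expect_equal(hit$pct_identity, 100)
  expect_equal(hit$aln_length, 9L)

  # 4 x s(A,A) = 4 x 4 on BLOSUM62
  expect_equal(align_pair("AAAA", "AAAA")$raw_score, 16)

  expect_error(align_pair("ACDB", "ACDE"), "non-amino-acid")
})

test_that("alignment score is symmetric and E-values follow the bit formula", {
  p <- align_params()
  set.seed(11)
  for (k in 1:5) {
    a <- paste(sample(amino_acids(), 40, TRUE), collapse = "")
    b <- paste(sample(amino_acids(), 60, TRUE), collapse = "")
    h1 <- align_pair(a, b, p); h2 <- align_pair(b, a, p)
    expect_equal(h1$raw_score, h2$raw_score)
    expect_equal(h1$evalue, p$K * 40 * 60 * exp(-p$lambda * h1$raw_score))
    expect_equal(h1$bit_score, (p$lambda * h1$raw_score - log(p$K)) / log(2))
  }
})

test_that("scores match exhaustive trace enumeration on short sequences", {
  p <- align_params()
  sub <- toy_submatrix()
  set.seed(21)
  for (k in 1:30) {
    a <- random_toy_sequence(sample(3:12, 1))
    b <- random_toy_sequence(sample(3:12, 1))
    expect_equal(align_pair(a, b, p)$raw_score,
                 oracle_local_score(a, b, sub),
                 info = paste(a, b))
  }
})

test_that("E-value calibration: hit counts grow about linearly in the cutoff", {
  set.seed(31)
  bg <- default_background()
  n <- 1500
  ev <- vapply(seq_len(n), function(k) {
    a <- paste(sample(amino_acids(), 150, TRUE, prob = bg), collapse = "")
    b <- paste(sample(amino_acids(), 150, TRUE, prob = bg), collapse = "")
    align_pair(a, b)$evalue
  }, numeric(1))
  counts <- vapply(c(0.05, 0.1, 0.2, 0.4), function(e) sum(ev <= e), numeric(1))
  expect_true(all(diff(counts) > 0))
  # doubling the cutoff should roughly double the count (factor 4 over the
  # grid, generously banded for sampling noise and the approximate K-A fit)
  expect_gt(counts[4] / max(counts[1], 1), 2.0)
  expect_lt(counts[4] / max(counts[1], 1), 16)
})

test_that("all_vs_all reports exactly the qualifying unordered pairs", {
  ids <- c("s1", "s2", "s3")
  seqs <- rep("MDELWKVAQHGMDELWKVAQHGMDELWKVAQHGLL", 3)
  recs <- sequence_records(ids, seqs)
  hits <- all_vs_all(recs, evalue_cutoff = 1e-5, min_length = 10)
  expect_equal(nrow(hits), 3)
  expect_true(all(hits$query_id < hits$subject_id))

  # unrelated random 150-mers: far above a 1e-15 cutoff
  set.seed(41)
  r2 <- sequence_records(c("a", "b"), vapply(1:2, function(i) {
    paste(sample(amino_acids(), 150, TRUE), collapse = "")
  }, character(1)))
  pair <- align_pair(r2[1, ], r2[2, ])
  expect_gt(pair$evalue, 1e-10)
  expect_equal(nrow(all_vs_all(r2, evalue_cutoff = 1e-15)), 0)

  short_recs <- sequence_records(
    c("x", "y", "z"),
    c("ACDEFGHIKL", strrep("ACDEFGHIKL", 5), strrep("ACDEFGHIKL", 5))
  )
  expect_warning(all_vs_all(short_recs), "shorter than")
})

test_that("redundancy filter keeps non-redundant and curated sequences", {
  # two identical sequences collapse
  recs <- sequence_records(c("a", "b"), rep(strrep("MDELWKVAQH", 4), 2))
  res <- redundancy_filter(recs, 0.7)
  expect_equal(nrow(res$representatives), 1)
  expect_equal(unique(res$assignment$representative_id),
               res$representatives$id)

  # mutually dissimilar sequences are all retained
  set.seed(51)
  dis <- sequence_records(sprintf("d%d", 1:5), vapply(1:5, function(i) {
    paste(sample(amino_acids(), 80, TRUE), collapse = "")
  }, character(1)))
  expect_equal(nrow(redundancy_filter(dis, c(0.9, 0.8, 0.7))$representatives), 5)

  # 10 near-copies of one ancestor + 1 unrelated -> 2 representatives
  anc <- paste(sample(amino_acids(), 100, TRUE), collapse = "")
  copies <- vapply(1:10, function(i) mutate_sequence(anc, 0.98, seed = i),
                   character(1))
  idy <- vapply(copies[-1], function(s) sequence_identity(copies[1], s),
                numeric(1))
  expect_true(all(idy >= 0.9))  # verified before trusting the collapse
  fam <- sequence_records(
    c(sprintf("c%02d", 1:10), "lone"),
    c(copies, paste(sample(amino_acids(), 100, TRUE), collapse = ""))
  )
  expect_equal(nrow(redundancy_filter(fam, 0.9)$representatives), 2)

  # curated members are never absorbed
  cur <- sequence_records(c("u", "v"), rep(strrep("MDELWKVAQH", 4), 2),
                          status = c("curated", "curated"))
  expect_equal(nrow(redundancy_filter(cur, 0.7)$representatives), 2)

  empty <- redundancy_filter(sequence_records(character(), character()), 0.7)
  expect_equal(nrow(empty$representatives), 0)
})
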