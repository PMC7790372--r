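test_that("generator produces the requested families deterministically", {
  specs <- lapply(1:3, function(i) family_spec(sprintf("F%d", i), 10))
  sim1 <- generate_superfamily(specs, seed = 7)
  expect_equal(nrow(sim1$records), 30)
  expect_equal(sort(unique(sim1$truth$membership$family_id)),
               c("F1", "F2", "F3"))
  expect_true(all(table(sim1$truth$membership$seq_id) == 1))

  # byte-identical FASTA on rerun with the same seed
  sim2 <- generate_superfamily(specs, seed = 7)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta_records(sim1$records, f1)
  write_fasta_records(sim2$records, f2)
  expect_identical(readLines(f1), readLines(f2))

  # at least one curated labelled member per family even at small fractions
  lab <- sim1$records[sim1$records$status == "curated", ]
  expect_true(all(c("F1", "F2", "F3") %in% lab$label))
})

test_that("generator rejects impossible motif layouts", {
  bad_overlap <- tibble::tibble(
    element = c("a1a2", "b4"), consensus = c("AAAAA", "CCCCC"),
    offset = c(10, 12)
  )
  expect_error(family_spec("F", 5, motifs = bad_overlap), "overlap")
  bad_fit <- tibble::tibble(element = "b6b7", consensus = "AAAAA", offset = 148)
  expect_error(family_spec("F", 5, motifs = bad_fit), "fit inside")
})

test_that("mutate_sequence honours its substitution contract", {
  parent <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  expect_identical(mutate_sequence(parent, 1.0, seed = 3), parent)

  out <- mutate_sequence(parent, 0.8, seed = 3)
  diffs <- sum(strsplit(parent, "")[[1]] != strsplit(out, "")[[1]])
  expect_equal(diffs, 20)
  expect_equal(nchar(out), nchar(parent))

  expect_identical(mutate_sequence(parent, 0.8, seed = 3), out)
  expect_error(mutate_sequence(parent, 0), "target_identity")
})

test_that("realized identities track the generator targets", {
  fx <- fixture_superfamily()
  r <- fx$sim$records
  fam <- split(r$id, fx$sim$truth$membership$family_id[
    match(r$id, fx$sim$truth$membership$seq_id)])
  within <- unlist(lapply(fam, function(ids) {
    prs <- combn(ids, 2)
    vapply(seq_len(ncol(prs)), function(k) {
      sequence_identity(r$residues[r$id == prs[1, k]],
                        r$residues[r$id == prs[2, k]])
    }, numeric(1))
  }))
  expect_gt(mean(within), 0.70)
  expect_lt(mean(within), 0.85)

  between <- vapply(1:15, function(k) {
    a <- sample(fam[[1]], 1); b <- sample(fam[[2]], 1)
    sequence_identity(r$residues[r$id == a], r$residues[r$id == b])
  }, numeric(1))
  expect_lt(mean(between), 0.15)
})

test_that("planted motif consensus stays modal across family members", {
  fx <- fixture_superfamily()
  r <- fx$sim$records
  planted <- fx$sim$truth$planted_motifs
  pos <- fx$sim$truth$motif_positions
  for (k in seq_len(nrow(planted))) {
    fam_ids <- fx$sim$truth$membership$seq_id[
      fx$sim$truth$membership$family_id == planted$family_id[k]]
    iv <- pos[pos$seq_id == fam_ids[1] & pos$element == planted$element[k], ]
    words <- substr(r$residues[match(fam_ids, r$id)], iv$start + 1, iv$end)
    cons <- strsplit(planted$consensus[k], "")[[1]]
    modal <- vapply(seq_along(cons), function(c) {
      names(sort(table(substr(words, c, c)), decreasing = TRUE))[1]
    }, character(1))
    expect_identical(modal, cons)
  }
})

test_that("Z-score matrix fixture has the promised block structure", {
  truth <- tibble::tibble(seq_id = sprintf("s%d", 1:8),
                          family_id = rep(c("A", "B"), each = 4))
  Z0 <- generate_zscore_matrix(truth, 20, 5, sd = 0, seed = 1)
  expect_identical(Z0, t(Z0))
  same <- outer(truth$family_id, truth$family_id, `==`)
  off <- upper.tri(Z0)
  expect_true(all(Z0[off][same[off]] == 20))
  expect_true(all(Z0[off][!same[off]] == 5))
  expect_true(all(diag(Z0) == max(Z0)))

  Z1 <- generate_zscore_matrix(truth, 20, 5, sd = 1, seed = 2)
  win <- Z1[off][same[off]]
  expect_lt(abs(mean(win) - 20), 3 * 1 / sqrt(length(win)))
  expect_error(generate_zscore_matrix(truth, 5, 5), "exceed")
})
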