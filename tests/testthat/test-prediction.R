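test_that("annotation transfer follows the isofunctionality rules", {
  nodes <- sprintf("s%02d", 1:10)
  cl <- manual_clustering(list(nodes), nodes)

  # one curated label spreads to the whole cluster
  recs <- sequence_records(nodes, strrep("ACDEFGHIKL", 4),
                           status = c("curated", rep("unreviewed", 9)),
                           label = c("NAA50", rep("unknown", 9)))
  out <- transfer_annotations(cl, recs)
  expect_equal(out$clusters$label, "NAA50")
  expect_equal(sum(out$annotations$provenance == "transferred"), 9)
  expect_true(all(out$annotations$label == "NAA50"))

  # conflicting curated labels: mixed, no transfer, curated labels kept
  recs2 <- sequence_records(nodes, strrep("ACDEFGHIKL", 4),
                            status = c("curated", "curated",
                                       rep("unreviewed", 8)),
                            label = c("NAA50", "NAA60", rep("unknown", 8)))
  out2 <- transfer_annotations(cl, recs2)
  expect_equal(out2$clusters$label, "mixed")
  expect_equal(out2$annotations$label[1:2], c("NAA50", "NAA60"))
  expect_true(all(out2$annotations$label[3:10] == "unknown"))

  # no labelled member: uncharacterized
  recs3 <- sequence_records(nodes, strrep("ACDEFGHIKL", 4))
  expect_equal(transfer_annotations(cl, recs3)$clusters$label,
               "uncharacterized")
})

# A pivot neighbourhood: known Group 2 cluster (1) with three
# uncharacterized neighbours - one rebuilt from the same fingerprint (2),
# one with a planted F->L modal change in the alpha1-alpha2 loop (3), and
# one of random sequences (4).
prediction_fixture <- function() {
  cache_fixture("prediction", function() {
    fps <- nat_reference_fingerprints()
    variant <- sub("^FP", "LP", nat_reference_regexes()$regex[
      nat_reference_regexes()$group == "Group 2"])
    g2 <- fps[["Group 2"]]
    mk <- function(prefix, n, generator, seed0) {
      sequence_records(
        sprintf("%s%02d", prefix, seq_len(n)),
        vapply(seq_len(n), function(i) generator(seed0 + i), character(1))
      )
    }
    known <- mk("kn", 8, function(s) sample_group_sequence(g2, seed = s), 100)
    known$status[1:2] <- "curated"
    known$label[1:2] <- "NAA50"
    same <- mk("sm", 8, function(s) sample_group_sequence(g2, seed = s), 200)
    divg <- mk("dv", 8, function(s) sample_group_sequence(variant, seed = s), 300)
    bg <- default_background()
    rand <- mk("rn", 8, function(s) {
      withr::with_seed(s, paste(sample(amino_acids(), 150, TRUE, prob = bg),
                                collapse = ""))
    }, 400)
    records <- dplyr::bind_rows(known, same, divg, rand)
    nodes <- records$id
    bridge <- c("kn01", "sm01", "kn02", "dv01", "kn03", "rn01")
    within <- unlist(lapply(list(known$id, same$id, divg$id, rand$id),
                            function(ids) {
                              as.vector(rbind(ids[-length(ids)], ids[-1]))
                            }))
    ssn <- manual_ssn(c(within, bridge), nodes)
    clustering <- manual_clustering(
      list(known$id, same$id, divg$id, rand$id), nodes)
    clustering <- transfer_annotations(clustering, records)
    list(records = records, ssn = ssn, clustering = clustering,
         pivot = contract(ssn, clustering), fps = fps)
  })
}

test_that("candidate nomination separates consistent, divergent and no-match", {
  fx <- prediction_fixture()
  expect_equal(fx$clustering$clusters$label,
               c("NAA50", rep("uncharacterized", 3)))
  rep <- predict_nat_candidates(fx$pivot, fx$clustering, fx$fps,
                                fx$records, alpha = 0.01)
  expect_setequal(rep$cluster_id, 2:4)
  expect_true(all(vapply(rep$neighbour_of, identical, logical(1), 1L)))

  same_row <- rep[rep$cluster_id == 2, ]
  expect_equal(same_row$best_group, "Group 2")
  expect_equal(same_row$verdict, "consistent")
  expect_equal(same_row$n_key_differences, 0L)

  div_row <- rep[rep$cluster_id == 3, ]
  expect_equal(div_row$best_group, "Group 2")
  expect_equal(div_row$verdict, "divergent")
  key <- div_row$differences[[1]]
  key <- key[key$key, ]
  expect_equal(nrow(key), 1)
  expect_equal(key$element, "a1a2")
  expect_equal(key$residue_1, "F")
  expect_equal(key$residue_2, "L")

  rand_row <- rep[rep$cluster_id == 4, ]
  expect_equal(rand_row$verdict, "no-match")
  expect_lt(rand_row$fraction_members, 0.5)
  expect_gt(rand_row$cluster_p, 0.05)

  # deterministic report
  rep2 <- predict_nat_candidates(fx$pivot, fx$clustering, fx$fps,
                                 fx$records, alpha = 0.01)
  expect_identical(rep$verdict, rep2$verdict)
  expect_identical(rep$cluster_p, rep2$cluster_p)

  # candidates are a subset of uncharacterized clusters
  expect_false(1L %in% rep$cluster_id)

  # report writers
  tp <- tempfile(fileext = ".tsv"); xp <- tempfile(fileext = ".txt")
  write_candidate_report(rep, tp, xp)
  expect_equal(nrow(read.table(tp, sep = "\t", header = TRUE)), 3)
  expect_true(any(grepl("replaced by", readLines(xp))))
})

test_that("prediction refuses to run without a known-NAT cluster", {
  fx <- prediction_fixture()
  unlabelled <- fx$clustering
  unlabelled$clusters$label <- "uncharacterized"
  expect_error(
    predict_nat_candidates(fx$pivot, unlabelled, fx$fps, fx$records, 0.01),
    "no known-NAT cluster"
  )
})
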