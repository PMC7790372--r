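test_that("the penalised ZOOPS log-likelihood never decreases", {
  seqs <- planted_set("YYAEKKWPG", n = 8, len = 60, seed = 2)
  enc <- ssnat:::encode_residues(seqs)
  bg <- sequence_background(seqs)
  win <- ssnat:::build_windows(enc, 9, lapply(enc, function(x) rep(FALSE, length(x))))
  word_idx <- match(strsplit("YYAEKKWPG", "")[[1]], amino_acids())
  fit <- ssnat:::zoops_em(win, ssnat:::seed_ppm(word_idx, bg), bg)
  expect_gte(min(diff(fit$ll)), -1e-8)
  expect_true(all(abs(colSums(fit$ppm) - 1) < 1e-9))
  expect_true(all(fit$ppm > 0))
})

test_that("a planted word is recovered with a significant E-value", {
  seqs <- planted_set("YYAEKKWPG", seed = 5)
  motifs <- discover_motifs(seqs, max_motifs = 3, seed = 3, n_shuffle = 10)
  expect_gte(length(motifs), 1)
  top <- motifs[[1]]
  expect_lt(top$evalue, 1)
  expect_gte(top$n_sites, 18)

  # modal consensus matches >= 8/9 planted columns at the best offset
  modal <- apply(top$ppm, 2, function(p) names(which.max(p)))
  planted <- strsplit("YYAEKKWPG", "")[[1]]
  best_match <- max(vapply(seq_len(top$width - 9 + 1) - 1, function(off) {
    sum(modal[off + seq_len(9)] == planted)
  }, numeric(1)), na.rm = TRUE)
  expect_gte(best_match, 8)
})

test_that("duplicating every input doubles the site count, not the motif", {
  seqs <- planted_set("HSFLPYYYSI", n = 10, len = 80, seed = 9)
  m1 <- discover_motifs(seqs, max_motifs = 1, seed = 4, n_shuffle = 10)
  m2 <- discover_motifs(c(seqs, seqs), max_motifs = 1, seed = 4, n_shuffle = 10)
  expect_gte(length(m1), 1); expect_gte(length(m2), 1)
  cons1 <- apply(m1[[1]]$ppm, 2, function(p) names(which.max(p)))
  cons2 <- apply(m2[[1]]$ppm, 2, function(p) names(which.max(p)))
  # same core consensus (widths may differ by a flank column)
  expect_true(grepl("HSFLPYYYSI", paste(cons2, collapse = "")) ==
                grepl("HSFLPYYYSI", paste(cons1, collapse = "")))
  expect_gte(m2[[1]]$n_sites, 2 * m1[[1]]$n_sites - 2)
})

test_that("discovery input contracts are enforced", {
  expect_error(discover_motifs(planted_set("YYAEKKW", n = 4)), "at least 5")
  expect_error(discover_motifs(planted_set("YYAEKKW", n = 6),
                               width_range = 3:6), "within 5..10")
})

test_that("consensus regex generation follows the column rules", {
  bg <- default_background()
  ppm <- matrix(bg, 20, 3, dimnames = list(names(bg), NULL))
  ppm[, 1] <- 0; ppm["Y", 1] <- 1
  ppm[, 2] <- 0; ppm[c("V", "I"), 2] <- c(0.5, 0.4); ppm["A", 2] <- 0.1
  m <- new_motif(sweep(ppm, 2, colSums(ppm), `/`), bg)
  rex <- regex_from_motif(m)
  expect_equal(substr(rex, 1, 1), "Y")
  expect_true(grepl("^Y\\[VI\\]", rex))
  expect_equal(substr(rex, nchar(rex), nchar(rex)), "X")  # uniform column
  expect_error(regex_from_motif(m, include_threshold = 0.9), "include_threshold")
})

test_that("regexes round-trip through sampled PPMs on most columns", {
  tab <- nat_reference_regexes()
  bg <- default_background()
  set.seed(131)
  agree <- total <- 0
  for (k in seq_len(nrow(tab))) {
    cols <- ssnat:::parse_motif_regex(tab$regex[k])
    words <- vapply(1:100, function(i) {
      paste(vapply(cols, function(set) {
        if (ssnat:::is_wildcard(set)) sample(amino_acids(), 1, prob = bg)
        else sample(rep(unlist(set), 2), 1)
      }, character(1)), collapse = "")
    }, character(1))
    counts <- matrix(0, 20, length(cols), dimnames = list(amino_acids(), NULL))
    for (wd in words) {
      ch <- strsplit(wd, "")[[1]]
      counts[cbind(match(ch, amino_acids()), seq_along(ch))] <-
        counts[cbind(match(ch, amino_acids()), seq_along(ch))] + 1
    }
    m <- new_motif(sweep(counts + 1e-9, 2, colSums(counts + 1e-9), `/`), bg)
    got <- ssnat:::parse_motif_regex(regex_from_motif(m))
    for (c in seq_along(cols)) {
      total <- total + 1
      want <- if (ssnat:::is_wildcard(cols[[c]])) "X" else
        paste(sort(unlist(cols[[c]])), collapse = "")
      have <- if (ssnat:::is_wildcard(got[[c]])) "X" else
        paste(sort(unlist(got[[c]])), collapse = "")
      if (want == have) agree <- agree + 1
    }
  }
  expect_gte(agree / total, 0.9)
})
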