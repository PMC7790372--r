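#' Construct a group fingerprint
#'
#' A fingerprint is the ordered set of key-element motifs characterising a
#' NAT group: one motif per fold element (alpha1-alpha2 loop, beta4,
#' beta5, beta6-beta7 loop), labelled by element.
#'
#' @param name Group name (e.g. `"Group 2"`).
#' @param motifs Named list of `nat_motif` objects; names are the element
#'   labels and must be unique.
#' @return A `group_fingerprint` object.
#' @export
group_fingerprint <- function(name, motifs) {
  if (!length(motifs) || is.null(names(motifs)) || anyDuplicated(names(motifs))) {
    abort("`motifs` must be a non-empty uniquely-named list")
  }
  stopifnot(all(vapply(motifs, inherits, logical(1), "nat_motif")))
  for (el in names(motifs)) motifs[[el]]$element <- el
  structure(list(name = name, motifs = motifs), class = "group_fingerprint")
}

#' @export
print.group_fingerprint <- function(x, ...) {
  cat(sprintf("Fingerprint %s (%d motifs):\n", x$name, length(x$motifs)))
  for (el in names(x$motifs)) {
    cat(sprintf("  %-5s %s\n", el, regex_from_motif(x$motifs[[el]])))
  }
  invisible(x)
}

# Parse a motif regex of the Table-style dialect: bare letters, bracketed
# alternative sets, and X wildcards. Returns a list of character vectors
# (NULL for wildcard columns).
parse_motif_regex <- function(regex) {
  out <- list()
  i <- 1
  chars <- strsplit(regex, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1
      set <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        set <- c(set, chars[j]); j <- j + 1
      }
      if (j > length(chars)) abort("unterminated [ ] set in regex")
      out[[length(out) + 1]] <- set
      i <- j + 1
    } else if (ch %in% c("X", ".")) {
      out[[length(out) + 1]] <- NULL_column()
      i <- i + 1
    } else if (ch %in% amino_acids()) {
      out[[length(out) + 1]] <- ch
      i <- i + 1
    } else {
      abort(sprintf("unsupported regex character '%s'", ch))
    }
  }
  out
}

NULL_column <- function() structure(list(), class = "wildcard_column")
is_wildcard <- function(x) inherits(x, "wildcard_column")

#' Build a motif from a consensus regex
#'
#' Listed residues share `match_weight` of the probability mass equally
#' (plus their share of the background remainder); wildcard (`X`) columns
#' take the background distribution. The inverse of [regex_from_motif()]
#' up to sampling noise.
#'
#' @param regex Regex string over bare letters, `[..]` sets and `X`.
#' @param background Background frequencies (motif alphabet).
#' @param match_weight Probability mass concentrated on listed residues.
#' @param element,name Passed to [new_motif()].
#' @return A `nat_motif`.
#' @export
motif_from_regex <- function(regex, background = default_background(),
                             match_weight = 0.9, element = NA_character_,
                             name = regex) {
  background <- check_background(background)
  cols <- parse_motif_regex(regex)
  ppm <- vapply(cols, function(set) {
    if (is_wildcard(set)) return(background)
    p <- (1 - match_weight) * background
    p[unlist(set)] <- p[unlist(set)] + match_weight / length(unlist(set))
    p / sum(p)
  }, numeric(20))
  rownames(ppm) <- amino_acids()
  m <- new_motif(ppm, background, element = element, name = name)
  m$consensus_regex <- regex
  m
}

#' Reference key-motif regular expressions of the five NAT groups
#'
#' The curated regular expressions for the key fold-element motifs
#' (alpha1-alpha2 loop, beta4 strand, beta5 strand, beta6-beta7 loop) of
#' NAT Groups 1a, 1b, 2, 3 and 4. Groups 3 and 4 have no conserved
#' beta6-beta7 motif. These are the fingerprints used to assign candidate
#' clusters to groups.
#'
#' @return Tibble: `group`, `element`, `regex`.
#' @export
nat_reference_regexes <- function() {
  tibble::tribble(
    ~group,      ~element, ~regex,
    "Group 1a",  "a1a2",   "[CV]NLD[CN]L[PT]E[NT]Y",
    "Group 1a",  "b4",     "[WP]HGH[IV]T[SA][LV][STA]V",
    "Group 1a",  "b5",     "[FY]V[DS]L[FH]VR[VK]SN",
    "Group 1a",  "b6b7",   "[VI]X[ED][VI]E[KP]KYYA",
    "Group 1b",  "a1a2",   "L[IV][DQ]K[DE]LSEPY",
    "Group 1b",  "b4",     "RGYIAMLAVD",
    "Group 1b",  "b5",     "E[VI]VLETE[VI][TD]N",
    "Group 1b",  "b6b7",   "R[DE]KRL[FH]RYYL",
    "Group 2",   "a1a2",   "FP[VI]XY[PNS][DE][KS][FW]Y",
    "Group 2",   "b4",     "[ML][TS]LGVLAPYR",
    "Group 2",   "b5",     "A[IV][YF]LHV[QL][TV][ST]N",
    "Group 2",   "b6b7",   "HS[FY]LPYYYSI",
    "Group 3",   "a1a2",   "YEQSSWGW[DN][DE]",
    "Group 3",   "b4",     "VLYCYE[IL]Q[LV]E",
    "Group 3",   "b5",     "KV[MV]LTV[FL]KHN",
    "Group 4",   "a1a2",   "CA[DE]L[LI]N[ES][EQ]W[PK]",
    "Group 4",   "b4",     "[SA][LC][FL]VE[ST]VVV[AS]",
    "Group 4",   "b5",     "L[TS]THDKQHFY"
  )
}

#' Reference fingerprints of the five NAT groups
#'
#' [nat_reference_regexes()] converted to scannable motif fingerprints
#' via [motif_from_regex()].
#'
#' @param background Background frequencies used for the motif PPMs.
#' @param match_weight Passed to [motif_from_regex()].
#' @return Named list of `group_fingerprint` objects.
#' @export
nat_reference_fingerprints <- function(background = default_background(),
                                       match_weight = 0.9) {
  tab <- nat_reference_regexes()
  lapply(split(tab, tab$group), function(g) {
    motifs <- setNames(
      lapply(seq_len(nrow(g)), function(i) {
        motif_from_regex(g$regex[i], background, match_weight,
                         element = g$element[i],
                         name = paste(g$group[i], g$element[i]))
      }),
      g$element
    )
    group_fingerprint(g$group[1], motifs)
  })
}

#' Sample a sequence realising a set of element regexes
#'
#' Draws one word per regex (uniform over bracketed alternatives,
#' background for wildcards) and embeds the words at the canonical fold
#' offsets in a background-sampled scaffold. Used to synthesise
#' group-typical sequences for validation.
#'
#' @param regexes Character vector of regexes (one per element, in fold
#'   order) or a `group_fingerprint` (consensus regexes are used).
#' @param seq_length Total sequence length.
#' @param background Background frequencies.
#' @param seed Integer seed.
#' @return Residue string.
#' @export
sample_group_sequence <- function(regexes, seq_length = 150,
                                  background = default_background(),
                                  seed = 1) {
  if (inherits(regexes, "group_fingerprint")) {
    regexes <- vapply(regexes$motifs, function(m) {
      m$consensus_regex %||% regex_from_motif(m)
    }, character(1))
  }
  background <- check_background(background)
  with_seed_(seed, {
    chars <- sample(amino_acids(), seq_length, replace = TRUE, prob = background)
    offs <- fold_element_offsets(seq_length)[seq_along(regexes)]
    for (k in seq_along(regexes)) {
      cols <- parse_motif_regex(regexes[k])
      word <- vapply(cols, function(set) {
        if (is_wildcard(set)) sample(amino_acids(), 1, prob = background)
        else sample(unlist(set), 1)
      }, character(1))
      chars[offs[k] + seq_along(word)] <- word
    }
    paste(chars, collapse = "")
  })
}

#' Report per-position differences between two fingerprints
#'
#' For each element shared by both fingerprints, the two motifs are
#' aligned at the ungapped offset maximising the mean column-wise Pearson
#' correlation of their PPMs, and every aligned column whose modal
#' residues differ is reported with both residues and their frequencies.
#' A difference is flagged `key` when the first fingerprint's modal
#' frequency is at least `key_freq` (a proxy for mutation-sensitive
#' positions).
#'
#' @param f1,f2 `group_fingerprint` objects sharing at least one element.
#' @param key_freq Modal-frequency threshold for flagging key positions.
#' @return Tibble: `element`, `position_1`, `position_2` (0-based column
#'   indices), `residue_1`, `freq_1`, `residue_2`, `freq_2`, `key`.
#' @export
diff_fingerprints <- function(f1, f2, key_freq = 0.7) {
  shared <- intersect(names(f1$motifs), names(f2$motifs))
  if (!length(shared)) {
    warn("fingerprints share no element labels; empty difference report")
    return(tibble(element = character(), position_1 = integer(),
                  position_2 = integer(), residue_1 = character(),
                  freq_1 = numeric(), residue_2 = character(),
                  freq_2 = numeric(), key = logical()))
  }
  bind_rows(lapply(shared, function(el) {
    m1 <- f1$motifs[[el]]; m2 <- f2$motifs[[el]]
    off <- best_ungapped_offset(m1$ppm, m2$ppm)
    diff_aligned_columns(m1, m2, off, el, key_freq)
  }))
}

# Offset of motif 2 relative to motif 1 (column j of m2 aligns with column
# j + off of m1) maximising mean column-wise Pearson correlation, with at
# least 4 overlapping columns (or the maximum possible).
best_ungapped_offset <- function(p1, p2) {
  w1 <- ncol(p1); w2 <- ncol(p2)
  min_ov <- min(4, w1, w2)
  best_off <- 0; best_cor <- -Inf
  for (off in seq(-(w2 - 1), w1 - 1)) {
    j2 <- seq_len(w2)
    j1 <- j2 + off
    ok <- j1 >= 1 & j1 <= w1
    if (sum(ok) < min_ov) next
    cors <- vapply(which(ok), function(j) {
      suppressWarnings(cor(p1[, j + off], p2[, j]))
    }, numeric(1))
    m <- mean(cors, na.rm = TRUE)
    if (m > best_cor + 1e-12) {
      best_cor <- m; best_off <- off
    }
  }
  best_off
}

diff_aligned_columns <- function(m1, m2, off, element, key_freq) {
  rows <- list()
  for (j2 in seq_len(m2$width)) {
    j1 <- j2 + off
    if (j1 < 1 || j1 > m1$width) next
    c1 <- m1$ppm[, j1]; c2 <- m2$ppm[, j2]
    r1 <- names(which.max(c1)); r2 <- names(which.max(c2))
    if (r1 != r2) {
      rows[[length(rows) + 1]] <- tibble(
        element = element,
        position_1 = j1 - 1L, position_2 = j2 - 1L,
        residue_1 = r1, freq_1 = unname(c1[r1]),
        residue_2 = r2, freq_2 = unname(c2[r2]),
        key = unname(c1[r1]) >= key_freq
      )
    }
  }
  if (length(rows)) bind_rows(rows) else
    tibble(element = character(), position_1 = integer(),
           position_2 = integer(), residue_1 = character(),
           freq_1 = numeric(), residue_2 = character(),
           freq_2 = numeric(), key = logical())
}

#' Write motifs in MEME minimal format
#'
#' Version header, alphabet and background lines, and one
#' letter-probability matrix block per motif, readable by MEME-suite
#' scanners.
#'
#' @param motifs List of `nat_motif` objects (or a `group_fingerprint`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme_minimal <- function(motifs, path) {
  if (inherits(motifs, "group_fingerprint")) motifs <- motifs$motifs
  con <- file(path, "w")
  on.exit(close(con))
  bg <- motifs[[1]]$background
  writeLines(c(
    "MEME version 4", "",
    sprintf("ALPHABET= %s", paste(names(bg), collapse = "")), "",
    "Background letter frequencies",
    paste(sprintf("%s %.5f", names(bg), bg), collapse = " "), ""
  ), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", gsub(" ", "_", m$name)), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= %d w= %d nsites= %d E= %s",
      length(m$alphabet), m$width,
      ifelse(is.na(m$n_sites), 0L, m$n_sites),
      format(ifelse(is.na(m$evalue), 1, m$evalue), digits = 3)
    ), con)
    for (c in seq_len(m$width)) {
      writeLines(paste(sprintf("%.6f", m$ppm[, c]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write a regex fingerprint table as TSV
#'
#' Columns `group`, `element`, `regex`, mirroring the reference table of
#' key-motif regular expressions.
#'
#' @param fingerprints Named list of `group_fingerprint` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_tsv <- function(fingerprints, path) {
  tab <- bind_rows(lapply(fingerprints, function(fp) {
    tibble(group = fp$name, element = names(fp$motifs),
           regex = vapply(fp$motifs, function(m) {
             m$consensus_regex %||% regex_from_motif(m)
           }, character(1)))
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
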