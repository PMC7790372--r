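#' Construct a motif object
#'
#' A motif is a position probability matrix (PPM) over an alphabet
#' (rows) with one column per motif position. Columns must sum to 1.
#' Discovery produces motifs over the 20 standard amino acids with widths
#' 5-10; the constructor itself accepts any alphabet/width so that toy
#' motifs can be built for scanning checks.
#'
#' @param ppm Numeric matrix, rows named by alphabet letters, columns
#'   summing to 1.
#' @param background Named background frequencies over the same alphabet.
#' @param n_sites Number of sequences contributing a site.
#' @param evalue Motif E-value (empirical shuffle null), `NA` if unknown.
#' @param objective Discovery objective (information content x site
#'   count), `NA` if unknown.
#' @param sites Optional tibble of site calls (`seq_id`, `start`,
#'   `posterior`), 0-based starts.
#' @param element Optional fold-element label (`"a1a2"`, `"b4"`, `"b5"`,
#'   `"b6b7"`) or `NA`.
#' @param name Motif name.
#' @return A `nat_motif` object.
#' @export
new_motif <- function(ppm, background, n_sites = NA_integer_,
                      evalue = NA_real_, objective = NA_real_,
                      sites = NULL, element = NA_character_,
                      name = "motif") {
  stopifnot(is.matrix(ppm), !is.null(rownames(ppm)))
  if (any(abs(colSums(ppm) - 1) > 1e-9)) abort("PPM columns must sum to 1")
  background <- background[rownames(ppm)]
  if (any(is.na(background))) abort("background must cover the motif alphabet")
  structure(
    list(ppm = ppm, width = ncol(ppm), alphabet = rownames(ppm),
         background = background / sum(background),
         n_sites = n_sites, evalue = evalue, objective = objective,
         consensus_regex = NULL, sites = sites,
         element = element, name = name),
    class = "nat_motif"
  )
}

#' @export
print.nat_motif <- function(x, ...) {
  cat(sprintf("Motif %s: width %d, %s site(s), E-value %s\n  consensus %s\n",
              x$name, x$width,
              ifelse(is.na(x$n_sites), "?", x$n_sites),
              ifelse(is.na(x$evalue), "?", format(x$evalue, digits = 3)),
              regex_from_motif(x)))
  invisible(x)
}

motif_information <- function(motif) {
  lr <- log2(motif$ppm / motif$background)
  lr[motif$ppm == 0] <- 0
  sum(motif$ppm * lr)
}

#' Consensus regular expression of a motif
#'
#' Per column, residues with probability at or above the inclusion
#' threshold: one residue gives a bare letter, two or three a bracketed
#' set ordered by descending probability, more than three (or none) the
#' wildcard `X`.
#'
#' @param motif A `nat_motif`.
#' @param include_threshold Inclusion threshold in (0, 0.5].
#' @return Regex string.
#' @export
regex_from_motif <- function(motif, include_threshold = 0.2) {
  if (include_threshold <= 0 || include_threshold > 0.5) {
    abort("`include_threshold` must be in (0, 0.5]")
  }
  cols <- vapply(seq_len(motif$width), function(c) {
    p <- motif$ppm[, c]
    keep <- names(sort(p[p >= include_threshold], decreasing = TRUE))
    if (length(keep) == 1) keep
    else if (length(keep) %in% 2:3) paste0("[", paste(keep, collapse = ""), "]")
    else "X"
  }, character(1))
  paste(cols, collapse = "")
}

# ---- ZOOPS EM internals -----------------------------------------------------

# Window view of a masked, integer-encoded sequence set for one width:
# a matrix of residue indices (rows = windows), the linear index matrix
# into a vectorised (A x w) score matrix, and the per-sequence grouping.
build_windows <- function(enc, w, masks) {
  rows <- list(); grp <- list(); starts <- list()
  for (i in seq_along(enc)) {
    x <- enc[[i]]
    L <- length(x)
    if (L < w) next
    st <- seq_len(L - w + 1)
    bad <- is.na(x) | masks[[i]]
    if (any(bad)) {
      badwin <- vapply(st, function(s) any(bad[s:(s + w - 1)]), logical(1))
      st <- st[!badwin]
    }
    if (!length(st)) next
    W <- outer(st, 0:(w - 1), `+`)
    rows[[length(rows) + 1]] <- matrix(x[W], nrow = length(st))
    grp[[length(grp) + 1]] <- rep(i, length(st))
    starts[[length(starts) + 1]] <- st
  }
  if (!length(rows)) return(NULL)
  W <- do.call(rbind, rows)
  A <- 20L
  idx <- W + matrix(rep((0:(w - 1)) * A, each = nrow(W)), nrow(W), w)
  grp <- unlist(grp)
  list(W = W, idx = idx, grp = grp, start = unlist(starts),
       grp_index = split(seq_along(grp), grp),
       n_seq = length(unique(grp)))
}

seed_ppm <- function(word_idx, bg, weight = 0.7) {
  w <- length(word_idx)
  ppm <- matrix(rep((1 - weight) * bg, w), nrow = 20,
                dimnames = list(names(bg), NULL))
  ppm[cbind(word_idx, seq_len(w))] <- ppm[cbind(word_idx, seq_len(w))] + weight
  sweep(ppm, 2, colSums(ppm), `/`)
}

# One ZOOPS EM run from a given starting PPM. Returns the fitted PPM,
# site-prior gamma, per-sequence site posteriors/positions and the
# (Dirichlet-penalised) log-likelihood trajectory, which is non-decreasing.
zoops_em <- function(win, ppm, bg, site_prior = 0.8, max_iter = 200,
                     tol = 1e-4, pseudocount = 0.01) {
  w <- ncol(ppm)
  gamma <- site_prior
  lbg <- log(bg)
  ll_trace <- numeric(0)
  m_per_seq <- lengths(win$grp_index)
  z <- NULL
  for (iter in seq_len(max_iter)) {
    lr <- log(ppm) - matrix(lbg, 20, w)
    S <- rowSums(matrix(as.vector(lr)[win$idx], nrow = nrow(win$idx)))
    # per-sequence log-sum-exp of window scores
    post_site <- numeric(length(m_per_seq))
    z <- numeric(length(S))
    ll <- 0
    for (k in seq_along(win$grp_index)) {
      jj <- win$grp_index[[k]]
      Sk <- S[jj]
      M <- max(Sk)
      t <- exp(Sk - M)
      st <- sum(t)
      log_site <- log(gamma / length(jj)) + M + log(st)
      log_none <- log1p(-gamma)
      Mx <- max(log_site, log_none)
      ll <- ll + Mx + log(exp(log_site - Mx) + exp(log_none - Mx))
      ps <- 1 / (1 + exp(log_none - log_site))
      post_site[k] <- ps
      z[jj] <- ps * t / st
    }
    ll <- ll + pseudocount * sum(log(ppm))
    ll_trace <- c(ll_trace, ll)
    if (iter > 1 && abs(ll - ll_trace[iter - 1]) < tol) break
    # M-step
    counts <- matrix(pseudocount, 20, w, dimnames = list(names(bg), NULL))
    for (c in seq_len(w)) {
      cs <- rowsum(z, win$W[, c])
      counts[as.integer(rownames(cs)), c] <- counts[as.integer(rownames(cs)), c] + cs[, 1]
    }
    ppm <- sweep(counts, 2, colSums(counts), `/`)
    gamma <- min(max(mean(post_site), 1e-3), 1 - 1e-3)
  }
  # site calls: best window per sequence with posterior > 0.5
  best_start <- integer(0); best_seq <- integer(0); best_post <- numeric(0)
  for (k in seq_along(win$grp_index)) {
    jj <- win$grp_index[[k]]
    b <- jj[which.max(z[jj])]
    best_seq <- c(best_seq, win$grp[b])
    best_start <- c(best_start, win$start[b])
    best_post <- c(best_post, sum(z[jj]))
  }
  list(ppm = ppm, gamma = gamma, ll = ll_trace,
       sites = tibble(seq = best_seq, start = best_start, posterior = best_post))
}

# Starting-point words for a width: the most repeated exact w-mers in the
# (unmasked) data, topped up with seeded random window draws.
candidate_words <- function(win, n_cand) {
  strs <- apply(matrix(amino_acids()[win$W], nrow = nrow(win$W)), 1, paste,
                collapse = "")
  tab <- sort(table(strs), decreasing = TRUE)
  words <- names(tab)[tab >= 2]
  if (length(words) < n_cand) {
    extra <- unique(strs[sample.int(length(strs), min(length(strs), 5 * n_cand))])
    words <- unique(c(words, extra))
  }
  head(words, n_cand)
}

# One discovery round over all widths: returns the best (objective) fitted
# motif on the current mask state.
discovery_round <- function(enc, masks, widths, bg, restarts, site_prior,
                            max_iter, tol, pseudocount) {
  best <- NULL
  for (w in widths) {
    win <- build_windows(enc, w, masks)
    if (is.null(win) || win$n_seq < 2) next
    words <- candidate_words(win, restarts)
    for (word in words) {
      word_idx <- match(strsplit(word, "")[[1]], amino_acids())
      fit <- zoops_em(win, seed_ppm(word_idx, bg), bg, site_prior,
                      max_iter, tol, pseudocount)
      called <- fit$sites[fit$sites$posterior > 0.5, , drop = FALSE]
      motif <- new_motif(fit$ppm, bg, n_sites = nrow(called))
      obj <- motif_information(motif) * nrow(called)
      if (is.null(best) || obj > best$obj) {
        best <- list(motif = motif, obj = obj, fit = fit, width = w,
                     called = called)
      }
    }
  }
  best
}

#' Discover motifs under a ZOOPS model
#'
#' Expectation-maximisation under a zero-or-one-occurrence-per-sequence
#' model, run per width from the most repeated exact substrings as
#' starting points. After each round the best motif (by total information
#' content x site count) is reported and its sites masked before the next
#' round. Motif E-values come from an empirical null: the same one-round
#' search is run on `n_shuffle` datasets with residues shuffled within
#' each sequence, and
#' `evalue = (1 + exceedances) / (1 + n_shuffle) * length(width_range)`.
#' Only motifs with `evalue < 1` are returned (at most `max_motifs`,
#' sorted by ascending E-value); discovery stops at the first motif
#' failing that filter, since later rounds only get weaker.
#'
#' @param sequences Record tibble or character vector (>= 5 sequences).
#' @param max_motifs Maximum number of motifs searched for.
#' @param width_range Candidate widths, a subset of 5:10.
#' @param seed Integer seed (shuffle null and window sampling).
#' @param background Null model; defaults to the letter frequencies of the
#'   supplied set.
#' @param n_shuffle Shuffled datasets for the empirical E-value.
#' @param restarts EM starting points per width.
#' @param max_iter,tol EM stopping rule (penalised log-likelihood change).
#' @param pseudocount Dirichlet pseudocount per residue and column.
#' @param site_prior Initial ZOOPS site probability.
#' @return List of `nat_motif` objects.
#' @export
discover_motifs <- function(sequences, max_motifs = 25, width_range = 5:10,
                            seed = 1, background = NULL, n_shuffle = 20,
                            restarts = 2, max_iter = 200, tol = 1e-4,
                            pseudocount = 0.01, site_prior = 0.8) {
  if (is.data.frame(sequences)) {
    residues <- sequences$residues
    ids <- sequences$id
  } else {
    residues <- toupper(as.character(sequences))
    ids <- names(sequences)
  }
  if (is.null(ids)) ids <- sprintf("seq%03d", seq_along(residues))
  if (length(residues) < 5) abort("motif discovery needs at least 5 sequences")
  if (!all(width_range %in% 5:10)) abort("`width_range` must be within 5..10")
  bg <- if (is.null(background)) sequence_background(residues) else check_background(background)
  enc <- encode_residues(residues)

  with_seed_(seed, {
    # empirical null: best one-round objective on shuffled datasets
    null_best <- vapply(seq_len(n_shuffle), function(s) {
      enc_sh <- lapply(enc, function(x) x[sample.int(length(x))])
      masks <- lapply(enc_sh, function(x) rep(FALSE, length(x)))
      b <- discovery_round(enc_sh, masks, width_range, bg, restarts,
                           site_prior, max_iter, tol, pseudocount)
      if (is.null(b)) -Inf else b$obj
    }, numeric(1))

    masks <- lapply(enc, function(x) rep(FALSE, length(x)))
    motifs <- list()
    for (round in seq_len(max_motifs)) {
      best <- discovery_round(enc, masks, width_range, bg, restarts,
                              site_prior, max_iter, tol, pseudocount)
      if (is.null(best)) break
      ev <- (1 + sum(null_best >= best$obj)) / (1 + n_shuffle) * length(width_range)
      if (ev >= 1) break
      m <- best$motif
      m$evalue <- ev
      m$objective <- best$obj
      m$name <- sprintf("motif_%d", length(motifs) + 1)
      m$sites <- tibble(seq_id = ids[best$called$seq],
                        start = best$called$start - 1L,
                        posterior = best$called$posterior)
      m$consensus_regex <- regex_from_motif(m)
      motifs[[length(motifs) + 1]] <- m
      # mask reported sites before the next round
      for (r in seq_len(nrow(best$called))) {
        i <- best$called$seq[r]
        st <- best$called$start[r]
        masks[[i]][st:(st + best$width - 1)] <- TRUE
      }
    }
    motifs[order(vapply(motifs, `[[`, numeric(1), "evalue"))]
  })
}
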