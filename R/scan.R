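# Integer-scaled log-odds matrix of a motif. Probability-zero cells are
# capped at a large negative score so that words containing them can never
# outscore any word made of positive-probability residues (cap chosen so
# cap + (w-1)*max < w*min_positive for widths up to 10 on protein
# backgrounds).
LOGODDS_SCALE <- 100
LOGODDS_CAP <- -3000

pwm_int_logodds <- function(motif) {
  lr <- log2(motif$ppm / motif$background)
  M <- round(LOGODDS_SCALE * lr)
  M[!is.finite(M)] <- LOGODDS_CAP
  M[M < LOGODDS_CAP] <- LOGODDS_CAP
  storage.mode(M) <- "integer"
  M
}

# Exact distribution of the window score under the background: convolution
# of the per-column score distributions over the integer score lattice.
# Returns list(min, probs) with probs[k] = P(S = min + k - 1).
pwm_score_distribution <- function(M, background) {
  w <- ncol(M)
  cur <- 1
  cur_lo <- 0
  for (c in seq_len(w)) {
    cmin <- min(M[, c]); cmax <- max(M[, c])
    new <- numeric(length(cur) + (cmax - cmin))
    for (r in seq_len(nrow(M))) {
      sh <- M[r, c] - cmin
      new[(1 + sh):(length(cur) + sh)] <-
        new[(1 + sh):(length(cur) + sh)] + cur * background[r]
    }
    cur <- new
    cur_lo <- cur_lo + cmin
  }
  list(min = cur_lo, probs = cur)
}

pwm_tail_pvalue <- function(dist, score) {
  # P(S >= score), exactly, over the integer lattice
  k <- score - dist$min + 1
  if (k <= 1) return(1)
  if (k > length(dist$probs)) return(0)
  min(1, sum(dist$probs[k:length(dist$probs)]))
}

#' Scan a sequence with one motif
#'
#' Scores every window with the integer-scaled log-odds matrix
#' `round(100 * log2(ppm / background))`, reports the best window, and
#' computes the exact position p-value `P(score >= observed)` under the
#' background by convolution of the per-column score distributions. The
#' sequence p-value is `1 - (1 - p_pos)^(L - w + 1)`. `X` residues score
#' 0 in every column.
#'
#' @param motif A `nat_motif`.
#' @param sequence Residue string or one-row record tibble; must be at
#'   least as long as the motif.
#' @param background Optional override of the motif's background.
#' @return One-row tibble: `seq_id`, `motif`, `position` (0-based),
#'   `score` (integer log-odds units), `p_position`, `p_sequence`.
#' @export
scan_with_motif <- function(motif, sequence, background = NULL) {
  rec <- one_record(sequence, "sequence")
  if (!is.null(background)) {
    motif$background <- background[motif$alphabet] / sum(background[motif$alphabet])
  }
  M <- pwm_int_logodds(motif)
  dist <- pwm_score_distribution(M, motif$background)
  scan_one(motif, M, dist, rec$id, rec$residues)
}

scan_one <- function(motif, M, dist, id, residues) {
  w <- motif$width
  chars <- strsplit(toupper(residues), "")[[1]]
  L <- length(chars)
  if (L < w) abort("sequence shorter than the motif width")
  ri <- match(chars, motif$alphabet)            # NA for X / unknown: scores 0
  Mx <- rbind(M, 0L)                            # extra row for unknowns
  ri[is.na(ri)] <- nrow(Mx)
  st <- seq_len(L - w + 1)
  W <- outer(st, 0:(w - 1), `+`)
  S <- rowSums(matrix(Mx[cbind(as.vector(matrix(ri[W], nrow = length(st))),
                               rep(seq_len(w), each = length(st)))],
                      nrow = length(st)))
  best <- which.max(S)
  p_pos <- pwm_tail_pvalue(dist, S[best])
  n_win <- L - w + 1
  p_seq <- if (p_pos >= 1) 1 else -expm1(n_win * log1p(-p_pos))
  tibble(
    seq_id = id, motif = motif$name,
    position = as.integer(best - 1), score = S[best],
    p_position = p_pos, p_sequence = min(1, p_seq)
  )
}

#' Combine p-values by the QFAST product rule
#'
#' For `k` independent p-values with raw product `p`, the combined
#' p-value is `p * sum_{i=0}^{k-1} (-ln p)^i / i!`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Combined p-value.
#' @export
qfast_combine <- function(p_values) {
  k <- length(p_values)
  if (k == 0) abort("need at least one p-value")
  p <- prod(p_values)
  if (p <= 0) return(0)
  if (p >= 1) return(1)
  lp <- -log(p)
  min(1, p * sum(exp(cumsum(c(0, log(lp) - log(seq_len(k - 1)))))))
}

#' Score sequences against a group fingerprint
#'
#' Each fingerprint motif is scanned over each sequence; per-sequence
#' motif p-values are combined by the QFAST product rule. The
#' cluster-level score of a set of sequences is the median combined
#' p-value across members.
#'
#' @param fingerprint A `group_fingerprint`.
#' @param sequences Record tibble or character vector.
#' @param alpha Presence call threshold on the per-motif sequence p-value.
#' @return A list of class `fingerprint_scan`: `per_sequence` tibble
#'   (`seq_id`, `combined_p`), `per_motif` tibble (per sequence and
#'   element: position, score, p-values, `present`), and `cluster_p`
#'   (median combined p).
#' @export
fingerprint_score <- function(fingerprint, sequences, alpha = 0.05) {
  stopifnot(inherits(fingerprint, "group_fingerprint"))
  records <- as_records(sequences)
  motifs <- fingerprint$motifs
  if (!length(motifs)) abort("fingerprint must contain at least one motif")
  pre <- lapply(motifs, function(m) {
    M <- pwm_int_logodds(m)
    list(motif = m, M = M, dist = pwm_score_distribution(M, m$background))
  })
  per_motif <- bind_rows(lapply(names(pre), function(el) {
    p <- pre[[el]]
    bind_rows(lapply(seq_len(nrow(records)), function(i) {
      scan_one(p$motif, p$M, p$dist, records$id[i], records$residues[i])
    })) %>% mutate(element = el)
  })) %>%
    mutate(present = .data$p_sequence <= alpha) %>%
    select("seq_id", "element", "motif", "position", "score",
           "p_position", "p_sequence", "present")
  per_sequence <- per_motif %>%
    group_by(.data$seq_id) %>%
    summarise(combined_p = qfast_combine(.data$p_sequence), .groups = "drop")
  structure(
    list(per_sequence = per_sequence, per_motif = per_motif,
         cluster_p = median(per_sequence$combined_p),
         group = fingerprint$name),
    class = "fingerprint_scan"
  )
}

#' @export
print.fingerprint_scan <- function(x, ...) {
  cat(sprintf("Fingerprint scan vs %s: %d sequence(s), median combined p = %.3g\n",
              x$group, nrow(x$per_sequence), x$cluster_p))
  invisible(x)
}
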