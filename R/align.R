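#' Alignment scoring configuration
#'
#' Local (Smith-Waterman) alignment with affine gaps. Defaults follow the
#' standard protein-BLAST parameterisation: BLOSUM62, gap open 11, gap
#' extend 1, and the published gapped Karlin-Altschul constants for that
#' triple (`lambda` = 0.267, `K` = 0.041). E-values are computed as
#' `K * m * n * exp(-lambda * raw_score)` without effective search-space
#' correction (desk-scale datasets). `X` scores 0 against everything.
#'
#' @param matrix Substitution matrix name (only `"BLOSUM62"` is shipped) or
#'   a numeric substitution matrix.
#' @param gap_open,gap_extend Affine gap penalties; a gap of length `L`
#'   costs `gap_open + gap_extend * L`.
#' @param lambda,K Karlin-Altschul constants for the chosen scoring system.
#' @return An `align_params` list.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                         lambda = 0.267, K = 0.041) {
  sub <- if (is.matrix(matrix)) matrix else substitution_matrix(matrix)
  structure(
    list(matrix = sub, matrix_name = if (is.matrix(matrix)) "custom" else matrix,
         gap_open = gap_open, gap_extend = gap_extend,
         lambda = lambda, K = K),
    class = "align_params"
  )
}

substitution_matrix <- function(name) {
  if (name != "BLOSUM62") abort("only BLOSUM62 is shipped")
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  m["X", ] <- 0L   # X tolerated, scored 0 against everything
  m[, "X"] <- 0L
  m
}

check_aa_string <- function(x, what = "sequence") {
  if (grepl(sprintf("[^%sX]", paste(amino_acids(), collapse = "")), x)) {
    abort(sprintf("%s contains non-amino-acid characters other than X", what))
  }
  x
}

#' Align one pair of sequences
#'
#' Smith-Waterman local alignment with affine gaps; identity and alignment
#' length come from the optimal traceback (identity denominator = aligned
#' columns, the BLAST convention used for SSN edge weights).
#'
#' @param a,b Residue strings, or single-row sequence-record tibbles.
#' @param params [align_params()] configuration.
#' @return One-row tibble: `query_id`, `subject_id`, `raw_score`,
#'   `bit_score`, `evalue`, `pct_identity`, `aln_length`.
#' @export
align_pair <- function(a, b, params = align_params()) {
  a <- one_record(a, "a"); b <- one_record(b, "b")
  check_aa_string(a$residues, a$id); check_aa_string(b$residues, b$id)
  aln <- Biostrings::pairwiseAlignment(
    a$residues, b$residues, type = "local",
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  hit_row(a$id, b$id, nchar(a$residues), nchar(b$residues),
          raw = Biostrings::score(aln),
          nmatch = Biostrings::nmatch(aln),
          aln_len = nchar(as.character(Biostrings::pattern(aln))),
          params = params)
}

one_record <- function(x, what) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort(sprintf("`%s` must be a single record", what))
    return(list(id = x$id, residues = toupper(x$residues)))
  }
  list(id = what, residues = toupper(as.character(x)))
}

hit_row <- function(qid, sid, m, n, raw, nmatch, aln_len, params) {
  tibble(
    query_id = qid, subject_id = sid,
    raw_score = as.numeric(raw),
    bit_score = (params$lambda * raw - log(params$K)) / log(2),
    evalue = karlin_evalue(raw, m, n, params),
    pct_identity = ifelse(aln_len > 0, 100 * nmatch / aln_len, 0),
    aln_length = as.integer(aln_len)
  )
}

karlin_evalue <- function(raw_score, m, n, params = align_params()) {
  params$K * m * n * exp(-params$lambda * raw_score)
}

#' Pairwise identity over the shorter sequence
#'
#' Identical matches of the optimal local alignment divided by the length
#' of the shorter sequence (the cd-hit convention used for redundancy
#' filtering and the generator's calibration checks).
#'
#' @inheritParams align_pair
#' @return Fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b, params = align_params()) {
  a <- one_record(a, "a"); b <- one_record(b, "b")
  hit <- align_pair(a$residues, b$residues, params)
  nmatch <- hit$pct_identity / 100 * hit$aln_length
  nmatch / min(nchar(a$residues), nchar(b$residues))
}

#' All-vs-all local alignment
#'
#' One hit per unordered pair with E-value at or below the cutoff; pairs
#' above the cutoff are omitted. Sequences shorter than `min_length`
#' residues are dropped with a warning (mirroring the shortest sequence
#' retained in the reference network, 34 residues). Output rows are sorted
#' by id pair, so the result is deterministic.
#'
#' @param records Sequence-record tibble (>= 2 sequences).
#' @param params [align_params()] configuration.
#' @param evalue_cutoff Maximum E-value for a hit to be reported.
#' @param min_length Minimum sequence length retained.
#' @return Tibble of pairwise hits (see [align_pair()]).
#' @export
all_vs_all <- function(records, params = align_params(),
                       evalue_cutoff = 1e-5, min_length = 34) {
  records <- as_records(records)
  short <- nchar(records$residues) < min_length
  if (any(short)) {
    warn(sprintf("dropping %d sequence(s) shorter than %d residues",
                 sum(short), min_length))
    records <- records[!short, ]
  }
  if (nrow(records) < 2) abort("need at least 2 sequences")
  records <- arrange(records, .data$id)
  for (r in records$residues) check_aa_string(r)
  seqs <- Biostrings::AAStringSet(setNames(records$residues, records$id))
  lens <- nchar(records$residues)
  n <- length(seqs)
  out <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    aln <- Biostrings::pairwiseAlignment(
      seqs[js], seqs[[i]], type = "local",
      substitutionMatrix = params$matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend
    )
    out[[i]] <- hit_row(
      qid = records$id[i], sid = records$id[js],
      m = lens[i], n = lens[js],
      raw = Biostrings::score(aln),
      nmatch = Biostrings::nmatch(aln),
      aln_len = nchar(as.character(Biostrings::pattern(aln))),
      params = params
    )
  }
  hits <- bind_rows(out) %>%
    filter(.data$evalue <= evalue_cutoff) %>%
    arrange(.data$query_id, .data$subject_id)
  hits
}

#' Write hits as BLAST outfmt-6 compatible TSV
#'
#' Twelve tab-separated columns (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore). Coordinate
#' columns are reported as 0 since full tracebacks are not retained.
#'
#' @param hits Hit tibble from [all_vs_all()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  nmatch <- round(hits$pct_identity / 100 * hits$aln_length)
  tab <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = sprintf("%.2f", hits$pct_identity),
    length = hits$aln_length,
    mismatch = hits$aln_length - nmatch,
    gapopen = 0L, qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
    evalue = format(hits$evalue, digits = 3),
    bitscore = sprintf("%.1f", hits$bit_score)
  )
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
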