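#' Construct a sequence-record tibble
#'
#' The canonical per-protein table used throughout the package: one row per
#' sequence with its curation status, taxon tag and functional label
#' (`"unknown"` for uncharacterized records).
#'
#' @param id Character vector of unique sequence identifiers.
#' @param residues Character vector of residue strings over the 20-letter
#'   amino-acid alphabet; `X` is tolerated (scored 0 in alignments).
#' @param status `"curated"` or `"unreviewed"` per record.
#' @param taxon Free-form taxon tags.
#' @param label Functional labels, `"unknown"` if uncharacterized.
#' @return A tibble of class `ssnat_records` with columns
#'   `id`, `residues`, `status`, `taxon`, `label`.
#' @export
sequence_records <- function(id, residues,
                             status = "unreviewed",
                             taxon = "synthetic",
                             label = "unknown") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(residues) == 1 && length(id) > 1) {
    residues <- rep(residues, length(id))
  }
  if (length(id) != length(residues)) {
    abort("`id` and `residues` must have the same length")
  }
  if (anyDuplicated(id)) {
    abort("sequence ids must be unique within a dataset")
  }
  if (any(!nzchar(residues))) {
    abort("residue strings must be non-empty")
  }
  bad <- grepl(sprintf("[^%sX]", paste(amino_acids(), collapse = "")), residues)
  if (any(bad)) {
    abort(sprintf("non-amino-acid characters (other than X) in: %s",
                  paste(head(id[bad], 5), collapse = ", ")))
  }
  out <- tibble(
    id = id,
    residues = residues,
    status = vctrs_recycle(as.character(status), length(id), "status"),
    taxon = vctrs_recycle(as.character(taxon), length(id), "taxon"),
    label = vctrs_recycle(as.character(label), length(id), "label")
  )
  if (!all(out$status %in% c("curated", "unreviewed"))) {
    abort('`status` must be "curated" or "unreviewed"')
  }
  class(out) <- c("ssnat_records", class(out))
  out
}

vctrs_recycle <- function(x, n, what) {
  if (length(x) == 1) x <- rep(x, n)
  if (length(x) != n) abort(sprintf("`%s` must have length 1 or %d", what, n))
  x
}

as_records <- function(x) {
  if (inherits(x, "ssnat_records")) return(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "residues") %in% names(x)))
    return(sequence_records(
      id = x$id, residues = x$residues,
      status = if ("status" %in% names(x)) x$status else "unreviewed",
      taxon = if ("taxon" %in% names(x)) x$taxon else "synthetic",
      label = if ("label" %in% names(x)) x$label else "unknown"
    ))
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("seq%03d", seq_along(x))
    return(sequence_records(ids, x))
  }
  abort("cannot interpret input as sequence records")
}

#' Read sequence records from FASTA
#'
#' Headers are parsed as `>id key=value key=value ...`; recognised keys are
#' `status`, `taxon` and `label` (missing keys default to
#' `unreviewed`/`synthetic`/`unknown`).
#'
#' @param path FASTA file path.
#' @return A sequence-record tibble (see [sequence_records()]).
#' @export
read_fasta_records <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  parse_field <- function(key, default) {
    m <- regmatches(headers, regexec(sprintf("%s=([^ ]+)", key), headers))
    vapply(m, function(g) if (length(g) == 2) g[2] else default, character(1))
  }
  sequence_records(
    id = vapply(strsplit(headers, " "), `[`, character(1), 1),
    residues = as.character(aa),
    status = parse_field("status", "unreviewed"),
    taxon = parse_field("taxon", "synthetic"),
    label = parse_field("label", "unknown")
  )
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta_records()]: metadata goes into the header as
#' space-separated `key=value` pairs.
#'
#' @param records Sequence-record tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_records <- function(records, path) {
  records <- as_records(records)
  lines <- character(2L * nrow(records))
  lines[c(TRUE, FALSE)] <- sprintf(
    ">%s status=%s label=%s taxon=%s",
    records$id, records$status, records$label, records$taxon
  )
  lines[c(FALSE, TRUE)] <- records$residues
  writeLines(lines, path)
  invisible(path)
}

# Run `code` under a fixed RNG state without disturbing the caller's RNG.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}
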