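#' The 20 standard amino acids
#'
#' One-letter codes in the conventional alphabetical order used throughout
#' the package for position probability matrices and background vectors.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# BLOSUM62 marginal amino-acid frequencies (Henikoff & Henikoff background
# model underlying the matrix), renormalised to sum to exactly 1.
.blosum62_marginals <- c(
  A = 0.0742, C = 0.0246, D = 0.0536, E = 0.0543, F = 0.0473,
  G = 0.0741, H = 0.0262, I = 0.0679, K = 0.0582, L = 0.0989,
  M = 0.0251, N = 0.0449, P = 0.0399, Q = 0.0342, R = 0.0520,
  S = 0.0572, T = 0.0508, V = 0.0729, W = 0.0131, Y = 0.0324
)

#' Default amino-acid background frequencies
#'
#' Marginal amino-acid frequencies of the BLOSUM62 substitution model.
#' These are the default residue frequencies for the synthetic-superfamily
#' generator and for motif scanning when no sequence-derived background is
#' supplied; they are more realistic for protein scoring than a uniform
#' background.
#'
#' @return Named numeric vector over [amino_acids()], summing to 1.
#' @export
default_background <- function() {
  p <- .blosum62_marginals[amino_acids()]
  p / sum(p)
}

#' Amino-acid frequencies of a sequence set
#'
#' Letter frequencies over the 20 standard residues observed in the supplied
#' sequences (the null model motif discovery is performed against).
#' `X` characters are ignored. A small floor keeps every residue possible.
#'
#' @param residues Character vector of residue strings, or a sequence
#'   records tibble with a `residues` column.
#' @param floor Minimum frequency assigned to any residue.
#' @return Named numeric vector over [amino_acids()], summing to 1.
#' @export
sequence_background <- function(residues, floor = 1e-4) {
  residues <- seq_residues(residues)
  counts <- table(factor(strsplit(paste(residues, collapse = ""), "")[[1]],
                         levels = amino_acids()))
  p <- pmax(as.numeric(counts) / max(sum(counts), 1), floor)
  setNames(p / sum(p), amino_acids())
}

# Pull the residue strings out of either a character vector or records tibble.
seq_residues <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("residues" %in% names(x))
    return(x$residues)
  }
  as.character(x)
}

check_background <- function(background) {
  if (!is.numeric(background) || length(background) != 20 ||
      is.null(names(background)) || !setequal(names(background), amino_acids())) {
    abort("`background` must be a named numeric vector over the 20 standard amino acids")
  }
  if (abs(sum(background) - 1) > 1e-6) {
    abort("`background` must sum to 1")
  }
  background[amino_acids()]
}

# Encode residue strings as integer indices into amino_acids(); X and any
# other letter become NA (callers decide how to treat them).
encode_residues <- function(residues) {
  lapply(strsplit(residues, ""), function(ch) {
    match(ch, amino_acids())
  })
}
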