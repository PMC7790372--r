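#' Specify one synthetic protein family
#'
#' A family is a set of sequences mutated from a common ancestor scaffold
#' that carries short conserved motifs at fixed fold positions (emulating
#' the key-motif structure of GNAT fold elements: the alpha1-alpha2 loop,
#' beta4 and beta5 strands and the beta6-beta7 loop).
#'
#' @param family_id Short identifier, also used as the functional label of
#'   curated members.
#' @param n_sequences Number of members.
#' @param scaffold_length Ancestor length in residues.
#' @param motifs Tibble with columns `element` (one of `"a1a2"`, `"b4"`,
#'   `"b5"`, `"b6b7"`), `consensus` (planted string, 5-10 residues) and
#'   `offset` (0-based scaffold offset); `NULL` lets
#'   [generate_superfamily()] plant seeded random motifs at canonical
#'   offsets.
#' @param target_within_identity Desired mean pairwise identity among
#'   members, in (0, 1].
#' @param labelled_fraction Fraction of members given the true family label
#'   as a curated annotation (rounded down, at least 1 when positive).
#' @return A `family_spec` object.
#' @export
family_spec <- function(family_id, n_sequences,
                        scaffold_length = 150,
                        motifs = NULL,
                        target_within_identity = 0.75,
                        labelled_fraction = 0.2) {
  stopifnot(n_sequences >= 1, scaffold_length >= 1)
  if (target_within_identity <= 0 || target_within_identity > 1) {
    abort("`target_within_identity` must be in (0, 1]")
  }
  if (labelled_fraction < 0 || labelled_fraction > 1) {
    abort("`labelled_fraction` must be in [0, 1]")
  }
  if (!is.null(motifs)) {
    motifs <- as_tibble(motifs)
    stopifnot(all(c("element", "consensus", "offset") %in% names(motifs)))
    check_motif_layout(motifs, scaffold_length)
  }
  structure(
    list(family_id = as.character(family_id),
         n_sequences = as.integer(n_sequences),
         scaffold_length = as.integer(scaffold_length),
         motifs = motifs,
         target_within_identity = target_within_identity,
         labelled_fraction = labelled_fraction),
    class = "family_spec"
  )
}

check_motif_layout <- function(motifs, scaffold_length) {
  w <- nchar(motifs$consensus)
  if (any(w < 5 | w > 10)) abort("planted consensus strings must be 5-10 residues")
  if (!all(motifs$element %in% c("a1a2", "b4", "b5", "b6b7"))) {
    abort('motif elements must be among "a1a2", "b4", "b5", "b6b7"')
  }
  start <- motifs$offset
  end <- start + w
  if (any(start < 0) || any(end > scaffold_length)) {
    abort("motif intervals must fit inside the scaffold")
  }
  o <- order(start)
  if (any(start[o][-1] < end[o][-length(o)])) {
    abort("motif intervals must not overlap")
  }
  invisible(motifs)
}

# Canonical fold-element offsets on a scaffold: loop / strand positions are
# spread over the sequence the way the four key GNAT elements are.
fold_element_offsets <- function(scaffold_length) {
  round(scaffold_length * c(a1a2 = 0.08, b4 = 0.35, b5 = 0.55, b6b7 = 0.80))
}

random_fold_motifs <- function(scaffold_length, background) {
  offs <- fold_element_offsets(scaffold_length)
  widths <- sample(5:10, 4, replace = TRUE)
  tibble(
    element = names(offs),
    consensus = vapply(widths, function(w) {
      paste(sample(amino_acids(), w, replace = TRUE, prob = background),
            collapse = "")
    }, character(1)),
    offset = as.integer(offs)
  )
}

#' Generate a synthetic superfamily with planted ground truth
#'
#' Per family one ancestor scaffold is drawn from the background, the
#' planted motifs are written onto it, and each member is obtained by
#' mutating the ancestor. The per-member substitution load is calibrated so
#' that the *pairwise* identity between members tracks
#' `target_within_identity` (two members mutated independently at per-site
#' retention `r` match at roughly `r^2` of unprotected sites, so members
#' are mutated at `1 - sqrt(target)`). Motif intervals are protected
#' (10-fold reduced substitution rate), leaving detectable but not frozen
#' motifs. Ancestors are drawn independently per family, so between-family
#' identity stays at random-background level.
#'
#' @param specs List of [family_spec()] objects (a single spec is accepted).
#' @param background Amino-acid frequency vector, default
#'   [default_background()].
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A list with `records` (sequence tibble, see [sequence_records()])
#'   and `truth` (list with `membership`, `motif_positions`, `seed`).
#' @export
generate_superfamily <- function(specs, background = default_background(),
                                 seed = 1) {
  if (inherits(specs, "family_spec")) specs <- list(specs)
  if (length(specs) == 0) abort("`specs` must be non-empty")
  stopifnot(all(vapply(specs, inherits, logical(1), "family_spec")))
  background <- check_background(background)
  ids <- vapply(specs, `[[`, character(1), "family_id")
  if (anyDuplicated(ids)) abort("family ids must be unique")

  with_seed_(seed, {
    fams <- lapply(specs, function(sp) {
      motifs <- sp$motifs %||% random_fold_motifs(sp$scaffold_length, background)
      check_motif_layout(motifs, sp$scaffold_length)
      scaffold <- sample(amino_acids(), sp$scaffold_length,
                         replace = TRUE, prob = background)
      for (k in seq_len(nrow(motifs))) {
        idx <- motifs$offset[k] + seq_len(nchar(motifs$consensus[k]))
        scaffold[idx] <- strsplit(motifs$consensus[k], "")[[1]]
      }
      protected <- lapply(seq_len(nrow(motifs)), function(k) {
        c(motifs$offset[k], motifs$offset[k] + nchar(motifs$consensus[k]))
      })
      member_identity <- sqrt(sp$target_within_identity)
      members <- vapply(seq_len(sp$n_sequences), function(i) {
        mutate_sequence(paste(scaffold, collapse = ""),
                        target_identity = member_identity,
                        protected = protected,
                        background = background,
                        seed = sample.int(.Machine$integer.max, 1))
      }, character(1))
      n_lab <- floor(sp$labelled_fraction * sp$n_sequences)
      if (sp$labelled_fraction > 0) n_lab <- max(1L, n_lab)
      seq_ids <- sprintf("%s_%03d", sp$family_id, seq_len(sp$n_sequences))
      rec <- sequence_records(
        id = seq_ids, residues = members,
        status = ifelse(seq_len(sp$n_sequences) <= n_lab, "curated", "unreviewed"),
        taxon = "synthetic",
        label = ifelse(seq_len(sp$n_sequences) <= n_lab, sp$family_id, "unknown")
      )
      pos <- tidyr::crossing(seq_id = seq_ids, k = seq_len(nrow(motifs))) %>%
        mutate(element = motifs$element[.data$k],
               start = motifs$offset[.data$k],
               end = motifs$offset[.data$k] + nchar(motifs$consensus[.data$k])) %>%
        select("seq_id", "element", "start", "end")
      list(records = rec,
           membership = tibble(seq_id = seq_ids, family_id = sp$family_id),
           motif_positions = pos,
           motifs = mutate(motifs, family_id = sp$family_id))
    })
    records <- bind_rows(lapply(fams, `[[`, "records"))
    class(records) <- c("ssnat_records", class(tibble()))
    truth <- list(
      membership = bind_rows(lapply(fams, `[[`, "membership")),
      motif_positions = bind_rows(lapply(fams, `[[`, "motif_positions")),
      planted_motifs = bind_rows(lapply(fams, `[[`, "motifs")),
      seed = as.integer(seed)
    )
    list(records = records, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mutate a sequence toward a target identity
#'
#' Exactly `round((1 - target_identity) * L_unprotected)` positions outside
#' the protected intervals are substituted by a different residue drawn
#' from the background. Protected positions mutate independently at a
#' 10-fold lower per-site rate, emulating conserved motifs with residual
#' within-family variation. Length is preserved; no indels.
#'
#' @param parent Residue string.
#' @param target_identity Fraction in (0, 1].
#' @param protected List of 0-based half-open intervals `c(start, end)`.
#' @param background Amino-acid frequency vector.
#' @param seed Integer seed.
#' @return Mutated residue string.
#' @export
mutate_sequence <- function(parent, target_identity,
                            protected = list(),
                            background = default_background(),
                            seed = 1) {
  if (target_identity <= 0 || target_identity > 1) {
    abort("`target_identity` must be in (0, 1]")
  }
  background <- check_background(background)
  chars <- strsplit(toupper(parent), "")[[1]]
  L <- length(chars)
  prot <- rep(FALSE, L)
  for (iv in protected) {
    if (iv[1] < 0 || iv[2] > L || iv[2] < iv[1]) abort("protected interval out of range")
    if (iv[2] > iv[1]) prot[(iv[1] + 1):iv[2]] <- TRUE
  }
  rate <- 1 - target_identity
  n_sub <- round(rate * sum(!prot))
  with_seed_(seed, {
    sub_at <- function(pos) {
      for (i in pos) {
        p <- background
        p[chars[i]] <- 0
        chars[i] <<- sample(amino_acids(), 1, prob = p / sum(p))
      }
    }
    if (n_sub > 0) {
      sub_at(sample(which(!prot), n_sub))
    }
    if (any(prot) && rate > 0) {
      hit <- which(prot)[runif(sum(prot)) < rate / 10]
      if (length(hit)) sub_at(hit)
    }
    paste(chars, collapse = "")
  })
}

#' Generate a structural Z-score matrix matching planted families
#'
#' Fixture generator for the structure-similarity stage: within-family
#' entries are drawn around `mu_within`, between-family entries around
#' `mu_between` (both truncated at 0), the matrix is symmetrised and the
#' diagonal set to the maximum entry (self-similarity).
#'
#' @param truth Truth list from [generate_superfamily()], or a two-column
#'   tibble/data.frame `seq_id`, `family_id`.
#' @param mu_within,mu_between Mean Z within / between families;
#'   `mu_within > mu_between >= 0` required.
#' @param sd Normal standard deviation for both.
#' @param seed Integer seed.
#' @return Symmetric numeric matrix with sequence ids as dimnames.
#' @export
generate_zscore_matrix <- function(truth, mu_within = 20, mu_between = 5,
                                   sd = 2, seed = 1) {
  membership <- if (is.data.frame(truth)) truth else truth$membership
  stopifnot(all(c("seq_id", "family_id") %in% names(membership)))
  if (!(mu_within > mu_between) || mu_between < 0) {
    abort("`mu_within` must exceed `mu_between`, and `mu_between` must be >= 0")
  }
  ids <- membership$seq_id
  fam <- membership$family_id
  n <- length(ids)
  with_seed_(seed, {
    Z <- matrix(0, n, n, dimnames = list(ids, ids))
    same <- outer(fam, fam, `==`)
    up <- upper.tri(Z)
    mu <- ifelse(same[up], mu_within, mu_between)
    vals <- pmax(0, rnorm(sum(up), mean = mu, sd = sd))
    Z[up] <- vals
    Z <- Z + t(Z)
    diag(Z) <- max(Z)
    Z
  })
}

#' Write the planted truth tables as TSV
#'
#' One row per (sequence, element): `seq_id`, `family_id`, `element_label`,
#' `start`, `end` with 0-based half-open intervals.
#'
#' @param truth Truth list from [generate_superfamily()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  tab <- truth$motif_positions %>%
    left_join(truth$membership, by = "seq_id") %>%
    select("seq_id", "family_id", element_label = "element", "start", "end")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a Z-score matrix as CSV
#'
#' The CSV carries the structure ids as header row and first column.
#'
#' @param Z Symmetric matrix with dimnames.
#' @param path File path.
#' @return `path` invisibly for the writer; the matrix for the reader.
#' @export
write_zscore_csv <- function(Z, path) {
  df <- data.frame(id = rownames(Z), Z, check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_zscore_csv
#' @export
read_zscore_csv <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE)
  Z <- as.matrix(df[, -1, drop = FALSE])
  rownames(Z) <- df[[1]]
  storage.mode(Z) <- "double"
  Z
}
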