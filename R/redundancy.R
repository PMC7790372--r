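#' Hierarchical greedy redundancy filtering
#'
#' Greedy incremental clustering in the cd-hit style, run once per identity
#' step (steps must be strictly descending, e.g. 90%, then 80%, then 70%):
#' sequences are taken longest-first, each joins the first existing
#' representative with identity at or above the step (identity = identical
#' matches / length of the shorter sequence, from the optimal local
#' alignment), otherwise it becomes a representative. The survivors of one
#' step are the input of the next. Curated records are never removed: they
#' are processed first and therefore preferentially become representatives.
#'
#' @param records Sequence-record tibble.
#' @param identity_steps Strictly descending fractions in (0, 1].
#' @param params [align_params()] configuration.
#' @return List with `representatives` (record tibble) and `assignment`
#'   (tibble `id`, `representative_id`; representatives map to themselves).
#' @export
redundancy_filter <- function(records, identity_steps = c(0.9, 0.8, 0.7),
                              params = align_params()) {
  records <- as_records(records)
  if (length(identity_steps) == 0 ||
      any(identity_steps <= 0) || any(identity_steps > 1) ||
      is.unsorted(rev(identity_steps), strictly = TRUE)) {
    abort("`identity_steps` must be strictly descending fractions in (0, 1]")
  }
  if (nrow(records) == 0) {
    return(list(representatives = records,
                assignment = tibble(id = character(), representative_id = character())))
  }
  assignment <- setNames(records$id, records$id)
  current <- records
  for (step in identity_steps) {
    res <- one_filter_pass(current, step, params)
    # compose: anything assigned to a sequence that itself got reassigned
    # follows its representative
    assignment[] <- res$assign[assignment[names(assignment)]]
    current <- res$reps
  }
  list(
    representatives = current,
    assignment = tibble(id = names(assignment),
                        representative_id = unname(assignment))
  )
}

one_filter_pass <- function(records, step, params) {
  ord <- order(records$status != "curated", -nchar(records$residues), records$id)
  records <- records[ord, ]
  rep_idx <- integer(0)
  assign <- setNames(records$id, records$id)
  for (i in seq_len(nrow(records))) {
    joined <- FALSE
    if (records$status[i] != "curated") {
      for (r in rep_idx) {
        idy <- sequence_identity(records$residues[i], records$residues[r], params)
        if (idy >= step) {
          assign[records$id[i]] <- records$id[r]
          joined <- TRUE
          break
        }
      }
    }
    if (!joined) rep_idx <- c(rep_idx, i)
  }
  list(reps = records[rep_idx, ], assign = assign)
}
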