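#' Transfer annotations within isofunctional clusters
#'
#' Under the isofunctionality assumption, a cluster whose curated labelled
#' members all agree on one functional label passes that label to the
#' cluster and to its unlabelled members (provenance `"transferred"`).
#' Clusters with conflicting curated labels are flagged `"mixed"` (no
#' transfer); clusters without any labelled curated member stay
#' `"uncharacterized"`. Curated labels are never overwritten.
#'
#' @param clustering A `nat_clustering`.
#' @param records Record tibble with `status` and `label`.
#' @return The clustering with cluster `label`s filled in and an
#'   `annotations` tibble (`id`, `cluster_id`, `label`, `provenance`).
#' @export
transfer_annotations <- function(clustering, records) {
  records <- as_records(records)
  info <- setNames(records$label, records$id)
  status <- setNames(records$status, records$id)
  ann <- list()
  for (i in seq_len(nrow(clustering$clusters))) {
    members <- clustering$clusters$members[[i]]
    cid <- clustering$clusters$cluster_id[i]
    lab <- info[members]
    st <- status[members]
    curated_labels <- unique(lab[st == "curated" & !is.na(lab) & lab != "unknown"])
    if (length(curated_labels) == 1) {
      cluster_label <- curated_labels
      out_label <- ifelse(st == "curated" & lab != "unknown", lab, cluster_label)
      prov <- ifelse(st == "curated" & lab != "unknown", "curated", "transferred")
    } else if (length(curated_labels) > 1) {
      cluster_label <- "mixed"
      out_label <- lab
      prov <- ifelse(st == "curated" & lab != "unknown", "curated", "none")
    } else {
      cluster_label <- "uncharacterized"
      out_label <- lab
      prov <- rep("none", length(members))
    }
    clustering$clusters$label[i] <- cluster_label
    ann[[i]] <- tibble(id = members, cluster_id = cid,
                       label = unname(out_label), provenance = unname(prov))
  }
  clustering$annotations <- bind_rows(ann)
  clustering
}

#' Nominate candidate NAT clusters among neighbours of known NATs
#'
#' Candidates are the uncharacterized clusters adjacent in the pivot
#' network to any cluster labelled with a known group, plus any isolated
#' uncharacterized clusters explicitly requested. Each candidate's member
#' sequences are scored against every group fingerprint; the best group
#' (lowest median combined p-value) is reported together with the
#' fraction of members whose combined p-value passes `alpha`, a
#' per-element difference summary against the best group (candidate
#' element motifs are rebuilt from the members' best-scoring sites), and
#' a verdict: `consistent` (fraction >= 0.5, no key-position difference),
#' `divergent` (the cluster carries the motif signal — half the members
#' pass `alpha`, or the median combined p-value is at most 0.05 — but key
#' positions differ or the match is partial) or `no-match` (no signal
#' beyond the false-positive noise the threshold admits).
#'
#' @param pivot A `pivot_network` from [contract()].
#' @param clustering A labelled `nat_clustering` (after
#'   [transfer_annotations()]).
#' @param fingerprints Named list of `group_fingerprint`s.
#' @param records Record tibble (sequences of all cluster members).
#' @param alpha Combined p-value threshold for a member to count as
#'   matching.
#' @param group_map Named character vector mapping cluster labels to
#'   fingerprint group names; defaults to the canonical NAT catalytic
#'   subunit mapping (NAA10/NAA20 -> Group 1a, NAA30 -> Group 1b,
#'   NAA50/NAA60 -> Group 2, NAA40 -> Group 3, NAA80 -> Group 4), extended
#'   with identity entries for labels that are themselves fingerprint
#'   names.
#' @param include_isolated Cluster ids of isolated uncharacterized
#'   clusters to scan as well.
#' @return Tibble of candidate reports: `cluster_id`, `neighbour_of`,
#'   `best_group`, `cluster_p`, `fraction_members`, `n_key_differences`,
#'   `verdict`, plus a `differences` list-column.
#' @export
predict_nat_candidates <- function(pivot, clustering, fingerprints, records,
                                   alpha = 0.01, group_map = NULL,
                                   include_isolated = integer(0)) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  records <- as_records(records)
  group_map <- c(group_map, default_group_map(names(fingerprints)))
  group_map <- group_map[!duplicated(names(group_map))]

  labels <- setNames(clustering$clusters$label, clustering$clusters$cluster_id)
  known <- as.integer(names(labels)[labels %in% names(group_map) &
                                      group_map[labels] %in% names(fingerprints)])
  if (!length(known)) abort("no known-NAT cluster in the clustering")
  unchar <- as.integer(names(labels)[labels == "uncharacterized"])

  adj <- pivot$edges
  neighbours_of <- function(cid) {
    c(adj$to[adj$from == cid], adj$from[adj$to == cid])
  }
  cand <- intersect(unchar, unique(unlist(lapply(known, neighbours_of))))
  cand <- sort(union(cand, intersect(include_isolated, unchar)))
  if (!length(cand)) {
    return(tibble(cluster_id = integer(), neighbour_of = list(),
                  best_group = character(), cluster_p = numeric(),
                  fraction_members = numeric(), n_key_differences = integer(),
                  verdict = character(), differences = list()))
  }

  members_of <- setNames(clustering$clusters$members, clustering$clusters$cluster_id)
  bind_rows(lapply(cand, function(cid) {
    mem <- records %>% filter(.data$id %in% members_of[[as.character(cid)]])
    scans <- lapply(fingerprints, fingerprint_score, sequences = mem,
                    alpha = alpha)
    best_i <- which.min(vapply(scans, `[[`, numeric(1), "cluster_p"))
    best <- scans[[best_i]]
    frac <- mean(best$per_sequence$combined_p <= alpha)
    cand_fp <- site_fingerprint(fingerprints[[best_i]], best, mem)
    diffs <- suppressWarnings(
      diff_fingerprints(fingerprints[[best_i]], cand_fp)
    )
    n_key <- sum(diffs$key)
    # "consistent": most members carry the fingerprint and no key position
    # changed. "divergent": motif signal is present (half the members pass,
    # or the median member matches at the 5% level) but key positions
    # differ or the match is partial. "no-match": no signal beyond the
    # false-positive noise a combined p-value threshold admits.
    verdict <- if (frac >= 0.5 && n_key == 0) "consistent"
      else if (frac >= 0.5 || best$cluster_p <= 0.05) "divergent"
      else "no-match"
    tibble(
      cluster_id = cid,
      neighbour_of = list(sort(intersect(known, neighbours_of(cid)))),
      best_group = fingerprints[[best_i]]$name,
      cluster_p = best$cluster_p,
      fraction_members = frac,
      n_key_differences = as.integer(n_key),
      verdict = verdict,
      differences = list(diffs)
    )
  }))
}

default_group_map <- function(fingerprint_names) {
  canonical <- c(
    NAA10 = "Group 1a", NAA20 = "Group 1a", NAA30 = "Group 1b",
    NAA50 = "Group 2", NAA60 = "Group 2", NAA40 = "Group 3",
    NAA80 = "Group 4"
  )
  c(canonical[canonical %in% fingerprint_names],
    setNames(fingerprint_names, fingerprint_names))
}

# Rebuild a candidate cluster's element motifs from the members' best
# hit sites for each reference element motif (MAST-style site alignment),
# so that reference and candidate can be diffed column by column.
site_fingerprint <- function(reference, scan, records) {
  residues <- setNames(records$residues, records$id)
  motifs <- list()
  for (el in names(reference$motifs)) {
    ref <- reference$motifs[[el]]
    hits <- scan$per_motif %>% filter(.data$element == el)
    if (!nrow(hits)) next
    words <- substr(residues[hits$seq_id], hits$position + 1,
                    hits$position + ref$width)
    counts <- matrix(0.01, 20, ref$width,
                     dimnames = list(amino_acids(), NULL))
    for (wd in words) {
      ch <- strsplit(wd, "")[[1]]
      ok <- which(ch %in% amino_acids())
      counts[cbind(match(ch[ok], amino_acids()), ok)] <-
        counts[cbind(match(ch[ok], amino_acids()), ok)] + 1
    }
    ppm <- sweep(counts, 2, colSums(counts), `/`)
    motifs[[el]] <- new_motif(ppm, ref$background, n_sites = length(words),
                              element = el, name = paste("candidate", el))
  }
  group_fingerprint(paste0(scan$group, " candidate"), motifs)
}

#' Write candidate reports as TSV and a human-readable text report
#'
#' @param reports Tibble from [predict_nat_candidates()].
#' @param tsv_path TSV output path (list columns flattened).
#' @param text_path Optional path for a per-candidate plain-text summary
#'   listing the per-element modal-residue differences.
#' @return `tsv_path`, invisibly.
#' @export
write_candidate_report <- function(reports, tsv_path, text_path = NULL) {
  flat <- reports %>%
    mutate(neighbour_of = vapply(.data$neighbour_of, paste, character(1),
                                 collapse = ","),
           n_differences = vapply(.data$differences, nrow, integer(1))) %>%
    select(-"differences")
  write.table(flat, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(reports))) {
      writeLines(sprintf(
        "Cluster %d (neighbour of %s): best match %s, median combined p = %.3g, verdict %s",
        reports$cluster_id[i],
        paste(reports$neighbour_of[[i]], collapse = ", "),
        reports$best_group[i], reports$cluster_p[i], reports$verdict[i]
      ), con)
      d <- reports$differences[[i]]
      for (j in seq_len(nrow(d))) {
        writeLines(sprintf(
          "  %s position %d: %s (%.2f) is replaced by %s (%.2f)%s",
          d$element[j], d$position_1[j], d$residue_1[j], d$freq_1[j],
          d$residue_2[j], d$freq_2[j],
          if (d$key[j]) " [key position]" else ""
        ), con)
      }
    }
  }
  invisible(tsv_path)
}
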