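#' Tidy an SSN into its edge table
#'
#' @param x An `ssn`.
#' @param ... Unused.
#' @return Tibble of edges: `query_id`, `subject_id`, `pct_identity`,
#'   `evalue`, `edge_score`.
#' @export
tidy.ssn <- function(x, ...) x$edges

#' One-row SSN summary
#'
#' @param x An `ssn`.
#' @param ... Unused.
#' @return Tibble: `n_nodes`, `n_edges`, `convergence_ratio`,
#'   `evalue_max`, `score_min`, `n_components`.
#' @export
glance.ssn <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    convergence_ratio = x$convergence_ratio,
    evalue_max = unname(x$thresholds["evalue_max"]),
    score_min = unname(x$thresholds["score_min"]),
    n_components = max(ssn_components(x)$component_id, 0)
  )
}

#' Tidy a clustering into its membership table
#'
#' @param x A `nat_clustering`.
#' @param ... Unused.
#' @return Tibble `id`, `cluster_id`, plus cluster `label` and `size`.
#' @export
tidy.nat_clustering <- function(x, ...) {
  x$membership %>%
    left_join(x$clusters %>% select("cluster_id", "size", "label"),
              by = "cluster_id")
}

#' One-row clustering summary
#'
#' @param x A `nat_clustering`.
#' @param ... Unused.
#' @return Tibble: `n_clusters`, `n_assigned`, `n_unassigned`,
#'   `mean_size`, `mean_cohesiveness`.
#' @export
glance.nat_clustering <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_assigned = length(unique(x$membership$id)),
    n_unassigned = length(x$unassigned),
    mean_size = if (nrow(x$clusters)) mean(x$clusters$size) else NA_real_,
    mean_cohesiveness = if (nrow(x$clusters)) mean(x$clusters$cohesiveness)
                        else NA_real_
  )
}

#' Tidy a motif into a long position/residue/probability table
#'
#' @param x A `nat_motif`.
#' @param ... Unused.
#' @return Tibble: `position` (1-based column), `residue`, `prob`.
#' @export
tidy.nat_motif <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$width), each = length(x$alphabet)),
    residue = rep(x$alphabet, x$width),
    prob = as.vector(x$ppm)
  )
}

#' One-row motif summary
#'
#' @param x A `nat_motif`.
#' @param ... Unused.
#' @return Tibble: `name`, `width`, `n_sites`, `evalue`,
#'   `information_bits`, `consensus`.
#' @export
glance.nat_motif <- function(x, ...) {
  tibble(
    name = x$name, width = x$width, n_sites = x$n_sites,
    evalue = x$evalue, information_bits = motif_information(x),
    consensus = regex_from_motif(x)
  )
}

#' Tidy a small-world result
#'
#' @param x A `smallworld_stats`.
#' @param ... Unused.
#' @return One-row tibble with `C`, `L`, `C_rand`, `L_rand`, `sigma`,
#'   `is_smallworld`.
#' @export
tidy.smallworld_stats <- function(x, ...) {
  tibble(C = x$C, L = x$L, C_rand = x$C_rand, L_rand = x$L_rand,
         sigma = x$sigma, is_smallworld = x$is_smallworld)
}

#' Tidy a fingerprint scan into its per-motif hit table
#'
#' @param x A `fingerprint_scan`.
#' @param ... Unused.
#' @return The per-motif tibble.
#' @export
tidy.fingerprint_scan <- function(x, ...) x$per_motif

#' One-row fingerprint-scan summary
#'
#' @param x A `fingerprint_scan`.
#' @param ... Unused.
#' @return Tibble: `group`, `n_sequences`, `cluster_p`,
#'   `fraction_present`.
#' @export
glance.fingerprint_scan <- function(x, ...) {
  tibble(
    group = x$group,
    n_sequences = nrow(x$per_sequence),
    cluster_p = x$cluster_p,
    fraction_present = mean(x$per_motif$present)
  )
}

#' Tidy a pipeline manifest into the stage/output/hash table
#'
#' @param x A `pipeline_manifest`.
#' @param ... Unused.
#' @return Tibble: `stage`, `output`, `md5`.
#' @export
tidy.pipeline_manifest <- function(x, ...) x$stages
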