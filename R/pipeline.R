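#' Assemble a pipeline configuration
#'
#' One flat, hashable list controlling every stage. Either `input_fasta`
#' or a `synthetic` block must be supplied. The configuration can be
#' round-tripped through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]).
#'
#' @param input_fasta FASTA path, or `NULL` when simulating.
#' @param synthetic `NULL`, or a list with `n_families`, `n_sequences`,
#'   `scaffold_length`, `within_identity`, `labelled_fraction` describing
#'   the synthetic superfamily to generate.
#' @param identity_steps Redundancy-filter steps (descending fractions).
#' @param evalue_max,score_min SSN edge thresholds.
#' @param min_size,penalty,overlap_omega,min_density Clustering controls
#'   (see [clustering_params()]).
#' @param max_motifs,width_range,n_shuffle Motif discovery controls.
#' @param alpha Prediction p-value threshold.
#' @param smallworld `NULL`, or a list with `grid` (data frame of
#'   `evalue_max`, `score_min`), `n_ref` and `k` (representatives per
#'   cluster).
#' @param zscore_csv Optional CSV of a structural Z-score matrix for the
#'   structure branch.
#' @param seed Integer master seed; per-stage seeds derive from it.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_fasta = NULL, synthetic = NULL,
                            identity_steps = c(0.9, 0.8, 0.7),
                            evalue_max = 1e-5, score_min = 5,
                            min_size = 10, penalty = 2.0,
                            overlap_omega = 0.8, min_density = "auto",
                            max_motifs = 25, width_range = 5:10,
                            n_shuffle = 20, alpha = 0.01,
                            smallworld = NULL, zscore_csv = NULL,
                            seed = 1, out_dir = tempfile("ssnat_run_")) {
  if (is.null(input_fasta) && is.null(synthetic)) {
    abort("supply `input_fasta` or a `synthetic` block")
  }
  structure(
    list(input_fasta = input_fasta, synthetic = synthetic,
         identity_steps = identity_steps,
         evalue_max = evalue_max, score_min = score_min,
         min_size = min_size, penalty = penalty,
         overlap_omega = overlap_omega, min_density = min_density,
         max_motifs = max_motifs, width_range = width_range,
         n_shuffle = n_shuffle, alpha = alpha,
         smallworld = smallworld, zscore_csv = zscore_csv,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$width_range <- if (!is.null(raw$width_range)) as.integer(raw$width_range)
  if (!is.null(raw$smallworld) && !is.null(raw$smallworld$grid)) {
    raw$smallworld$grid <- as_tibble(as.data.frame(raw$smallworld$grid))
  }
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$smallworld) && is.data.frame(cfg$smallworld$grid)) {
    cfg$smallworld$grid <- as.list(as.data.frame(cfg$smallworld$grid))
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Demo configuration on a packaged synthetic superfamily
#'
#' Three planted families of ten 150-residue sequences at 0.75 pairwise
#' within-family identity, run at the permissive SSN thresholds used for
#' validation (E <= 1e-5, score >= 5). Redundancy filtering uses the 0.9
#' step only: the planted families sit at ~0.75-0.80 pairwise identity,
#' which a 70-80% collapse would erase before clustering could see them.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param n_families,n_sequences Family layout.
#' @param ... Further overrides passed to [pipeline_config()].
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1, out_dir = tempfile("ssnat_demo_"),
                                 n_families = 3, n_sequences = 10, ...) {
  pipeline_config(
    synthetic = list(n_families = n_families, n_sequences = n_sequences,
                     scaffold_length = 150, within_identity = 0.75,
                     labelled_fraction = 0.2),
    identity_steps = 0.9,
    evalue_max = 1e-5, score_min = 5, min_size = min(10, n_sequences),
    seed = seed, out_dir = out_dir, ...
  )
}

stage_log <- function(stage, fmt, ...) {
  inform(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                 sprintf(fmt, ...)))
}

#' Run the full classification pipeline
#'
#' Stages execute in order: simulate/read, redundancy filter, all-vs-all
#' alignment, SSN construction, cluster detection, pivot contraction,
#' annotation transfer, per-group motif discovery, fingerprint assembly,
#' candidate prediction; optionally the small-world grid scan with
#' representative selection and the structure branch. Every output file
#' is recorded in a manifest with its content hash; a rerun with the same
#' configuration and seed reproduces identical hashes.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_manifest`: list with `config`, `stages` (tibble:
#'   `stage`, `output`, `md5`), `counts`, and the in-memory `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  seed <- config$seed
  record <- function(stage, ...) {
    files <- c(...)
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, output = basename(files),
      md5 = unname(tools::md5sum(files))
    )
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            parent = e)
    })
  }

  # -- input ------------------------------------------------------------
  run_stage("input", {
    if (!is.null(config$synthetic)) {
      sy <- config$synthetic
      specs <- lapply(seq_len(sy$n_families), function(i) {
        family_spec(sprintf("FAM%02d", i), sy$n_sequences,
                    scaffold_length = sy$scaffold_length %||% 150,
                    target_within_identity = sy$within_identity %||% 0.75,
                    labelled_fraction = sy$labelled_fraction %||% 0.2)
      })
      sim <- generate_superfamily(specs, seed = seed)
      results$records <- sim$records
      results$truth <- sim$truth
      f1 <- file.path(out, "sequences.fasta")
      write_fasta_records(sim$records, f1)
      f2 <- file.path(out, "truth.tsv")
      write_truth_tsv(sim$truth, f2)
      record("input", f1, f2)
    } else {
      results$records <- read_fasta_records(config$input_fasta)
      f1 <- file.path(out, "sequences.fasta")
      write_fasta_records(results$records, f1)
      record("input", f1)
    }
    stage_log("input", "%d sequences", nrow(results$records))
  })

  params <- align_params()

  run_stage("filter", {
    flt <- redundancy_filter(results$records, config$identity_steps, params)
    results$representatives <- flt$representatives
    f1 <- file.path(out, "representatives.fasta")
    write_fasta_records(flt$representatives, f1)
    f2 <- file.path(out, "assignment.tsv")
    write.table(flt$assignment, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    record("filter", f1, f2)
    stage_log("filter", "%d representatives", nrow(flt$representatives))
  })

  run_stage("allvsall", {
    cutoff <- config$evalue_max
    if (!is.null(config$smallworld)) {
      cutoff <- max(cutoff, config$smallworld$grid$evalue_max)
    }
    results$hits <- all_vs_all(results$representatives, params,
                                evalue_cutoff = cutoff)
    f1 <- file.path(out, "hits.tsv")
    write_hits_tsv(results$hits, f1)
    record("allvsall", f1)
    stage_log("allvsall", "%d hits", nrow(results$hits))
  })

  run_stage("ssn", {
    results$ssn <- build_ssn(results$hits, config$evalue_max,
                              config$score_min, results$representatives)
    f1 <- file.path(out, "ssn_edges.tsv"); f2 <- file.path(out, "ssn_nodes.tsv")
    write_ssn_tsv(results$ssn, f1, f2)
    f3 <- file.path(out, "ssn.graphml")
    write_network_graphml(results$ssn, f3)
    record("ssn", f1, f2, f3)
    stage_log("ssn", "%d edges, convergence ratio %.4g",
              nrow(results$ssn$edges), results$ssn$convergence_ratio)
  })

  run_stage("cluster", {
    cp <- clustering_params(config$min_size, config$penalty,
                            config$overlap_omega, config$min_density)
    results$clustering <- detect_clusters(results$ssn, cp)
    f1 <- file.path(out, "cluster_membership.tsv")
    f2 <- file.path(out, "cluster_summary.tsv")
    write_clustering_tsv(results$clustering, f1, f2, results$representatives)
    record("cluster", f1, f2)
    stage_log("cluster", "%d clusters", nrow(results$clustering$clusters))
  })

  run_stage("pivot", {
    results$pivot <- contract(results$ssn, results$clustering)
    f1 <- file.path(out, "pivot.graphml")
    write_network_graphml(results$pivot, f1)
    f2 <- file.path(out, "pivot_topology.tsv")
    write_pivot_report(results$pivot, f2)
    f3 <- file.path(out, "pivot.xgmml")
    write_network_xgmml(results$pivot, f3, "pivot network")
    record("pivot", f1, f2, f3)
    stage_log("pivot", "%d nodes, %d edges",
              nrow(results$pivot$nodes), nrow(results$pivot$edges))
  })

  run_stage("transfer", {
    results$clustering <- transfer_annotations(results$clustering,
                                                results$records)
    f1 <- file.path(out, "annotations.tsv")
    write.table(results$clustering$annotations, f1, sep = "\t",
                quote = FALSE, row.names = FALSE)
    record("transfer", f1)
    stage_log("transfer", "%d labelled clusters",
              sum(!results$clustering$clusters$label %in%
                    c("uncharacterized", "mixed")))
  })

  run_stage("motifs", {
    results$group_motifs <- discover_group_motifs(
      results$clustering, results$records,
      max_motifs = config$max_motifs, width_range = config$width_range,
      n_shuffle = config$n_shuffle, seed = seed + 1,
      truth = results$truth
    )
    f1 <- file.path(out, "group_motifs.meme")
    all_motifs <- unlist(lapply(results$group_motifs, `[[`, "motifs"),
                         recursive = FALSE)
    if (length(all_motifs)) write_meme_minimal(all_motifs, f1) else writeLines("", f1)
    record("motifs", f1)
    stage_log("motifs", "%d groups with motifs", length(results$group_motifs))
  })

  run_stage("fingerprints", {
    results$fingerprints <- lapply(results$group_motifs, function(gm) {
      group_fingerprint(gm$group, gm$motifs)
    })
    f1 <- file.path(out, "fingerprints.tsv")
    if (length(results$fingerprints)) {
      write_fingerprint_tsv(results$fingerprints, f1)
    } else {
      writeLines("group\telement\tregex", f1)
    }
    record("fingerprints", f1)
    stage_log("fingerprints", "%d fingerprints", length(results$fingerprints))
  })

  run_stage("predict", {
    results$candidates <- if (length(results$fingerprints)) {
      predict_nat_candidates(results$pivot, results$clustering,
                             results$fingerprints, results$records,
                             alpha = config$alpha)
    } else {
      abort("no known-NAT cluster (no fingerprints could be built)")
    }
    f1 <- file.path(out, "candidates.tsv")
    f2 <- file.path(out, "candidates.txt")
    write_candidate_report(results$candidates, f1, f2)
    record("predict", f1, f2)
    stage_log("predict", "%d candidate clusters", nrow(results$candidates))
  })

  if (!is.null(config$smallworld)) {
    run_stage("smallworld", {
      sw <- config$smallworld
      results$grid <- grid_scan(results$hits, sw$grid,
                                 results$representatives,
                                 n_ref = sw$n_ref %||% 10, seed = seed + 2)
      f1 <- file.path(out, "smallworld_grid.tsv")
      write.table(results$grid %>% select(-"component"), f1, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      chosen <- select_phylogeny_component(results$grid)
      results$phylogeny_component <- chosen
      reps <- select_representatives(results$clustering, chosen,
                                     results$records,
                                     k = sw$k %||% 3, seed = seed + 3)
      results$phylogeny_representatives <- reps
      f2 <- file.path(out, "phylogeny_representatives.fasta")
      write_fasta_records(
        results$records %>% filter(.data$id %in% reps$seq_id), f2)
      record("smallworld", f1, f2)
      stage_log("smallworld", "component of %d chosen",
                chosen$largest_component_size)
    })
  }

  if (!is.null(config$zscore_csv)) {
    run_stage("structnet", {
      Z <- read_zscore_csv(config$zscore_csv)
      f1 <- file.path(out, "structure_dendrogram.nwk")
      build_dendrogram(Z, f1)
      zsep <- separation_threshold(Z)
      results$separation_z <- zsep
      f2 <- file.path(out, "structure_network.graphml")
      write_network_graphml(threshold_network(Z, if (is.na(zsep)) 2 else zsep), f2)
      record("structnet", f1, f2)
      stage_log("structnet", "separation threshold %s", zsep)
    })
  }

  stages <- bind_rows(manifest)
  structure(
    list(config = config, stages = stages, results = results,
         counts = list(
           n_sequences = nrow(results$records),
           n_representatives = nrow(results$representatives),
           n_hits = nrow(results$hits),
           n_edges = nrow(results$ssn$edges),
           n_clusters = nrow(results$clustering$clusters),
           n_candidates = if (is.null(results$candidates)) 0L
                          else nrow(results$candidates)
         )),
    class = "pipeline_manifest"
  )
}

# Discover motifs per labelled group, pooling member sequences of all
# clusters sharing the label. When planted truth is available, element
# labels are assigned to discovered motifs by majority overlap of their
# sites with the planted intervals.
discover_group_motifs <- function(clustering, records, max_motifs,
                                  width_range, n_shuffle, seed,
                                  truth = NULL) {
  records <- as_records(records)
  labs <- clustering$clusters$label
  groups <- setdiff(unique(labs), c("uncharacterized", "mixed"))
  out <- list()
  for (g in sort(groups)) {
    members <- unique(unlist(
      clustering$clusters$members[labs == g]
    ))
    seqs <- records %>% filter(.data$id %in% members)
    if (nrow(seqs) < 5) next
    motifs <- discover_motifs(seqs, max_motifs = max_motifs,
                              width_range = width_range, seed = seed,
                              n_shuffle = n_shuffle)
    if (!length(motifs)) next
    names(motifs) <- vapply(seq_along(motifs), function(i) {
      el <- if (!is.null(truth)) motif_element_from_truth(motifs[[i]], truth)
            else NA_character_
      if (!is.na(el) ) el else sprintf("m%d", i)
    }, character(1))
    # element labels must be unique within a fingerprint
    names(motifs) <- make.unique(names(motifs), sep = "_")
    for (i in seq_along(motifs)) motifs[[i]]$element <- names(motifs)[i]
    out[[g]] <- list(group = g, motifs = motifs)
  }
  out
}

motif_element_from_truth <- function(motif, truth) {
  if (is.null(motif$sites) || !nrow(motif$sites)) return(NA_character_)
  hits <- motif$sites %>%
    left_join(truth$motif_positions, by = "seq_id",
              relationship = "many-to-many") %>%
    filter(!is.na(.data$start.y)) %>%
    mutate(ov = pmax(0, pmin(.data$start.x + motif$width, .data$end) -
                       pmax(.data$start.x, .data$start.y))) %>%
    filter(.data$ov >= motif$width / 2)
  if (!nrow(hits)) return(NA_character_)
  names(sort(table(hits$element), decreasing = TRUE))[1]
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run: %d stage(s), %d output file(s)\n",
              length(unique(x$stages$stage)), nrow(x$stages)))
  cat(sprintf("  sequences %d | representatives %d | hits %d | edges %d | clusters %d | candidates %d\n",
              x$counts$n_sequences, x$counts$n_representatives,
              x$counts$n_hits, x$counts$n_edges, x$counts$n_clusters,
              x$counts$n_candidates))
  invisible(x)
}

#' Write the run manifest as JSON
#'
#' Stage/output/hash triples plus the configuration; deliberately free of
#' timestamps so reruns with identical config and seeds are
#' byte-identical.
#'
#' @param manifest A `pipeline_manifest`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(manifest, path) {
  cfg <- unclass(manifest$config)
  cfg$out_dir <- NULL  # run-specific, would break rerun identity
  if (!is.null(cfg$smallworld) && is.data.frame(cfg$smallworld$grid)) {
    cfg$smallworld$grid <- as.list(as.data.frame(cfg$smallworld$grid))
  }
  jsonlite::write_json(
    list(config = cfg,
         counts = manifest$counts,
         stages = manifest$stages),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
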