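#' Hierarchical clustering dendrogram from a structural Z-score matrix
#'
#' Similarities are converted to distances by `d = Z_max - Z` (with
#' `Z_max` the largest off-diagonal entry) and clustered by average
#' linkage. Input rows/columns are reordered lexicographically by id
#' first so the result is invariant to input order (ties in the merge
#' sequence are then resolved identically for any permutation of the same
#' matrix).
#'
#' @param zmatrix Symmetric non-negative matrix with structure ids as
#'   dimnames (>= 2 structures); asymmetries beyond 1e-6 are an error.
#' @param newick_path Optional path to also write the tree as newick.
#' @return An [ape::as.phylo()] tree; branch lengths from merge heights.
#' @export
build_dendrogram <- function(zmatrix, newick_path = NULL) {
  Z <- check_zmatrix(zmatrix)
  if (nrow(Z) < 2) abort("need at least 2 structures")
  ord <- order(rownames(Z))
  Z <- Z[ord, ord]
  off <- Z; diag(off) <- NA
  zmax <- max(off, na.rm = TRUE)
  d <- zmax - Z
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  tree <- ape::as.phylo(hc)
  if (!is.null(newick_path)) ape::write.tree(tree, newick_path)
  tree
}

check_zmatrix <- function(Z) {
  stopifnot(is.matrix(Z), nrow(Z) == ncol(Z), !is.null(rownames(Z)))
  if (max(abs(Z - t(Z))) > 1e-6) abort("Z-score matrix must be symmetric")
  off <- Z; diag(off) <- 0
  if (any(off < 0)) abort("off-diagonal Z-scores must be non-negative")
  Z
}

#' Structure similarity network at a Z-score threshold
#'
#' Edge (i, j) iff `Z_ij > z_min` (strict); no self-edges.
#'
#' @param zmatrix Symmetric Z-score matrix with ids as dimnames.
#' @param z_min Non-negative threshold.
#' @return An igraph on the structure ids.
#' @export
threshold_network <- function(zmatrix, z_min) {
  Z <- check_zmatrix(zmatrix)
  if (z_min < 0) abort("`z_min` must be >= 0")
  A <- Z > z_min
  diag(A) <- FALSE
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

#' Smallest integer Z threshold separating structural clusters
#'
#' Scans integer thresholds from 0 up to `ceiling(Z_max)` and returns the
#' first at which the threshold network splits into at least 2 components
#' of size `min_component_size` or more (stripping singletons off a
#' hairball does not count as separation). Returns `NA` with a message if
#' no threshold qualifies.
#'
#' @param zmatrix Symmetric Z-score matrix.
#' @param min_component_size Minimum size of the separated components
#'   (>= 2; default 3).
#' @return Integer threshold, or `NA_integer_`.
#' @export
separation_threshold <- function(zmatrix, min_component_size = 3) {
  stopifnot(min_component_size >= 2)
  Z <- check_zmatrix(zmatrix)
  off <- Z; diag(off) <- NA
  zmax <- max(off, na.rm = TRUE)
  for (z in 0:ceiling(zmax)) {
    g <- threshold_network(Z, z)
    sizes <- igraph::components(g)$csize
    if (sum(sizes >= min_component_size) >= 2) return(as.integer(z))
  }
  inform("no integer threshold separates the structures into >= 2 sizeable components")
  NA_integer_
}

#' Read a PDB chain list for structure labelling
#'
#' Plain-text TSV with columns `pdb`, `chain`, `name`; used only to label
#' structures in reports and dendrograms.
#'
#' @param path TSV path.
#' @return Tibble `pdb`, `chain`, `name`.
#' @export
read_pdb_list <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("pdb", "chain", "name") %in% names(df)))
  as_tibble(df)
}
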