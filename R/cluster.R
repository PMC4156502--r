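#' Hierarchical correlation clustering of expression profiles
#'
#' Groups genes by profile shape using agglomerative clustering with
#' distance `1 - Pearson correlation` between log2 profiles, cut into a
#' requested number of groups. This is the built-in, pluggable clustering
#' stage; externally computed assignments (e.g., from a Bayesian spline
#' clustering tool) can be imported with [load_external_clusters()]
#' instead. Genes with constant profiles (undefined correlation) are
#' excluded with a warning.
#'
#' @param profiles Gene-by-time matrix of log2 profiles (complete).
#' @param n_clusters Number of clusters (1..number of genes).
#' @param linkage Agglomeration method (default `"average"`).
#' @return Object of class `"cluster_assignment"`: `assignment` (named
#'   integer vector, ids contiguous from 1), `method`, `parameters`,
#'   `excluded`, and the underlying `hclust` tree.
#' @export
cluster_profiles <- function(profiles, n_clusters, linkage = "average") {
  stopifnot(is.matrix(profiles))
  if (anyNA(profiles)) stop("profiles must be complete")
  ids <- rownames(profiles) %||% sprintf("g%04d", seq_len(nrow(profiles)))
  rownames(profiles) <- ids
  sds <- apply(profiles, 1L, sd)
  excluded <- ids[sds == 0]
  if (length(excluded))
    warning(length(excluded),
            " constant profile(s) excluded from clustering")
  keep <- profiles[sds > 0, , drop = FALSE]
  n <- nrow(keep)
  if (n_clusters < 1L || n_clusters > n)
    stop("n_clusters must be between 1 and the number of usable genes")
  d <- as.dist(1 - cor(t(keep)))
  hc <- hclust(d, method = linkage)
  cl <- cutree(hc, k = n_clusters)
  # contiguous ids in order of first appearance in the input
  cl <- as.integer(factor(cl, levels = unique(cl)))
  names(cl) <- rownames(keep)
  structure(list(assignment = cl, method = "hclust_pearson",
                 parameters = list(n_clusters = n_clusters,
                                   linkage = linkage),
                 excluded = excluded, hclust = hc),
            class = "cluster_assignment")
}

#' Import an externally computed cluster assignment
#'
#' Reads a two-column TSV (`gene_id`, `cluster_id`); cluster ids are
#' remapped to contiguous integers from 1 in order of first appearance.
#' Genes absent from `cohort_genes` (when given) are reported with a
#' warning.
#'
#' @param path Path to the TSV file.
#' @param cohort_genes Optional character vector of known gene ids.
#' @return A `"cluster_assignment"` (without a tree).
#' @export
load_external_clusters <- function(path, cohort_genes = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expected a two-column TSV: gene_id, cluster_id")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene_id rows: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  cl <- as.integer(factor(tab[[2L]], levels = unique(tab[[2L]])))
  names(cl) <- genes
  unknown <- character(0)
  if (!is.null(cohort_genes)) {
    unknown <- setdiff(genes, cohort_genes)
    if (length(unknown))
      warning("genes not in the cohort: ",
              paste(head(unknown, 5), collapse = ", "))
  }
  structure(list(assignment = cl, method = "external",
                 parameters = list(path = path), excluded = character(0),
                 unknown = unknown, hclust = NULL),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment (%s): %d genes in %d clusters\n",
              x$method, length(x$assignment), max(x$assignment)))
  if (length(x$excluded))
    cat(sprintf("  excluded constant profiles: %d\n", length(x$excluded)))
  invisible(x)
}

#' Split a cluster assignment into a list of gene-id vectors
#'
#' @param assignment A `"cluster_assignment"`.
#' @return Named list (cluster id as name) of character vectors.
#' @export
cluster_members <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  split(names(assignment$assignment), assignment$assignment)
}

#' Export the clustering dendrogram as Newick
#'
#' Writes the hierarchical tree (leaf names = gene ids) in Newick format
#' for external inspection.
#'
#' @param assignment A `"cluster_assignment"` produced by
#'   [cluster_profiles()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_dendrogram <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (is.null(assignment$hclust))
    stop("no dendrogram available (external assignment)")
  phy <- ape::as.phylo(assignment$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
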