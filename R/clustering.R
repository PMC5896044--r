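#' Drug clustering result
#'
#' A possibly-overlapping assignment of drugs to clusters with provenance.
#' Partial coverage is allowed: algorithms such as ClusterONE or MCODE may
#' leave some drugs outside every cluster.
#'
#' @param membership named list, cluster id -> non-empty character vector of
#'   drug ids; a drug may appear in several clusters.
#' @param algorithm label of the producing algorithm.
#' @param parameters named list recording the parameters used.
#' @return an object of class `drug_clustering`.
#' @export
drug_clustering <- function(membership, algorithm = "unknown",
                            parameters = list()) {
  if (!length(membership)) membership <- structure(list(), names = character(0))
  if (is.null(names(membership)) && length(membership))
    names(membership) <- as.character(seq_along(membership))
  membership <- lapply(membership, function(m) sort(unique(as.character(m))))
  if (any(lengths(membership) == 0L)) stop("clusters must be non-empty")
  structure(
    list(algorithm = as.character(algorithm)[1], parameters = parameters,
         membership = membership),
    class = "drug_clustering")
}

#' @export
print.drug_clustering <- function(x, ...) {
  sizes <- lengths(x$membership)
  cat("Drug clustering [", x$algorithm, "]: ", length(sizes), " clusters, ",
      length(covered_drugs(x)), " drugs covered", sep = "")
  if (length(sizes))
    cat(" (sizes ", min(sizes), "-", max(sizes), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Drugs covered by a clustering
#'
#' @param clustering a [drug_clustering()].
#' @return sorted character vector, the union of all cluster memberships.
#' @export
covered_drugs <- function(clustering) {
  stopifnot(inherits(clustering, "drug_clustering"))
  sort(unique(unlist(clustering$membership, use.names = FALSE)))
}

#' Reduce a clustering to a partition label vector
#'
#' External comparison indices (mutual-information based) are defined on
#' partitions. Overlapping assignments are resolved by keeping, for each
#' drug, its largest containing cluster (ties broken by lexicographic
#' cluster id); drugs outside every cluster receive their own singleton
#' label so that every drug of the universe is labeled.
#'
#' @param clustering a [drug_clustering()].
#' @param universe drug ids the labels must cover; defaults to the covered
#'   drugs.
#' @return named character vector of cluster labels, in `universe` order.
#' @export
clustering_to_partition <- function(clustering, universe = NULL) {
  stopifnot(inherits(clustering, "drug_clustering"))
  if (is.null(universe)) universe <- covered_drugs(clustering)
  universe <- as.character(universe)
  mem <- clustering$membership
  ord <- order(-lengths(mem), names(mem))   # biggest first, then lexicographic
  labels <- stats::setNames(rep(NA_character_, length(universe)), universe)
  for (cl in ord) {
    members <- intersect(mem[[cl]], universe)
    take <- members[is.na(labels[members])]
    labels[take] <- names(mem)[cl]
  }
  orphan <- is.na(labels)
  labels[orphan] <- paste0(".singleton.", names(labels)[orphan])
  labels
}

#' Read / write clusterings as membership TSV
#'
#' Serialized as two columns `drug_id`, `cluster_id`, one row per
#' membership; overlap shows up as repeated drug ids.
#'
#' @param path file path.
#' @param algorithm,parameters provenance attached on read.
#' @return [read_clustering()] returns a [drug_clustering()];
#'   [write_clustering()] returns `path` invisibly.
#' @export
read_clustering <- function(path, algorithm = "unknown", parameters = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  membership <- split(tab$drug_id, tab$cluster_id)
  drug_clustering(membership, algorithm, parameters)
}

#' @rdname read_clustering
#' @param clustering a [drug_clustering()].
#' @export
write_clustering <- function(clustering, path) {
  stopifnot(inherits(clustering, "drug_clustering"))
  df <- data.frame(
    drug_id = unlist(clustering$membership, use.names = FALSE),
    cluster_id = rep(names(clustering$membership),
                     lengths(clustering$membership)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write weighted graphs as edge-list TSV
#'
#' Three columns `drug_a`, `drug_b`, `weight`; undirected, weights in (0, 1].
#'
#' @param path file path.
#' @return [read_edge_list()] returns an undirected weighted [igraph::graph].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           colClasses = c("character", "character", "numeric"))
  igraph::graph_from_data_frame(tab, directed = FALSE)
}

#' @rdname read_edge_list
#' @param graph an undirected weighted igraph object.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  names(el)[1:2] <- c("drug_a", "drug_b")
  utils::write.table(el[, c("drug_a", "drug_b", "weight")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
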