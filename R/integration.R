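#' Drug-drug relation (DDR) matrix
#'
#' Symmetric drug x drug similarity in \[0, 1\]. A per-view DDR derived
#' from one clustering is binary (co-membership indicator); the average of
#' `m` binary DDRs takes values in `{0, 1/m, ..., 1}`.
#'
#' @param values symmetric numeric matrix in \[0, 1\] with drug ids as
#'   dimnames.
#' @param source provenance record (free-form list).
#' @return an object of class `ddr_matrix`.
#' @export
ddr_matrix <- function(values, source = list()) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("DDR matrix must be square")
  if (is.null(rownames(values))) stop("DDR matrix needs drug ids as dimnames")
  if (max(abs(values - t(values))) > 1e-9) stop("DDR matrix must be symmetric")
  if (min(values) < -1e-12 || max(values) > 1 + 1e-12)
    stop("DDR values must lie in [0, 1]")
  structure(list(drug_ids = rownames(values), values = values,
                 source = source),
            class = "ddr_matrix")
}

#' @export
print.ddr_matrix <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  cat("DDR matrix: ", length(x$drug_ids), " drugs, ",
      signif(100 * mean(v > 0), 3), "% positive off-diagonal entries\n",
      sep = "")
  invisible(x)
}

#' Derive a binary DDR matrix from a clustering
#'
#' Entry (i, j) is 1 iff drugs i and j share at least one cluster. The
#' diagonal is 1 for drugs covered by the clustering; drugs of the
#' universe left uncovered get all-zero rows (flagged in the provenance).
#'
#' @param clustering a [drug_clustering()].
#' @param universe ordered drug ids of the output matrix; the clustering's
#'   covered drugs must be a subset.
#' @return a binary [ddr_matrix()].
#' @examples
#' cl <- drug_clustering(list(C1 = c("D1", "D2"), C2 = "D3"))
#' ddr_from_clustering(cl, c("D1", "D2", "D3"))$values
#' @export
ddr_from_clustering <- function(clustering, universe) {
  stopifnot(inherits(clustering, "drug_clustering"))
  universe <- as.character(universe)
  cov <- covered_drugs(clustering)
  unknown <- setdiff(cov, universe)
  if (length(unknown))
    stop("clustering contains drugs outside the universe: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  n <- length(universe)
  m <- matrix(0, n, n, dimnames = list(universe, universe))
  for (members in clustering$membership) {
    idx <- match(members, universe)
    m[idx, idx] <- 1
  }
  ddr_matrix(m, source = list(type = "co_membership",
                              algorithm = clustering$algorithm,
                              uncovered = setdiff(universe, cov)))
}

#' Average DDR matrices into one heterogeneous similarity
#'
#' Entrywise arithmetic mean with equal weight per view: each clustering
#' contributes equally to the integrated drug-drug similarity.
#'
#' @param matrices list of [ddr_matrix()] objects sharing one drug order.
#' @return a [ddr_matrix()].
#' @export
average_ddr <- function(matrices) {
  if (inherits(matrices, "ddr_matrix")) matrices <- list(matrices)
  if (!length(matrices)) stop("no DDR matrices to average")
  lapply(matrices, function(m) stopifnot(inherits(m, "ddr_matrix")))
  ids <- matrices[[1]]$drug_ids
  for (m in matrices)
    if (!identical(m$drug_ids, ids))
      stop("DDR matrices do not share the same drug ordering")
  avg <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  ddr_matrix(avg, source = list(type = "average",
                                n_views = length(matrices),
                                views = lapply(matrices, `[[`, "source")))
}

#' Build a weighted graph from a DDR matrix
#'
#' Keeps edges whose similarity reaches `min_weight` and drops self-loops.
#' By default every strictly positive entry is kept, so the exact zeros of
#' an averaged co-membership DDR carve the graph into a sparse structure --
#' the property that makes graph clustering effective on it, in contrast
#' to dense pairwise-similarity integration which yields a complete graph.
#'
#' @param ddr a [ddr_matrix()].
#' @param min_weight minimum edge weight in (0, 1]; `NULL` keeps all
#'   positive entries.
#' @return an undirected weighted [igraph::graph] over all drugs (isolated
#'   vertices included).
#' @export
graph_from_ddr <- function(ddr, min_weight = NULL) {
  stopifnot(inherits(ddr, "ddr_matrix"))
  if (is.null(min_weight)) {
    pos <- ddr$values[ddr$values > 0]
    min_weight <- if (length(pos)) min(pos) else 1
  }
  if (min_weight <= 0)
    stop("min_weight must be positive (a zero threshold would emit a ",
         "complete graph)")
  a <- ddr$values
  a[a < min_weight] <- 0
  diag(a) <- 0
  igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                      weighted = TRUE)
}

#' Concatenate profile views into one wide view (baseline H_y)
#'
#' Input-level integration baseline: all per-view feature vectors are
#' concatenated column-wise into a single binary view whose width is the
#' sum of the per-view widths.
#'
#' @param collection an aligned `profile_collection`.
#' @return a [drug_profile_view()] named `"concat"`.
#' @export
concat_views <- function(collection) {
  if (!inherits(collection, "profile_collection"))
    stop("an aligned profile collection is required")
  mats <- lapply(collection$views, `[[`, "incidence")
  feats <- unlist(lapply(collection$views, `[[`, "feature_ids"),
                  use.names = FALSE)
  if (anyDuplicated(feats))
    feats <- unlist(lapply(collection$views, function(v)
      paste(v$view_name, v$feature_ids, sep = ":")), use.names = FALSE)
  wide <- do.call(cbind, mats)
  colnames(wide) <- feats
  drug_profile_view(wide, "concat")
}

#' Jaccard similarity of two binary vectors
#'
#' `|u AND v| / |u OR v|`; defined as 0 when both vectors are all-zero
#' (two drugs sharing no recorded feature give no evidence of similarity).
#'
#' @param u,v binary vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
jaccard <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  un <- sum(u > 0 | v > 0)
  if (un == 0) return(0)
  sum(u > 0 & v > 0) / un
}

# full pairwise Jaccard matrix of a binary incidence matrix
jaccard_matrix <- function(x) {
  x <- (x > 0) * 1
  inter <- tcrossprod(x)
  r <- rowSums(x)
  union <- outer(r, r, "+") - inter
  j <- ifelse(union == 0, 0, inter / union)
  diag(j) <- 1
  j
}

#' Averaged pairwise Jaccard similarity (baseline H_z)
#'
#' Intermediate-level integration baseline: the per-view Jaccard
#' similarity of every drug pair is averaged over views with equal
#' weights. The result is typically a dense similarity (almost all entries
#' positive), i.e. a complete graph once thresholded at zero.
#'
#' @param collection an aligned `profile_collection`.
#' @return a [ddr_matrix()].
#' @export
average_pairwise_similarity <- function(collection) {
  if (!inherits(collection, "profile_collection"))
    stop("an aligned profile collection is required")
  mats <- lapply(collection$views, function(v) jaccard_matrix(v$incidence))
  avg <- Reduce(`+`, mats) / length(mats)
  diag(avg) <- 1
  ddr_matrix(avg, source = list(type = "average_jaccard",
                                views = names(collection$views)))
}
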