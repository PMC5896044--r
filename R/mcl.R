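#' Markov Clustering (MCL) of a weighted graph
#'
#' Simulates stochastic flow on the graph: the column-stochastic transition
#' matrix is alternately expanded (matrix power) and inflated (entrywise
#' power followed by column renormalization) until the flow is idempotent.
#' Inflation strengthens strong currents and weakens weak ones, so the
#' limiting flow decomposes the graph into attractor regions that are read
#' out as clusters. Larger inflation yields more, smaller clusters.
#'
#' Self-loops are added with weight equal to each vertex's maximum incident
#' edge weight (1 for isolated vertices), the canonical regularization.
#' The attractor structure is symmetrized and its connected components
#' returned, so the output is a partition.
#'
#' @param graph an undirected [igraph::graph] with an edge `weight`
#'   attribute (unit weights assumed otherwise).
#' @param inflation inflation exponent, must exceed 1.
#' @param expansion expansion power, integer >= 2.
#' @param prune_threshold entries below this are zeroed each iteration.
#' @param max_iterations iteration cap; non-convergence raises a warning and
#'   the last iterate is used.
#' @param convergence_tol maximum absolute change defining convergence.
#' @return a [drug_clustering()]; `parameters$converged` and
#'   `parameters$iterations` record convergence diagnostics.
#' @examples
#' g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
#' igraph::V(g)$name <- paste0("d", 1:6)
#' igraph::E(g)$weight <- 1
#' mcl(g)
#' @export
mcl <- function(graph, inflation = 2, expansion = 2L,
                prune_threshold = 1e-5, max_iterations = 100L,
                convergence_tol = 1e-6) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  if (!(inflation > 1)) stop("inflation must exceed 1")
  stopifnot(expansion >= 2, max_iterations >= 1)
  A <- graph_adjacency(graph)
  n <- nrow(A)
  loops <- apply(A, 1, max)
  loops[loops <= 0] <- 1
  diag(A) <- loops
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iterations)) {
    prev <- M
    E <- M
    for (k in seq_len(expansion - 1L)) E <- E %*% M
    E <- E^inflation
    E[E < prune_threshold] <- 0
    cs <- colSums(E)
    cs[cs == 0] <- 1
    M <- sweep(E, 2, cs, "/")
    if (max(abs(M - prev)) < convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iterations,
            " iterations; clustering read from the last iterate")
  # clusters: connected components of the symmetrized attractor support
  S <- (M + t(M)) > prune_threshold
  diag(S) <- TRUE
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(S, mode = "undirected"))
  ids <- rownames(A)
  membership <- split(ids, paste0("mcl_", comp$membership))
  drug_clustering(membership, algorithm = "mcl",
                  parameters = list(inflation = inflation,
                                    expansion = expansion,
                                    prune_threshold = prune_threshold,
                                    iterations = iter,
                                    converged = converged))
}

# dense weighted adjacency with vertex names
graph_adjacency <- function(graph) {
  if (is.null(igraph::E(graph)$weight) && igraph::ecount(graph) > 0)
    igraph::E(graph)$weight <- 1
  A <- as.matrix(igraph::as_adjacency_matrix(
    graph, attr = if (igraph::ecount(graph) > 0) "weight" else NULL,
    sparse = TRUE))
  if (is.null(rownames(A)))
    rownames(A) <- colnames(A) <- as.character(seq_len(nrow(A)))
  A
}

#' One expansion + inflation step of the MCL flow
#'
#' Exposed for inspection of the iteration (e.g. verifying that the final
#' flow matrix is idempotent under one more step).
#'
#' @param M column-stochastic matrix.
#' @inheritParams mcl
#' @return the next column-stochastic iterate.
#' @export
mcl_step <- function(M, inflation = 2, expansion = 2L,
                     prune_threshold = 1e-5) {
  E <- M
  for (k in seq_len(expansion - 1L)) E <- E %*% M
  E <- E^inflation
  E[E < prune_threshold] <- 0
  cs <- colSums(E)
  cs[cs == 0] <- 1
  sweep(E, 2, cs, "/")
}

#' Final MCL flow matrix
#'
#' Runs the same iteration as [mcl()] but returns the converged flow matrix
#' instead of the clustering.
#'
#' @inheritParams mcl
#' @return column-stochastic matrix.
#' @export
mcl_flow <- function(graph, inflation = 2, expansion = 2L,
                     prune_threshold = 1e-5, max_iterations = 100L,
                     convergence_tol = 1e-6) {
  A <- graph_adjacency(graph)
  loops <- apply(A, 1, max)
  loops[loops <= 0] <- 1
  diag(A) <- loops
  M <- sweep(A, 2, colSums(A), "/")
  for (iter in seq_len(max_iterations)) {
    prev <- M
    M <- mcl_step(M, inflation, expansion, prune_threshold)
    if (max(abs(M - prev)) < convergence_tol) break
  }
  M
}
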