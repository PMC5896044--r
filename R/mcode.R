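#' MCODE vertex weight
#'
#' The weight of a vertex is `k * d` where `k` is the core number of the
#' highest k-core of the vertex's closed neighborhood and `d` is that
#' core's density `2|E| / (|V|(|V|-1))`. Dense, clique-like neighborhoods
#' give high weights (3.0 for a vertex of a 4-clique); isolated vertices
#' weigh 0.
#'
#' @param graph an undirected [igraph::graph].
#' @param v vertex name (or all vertices when `NULL`).
#' @return named numeric vector of weights.
#' @export
mcode_vertex_weight <- function(graph, v = NULL) {
  vn <- igraph::V(graph)$name
  if (is.null(vn)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
    vn <- igraph::V(graph)$name
  }
  targets <- if (is.null(v)) vn else as.character(v)
  if (!all(targets %in% vn)) stop("vertex not in graph")
  w <- vapply(targets, function(u) {
    nb <- igraph::neighbors(graph, u)
    if (length(nb) == 0L) return(0)
    closed <- unique(c(u, nb$name))
    sub <- igraph::induced_subgraph(graph, closed)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0L) return(0)
    core_vs <- names(core)[core == kmax]
    core_sub <- igraph::induced_subgraph(sub, core_vs)
    nv <- igraph::vcount(core_sub)
    dens <- if (nv < 2) 0 else
      2 * igraph::ecount(core_sub) / (nv * (nv - 1))
    kmax * dens
  }, numeric(1))
  stats::setNames(w, targets)
}

#' MCODE molecular-complex detection
#'
#' Three stages: vertex weighting (see [mcode_vertex_weight()]), complex
#' prediction, and optional post-processing. Seeds are taken in decreasing
#' vertex-weight order (ties by vertex name); a complex grows outward from
#' its seed, recursively admitting neighbors whose vertex weight is at
#' least `(1 - vwp)` times the seed weight. Every vertex can belong to at
#' most one complex. The haircut removes members connected to the complex
#' by fewer than two edges; fluff (off by default) adds back neighbors
#' whose closed-neighborhood density exceeds `fluff_density_threshold`,
#' and may produce overlap. Complexes of size < 2 are discarded.
#'
#' The algorithm is purely topological: edge weights play no role, so a
#' complete graph always yields a single complex covering every vertex.
#'
#' @param graph an undirected [igraph::graph].
#' @param vwp vertex weight percentage in \[0, 1): larger values admit
#'   vertices with weights further below the seed's.
#' @param haircut remove singly-connected complex members (default on).
#' @param fluff add dense neighborhood vertices after the haircut.
#' @param fluff_density_threshold density cutoff for fluffing.
#' @return a [drug_clustering()].
#' @export
mcode <- function(graph, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                  fluff_density_threshold = 0.5) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  stopifnot(vwp >= 0, vwp < 1)
  if (is.null(igraph::V(graph)$name))
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  w <- mcode_vertex_weight(graph)
  ord <- names(w)[order(-w, names(w))]
  used <- character(0)
  complexes <- list()
  for (seed in ord) {
    if (seed %in% used || w[[seed]] <= 0) next
    cutoff <- (1 - vwp) * w[[seed]]
    members <- seed
    frontier <- seed
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(u)
        igraph::neighbors(graph, u)$name)))
      nxt <- setdiff(nxt, c(members, used))
      nxt <- nxt[w[nxt] >= cutoff]
      members <- c(members, nxt)
      frontier <- nxt
    }
    if (haircut && length(members) > 1) {
      repeat {
        sub <- igraph::induced_subgraph(graph, members)
        deg <- igraph::degree(sub)
        drop <- names(deg)[deg < 2]
        drop <- setdiff(drop, seed)      # the seed anchors its complex
        if (!length(drop)) break
        members <- setdiff(members, drop)
      }
    }
    used <- c(used, members)
    if (length(members) >= 2)
      complexes[[length(complexes) + 1L]] <-
        list(seed = seed, members = sort(members))
  }
  if (fluff) {
    for (i in seq_along(complexes)) {
      members <- complexes[[i]]$members
      cand <- setdiff(unique(unlist(lapply(members, function(u)
        igraph::neighbors(graph, u)$name))), members)
      keep <- cand[vapply(cand, function(u) {
        closed <- unique(c(u, igraph::neighbors(graph, u)$name))
        sub <- igraph::induced_subgraph(graph, closed)
        nv <- igraph::vcount(sub)
        dens <- if (nv < 2) 0 else 2 * igraph::ecount(sub) / (nv * (nv - 1))
        dens > fluff_density_threshold
      }, logical(1))]
      complexes[[i]]$members <- sort(c(members, keep))
    }
  }
  membership <- lapply(complexes, `[[`, "members")
  names(membership) <- if (length(membership))
    paste0("mcode_", seq_along(membership)) else character(0)
  cl <- drug_clustering(membership, algorithm = "mcode",
                        parameters = list(vwp = vwp, haircut = haircut,
                                          fluff = fluff))
  attr(cl, "seeds") <- vapply(complexes, `[[`, "", "seed")
  cl
}
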