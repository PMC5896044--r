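#' Cohesiveness of a vertex group
#'
#' `f(S) = w_in / (w_in + w_bound + p * |S|)` where `w_in` is the total
#' edge weight inside `S`, `w_bound` the total weight of edges crossing the
#' boundary of `S`, and `p` a penalty modeling unobserved connections.
#'
#' @param graph an undirected weighted [igraph::graph].
#' @param S character vector of vertex names (non-empty).
#' @param penalty per-vertex penalty `p` (non-negative).
#' @return the cohesiveness in \[0, 1\].
#' @examples
#' tri <- igraph::make_full_graph(3)
#' igraph::V(tri)$name <- c("a", "b", "c"); igraph::E(tri)$weight <- 1
#' cohesiveness(tri, c("a", "b", "c"), penalty = 0)  # 1
#' cohesiveness(tri, c("a", "b", "c"), penalty = 1)  # 0.5
#' @export
cohesiveness <- function(graph, S, penalty = 2) {
  if (!length(S)) stop("S must be non-empty")
  A <- graph_adjacency(graph)
  S <- as.character(S)
  if (!all(S %in% rownames(A))) stop("vertex not in graph")
  cohesiveness_adj(A, match(S, rownames(A)), penalty)
}

cohesiveness_val <- function(w_in, w_bound, size, penalty) {
  denom <- w_in + w_bound + penalty * size
  ifelse(denom <= 0, 0, w_in / denom)
}

# adjacency-matrix version used by the greedy loop
cohesiveness_adj <- function(A, idx, penalty) {
  w_in <- sum(A[idx, idx, drop = FALSE]) / 2
  w_bound <- sum(A[idx, -idx, drop = FALSE])
  denom <- w_in + w_bound + penalty * length(idx)
  if (denom <= 0) return(0)
  w_in / denom
}

#' ClusterONE: greedy growth of cohesive, possibly overlapping groups
#'
#' Starting from seed vertices, groups are grown greedily: at each step the
#' single addition of an adjacent external vertex or removal of an internal
#' vertex that most increases the cohesiveness is applied, until no move
#' improves it. Grown groups with weighted density below
#' `density_threshold` or fewer than `min_size` members are discarded;
#' remaining groups whose pairwise overlap score
#' `omega(A, B) = |A ∩ B|^2 / (|A| |B|)` reaches
#' `overlap_merge_threshold` are merged. The output may be overlapping and
#' need not cover every vertex.
#'
#' @param graph an undirected weighted [igraph::graph].
#' @param density_threshold minimum weighted density
#'   `2 w_in / (|S| (|S|-1))` of an emitted group.
#' @param seed_method `"nodes"` grows a group from every vertex (decreasing
#'   weighted degree); `"unused_nodes"` repeatedly seeds the
#'   highest-degree vertex not yet covered by a grown group.
#' @param penalty cohesiveness penalty `p`.
#' @param overlap_merge_threshold merge groups with overlap score at or
#'   above this value, in (0, 1].
#' @param min_size minimum group size.
#' @return a [drug_clustering()]; attribute `"growth_history"` records the
#'   cohesiveness trajectory of each grown seed.
#' @export
cluster_one <- function(graph, density_threshold = 0.6,
                        seed_method = c("nodes", "unused_nodes"),
                        penalty = 2, overlap_merge_threshold = 0.8,
                        min_size = 2) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  seed_method <- match.arg(seed_method)
  stopifnot(density_threshold >= 0, density_threshold <= 1, penalty >= 0,
            overlap_merge_threshold > 0, overlap_merge_threshold <= 1)
  A <- graph_adjacency(graph)
  n <- nrow(A)
  vn <- rownames(A)
  wdeg <- rowSums(A)
  ord <- order(-wdeg, vn)

  # incremental greedy growth: w_in / w_bound are updated in O(1) per
  # candidate from av = weight of each vertex toward the current group
  grow <- function(seed_idx) {
    S <- seed_idx
    w_in <- 0
    w_bound <- wdeg[seed_idx]
    f <- cohesiveness_val(w_in, w_bound, length(S), penalty)
    hist <- f
    repeat {
      av <- rowSums(A[, S, drop = FALSE])
      ext <- setdiff(which(av > 0), S)
      best_f <- f + 1e-12
      best_v <- NA_integer_
      best_add <- TRUE
      if (length(ext)) {
        f_add <- cohesiveness_val(w_in + av[ext],
                                  w_bound - 2 * av[ext] + wdeg[ext],
                                  length(S) + 1, penalty)
        i <- which.max(f_add)
        if (f_add[i] > best_f) {
          best_f <- f_add[i]; best_v <- ext[i]; best_add <- TRUE
        }
      }
      if (length(S) > 1) {
        f_rm <- cohesiveness_val(w_in - av[S],
                                 w_bound + 2 * av[S] - wdeg[S],
                                 length(S) - 1, penalty)
        i <- which.max(f_rm)
        if (f_rm[i] > best_f) {
          best_f <- f_rm[i]; best_v <- S[i]; best_add <- FALSE
        }
      }
      if (is.na(best_v)) break
      av_v <- av[best_v]
      if (best_add) {
        S <- c(S, best_v)
        w_in <- w_in + av_v
        w_bound <- w_bound - 2 * av_v + wdeg[best_v]
      } else {
        S <- setdiff(S, best_v)
        w_in <- w_in - av_v
        w_bound <- w_bound + 2 * av_v - wdeg[best_v]
      }
      f <- cohesiveness_val(w_in, w_bound, length(S), penalty)
      hist <- c(hist, f)
    }
    list(members = sort(S), history = hist)
  }

  groups <- list()
  histories <- list()
  if (seed_method == "nodes") {
    for (s in ord) {
      g <- grow(s)
      key <- paste(g$members, collapse = ",")
      if (is.null(groups[[key]])) {
        groups[[key]] <- g$members
        histories[[key]] <- g$history
      }
    }
  } else {
    covered <- logical(n)
    for (s in ord) {
      if (covered[s]) next
      g <- grow(s)
      covered[g$members] <- TRUE
      covered[s] <- TRUE
      key <- paste(g$members, collapse = ",")
      if (is.null(groups[[key]])) {
        groups[[key]] <- g$members
        histories[[key]] <- g$history
      }
    }
  }

  dens <- function(idx) {
    if (length(idx) < 2) return(0)
    2 * (sum(A[idx, idx]) / 2) / (length(idx) * (length(idx) - 1))
  }
  keep <- vapply(groups, function(idx)
    length(idx) >= min_size && dens(idx) >= density_threshold, logical(1))
  groups <- groups[keep]

  # merge heavily overlapping groups (components of the omega >= threshold
  # overlap graph)
  if (length(groups) > 1) {
    m <- length(groups)
    om <- matrix(0, m, m)
    for (i in seq_len(m - 1))
      for (j in (i + 1):m) {
        ov <- length(intersect(groups[[i]], groups[[j]]))
        om[i, j] <- om[j, i] <-
          ov^2 / (length(groups[[i]]) * length(groups[[j]]))
      }
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      om >= overlap_merge_threshold, mode = "undirected"))
    groups <- lapply(split(seq_len(m), comp$membership), function(ii)
      sort(unique(unlist(groups[ii]))))
  }

  membership <- lapply(groups, function(idx) vn[idx])
  names(membership) <- if (length(membership))
    paste0("cl1_", seq_along(membership)) else character(0)
  cl <- drug_clustering(membership, algorithm = "cluster_one",
                        parameters = list(density_threshold = density_threshold,
                                          seed_method = seed_method,
                                          penalty = penalty,
                                          overlap_merge_threshold =
                                            overlap_merge_threshold,
                                          min_size = min_size))
  attr(cl, "growth_history") <- unname(histories)
  cl
}
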