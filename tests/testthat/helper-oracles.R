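# Independent oracles and small builders shared across tests.

# all permutations of 1..n as rows (n <= 8 in tests)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(p >= k, p + 1L, p))))
}

# mutual information of two label vectors, natural log, from first
# principles (independent of the package internals)
oracle_mi <- function(u, v) {
  ct <- table(u, v)
  n <- sum(ct)
  a <- rowSums(ct)
  b <- colSums(ct)
  idx <- which(ct > 0, arr.ind = TRUE)
  sum((ct[idx] / n) * log(n * ct[idx] / (a[idx[, 1]] * b[idx[, 2]])))
}

# exhaustive permutation-model moments of MI for fixed labelings
oracle_mi_moments <- function(u, v) {
  P <- all_perms(length(u))
  mis <- apply(P, 1, function(p) oracle_mi(u, v[p]))
  c(mean = mean(mis), var = mean(mis^2) - mean(mis)^2)
}

# brute-force silhouette from the definition
oracle_silhouette <- function(labels, d) {
  vapply(seq_along(labels), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# undirected weighted graph from an edge data frame (weight defaults to 1)
toy_graph <- function(edges, vertices = NULL) {
  if (is.null(edges$weight)) edges$weight <- 1
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

# edge list of a clique over the given vertex names
clique_edges <- function(vs, weight = 1) {
  cmb <- t(utils::combn(vs, 2))
  data.frame(from = cmb[, 1], to = cmb[, 2], weight = weight)
}

# named label vector for quick partitions: list of id vectors -> labels
labels_of <- function(groups) {
  lab <- rep(names(groups), lengths(groups))
  stats::setNames(lab, unlist(groups, use.names = FALSE))
}

# small aligned two-view collection used in IO and integration tests
tiny_collection <- function() {
  m1 <- rbind(D1 = c(1, 1, 0, 0), D2 = c(0, 1, 1, 0), D3 = c(0, 0, 1, 1))
  colnames(m1) <- paste0("F", 1:4)
  m2 <- rbind(D1 = c(1, 0), D2 = c(1, 0), D3 = c(0, 1))
  colnames(m2) <- paste0("G", 1:2)
  align_collection(list(drug_profile_view(m1, "chemical"),
                        drug_profile_view(m2, "disease")))
}
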