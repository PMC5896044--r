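# External (information-theoretic) and internal (Silhouette) cluster
# evaluation. Mutual information uses natural logs throughout; NMI and SMI
# are invariant to the log base, which therefore never shows in reported
# values.

as_partition_labels <- function(x, universe = NULL) {
  if (inherits(x, "drug_clustering"))
    return(clustering_to_partition(x, universe))
  if (is.null(names(x))) stop("label vectors must be named by item id")
  x <- stats::setNames(as.character(x), names(x))
  if (!is.null(universe)) {
    if (!all(universe %in% names(x)))
      stop("labels missing for some items of the universe")
    x <- x[as.character(universe)]
  }
  x
}

#' Cross-tabulate two labelings
#'
#' @param u,v partitions of the same item set: named label vectors, or
#'   [drug_clustering()] objects (overlap is resolved to a partition by
#'   [clustering_to_partition()]).
#' @param universe optional item ids both labelings are restricted to.
#' @return an object of class `contingency_table` with the count matrix
#'   `counts`, row marginals `a`, column marginals `b` and total `n`.
#' @export
contingency <- function(u, v, universe = NULL) {
  if (is.null(universe)) {
    nu <- if (inherits(u, "drug_clustering")) covered_drugs(u) else names(u)
    nv <- if (inherits(v, "drug_clustering")) covered_drugs(v) else names(v)
    if (!setequal(nu, nv))
      stop("labelings cover different item sets; supply a common universe")
    universe <- sort(nu)
  }
  lu <- as_partition_labels(u, universe)
  lv <- as_partition_labels(v, universe)
  counts <- unclass(table(lu, lv))
  dimnames(counts) <- unname(dimnames(counts))
  structure(list(counts = counts, a = rowSums(counts), b = colSums(counts),
                 n = sum(counts)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table: ", nrow(x$counts), " x ", ncol(x$counts),
      " clusters, n = ", x$n, "\n", sep = "")
  invisible(x)
}

entropy_marginal <- function(a, n) {
  p <- a[a > 0] / n
  -sum(p * log(p))
}

mi_from_counts <- function(counts) {
  n <- sum(counts)
  a <- rowSums(counts)
  b <- colSums(counts)
  idx <- which(counts > 0, arr.ind = TRUE)
  nij <- counts[idx]
  sum((nij / n) * log(n * nij / (a[idx[, 1]] * b[idx[, 2]])))
}

#' Mutual information of two labelings
#'
#' @inheritParams contingency
#' @return MI in nats.
#' @export
mutual_information <- function(u, v, universe = NULL) {
  ct <- if (inherits(u, "contingency_table")) u else contingency(u, v, universe)
  mi_from_counts(ct$counts)
}

#' Normalized mutual information (geometric-mean form)
#'
#' `NMI_sqrt(U, V) = MI(U, V) / sqrt(H(U) H(V))`, in \[0, 1\]; equals 1
#' for identical partitions. Undefined when both labelings consist of a
#' single cluster (both entropies zero).
#'
#' @inheritParams contingency
#' @return NMI in \[0, 1\].
#' @export
nmi_sqrt <- function(u, v, universe = NULL) {
  ct <- if (inherits(u, "contingency_table")) u else contingency(u, v, universe)
  hu <- entropy_marginal(ct$a, ct$n)
  hv <- entropy_marginal(ct$b, ct$n)
  if (hu == 0 && hv == 0)
    stop("NMI undefined: both labelings are a single cluster")
  if (hu == 0 || hv == 0) return(0)
  mi <- mi_from_counts(ct$counts)
  min(max(mi / sqrt(hu * hv), 0), 1)
}

# log hypergeometric pmf: P(X = x) drawing m from N with K successes
lhyper <- function(x, N, K, m) {
  lchoose(K, x) + lchoose(N - K, m - x) - lchoose(N, m)
}

# per-cell MI contribution (a/n) log(n a / (ai bj)); 0 at a = 0
mi_cell_term <- function(a, n, ai, bj) {
  out <- numeric(length(a))
  pos <- a > 0
  out[pos] <- (a[pos] / n) * log(n * a[pos] / (ai * bj))
  out
}

#' Exact expected mutual information under the permutation null
#'
#' Expectation of MI over all relabelings that preserve both sets of
#' marginals (the fixed-marginals hypergeometric model), computed by the
#' exact summation over feasible cell counts.
#'
#' @param a,b integer marginal vectors (row and column cluster sizes).
#' @param n total item count, `sum(a) == sum(b) == n`.
#' @return E\[MI\] in nats.
#' @export
expected_mi <- function(a, b, n = sum(a)) {
  stopifnot(sum(a) == n, sum(b) == n)
  emi <- 0
  for (ai in a) for (bj in b) {
    lo <- max(1, ai + bj - n)
    hi <- min(ai, bj)
    if (hi < lo) next
    nij <- lo:hi
    p <- exp(lhyper(nij, n, bj, ai))
    emi <- emi + sum(p * mi_cell_term(nij, n, ai, bj))
  }
  emi
}

#' Exact variance of mutual information under the permutation null
#'
#' `Var[MI] = E[MI^2] - E[MI]^2` over the same fixed-marginals model as
#' [expected_mi()]. `E[MI^2]` sums the expected products of all ordered
#' pairs of cell contributions; the joint cell-count distributions are
#' bivariate hypergeometric for cells sharing a row or column, and are
#' obtained by conditioning on the first row's draw for disjoint cells.
#'
#' @inheritParams expected_mi
#' @return Var\[MI\], non-negative up to numerical round-off.
#' @export
variance_mi <- function(a, b, n = sum(a)) {
  stopifnot(sum(a) == n, sum(b) == n)
  r <- length(a); cc <- length(b)
  # single-cell expectations E[X_ij]
  ex <- matrix(0, r, cc)
  for (i in seq_len(r)) for (j in seq_len(cc)) {
    lo <- max(1, a[i] + b[j] - n); hi <- min(a[i], b[j])
    if (hi < lo) next
    nij <- lo:hi
    ex[i, j] <- sum(exp(lhyper(nij, n, b[j], a[i])) *
                      mi_cell_term(nij, n, a[i], b[j]))
  }
  exx <- 0  # accumulates E[MI^2]
  for (i in seq_len(r)) for (j in seq_len(cc)) {
    ai <- a[i]; bj <- b[j]
    lo <- max(1, ai + bj - n); hi <- min(ai, bj)
    if (hi >= lo) {
      va <- lo:hi
      xa <- mi_cell_term(va, n, ai, bj)
      pa <- exp(lhyper(va, n, bj, ai))
      # same cell
      exx <- exx + sum(pa * xa^2)
    }
    for (jp in seq_len(cc)) {
      if (jp == j) next
      bjp <- b[jp]
      # same row, different columns: (n_ij, n_ijp) bivariate hypergeometric
      for (va_ in if (hi >= lo) lo:hi else integer(0)) {
        xb_hi <- min(ai - va_, bjp)
        if (xb_hi < 1) next
        vb <- 1:xb_hi
        lp <- lchoose(bj, va_) + lchoose(bjp, vb) +
          lchoose(n - bj - bjp, ai - va_ - vb) - lchoose(n, ai)
        exx <- exx + mi_cell_term(va_, n, ai, bj) *
          sum(exp(lp) * mi_cell_term(vb, n, ai, bjp))
      }
    }
  }
  # same column, different rows: by the row/column symmetry of the model
  for (j in seq_len(cc)) for (i in seq_len(r)) for (ip in seq_len(r)) {
    if (ip == i) next
    bj <- b[j]; ai <- a[i]; aip <- a[ip]
    for (va_ in seq_len(min(ai, bj))) {
      xb_hi <- min(bj - va_, aip)
      if (xb_hi < 1) next
      vb <- 1:xb_hi
      lp <- lchoose(ai, va_) + lchoose(aip, vb) +
        lchoose(n - ai - aip, bj - va_ - vb) - lchoose(n, bj)
      exx <- exx + mi_cell_term(va_, n, ai, bj) *
        sum(exp(lp) * mi_cell_term(vb, n, aip, bj))
    }
  }
  # disjoint cells: condition on row i's draw of columns j and jp
  for (i in seq_len(r)) for (ip in seq_len(r)) {
    if (ip == i) next
    ai <- a[i]; aip <- a[ip]
    for (jp in seq_len(cc)) {
      bjp <- b[jp]
      # G[K+1] = E[x_{ip,jp}(B)], B ~ Hyper(n - ai, K, aip)
      G <- vapply(0:bjp, function(K) {
        bb_hi <- min(K, aip)
        if (bb_hi < 1) return(0)
        bb <- 1:bb_hi
        sum(exp(lhyper(bb, n - ai, K, aip)) *
              mi_cell_term(bb, n, aip, bjp))
      }, numeric(1))
      for (j in seq_len(cc)) {
        if (j == jp) next
        bj <- b[j]
        for (va_ in seq_len(min(ai, bj))) {
          k_hi <- min(ai - va_, bjp)
          kk <- 0:k_hi
          lp <- lchoose(bj, va_) + lchoose(bjp, kk) +
            lchoose(n - bj - bjp, ai - va_ - kk) - lchoose(n, ai)
          exx <- exx + mi_cell_term(va_, n, ai, bj) *
            sum(exp(lp) * G[bjp - kk + 1])
        }
      }
    }
  }
  max(exx - sum(ex)^2, 0)
}

#' Standardized mutual information
#'
#' `SMI(U, V) = (MI - E[MI]) / sqrt(Var[MI])` under the fixed-marginals
#' permutation null: the number of standard deviations the observed MI
#' lies above chance. Unbounded above; its maximum for a fixed reference
#' depends on that reference's marginals. Undefined when the null variance
#' is zero (degenerate labelings).
#'
#' @inheritParams contingency
#' @return the standardized MI.
#' @export
smi <- function(u, v, universe = NULL) {
  ct <- if (inherits(u, "contingency_table")) u else contingency(u, v, universe)
  v_mi <- variance_mi(ct$a, ct$b, ct$n)
  if (v_mi <= 1e-14)
    stop("SMI undefined: zero MI variance under the permutation null ",
         "(degenerate labeling)")
  (mi_from_counts(ct$counts) - expected_mi(ct$a, ct$b, ct$n)) / sqrt(v_mi)
}

#' Silhouette analysis of a partition
#'
#' For each item, `a(i)` is the mean distance to the other members of its
#' own cluster and `b(i)` the smallest mean distance to any other cluster;
#' the Silhouette value is `(b(i) - a(i)) / max(a(i), b(i))` in \[-1, 1\].
#' Items in singleton clusters score 0 by convention.
#'
#' @param labels named label vector (or [drug_clustering()], resolved to a
#'   partition).
#' @param d square symmetric distance matrix with matching dimnames.
#' @return an object of class `silhouette_report`: per-item data frame
#'   `items` (`a`, `b`, `s`), `cluster_means`, and the overall `mean`.
#' @export
silhouette_report <- function(labels, d) {
  if (inherits(labels, "drug_clustering"))
    labels <- clustering_to_partition(labels, rownames(d))
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-9 || min(d) < 0)
    stop("distance matrix must be symmetric and non-negative")
  ids <- rownames(d)
  if (is.null(ids)) ids <- names(labels)
  labels <- labels[ids]
  if (anyNA(labels)) stop("labels missing for some items")
  cls <- sort(unique(labels))
  if (length(cls) < 2)
    stop("Silhouette undefined for a single cluster")
  a_i <- b_i <- s_i <- numeric(length(ids))
  for (k in seq_along(ids)) {
    own <- which(labels == labels[k])
    own_others <- setdiff(own, k)
    if (!length(own_others)) { a_i[k] <- 0; b_i[k] <- 0; s_i[k] <- 0; next }
    a_i[k] <- mean(d[k, own_others])
    b_i[k] <- min(vapply(setdiff(cls, labels[k]), function(cl)
      mean(d[k, labels == cl]), numeric(1)))
    m <- max(a_i[k], b_i[k])
    s_i[k] <- if (m == 0) 0 else (b_i[k] - a_i[k]) / m
  }
  items <- data.frame(id = ids, cluster = unname(labels),
                      a = a_i, b = b_i, s = s_i)
  structure(list(items = items,
                 cluster_means = tapply(items$s, items$cluster, mean),
                 mean = mean(items$s)),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat("Silhouette: mean ", round(x$mean, 3), " over ", nrow(x$items),
      " items in ", length(x$cluster_means), " clusters\n", sep = "")
  invisible(x)
}

#' Drug pairs co-clustered in every clustering
#'
#' Returns all unordered drug pairs that share at least one cluster in
#' each of the supplied clusterings -- the cross-view co-occurrence
#' analysis used to spot consistently similar drugs.
#'
#' @param clusterings list of at least two [drug_clustering()] objects.
#' @return data frame with columns `drug_a`, `drug_b` (lexicographic).
#' @export
common_pairs <- function(clusterings) {
  if (length(clusterings) < 2) stop("need at least two clusterings")
  pair_keys <- lapply(clusterings, function(cl) {
    keys <- unlist(lapply(cl$membership, function(members) {
      if (length(members) < 2) return(character(0))
      cmb <- utils::combn(sort(members), 2)
      paste(cmb[1, ], cmb[2, ], sep = "\r")
    }), use.names = FALSE)
    unique(keys)
  })
  shared <- Reduce(intersect, pair_keys)
  if (!length(shared))
    return(data.frame(drug_a = character(0), drug_b = character(0)))
  parts <- do.call(rbind, strsplit(sort(shared), "\r", fixed = TRUE))
  data.frame(drug_a = parts[, 1], drug_b = parts[, 2])
}

#' Resolve multi-class ATC assignments to single labels
#'
#' External comparison against a reference classification needs one label
#' per item; drugs carrying several ATC codes get one chosen uniformly at
#' random (reproducibly under `seed`), and unclassified drugs are dropped.
#'
#' @param atc an [atc_reference()].
#' @param seed integer seed.
#' @return named character vector, drug id -> single ATC code.
#' @export
resolve_multilabel <- function(atc, seed = 1L) {
  stopifnot(inherits(atc, "atc_reference"))
  drugs <- sort(names(atc)[lengths(atc) > 0])
  with_seed(seed, {
    stats::setNames(vapply(drugs, function(d) {
      codes <- atc[[d]]
      if (length(codes) == 1) codes else sample(codes, 1)
    }, character(1)), drugs)
  })
}
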