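#' GSOM growth threshold
#'
#' The growth threshold of a Growing Self-Organizing Map is
#' `GT = -D * ln(SF)` where `D` is the input dimensionality and `SF` the
#' spread factor in (0, 1). The spread factor controls map granularity
#' independently of dimensionality: smaller values give a higher threshold
#' and hence fewer nodes, values near 1 let the map grow maximally.
#'
#' @param D input dimensionality (number of features).
#' @param spread_factor spread factor in (0, 1).
#' @return the growth threshold, a non-negative number.
#' @examples
#' growth_threshold(2, 0.1)   # 4.60517...
#' @export
growth_threshold <- function(D, spread_factor) {
  if (!(D >= 1)) stop("dimensionality must be >= 1")
  if (!(spread_factor > 0 && spread_factor < 1))
    stop("spread factor must lie strictly between 0 and 1")
  -D * log(spread_factor)
}

#' Train a Growing Self-Organizing Map
#'
#' Vector clustering by a self-organizing map that grows during training:
#' starting from a 2x2 grid, each sample moves its best-matching node (and
#' the node's grid neighborhood) toward itself, the winner accumulates
#' quantization error, and nodes whose error exceeds the growth threshold
#' spawn new nodes at free grid positions (boundary nodes) or spread their
#' error (interior nodes). A smoothing phase with a reduced learning rate
#' and no growth follows. Sample presentation order is reshuffled every
#' epoch under `seed`, so training is deterministic for a fixed seed.
#'
#' @param x numeric matrix (rows = items, e.g. binary drug profiles or rows
#'   of an averaged drug-drug relation matrix); row names are the item ids.
#' @param spread_factor map granularity in (0, 1); larger values grow more
#'   nodes.
#' @param learning_rate initial learning rate of the growing phase.
#' @param radius initial neighborhood radius on the grid, shrinking to 1.
#' @param grow_epochs,smooth_epochs number of passes over the data in the
#'   growing and smoothing phases.
#' @param smooth_lr_factor learning-rate multiplier of the smoothing phase.
#' @param max_nodes safety cap on map size.
#' @param distance `"euclidean"` (default) or `"jaccard"` for binary data.
#' @param initial_nodes 4 (default, a 2x2 grid, the more stable start) or 1
#'   (the single-node emergent start).
#' @param seed integer seed controlling sample presentation order.
#' @return an object of class `gsom_map`: a list with `nodes` (data frame of
#'   grid coordinates and accumulated error), `weights` (node x feature
#'   matrix), `growth_threshold`, and the call parameters.
#' @seealso [gsom_assign()], [growth_threshold()]
#' @export
gsom <- function(x, spread_factor = 0.3, learning_rate = 0.3, radius = 3,
                 grow_epochs = 50, smooth_epochs = 50,
                 smooth_lr_factor = 0.2, max_nodes = 4 * nrow(x),
                 distance = c("euclidean", "jaccard"), initial_nodes = 4L,
                 seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("empty input matrix")
  if (anyNA(x)) stop("input matrix contains missing cells")
  stopifnot(grow_epochs >= 1, smooth_epochs >= 1)
  distance <- match.arg(distance)
  gt <- growth_threshold(ncol(x), spread_factor)
  total <- grow_epochs + smooth_epochs
  orders <- with_seed(seed, {
    t(vapply(seq_len(total), function(e) sample.int(nrow(x)) - 1L,
             integer(nrow(x))))
  })
  if (nrow(x) == 1L) orders <- matrix(0L, total, 1L)
  if (!initial_nodes %in% c(1L, 4L))
    stop("initial_nodes must be 1 or 4")
  fit <- gsom_train_cpp(x, gt, learning_rate, radius,
                        as.integer(grow_epochs), as.integer(smooth_epochs),
                        orders, smooth_lr_factor, 0.25,
                        as.integer(max(max_nodes, 4L)),
                        if (distance == "jaccard") 1L else 0L,
                        as.integer(initial_nodes))
  nodes <- data.frame(x = fit$x, y = fit$y, error = fit$error)
  # order nodes lexicographically by grid coordinate: deterministic ids and
  # tie-breaking downstream
  ord <- order(nodes$x, nodes$y)
  structure(
    list(nodes = nodes[ord, , drop = FALSE],
         weights = fit$weights[ord, , drop = FALSE],
         growth_threshold = gt,
         params = list(spread_factor = spread_factor,
                       learning_rate = learning_rate, radius = radius,
                       grow_epochs = grow_epochs,
                       smooth_epochs = smooth_epochs,
                       smooth_lr_factor = smooth_lr_factor,
                       distance = distance, seed = seed),
         dim = ncol(x)),
    class = "gsom_map")
}

#' @export
print.gsom_map <- function(x, ...) {
  cat("GSOM map: ", nrow(x$weights), " nodes, input dimension ", x$dim,
      ", SF = ", x$params$spread_factor,
      " (GT = ", signif(x$growth_threshold, 4), ")\n", sep = "")
  invisible(x)
}

# squared euclidean / jaccard distances rows of x vs node weights
gsom_distances <- function(map, x) {
  w <- map$weights
  if (map$params$distance == "jaccard") {
    d <- matrix(0, nrow(x), nrow(w))
    for (k in seq_len(nrow(w))) {
      mn <- pmin(x, rep(w[k, ], each = nrow(x)))
      mx <- pmax(x, rep(w[k, ], each = nrow(x)))
      smx <- rowSums(mx)
      d[, k] <- ifelse(smx <= 0, 0, 1 - rowSums(mn) / smx)
    }
    d
  } else {
    outer(rowSums(x^2), rep(1, nrow(w))) +
      outer(rep(1, nrow(x)), rowSums(w^2)) - 2 * x %*% t(w)
  }
}

#' Assign items to GSOM nodes
#'
#' Each row of `x` is assigned to its nearest node; every non-empty node
#' becomes one cluster. Ties go to the node with the lexicographically
#' smallest grid coordinate. The result is a non-overlapping clustering.
#'
#' @param map a [gsom()] fit.
#' @param x numeric matrix with the same number of columns as the training
#'   data; row names are used as item ids.
#' @return a [drug_clustering()] with cluster ids `node_<x>_<y>`.
#' @export
gsom_assign <- function(map, x) {
  stopifnot(inherits(map, "gsom_map"))
  x <- as.matrix(x)
  if (ncol(x) != map$dim)
    stop("dimension mismatch: map expects ", map$dim, " features, got ",
         ncol(x))
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  d <- gsom_distances(map, x)
  # nodes are stored in lexicographic grid order, so the first minimum is
  # the documented tie-break
  win <- apply(round(d, 12), 1, which.min)
  cl <- paste0("node_", map$nodes$x[win], "_", map$nodes$y[win])
  drug_clustering(split(ids, cl), algorithm = "gsom",
                  parameters = map$params)
}

#' Cluster a matrix with a GSOM in one step
#'
#' Convenience wrapper: train with [gsom()] and assign the training rows
#' with [gsom_assign()].
#'
#' @inheritParams gsom
#' @param ... passed to [gsom()].
#' @return a [drug_clustering()].
#' @export
gsom_cluster <- function(x, ...) {
  gsom_assign(gsom(x, ...), x)
}

#' Write a GSOM map as TSV
#'
#' One row per node: grid coordinates followed by the weight vector.
#'
#' @param map a [gsom()] fit.
#' @param path destination file.
#' @export
write_gsom_map <- function(map, path) {
  df <- data.frame(x = map$nodes$x, y = map$nodes$y, map$weights)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
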