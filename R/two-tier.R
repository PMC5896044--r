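#' Fit the two-tiered heterogeneous drug clustering model
#'
#' Runs the complete pipeline: (Tier 1) each profile view is clustered
#' independently with a GSOM; (integration) every Tier-1 clustering is
#' turned into a binary co-membership drug-drug relation (DDR) matrix and
#' the matrices are averaged with equal weights; (Tier 2) the averaged
#' similarity is clustered by each requested algorithm -- the graph
#' methods (MCL, MCODE, ClusterONE) on the thresholded similarity graph,
#' GSOM on the rows of the averaged matrix; (labeling) each Tier-2 cluster
#' receives its majority ATC class with a confidence, and repositioning
#' candidates are inferred. Two baseline integration modes are available
#' for comparison: `"concat_hy"` concatenates all views into one wide
#' binary profile (clustered by GSOM only) and `"avg_sim_hz"` averages
#' per-view pairwise Jaccard similarities into a dense matrix.
#'
#' @param collection a `profile_collection` from [align_collection()] or
#'   [synth_profiles()], or a list of views.
#' @param atc optional [atc_reference()]; enables external evaluation
#'   (NMI/SMI against the resolved single-label reference) and candidate
#'   inference.
#' @param tier1_views names of the views used (default: all).
#' @param integration `"two_tier"` (the model), `"concat_hy"` or
#'   `"avg_sim_hz"`.
#' @param spread_factor GSOM spread factor(s) for Tier 1, recycled over
#'   views.
#' @param tier2_spread_factor spread factor of the Tier-2 GSOM.
#' @param tier2_algorithms subset of `c("gsom", "mcl", "mcode",
#'   "cluster_one")`.
#' @param min_weight edge threshold for the Tier-2 graph (`NULL`: keep all
#'   positive similarities).
#' @param min_confidence confidence filter for candidate inference.
#' @param compute_smi also compute SMI in the evaluation table (exact
#'   permutation-null moments; slower than NMI).
#' @param mcl_args,mcode_args,cluster_one_args,gsom_args named lists of
#'   extra arguments for the Tier-2 algorithms / the GSOMs.
#' @param seed integer master seed; all stage seeds derive from it.
#' @return an object of class `two_tier` with elements `tier1`
#'   (clusterings per view), `ddr` (averaged [ddr_matrix()]), `graph`,
#'   `tier2` (clusterings per algorithm), `evaluation` (data frame),
#'   `candidates`, `consistent`, `warnings` and `params`.
#' @examples
#' \donttest{
#' d <- synth_profiles(synth_spec(n_drugs = 60, k_groups = 3,
#'   features_per_view = c(chemical = 30, disease = 30), seed = 7))
#' fit <- two_tier(d$collection, d$truth$atc,
#'                 tier2_algorithms = c("mcl", "mcode"))
#' fit
#' }
#' @export
two_tier <- function(collection, atc = NULL,
                     tier1_views = NULL,
                     integration = c("two_tier", "concat_hy", "avg_sim_hz"),
                     spread_factor = 0.01, tier2_spread_factor = 0.01,
                     tier2_algorithms = c("gsom", "mcl", "mcode",
                                          "cluster_one"),
                     min_weight = NULL, min_confidence = 0.5,
                     compute_smi = TRUE,
                     mcl_args = list(), mcode_args = list(),
                     cluster_one_args = list(), gsom_args = list(),
                     seed = 1L) {
  collection <- align_collection(collection)
  integration <- match.arg(integration)
  tier2_algorithms <- match.arg(tier2_algorithms,
                                c("gsom", "mcl", "mcode", "cluster_one"),
                                several.ok = TRUE)
  if (is.null(tier1_views)) tier1_views <- names(collection$views)
  if (!all(tier1_views %in% names(collection$views)))
    stop("unknown view: ",
         paste(setdiff(tier1_views, names(collection$views)), collapse = ", "))
  universe <- collection$drug_ids
  ref <- if (!is.null(atc)) resolve_multilabel(atc, seed = seed) else NULL
  warnings <- character(0)

  evaluate <- function(clustering, stage, name) {
    part <- clustering_to_partition(clustering, universe)
    row <- data.frame(stage = stage, name = name,
                      algorithm = clustering$algorithm,
                      n_clusters = length(clustering$membership),
                      n_drugs = length(covered_drugs(clustering)),
                      nmi = NA_real_, smi = NA_real_)
    if (!is.null(ref)) {
      ids <- intersect(universe, names(ref))
      ct <- contingency(part[ids], ref[ids])
      row$nmi <- nmi_sqrt(ct)
      if (compute_smi) row$smi <- tryCatch(smi(ct), error = function(e) NA_real_)
    }
    row
  }

  # --- Tier 1: one GSOM per view -------------------------------------------
  tier1 <- list()
  eval_rows <- list()
  if (integration %in% c("two_tier", "concat_hy")) {
    sf <- rep_len(spread_factor, length(tier1_views))
    names(sf) <- tier1_views
    if (integration == "two_tier") {
      for (k in seq_along(tier1_views)) {
        v <- tier1_views[k]
        cl <- do.call(gsom_cluster, c(
          list(x = collection$views[[v]]$incidence, spread_factor = sf[[v]],
               seed = seed + k),
          gsom_args))
        cl$parameters$view <- v
        tier1[[v]] <- cl
        eval_rows[[length(eval_rows) + 1L]] <- evaluate(cl, "tier1", v)
      }
    }
  }

  # --- integration ----------------------------------------------------------
  ddr <- NULL
  graph <- NULL
  tier2_input <- NULL
  if (integration == "two_tier") {
    per_view <- lapply(tier1, ddr_from_clustering, universe = universe)
    ddr <- average_ddr(per_view)
    graph <- graph_from_ddr(ddr, min_weight = min_weight)
    tier2_input <- ddr$values
  } else if (integration == "avg_sim_hz") {
    sub <- align_collection(collection$views[tier1_views])
    ddr <- average_pairwise_similarity(sub)
    graph <- graph_from_ddr(ddr, min_weight = min_weight)
    tier2_input <- ddr$values
  } else { # concat_hy
    sub <- align_collection(collection$views[tier1_views])
    tier2_input <- concat_views(sub)$incidence
  }

  # --- Tier 2 ---------------------------------------------------------------
  tier2 <- list()
  if (integration == "concat_hy") {
    cl <- do.call(gsom_cluster, c(
      list(x = tier2_input, spread_factor = tier2_spread_factor,
           seed = seed + 101L), gsom_args))
    cl$algorithm <- "gsom"
    tier2[["gsom"]] <- cl
    eval_rows[[length(eval_rows) + 1L]] <- evaluate(cl, "tier2_hy", "concat")
  } else {
    for (alg in tier2_algorithms) {
      cl <- switch(alg,
        gsom = {
          g <- do.call(gsom_cluster, c(
            list(x = tier2_input, spread_factor = tier2_spread_factor,
                 seed = seed + 101L), gsom_args))
          g
        },
        mcl = do.call(mcl, c(list(graph = graph), mcl_args)),
        mcode = do.call(mcode, c(list(graph = graph), mcode_args)),
        cluster_one = do.call(cluster_one, c(list(graph = graph),
                                             cluster_one_args)))
      if (alg != "gsom" && length(cl$membership) <= 1L) {
        msg <- paste0("tier-2 algorithm '", alg, "' produced a single ",
                      "cluster: the similarity graph carries no usable ",
                      "separation (dense-integration failure mode)")
        warnings <- c(warnings, msg)
        warning(msg)
      }
      tier2[[alg]] <- cl
      eval_rows[[length(eval_rows) + 1L]] <-
        evaluate(cl, paste0("tier2_", substr(integration, 1, 2)), alg)
    }
  }

  # --- repositioning --------------------------------------------------------
  candidates <- NULL
  consistent <- NULL
  if (!is.null(atc)) {
    cand <- lapply(tier2, infer_candidates, atc = atc,
                   min_confidence = min_confidence)
    candidates <- do.call(rbind, cand)
    rownames(candidates) <- NULL
    consistent <- consistent_candidates(cand)
  }

  structure(
    list(tier1 = tier1, ddr = ddr, graph = graph, tier2 = tier2,
         evaluation = do.call(rbind, eval_rows),
         candidates = candidates, consistent = consistent,
         warnings = warnings,
         drug_ids = universe,
         params = list(integration = integration,
                       tier1_views = tier1_views,
                       spread_factor = spread_factor,
                       tier2_spread_factor = tier2_spread_factor,
                       tier2_algorithms = tier2_algorithms,
                       min_weight = min_weight,
                       min_confidence = min_confidence,
                       seed = seed)),
    class = "two_tier")
}

#' @export
print.two_tier <- function(x, ...) {
  cat("Two-tiered drug clustering (", x$params$integration, " integration)\n",
      sep = "")
  cat("  ", length(x$drug_ids), " drugs; Tier-1 views: ",
      paste(names(x$tier1), collapse = ", "), "\n", sep = "")
  for (alg in names(x$tier2))
    cat("  Tier-2 ", format(alg, width = 12), ": ",
        length(x$tier2[[alg]]$membership), " clusters\n", sep = "")
  if (!is.null(x$candidates))
    cat("  ", nrow(x$candidates), " repositioning candidates (",
        nrow(x$consistent), " consistent records)\n", sep = "")
  invisible(x)
}

#' @export
summary.two_tier <- function(object, ...) {
  structure(list(evaluation = object$evaluation,
                 candidates = utils::head(
                   object$candidates[order(-object$candidates$confidence), ,
                                     drop = FALSE], 10),
                 warnings = object$warnings,
                 params = object$params),
            class = "summary.two_tier")
}

#' @export
print.summary.two_tier <- function(x, ...) {
  cat("Evaluation (NMI/SMI vs reference classification):\n")
  print(x$evaluation, row.names = FALSE, digits = 3)
  if (!is.null(x$candidates) && nrow(x$candidates)) {
    cat("\nTop repositioning candidates:\n")
    print(x$candidates, row.names = FALSE, digits = 2)
  }
  if (length(x$warnings))
    cat("\nWarnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
plot.two_tier <- function(x, ...) {
  if (is.null(x$ddr)) stop("no DDR matrix in a concat_hy fit")
  ref_cl <- x$tier2[[1]]
  ord <- order(clustering_to_partition(ref_cl, x$drug_ids)[x$drug_ids])
  v <- x$ddr$values[ord, ord]
  graphics::image(seq_len(nrow(v)), seq_len(ncol(v)), v[, rev(seq_len(ncol(v)))],
                  col = grey.colors(32, start = 1, end = 0),
                  xlab = "drugs (cluster order)", ylab = "drugs",
                  main = "Averaged drug-drug relation matrix", ...)
  invisible(x)
}

#' Tier-1 clustering of every profile view
#'
#' The first stage of [two_tier()] as a standalone step: one GSOM
#' clustering per view, with optional external evaluation.
#'
#' @inheritParams two_tier
#' @param views names of the views to cluster.
#' @return list with `clusterings` (per view) and `evaluation`.
#' @export
run_tier1 <- function(collection, atc = NULL, views = NULL,
                      spread_factor = 0.01, gsom_args = list(), seed = 1L,
                      compute_smi = FALSE) {
  collection <- align_collection(collection)
  if (is.null(views)) views <- names(collection$views)
  if (!all(views %in% names(collection$views)))
    stop("unknown view: ",
         paste(setdiff(views, names(collection$views)), collapse = ", "))
  ref <- if (!is.null(atc)) resolve_multilabel(atc, seed = seed) else NULL
  sf <- rep_len(spread_factor, length(views))
  clusterings <- list()
  rows <- list()
  for (k in seq_along(views)) {
    v <- views[k]
    cl <- do.call(gsom_cluster, c(
      list(x = collection$views[[v]]$incidence, spread_factor = sf[k],
           seed = seed + k), gsom_args))
    cl$parameters$view <- v
    clusterings[[v]] <- cl
    row <- data.frame(view = v, n_clusters = length(cl$membership),
                      nmi = NA_real_, smi = NA_real_)
    if (!is.null(ref)) {
      ids <- intersect(collection$drug_ids, names(ref))
      part <- clustering_to_partition(cl, collection$drug_ids)
      ct <- contingency(part[ids], ref[ids])
      row$nmi <- nmi_sqrt(ct)
      if (compute_smi) row$smi <- tryCatch(smi(ct), error = function(e) NA_real_)
    }
    rows[[k]] <- row
  }
  list(clusterings = clusterings, evaluation = do.call(rbind, rows))
}

#' Tier-2 clustering of integrated Tier-1 results
#'
#' The integration + second clustering stage of [two_tier()] as a
#' standalone step, starting from existing Tier-1 clusterings.
#'
#' @param tier1 named list of [drug_clustering()] objects (>= 2 for the
#'   two-tier mode).
#' @param universe ordered drug ids.
#' @inheritParams two_tier
#' @param algorithms Tier-2 algorithms to run.
#' @return list with `ddr`, `graph` and `clusterings` per algorithm.
#' @export
run_tier2 <- function(tier1, universe,
                      algorithms = c("gsom", "mcl", "mcode", "cluster_one"),
                      tier2_spread_factor = 0.01, min_weight = NULL,
                      mcl_args = list(), mcode_args = list(),
                      cluster_one_args = list(), gsom_args = list(),
                      seed = 1L) {
  if (length(tier1) < 2)
    stop("two-tier integration needs at least two Tier-1 clusterings")
  algorithms <- match.arg(algorithms,
                          c("gsom", "mcl", "mcode", "cluster_one"),
                          several.ok = TRUE)
  ddr <- average_ddr(lapply(tier1, ddr_from_clustering, universe = universe))
  graph <- graph_from_ddr(ddr, min_weight = min_weight)
  clusterings <- list()
  for (alg in algorithms)
    clusterings[[alg]] <- switch(alg,
      gsom = do.call(gsom_cluster, c(
        list(x = ddr$values, spread_factor = tier2_spread_factor,
             seed = seed + 101L), gsom_args)),
      mcl = do.call(mcl, c(list(graph = graph), mcl_args)),
      mcode = do.call(mcode, c(list(graph = graph), mcode_args)),
      cluster_one = do.call(cluster_one, c(list(graph = graph),
                                           cluster_one_args)))
  list(ddr = ddr, graph = graph, clusterings = clusterings)
}

#' Write the artifacts of a fitted two-tier model
#'
#' Writes one clustering TSV per Tier-1 view and Tier-2 algorithm, the
#' averaged DDR edge list, the evaluation table and the candidate tables.
#' Every file starts with a comment line carrying the run-manifest hash
#' (a digest of the parameters and seed), so reruns with an identical
#' configuration produce bit-identical artifacts.
#'
#' @param fit a [two_tier()] fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_two_tier <- function(fit, dir) {
  stopifnot(inherits(fit, "two_tier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- manifest_hash(fit$params)
  stamp <- paste0("# run ", hash)
  put <- function(writer, obj, file) {
    path <- file.path(dir, file)
    writeLines(stamp, path)
    tmp <- tempfile()
    writer(obj, tmp)
    file.append(path, tmp)
    unlink(tmp)
  }
  for (v in names(fit$tier1))
    put(write_clustering, fit$tier1[[v]], paste0("tier1_", v, ".tsv"))
  for (alg in names(fit$tier2))
    put(write_clustering, fit$tier2[[alg]], paste0("tier2_", alg, ".tsv"))
  if (!is.null(fit$graph) && igraph::ecount(fit$graph) > 0)
    put(write_edge_list, fit$graph, "ddr_graph.tsv")
  wt <- function(df, path) utils::write.table(df, path, sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  put(wt, fit$evaluation, "evaluation.tsv")
  if (!is.null(fit$candidates)) {
    put(wt, fit$candidates, "candidates.tsv")
    put(wt, fit$consistent, "consistent_candidates.tsv")
  }
  flat <- unlist(fit$params)
  man <- data.frame(key = c("hash", names(flat)),
                    value = c(hash, as.character(flat)))
  wt(man, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

# order-dependent polynomial digest of the deparsed parameter list
manifest_hash <- function(params) {
  txt <- paste(deparse(params), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Reference benchmark values from the original 417-drug corpus
#'
#' NMI and SMI values reported for the corpus of 417 drugs shared by five
#' public profile sources (chemical fingerprints, disease indications,
#' genes, target proteins, side effects) against its 66-class second-level
#' ATC reference: the five Tier-1 GSOM clusterings, the four Tier-2
#' algorithms on the averaged DDR matrix, and the two baseline
#' integration strategies. Shipped for comparative reporting; these
#' numbers depend on that corpus and are not recomputed here.
#'
#' @return data frame with columns `stage`, `name`, `nmi`, `smi`.
#' @export
tier_benchmarks <- function() {
  data.frame(
    stage = c(rep("tier1", 5), rep("tier2", 4), "baseline", "baseline"),
    name = c("chemical", "disease", "gene", "protein", "side_effect",
             "gsom", "mcl", "cluster_one", "mcode", "concat_hy",
             "avg_sim_hz"),
    nmi = c(0.59, 0.68, 0.46, 0.63, 0.58,
            0.66, 0.59, 0.56, 0.52, 0.60, 0.64),
    smi = c(20.09, 39.33, 2.91, 30.38, 21.07,
            36.11, 26.49, 21.37, 11.57, 22.26, 33.59))
}

#' Relative NMI change of Tier-2 integration vs each Tier-1 view
#'
#' Percentage change `100 * (NMI_tier2 - NMI_view) / NMI_view` of the
#' Tier-2 GSOM result relative to each single-view Tier-1 result, computed
#' from a benchmark table in the format of [tier_benchmarks()].
#'
#' @param benchmarks data frame with `stage`, `name`, `nmi` columns.
#' @return named numeric vector of percentage changes (positive = gain).
#' @export
relative_nmi_change <- function(benchmarks = tier_benchmarks()) {
  t2 <- benchmarks$nmi[benchmarks$stage == "tier2" &
                         benchmarks$name == "gsom"]
  t1 <- benchmarks[benchmarks$stage == "tier1", ]
  stats::setNames(100 * (t2 - t1$nmi) / t1$nmi, t1$name)
}
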