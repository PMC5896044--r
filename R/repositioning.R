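#' Label a drug cluster with its majority ATC class
#'
#' A drug supports every ATC class it carries; the majority class is the
#' most supported one (ties broken by the lexicographically smallest
#' code). The confidence is the fraction of *all* cluster members --
#' including unclassified drugs -- that carry the majority class:
#' `confidence = n_majority / n_total`.
#'
#' @param cluster character vector of drug ids (non-empty).
#' @param atc an [atc_reference()].
#' @return a list of class `cluster_label` with `majority_class`,
#'   `confidence`, `n_total`, `n_majority`; or `NULL` when no member is
#'   classified (the cluster is skipped for inference).
#' @examples
#' atc <- atc_reference(list(d1 = "C03", d2 = "C03", d3 = character(0)))
#' label_cluster(c("d1", "d2", "d3"), atc)
#' @export
label_cluster <- function(cluster, atc) {
  stopifnot(length(cluster) > 0, inherits(atc, "atc_reference"))
  codes <- lapply(cluster, function(d) atc_codes(atc, d))
  support <- table(unlist(codes))
  if (!length(support)) return(NULL)
  top <- max(support)
  majority <- sort(names(support)[support == top])[1]
  structure(list(majority_class = majority,
                 confidence = as.numeric(top) / length(cluster),
                 n_total = length(cluster),
                 n_majority = as.integer(top)),
            class = "cluster_label")
}

#' @export
print.cluster_label <- function(x, ...) {
  cat("Majority class ", x$majority_class, " (", x$n_majority, "/",
      x$n_total, ", confidence ", round(x$confidence, 2), ")\n", sep = "")
  invisible(x)
}

#' Infer drug repositioning candidates from a clustering
#'
#' Each cluster whose majority-class confidence reaches `min_confidence`
#' proposes its majority ATC class to the members that do not already
#' carry it: unclassified drugs receive it as a new assignment, and
#' classified drugs lacking it are flagged for reclassification. Members
#' already carrying the majority class yield no candidate.
#'
#' @param clustering a [drug_clustering()].
#' @param atc an [atc_reference()].
#' @param min_confidence minimum cluster confidence, default 0.5.
#' @return data frame with columns `drug_id`, `cluster_id`, `old_atc`
#'   (semicolon-separated, empty for unclassified drugs), `new_atc`,
#'   `confidence`, `algorithm`, sorted by decreasing confidence.
#' @export
infer_candidates <- function(clustering, atc, min_confidence = 0.5) {
  stopifnot(inherits(clustering, "drug_clustering"),
            inherits(atc, "atc_reference"),
            min_confidence >= 0, min_confidence <= 1)
  rows <- list()
  for (cid in names(clustering$membership)) {
    members <- clustering$membership[[cid]]
    lab <- label_cluster(members, atc)
    if (is.null(lab) || lab$confidence < min_confidence) next
    for (d in members) {
      old <- atc_codes(atc, d)
      if (lab$majority_class %in% old) next
      rows[[length(rows) + 1L]] <- data.frame(
        drug_id = d, cluster_id = cid,
        old_atc = paste(old, collapse = ";"),
        new_atc = lab$majority_class,
        confidence = lab$confidence,
        algorithm = clustering$algorithm)
    }
  }
  if (!length(rows))
    return(data.frame(drug_id = character(0), cluster_id = character(0),
                      old_atc = character(0), new_atc = character(0),
                      confidence = numeric(0), algorithm = character(0)))
  out <- do.call(rbind, rows)
  out[order(-out$confidence, out$drug_id, out$cluster_id), , drop = FALSE]
}

#' Repositioning candidates consistent across runs
#'
#' Groups candidate records by (drug, proposed class) and keeps the groups
#' supported by at least two distinct algorithms or by at least two
#' distinct clusters (e.g. overlapping clusters of one algorithm) --
#' consistently re-identified proposals are the more trustworthy ones.
#'
#' @param runs list of candidate data frames from [infer_candidates()]
#'   (each carrying its `algorithm` column), or one combined data frame.
#' @return data frame of the retained records with an added `proposal`
#'   key, ordered by proposal and decreasing confidence.
#' @export
consistent_candidates <- function(runs) {
  if (is.data.frame(runs)) runs <- list(runs)
  all_rows <- do.call(rbind, runs)
  if (is.null(all_rows) || !nrow(all_rows))
    return(cbind(infer_candidates_empty(), proposal = character(0)))
  key <- paste(all_rows$drug_id, all_rows$new_atc, sep = " -> ")
  keep <- vapply(split(seq_len(nrow(all_rows)), key), function(ii) {
    length(unique(all_rows$algorithm[ii])) >= 2 ||
      length(unique(paste(all_rows$algorithm[ii],
                          all_rows$cluster_id[ii]))) >= 2
  }, logical(1))
  sel <- key %in% names(keep)[keep]
  out <- all_rows[sel, , drop = FALSE]
  out$proposal <- key[sel]
  out[order(out$proposal, -out$confidence), , drop = FALSE]
}

infer_candidates_empty <- function() {
  data.frame(drug_id = character(0), cluster_id = character(0),
             old_atc = character(0), new_atc = character(0),
             confidence = numeric(0), algorithm = character(0))
}
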