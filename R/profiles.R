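#' Binary drug-profile view
#'
#' A drug profile view is one binary drug x feature incidence matrix for a
#' single data modality (e.g. chemical fingerprints, disease indications,
#' target proteins, side effects, genes). Rows are drugs, columns features;
#' a cell of 1 records that the drug carries the feature.
#'
#' @param incidence numeric or integer matrix of 0/1 values with unique row
#'   and column names (or supply `drug_ids`/`feature_ids`).
#' @param view_name label for the modality, e.g. `"chemical"`.
#' @param drug_ids,feature_ids optional identifier vectors overriding the
#'   matrix dimnames.
#' @return an object of class `drug_profile_view` with elements `view_name`,
#'   `drug_ids`, `feature_ids` and `incidence`.
#' @examples
#' m <- rbind(D1 = c(1, 1, 0, 0), D2 = c(0, 1, 1, 0), D3 = c(0, 0, 1, 1))
#' colnames(m) <- paste0("F", 1:4)
#' v <- drug_profile_view(m, "chemical")
#' v
#' @export
drug_profile_view <- function(incidence, view_name = "custom",
                              drug_ids = rownames(incidence),
                              feature_ids = colnames(incidence)) {
  if (!is.matrix(incidence)) incidence <- as.matrix(incidence)
  storage.mode(incidence) <- "double"
  if (ncol(incidence) == 0L) stop("view '", view_name, "' has no features")
  if (nrow(incidence) == 0L) stop("view '", view_name, "' has no drugs")
  if (is.null(drug_ids)) stop("drug identifiers are required (row names)")
  if (is.null(feature_ids)) stop("feature identifiers are required (column names)")
  drug_ids <- as.character(drug_ids)
  feature_ids <- as.character(feature_ids)
  if (nrow(incidence) != length(drug_ids) ||
      ncol(incidence) != length(feature_ids))
    stop("incidence dimensions do not match identifier lists")
  if (anyDuplicated(drug_ids))
    stop("duplicate drug identifier: ",
         paste(unique(drug_ids[duplicated(drug_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifier: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  bad <- which(!(incidence %in% c(0, 1)) | is.na(incidence))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(incidence)) + 1
    j <- ((bad[1] - 1) %/% nrow(incidence)) + 1
    stop("non-binary cell at drug '", drug_ids[i], "', feature '",
         feature_ids[j], "': ", incidence[bad[1]])
  }
  dimnames(incidence) <- list(drug_ids, feature_ids)
  structure(
    list(view_name = as.character(view_name)[1], drug_ids = drug_ids,
         feature_ids = feature_ids, incidence = incidence),
    class = "drug_profile_view")
}

#' @export
print.drug_profile_view <- function(x, ...) {
  cat("Drug profile view '", x$view_name, "': ", length(x$drug_ids),
      " drugs x ", length(x$feature_ids), " features, density ",
      signif(mean(x$incidence), 3), "\n", sep = "")
  invisible(x)
}

#' Read a binary profile view from TSV
#'
#' Expects a tab-separated file whose header row lists the feature
#' identifiers (first column header `drug_id`) and whose first column holds
#' the drug identifiers. All remaining cells must parse as 0 or 1.
#'
#' @param path file path.
#' @param view_name modality label attached to the returned view.
#' @return a [drug_profile_view()].
#' @seealso [write_profile_view()]
#' @export
read_profile_view <- function(path, view_name = "custom") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L) stop("view '", view_name, "' has no feature columns")
  ids <- tab[[1]]
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab[, -1, drop = FALSE])), nrow = nrow(tab),
           dimnames = list(ids, colnames(tab)[-1])))
  drug_profile_view(m, view_name)
}

#' Write a profile view as TSV
#'
#' @param view a [drug_profile_view()].
#' @param path destination file.
#' @export
write_profile_view <- function(view, path) {
  stopifnot(inherits(view, "drug_profile_view"))
  df <- data.frame(drug_id = view$drug_ids,
                   view$incidence, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align profile views on their common drug universe
#'
#' The drug universe is the lexicographically sorted intersection of the
#' views' drug identifier sets (the multi-source corpora this method targets
#' typically share only part of their drugs, e.g. 417 drugs common to five
#' databases). Every view is filtered and reordered to that universe.
#'
#' @param views a list of [drug_profile_view()] objects (or a single view).
#' @return an object of class `profile_collection` with elements `views`
#'   (named by view name) and `drug_ids` (the universe).
#' @export
align_collection <- function(views) {
  if (inherits(views, "drug_profile_view")) views <- list(views)
  if (inherits(views, "profile_collection")) return(align_collection(views$views))
  if (!length(views)) stop("at least one view is required")
  lapply(views, function(v) stopifnot(inherits(v, "drug_profile_view")))
  universe <- Reduce(intersect, lapply(views, `[[`, "drug_ids"))
  if (!length(universe))
    stop("views share no drugs: the sources are disjoint")
  universe <- sort(universe)
  views <- lapply(views, function(v)
    drug_profile_view(v$incidence[universe, , drop = FALSE], v$view_name))
  names(views) <- vapply(views, `[[`, "", "view_name")
  structure(list(views = views, drug_ids = universe),
            class = "profile_collection")
}

#' @export
print.profile_collection <- function(x, ...) {
  cat("Profile collection: ", length(x$drug_ids), " drugs, ",
      length(x$views), " views (",
      paste(names(x$views), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' ATC reference table
#'
#' Maps each drug to a (possibly empty) set of second-level ATC therapeutic
#' codes, one uppercase letter followed by two digits (`C03`, `N05`, ...).
#' Drugs absent from the mapping are treated as unclassified.
#'
#' @param x a named list of character vectors (drug id -> codes); empty
#'   vectors mark unclassified drugs.
#' @return an object of class `atc_reference`.
#' @export
atc_reference <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("ATC mapping must be named by drug id")
  if (anyDuplicated(names(x)))
    stop("duplicate drug in ATC mapping: ",
         names(x)[duplicated(names(x))][1])
  x <- lapply(x, function(codes) {
    codes <- as.character(codes)
    codes <- codes[nzchar(codes)]
    bad <- codes[!grepl("^[A-Z][0-9]{2}$", codes)]
    if (length(bad)) stop("malformed ATC level-2 code: ", bad[1])
    sort(unique(codes))
  })
  structure(x, class = "atc_reference")
}

#' @export
print.atc_reference <- function(x, ...) {
  nn <- lengths(x)
  cat("ATC reference: ", length(x), " drugs (", sum(nn == 0),
      " unclassified, ", sum(nn > 1), " multi-class), ",
      length(unique(unlist(x))), " distinct level-2 codes\n", sep = "")
  invisible(x)
}

#' Read an ATC reference table from TSV
#'
#' Two columns: `drug_id` and a semicolon-separated list of second-level ATC
#' codes (empty for unclassified drugs). A header row is expected.
#'
#' @param path file path.
#' @return an [atc_reference()].
#' @export
read_atc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "", fill = TRUE)
  if (ncol(tab) < 2L) tab[[2]] <- rep("", nrow(tab))
  codes <- strsplit(tab[[2]], ";", fixed = TRUE)
  codes <- lapply(codes, function(cc) trimws(cc[nzchar(trimws(cc))]))
  names(codes) <- tab[[1]]
  atc_reference(codes)
}

#' Write an ATC reference table as TSV
#'
#' @param atc an [atc_reference()].
#' @param path destination file.
#' @export
write_atc_table <- function(atc, path) {
  stopifnot(inherits(atc, "atc_reference"))
  df <- data.frame(drug_id = names(atc),
                   atc_codes = vapply(atc, paste, "", collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up the ATC code set of one drug
#'
#' @param atc an [atc_reference()].
#' @param drug_id drug identifier.
#' @return character vector of codes; empty if unclassified or unknown.
#' @export
atc_codes <- function(atc, drug_id) {
  stopifnot(inherits(atc, "atc_reference"))
  codes <- atc[[drug_id]]
  if (is.null(codes)) character(0) else codes
}
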