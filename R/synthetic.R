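#' Specification for synthetic multi-view drug profiles
#'
#' Describes a planted-group generative model that emulates the structure of
#' heterogeneous binary drug profiles: each drug belongs to exactly one
#' latent group; within every view each group owns a disjoint block of
#' characteristic features that its members carry with probability `p_in`,
#' all other cells are background noise at `p_out`, and each view is finally
#' corrupted by independent bit flips. An ATC-like reference is derived from
#' the groups with a configurable fraction of multi-labeled and unlabeled
#' drugs, mirroring real reference tables (roughly 16% multi-class and 3%
#' unclassified drugs in the corpus this method was developed on).
#'
#' @param n_drugs number of drugs.
#' @param k_groups number of planted groups.
#' @param features_per_view named integer vector, view name -> feature count.
#' @param p_in probability a member carries a characteristic feature.
#' @param p_out background feature probability (`p_out < p_in`).
#' @param view_corruption per-view cell flip probability; recycled if scalar.
#' @param frac_multiclass fraction of drugs given a second, wrong, ATC-like
#'   label.
#' @param frac_unlabeled fraction of drugs with an empty label set.
#' @param seed integer seed making generation reproducible.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_drugs = 120, k_groups = 6,
                       features_per_view = c(chemical = 60, disease = 60,
                                             gene = 60, protein = 60,
                                             side_effect = 60),
                       p_in = 0.9, p_out = 0.05, view_corruption = 0.02,
                       frac_multiclass = 0.16, frac_unlabeled = 0.03,
                       seed = 1L) {
  stopifnot(n_drugs >= 1, k_groups >= 1, k_groups <= n_drugs,
            p_out >= 0, p_out < p_in, p_in <= 1,
            frac_multiclass >= 0, frac_multiclass <= 1,
            frac_unlabeled >= 0, frac_unlabeled <= 1)
  if (k_groups > 99) stop("at most 99 groups (two-digit synthetic codes)")
  if (is.null(names(features_per_view)))
    names(features_per_view) <- paste0("view", seq_along(features_per_view))
  if (any(features_per_view < k_groups))
    stop("every view needs at least k_groups features to allocate blocks")
  if (length(view_corruption) == 1L)
    view_corruption <- stats::setNames(
      rep(view_corruption, length(features_per_view)),
      names(features_per_view))
  stopifnot(all(view_corruption >= 0), all(view_corruption <= 1),
            identical(sort(names(view_corruption)),
                      sort(names(features_per_view))))
  structure(list(n_drugs = as.integer(n_drugs),
                 k_groups = as.integer(k_groups),
                 features_per_view = features_per_view,
                 p_in = p_in, p_out = p_out,
                 view_corruption = view_corruption,
                 frac_multiclass = frac_multiclass,
                 frac_unlabeled = frac_unlabeled,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic multi-view profiles with planted groups
#'
#' @param spec a [synth_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{collection}{a `profile_collection` of binary views,}
#'     \item{truth}{a list with `group_of` (named vector drug -> group id),
#'       `class_of_group` (group -> synthetic ATC-like code) and `atc`
#'       (the [atc_reference()] with injected multi/empty labels).}
#'   }
#' @examples
#' d <- synth_profiles(synth_spec(n_drugs = 30, k_groups = 3,
#'                                features_per_view = c(a = 12, b = 12)))
#' d$collection
#' @export
synth_profiles <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    n <- spec$n_drugs; k <- spec$k_groups
    drugs <- sprintf("drug%04d", seq_len(n))
    group_of <- stats::setNames(rep_len(seq_len(k), n), drugs)

    views <- vector("list", length(spec$features_per_view))
    names(views) <- names(spec$features_per_view)
    for (v in names(spec$features_per_view)) {
      f <- spec$features_per_view[[v]]
      block <- f %/% k                      # disjoint block per group
      owner <- rep(0L, f)                   # 0 = background-only feature
      owner[seq_len(block * k)] <- rep(seq_len(k), each = block)
      p <- matrix(spec$p_out, n, f)
      for (g in seq_len(k))
        p[group_of == g, owner == g] <- spec$p_in
      m <- matrix(as.double(stats::runif(n * f) < p), n, f)
      flip <- matrix(stats::runif(n * f) < spec$view_corruption[[v]], n, f)
      m[flip] <- 1 - m[flip]
      dimnames(m) <- list(drugs, sprintf("%s_f%04d", v, seq_len(f)))
      views[[v]] <- drug_profile_view(m, v)
    }

    class_of_group <- stats::setNames(sprintf("X%02d", seq_len(k)),
                                      seq_len(k))
    atc <- lapply(drugs, function(d) class_of_group[[group_of[[d]]]])
    names(atc) <- drugs
    n_unlab <- round(spec$frac_unlabeled * n)
    n_multi <- round(spec$frac_multiclass * n)
    pick <- sample(drugs, min(n, n_unlab + n_multi))
    unlabeled <- pick[seq_len(n_unlab)]
    multi <- setdiff(pick, unlabeled)
    for (d in unlabeled) atc[[d]] <- character(0)
    for (d in multi) {
      other <- setdiff(class_of_group, class_of_group[[group_of[[d]]]])
      if (length(other)) atc[[d]] <- c(atc[[d]], sample(other, 1))
    }

    list(collection = align_collection(views),
         truth = list(group_of = group_of,
                      class_of_group = class_of_group,
                      atc = atc_reference(atc)))
  })
}

#' Corrupt a profile view by random bit flips
#'
#' Each cell is flipped independently with probability `flip_prob`; models
#' the inaccuracy/incompleteness of a single data source.
#'
#' @param view a [drug_profile_view()].
#' @param flip_prob flip probability in \[0, 1\].
#' @param seed integer seed.
#' @return a [drug_profile_view()] of the same shape.
#' @export
degrade_view <- function(view, flip_prob, seed = 1L) {
  stopifnot(inherits(view, "drug_profile_view"),
            flip_prob >= 0, flip_prob <= 1)
  with_seed(seed, {
    m <- view$incidence
    flip <- matrix(stats::runif(length(m)) < flip_prob, nrow(m), ncol(m))
    m[flip] <- 1 - m[flip]
    drug_profile_view(m, view$view_name)
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes one profile TSV per view, the ATC-like reference table, the true
#' group assignment, and a manifest recording the generating spec and seed.
#'
#' @param dataset result of [synth_profiles()].
#' @param dir output directory (created if needed).
#' @param spec the generating [synth_spec()], recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dataset, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in dataset$collection$views)
    write_profile_view(v, file.path(dir, paste0("profile_", v$view_name, ".tsv")))
  write_atc_table(dataset$truth$atc, file.path(dir, "atc_reference.tsv"))
  utils::write.table(
    data.frame(drug_id = names(dataset$truth$group_of),
               group = unname(dataset$truth$group_of)),
    file.path(dir, "truth_groups.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(spec)) {
    flat <- unlist(unclass(spec))
    utils::write.table(
      data.frame(key = names(flat), value = as.character(flat)),
      file.path(dir, "manifest.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
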