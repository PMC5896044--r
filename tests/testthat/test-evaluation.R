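test_that("contingency tables count co-assignments with marginals", {
  u <- labels_of(list(A = c("i1", "i2"), B = c("i3", "i4")))
  ct <- contingency(u, u)
  expect_identical(unname(ct$counts), rbind(c(2L, 0L), c(0L, 2L)))
  expect_equal(ct$n, 4)

  v <- labels_of(list(X = c("i1", "i3"), Y = c("i2", "i4")))
  ct2 <- contingency(u, v)
  expect_true(all(ct2$counts == 1))
  expect_equal(sum(ct2$counts), 4)

  w <- labels_of(list(X = c("i1", "i9")))
  expect_error(contingency(u, w), "different item sets")
})

test_that("NMI is 1 for identical partitions, 0 for crossed ones, and
           matches hand computation", {
  u <- labels_of(list(A = paste0("i", 1:5), B = paste0("i", 6:10)))
  expect_identical(nmi_sqrt(u, u), 1)

  a <- labels_of(list(A = c("i1", "i2"), B = c("i3", "i4")))
  b <- labels_of(list(X = c("i1", "i3"), Y = c("i2", "i4")))
  expect_equal(nmi_sqrt(a, b), 0)

  # U = {123|45}, V = {12|345}: table [[2,1],[0,2]], computed by hand
  u2 <- labels_of(list(A = c("i1", "i2", "i3"), B = c("i4", "i5")))
  v2 <- labels_of(list(X = c("i1", "i2"), Y = c("i3", "i4", "i5")))
  mi_hand <- (2 / 5) * log(5 * 2 / (3 * 2)) + (1 / 5) * log(5 * 1 / (3 * 3)) +
    (2 / 5) * log(5 * 2 / (2 * 3))
  h <- -(3 / 5) * log(3 / 5) - (2 / 5) * log(2 / 5)
  expect_equal(nmi_sqrt(u2, v2), mi_hand / h, tolerance = 1e-12)

  # symmetry
  expect_equal(nmi_sqrt(u2, v2), nmi_sqrt(v2, u2), tolerance = 1e-12)

  single <- stats::setNames(rep("A", 4), paste0("i", 1:4))
  expect_error(nmi_sqrt(single, single), "single cluster")
})

test_that("exact E[MI] and Var[MI] match exhaustive permutation oracles", {
  cases <- list(
    list(u = c(1, 1, 2, 2), v = c(1, 2, 1, 2)),
    list(u = c(1, 1, 1, 2, 2, 2), v = c(1, 1, 2, 2, 3, 3)),
    list(u = c(1, 1, 1, 1, 2, 2, 3), v = c(1, 1, 1, 2, 2, 3, 3)),
    list(u = c(1, 1, 2, 2, 3, 3, 4, 4), v = c(1, 1, 2, 2, 3, 3, 4, 4)),
    list(u = c(1, 1, 1, 1, 1, 2, 2, 2), v = c(1, 1, 1, 1, 2, 2, 2, 2)))
  for (cs in cases) {
    o <- oracle_mi_moments(cs$u, cs$v)
    a <- as.vector(table(cs$u)); b <- as.vector(table(cs$v))
    expect_equal(expected_mi(a, b), unname(o["mean"]), tolerance = 1e-9)
    expect_equal(variance_mi(a, b), unname(o["var"]), tolerance = 1e-9)
  }
  # single-cluster labelings have zero expected MI and zero variance
  expect_equal(expected_mi(4, c(2, 2)), 0)
  expect_equal(variance_mi(4, c(2, 2)), 0)
})

test_that("Var[MI] is non-negative across random marginal configurations", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(6:24, 1)
    r <- sample(2:4, 1); cc <- sample(2:4, 1)
    a <- as.vector(table(sample(r, n, replace = TRUE)))
    b <- as.vector(table(sample(cc, n, replace = TRUE)))
    expect_gte(variance_mi(a, b, n), 0)
  }
})

test_that("SMI matches its permutation oracle and is maximal at self", {
  u <- labels_of(split(paste0("i", 1:8), rep(1:4, each = 2)))
  o <- oracle_mi_moments(rep(1:4, each = 2), rep(1:4, each = 2))
  smi_oracle <- (oracle_mi(rep(1:4, each = 2), rep(1:4, each = 2)) -
                   o["mean"]) / sqrt(o["var"])
  expect_equal(smi(u, u), unname(smi_oracle), tolerance = 1e-9)

  v <- labels_of(split(paste0("i", 1:8), c(1, 2, 1, 2, 3, 4, 3, 4)))
  expect_lt(smi(u, v), smi(v, v))
  expect_equal(smi(u, v), smi(v, u), tolerance = 1e-12)

  degenerate <- stats::setNames(rep("A", 8), paste0("i", 1:8))
  expect_error(smi(u, degenerate), "undefined")
})

test_that("silhouette matches brute force and obeys its conventions", {
  # two tight, far-apart pairs: all values near +1
  x <- c(0, 0.1, 10, 10.1)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(paste0("p", 1:4), paste0("p", 1:4))
  lab <- stats::setNames(c("A", "A", "B", "B"), rownames(d))
  rep1 <- silhouette_report(lab, d)
  expect_true(all(rep1$items$s > 0.95))

  # item equidistant between its own and the nearest other cluster: 0
  x2 <- c(0, 2, 1)  # p3 at distance 1 from p2 (own) and ... craft below
  d2 <- rbind(c(0, 2, 1), c(2, 0, 1), c(1, 1, 0))
  dimnames(d2) <- list(paste0("q", 1:3), paste0("q", 1:3))
  lab2 <- stats::setNames(c("A", "B", "B"), rownames(d2))
  rep2 <- silhouette_report(lab2, d2)
  expect_equal(rep2$items$s[rep2$items$id == "q3"], 0)

  # 5-point configuration vs the brute-force oracle (plus a singleton)
  x5 <- c(0, 0.5, 4, 4.6, 9)
  d5 <- as.matrix(stats::dist(x5))
  dimnames(d5) <- list(paste0("r", 1:5), paste0("r", 1:5))
  lab5 <- stats::setNames(c("A", "A", "B", "B", "C"), rownames(d5))
  rep5 <- silhouette_report(lab5, d5)
  expect_equal(rep5$items$s, oracle_silhouette(unname(lab5), d5),
               tolerance = 1e-12)
  expect_equal(rep5$items$s[5], 0)  # singleton convention
  expect_true(all(abs(rep5$items$s) <= 1))

  # independent cross-check against the recommended cluster package
  ref <- cluster::silhouette(as.integer(factor(lab5)), dmatrix = d5)
  expect_equal(rep5$items$s, unname(ref[, "sil_width"]), tolerance = 1e-12)

  expect_error(silhouette_report(
    stats::setNames(rep("A", 5), rownames(d5)), d5), "single cluster")
})

test_that("NMI and SMI both rank progressively corrupted clusterings", {
  base <- rep(1:6, each = 10)
  ids <- paste0("i", seq_along(base))
  corrupt <- function(m, s) {
    set.seed(s)
    lab <- base
    idx <- sample(length(lab), m)
    lab[idx] <- sample(6, m, replace = TRUE)
    stats::setNames(as.character(lab), ids)
  }
  ref <- stats::setNames(as.character(base), ids)
  for (metric in c(nmi_sqrt, smi)) {
    means <- vapply(c(0, 10, 25, 45), function(m)
      mean(vapply(1:5, function(s) metric(corrupt(m, s), ref), numeric(1))),
      numeric(1))
    expect_true(all(diff(means) < 0))
  }
})

test_that("reference classes on noisy profiles score a lower silhouette
           than the generating partition", {
  d <- synth_profiles(synth_spec(n_drugs = 60, k_groups = 4,
                                 features_per_view = c(a = 30),
                                 frac_multiclass = 0.3,
                                 frac_unlabeled = 0, seed = 41))
  x <- d$collection$views$a$incidence
  dm <- as.matrix(stats::dist(x))
  truth <- stats::setNames(as.character(d$truth$group_of),
                           names(d$truth$group_of))
  ref <- resolve_multilabel(d$truth$atc, seed = 1)
  ids <- names(ref)
  s_truth <- silhouette_report(truth[ids], dm[ids, ids])$mean
  s_ref <- silhouette_report(ref, dm[ids, ids])$mean
  expect_lt(s_ref, s_truth)
})

test_that("common pairs are the intersection of co-membership relations", {
  cl1 <- drug_clustering(list(a = c("d1", "d2", "d3"), b = c("d4", "d5")))
  expect_equal(nrow(common_pairs(list(cl1, cl1))), 4)  # 3 + 1 pairs

  cl2 <- drug_clustering(list(a = c("d1", "d4"), b = c("d2", "d5"),
                              c = "d3"))
  expect_equal(nrow(common_pairs(list(cl1, cl2))), 0)

  cl3 <- drug_clustering(list(z = c("d1", "d2"), y = c("d3", "d4", "d5")))
  got <- common_pairs(list(cl1, cl3))
  expect_identical(got$drug_a, c("d1", "d4"))
  expect_identical(got$drug_b, c("d2", "d5"))
  expect_error(common_pairs(list(cl1)), "at least two")
})

test_that("common pairs on planted multi-view clusterings stay within
           groups", {
  d <- synth_profiles(synth_spec(n_drugs = 48, k_groups = 4,
                                 features_per_view = c(a = 24, b = 24,
                                                       c = 24, e = 24),
                                 seed = 43))
  t1 <- run_tier1(d$collection, seed = 43)
  pairs <- common_pairs(unname(t1$clusterings))
  expect_gt(nrow(pairs), 0)
  g <- d$truth$group_of
  expect_true(all(g[pairs$drug_a] == g[pairs$drug_b]))
})

test_that("multi-label resolution is seeded, uniform and drops unlabeled", {
  atc <- atc_reference(list(a = "C03", b = c("A10", "L01"),
                            c = character(0)))
  r1 <- resolve_multilabel(atc, seed = 5)
  expect_identical(r1, resolve_multilabel(atc, seed = 5))
  expect_identical(r1[["a"]], "C03")
  expect_false("c" %in% names(r1))

  two <- atc_reference(stats::setNames(
    rep(list(c("A01", "B01")), 100), sprintf("d%03d", 1:100)))
  picks <- vapply(1:60, function(s)
    mean(resolve_multilabel(two, seed = s) == "A01"), numeric(1))
  # each class chosen about half the time (3 binomial SDs at n = 6000)
  expect_lt(abs(mean(picks) - 0.5), 3 * sqrt(0.25 / 6000))
})
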