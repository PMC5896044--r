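test_that("co-membership DDR matrices follow the shared-cluster rule", {
  cl <- drug_clustering(list(C1 = c("D1", "D2"), C2 = "D3"))
  ddr <- ddr_from_clustering(cl, c("D1", "D2", "D3"))
  expect_identical(unname(ddr$values),
                   rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))

  singletons <- drug_clustering(list(a = "D1", b = "D2", c = "D3"))
  expect_identical(unname(ddr_from_clustering(
    singletons, c("D1", "D2", "D3"))$values), diag(3))

  overlap <- drug_clustering(list(C1 = c("D1", "D2"), C2 = c("D2", "D3")))
  v <- ddr_from_clustering(overlap, c("D1", "D2", "D3"))$values
  expect_equal(v["D1", "D3"], 0)
  expect_equal(v["D1", "D2"], 1)
  expect_equal(v["D2", "D3"], 1)

  expect_error(ddr_from_clustering(cl, c("D1", "D2")), "outside")
})

test_that("uncovered drugs get zero rows and are flagged in provenance", {
  cl <- drug_clustering(list(C1 = c("D1", "D2")))
  ddr <- ddr_from_clustering(cl, c("D1", "D2", "D3"))
  expect_equal(unname(ddr$values["D3", ]), c(0, 0, 0))
  expect_identical(ddr$source$uncovered, "D3")
  # validity: symmetric, binary, reflexive on covered drugs
  expect_true(all(ddr$values %in% c(0, 1)))
  expect_identical(ddr$values, t(ddr$values))
  expect_equal(diag(ddr$values)[c("D1", "D2")], c(D1 = 1, D2 = 1))
})

test_that("averaging DDRs gives the m+1 rational levels and is
           order-equivariant", {
  ids <- c("a", "b", "c", "d")
  set.seed(8)
  mk <- function() {
    groups <- split(ids, sample(2, 4, replace = TRUE))
    groups <- groups[lengths(groups) > 0]
    ddr_from_clustering(drug_clustering(groups), ids)
  }
  mats <- replicate(4, mk(), simplify = FALSE)
  avg <- average_ddr(mats)
  expect_true(all(avg$values %in% c(0, 0.25, 0.5, 0.75, 1)))
  expect_identical(average_ddr(mats[1])$values, mats[[1]]$values)

  # permutation equivariance
  perm <- c("c", "a", "d", "b")
  mats_p <- lapply(mats, function(m)
    ddr_matrix(m$values[perm, perm], m$source))
  expect_identical(average_ddr(mats_p)$values, avg$values[perm, perm])

  bad <- ddr_matrix(mats[[1]]$values[perm, perm])
  expect_error(average_ddr(list(mats[[1]], bad)), "ordering")
})

test_that("graph construction thresholds edges and refuses zero cutoffs", {
  v <- rbind(c(1, 0.75, 0), c(0.75, 1, 0.25), c(0, 0.25, 1))
  dimnames(v) <- list(c("a", "b", "c"), c("a", "b", "c"))
  ddr <- ddr_matrix(v)
  g <- graph_from_ddr(ddr)             # keep all positive entries
  expect_equal(igraph::ecount(g), 2)
  expect_false(igraph::are_adjacent(g, "a", "c"))
  g2 <- graph_from_ddr(ddr, min_weight = 0.75)
  expect_equal(igraph::ecount(g2), 1)  # only pairs co-clustered in >= 3/4
  expect_error(graph_from_ddr(ddr, min_weight = 0), "positive")
})

test_that("strict-consensus graph has at least as many components as
           planted groups", {
  d <- synth_profiles(synth_spec(n_drugs = 48, k_groups = 4,
                                 features_per_view = c(a = 20, b = 20),
                                 seed = 19))
  t1 <- run_tier1(d$collection, seed = 19)
  ddr <- average_ddr(lapply(t1$clusterings, ddr_from_clustering,
                            universe = d$collection$drug_ids))
  g <- graph_from_ddr(ddr, min_weight = 1.0)
  expect_gte(igraph::components(g)$no, 4)
})

test_that("view concatenation (H_y) sums the per-view widths", {
  widths <- c(chemical = 881, disease = 719)
  views <- lapply(names(widths), function(nm) {
    m <- matrix(rbinom(2 * widths[[nm]], 1, 0.05), 2, widths[[nm]],
                dimnames = list(c("d1", "d2"),
                                paste0(nm, "_", seq_len(widths[[nm]]))))
    drug_profile_view(m, nm)
  })
  col <- align_collection(views)
  wide <- concat_views(col)
  expect_equal(length(wide$feature_ids), 1600)
  expect_identical(wide$incidence[, 1:881],
                   col$views$chemical$incidence)

  # five corpus-sized views concatenate to width 5264
  w5 <- c(881, 719, 775, 1385, 1504)
  views5 <- lapply(seq_along(w5), function(k) {
    m <- matrix(0, 2, w5[k], dimnames = list(c("d1", "d2"),
                                             paste0("v", k, "_", 1:w5[k])))
    m[1, 1] <- 1
    drug_profile_view(m, paste0("view", k))
  })
  expect_equal(length(concat_views(align_collection(views5))$feature_ids),
               5264)

  one <- align_collection(views[1])
  expect_identical(concat_views(one)$incidence,
                   one$views$chemical$incidence)
  expect_error(concat_views(views), "collection")
})

test_that("jaccard similarity handles identity, disjointness and zeros", {
  expect_equal(jaccard(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(jaccard(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(jaccard(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(jaccard(c(0, 0), c(0, 0)), 0)
  expect_error(jaccard(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("averaged pairwise similarity (H_z) is the mean of per-view
           Jaccard", {
  col <- tiny_collection()
  hz <- average_pairwise_similarity(col)
  j1 <- jaccard(col$views$chemical$incidence["D1", ],
                col$views$chemical$incidence["D2", ])
  j2 <- jaccard(col$views$disease$incidence["D1", ],
                col$views$disease$incidence["D2", ])
  expect_equal(hz$values["D1", "D2"], mean(c(j1, j2)))
  expect_equal(diag(hz$values), c(D1 = 1, D2 = 1, D3 = 1))

  dup <- align_collection(list(col$views$chemical,
                               drug_profile_view(col$views$chemical$incidence,
                                                 "copy")))
  single <- average_pairwise_similarity(align_collection(col$views["chemical"]))
  expect_equal(average_pairwise_similarity(dup)$values, single$values)
})

test_that("H_z is dense where the averaged DDR keeps exact zeros", {
  d <- synth_profiles(synth_spec(seed = 29))  # study-scale 5-view profiles
  same <- outer(d$truth$group_of, d$truth$group_of, "==")
  ut <- upper.tri(same)

  hz <- average_pairwise_similarity(d$collection)
  expect_gt(mean(hz$values[ut] > 0), 0.99)
  expect_gt(mean(hz$values[ut & same]), mean(hz$values[ut & !same]))

  t1 <- run_tier1(d$collection, seed = 29)
  ddr <- average_ddr(lapply(t1$clusterings, ddr_from_clustering,
                            universe = d$collection$drug_ids))
  expect_gt(sum(ddr$values == 0), 0)
  expect_gt(mean(ddr$values[ut & same]), mean(ddr$values[ut & !same]))
})
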