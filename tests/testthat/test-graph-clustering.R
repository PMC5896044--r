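# --- MCL ------------------------------------------------------------------

test_that("MCL separates disconnected and bridged structures", {
  g <- toy_graph(rbind(clique_edges(c("a1", "a2", "a3")),
                       clique_edges(c("b1", "b2", "b3"))))
  cl <- mcl(g, inflation = 2)
  expect_length(cl$membership, 2)
  expect_setequal(lapply(unname(cl$membership), sort),
                  list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))

  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "lonely"
  expect_identical(unname(mcl(iso)$membership), list("lonely"))

  # barbell: two 4-cliques joined by one weak edge split at the bridge
  barbell <- rbind(clique_edges(paste0("a", 1:4)),
                   clique_edges(paste0("b", 1:4)),
                   data.frame(from = "a1", to = "b1", weight = 0.1))
  cl2 <- mcl(toy_graph(barbell), inflation = 2)
  expect_length(cl2$membership, 2)
  expect_setequal(lapply(unname(cl2$membership), sort),
                  list(paste0("a", 1:4), paste0("b", 1:4)))
})

test_that("the MCL iterate stays column-stochastic and converges to an
           idempotent flow", {
  barbell <- rbind(clique_edges(paste0("a", 1:4)),
                   clique_edges(paste0("b", 1:4)),
                   data.frame(from = "a1", to = "b1", weight = 0.1))
  g <- toy_graph(barbell)
  M <- ttclust:::graph_adjacency(g)
  loops <- apply(M, 1, max); diag(M) <- loops
  M <- sweep(M, 2, colSums(M), "/")
  for (i in 1:30) {
    M <- mcl_step(M, inflation = 2)
    expect_equal(unname(colSums(M)), rep(1, ncol(M)), tolerance = 1e-9)
  }
  flow <- mcl_flow(g, inflation = 2)
  expect_lt(max(abs(mcl_step(flow, inflation = 2) - flow)), 1e-5)
})

test_that("MCL cluster count is non-decreasing in inflation", {
  set.seed(5)
  edges <- rbind(clique_edges(paste0("a", 1:5), weight = 1),
                 clique_edges(paste0("b", 1:5), weight = 1),
                 clique_edges(paste0("c", 1:4), weight = 1),
                 data.frame(from = c("a1", "b1"), to = c("b2", "c1"),
                            weight = 0.3))
  g <- toy_graph(edges)
  counts <- vapply(c(1.3, 2, 4, 8), function(infl)
    length(mcl(g, inflation = infl)$membership), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("MCL validates parameters and warns on non-convergence", {
  g <- toy_graph(clique_edges(c("a", "b", "c")))
  expect_error(mcl(g, inflation = 0.048), "inflation")
  barbell <- toy_graph(rbind(clique_edges(paste0("a", 1:4)),
                             clique_edges(paste0("b", 1:4)),
                             data.frame(from = "a1", to = "b1",
                                        weight = 0.1)))
  expect_warning(mcl(barbell, max_iterations = 1, convergence_tol = 1e-15),
                 "did not converge")
})

# --- MCODE ----------------------------------------------------------------

test_that("MCODE vertex weights follow core number times core density", {
  cl4 <- toy_graph(clique_edges(paste0("k", 1:4)))
  expect_equal(unname(mcode_vertex_weight(cl4, "k1")), 3.0)

  iso <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(iso)$name <- c("u", "v")
  expect_equal(unname(mcode_vertex_weight(iso, "u")), 0)

  # 5-star: the closed neighborhood of the hub is the whole star, whose
  # highest core is the 1-core with density 2*5/(6*5) = 1/3
  star <- toy_graph(data.frame(from = "hub", to = paste0("s", 1:5)))
  expect_equal(unname(mcode_vertex_weight(star, "hub")), 1 / 3)
  expect_error(mcode_vertex_weight(star, "zz"), "not in graph")
})

test_that("MCODE finds dense complexes and haircuts pendants", {
  g <- toy_graph(rbind(clique_edges(paste0("c", 1:5)),
                       data.frame(from = "c1", to = "pendant", weight = 1)))
  cl <- mcode(g, vwp = 0.1, haircut = TRUE)
  expect_length(cl$membership, 1)
  expect_identical(cl$membership[[1]], paste0("c", 1:5))

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- c("x", "y", "z")
  expect_length(mcode(edgeless)$membership, 0)
})

test_that("two 4-cliques sharing a vertex split according to the weight
           cutoff", {
  shared <- rbind(clique_edges(c("a1", "a2", "a3", "s")),
                  clique_edges(c("b1", "b2", "b3", "s")))
  g <- toy_graph(shared)
  # shared vertex weight: its closed neighborhood is the full 7-vertex
  # union, a 3-core of density 12/21, so weight 12/7 < (1-0.2)*3
  expect_equal(unname(mcode_vertex_weight(g, "s")), 3 * 12 / 21)
  cl <- mcode(g, vwp = 0.2, haircut = FALSE)
  expect_length(cl$membership, 2)
  expect_false("s" %in% unlist(cl$membership))
  # a looser cutoff admits the shared vertex, through which the growth
  # reaches the second clique: one complex covering everything
  cl2 <- mcode(g, vwp = 0.5, haircut = FALSE)
  expect_length(cl2$membership, 1)
  expect_length(cl2$membership[[1]], 7)
})

test_that("MCODE complexes are vertex-disjoint and seed-dominated", {
  d <- synth_profiles(synth_spec(n_drugs = 40, k_groups = 4,
                                 features_per_view = c(a = 20, b = 20),
                                 seed = 31))
  t1 <- run_tier1(d$collection, seed = 31)
  t2 <- run_tier2(t1$clusterings, d$collection$drug_ids,
                  algorithms = "mcode", seed = 31)
  cl <- t2$clusterings$mcode
  members <- unlist(cl$membership, use.names = FALSE)
  expect_identical(anyDuplicated(members), 0L)
  w <- mcode_vertex_weight(t2$graph)
  seeds <- attr(cl, "seeds")
  for (i in seq_along(cl$membership))
    expect_equal(w[[seeds[i]]], max(w[cl$membership[[i]]]))
})

# --- ClusterONE -----------------------------------------------------------

test_that("cohesiveness matches its closed form on small graphs", {
  tri <- toy_graph(clique_edges(c("a", "b", "c")))
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 0), 1.0)
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 1), 0.5)

  g <- toy_graph(rbind(clique_edges(paste0("k", 1:4)),
                       data.frame(from = "k1", to = "out", weight = 1)))
  expect_equal(cohesiveness(g, paste0("k", 1:4), penalty = 0), 6 / 7)
  expect_error(cohesiveness(g, character(0)), "non-empty")
})

test_that("ClusterONE recovers disjoint triangles and filters by density", {
  g <- toy_graph(rbind(clique_edges(c("a1", "a2", "a3")),
                       clique_edges(c("b1", "b2", "b3"))))
  cl <- cluster_one(g, density_threshold = 0.5, penalty = 0.5)
  expect_length(cl$membership, 2)
  expect_setequal(lapply(unname(cl$membership), sort),
                  list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))

  path <- toy_graph(data.frame(from = c("p1", "p2", "p3"),
                               to = c("p2", "p3", "p4")))
  expect_length(cluster_one(path, density_threshold = 1.0)$membership, 0)
})

test_that("overlapping groups merge iff the overlap score reaches the
           threshold", {
  # two 4-cliques joined through a shared bridge vertex x
  edges <- rbind(clique_edges(paste0("a", 1:4)),
                 clique_edges(paste0("b", 1:4)),
                 data.frame(from = "x", to = c("a1", "a2", "b1", "b2"),
                            weight = 1))
  g <- toy_graph(edges)
  cl <- cluster_one(g, density_threshold = 0.5,
                    overlap_merge_threshold = 0.8)
  expect_length(cl$membership, 2)
  shared <- intersect(cl$membership[[1]], cl$membership[[2]])
  # omega({A, x}, {B, x}) = 1^2 / (5 * 5) = 0.04 < 0.8: kept apart
  expect_identical(shared, "x")
  merged <- cluster_one(g, density_threshold = 0.5,
                        overlap_merge_threshold = 0.04)
  expect_length(merged$membership, 1)
  expect_length(merged$membership[[1]], 9)
})

test_that("emitted groups satisfy the density bound and growth never
           decreases cohesiveness", {
  d <- synth_profiles(synth_spec(n_drugs = 40, k_groups = 4,
                                 features_per_view = c(a = 20, b = 20),
                                 seed = 17))
  t1 <- run_tier1(d$collection, seed = 17)
  t2 <- run_tier2(t1$clusterings, d$collection$drug_ids,
                  algorithms = "cluster_one", seed = 17)
  cl <- t2$clusterings$cluster_one
  A <- ttclust:::graph_adjacency(t2$graph)
  for (members in cl$membership) {
    idx <- match(members, rownames(A))
    dens <- sum(A[idx, idx]) / (length(idx) * (length(idx) - 1))
    expect_gte(dens, cl$parameters$density_threshold - 1e-9)
  }
  for (hist in attr(cl, "growth_history"))
    expect_true(all(diff(hist) > -1e-12))
})

# --- planted-partition recovery for all three ------------------------------

test_that("all graph algorithms recover a noiseless planted partition
           exactly", {
  d <- synth_profiles(synth_spec(n_drugs = 36, k_groups = 4,
                                 features_per_view = c(a = 16, b = 16),
                                 p_in = 1, p_out = 0, view_corruption = 0,
                                 seed = 23))
  truth_groups <- split(names(d$truth$group_of), d$truth$group_of)
  t1 <- run_tier1(d$collection, seed = 23)
  t2 <- run_tier2(t1$clusterings, d$collection$drug_ids, seed = 23)
  for (alg in c("mcl", "mcode", "cluster_one")) {
    got <- lapply(unname(t2$clusterings[[alg]]$membership), sort)
    expect_setequal(got, lapply(unname(truth_groups), sort))
  }
})
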