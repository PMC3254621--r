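test_that("cross-locus extraction keeps only bipartite edges", {
  edges <- rbind(string_edge("a1", "b1"), string_edge("a1", "a2"),
                 string_edge("b1", "b2"), string_edge("a2", "b2"),
                 string_edge("a2", "x1"))
  pp <- new_ppin(edges)
  sets <- candidate_sets(c("a1", "a2"), c("b1", "b2"))
  sub <- cross_locus_subgraph(pp, sets)
  keys <- paste(sub$protein1, sub$protein2)
  expect_setequal(keys, c("a1 b1", "a2 b2"))

  empty <- cross_locus_subgraph(pp, candidate_sets("q1", "q2"))
  expect_equal(nrow(empty), 0L)
  expect_error(candidate_sets(c("a", "b"), c("b", "c")), "disjoint")
})

test_that("randomization conserves degrees, edge count and simplicity", {
  pp <- simulate_ppin(40, 90, seed = 10)
  deg0 <- sort(tabulate(factor(c(pp$edges$protein1, pp$edges$protein2),
                               levels = pp$nodes)))
  for (s in 1:20) {
    r <- randomize_network(pp, swaps_per_edge = 10, seed = s)
    expect_equal(nrow(r$edges), nrow(pp$edges))
    deg <- sort(tabulate(factor(c(r$edges$protein1, r$edges$protein2),
                                levels = r$nodes)))
    expect_equal(deg, deg0)
    key <- paste(r$edges$protein1, r$edges$protein2)
    expect_false(any(duplicated(key)))
    expect_false(any(r$edges$protein1 == r$edges$protein2))
  }
})

test_that("a rigid triangle cannot be rewired", {
  tri <- new_ppin(rbind(string_edge("x", "y"), string_edge("x", "z"),
                        string_edge("y", "z")))
  r <- randomize_network(tri, 10, seed = 1)
  expect_identical(r$edges[, 1:2], tri$edges[, 1:2])
  # and all SPAN p-values there are exactly 1
  sets <- candidate_sets("x", c("y", "z"))
  np <- node_priority(tri, sets, n_rand = 50, seed = 2)
  ep <- edge_priority(tri, sets, n_rand = 50, seed = 2)
  expect_equal(np$p_value, rep(1, 3))
  expect_equal(ep$p_value, rep(1, 2))
})

test_that("the two-edge matching is sampled uniformly over its 3 states", {
  pm <- new_ppin(rbind(string_edge("a", "b"), string_edge("c", "d")))
  sets <- candidate_sets("a", "b")
  np <- node_priority(pm, sets, n_rand = 3000, seed = 3)
  ep <- edge_priority(pm, sets, n_rand = 3000, seed = 3)
  # P(edge ab under the null) = 1/3 over the three perfect matchings
  se <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_lt(abs(ep$p_value - 1 / 3), 4 * se)
  expect_equal(np$p_value, rep(ep$p_value, 2))
})

test_that("Monte-Carlo p-values match exhaustive enumeration", {
  # 5 nodes, degrees (1,1,2,1,1): non-trivial configuration space
  edges <- rbind(string_edge("a", "b"), string_edge("c", "d"),
                 string_edge("c", "e"))
  pp <- new_ppin(edges)
  sets <- candidate_sets(c("a", "c"), c("b", "d"))
  exact <- enum_span_pvalues(pp$nodes, pp$edges[, 1:2],
                             sets$set_a, sets$set_b)
  expect_gt(exact$n_graphs, 1)
  n_rand <- 5000
  np <- node_priority(pp, sets, n_rand = n_rand, seed = 4)
  ep <- edge_priority(pp, sets, n_rand = n_rand, seed = 4)
  for (i in seq_len(nrow(np))) {
    p0 <- exact$node[[np$protein[i]]]
    se <- sqrt(max(p0 * (1 - p0), 1e-6) / n_rand)
    expect_lt(abs(np$p_value[i] - p0), 3 * se + 2 / n_rand)
  }
  for (i in seq_len(nrow(ep))) {
    k <- paste(ep$protein_a[i], ep$protein_b[i])
    p0 <- exact$edge[[k]]
    se <- sqrt(max(p0 * (1 - p0), 1e-6) / n_rand)
    expect_lt(abs(ep$p_value[i] - p0), 3 * se + 2 / n_rand)
  }
})

test_that("p-values use the pseudocount estimator and never reach zero", {
  pp <- simulate_ppin(30, 45, seed = 12)
  sets <- candidate_sets(pp$nodes[1:5], pp$nodes[6:10])
  np <- node_priority(pp, sets, n_rand = 20, seed = 13)
  expect_true(all(np$p_value > 0 & np$p_value <= 1))
  expect_true(all(np$p_value >= 1 / 21))
  # proteins absent from the network score p = 1
  sets2 <- candidate_sets("ZZ_not_there", pp$nodes[2])
  np2 <- node_priority(pp, sets2, n_rand = 20, seed = 13)
  expect_equal(np2$observed_cross_degree[np2$protein == "ZZ_not_there"], 0L)
  expect_equal(np2$p_value[np2$protein == "ZZ_not_there"], 1)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.1, 0)), "p-values")
  set.seed(1)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  # q weakly monotone in sorted-p order
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("prioritization ranks a planted low-degree cross edge first", {
  # planted edge between two degree-1 nodes; decoy cross edges attach to
  # hubs, so the planted interaction is the least likely under the null
  set.seed(20)
  hubs_a <- sprintf("HA%02d", 1:6); hubs_b <- sprintf("HB%02d", 1:6)
  planted <- rbind(c("LOWA", "LOWB"), c("HA01", "HB01"))
  extra <- rbind(cbind("HA01", sprintf("X%02d", 1:8)),
                 cbind("HB01", sprintf("X%02d", 9:16)))
  nodes <- c("LOWA", "LOWB", hubs_a, hubs_b, sprintf("X%02d", 1:40))
  pp <- simulate_ppin(length(nodes), 70,
                      planted_edges = rbind(planted, extra),
                      degree_skew = 0.5, seed = 21, node_ids = nodes)
  sets <- candidate_sets(c("LOWA", hubs_a), c("LOWB", hubs_b))
  pr <- prioritize(pp, sets, n_rand = 400, seed = 22)
  expect_true(all(pr$nodes$q_value >= pr$nodes$p_value - 1e-12))
  expect_true(all(pr$edges$q_value >= pr$edges$p_value - 1e-12))
  key <- paste(pr$edges$protein_a, pr$edges$protein_b)
  expect_equal(key[which.min(pr$edges$p_value)], "LOWA LOWB")
  expect_equal(min(pr$edges$q_value),
               pr$edges$q_value[key == "LOWA LOWB"])
})

test_that("isolated candidate proteins give a fully null prioritization", {
  pp <- simulate_ppin(20, 30, seed = 30)
  sets <- candidate_sets(c("I1", "I2"), c("I3", "I4"))
  pr <- prioritize(pp, sets, n_rand = 20, seed = 31)
  expect_equal(pr$nodes$p_value, rep(1, 4))
  expect_equal(pr$nodes$q_value, rep(1, 4))
  expect_equal(nrow(pr$edges), 0L)
  expect_equal(nrow(pr$headline), 0L)
})

test_that("subnetwork exports are Cytoscape-readable", {
  pp <- simulate_ppin(20, 35, seed = 40)
  sets <- candidate_sets(pp$nodes[1:4], pp$nodes[5:8])
  pr <- prioritize(pp, sets, n_rand = 30, seed = 41)
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_sif(pr$edges, sif)
  write_graphml(pr, gml, seed_info = "seed=41")
  if (nrow(pr$edges)) {
    lines <- readLines(sif)
    expect_true(all(grepl(" pp ", lines)))
  }
  g <- igraph::read_graph(gml, format = "graphml")
  expect_s3_class(g, "igraph")
  expect_equal(igraph::ecount(g), nrow(pr$edges))
})
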