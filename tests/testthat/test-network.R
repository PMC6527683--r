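make_graph <- function(edges, isolated = character()) {
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}

test_that("expression filtering induces the subgraph on expressed genes", {
  ppi <- make_graph(c("a", "b", "b", "c"))
  ci <- filter_interactome(ppi, c("a", "b"), "T")
  expect_s3_class(ci, "cell_interactome")
  expect_equal(igraph::ecount(ci$graph), 1L)
  expect_setequal(igraph::V(ci$graph)$name, c("a", "b"))
  # full expression reproduces the graph
  ci2 <- filter_interactome(ppi, c("a", "b", "c"), "T")
  expect_equal(igraph::ecount(ci2$graph), 2L)
  expect_error(filter_interactome(ppi, c("x", "y"), "T"), "T")
  expect_error(filter_interactome(ppi, character(), "T"), "empty")
})

test_that("subnetwork extraction finds the largest connected component", {
  g <- make_graph(c("a", "b", "b", "c", "d", "e"))
  sub <- extract_subnetwork(g, c("a", "b", "c", "d", "e"))
  expect_equal(sub$metrics$lcc_nodes, 3L)
  expect_equal(sub$metrics$lcc_edges, 2L)
  expect_setequal(igraph::V(sub$lcc)$name, c("a", "b", "c"))
  expect_false(sub$metrics$eligible)   # LCC of 3 <= 15

  # isolated selection: LCC of one node, flagged ineligible
  g2 <- make_graph(c("a", "b"), isolated = c("x", "y"))
  sub2 <- extract_subnetwork(g2, c("x", "y"))
  expect_equal(sub2$metrics$n_edges, 0L)
  expect_equal(sub2$metrics$lcc_nodes, 1L)
  expect_false(sub2$metrics$eligible)

  # eligibility threshold is strict and can apply to the whole subnetwork
  ring <- igraph::make_ring(16)
  igraph::V(ring)$name <- paste0("n", 1:16)
  expect_true(extract_subnetwork(ring, paste0("n", 1:16))$metrics$eligible)
  chain <- igraph::make_ring(15, circular = FALSE)
  igraph::V(chain)$name <- paste0("n", 1:15)
  expect_false(extract_subnetwork(chain, paste0("n", 1:15))$metrics$eligible)
})

test_that("LCC extraction agrees with a transitive-closure oracle", {
  set.seed(5)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    adj <- matrix(runif(n * n) < 0.3, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- paste0("v", seq_len(n))
    sub <- extract_subnetwork(g, paste0("v", seq_len(n)))
    want <- oracle_lcc(adj)
    expect_equal(sub$metrics$lcc_nodes, want$nodes)
    expect_equal(sub$metrics$lcc_edges, as.integer(want$edges))
    expect_equal(sub$metrics$n_edges, as.integer(sum(adj) / 2))
  }
})

test_that("component ties break deterministically by edges then names", {
  # two components of equal node count; the denser one wins
  g <- make_graph(c("a", "b", "b", "c", "a", "c",   # triangle
                    "x", "y", "y", "z"))            # path
  sub <- extract_subnetwork(g, c("a", "b", "c", "x", "y", "z"))
  expect_setequal(igraph::V(sub$lcc)$name, c("a", "b", "c"))
  # equal nodes and edges: lexicographically smallest member set
  g2 <- make_graph(c("m", "n", "a", "b"))
  sub2 <- extract_subnetwork(g2, c("m", "n", "a", "b"))
  expect_setequal(igraph::V(sub2$lcc)$name, c("a", "b"))
})

test_that("null sampling hits the degenerate cases exactly", {
  g <- igraph::sample_gnp(30, 0.2)
  igraph::V(g)$name <- paste0("v", 1:30)
  # k = all nodes reproduces the full graph every draw
  null_all <- sample_null(g, 30, reps = 5, seed = 1)
  expect_true(all(null_all$n_edges == igraph::ecount(g)))
  comp <- igraph::components(g)
  expect_true(all(null_all$lcc_nodes == max(comp$csize)))
  # k = 1: no edges, singleton component
  null_1 <- sample_null(g, 1, reps = 10, seed = 1)
  expect_true(all(null_1$n_edges == 0L))
  expect_true(all(null_1$lcc_nodes == 1L))
  expect_error(sample_null(g, 31, reps = 2), "exceeds")
})

test_that("null sampling is seed-reproducible and seed-sensitive", {
  g <- igraph::sample_gnp(100, 0.05)
  igraph::V(g)$name <- paste0("v", 1:100)
  a <- sample_null(g, 20, reps = 200, seed = 99)
  b <- sample_null(g, 20, reps = 200, seed = 99)
  expect_identical(a, b)
  c <- sample_null(g, 20, reps = 200, seed = 100)
  expect_false(identical(a, c))
})

test_that("mean induced edge count matches the closed form on random graphs", {
  set.seed(2)
  g <- igraph::sample_gnp(200, 0.05)
  igraph::V(g)$name <- paste0("v", 1:200)
  null <- sample_null(g, 50, reps = 2000, seed = 3)
  expected <- igraph::ecount(g) / choose(200, 2) * choose(50, 2)
  se <- sd(null$n_edges) / sqrt(nrow(null))
  expect_lt(abs(mean(null$n_edges) - expected), 3 * se + 1e-9)
})

test_that("empirical p-values use the add-one rule and never reach zero", {
  expect_equal(empirical_p(3, c(1, 2, 3, 4)), 0.6)
  null <- rep(0, 10000)
  expect_equal(empirical_p(1, null), 1 / 10001)
  expect_equal(empirical_p(-1, c(1, 2, 3)), 1)
  expect_error(empirical_p(1, numeric()), "empty")
  # appending the observed value to its own null cannot make the result
  # more significant, and the bounds 1/(R+1) <= p <= 1 always hold
  set.seed(7)
  for (i in 1:20) {
    null <- rpois(50, 10); obs <- rpois(1, 10)
    p_aug <- empirical_p(obs, c(null, obs))
    p <- empirical_p(obs, null)
    expect_gte(p_aug, p - 1e-12)
    expect_gte(p, 1 / (length(null) + 1))
    expect_lte(p_aug, 1)
  }
})

test_that("enrichment flags a planted module as significant", {
  cfg <- small_sim_config()
  ppi <- simulate_ppi(cfg)
  gl <- prenet:::sim_genes(cfg)
  ci <- filter_interactome(ppi, igraph::V(ppi)$name, "T")
  nm <- enrich_test(ci, gl$module_genes, reps = 500, seed = 4)
  expect_lt(nm$p[["n_edges"]], 0.05)
  expect_s3_class(nm, "network_metrics")
  expect_output(print(nm), "empirical p")
})

test_that("degree-matched sampling preserves the degree profile", {
  g <- igraph::sample_gnp(150, 0.08)
  igraph::V(g)$name <- paste0("v", 1:150)
  sel <- paste0("v", order(igraph::degree(g), decreasing = TRUE)[1:15])
  plain <- sample_null(g, 15, reps = 300, seed = 5)
  matched <- sample_null(g, 15, reps = 300, seed = 5,
                         degree_matched = TRUE, match_nodes = sel)
  # high-degree selection: degree-matched nulls carry more edges on average
  expect_gt(mean(matched$n_edges), mean(plain$n_edges))
})

test_that("the sensitivity grid covers every combination and marks absences", {
  cfg <- small_sim_config()
  sim <- simulate_catalogue(cfg)
  cat_cl <- classify_catalogue(sim$catalogue, sim$class_map, sim$bucket_map,
                               quiet = TRUE)
  ppi <- simulate_ppi(cfg)
  interactomes <- lapply(setNames(nm = cfg$buckets), function(b)
    filter_interactome(ppi, igraph::V(ppi)$name, b))
  tiers <- list(GW = list(effects = sim$effects$GW,
                          proxies = sim$proxies$GW),
                SR = NULL)
  grid <- sensitivity_grid(tiers, cat_cl, interactomes,
                           r2_values = c(0.5, 0.8), q_values = c(25, 50),
                           reps = 50, seed = 9)
  expect_equal(nrow(grid), 2 * 2 * 2 * 3)
  expect_true(all(grid[tier == "SR"]$absent))
  expect_true(all(!grid[tier == "GW"]$absent))
  # a single-cell grid reproduces a direct run
  g1 <- sensitivity_grid(tiers["GW"], cat_cl, interactomes["T"],
                         r2_values = 0.5, q_values = 25, reps = 50, seed = 9)
  expect_equal(nrow(g1), 1L)
  region_snps <- expand_ld(sim$effects$GW, sim$proxies$GW, 0.5)
  gp <- aggregate_gene_pre(compute_pre(region_snps, cat_cl))
  gb <- gp[bucket == "T"]
  sel <- select_high_pre(setNames(gb$pre, gb$gene), 25)
  direct <- enrich_test(interactomes$T, sel, reps = 50, seed = 9 + 1)
  expect_equal(g1$n_edges, direct$n_edges)
  expect_equal(g1$p_edges, direct$p[["n_edges"]])
})
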