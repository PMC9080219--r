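fake_assoc <- function(ls, rho, q) {
  k <- length(ls)
  data.frame(node_a = sprintf("a%02d", seq_len(k)),
             node_b = sprintf("b%02d", seq_len(k)),
             kind = "otu-otu", ls = ls, sign = ifelse(ls >= 0, "+", "-"),
             spearman = rho, q = q, stringsAsFactors = FALSE)
}

test_that("the core filter applies all three cut-offs strictly", {
  assoc <- fake_assoc(ls = c(0.75, 0.75, 0.75, 0.69, -0.8),
                      rho = c(0.80, 0.65, 0.80, 0.9, -0.9),
                      q = c(1e-4, 1e-4, 0.01, 1e-5, 1e-6))
  g <- filter_core(assoc)
  el <- igraph::as_data_frame(g, "edges")
  expect_equal(nrow(el), 2)  # rows 1 and 5 survive
  expect_equal(igraph::vcount(g), 4)  # only incident nodes kept
  # monotone: tightening never adds edges
  for (lsm in c(0.7, 0.76, 0.81)) {
    expect_lte(igraph::ecount(filter_core(assoc, ls_min = lsm)),
               igraph::ecount(filter_core(assoc, ls_min = 0.7)))
  }
  # fixture count equals a hand filter
  keep <- abs(assoc$ls) > 0.7 & abs(assoc$spearman) > 0.7 & assoc$q < 0.001
  expect_equal(igraph::ecount(filter_core(assoc)), sum(keep))
})

test_that("network statistics match closed forms on canonical graphs", {
  tri <- igraph::make_full_graph(3)
  s <- network_stats(tri)
  expect_equal(s$density, 1)
  expect_equal(s$average_clustering, 1)
  expect_equal(s$average_path_length, 1)
  expect_equal(s$diameter, 1)
  p3 <- igraph::make_graph(~ a - b, b - c)
  s3 <- network_stats(p3)
  expect_equal(s3$density, 2 / 3)
  expect_equal(s3$average_path_length, 4 / 3)
  expect_equal(s3$largest_clique_size, 2)
  expect_error(network_stats(igraph::make_empty_graph(1, directed = FALSE)),
               "2 nodes")
  # density of G(n, m) equals m / (n(n-1)/2) for every realization
  for (seed in 1:5) {
    g <- random_baseline(40, 100, "er", seed = seed)
    expect_equal(network_stats(g)$density, 100 / (40 * 39 / 2))
  }
})

test_that("node metrics are normalized centralities", {
  star <- igraph::make_star(5, "undirected", center = 1)
  igraph::V(star)$name <- letters[1:5]
  m <- node_metrics(star)
  expect_equal(m$betweenness[1], 1)
  expect_equal(m$betweenness[2:5], rep(0, 4))
  expect_equal(m$closeness[1], 1)
  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- letters[1:4]
  m2 <- node_metrics(ring)
  expect_equal(m2$degree, rep(2, 4))
  expect_equal(m2$clustering, rep(0, 4))  # no triangles in a 4-cycle
})

test_that("random baselines match the requested size", {
  er <- random_baseline(262, 1411, "er", seed = 1)
  expect_equal(igraph::vcount(er), 262)
  expect_equal(igraph::ecount(er), 1411)
  expect_equal(mean(igraph::degree(er)), 2 * 1411 / 262)
  ws <- random_baseline(262, 1411, "ws", seed = 2)
  expect_equal(igraph::ecount(ws), 1411)
  expect_true(igraph::is_simple(ws))
  ba <- random_baseline(262, 1411, "ba", seed = 3)
  expect_equal(igraph::ecount(ba), 1411)
  expect_error(random_baseline(5, 11, "er"), "infeasible")
  expect_true(igraph::identical_graphs(random_baseline(50, 120, "er", seed = 9),
                                       random_baseline(50, 120, "er", seed = 9)))
})

test_that("seasonal subnetworks are induced OTU subgraphs", {
  el <- rbind(c("w1", "w2"), c("w2", "w3"), c("w1", "s1"), c("s1", "s2"),
              c("w1", "temperature"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$kind <- ifelse(igraph::V(g)$name == "temperature", "env",
                              "otu")
  seasons <- c(w1 = "winter", w2 = "winter", w3 = "winter",
               s1 = "summer", s2 = "summer")
  w <- seasonal_subnetwork(g, seasons, "winter")
  expect_equal(igraph::vcount(w), 3)
  expect_equal(igraph::ecount(w), 2)  # hand count of winter-winter edges
  expect_false("temperature" %in% igraph::V(w)$name)
  s <- seasonal_subnetwork(g, seasons, "summer")
  expect_equal(igraph::ecount(s), 1)
  expect_equal(igraph::vcount(seasonal_subnetwork(g, seasons, "autumn")), 0)
  expect_error(seasonal_subnetwork(g, seasons, "monsoon"), "unknown season")
})

test_that("MCODE finds dense modules with the expected scores", {
  clique5 <- igraph::make_full_graph(5)
  igraph::V(clique5)$name <- paste0("v", 1:5)
  mods <- mcode_modules(clique5)
  expect_length(mods, 1)
  expect_equal(mods[[1]]$score, 5)
  expect_true(mods[[1]]$main)
  # two 5-cliques joined by a single bridge edge: two modules of 5
  g2 <- two_cliques(5)
  igraph::V(g2)$name <- paste0("n", 1:10)
  mods2 <- mcode_modules(g2)
  expect_length(mods2, 2)
  expect_equal(sort(vapply(mods2, `[[`, 0, "n_nodes")), c(5, 5))
  expect_equal(vapply(mods2, `[[`, 0, "score"), c(5, 5))
  # edgeless graph: no modules
  expect_length(mcode_modules(igraph::make_empty_graph(4, directed = FALSE)),
                0)
})

test_that("MCODE output is invariant to node relabeling", {
  set.seed(17)
  for (i in 1:20) {
    g <- igraph::sample_gnp(12, 0.35)
    igraph::V(g)$name <- sprintf("x%02d", 1:12)
    perm <- sample(12)
    g2 <- igraph::permute(g, perm)
    sig <- function(mods) {
      if (length(mods) == 0) return("empty")
      paste(sort(vapply(mods, function(m)
        sprintf("%d:%.6f", m$n_nodes, m$score), "")), collapse = ";")
    }
    expect_equal(sig(mcode_modules(g)), sig(mcode_modules(g2)))
  }
})

test_that("edge-betweenness modularity matches worked examples", {
  g <- two_cliques(4)
  r <- girvan_newman_modularity(g)
  expect_equal(r$Q, 12 / 13 - 0.5, tolerance = 1e-10)
  expect_equal(length(unique(r$partition)), 2)
  # complete graph: no split improves on a single community
  full <- igraph::make_full_graph(6)
  rf <- girvan_newman_modularity(full)
  expect_equal(rf$Q, 0)
  expect_equal(length(unique(rf$partition)), 1)
  # two disconnected triangles: Q = 0.5
  tt <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)),
    directed = FALSE)
  expect_equal(girvan_newman_modularity(tt)$Q, 0.5)
  expect_error(girvan_newman_modularity(igraph::make_empty_graph(3)),
               "edge")
})

test_that("edge-betweenness modularity never exceeds the global optimum", {
  # GN is restricted to its dendrogram, so its Q is bounded by (and on
  # structured graphs equal to) the brute-force maximum over all partitions
  set.seed(23)
  agree <- 0
  for (i in 1:40) {
    g <- igraph::sample_gnp(sample(5:7, 1), 0.45)
    if (igraph::ecount(g) < 1) next
    q_gn <- girvan_newman_modularity(g)$Q
    q_opt <- brute_force_modularity(g)
    expect_lte(q_gn, q_opt + 1e-9)
    if (abs(q_gn - q_opt) < 1e-9) agree <- agree + 1
  }
  expect_gt(agree, 15)  # exact on the majority of small graphs
  # and exact on the canonical two-community graph
  g2 <- two_cliques(4)
  expect_equal(girvan_newman_modularity(g2)$Q, brute_force_modularity(g2),
               tolerance = 1e-10)
})

test_that("hub and connector classification matches the printed examples", {
  m <- data.frame(node = c("h", "c1", "c2", "mid", "low"),
                  degree = c(60, 2, 5, 12, 3),
                  betweenness = c(0.06, 1.00, 0.05, 0.50, 0.01),
                  closeness = c(0.43, 1.00, 0.30, 0.60, 0.50))
  cls <- classify_central(m)
  expect_equal(cls$class, c("hub", "connector", "connector", "none", "none"))
  # hub and connector are mutually exclusive by construction
  expect_false(any(cls$class == "hub" & cls$class == "connector"))
})
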