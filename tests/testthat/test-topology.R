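# Network topology metrics against closed forms and brute-force oracles;
# per-sample induced subgraphs; keystone classification.

triangle_net <- function() {
  structure(list(nodes = c("a", "b", "c"),
                 edges = data.frame(otu_a = c("a", "a", "b"),
                                    otu_b = c("b", "c", "c"),
                                    rho = c(0.9, 0.9, 0.9),
                                    q = c(0, 0, 0)),
                 threshold_used = 0.8, fdr_alpha = 0.05, site = NA_character_),
            class = "coocnet")
}

test_that("closed-form graphs give known topology values", {
  tri <- global_topology(triangle_net())
  expect_equal(tri$node_number, 3)
  expect_equal(tri$edge_number, 3)
  expect_equal(tri$transitivity, 1)
  expect_equal(tri$betweenness, 0)

  # star with 4 leaves: perfectly disassortative
  star <- structure(list(nodes = c("h", "l1", "l2", "l3", "l4"),
                         edges = data.frame(otu_a = "h",
                                            otu_b = paste0("l", 1:4),
                                            rho = rep(0.9, 4), q = rep(0, 4)),
                         threshold_used = 0.8, fdr_alpha = 0.05,
                         site = NA_character_), class = "coocnet")
  expect_equal(global_topology(star)$assortativity, -1, tolerance = 1e-12)

  # path a-b-c: b bridges the single pair, normalized betweenness 1
  path <- structure(list(nodes = c("a", "b", "c"),
                         edges = data.frame(otu_a = c("a", "b"),
                                            otu_b = c("b", "c"),
                                            rho = c(0.9, 0.9), q = c(0, 0)),
                         threshold_used = 0.8, fdr_alpha = 0.05,
                         site = NA_character_), class = "coocnet")
  ks <- identify_keystones(path)
  expect_equal(ks$betweenness[ks$otu == "b"], 1)

  empty <- structure(list(nodes = character(0),
                          edges = triangle_net()$edges[0, ],
                          threshold_used = 0.8, fdr_alpha = 0.05,
                          site = NA_character_), class = "coocnet")
  expect_equal(global_topology(empty)$node_number, 0)
  expect_equal(nrow(identify_keystones(empty)), 0)
})

test_that("topology metrics match brute-force oracles on random graphs", {
  set.seed(123)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    net <- random_net(n, p_edge = runif(1, 0.2, 0.8))
    if (length(net$nodes) < 1) next
    a <- net_adjacency(net)
    topo <- global_topology(net)
    ks <- identify_keystones(net)
    expect_equal(topo$node_number, nrow(a))
    expect_equal(topo$edge_number, sum(a) / 2)
    expect_equal(topo$degree, mean(rowSums(a)), tolerance = 1e-12)
    if (nrow(a) >= 3) {
      expect_equal(topo$betweenness, mean(oracle_betweenness(a)),
                   tolerance = 1e-9)
      expect_equal(ks$betweenness, oracle_betweenness(a), tolerance = 1e-9)
    }
    gt <- oracle_global_transitivity(a)
    if (!is.nan(gt)) expect_equal(topo$transitivity, gt, tolerance = 1e-12)
    oa <- oracle_assortativity(a)
    if (!is.na(oa) && !is.na(topo$assortativity)) {
      expect_equal(topo$assortativity, oa, tolerance = 1e-9)
    }
    expect_equal(ks$closeness, oracle_closeness(a), tolerance = 1e-9)
    expect_equal(ks$degree, unname(rowSums(a)), tolerance = 1e-12)
    lt <- oracle_local_transitivity(a)
    expect_equal(is.na(ks$transitivity), is.nan(lt))
    expect_equal(ks$transitivity[!is.na(ks$transitivity)],
                 lt[!is.nan(lt)], tolerance = 1e-12)
  }
})

test_that("induced subgraph metrics match direct edge enumeration", {
  set.seed(7)
  b <- generate_dataset(small_config(seed = 7, n_sites = 1))
  counts <- filter_otus(b$otu_table)
  corr <- spearman_matrix(counts)
  net <- build_network(corr, 0.6)
  st <- sample_subgraph_topology(net, counts)
  for (s in sample(rownames(counts), 5)) {
    present <- net$nodes[counts[s, net$nodes] > 0]
    in_sub <- net$edges$otu_a %in% present & net$edges$otu_b %in% present
    row <- st[st$sample_id == s, ]
    expect_equal(row$node_number, length(present))
    expect_equal(row$edge_number, sum(in_sub))
  }
  # a sample containing every network OTU reproduces the global summary
  full <- counts
  full[1, net$nodes] <- pmax(full[1, net$nodes], 1L)
  st_full <- sample_subgraph_topology(net, full)
  expect_equal(st_full$edge_number[1], global_topology(net)$edge_number)
  # a sample with none of the network OTUs gives a missing row
  none <- counts
  none[2, ] <- 0L
  none[2, setdiff(colnames(counts), net$nodes)[1]] <- 1L
  st_none <- sample_subgraph_topology(net, none)
  expect_equal(st_none$node_number[2], 0)
  expect_true(is.na(st_none$betweenness[2]))
})

test_that("a subgraph isolating one triangle reports its 3 edges", {
  # graph: triangle a-b-c plus pendant d attached to a
  net <- structure(list(nodes = c("a", "b", "c", "d"),
                        edges = data.frame(otu_a = c("a", "a", "b", "a"),
                                           otu_b = c("b", "c", "c", "d"),
                                           rho = rep(0.9, 4), q = rep(0, 4)),
                        threshold_used = 0.8, fdr_alpha = 0.05,
                        site = NA_character_), class = "coocnet")
  counts <- rbind(s1 = c(a = 1L, b = 1L, c = 1L, d = 0L))
  st <- sample_subgraph_topology(net, counts)
  expect_equal(st$edge_number, 3)
  expect_equal(st$node_number, 3)
})

test_that("keystone flags implement the five strict conditions", {
  # hub-and-clique construction: node passing all five thresholds
  nodes <- c("k", paste0("m", 1:9))
  edges <- rbind(
    data.frame(otu_a = "k", otu_b = paste0("m", 1:7),
               rho = 0.95, q = 0),
    data.frame(otu_a = paste0("m", c(1, 1, 2, 3, 4, 5, 6)),
               otu_b = paste0("m", c(2, 3, 3, 4, 5, 6, 7)),
               rho = 0.9, q = 0),
    data.frame(otu_a = "m8", otu_b = "m9", rho = 0.9, q = 0))
  net <- structure(list(nodes = nodes, edges = edges, threshold_used = 0.8,
                        fdr_alpha = 0.05, site = NA_character_),
                   class = "coocnet")
  ks <- identify_keystones(net)
  k <- ks[ks$otu == "k", ]
  expect_equal(k$degree, 7)
  expect_gt(k$weighted_degree, 6)
  expect_true(k$keystone == (k$degree > 6 & k$weighted_degree > 6 &
                               k$closeness > 0.14 & k$betweenness < 0.05 &
                               k$transitivity > 0.09))
  # degree exactly 6 fails the strict inequality even if all else passes
  ks2 <- identify_keystones(net, thresholds = list(
    degree_min = 7, weighted_degree_min = 0, closeness_min = 0,
    betweenness_max = 1, transitivity_min = 0))
  expect_false(ks2$keystone[ks2$otu == "k"])   # 7 > 7 is false
})
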