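two_cliques <- function(k) {
  a <- matrix(0L, 2L * k, 2L * k)
  a[1:k, 1:k] <- adj_complete(k)
  a[(k + 1):(2 * k), (k + 1):(2 * k)] <- adj_complete(k)
  a[k, k + 1L] <- a[k + 1L, k] <- 1L   # bridge
  a
}

test_that("modularity matches hand values and the formula oracle", {
  g <- graph_from_adj(two_cliques(3L))
  p_one <- structure(list(method = "fast_greedy",
                          labels = stats::setNames(rep(0L, 6L),
                                                   igraph::V(g)$name)),
                     class = "gene_partition")
  expect_equal(graph_modularity(g, p_one), 0)

  p_tri <- p_one
  p_tri$labels[] <- rep(c(0L, 1L), each = 3L)
  expect_equal(graph_modularity(g, p_tri), 5 / 14)  # 2*(3/7 - (7/14)^2)

  set.seed(6)
  a <- adj_random(7L, 0.5)
  g2 <- graph_from_adj(a)
  k <- rowSums(a); m <- sum(a) / 2
  p_single <- p_one
  p_single$labels <- stats::setNames(0:6, igraph::V(g2)$name)
  expect_equal(graph_modularity(g2, p_single), -sum((k / (2 * m))^2))
  labs <- sample(0:2, 7L, TRUE)
  p_rand <- p_one
  p_rand$labels <- stats::setNames(labs, igraph::V(g2)$name)
  expect_equal(graph_modularity(g2, p_rand), oracle_modularity(a, labs))

  g_empty <- graph_from_adj(matrix(0L, 3L, 3L))
  expect_error(graph_modularity(g_empty, p_tri),
               class = "pivcomm_degenerate_error")
})

test_that("all four methods split the two-clique benchmark at the clique boundary", {
  a <- two_cliques(5L)
  g <- graph_from_adj(a)
  for (method in c("fast_greedy", "louvain", "walktrap", "infomap")) {
    p <- detect_communities(g, method, seed = 11L)
    expect_equal(p$n_communities, 2L, info = method)
    expect_equal(unname(p$labels[1:5] == p$labels[1L]), rep(TRUE, 5L))
    expect_equal(unname(p$labels[6:10] == p$labels[6L]), rep(TRUE, 5L))
    expect_false(p$labels[1L] == p$labels[6L])
  }
})

test_that("the clique split maximises modularity (exhaustive check, 6 nodes)", {
  a <- two_cliques(3L)
  g <- graph_from_adj(a)
  best <- max(vapply(all_partitions(6L), function(lab)
    oracle_modularity(a, lab), numeric(1L)))
  p <- detect_communities(g, "fast_greedy", seed = 1L)
  expect_equal(graph_modularity(g, p), best, tolerance = 1e-12)
})

test_that("a single clique is one community; detection is deterministic per seed", {
  g <- graph_from_adj(adj_complete(6L))
  for (method in c("fast_greedy", "louvain", "walktrap", "infomap"))
    expect_equal(detect_communities(g, method, seed = 2L)$n_communities, 1L)

  set.seed(99)
  g2 <- graph_from_adj(adj_random(20L, 0.2))
  for (method in c("louvain", "infomap")) {
    p1 <- detect_communities(g2, method, seed = 7L)
    p2 <- detect_communities(g2, method, seed = 7L)
    expect_identical(p1$labels, p2$labels)
  }
})

test_that("isolated nodes become singletons and edgeless graphs all-singleton", {
  a <- rbind(cbind(adj_complete(3L), 0L), 0L)
  g <- graph_from_adj(a)
  p <- detect_communities(g, "fast_greedy", seed = 1L)
  expect_equal(sum(p$labels == p$labels[[4L]]), 1L)
  p0 <- detect_communities(graph_from_adj(matrix(0L, 4L, 4L)), "louvain")
  expect_equal(p0$n_communities, 4L)
  expect_equal(sort(unique(p0$labels)), 0:3)   # contiguous ids from 0
})

test_that("target_community extracts the right member set", {
  a <- two_cliques(4L)
  g <- graph_from_adj(a)
  p <- detect_communities(g, "walktrap", seed = 1L)
  tc <- target_community(p, "v2")
  expect_true("v2" %in% tc$members)
  expect_setequal(tc$members, paste0("v", 1:4))

  # invariance under community-id relabeling
  p2 <- p
  p2$labels <- stats::setNames(1L - p$labels, names(p$labels))
  expect_setequal(target_community(p2, "v2")$members, tc$members)

  p3 <- detect_communities(graph_from_adj(matrix(0L, 4L, 4L)), "infomap")
  expect_identical(target_community(p3, "v3")$members, "v3")
  expect_error(target_community(p, "nope"), class = "pivcomm_target_error")
})

test_that("the four methods concur on planted data at a core-resolving threshold", {
  sim <- simulate_expression(
    planted_design(n_subjects = 150L, module_genes = 40L, core_genes = 14L,
                   r_core = 0.75, r_module = 0.3), seed = 8L)
  net <- correlation_network(sim$expr)
  g <- hard_threshold(net, 0.5)
  comms <- lapply(c("fast_greedy", "louvain", "walktrap", "infomap"),
                  function(m) target_community(
                    detect_communities(g, m, seed = 3L), "TARGET")$members)
  for (i in 1:3) for (j in (i + 1):4)
    expect_gte(dice(comms[[i]], comms[[j]]), 0.8)
  for (cm in comms) expect_gte(dice(cm, sim$core), 0.8)
})
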