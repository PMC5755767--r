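test_that("target strength per node matches closed forms and the sum oracle", {
  # all similarities equal c: strength per node = c (N-1) / N
  net <- make_net(6L, fill = 0.34)
  expect_equal(target_strength_per_node(net, rownames(net), "g1"),
               0.34 * 5 / 6)
  # pair with s = 0.8 -> 0.4
  net2 <- make_net(3L, pairs = list(list("g1", "g2", 0.8)))
  expect_equal(target_strength_per_node(net2, c("g1", "g2"), "g1"), 0.4)

  set.seed(30)
  w <- matrix(runif(64), 8L, 8L); w <- (w + t(w)) / 2; diag(w) <- 0
  dimnames(w) <- list(paste0("g", 1:8), paste0("g", 1:8))
  st <- c("g1", "g3", "g5", "g8")
  expect_equal(target_strength_per_node(w, st, "g3"),
               sum(w["g3", c("g1", "g5", "g8")]) / 4)

  expect_error(target_strength_per_node(net, c("g2", "g3"), "g1"),
               class = "pivcomm_target_error")
  expect_error(target_strength_per_node(net, "g1", "g1"),
               class = "pivcomm_degenerate_error")
})

test_that("diluting a strong-partner set with weak genes lowers the measure", {
  net <- make_net(8L)
  strong <- paste0("g", 2:4); weak <- paste0("g", 5:8)
  for (s in strong) { net["g1", s] <- net[s, "g1"] <- 0.9 }
  for (s in weak) { net["g1", s] <- net[s, "g1"] <- 0.1 }
  tight <- target_strength_per_node(net, c("g1", strong), "g1")
  diluted <- target_strength_per_node(net, c("g1", strong, weak), "g1")
  expect_lt(diluted, tight)
})

test_that("random-community null is deterministic and matches closed forms", {
  net <- make_net(10L, fill = 0.5)
  # uniform weights: every draw gives the same value, sd = 0
  nl <- random_community_null(net, "g1", size = 4L, n_reps = 50L, seed = 9L)
  expect_equal(nl$mean, 0.5 * 3 / 4)
  expect_equal(nl$sd, 0)

  # pool of exactly size - 1 genes: all draws identical
  nl2 <- random_community_null(net, "g1", size = 4L, n_reps = 20L, seed = 1L,
                               pool = c("g2", "g3", "g4"))
  expect_equal(nl2$sd, 0)

  set.seed(31)
  w <- matrix(runif(100), 10L, 10L); w <- (w + t(w)) / 2; diag(w) <- 0
  dimnames(w) <- list(paste0("g", 1:10), paste0("g", 1:10))
  a <- random_community_null(w, "g1", size = 5L, n_reps = 300L, seed = 4L)
  b <- random_community_null(w, "g1", size = 5L, n_reps = 300L, seed = 4L)
  expect_identical(a, b)
  # law of large numbers: null mean -> (size-1)/size * mean similarity to pool
  big <- random_community_null(w, "g1", size = 5L, n_reps = 5000L, seed = 2L)
  expect_equal(big$mean, 4 / 5 * mean(w["g1", -1L]), tolerance = 0.02)

  expect_error(random_community_null(net, "g1", size = 12L, n_reps = 5L),
               class = "pivcomm_parse_error")
})

test_that("hub tables scale by the maximum strength and sort hubs", {
  s <- c(A = 2, B = 3, C = 1, D = 2.2)
  tab <- hub_table(s, cutoff = 0.70)
  expect_equal(tab$gene[1L], "B")
  expect_equal(tab$scaled_strength[1L], 1)
  expect_setequal(tab$gene, c("B", "D"))          # 2.2/3 = 0.733 > 0.7 > 2/3
  expect_true(all(diff(tab$strength) <= 0))

  # all-equal strengths: every gene is a hub at scaled strength 1
  tab2 <- hub_table(c(x = 1.5, y = 1.5, z = 1.5))
  expect_equal(tab2$scaled_strength, rep(1, 3L))

  net <- make_net(4L, fill = 0.6)
  tab3 <- hub_table(net)
  expect_equal(nrow(tab3), 4L)
  expect_equal(attr(tab3, "cutoff"), 0.70)
})

test_that("hub overlap is the captured fraction", {
  hubs <- hub_table(c(A = 3, B = 2.9, C = 2.8, D = 2.7))
  expect_equal(hub_overlap(hubs, c("A", "B", "C", "D", "E")), 1)
  expect_equal(hub_overlap(hubs, c("X", "Y")), 0)
  expect_equal(hub_overlap(paste0("h", 1:10), paste0("h", 1:7)), 0.7)
})

test_that("on planted data the detected core outruns the random null", {
  sim <- simulate_expression(
    planted_design(n_subjects = 120L, module_genes = 30L, core_genes = 10L,
                   r_core = 0.7, r_module = 0.3), seed = 14L)
  net <- correlation_network(sim$expr)
  comm <- target_community(
    detect_communities(hard_threshold(net, 0.5), "fast_greedy", seed = 2L),
    "TARGET")
  st <- target_strength_per_node(net, comm, "TARGET")
  nl <- random_community_null(net, "TARGET", size = length(comm$members),
                              n_reps = 500L, seed = 6L)
  expect_gt(st, nl$mean + 2 * nl$sd)
})
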