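# graph: a 3-path {g1-g2-g3}, a 4-star {h1..h4}, one clique {c1..c4}, all
# disconnected from each other, plus an isolated gene
compound_graph <- function() {
  blocks <- list(adj_path(3L), adj_star(4L), adj_complete(4L), matrix(0L, 1L, 1L))
  n <- sum(vapply(blocks, nrow, integer(1L)))
  a <- matrix(0L, n, n)
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    a[idx, idx] <- b
    at <- at + nrow(b)
  }
  graph_from_adj(a, names = c("g1", "g2", "g3", "h1", "h2", "h3", "h4",
                              "c1", "c2", "c3", "c4", "iso"))
}

test_that("PMI reproduces the hand-computed cases", {
  g <- compound_graph()
  # clique community: no intermediaries anywhere, PMI = 0
  expect_equal(pmi(g, c("c1", "c2", "c3", "c4")), 0)
  # path on 3: mean degree 4/3, mean betweenness 1/3, D = 2, N = 3
  expect_equal(pmi(g, c("g1", "g2", "g3")), 2 / 27)
  # star on 4: mean degree 1.5, mean betweenness 0.75, D = 2, N = 4
  expect_equal(pmi(g, c("h1", "h2", "h3", "h4")), 0.140625)
})

test_that("PMI signals degenerate communities and is relabel-invariant", {
  g <- compound_graph()
  expect_error(pmi(g, "g1"), class = "pivcomm_degenerate_error")
  expect_error(pmi(g, c("g1", "iso")), class = "pivcomm_degenerate_error")
  expect_error(pmi(g, c("g1", "nope")), class = "pivcomm_parse_error")

  set.seed(10)
  a <- adj_random(9L, 0.4)
  g1 <- graph_from_adj(a)
  perm <- sample(9L)
  g2 <- graph_from_adj(a[perm, perm], names = paste0("v", perm))
  members <- c("v1", "v2", "v3", "v4", "v5")
  if (igraph::ecount(igraph::induced_subgraph(g1, members)) > 0)
    expect_equal(pmi(g1, members), pmi(g2, members))
})

test_that("full-graph and induced-subgraph PMI variants differ as documented", {
  # P4 with community = middle two nodes: induced subgraph is one edge
  g <- graph_from_adj(adj_path(4L))
  members <- c("v2", "v3")
  expect_equal(pmi(g, members), 0)  # induced: a 2-clique, b = 0
  # full graph: degrees (2,2), betweenness (2,2), D(induced) = 1, N = 2
  expect_equal(pmi(g, members, subgraph = FALSE), (2 * 2) / (1 * 2))
})

test_that("pmi_scan flags degenerate and whole-graph records", {
  net <- make_net(5L, pairs = list(
    list("g1", "g2", 0.9), list("g2", "g3", 0.85), list("g1", "g3", 0.8),
    list("g3", "g4", 0.6), list("g4", "g5", 0.55)))
  one <- pmi_scan(net, 0.7, methods = "fast_greedy", target = "g1")
  expect_equal(nrow(one), 1L)
  expect_true(one$valid)
  expect_equal(one$size, 3L)
  expect_equal(one$pmi, 0)          # triangle community is a clique

  empty <- pmi_scan(net, 0.95, methods = "fast_greedy", target = "g1")
  expect_false(empty$valid)         # singleton community below min_size
  expect_true(is.na(empty$pmi))

  whole <- pmi_scan(net, 0.5, methods = "fast_greedy", target = "g1")
  if (whole$size == 5L) expect_false(whole$valid)  # whole-graph "community"

  multi <- pmi_scan(net, c(0.7, 0.95), target = "g1", seed = 2L)
  expect_equal(nrow(multi), 2L * 4L)
  expect_error(pmi_scan(net, 0.7, target = "nope"),
               class = "pivcomm_target_error")
})

test_that("bootstrap PMI quantiles are deterministic, ordered, and degenerate at |r| = 1", {
  sim <- simulate_expression(
    planted_design(n_subjects = 50L, module_genes = 12L, core_genes = 5L,
                   r_core = 0.8, r_module = 0.3), seed = 2L)
  b1 <- bootstrap_pmi(sim$expr, 0.5, "fast_greedy", "TARGET",
                      n_boot = 30L, seed = 5L)
  b2 <- bootstrap_pmi(sim$expr, 0.5, "fast_greedy", "TARGET",
                      n_boot = 30L, seed = 5L)
  expect_identical(b1, b2)
  expect_lte(b1$q25, b1$median)
  expect_lte(b1$median, b1$q75)

  # exact-multiple rows: |r| = 1 within the core no matter the resample
  set.seed(1)
  base <- rnorm(30)
  m <- rbind(TARGET = base, gA = 2 * base, gB = -base + 0,
             gC = rnorm(30), gD = rnorm(30), gE = rnorm(30))
  colnames(m) <- paste0("s", 1:30)
  b <- bootstrap_pmi(m, 0.9, "fast_greedy", "TARGET", n_boot = 25L, seed = 3L)
  expect_equal(b$q25, b$q75)        # clique community every time: PMI 0
  expect_equal(b$median, 0)
})

test_that("weighted trend fit matches lm() and flags an inflated point", {
  t <- c(0.40, 0.45, 0.50, 0.55)
  y <- c(0.2, 0.35, 0.38, 0.52)
  s <- c(0.05, 0.02, 0.03, 0.08)
  fit <- pmi_trend_test(t, y, s)
  ref <- lm(y ~ t, weights = 1 / s^2)
  expect_equal(unname(fit$intercept), unname(coef(ref)[1L]))
  expect_equal(unname(fit$slope), unname(coef(ref)[2L]))

  # exactly collinear points: chi2 ~ 0, nothing flagged
  yc <- 0.1 + 0.5 * t
  fitc <- pmi_trend_test(t, yc, rep(0.01, 4L))
  expect_lt(fitc$chi2_reduced, 1e-10)
  expect_false(any(fitc$excess))

  # one point hoisted 5 sigma above the line gets flagged
  t5 <- seq(0.30, 0.60, 0.05)
  y5 <- 0.1 + 0.5 * t5
  y5[4L] <- y5[4L] + 5 * 0.01
  fit5 <- pmi_trend_test(t5, y5, rep(0.01, length(t5)))
  expect_true(fit5$excess[4L])

  expect_error(pmi_trend_test(t[1:2], y[1:2], s[1:2]),
               class = "pivcomm_degenerate_error")
})
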