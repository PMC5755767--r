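#' Pivotal Module Index of a target community
#'
#' The PMI condenses the target community's topology into
#' `PMI = (k_tc * b_tc) / (D_tc * N_tc)`: mean degree times mean betweenness
#' of the community's nodes, divided by community diameter times community
#' size. Intense connections (degree) and strategic connections (betweenness)
#' push the index up; spread-out (large diameter) or inflated (large N)
#' communities are penalised. A community that induces a complete subgraph
#' has zero betweenness everywhere, hence PMI = 0.
#'
#' By default all four ingredients are measured on the subgraph induced by
#' the community, so the index reflects internal cohesion; with
#' `subgraph = FALSE` degree and betweenness are taken from the full
#' thresholded network instead (diameter stays within the community, as the
#' community's own extent).
#'
#' @param g thresholded graph containing the community's nodes.
#' @param community a `target_community` or character vector of gene ids
#'   (at least 2).
#' @param subgraph logical; measure node properties on the induced subgraph
#'   (default) or on the whole graph.
#' @return single non-negative number.
#' @export
pmi <- function(g, community, subgraph = TRUE) {
  members <- community_members(community)
  if (length(members) < 2L)
    abort("PMI is undefined for communities of fewer than 2 genes",
          "pivcomm_degenerate_error")
  if (!all(members %in% igraph::V(g)$name))
    abort("community contains genes absent from the graph",
          "pivcomm_parse_error")
  sub <- igraph::induced_subgraph(g, members)
  d_tc <- graph_diameter(sub)
  if (d_tc == 0)
    abort("community diameter is zero (edgeless induced subgraph); PMI undefined",
          "pivcomm_degenerate_error")
  if (subgraph) {
    k_tc <- mean(node_degree(sub))
    b_tc <- mean(node_betweenness(sub))
  } else {
    k_tc <- mean(node_degree(g)[members])
    b_tc <- mean(node_betweenness(g)[members])
  }
  (k_tc * b_tc) / (d_tc * length(members))
}

#' Scan the Pivotal Module Index over thresholds and methods
#'
#' For every threshold in the grid and every detection method: threshold the
#' network, partition it, extract the community containing the target gene,
#' and compute its PMI. Communities smaller than `min_size` (default 3, the
#' smallest set that still deserves the name "community") are recorded but
#' flagged invalid with `NA` PMI, as are degenerate cases (edgeless induced
#' subgraph).
#'
#' A record is only `valid` when the community is a *proper* subgraph:
#' `min_size <= size < n_nodes`. A detector that returns the entire vertex
#' set as one block has found no community structure at that threshold, so
#' such records keep their PMI for inspection but are excluded from ranking.
#'
#' @param net `correlation_network` matrix.
#' @param grid numeric thresholds, see [threshold_grid()].
#' @param methods subset of `c("fast_greedy","louvain","walktrap","infomap")`.
#' @param target target gene id.
#' @param min_size minimum community size for a valid PMI record.
#' @param seed detection seed (one seed, every detection call is seeded with
#'   it, so identical graphs give identical partitions).
#' @param subgraph see [pmi()].
#' @return data.frame with columns `threshold`, `method`, `size`, `pmi`,
#'   `valid`.
#' @export
pmi_scan <- function(net, grid = threshold_grid(), methods = pivcomm_methods,
                     target, min_size = 3L, seed = 1L, subgraph = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!target %in% rownames(net))
    abort(paste0("target gene '", target, "' not in network"),
          "pivcomm_target_error")
  rows <- list()
  for (t in grid) {
    g <- hard_threshold(net, t)
    for (method in methods) {
      p <- detect_communities(g, method, seed = seed)
      tc <- target_community(p, target)
      n <- length(tc$members)
      value <- NA_real_
      ok <- n >= min_size && n < igraph::vcount(g)
      if (n >= min_size) {
        value <- tryCatch(pmi(g, tc, subgraph = subgraph),
                          pivcomm_degenerate_error = function(e) NA_real_)
        ok <- ok && is.finite(value)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(threshold = t, method = method, size = n,
                   pmi = value, valid = ok)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# One bootstrap pass: resample subjects with replacement, rebuild the
# |Pearson| network, and recompute community size and PMI for every
# (threshold, method) cell. Returns 3-d arrays [rep, threshold, method].
bootstrap_scan <- function(m, grid, methods, target, n_boot, seed,
                           min_size = 3L, subgraph = TRUE) {
  nt <- length(grid); nm <- length(methods)
  pmi_arr <- array(NA_real_, dim = c(n_boot, nt, nm),
                   dimnames = list(NULL, format(grid), methods))
  size_arr <- pmi_arr
  cols <- with_seed(seed, matrix(sample.int(ncol(m), n_boot * ncol(m),
                                            replace = TRUE),
                                 nrow = n_boot))
  for (r in seq_len(n_boot)) {
    mb <- m[, cols[r, ], drop = FALSE]
    colnames(mb) <- sprintf("bs%03d", seq_len(ncol(mb)))
    net <- tryCatch(
      suppressWarnings(correlation_network(mb)),
      pivcomm_error = function(e) NULL)
    if (is.null(net) || !target %in% rownames(net)) next
    for (i in seq_len(nt)) {
      g <- hard_threshold(net, grid[i])
      for (j in seq_len(nm)) {
        p <- detect_communities(g, methods[j], seed = seed)
        tc <- target_community(p, target)
        size_arr[r, i, j] <- length(tc$members)
        if (length(tc$members) >= min_size &&
            length(tc$members) < igraph::vcount(g)) {
          pmi_arr[r, i, j] <- tryCatch(pmi(g, tc, subgraph = subgraph),
                                       pivcomm_degenerate_error =
                                         function(e) NA_real_)
        }
      }
    }
  }
  list(pmi = pmi_arr, size = size_arr)
}

#' Bootstrap error band for the PMI at one threshold
#'
#' Resamples subjects (columns) with replacement `n_boot` times; each
#' replicate rebuilds the similarity network, re-thresholds, re-detects
#' communities and recomputes the target community's PMI. Replicates whose
#' target community falls below `min_size` (or is otherwise degenerate)
#' contribute no PMI. The spread between the 25th and 75th percentiles of
#' the replicate distribution is the statistical error attached to the index.
#'
#' @param m expression matrix (genes x subjects).
#' @param t threshold.
#' @param method detection method.
#' @param target target gene id.
#' @param n_boot number of resamples (>= 2), default 1000.
#' @param seed RNG seed; results are reproducible per seed.
#' @param min_size,subgraph see [pmi_scan()].
#' @return list with `q25`, `q75`, `median`, `values` (replicate PMIs, `NA`
#'   for degenerate replicates) and `n_valid`.
#' @export
bootstrap_pmi <- function(m, t, method = pivcomm_methods, target,
                          n_boot = 1000L, seed = 1L, min_size = 3L,
                          subgraph = TRUE) {
  method <- match.arg(method)
  if (n_boot < 2L) abort("n_boot must be >= 2", "pivcomm_parse_error")
  arr <- bootstrap_scan(m, grid = t, methods = method, target = target,
                        n_boot = n_boot, seed = seed, min_size = min_size,
                        subgraph = subgraph)$pmi
  vals <- arr[, 1L, 1L]
  ok <- vals[is.finite(vals)]
  if (!length(ok))
    abort("every bootstrap replicate was degenerate", "pivcomm_degenerate_error")
  qs <- stats::quantile(ok, c(0.25, 0.5, 0.75), names = FALSE)
  list(q25 = qs[1L], median = qs[2L], q75 = qs[3L],
       values = vals, n_valid = length(ok))
}

#' Weighted linear trend test for PMI excess
#'
#' Fits a straight line to the cross-method average PMI as a function of
#' threshold by weighted least squares with known per-point errors
#' (weights `1/sigma^2`), reports the reduced chi-square of the fit, the
#' pointwise 95% confidence band of the fitted line, and flags thresholds
#' whose observed PMI lies above the upper band -- i.e. thresholds that stand
#' significantly above the overall linear trend and therefore single out a
#' preferred community.
#'
#' @param threshold numeric vector of thresholds (>= 3 points).
#' @param pmi observed (average) PMI per threshold.
#' @param sigma per-point standard errors; typically half the bootstrap
#'   interquartile range. Nonpositive values are floored at a small fraction
#'   of the largest error (all-zero errors fall back to unit weights).
#' @return object of class `pmi_trend`: list with `slope`, `intercept`,
#'   `chi2_reduced`, `band` (data.frame `threshold`, `fit`, `lower`,
#'   `upper`), `excess` (logical per threshold).
#' @export
pmi_trend_test <- function(threshold, pmi, sigma) {
  keep <- is.finite(threshold) & is.finite(pmi) & is.finite(sigma)
  threshold <- threshold[keep]; pmi <- pmi[keep]; sigma <- sigma[keep]
  if (length(pmi) < 3L)
    abort("trend test needs at least 3 finite points", "pivcomm_degenerate_error")
  if (all(sigma <= 0)) sigma <- rep(1, length(sigma))
  sigma <- pmax(sigma, 1e-6 * max(sigma))
  w <- 1 / sigma^2
  X <- cbind(1, threshold)
  xtwx <- crossprod(X, w * X)
  beta <- solve(xtwx, crossprod(X, w * pmi))
  fit <- drop(X %*% beta)
  chi2 <- sum(((pmi - fit) / sigma)^2)
  covb <- solve(xtwx)
  se_fit <- sqrt(rowSums((X %*% covb) * X))
  upper <- fit + 1.96 * se_fit
  lower <- fit - 1.96 * se_fit
  structure(list(slope = beta[2L], intercept = beta[1L],
                 chi2_reduced = chi2 / (length(pmi) - 2L),
                 band = data.frame(threshold = threshold, fit = fit,
                                   lower = lower, upper = upper),
                 excess = pmi > upper),
            class = "pmi_trend")
}

#' @export
print.pmi_trend <- function(x, ...) {
  cat(sprintf("PMI linear trend: slope %.4g, intercept %.4g, reduced chi2 %.3g\n",
              x$slope, x$intercept, x$chi2_reduced))
  if (any(x$excess))
    cat("thresholds above the 95% band:",
        paste(format(x$band$threshold[x$excess]), collapse = ", "), "\n")
  invisible(x)
}
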