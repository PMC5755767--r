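#' Betweenness-based Shannon entropy of a graph
#'
#' Measures the information content of a graph's shortest-path structure.
#' The betweenness vector `b` is normalised to a probability mass
#' `p_i = b_i / sum(b)` and fed into Shannon's formula
#' `H = -sum_i p_i log2 p_i` (with `0 log 0 := 0`); the result is divided by
#' the number of nodes so that networks and communities of different sizes
#' are comparable. A graph whose betweenness is concentrated on few nodes is
#' low-entropy; one whose shortest paths are spread over many intermediaries
#' is high-entropy. All-zero betweenness (e.g. a complete graph, where every
#' pair is adjacent) gives entropy 0 by convention.
#'
#' `normalize = FALSE` evaluates Shannon's sum on the raw betweenness values
#' instead (only terms with `b_i > 0` enter). That variant is not a proper
#' entropy -- it can go negative and grows with graph size -- and is provided
#' for comparison only.
#'
#' @param g undirected graph.
#' @param normalize normalise betweenness to a probability mass first
#'   (default `TRUE`).
#' @return entropy in bits per node.
#' @export
betweenness_entropy <- function(g, normalize = TRUE) {
  n <- igraph::vcount(g)
  if (n == 0L)
    abort("empty graph has no entropy", "pivcomm_degenerate_error")
  b <- node_betweenness(g)
  tot <- sum(b)
  if (tot == 0) return(0)
  x <- if (normalize) b / tot else b
  x <- x[x > 0]
  -sum(x * log2(x)) / n
}

#' Entropy-versus-threshold scan
#'
#' For every threshold: the per-node betweenness entropy of the whole
#' thresholded network, and of the subgraph induced by the target gene's
#' community (detected with `method`). The threshold at which both curves
#' peak is the most informative one and should corroborate the PMI-selected
#' threshold.
#'
#' @inheritParams pmi_scan
#' @param method single detection method used to extract the target
#'   community (default `"fast_greedy"`).
#' @return data.frame with columns `threshold`, `h_network`, `h_community`,
#'   `n_network`, `n_community`.
#' @export
entropy_scan <- function(net, grid = threshold_grid(), target,
                         method = "fast_greedy", seed = 1L) {
  method <- match.arg(method, pivcomm_methods)
  if (!target %in% rownames(net))
    abort(paste0("target gene '", target, "' not in network"),
          "pivcomm_target_error")
  rows <- lapply(grid, function(t) {
    g <- hard_threshold(net, t)
    p <- detect_communities(g, method, seed = seed)
    tc <- target_community(p, target)
    sub <- igraph::induced_subgraph(g, tc$members)
    data.frame(threshold = t,
               h_network = betweenness_entropy(g),
               h_community = betweenness_entropy(sub),
               n_network = igraph::vcount(g),
               n_community = length(tc$members))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
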