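#' Node-level topological properties
#'
#' Thin, consistently named wrappers around the graph backend, fixed to the
#' conventions used throughout the threshold scan: undirected graphs,
#' Freeman (unordered-pair, endpoint-excluded, unnormalised) betweenness, and
#' finite-distance conventions on disconnected graphs.
#'
#' @param g an undirected [igraph::graph], typically from [hard_threshold()].
#' @return `node_degree`, `node_betweenness`, `node_eccentricity`: named
#'   numeric vector over vertices. `geodesic_matrix`: symmetric matrix of
#'   shortest-path lengths (`Inf` between components). `graph_diameter`:
#'   single number, the largest *finite* geodesic (0 for an edgeless graph).
#' @name topology
NULL

#' @rdname topology
#' @export
node_degree <- function(g) igraph::degree(g)

#' @rdname topology
#' @export
node_betweenness <- function(g) {
  igraph::betweenness(g, directed = FALSE, normalized = FALSE)
}

#' @rdname topology
#' @export
geodesic_matrix <- function(g) igraph::distances(g)

#' @rdname topology
#' @export
graph_diameter <- function(g) {
  if (igraph::vcount(g) == 0L)
    abort("empty graph has no diameter", "pivcomm_degenerate_error")
  if (igraph::ecount(g) == 0L) return(0)
  igraph::diameter(g, unconnected = TRUE)
}

#' @rdname topology
#' @export
node_eccentricity <- function(g) {
  if (igraph::vcount(g) == 0L)
    abort("empty graph has no eccentricity", "pivcomm_degenerate_error")
  # igraph restricts to reachable vertices, so each node's eccentricity is
  # taken within its own component and isolated nodes get 0
  igraph::eccentricity(g)
}

#' Node strength in the weighted similarity network
#'
#' Strength is the weighted analogue of degree: the sum of a gene's
#' similarity weights to every other gene, `sum_j s_ij`.
#'
#' @param net `correlation_network` matrix (zero diagonal).
#' @return named numeric vector of strengths.
#' @export
node_strength <- function(net) rowSums(unclass(net))

#' Topology-versus-threshold profile
#'
#' Summarises each thresholded graph by its mean degree, mean betweenness,
#' diameter and mean eccentricity (plus node/edge counts). Averages run over
#' all vertices including isolated ones, so profiles remain comparable across
#' thresholds where the graph fragments. The rise-then-decay of these curves
#' over the grid delimits the threshold range where community structure is
#' expressed.
#'
#' @param net `correlation_network` matrix.
#' @param grid numeric vector of thresholds, see [threshold_grid()].
#' @return data.frame with one row per threshold: `threshold`, `n_nodes`,
#'   `n_edges`, `mean_degree`, `mean_betweenness`, `diameter`,
#'   `mean_eccentricity`.
#' @export
topology_profile <- function(net, grid = threshold_grid()) {
  rows <- lapply(grid, function(t) {
    g <- hard_threshold(net, t)
    data.frame(threshold = t,
               n_nodes = igraph::vcount(g),
               n_edges = igraph::ecount(g),
               mean_degree = mean(node_degree(g)),
               mean_betweenness = mean(node_betweenness(g)),
               diameter = graph_diameter(g),
               mean_eccentricity = mean(node_eccentricity(g)))
  })
  do.call(rbind, rows)
}

#' Select the threshold range where community structure is expressed
#'
#' Mean degree decays monotonically as the threshold rises, but mean
#' betweenness, diameter and mean eccentricity rise and then collapse:
#' below the interesting range the graph is a noisy near-complete blob,
#' above it the graph shatters and the properties fall to zero. The
#' community search is therefore restricted to the range spanned by the
#' argmax thresholds of those three non-monotonic properties, widened by
#' one grid step on each side.
#'
#' @param profile a [topology_profile()] data.frame.
#' @return the thresholds of `profile$threshold` inside the selected range.
#' @export
select_threshold_range <- function(profile) {
  grid <- profile$threshold
  if (length(grid) < 2L) return(grid)
  peaks <- c(grid[which.max(profile$mean_betweenness)],
             grid[which.max(profile$diameter)],
             grid[which.max(profile$mean_eccentricity)])
  step <- max(diff(grid))
  grid[grid >= min(peaks) - step - 1e-9 & grid <= max(peaks) + step + 1e-9]
}
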