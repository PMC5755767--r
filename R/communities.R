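pivcomm_methods <- c("fast_greedy", "louvain", "walktrap", "infomap")

#' Partition a thresholded graph into gene communities
#'
#' Runs one of four standard community detection algorithms: two modularity
#' optimisers (`fast_greedy`, `louvain`), a random-walk agglomerative method
#' (`walktrap`), and the map-equation method (`infomap`, best of
#' `infomap_trials` runs). Dendrogram-producing methods are cut at maximum
#' modularity. Results are deterministic given `(graph, method, seed)`: the
#' RNG is seeded locally and the caller's RNG state is restored afterwards.
#' Isolated nodes always end up in singleton communities; an edgeless graph
#' yields the all-singleton partition without invoking the backend.
#'
#' @param g undirected graph from [hard_threshold()].
#' @param method one of `"fast_greedy"`, `"louvain"`, `"walktrap"`,
#'   `"infomap"`.
#' @param seed integer seed for the stochastic methods.
#' @param infomap_trials number of infomap attempts; the best (shortest
#'   description length) is kept.
#' @return object of class `gene_partition`: list with `method`, `labels`
#'   (named integer vector, community ids contiguous from 0), `threshold`,
#'   `seed`, `n_communities`.
#' @export
detect_communities <- function(g, method = pivcomm_methods, seed = 1L,
                               infomap_trials = 10L) {
  method <- match.arg(method)
  if (igraph::ecount(g) == 0L) {
    memb <- seq_len(igraph::vcount(g))
  } else {
    comm <- with_seed(seed, switch(method,
      fast_greedy = igraph::cluster_fast_greedy(g),
      louvain     = igraph::cluster_louvain(g),
      walktrap    = igraph::cluster_walktrap(g),
      infomap     = igraph::cluster_infomap(g, nb.trials = infomap_trials)))
    if (method %in% c("fast_greedy", "walktrap")) {
      # cut the agglomerative dendrogram at its max-modularity step ourselves:
      # the backend's stored membership can miss ties/fp-degenerate optima
      j <- which.max(comm$modularity)            # state after j - 1 merges
      memb <- igraph::cut_at(comm, no = igraph::vcount(g) - (j - 1L))
    } else {
      memb <- igraph::membership(comm)
    }
  }
  labels <- as.integer(factor(memb, levels = unique(memb))) - 1L
  names(labels) <- igraph::V(g)$name
  structure(list(method = method, labels = labels,
                 threshold = igraph::graph_attr(g, "threshold"),
                 seed = as.integer(seed),
                 n_communities = length(unique(labels))),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("gene_partition: %s, %d genes in %d communities (t = %s)\n",
              x$method, length(x$labels), x$n_communities,
              format(x$threshold %||% NA)))
  invisible(x)
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` where `e_c` is the number of edges
#' inside community c, `d_c` the total degree of its nodes and `m` the edge
#' count. Q = 0 for the one-community partition; good partitions of modular
#' graphs have Q well above 0.
#'
#' @param g undirected graph with at least one edge.
#' @param p `gene_partition` covering all vertices of `g`.
#' @return modularity value.
#' @export
graph_modularity <- function(g, p) {
  if (igraph::ecount(g) == 0L)
    abort("modularity is undefined on an edgeless graph",
          "pivcomm_degenerate_error")
  labels <- p$labels[igraph::V(g)$name]
  if (anyNA(labels))
    abort("partition does not cover every vertex", "pivcomm_parse_error")
  igraph::modularity(g, labels + 1L)
}

#' Extract the community containing the target gene
#'
#' @param p `gene_partition`.
#' @param target gene identifier.
#' @return object of class `target_community`: list with `target`, `members`
#'   (character vector including the target), `threshold`, `method`.
#' @export
target_community <- function(p, target) {
  if (!target %in% names(p$labels))
    abort(paste0("target gene '", target, "' not in partition"),
          "pivcomm_target_error")
  members <- names(p$labels)[p$labels == p$labels[[target]]]
  structure(list(target = target, members = members,
                 threshold = p$threshold, method = p$method),
            class = "target_community")
}

#' @export
print.target_community <- function(x, ...) {
  cat(sprintf("target_community of %s: %d genes (%s, t = %s)\n",
              x$target, length(x$members), x$method,
              format(x$threshold %||% NA)))
  invisible(x)
}

community_members <- function(x) {
  if (inherits(x, "target_community")) x$members else as.character(x)
}
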