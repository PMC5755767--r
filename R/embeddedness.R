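#' Strength per node of the target gene within a gene set
#'
#' The target's summed similarity to the other members of the set, divided
#' by the set size: `sum_{j in set, j != target} s_{target,j} / |set|`.
#' Computed on the unthresholded weighted network, so it reflects the actual
#' correlation mass tying the target to the set. Comparing this quantity for
#' the whole module, the detected community, and random same-size communities
#' measures how embedded the target is in its community.
#'
#' @param net `correlation_network` matrix.
#' @param gene_set character vector (or `target_community`) containing the
#'   target, at least 2 genes.
#' @param target target gene id.
#' @return strength per node (single number).
#' @export
target_strength_per_node <- function(net, gene_set, target) {
  members <- unique(community_members(gene_set))
  if (!target %in% members)
    abort(paste0("target '", target, "' is not in the gene set"),
          "pivcomm_target_error")
  if (length(members) < 2L)
    abort("gene set must contain at least 2 genes", "pivcomm_degenerate_error")
  if (!all(members %in% rownames(net)))
    abort("gene set contains genes absent from the network",
          "pivcomm_parse_error")
  others <- setdiff(members, target)
  sum(unclass(net)[target, others]) / length(members)
}

#' Random-community null for the target's strength per node
#'
#' Draws `n_reps` random communities of the same size as the detected one --
#' each consisting of the target plus `size - 1` genes sampled without
#' replacement from `pool` -- and computes the target's strength per node in
#' each. The detected community is convincingly special only when its
#' strength per node exceeds this null by a comfortable margin.
#'
#' @param net `correlation_network` matrix.
#' @param target target gene id.
#' @param size community size (target included), >= 2.
#' @param n_reps number of random communities, default 1000.
#' @param seed RNG seed.
#' @param pool genes to draw from; default all network genes except the
#'   target.
#' @return list with `mean`, `sd`, `samples` (vector of length `n_reps`) and
#'   `n_reps`.
#' @export
random_community_null <- function(net, target, size, n_reps = 1000L,
                                  seed = 1L, pool = NULL) {
  pool <- setdiff(pool %||% rownames(net), target)
  if (size < 2L) abort("size must be >= 2", "pivcomm_parse_error")
  if (length(pool) < size - 1L)
    abort("pool is smaller than size - 1", "pivcomm_parse_error")
  samples <- with_seed(seed, vapply(seq_len(n_reps), function(r) {
    picked <- sample(pool, size - 1L)
    target_strength_per_node(net, c(target, picked), target)
  }, numeric(1L)))
  list(mean = mean(samples), sd = stats::sd(samples),
       samples = samples, n_reps = as.integer(n_reps))
}

#' Hub genes of a weighted network
#'
#' A gene's scaled strength is its strength divided by the maximum strength
#' in the network, so the strongest gene scores exactly 1. Genes with scaled
#' strength above `cutoff` (default 0.70) are hubs.
#'
#' @param x a `correlation_network` matrix, or a named numeric vector of
#'   precomputed strengths.
#' @param cutoff scaled-strength cutoff for hub status.
#' @return data.frame of hub rows (`gene`, `strength`, `scaled_strength`),
#'   sorted by decreasing strength, with attributes `cutoff` and
#'   `all_strengths`.
#' @export
hub_table <- function(x, cutoff = 0.70) {
  s <- if (is.matrix(x)) node_strength(x) else x
  if (!length(s) || is.null(names(s)))
    abort("need a nonempty named strength vector or network",
          "pivcomm_parse_error")
  scaled <- s / max(s)
  keep <- scaled > cutoff
  out <- data.frame(gene = names(s)[keep], strength = unname(s[keep]),
                    scaled_strength = unname(scaled[keep]))
  out <- out[order(-out$strength), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "all_strengths") <- s
  out
}

#' Fraction of hub genes captured by a community
#'
#' @param hubs a [hub_table()] result (or character vector of hub gene ids).
#' @param community character vector (or `target_community`).
#' @return `|hubs intersect community| / |hubs|`.
#' @export
hub_overlap <- function(hubs, community) {
  hub_genes <- if (is.data.frame(hubs)) hubs$gene else as.character(hubs)
  if (!length(hub_genes))
    abort("hub set is empty", "pivcomm_degenerate_error")
  members <- community_members(community)
  length(intersect(hub_genes, members)) / length(hub_genes)
}
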