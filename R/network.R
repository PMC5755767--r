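#' Absolute-Pearson co-expression network
#'
#' Builds the weighted similarity network over genes: `s_ij = |cor(x_i, x_j)|`
#' across subjects, where `x_i` is gene i's expression profile. The sign of
#' the correlation is discarded -- only the strength of co-expression matters
#' for module structure. The diagonal is set to 0 (self-similarity carries no
#' graph structure).
#'
#' @param m expression matrix (genes x subjects), see [as_expression_matrix()].
#' @param on_zero_variance what to do with genes whose expression is constant
#'   across subjects (Pearson correlation undefined): `"drop"` removes them
#'   with a warning naming them, `"error"` aborts naming the first offender.
#' @return symmetric numeric matrix of class `correlation_network` with
#'   entries in `[0, 1]` and zero diagonal.
#' @export
correlation_network <- function(m, on_zero_variance = c("drop", "error")) {
  on_zero_variance <- match.arg(on_zero_variance)
  as_expression_matrix(m)
  if (ncol(m) < 3L)
    abort("need at least 3 subjects for a meaningful correlation",
          "pivcomm_degenerate_error")
  v <- apply(m, 1L, stats::var)
  flat <- rownames(m)[v == 0]
  if (length(flat)) {
    if (on_zero_variance == "error")
      abort(paste0("zero-variance gene(s): ", paste(flat, collapse = ", ")),
            "pivcomm_degenerate_error")
    warning("dropping zero-variance gene(s): ", paste(flat, collapse = ", "))
    m <- m[setdiff(rownames(m), flat), , drop = FALSE]
    if (nrow(m) < 3L)
      abort("fewer than 3 genes remain after dropping constant rows",
            "pivcomm_degenerate_error")
  }
  s <- abs(stats::cor(t(m)))
  s[s > 1] <- 1   # guard tiny fp overshoot
  diag(s) <- 0
  class(s) <- c("correlation_network", class(s))
  s
}

#' Hard-threshold a similarity network into an unweighted graph
#'
#' Applies the step function: genes i and j are connected iff
#' `s_ij >= t`. Ties at exactly `t` are edges. Isolated nodes are retained,
#' so the vertex set is identical across the whole threshold grid -- community
#' sizes and per-node entropy normalisations stay comparable.
#'
#' @param net `correlation_network` matrix.
#' @param t threshold in `[0, 1]`.
#' @return an undirected simple [igraph::graph] with gene names as vertex
#'   names and graph attribute `threshold`.
#' @export
hard_threshold <- function(net, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
    abort("threshold t must be a single number in [0, 1]",
          "pivcomm_parse_error")
  a <- (unclass(net) >= t) * 1L
  diag(a) <- 0L
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           diag = FALSE)
  igraph::graph_attr(g, "threshold") <- t
  g
}

#' Threshold grid constructor
#'
#' Strictly increasing thresholds in `[0, 1]`. The default grid 0.30--0.60 in
#' steps of 0.01 covers the range where module structure typically emerges in
#' an |Pearson| network while staying below the decay regime where the graph
#' shatters.
#'
#' @param from,to,by grid limits and step.
#' @return numeric vector of thresholds.
#' @export
threshold_grid <- function(from = 0.30, to = 0.60, by = 0.01) {
  g <- round(seq(from, to, by = by), 10L)
  if (any(g < 0) || any(g > 1) || is.unsorted(g, strictly = TRUE))
    abort("grid must be strictly increasing within [0, 1]",
          "pivcomm_parse_error")
  g
}
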