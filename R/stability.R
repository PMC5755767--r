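#' Dice overlap of two gene sets
#'
#' `Dice = 2 |A intersect B| / (|A| + |B|)`, in `[0, 1]`: 1 means identical
#' sets, 0 means no gene in common. Duplicated ids within a set are counted
#' once.
#'
#' @param a,b character vectors of gene ids; not both empty.
#' @return Dice coefficient.
#' @export
dice <- function(a, b) {
  a <- unique(community_members(a)); b <- unique(community_members(b))
  if (length(a) + length(b) == 0L)
    abort("Dice is undefined for two empty sets", "pivcomm_degenerate_error")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Cross-method concordance of the target community
#'
#' At a fixed threshold, extracts the target gene's community with every
#' method and reports each community's size and its Dice overlap with the
#' community found by the reference method (so the reference row has
#' Dice = 1 by construction). When an expression matrix and `n_boot` are
#' supplied, community sizes additionally carry bootstrap 25th/75th
#' percentile spreads from subject resampling.
#'
#' @param net `correlation_network` matrix.
#' @param t threshold.
#' @param methods methods to compare.
#' @param target target gene id.
#' @param reference reference method (default `"fast_greedy"`).
#' @param seed detection / bootstrap seed.
#' @param m expression matrix; only needed when `n_boot > 0`.
#' @param n_boot bootstrap resamples for the size spread (0 = none).
#' @param min_size communities below this size are flagged invalid.
#' @return data.frame with one row per method: `method`, `size`,
#'   `size_q25`, `size_q75`, `dice`, `valid`.
#' @export
method_concordance <- function(net, t, methods = pivcomm_methods, target,
                               reference = "fast_greedy", seed = 1L,
                               m = NULL, n_boot = 0L, min_size = 3L) {
  methods <- match.arg(methods, several.ok = TRUE)
  reference <- match.arg(reference, pivcomm_methods)
  if (!reference %in% methods) methods <- c(reference, methods)
  g <- hard_threshold(net, t)
  comms <- lapply(methods, function(meth)
    target_community(detect_communities(g, meth, seed = seed), target))
  names(comms) <- methods
  ref_members <- comms[[reference]]$members
  size_q <- matrix(NA_real_, length(methods), 2L,
                   dimnames = list(methods, c("q25", "q75")))
  if (n_boot > 0L) {
    if (is.null(m))
      abort("bootstrap size spreads need the expression matrix m",
            "pivcomm_parse_error")
    sizes <- bootstrap_scan(m, grid = t, methods = methods, target = target,
                            n_boot = n_boot, seed = seed,
                            min_size = min_size)$size
    for (j in seq_along(methods)) {
      v <- sizes[, 1L, j]
      v <- v[is.finite(v)]
      if (length(v))
        size_q[j, ] <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    }
  }
  data.frame(method = methods,
             size = vapply(comms, function(x) length(x$members), integer(1L)),
             size_q25 = size_q[, 1L], size_q75 = size_q[, 2L],
             dice = vapply(comms, function(x) dice(x$members, ref_members),
                           numeric(1L)),
             valid = vapply(comms, function(x)
               length(x$members) >= min_size, logical(1L)),
             row.names = NULL)
}

#' Threshold-neighbourhood stability of the chosen community
#'
#' Fixes the community detected at the chosen threshold `best_t` and tracks,
#' across the whole grid, the Dice overlap between it and the community the
#' same method finds at each other threshold. Persistently high Dice across
#' the neighbourhood of `best_t` indicates a robust core of genes rather
#' than a threshold artefact.
#'
#' @param net `correlation_network` matrix.
#' @param best_t the chosen threshold.
#' @param grid thresholds to scan.
#' @param method single detection method.
#' @param target target gene id.
#' @param seed detection seed.
#' @param min_size records with a community smaller than this are flagged.
#' @return data.frame with columns `threshold`, `dice`, `size`, `valid`.
#' @export
dice_scan <- function(net, best_t, grid = threshold_grid(), method = "fast_greedy",
                      target, seed = 1L, min_size = 3L) {
  method <- match.arg(method, pivcomm_methods)
  g_ref <- hard_threshold(net, best_t)
  ref <- target_community(detect_communities(g_ref, method, seed = seed),
                          target)
  if (length(ref$members) < min_size)
    abort("community at the chosen threshold is below min_size",
          "pivcomm_degenerate_error")
  rows <- lapply(grid, function(t) {
    tc <- target_community(
      detect_communities(hard_threshold(net, t), method, seed = seed),
      target)
    data.frame(threshold = t, dice = dice(tc$members, ref$members),
               size = length(tc$members),
               valid = length(tc$members) >= min_size)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
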