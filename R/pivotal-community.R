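#' Detect the pivotal community around a target gene
#'
#' End-to-end estimator. Starting from a gene x subject expression matrix
#' restricted to one co-expression module, it:
#' \enumerate{
#'   \item builds the absolute-Pearson similarity network;
#'   \item profiles degree, betweenness, diameter and eccentricity over the
#'     threshold grid and restricts the community search to the range where
#'     the non-monotonic properties peak (see
#'     [select_threshold_range()]; disable with `restrict_grid = FALSE`);
#'   \item scans the Pivotal Module Index per threshold and detection method
#'     across that range, with subject-bootstrap 25th/75th percentile error
#'     bands;
#'   \item fits the weighted linear trend of the cross-method average PMI and
#'     flags thresholds in significant excess of it;
#'   \item scans the betweenness entropy of the network and of the target
#'     community;
#'   \item chooses the threshold maximising the cross-method average PMI
#'     among thresholds where every method yields a valid community (ties go
#'     to the lower threshold); the entropy argmax is required to agree
#'     within one grid step, otherwise the disagreement is messaged and the
#'     PMI choice stands;
#'   \item computes cross-method Dice concordance at the chosen threshold and
#'     Dice stability across its neighbourhood;
#'   \item measures the target's embeddedness: strength per node in the whole
#'     module versus the detected community versus a random-community null;
#'   \item tabulates hub genes (scaled strength > `hub_cutoff`) and their
#'     overlap with the community.
#' }
#' The run is fully deterministic given `seed`, which is expanded into fixed
#' per-stage seeds.
#'
#' @param expr expression matrix (genes x subjects), see
#'   [as_expression_matrix()].
#' @param target target gene id (must be a row of `expr`).
#' @param grid threshold grid, default [threshold_grid()] (0.30--0.60 step
#'   0.01).
#' @param methods community detection methods to scan.
#' @param reference_method method used for the reported community, Dice
#'   reference, entropy and stability scans.
#' @param min_size smallest community size considered valid, default 3.
#' @param n_boot bootstrap resamples for PMI / size error bands, default
#'   1000; `0` disables the bootstrap (trend test then uses unit weights).
#' @param n_null random communities for the strength null, default 1000.
#' @param hub_cutoff scaled-strength hub cutoff, default 0.70.
#' @param seed single integer seed.
#' @param subgraph measure PMI ingredients on the community-induced subgraph
#'   (default) or the full graph; see [pmi()].
#' @param restrict_grid restrict the PMI/entropy scans and the threshold
#'   choice to the topology-selected range (default `TRUE`); the Dice
#'   stability scan always covers the full grid.
#' @return object of class `pivotal_community`; see Details.
#' @details The returned object carries: `network` (similarity matrix),
#'   `topology` (profile data.frame), `pmi_records` (scan + bootstrap
#'   quantiles), `pmi_average` (per-threshold cross-method mean and error),
#'   `trend` (`pmi_trend`), `entropy` (scan data.frame), `best_threshold`,
#'   `entropy_argmax`, `entropy_agrees`, `community` (`target_community` at
#'   the chosen threshold, reference method), `communities` (per-method
#'   target communities at the chosen threshold), `concordance`, `stability`
#'   (Dice scan), `strength` (module / community / null comparison), `hubs`,
#'   `hub_overlap`, plus the call parameters.
#' @examples
#' sim <- simulate_expression(planted_design(n_subjects = 120,
#'   module_genes = 30, core_genes = 10, r_core = 0.7, r_module = 0.3),
#'   seed = 42)
#' fit <- pivotal_community(sim$expr, target = "TARGET",
#'   grid = threshold_grid(0.30, 0.60, 0.10), n_boot = 20, n_null = 100,
#'   seed = 42)
#' print(fit)
#' dice(fit$community, sim$core)
#' @export
pivotal_community <- function(expr, target,
                              grid = threshold_grid(),
                              methods = pivcomm_methods,
                              reference_method = "fast_greedy",
                              min_size = 3L, n_boot = 1000L, n_null = 1000L,
                              hub_cutoff = 0.70, seed = 1L,
                              subgraph = TRUE, restrict_grid = TRUE) {
  as_expression_matrix(expr)
  methods <- match.arg(methods, several.ok = TRUE)
  reference_method <- match.arg(reference_method, pivcomm_methods)
  if (!reference_method %in% methods)
    abort("reference_method must be among methods", "pivcomm_parse_error")
  if (!target %in% rownames(expr))
    abort(paste0("target gene '", target, "' not in expression matrix"),
          "pivcomm_target_error")

  net <- correlation_network(expr)
  if (!target %in% rownames(net))
    abort("target gene lost to zero-variance filtering",
          "pivcomm_degenerate_error")

  topo <- topology_profile(net, grid)
  scan_grid <- if (restrict_grid) select_threshold_range(topo) else grid

  seed_scan <- stage_seed(seed, "scan")
  records <- pmi_scan(net, scan_grid, methods, target, min_size = min_size,
                      seed = seed_scan, subgraph = subgraph)

  boot <- NULL
  records$q25 <- NA_real_; records$q75 <- NA_real_
  if (n_boot > 0L) {
    boot <- bootstrap_scan(expr, scan_grid, methods, target, n_boot = n_boot,
                           seed = stage_seed(seed, "boot"),
                           min_size = min_size, subgraph = subgraph)
    for (i in seq_along(scan_grid)) {
      for (j in seq_along(methods)) {
        v <- boot$pmi[, i, j]
        v <- v[is.finite(v)]
        if (length(v) >= 2L) {
          k <- which(records$threshold == scan_grid[i] &
                       records$method == methods[j])
          records$q25[k] <- stats::quantile(v, 0.25, names = FALSE)
          records$q75[k] <- stats::quantile(v, 0.75, names = FALSE)
        }
      }
    }
  }

  # cross-method average PMI per threshold, with bootstrap error = half the
  # IQR of the replicate-level cross-method mean
  avg <- data.frame(threshold = scan_grid,
                    pmi = vapply(scan_grid, function(t) {
                      v <- records$pmi[records$threshold == t]
                      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
                    }, numeric(1L)),
                    sigma = NA_real_,
                    all_valid = vapply(scan_grid, function(t)
                      all(records$valid[records$threshold == t]),
                      logical(1L)))
  if (!is.null(boot)) {
    rep_means <- apply(boot$pmi, c(1L, 2L), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    avg$sigma <- apply(rep_means, 2L, function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 2L) NA_real_
      else diff(stats::quantile(v, c(0.25, 0.75), names = FALSE)) / 2
    })
  } else {
    avg$sigma <- 1
  }

  trend <- tryCatch(
    pmi_trend_test(avg$threshold, avg$pmi, avg$sigma),
    pivcomm_degenerate_error = function(e) NULL)

  entropy <- entropy_scan(net, scan_grid, target, method = reference_method,
                          seed = seed_scan)

  eligible <- which(avg$all_valid & is.finite(avg$pmi))
  if (!length(eligible))
    abort("no threshold yields a valid community for every method",
          "pivcomm_degenerate_error")
  best_i <- eligible[which.max(avg$pmi[eligible])]  # which.max: first max,
  best_t <- scan_grid[best_i]                       # ties go to lower t
  step <- if (length(grid) > 1L) max(diff(grid)) else 0

  ent_i <- which.max(entropy$h_network)
  entropy_agrees <- abs(scan_grid[ent_i] - best_t) <= step + 1e-9
  if (!entropy_agrees)
    message(sprintf(paste0("entropy argmax (t = %s) disagrees with PMI ",
                           "argmax (t = %s); keeping the PMI choice"),
                    format(scan_grid[ent_i]), format(best_t)))

  g_best <- hard_threshold(net, best_t)
  community <- target_community(
    detect_communities(g_best, reference_method, seed = seed_scan), target)

  concordance <- method_concordance(net, best_t, methods, target,
                                    reference = reference_method,
                                    seed = seed_scan, m = expr,
                                    n_boot = n_boot, min_size = min_size)

  communities <- lapply(methods, function(meth)
    target_community(detect_communities(g_best, meth, seed = seed_scan),
                     target))
  names(communities) <- methods

  stability <- dice_scan(net, best_t, grid, method = reference_method,
                         target = target, seed = seed_scan,
                         min_size = min_size)

  null <- random_community_null(net, target, size = length(community$members),
                                n_reps = n_null,
                                seed = stage_seed(seed, "null"))
  strength <- data.frame(
    set = c("whole_network", "detected_community", "random_null"),
    strength_per_node = c(
      target_strength_per_node(net, rownames(net), target),
      target_strength_per_node(net, community$members, target),
      null$mean),
    sd = c(NA_real_, NA_real_, null$sd))

  hubs <- hub_table(net, cutoff = hub_cutoff)
  overlap <- if (nrow(hubs)) hub_overlap(hubs, community) else NA_real_

  structure(list(target = target, grid = grid, scan_grid = scan_grid,
                 methods = methods,
                 reference_method = reference_method, min_size = min_size,
                 n_boot = n_boot, n_null = n_null, seed = as.integer(seed),
                 subgraph = subgraph,
                 network = net, topology = topo,
                 pmi_records = records, pmi_average = avg, trend = trend,
                 entropy = entropy,
                 best_threshold = best_t,
                 entropy_argmax = scan_grid[ent_i],
                 entropy_agrees = entropy_agrees,
                 community = community, communities = communities,
                 concordance = concordance, stability = stability,
                 strength = strength, null = null,
                 hubs = hubs, hub_overlap = overlap,
                 call = match.call()),
            class = "pivotal_community")
}

#' @export
print.pivotal_community <- function(x, ...) {
  cat("Pivotal community detection\n")
  cat(sprintf("  target gene:    %s\n", x$target))
  cat(sprintf("  grid:           %s .. %s (%d thresholds)\n",
              format(min(x$grid)), format(max(x$grid)), length(x$grid)))
  cat(sprintf("  scan range:     %s .. %s (topology-selected)\n",
              format(min(x$scan_grid)), format(max(x$scan_grid))))
  cat(sprintf("  best threshold: %s (PMI argmax%s)\n", format(x$best_threshold),
              if (isTRUE(x$entropy_agrees)) ", entropy concurs"
              else sprintf("; entropy argmax at %s", format(x$entropy_argmax))))
  cat(sprintf("  community:      %d genes (%s)\n",
              length(x$community$members), x$reference_method))
  invisible(x)
}

#' @export
summary.pivotal_community <- function(object, ...) {
  x <- object
  print(x)
  cat("\nMethod concordance at the best threshold (Dice vs",
      paste0(x$reference_method, "):\n"))
  print(x$concordance, digits = 3)
  cat("\nTarget strength per node:\n")
  print(x$strength, digits = 3)
  if (!is.null(x$trend)) {
    cat("\n")
    print(x$trend)
  }
  nb <- x$stability
  cat(sprintf("\nDice stability: min %.3f / median %.3f across the grid\n",
              min(nb$dice), stats::median(nb$dice)))
  cat(sprintf("Hub genes: %d; fraction inside community: %s\n",
              nrow(x$hubs),
              if (is.na(x$hub_overlap)) "NA" else
                sprintf("%.2f", x$hub_overlap)))
  cat("\nCommunity members:\n")
  cat(strwrap(paste(sort(x$community$members), collapse = " "),
              width = 72, prefix = "  "), sep = "\n")
  invisible(x)
}

#' Plot method for pivotal community fits
#'
#' Four panels against threshold: topology profile (mean degree and mean
#' betweenness), per-method PMI with the bootstrap band of the cross-method
#' average and its linear trend, betweenness entropy of network and
#' community, and Dice stability relative to the chosen threshold. The
#' chosen threshold is marked in every panel.
#'
#' @param x `pivotal_community` object.
#' @param ... ignored.
#' @export
plot.pivotal_community <- function(x, ...) {
  op <- graphics::par(mfrow = c(2L, 2L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  mark <- function() graphics::abline(v = x$best_threshold, lty = 3L,
                                      col = "grey40")

  topo <- x$topology
  graphics::plot(topo$threshold, topo$mean_degree, type = "b", pch = 20,
                 xlab = "threshold", ylab = "mean degree",
                 main = "Topology profile")
  graphics::par(new = TRUE)
  graphics::plot(topo$threshold, topo$mean_betweenness, type = "b", pch = 1,
                 col = "firebrick", axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4L, col.axis = "firebrick")
  mark()

  avg <- x$pmi_average
  cols <- grDevices::hcl.colors(length(x$methods), "Dark 3")
  graphics::plot(NA, xlim = range(x$grid),
                 ylim = range(c(x$pmi_records$pmi, avg$pmi), na.rm = TRUE),
                 xlab = "threshold", ylab = "PMI",
                 main = "Pivotal Module Index")
  for (j in seq_along(x$methods)) {
    r <- x$pmi_records[x$pmi_records$method == x$methods[j], ]
    graphics::lines(r$threshold, r$pmi, col = cols[j], type = "b", pch = 20)
  }
  if (!is.null(x$trend))
    graphics::lines(x$trend$band$threshold, x$trend$band$fit, lty = 2L)
  graphics::legend("topleft", legend = x$methods, col = cols, lty = 1L,
                   cex = 0.7, bty = "n")
  mark()

  ent <- x$entropy
  graphics::plot(ent$threshold, ent$h_network, type = "b", pch = 20,
                 ylim = range(c(ent$h_network, ent$h_community)),
                 xlab = "threshold", ylab = "bits / node",
                 main = "Betweenness entropy")
  graphics::lines(ent$threshold, ent$h_community, type = "b", pch = 1,
                  col = "firebrick")
  graphics::legend("topleft", legend = c("network", "community"),
                   col = c("black", "firebrick"), lty = 1L, cex = 0.7,
                   bty = "n")
  mark()

  st <- x$stability
  graphics::plot(st$threshold, st$dice, type = "b", pch = 20, ylim = c(0, 1),
                 xlab = "threshold", ylab = "Dice vs chosen community",
                 main = "Stability")
  mark()
  invisible(x)
}

#' Write a pivotal community report to disk as TSV files
#'
#' Emits `topology.tsv`, `pmi.tsv`, `pmi_average.tsv`, `entropy.tsv`,
#' `concordance.tsv`, `stability.tsv`, `strength.tsv`, `hubs.tsv`,
#' `community.txt` (one gene per line) and `summary.tsv` (scalar results) in
#' `dir`.
#'
#' @param x `pivotal_community` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "pivotal_community"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  w(x$topology, "topology.tsv")
  w(x$pmi_records, "pmi.tsv")
  w(x$pmi_average, "pmi_average.tsv")
  w(x$entropy, "entropy.tsv")
  w(x$concordance, "concordance.tsv")
  w(x$stability, "stability.tsv")
  w(x$strength, "strength.tsv")
  w(x$hubs, "hubs.tsv")
  write_gene_set(sort(x$community$members), file.path(dir, "community.txt"))
  w(data.frame(key = c("target", "best_threshold", "entropy_argmax",
                       "entropy_agrees", "community_size", "hub_overlap",
                       "seed"),
               value = c(x$target, x$best_threshold, x$entropy_argmax,
                         x$entropy_agrees, length(x$community$members),
                         x$hub_overlap, x$seed)),
    "summary.tsv")
  invisible(dir)
}
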