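#' Design of a planted pivotal-community expression dataset
#'
#' Describes a gene x subject dataset with a three-level block correlation
#' structure: a tight core community (pairwise correlation `r_core`) that
#' contains the target gene, embedded in a looser co-expression module
#' (`r_module` between all other within-module pairs, including core-to-rest
#' pairs), plus optional weakly correlated background genes
#' (`r_background`). Defaults mirror a post-mortem brain expression study of
#' one module: 199 subjects, an 85-gene module and a 28-gene core at
#' within-core |r| 0.6 against a module-level |r| of 0.35.
#'
#' @param n_subjects number of subjects (columns), default 199.
#' @param module_genes module size including the core, default 85.
#' @param core_genes planted core size including the target, default 28.
#' @param background_genes genes outside the module, default 0.
#' @param r_core,r_module,r_background block correlation levels; must satisfy
#'   `0 <= r_background < r_module < r_core < 1`.
#' @param noise_sd standard deviation of extra iid Gaussian measurement
#'   noise added after the correlated draw, default 0. Note nonzero noise
#'   attenuates every block correlation by `1 / (1 + noise_sd^2)`.
#' @param target id given to the target gene (first core gene), default
#'   `"TARGET"`.
#' @return object of class `planted_design`.
#' @export
planted_design <- function(n_subjects = 199L, module_genes = 85L,
                           core_genes = 28L, background_genes = 0L,
                           r_core = 0.6, r_module = 0.35,
                           r_background = 0.05, noise_sd = 0,
                           target = "TARGET") {
  if (core_genes < 3L || core_genes > module_genes)
    abort("need 3 <= core_genes <= module_genes", "pivcomm_parse_error")
  if (n_subjects < 4L)
    abort("need at least 4 subjects", "pivcomm_parse_error")
  if (!(0 <= r_background && r_background < r_module && r_module < r_core &&
        r_core < 1))
    abort("need 0 <= r_background < r_module < r_core < 1",
          "pivcomm_parse_error")
  if (noise_sd < 0)
    abort("noise_sd must be >= 0", "pivcomm_parse_error")
  structure(list(n_subjects = as.integer(n_subjects),
                 module_genes = as.integer(module_genes),
                 core_genes = as.integer(core_genes),
                 background_genes = as.integer(background_genes),
                 r_core = r_core, r_module = r_module,
                 r_background = r_background, noise_sd = noise_sd,
                 target = target),
            class = "planted_design")
}

#' @export
print.planted_design <- function(x, ...) {
  cat(sprintf(paste0("planted_design: %d subjects; module %d genes ",
                     "(core %d incl. target '%s'), %d background\n",
                     "block |r|: core %.2f, module %.2f, background %.2f; ",
                     "noise_sd %.2f\n"),
              x$n_subjects, x$module_genes, x$core_genes, x$target,
              x$background_genes, x$r_core, x$r_module, x$r_background,
              x$noise_sd))
  invisible(x)
}

planted_correlation <- function(design) {
  g <- design$module_genes + design$background_genes
  sigma <- matrix(design$r_background, g, g)
  mod <- seq_len(design$module_genes)
  sigma[mod, mod] <- design$r_module
  core <- seq_len(design$core_genes)
  sigma[core, core] <- design$r_core
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    sigma <- as.matrix(Matrix::nearPD(sigma, corr = TRUE)$mat)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10)
      abort("planted correlation matrix is not repairable to positive definite",
            "pivcomm_degenerate_error")
  }
  sigma
}

#' Simulate expression data with a planted pivotal community
#'
#' Subjects are independent draws from a zero-mean multivariate normal whose
#' correlation matrix carries the design's block structure (repaired to the
#' nearest positive-definite correlation matrix if needed). Gene ids are
#' `g002, g003, ...` with the first core gene named after the design's
#' `target`; the planted core is returned alongside the matrix as ground
#' truth. Optional per-gene affine scaling emulates log-intensity ranges
#' without affecting any Pearson correlation.
#'
#' @param design a [planted_design()].
#' @param seed RNG seed; draws are reproducible per seed.
#' @param gene_scale,gene_offset optional vectors (recycled) of per-gene
#'   multiplicative scale and additive offset.
#' @return list of class `planted_expression` with elements `expr`
#'   (genes x subjects matrix), `core` (character vector of planted core
#'   gene ids, target included) and `design`.
#' @export
simulate_expression <- function(design, seed = 1L, gene_scale = 1,
                                gene_offset = 0) {
  stopifnot(inherits(design, "planted_design"))
  sigma <- planted_correlation(design)
  g <- nrow(sigma)
  n <- design$n_subjects
  ch <- chol(sigma)
  x <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * g), n, g) %*% ch
    if (design$noise_sd > 0)
      z <- z + design$noise_sd * matrix(stats::rnorm(n * g), n, g)
    z
  })
  gene_ids <- c(design$target, sprintf("g%03d", seq_len(g)[-1L]))
  x <- sweep(x, 2L, rep(gene_scale, length.out = g), "*")
  x <- sweep(x, 2L, rep(gene_offset, length.out = g), "+")
  expr <- t(x)
  dimnames(expr) <- list(gene_ids, sprintf("s%03d", seq_len(n)))
  structure(list(expr = expr,
                 core = gene_ids[seq_len(design$core_genes)],
                 design = design),
            class = "planted_expression")
}

#' @export
print.planted_expression <- function(x, ...) {
  cat(sprintf("planted_expression: %d genes x %d subjects, core of %d (target '%s')\n",
              nrow(x$expr), ncol(x$expr), length(x$core), x$design$target))
  invisible(x)
}
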