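#' Validate a gene-by-subject expression matrix
#'
#' An expression matrix is a numeric matrix with genes in rows and subjects in
#' columns; rownames are gene identifiers, colnames are subject identifiers.
#' Values are on whatever (typically log-intensity) scale the upstream
#' preprocessing produced -- only Pearson correlations of rows are ever used,
#' so the scale is immaterial.
#'
#' @param m numeric matrix, genes x subjects, with row and column names.
#' @return `m`, invisibly unchanged, after validation.
#' @details Requirements: at least 3 genes and 2 subjects, unique non-empty
#'   row/column names, and all values finite. Genes carrying any non-finite
#'   value are reported by name in the error.
#' @export
as_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    abort("expression data must be a numeric matrix (genes x subjects)",
          "pivcomm_parse_error")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    abort("expression matrix needs gene rownames and subject colnames",
          "pivcomm_parse_error")
  if (nrow(m) < 3L)
    abort("need at least 3 genes", "pivcomm_parse_error")
  if (ncol(m) < 2L)
    abort("need at least 2 subjects", "pivcomm_parse_error")
  if (anyDuplicated(rownames(m)))
    abort(paste0("duplicate gene ids: ",
                 paste(unique(rownames(m)[duplicated(rownames(m))]),
                       collapse = ", ")),
          "pivcomm_parse_error")
  if (anyDuplicated(colnames(m)))
    abort(paste0("duplicate subject ids: ",
                 paste(unique(colnames(m)[duplicated(colnames(m))]),
                       collapse = ", ")),
          "pivcomm_parse_error")
  bad <- rownames(m)[apply(m, 1L, function(x) any(!is.finite(x)))]
  if (length(bad))
    abort(paste0("non-finite expression values for gene(s): ",
                 paste(bad, collapse = ", ")),
          "pivcomm_nonfinite_error")
  invisible(m)
}

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of subject identifiers and one row per gene whose
#' first field is the gene identifier. Tab and comma dialects are both
#' accepted; by default the delimiter is auto-detected from the header line.
#'
#' @param path path to a TSV/CSV file.
#' @param delimiter `"auto"` (default), `"\t"` or `","`.
#' @return validated numeric matrix, genes x subjects.
#' @export
read_expression <- function(path, delimiter = "auto") {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), "pivcomm_io_error")
  sep <- if (identical(delimiter, "auto")) detect_delimiter(path) else delimiter
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 3L)
    abort("malformed header: expected gene id column plus >=2 subjects",
          "pivcomm_parse_error")
  genes <- raw[[1L]]
  subjects <- colnames(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(vals) && !anyNA(body)) {
    bad <- which(is.na(vals) & !is.na(body), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-numeric cell at gene '%s', subject '%s': '%s'",
                  genes[bad[1L]], subjects[bad[2L]], body[bad[1L], bad[2L]]),
          "pivcomm_parse_error")
  }
  dimnames(vals) <- list(genes, subjects)
  as_expression_matrix(vals)
  vals
}

#' Write an expression matrix as delimited text
#'
#' Round-trips with [read_expression()]: the header row holds subject ids and
#' the first column holds gene ids. Values are written with full double
#' precision (17 significant digits) so exactly representable values survive
#' a write/read cycle bit-for-bit.
#'
#' @param m expression matrix (genes x subjects).
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @export
write_expression <- function(m, path, delimiter = "\t") {
  as_expression_matrix(m)
  header <- paste(c("gene", colnames(m)), collapse = delimiter)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], format = "g", digits = 17)),
          collapse = delimiter)
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a subject metadata table
#'
#' A TSV/CSV with (at least) columns `subject_id`, `rin`, `group`, `age`:
#' RNA integrity number, ethnicity label and age in years per subject.
#'
#' @inheritParams read_expression
#' @return data.frame with one row per subject.
#' @export
read_subject_metadata <- function(path, delimiter = "auto") {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), "pivcomm_io_error")
  sep <- if (identical(delimiter, "auto")) detect_delimiter(path) else delimiter
  meta <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", "rin", "group", "age")
  missing_cols <- setdiff(need, colnames(meta))
  if (length(missing_cols))
    abort(paste0("metadata lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          "pivcomm_parse_error")
  if (anyDuplicated(meta$subject_id))
    abort("duplicate subject_id in metadata", "pivcomm_parse_error")
  if (any(!is.finite(meta$rin)) || any(meta$rin < 0))
    abort("rin must be finite and >= 0", "pivcomm_parse_error")
  meta
}

#' Filter subjects on tissue quality and group membership
#'
#' Keeps exactly the subjects whose RNA integrity number is strictly greater
#' than `min_rin` and whose group label is among `allowed_groups`; the
#' original column order is preserved. Strict inequality follows the source
#' protocol of retaining samples with RIN above 7.0.
#'
#' @param m expression matrix (genes x subjects).
#' @param meta data.frame with columns `subject_id`, `rin`, `group`.
#' @param min_rin RIN cutoff; subjects must exceed it strictly. Default 7.0.
#' @param allowed_groups character vector of retained group labels, or `NULL`
#'   (default) to allow every group.
#' @return expression matrix restricted to surviving subjects.
#' @export
filter_subjects <- function(m, meta, min_rin = 7.0, allowed_groups = NULL) {
  as_expression_matrix(m)
  missing_subj <- setdiff(colnames(m), meta$subject_id)
  if (length(missing_subj))
    abort(paste0("subject(s) absent from metadata: ",
                 paste(missing_subj, collapse = ", ")),
          "pivcomm_metadata_error")
  idx <- match(colnames(m), meta$subject_id)
  keep <- meta$rin[idx] > min_rin
  if (!is.null(allowed_groups))
    keep <- keep & meta$group[idx] %in% allowed_groups
  if (!any(keep))
    abort("no subjects survive the filter", "pivcomm_degenerate_error")
  m[, keep, drop = FALSE]
}

#' Read / write plain-text gene sets
#'
#' One gene identifier per line; blank lines are ignored.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' @rdname read_gene_set
#' @param genes character vector of gene ids.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Write a network as a TSV edge list
#'
#' For a similarity network, writes every off-diagonal pair once with its
#' weight (`geneA geneB weight`); for a thresholded graph, writes the binary
#' edge list with weight 1.
#'
#' @param x a correlation network matrix or an igraph thresholded graph.
#' @param path output path.
#' @param min_weight for weighted networks, smallest weight written
#'   (default 0: all pairs).
#' @export
write_edge_list <- function(x, path, min_weight = 0) {
  if (inherits(x, "igraph")) {
    el <- igraph::as_edgelist(x)
    df <- data.frame(geneA = el[, 1L], geneB = el[, 2L], weight = 1)
  } else {
    ut <- upper.tri(x)
    idx <- which(ut & x >= min_weight, arr.ind = TRUE)
    df <- data.frame(geneA = rownames(x)[idx[, 1L]],
                     geneB = colnames(x)[idx[, 2L]],
                     weight = x[idx])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
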