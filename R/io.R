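# File dialects: Matrix-Market sparse triples with row/column name sidecar
# files (the 10x-style layout: matrix.mtx + barcodes.tsv + features.tsv),
# and dense CSV (observations in rows, genes in columns). Gene identifiers
# are matched case-sensitively after stripping surrounding whitespace.

#' Read an expression matrix from Matrix-Market files
#'
#' Expects `<prefix>.mtx` (genes x observations sparse counts, the
#' convention of 10x-style exports), `<prefix>.features.tsv` (gene ids, one
#' per line) and `<prefix>.barcodes.tsv` (observation ids).
#'
#' @param prefix path prefix of the three files.
#' @param modality `"ST"` or `"SC"`.
#' @param layer `"counts"` (default) or `"normalized"`.
#' @return an [expression_matrix()].
#' @export
read_expression_mtx <- function(prefix, modality, layer = "counts") {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  genes <- readLines(paste0(prefix, ".features.tsv"))
  obs <- readLines(paste0(prefix, ".barcodes.tsv"))
  if (nrow(m) != length(genes) || ncol(m) != length(obs))
    stop("sidecar files do not match matrix dimensions")
  vals <- t(as.matrix(m))
  dimnames(vals) <- list(obs, genes)
  expression_matrix(vals, modality = modality, layer = layer)
}

#' Write an expression matrix to Matrix-Market files
#'
#' @param x an [expression_matrix()].
#' @param prefix output path prefix (writes `.mtx`, `.features.tsv`,
#'   `.barcodes.tsv`).
#' @export
write_expression_mtx <- function(x, prefix) {
  stopifnot(inherits(x, "expression_matrix"))
  Matrix::writeMM(methods::as(Matrix::Matrix(t(x$values), sparse = TRUE),
                              "generalMatrix"),
                  paste0(prefix, ".mtx"))
  writeLines(x$gene_ids, paste0(prefix, ".features.tsv"))
  writeLines(x$obs_ids, paste0(prefix, ".barcodes.tsv"))
  invisible(prefix)
}

#' Read an expression matrix from dense CSV
#'
#' Observations in rows (first column = observation ids), genes in columns
#' (header = gene ids).
#'
#' @param path CSV file (optionally gzipped).
#' @param modality `"ST"` or `"SC"`.
#' @param layer `"counts"` or `"normalized"`.
#' @return an [expression_matrix()].
#' @export
read_expression_csv <- function(path, modality, layer = "counts") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  expression_matrix(as.matrix(df), modality = modality, layer = layer)
}

#' Write an expression matrix to dense CSV
#'
#' @param x an [expression_matrix()].
#' @param path output file; a `.gz` suffix writes gzipped.
#' @export
write_expression_csv <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(as.data.frame(x$values), con)
  invisible(path)
}
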