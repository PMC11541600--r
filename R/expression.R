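#' Expression matrix container
#'
#' A light S3 container for a named observations x genes expression matrix
#' with a modality tag (`"ST"` for spatial spots, `"SC"` for single cells)
#' and a layer tag (`"counts"` or `"normalized"`). Storage is observations x
#' genes (the ecosystem convention); the model-facing code uses the
#' gene-major view from [gene_major()], because the diffusion model treats
#' each gene as one sample.
#'
#' @param values numeric matrix, observations in rows, genes in columns.
#' @param gene_ids character vector of unique gene identifiers (length
#'   `ncol(values)`). Defaults to `colnames(values)`.
#' @param obs_ids character vector of unique observation identifiers (length
#'   `nrow(values)`). Defaults to `rownames(values)`.
#' @param modality `"ST"` or `"SC"`.
#' @param layer `"counts"` or `"normalized"`. A counts layer must be
#'   non-negative.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = colnames(values),
                              obs_ids = rownames(values),
                              modality = c("ST", "SC"),
                              layer = c("counts", "normalized")) {
  modality <- match.arg(modality)
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  if (is.null(obs_ids)) {
    obs_ids <- paste0(if (modality == "ST") "spot" else "cell",
                      seq_len(nrow(values)))
  }
  gene_ids <- trimws(as.character(gene_ids))
  obs_ids <- trimws(as.character(obs_ids))
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length must match ncol(values)")
  if (length(obs_ids) != nrow(values))
    stop("obs_ids length must match nrow(values)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids are not allowed")
  if (anyDuplicated(obs_ids))
    stop("duplicate obs_ids are not allowed")
  if (layer == "counts" && any(values < 0))
    stop("counts layer must be non-negative")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  dimnames(values) <- list(obs_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids, obs_ids = obs_ids,
                 modality = modality, layer = layer),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %s/%s: %d %s x %d genes\n",
              x$modality, x$layer, length(x$obs_ids),
              if (x$modality == "ST") "spots" else "cells",
              length(x$gene_ids)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene-major view of an expression matrix
#'
#' Returns the genes x observations matrix: row `i` is the expression
#' profile of gene `i` across all spots/cells. This is the orientation the
#' diffusion model consumes (each gene is a token/sample).
#'
#' @param x an [expression_matrix()].
#' @param genes optional character vector restricting (and ordering) rows.
#' @return numeric matrix, genes x observations.
#' @export
gene_major <- function(x, genes = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  m <- t(x$values)
  if (!is.null(genes)) {
    missing <- setdiff(genes, x$gene_ids)
    if (length(missing))
      stop("unknown gene id(s): ", paste(utils::head(missing, 5), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  m
}

#' Paired ST + SC dataset
#'
#' Aligns a spatial (ST) and a single-cell (SC) expression matrix. The
#' shared-gene panel `G_share` is the intersection of the two gene sets, in
#' the ST gene order (a fixed canonical order); `G_unique` are the SC-only
#' genes. An optional per-gene split labels each ST gene `train`, `val` or
#' `test` (see [split_genes()]).
#'
#' @param st an [expression_matrix()] with `modality = "ST"`.
#' @param sc an [expression_matrix()] with `modality = "SC"`.
#' @param split optional named character vector over ST genes with values in
#'   `train/val/test`.
#' @return An object of class `paired_dataset` with fields `st`, `sc`,
#'   `shared_genes`, `sc_unique_genes`, `split`.
#' @export
paired_dataset <- function(st, sc, split = NULL) {
  stopifnot(inherits(st, "expression_matrix"), inherits(sc, "expression_matrix"))
  if (st$modality != "ST" || sc$modality != "SC")
    stop("paired_dataset(st, sc) expects modalities ST and SC")
  shared <- st$gene_ids[st$gene_ids %in% sc$gene_ids]
  unique_sc <- setdiff(sc$gene_ids, shared)
  if (!is.null(split)) {
    if (!setequal(names(split), st$gene_ids))
      stop("split must cover exactly the ST genes")
    if (!all(split %in% c("train", "val", "test")))
      stop("split values must be train/val/test")
    split <- split[st$gene_ids]
  }
  structure(list(st = st, sc = sc, shared_genes = shared,
                 sc_unique_genes = unique_sc, split = split),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf(paste0("<paired_dataset> ST %d spots x %d genes | SC %d cells x ",
                     "%d genes | %d shared\n"),
              length(x$st$obs_ids), length(x$st$gene_ids),
              length(x$sc$obs_ids), length(x$sc$gene_ids),
              length(x$shared_genes)))
  if (!is.null(x$split))
    cat("  split:", paste(names(table(x$split)), table(x$split),
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Genes belonging to one split partition
#'
#' @param ds a [paired_dataset()] with a split.
#' @param which one of `"train"`, `"val"`, `"test"`.
#' @return character vector of gene ids.
#' @export
split_partition <- function(ds, which = c("train", "val", "test")) {
  which <- match.arg(which)
  if (is.null(ds$split)) stop("dataset has no split; call split_genes() first")
  names(ds$split)[ds$split == which]
}
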