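#' Quality-control filtering of a paired dataset
#'
#' Removes low-quality observations: SC cells detecting fewer than
#' `min_genes_sc` genes (default 500) and ST spots detecting fewer than
#' `min_genes_st` genes (default 1, i.e. all-zero spots). Gene sets are left
#' untouched. The operation is idempotent.
#'
#' @param ds a [paired_dataset()] whose matrices hold raw counts.
#' @param min_genes_sc minimum detected genes for an SC cell to be kept.
#' @param min_genes_st minimum detected genes for an ST spot to be kept.
#' @return the filtered [paired_dataset()].
#' @export
qc_filter <- function(ds, min_genes_sc = 500L, min_genes_st = 1L) {
  stopifnot(inherits(ds, "paired_dataset"))
  if (ds$st$layer != "counts" || ds$sc$layer != "counts")
    stop("qc_filter() expects counts layers")
  keep_cell <- rowSums(ds$sc$values > 0) >= min_genes_sc
  keep_spot <- rowSums(ds$st$values > 0) >= min_genes_st
  if (!any(keep_cell)) stop("qc_filter() removed every SC cell")
  if (!any(keep_spot)) stop("qc_filter() removed every ST spot")
  sc <- expression_matrix(ds$sc$values[keep_cell, , drop = FALSE],
                          modality = "SC", layer = "counts")
  st <- expression_matrix(ds$st$values[keep_spot, , drop = FALSE],
                          modality = "ST", layer = "counts")
  paired_dataset(st, sc, split = ds$split)
}

#' Median-count log normalization of ST counts
#'
#' Per-spot normalization `D_ij = log(N * C_ij / sum_j C_ij + 1)` where `N`
#' is the median total count over spots and the log is natural. Every spot
#' is rescaled to the median library size before the log1p transform, so the
#' result is invariant to per-spot count scaling and zeros map to zeros.
#'
#' @param st an ST [expression_matrix()] with a counts layer; spots with
#'   zero total counts must already have been removed (see [qc_filter()]).
#' @return an [expression_matrix()] with `layer = "normalized"`.
#' @export
normalize_st <- function(st) {
  stopifnot(inherits(st, "expression_matrix"))
  if (st$modality != "ST") stop("normalize_st() expects an ST matrix")
  if (st$layer != "counts") stop("normalize_st() expects a counts layer")
  totals <- rowSums(st$values)
  if (any(totals == 0))
    stop("spots with zero total counts present; run qc_filter() first")
  n_med <- stats::median(totals)
  vals <- log1p(st$values * (n_med / totals))
  expression_matrix(vals, modality = "ST", layer = "normalized")
}

#' Log normalization of SC counts
#'
#' Per-cell log normalization `log(1 + s * C_ij / sum_j C_ij)` with scale
#' factor `s = 1e4` (the standard single-cell LogNormalize default).
#' Proportional cells map to identical normalized rows; zeros map to zeros.
#'
#' @param sc an SC [expression_matrix()] with a counts layer and no
#'   zero-total cells.
#' @param scale_factor library-size target, default `1e4`.
#' @return an [expression_matrix()] with `layer = "normalized"`.
#' @export
normalize_sc <- function(sc, scale_factor = 1e4) {
  stopifnot(inherits(sc, "expression_matrix"))
  if (sc$modality != "SC") stop("normalize_sc() expects an SC matrix")
  if (sc$layer != "counts") stop("normalize_sc() expects a counts layer")
  totals <- rowSums(sc$values)
  if (any(totals == 0))
    stop("cells with zero total counts present; run qc_filter() first")
  vals <- log1p(sc$values * (scale_factor / totals))
  expression_matrix(vals, modality = "SC", layer = "normalized")
}

#' Highly variable gene selection by coefficient of variation
#'
#' Ranks genes by `CV_i = sigma_i / mu_i` (sample standard deviation over
#' observations divided by mean) and returns the top `ceiling(frac * G)`
#' genes. Genes with zero mean are excluded before ranking; ties are broken
#' by gene id (lexicographic) so the selection is deterministic and
#' invariant to input gene order.
#'
#' @param mat a normalized [expression_matrix()].
#' @param frac fraction of genes to keep, default 0.25.
#' @return character vector of selected gene ids, highest CV first.
#' @export
select_hvg <- function(mat, frac = 0.25) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (mat$layer != "normalized")
    stop("select_hvg() expects a normalized layer")
  g <- length(mat$gene_ids)
  if (g < 4) stop("select_hvg() needs at least 4 genes")
  mu <- colMeans(mat$values)
  sigma <- apply(mat$values, 2, stats::sd)
  keep <- mu > 0
  cv <- sigma[keep] / mu[keep]
  ids <- mat$gene_ids[keep]
  ord <- order(-cv, ids)
  n_top <- ceiling(frac * g)
  ids[ord][seq_len(min(n_top, length(ids)))]
}

#' Random 7:2:1 gene split
#'
#' Partitions the ST genes into train/validation/test sets with the given
#' ratios using largest-remainder apportionment, deterministically under
#' `seed`. In this framework genes are the samples, so the split is over
#' genes, not spots.
#'
#' @param ds a [paired_dataset()].
#' @param seed integer seed controlling the permutation.
#' @param ratios numeric length-3 vector of train/val/test proportions
#'   (normalized internally), default `c(0.7, 0.2, 0.1)`.
#' @return the [paired_dataset()] with its `split` field populated.
#' @export
split_genes <- function(ds, seed, ratios = c(0.7, 0.2, 0.1)) {
  stopifnot(inherits(ds, "paired_dataset"), length(ratios) == 3)
  genes <- ds$st$gene_ids
  n <- length(genes)
  if (n < 10) stop("split_genes() needs at least 10 genes")
  sizes <- largest_remainder(n, ratios / sum(ratios))
  perm <- with_seed(seed, sample.int(n))
  lab <- rep(c("train", "val", "test"), times = sizes)
  split <- stats::setNames(rep(NA_character_, n), genes)
  split[perm] <- lab  # gene perm[k] receives the k-th label
  paired_dataset(ds$st, ds$sc, split = split)
}

# Largest-remainder apportionment of n items into parts with target shares.
largest_remainder <- function(n, shares) {
  quota <- n * shares
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
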