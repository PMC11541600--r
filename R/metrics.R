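#' Pearson correlation between predicted and true profiles
#'
#' Plain Pearson correlation. If either vector is constant the correlation
#' is undefined; it is reported as 0 with a warning, which is the convention
#' used throughout the package (a constant prediction carries no spatial
#' information).
#'
#' @param pred,truth numeric vectors of equal length (>= 2).
#' @return correlation in `[-1, 1]`.
#' @export
pcc <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 2) stop("need at least 2 observations")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    warning("constant input; PCC reported as 0")
    return(0)
  }
  stats::cor(pred, truth)
}

#' Root mean square error
#'
#' By default both vectors are z-scored (gene-wise standardization) before
#' comparison, so the error measures disagreement in spatial shape rather
#' than in scale; set `scale = FALSE` for the raw RMSE. A constant vector
#' z-scores to all zeros.
#'
#' @param pred,truth numeric vectors of equal length.
#' @param scale z-score both inputs first (default `TRUE`).
#' @return non-negative error.
#' @export
rmse <- function(pred, truth, scale = TRUE) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (scale) {
    pred <- zscore(pred)
    truth <- zscore(truth)
  }
  sqrt(mean((pred - truth)^2))
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Jensen-Shannon divergence between two expression profiles
#'
#' Each vector is shifted to be non-negative (subtracting its minimum when
#' negative values are present), floored at `eps`, and normalized to a
#' probability distribution; the JS divergence is then computed with base-2
#' logarithms so the value lies in `[0, 1]`.
#'
#' @param pred,truth numeric vectors of equal length.
#' @param eps floor applied before normalization, default `1e-12`.
#' @return divergence in `[0, 1]` (bits).
#' @export
js_divergence <- function(pred, truth, eps = 1e-12) {
  if (length(pred) != length(truth)) stop("length mismatch")
  p <- to_distribution(pred, eps)
  q <- to_distribution(truth, eps)
  m <- (p + q) / 2
  0.5 * kl2(p, m) + 0.5 * kl2(q, m)
}

to_distribution <- function(x, eps) {
  if (any(x < 0)) x <- x - min(x)
  s <- sum(x)
  if (s == 0) stop("all-zero vector cannot be normalized to a distribution")
  x <- pmax(x / s, eps)
  x / sum(x)
}

kl2 <- function(p, q) sum(p * (log2(p) - log2(q)))

#' Structural similarity between two spatial profiles
#'
#' Global (single-window) SSIM over the per-gene spot vectors. Both inputs
#' are min-max scaled to `[0, 1]` first, so the stabilizers use the standard
#' constants for data range 1: `C1 = 0.01^2`, `C2 = 0.03^2`. Variances and
#' the covariance use the unbiased (n-1) estimator. Symmetric in its
#' arguments.
#'
#' @param pred,truth numeric vectors of equal length (>= 2).
#' @param scale min-max scale inputs to `[0, 1]` first (default `TRUE`).
#' @return similarity in `[-1, 1]`.
#' @export
ssim <- function(pred, truth, scale = TRUE) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 2) stop("need at least 2 observations")
  if (scale) {
    pred <- minmax(pred)
    truth <- minmax(truth)
  }
  c1 <- 0.01^2
  c2 <- 0.03^2
  mx <- mean(pred); my <- mean(truth)
  vx <- stats::var(pred); vy <- stats::var(truth)
  cxy <- stats::cov(pred, truth)
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

minmax <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Composite accuracy score across methods
#'
#' Ranks each method on each of the four metrics (PCC and SSIM: higher is
#' better; RMSE and JS: lower is better), converts ranks to normalized
#' ranks `(rank - 1) / (M - 1)` and averages them; the accuracy score is
#' `AS = 1 - mean normalized rank`, in `[0, 1]`, higher is better. Ties
#' share the average rank.
#'
#' @param per_method_metrics named list (one element per method, `M >= 2`)
#'   of lists/vectors with entries `pcc`, `ssim`, `rmse`, `js`.
#' @return named numeric vector of accuracy scores.
#' @export
accuracy_score <- function(per_method_metrics) {
  m_names <- names(per_method_metrics)
  if (length(per_method_metrics) < 2)
    stop("accuracy_score() needs at least 2 methods")
  needed <- c("pcc", "ssim", "rmse", "js")
  tab <- vapply(per_method_metrics, function(m) {
    m <- unlist(m)
    if (!all(needed %in% names(m)))
      stop("missing metric(s): ", paste(setdiff(needed, names(m)), collapse = ", "))
    m[needed]
  }, numeric(4))
  # tab: 4 metrics x M methods
  M <- ncol(tab)
  higher_better <- c(TRUE, TRUE, FALSE, FALSE)
  nr <- vapply(seq_len(4), function(i) {
    v <- tab[i, ]
    r <- if (higher_better[i]) rank(-v, ties.method = "average")
         else rank(v, ties.method = "average")
    (r - 1) / (M - 1)
  }, numeric(M))
  # nr: M methods x 4 metrics
  stats::setNames(1 - rowMeans(nr), m_names)
}

#' Binomial downsampling of a counts matrix
#'
#' Each count `c` is replaced by a `Binomial(c, 1 - rate)` draw: `rate` is
#' the expected fraction of transcripts removed, so larger rates give
#' sparser matrices. Deterministic under `seed`; zeros stay zero.
#'
#' @param counts an [expression_matrix()] with a counts layer.
#' @param rate fraction of transcripts to remove, in `[0, 1)`.
#' @param seed integer seed.
#' @return an [expression_matrix()] of thinned counts.
#' @export
downsample_counts <- function(counts, rate, seed) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$layer != "counts")
    stop("downsample_counts() expects a counts layer")
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(counts)
  vals <- counts$values
  thinned <- with_seed(seed, {
    v <- stats::rbinom(length(vals), size = as.integer(round(vals)),
                       prob = 1 - rate)
    matrix(v, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  })
  expression_matrix(thinned, modality = counts$modality, layer = "counts")
}

#' Robustness score across a downsampling experiment
#'
#' Fraction of genes whose prediction accuracy (PCC) is strictly greater
#' than `threshold` in BOTH the original and the downsampled data.
#'
#' @param pcc_original,pcc_downsampled named numeric vectors of per-gene
#'   PCC over the same gene set.
#' @param threshold PCC cutoff, default 0.5 (strict inequality).
#' @return fraction in `[0, 1]`.
#' @export
robustness_score <- function(pcc_original, pcc_downsampled, threshold = 0.5) {
  if (is.null(names(pcc_original)) || is.null(names(pcc_downsampled)) ||
      !setequal(names(pcc_original), names(pcc_downsampled)))
    stop("gene sets must match (named vectors over the same genes)")
  pcc_downsampled <- pcc_downsampled[names(pcc_original)]
  mean(pcc_original > threshold & pcc_downsampled > threshold)
}

#' Per-gene metric report for a predicted expression matrix
#'
#' Computes PCC, SSIM, RMSE and JS for every gene (column) of a predicted
#' spots x genes matrix against the matching truth, plus aggregate
#' mean/sd per metric.
#'
#' @param pred,truth numeric matrices (spots x genes) with identical
#'   dimnames, or [expression_matrix()] objects.
#' @return list with `per_gene` (data.frame) and `aggregate` (data.frame of
#'   mean and sd per metric).
#' @export
metric_report <- function(pred, truth) {
  if (inherits(pred, "expression_matrix")) pred <- pred$values
  if (inherits(truth, "expression_matrix")) truth <- truth$values
  if (is.null(colnames(pred)) || is.null(colnames(truth)))
    stop("matrices must carry gene column names")
  genes <- colnames(pred)
  if (!all(genes %in% colnames(truth))) stop("gene sets must match")
  truth <- truth[, genes, drop = FALSE]
  per <- do.call(rbind, lapply(genes, function(g) {
    p <- pred[, g]; y <- truth[, g]
    data.frame(gene = g,
               pcc = suppressWarnings(pcc(p, y)),
               ssim = ssim(p, y),
               rmse = rmse(p, y),
               js = js_divergence(p, y))
  }))
  agg <- data.frame(
    metric = c("pcc", "ssim", "rmse", "js"),
    mean = vapply(per[c("pcc", "ssim", "rmse", "js")], mean, 0),
    sd = vapply(per[c("pcc", "ssim", "rmse", "js")], stats::sd, 0))
  list(per_gene = per, aggregate = agg)
}
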