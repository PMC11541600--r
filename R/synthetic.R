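#' Configuration for the synthetic paired-data generator
#'
#' Describes a paired SC/ST simulation: a low-rank cell-state model shared
#' between the two modalities, planted 2-D spatial patterns on a lattice,
#' per-observation lognormal library-size factors, and Bernoulli dropout
#' matching the zero-inflation levels of real image-based/seq-based ST data
#' (observed dropout around 60-85%).
#'
#' Defaults describe the package's reference simulation: 500 cells, an
#' 8 x 8 lattice of 64 spots, 300 SC genes of which 120 form the shared
#' (ST-measured) panel, 6 latent factors, 70%/60% SC/ST dropout.
#'
#' @param n_cells,n_spots number of SC cells and ST spots.
#' @param n_sc_genes,n_shared_genes SC panel size and shared-panel size
#'   (`n_shared_genes <= n_sc_genes`); the ST panel equals the shared panel.
#' @param n_factors number of latent cell states.
#' @param grid_side spots are laid on a `grid_side x grid_side` lattice
#'   (row-major, first `n_spots` positions); `grid_side^2 >= n_spots`.
#' @param dropout_sc,dropout_st Bernoulli zero-masking fractions in `[0, 1)`.
#' @param noise_sd standard deviation of Gaussian noise added to the
#'   log-scale linear predictor.
#' @param seed single integer seed; sub-streams for loadings, factors,
#'   noise and dropout are derived from it deterministically.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_cells = 500L, n_spots = 64L, n_sc_genes = 300L,
                         n_shared_genes = 120L, n_factors = 6L,
                         grid_side = 8L, dropout_sc = 0.7, dropout_st = 0.6,
                         noise_sd = 0.2, seed = 0L) {
  cfg <- list(n_cells = as.integer(n_cells), n_spots = as.integer(n_spots),
              n_sc_genes = as.integer(n_sc_genes),
              n_shared_genes = as.integer(n_shared_genes),
              n_factors = as.integer(n_factors),
              grid_side = as.integer(grid_side),
              dropout_sc = dropout_sc, dropout_st = dropout_st,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (any(unlist(cfg[c("n_cells", "n_spots", "n_sc_genes", "n_shared_genes",
                       "n_factors", "grid_side")]) <= 0))
    stop("all sizes must be positive integers")
  if (cfg$n_shared_genes > cfg$n_sc_genes)
    stop("n_shared_genes must be <= n_sc_genes")
  if (cfg$grid_side^2 < cfg$n_spots)
    stop("grid_side^2 must be >= n_spots")
  if (dropout_sc < 0 || dropout_sc >= 1 || dropout_st < 0 || dropout_st >= 1)
    stop("dropout fractions must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  class(cfg) <- "synth_config"
  cfg
}

# Deterministic sub-seed for stage k of a generator run (kept below 2^31).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65011) * 33013 + 7907 * k) %% 2147483629L
}

# Planted spatial pattern on the lattice, scaled to [0, 1].
# kind: "blob" (Gaussian bump), "stripe" (axis-aligned band),
# "gradient" (linear ramp along a random direction).
planted_pattern <- function(kind, xy, grid_side) {
  g <- grid_side
  z <- switch(kind,
    blob = {
      ctr <- stats::runif(2, 0.25 * g, 0.75 * g)
      s <- stats::runif(1, 0.15 * g, 0.3 * g)
      exp(-((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2) / (2 * s^2))
    },
    stripe = {
      axis <- sample(1:2, 1)
      ctr <- stats::runif(1, 0.2 * g, 0.8 * g)
      w <- stats::runif(1, 0.1 * g, 0.2 * g)
      exp(-(xy[, axis] - ctr)^2 / (2 * w^2))
    },
    gradient = {
      theta <- stats::runif(1, 0, 2 * pi)
      xy[, 1] * cos(theta) + xy[, 2] * sin(theta)
    },
    stop("unknown pattern kind: ", kind))
  rng <- range(z)
  if (diff(rng) < 1e-12) return(rep(0.5, nrow(xy)))
  (z - rng[1]) / diff(rng)
}

#' Generate a paired SC/ST dataset with known ground truth
#'
#' Both modalities are driven by the same gene x factor loading matrix.
#' Cells mix the latent factors with one dominant state each; spots follow
#' smooth planted 2-D patterns (Gaussian blob, axis stripe, linear gradient,
#' cycling over factors) on the lattice, mean-matched to the cell-state
#' activation scale so the factor-weighted pseudo-bulk profiles of the two
#' modalities coincide. Counts are
#' `round(size_factor * exp(loadings . factors + noise))` with the
#' log-predictor centered per observation (compositional sequencing: depth
#' is governed by the lognormal size factor, sdlog 0.3, so the median-count
#' normalization is non-trivially exercised), thinned entrywise by
#' Bernoulli(1 - dropout). The ST zero fraction tracks `dropout_st`
#' directly; the SC side gains some additional natural zeros from
#' low-abundance off-state genes, as in real scRNA-seq. Genes outside the
#' shared panel appear only in SC. Identical seeds give bit-identical
#' output.
#'
#' @param config a [synth_config()].
#' @return list with elements `dataset` (a [paired_dataset()] of counts) and
#'   `truth` (factor loadings, spot/cell factor matrices, the noiseless
#'   log-mean ST surface `st_log_mean`, per-observation size factors, spot
#'   lattice coordinates and per-factor pattern labels).
#' @export
generate_paired <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  K <- cf$n_factors
  gene_ids <- sprintf("gene%04d", seq_len(cf$n_sc_genes))
  shared <- gene_ids[seq_len(cf$n_shared_genes)]
  kinds <- rep(c("blob", "stripe", "gradient"), length.out = K)

  # gene x factor loadings: each gene has one dominant factor
  loadings <- with_seed(derive_seed(cf$seed, 1L), {
    primary <- rep_len(seq_len(K), cf$n_sc_genes)
    L <- matrix(stats::runif(cf$n_sc_genes * K, 0, 0.25), cf$n_sc_genes, K)
    L[cbind(seq_len(cf$n_sc_genes), primary)] <- stats::runif(cf$n_sc_genes, 2.0, 3.5)
    dimnames(L) <- list(gene_ids, paste0("factor", seq_len(K)))
    L
  })

  # cells: dominant state + background activity
  cell_factors <- with_seed(derive_seed(cf$seed, 2L), {
    state <- sample.int(K, cf$n_cells, replace = TRUE)
    Fc <- matrix(stats::runif(cf$n_cells * K, 0, 0.1), cf$n_cells, K)
    Fc[cbind(seq_len(cf$n_cells), state)] <- stats::runif(cf$n_cells, 1.5, 2.5)
    Fc
  })

  # spots: planted smooth spatial patterns per factor
  g <- cf$grid_side
  xy <- cbind(x = rep(seq_len(g), each = g), y = rep(seq_len(g), times = g))
  xy <- xy[seq_len(cf$n_spots), , drop = FALSE]
  spot_factors <- with_seed(derive_seed(cf$seed, 3L), {
    Fs <- vapply(seq_len(K),
                 function(k) 0.1 + 1.3 * planted_pattern(kinds[k], xy, g),
                 numeric(cf$n_spots))
    Fs <- matrix(Fs, nrow = cf$n_spots, ncol = K)
    # sharpen the [0,1] patterns (squaring keeps them non-negative and
    # monotone in the planted shape) and match each factor's mean
    # activation to the cell side multiplicatively, so the factor-weighted
    # pseudo-bulk profiles of the two modalities coincide while the
    # spatial contrast stays comparable to the cell-state contrast
    Fs <- ((Fs - 0.1) / 1.3)^2
    sweep(Fs, 2, colMeans(cell_factors) / pmax(colMeans(Fs), 1e-8), "*")
  })

  # Counts are rounded exponentials of the factor model. The log-predictor
  # is centered per observation (each row's mean expression is pinned to
  # `base_mean`), which mimics the compositional nature of sequencing: the
  # observation's total depth is governed by its lognormal size factor
  # alone, and the planted patterns live in the relative (per-gene)
  # composition, so they survive library-size normalization.
  # base_mean sets the expected count depth; it is high enough that
  # rounding produces few extra zeros, so the observed zero fraction is
  # governed directly by the Bernoulli dropout
  base_mean <- 25
  centered_eta <- function(factors, L) {
    eta <- factors %*% t(L)
    eta - log(rowMeans(exp(eta))) + log(base_mean)
  }
  synth_counts <- function(eta, sizef, dropout, noise_sd) {
    if (noise_sd > 0)
      eta <- eta + stats::rnorm(length(eta), sd = noise_sd)
    counts <- round(sizef * exp(eta))
    if (dropout > 0) {
      keep <- matrix(stats::rbinom(length(counts), 1L, 1 - dropout),
                     nrow(counts), ncol(counts))
      counts <- counts * keep
    }
    counts
  }
  st_log_mean <- centered_eta(spot_factors, loadings[shared, , drop = FALSE])
  dimnames(st_log_mean) <- list(sprintf("spot%04d", seq_len(cf$n_spots)), shared)

  sc_sizef <- with_seed(derive_seed(cf$seed, 6L),
                        stats::rlnorm(cf$n_cells, 0, 0.3))
  st_sizef <- with_seed(derive_seed(cf$seed, 7L),
                        stats::rlnorm(cf$n_spots, 0, 0.3))

  sc_counts <- with_seed(derive_seed(cf$seed, 4L), {
    counts <- synth_counts(centered_eta(cell_factors, loadings), sc_sizef,
                           cf$dropout_sc, cf$noise_sd)
    dimnames(counts) <- list(sprintf("cell%04d", seq_len(cf$n_cells)), gene_ids)
    counts
  })

  st_counts <- with_seed(derive_seed(cf$seed, 5L), {
    counts <- synth_counts(st_log_mean, st_sizef, cf$dropout_st,
                           cf$noise_sd)
    counts
  })

  st <- expression_matrix(st_counts, modality = "ST", layer = "counts")
  sc <- expression_matrix(sc_counts, modality = "SC", layer = "counts")
  truth <- structure(list(factor_loadings = loadings,
                          spot_factors = spot_factors,
                          cell_factors = cell_factors,
                          st_log_mean = st_log_mean,
                          st_size_factors = st_sizef,
                          sc_size_factors = sc_sizef,
                          spot_coords = xy,
                          spatial_pattern_ids = kinds),
                     class = "synth_truth")
  list(dataset = paired_dataset(st, sc), truth = truth)
}
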