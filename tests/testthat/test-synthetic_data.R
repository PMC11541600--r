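test_that("generation is deterministic under a fixed seed", {
  a <- generate_paired(synth_config(seed = 7))
  b <- generate_paired(synth_config(seed = 7))
  expect_identical(a$dataset$st$values, b$dataset$st$values)
  expect_identical(a$dataset$sc$values, b$dataset$sc$values)
  expect_identical(a$truth$factor_loadings, b$truth$factor_loadings)
  c <- generate_paired(synth_config(seed = 8))
  expect_false(identical(a$dataset$st$values, c$dataset$st$values))
})

test_that("counts are non-negative integers with consistent shapes", {
  g <- generate_paired(synth_config(seed = 3))
  cf <- synth_config()
  expect_true(all(g$dataset$st$values >= 0))
  expect_true(all(g$dataset$sc$values >= 0))
  expect_identical(g$dataset$st$values, round(g$dataset$st$values))
  expect_identical(dim(g$dataset$sc$values), c(cf$n_cells, cf$n_sc_genes))
  expect_identical(dim(g$dataset$st$values), c(cf$n_spots, cf$n_shared_genes))
  expect_identical(g$dataset$shared_genes, g$dataset$st$gene_ids)
  expect_identical(dim(g$truth$spot_factors), c(cf$n_spots, cf$n_factors))
  expect_identical(dim(g$truth$cell_factors), c(cf$n_cells, cf$n_factors))
})

test_that("observed zero fraction tracks the configured dropout", {
  # direct Monte-Carlo count of zeros on a 200 x 500 matrix
  g <- generate_paired(synth_config(n_spots = 200L, grid_side = 15L,
                                    n_sc_genes = 500L, n_shared_genes = 500L,
                                    dropout_st = 0.8, seed = 1))
  expect_lt(abs(mean(g$dataset$st$values == 0) - 0.8), 0.05)
  g2 <- generate_paired(synth_config(seed = 2))
  expect_lt(abs(mean(g2$dataset$st$values == 0) - 0.6), 0.05)
  # SC zeros: Bernoulli floor plus a bounded natural-zero excess from
  # low-abundance off-state genes
  sc_frac <- mean(g2$dataset$sc$values == 0)
  expect_gte(sc_frac, 0.7 - 0.01)
  expect_lt(sc_frac, 0.7 + 0.12)
})

test_that("no-noise no-dropout counts are an exact function of the stored truth", {
  g <- generate_paired(synth_config(n_cells = 40L, n_spots = 16L,
                                    grid_side = 4L, n_sc_genes = 20L,
                                    n_shared_genes = 10L, n_factors = 2L,
                                    dropout_sc = 0, dropout_st = 0,
                                    noise_sd = 0, seed = 5))
  rec <- round(g$truth$st_size_factors * exp(g$truth$st_log_mean))
  expect_identical(unname(g$dataset$st$values), unname(rec))
})

test_that("paired modalities share loadings: pseudo-bulk profiles correlate", {
  for (s in 0:2) {
    g <- generate_paired(synth_config(noise_sd = 0, dropout_sc = 0,
                                      dropout_st = 0, seed = s))
    # factor-weighted pseudo-bulk: loadings applied to mean factor activity
    L <- g$truth$factor_loadings[g$dataset$shared_genes, ]
    fw_sc <- L %*% colMeans(g$truth$cell_factors)
    fw_st <- L %*% colMeans(g$truth$spot_factors)
    expect_gt(cor(fw_sc, fw_st), 0.9)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_sc_genes = 0), "positive")
  expect_error(synth_config(n_shared_genes = 400), "n_shared_genes")
  expect_error(synth_config(dropout_st = 1), "dropout")
  expect_error(synth_config(grid_side = 3, n_spots = 64), "grid_side")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
})
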