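test_that("pcc handles exact, anti- and constant correlation", {
  x <- c(0.3, 1.7, 2.2, 5)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  # independent oracle: explicit Pearson formula
  a <- c(1, 2, 3); b <- c(1, 2, 4)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pcc(a, b), r_hand, tolerance = 1e-6)
  expect_equal(round(r_hand, 5), 0.98198)
  expect_warning(z <- pcc(rep(1, 4), x), "constant")
  expect_equal(z, 0)
  expect_error(pcc(1:3, 1:4), "length")
})

test_that("rmse matches the direct formula and the z-score invariance", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4), scale = FALSE), sqrt(12.5),
               tolerance = 1e-12)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(rmse(x, y), rmse(x + 5, y + 5), tolerance = 1e-12)
  expect_equal(rmse(x, y), rmse(3 * x, y), tolerance = 1e-12)
})

test_that("js_divergence is base-2, bounded and matches direct summation", {
  expect_equal(js_divergence(c(1, 2, 3), c(2, 4, 6)), 0, tolerance = 1e-9)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1, tolerance = 1e-6)
  # independent oracle: direct evaluation of the definition
  p <- c(0.5, 0.5); q <- c(0.9, 0.1); m <- (p + q) / 2
  kl <- function(a, b) sum(a * log2(a / b))
  js_hand <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  expect_equal(js_divergence(p, q), js_hand, tolerance = 1e-6)
  # negative values are shifted before normalization
  expect_gte(js_divergence(c(-1, 0, 2), c(1, 1, 1)), 0)
  expect_error(js_divergence(c(0, 0), c(1, 1)), "all-zero")
})

test_that("ssim matches the stabilized formula and is symmetric", {
  x <- runif(30)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  y <- runif(30)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  # degenerate constant case, no rescaling: governed by the C1 stabilizer
  c1 <- 0.01^2; c2 <- 0.03^2
  hand <- ((2 * 0 * 1 + c1) * (0 + c2)) / ((0 + 1 + c1) * (0 + c2))
  expect_equal(ssim(rep(0, 5), rep(1, 5), scale = FALSE), hand,
               tolerance = 1e-12)
  expect_true(abs(ssim(x, y)) <= 1 + 1e-12)
})

test_that("accuracy_score reproduces hand-ranked composites", {
  # method A best on everything -> AS 1; C worst on everything -> AS 0
  tab <- list(
    A = list(pcc = 0.9, ssim = 0.8, rmse = 0.5, js = 0.1),
    B = list(pcc = 0.7, ssim = 0.6, rmse = 0.7, js = 0.2),
    C = list(pcc = 0.5, ssim = 0.4, rmse = 0.9, js = 0.3))
  as3 <- accuracy_score(tab)
  expect_equal(unname(as3["A"]), 1)
  expect_equal(unname(as3["C"]), 0)
  expect_equal(unname(as3["B"]), 0.5)
  # hand-built mixed ranking: B best on pcc+ssim, A best on rmse+js
  tab2 <- list(
    A = list(pcc = 0.5, ssim = 0.5, rmse = 0.5, js = 0.1),
    B = list(pcc = 0.9, ssim = 0.9, rmse = 0.9, js = 0.3))
  as2 <- accuracy_score(tab2)
  expect_equal(unname(as2["A"]), 0.5)
  expect_equal(unname(as2["B"]), 0.5)
  # ties share the average rank
  tabt <- list(
    A = list(pcc = 0.5, ssim = 0.5, rmse = 1, js = 0.1),
    B = list(pcc = 0.5, ssim = 0.5, rmse = 2, js = 0.2))
  ast <- accuracy_score(tabt)
  expect_equal(unname(ast["A"]), 1 - mean(c(0.5, 0.5, 0, 0)))
  expect_error(accuracy_score(tab[1]), "at least 2")
  expect_error(accuracy_score(list(A = list(pcc = 1), B = list(pcc = 2))),
               "missing metric")
})

test_that("downsample_counts thins binomially with rate = fraction removed", {
  v <- matrix(rpois(5000, 20), 50, 100,
              dimnames = list(NULL, sprintf("g%03d", 1:100)))
  m <- expression_matrix(v, modality = "ST", layer = "counts")
  expect_identical(downsample_counts(m, 0, seed = 1)$values, m$values)
  d <- downsample_counts(m, 0.5, seed = 1)
  tot <- sum(v)
  # binomial expectation: kept total ~ Binomial(tot, 0.5)
  expect_lt(abs(sum(d$values) - 0.5 * tot), 4 * sqrt(tot * 0.25))
  expect_true(all(d$values[v == 0] == 0))
  expect_true(all(d$values <= v))
  expect_identical(d$values, downsample_counts(m, 0.5, seed = 1)$values)
  norm <- normalize_st(m)
  expect_error(downsample_counts(norm, 0.5, seed = 1), "counts")
})

test_that("robustness_score counts strict joint exceedance", {
  po <- c(a = 0.6, b = 0.6, c = 0.4, d = 0.4)
  pd <- c(a = 0.6, b = 0.4, c = 0.6, d = 0.4)
  expect_equal(robustness_score(po, pd), 0.25)
  expect_equal(robustness_score(c(a = 1, b = 1), c(a = 0.9, b = 0.8)), 1)
  # exactly 0.5 does not count
  expect_equal(robustness_score(c(a = 0.5), c(a = 0.9)), 0)
  # monotone non-increasing in the threshold
  set.seed(1)
  po <- setNames(runif(50), paste0("g", 1:50))
  pd <- setNames(runif(50), paste0("g", 1:50))
  rs <- sapply(c(0.2, 0.4, 0.6, 0.8), function(th)
    robustness_score(po, pd, threshold = th))
  expect_true(all(diff(rs) <= 0))
  expect_error(robustness_score(po, pd[-1]), "match")
})

test_that("metric_report aggregates per-gene metrics", {
  set.seed(2)
  truth <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("g", 1:4)))
  pred <- truth + rnorm(40, sd = 0.2)
  rep <- metric_report(pred, truth)
  expect_identical(nrow(rep$per_gene), 4L)
  expect_true(all(rep$per_gene$pcc > 0.5))
  expect_identical(rep$aggregate$metric, c("pcc", "ssim", "rmse", "js"))
  expect_equal(rep$aggregate$mean[1], mean(rep$per_gene$pcc))
})
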