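test_that("structural similarity is one for identical images and symmetric", {
  img <- renderPhantom(tinyPhantomSpec())
  expect_equal(ssi(img, img), 1, tolerance = 1e-9)
  expect_equal(ssi(img, img, MetricConfig(ssiMode = "global")), 1,
               tolerance = 1e-9)
  other <- degradeImage(img, tinyDegradationSpec())
  expect_equal(ssi(img, other), ssi(other, img), tolerance = 1e-12)
  expect_error(ssi(img, img[1:32, 1:32]), "dimensions")
})

test_that("global-mode structural similarity matches the constant-image formula", {
  a <- 0.6; b <- 0.3
  C1 <- 0.01^2
  H <- matrix(a, 16, 16); Hp <- matrix(b, 16, 16)
  cfg <- MetricConfig(ssiMode = "global")
  expect_equal(ssi(H, Hp, cfg), (2 * a * b + C1) / (a^2 + b^2 + C1),
               tolerance = 1e-12)
  # windowed and global agree exactly on constant images
  expect_equal(ssi(H, Hp, MetricConfig()), ssi(H, Hp, cfg), tolerance = 1e-12)
})

test_that("local correlation is affine-invariant and sign-sensitive", {
  img <- renderPhantom(tinyPhantomSpec(seed = 13L))
  expect_equal(lncc(img, img), 1, tolerance = 1e-5)
  expect_equal(lncc(img, 0.5 * img + 0.2), 1, tolerance = 1e-5)
  z <- img - mean(img)
  expect_equal(lncc(z, -z), -1, tolerance = 1e-5)
  d <- degradeImage(img, tinyDegradationSpec())
  v <- lncc(img, d)
  expect_gte(v, -1); expect_lte(v, 1)
})

test_that("peak signal-to-noise ratio matches closed-form arithmetic", {
  cfg8 <- MetricConfig(dataRange = 255)
  H <- matrix(100, 24, 24)
  expect_identical(psnr(H, H), Inf)
  expect_equal(psnr(H, H + 16, cfg8), 10 * log10(255^2 / 256),
               tolerance = 1e-9)
  expect_equal(psnr(matrix(0, 8, 8), matrix(255, 8, 8), cfg8), 0,
               tolerance = 1e-12)
})

test_that("perceptual metric delegates to the feature distance", {
  fx <- tinyExtractor()
  img <- renderPhantom(tinyPhantomSpec())
  expect_identical(lpipsMetric(img, img, fx), 0)
  other <- degradeImage(img, tinyDegradationSpec())
  expect_equal(lpipsMetric(img, other, fx), lpipsMetric(other, img, fx),
               tolerance = 1e-12)
  idfx <- identityFeatureExtractor()
  expect_equal(lpipsMetric(matrix(0.75, 1, 1), matrix(0.25, 1, 1), idfx), 4,
               tolerance = 1e-6)
})

test_that("dataset evaluation reproduces the ideal vector on perfect pairs", {
  img <- renderPhantom(tinyPhantomSpec())
  pairs <- list(ImagePair("a", img, img, TRUE),
                ImagePair("b", img * 0.5, img * 0.5, TRUE))
  fx <- tinyExtractor()
  rep <- evaluateDataset(pairs, enhancer = NULL, fx = fx)
  expect_equal(unname(rep@means["ssi"]), 1, tolerance = 1e-9)
  expect_equal(unname(rep@means["lncc"]), 1, tolerance = 1e-5)
  expect_equal(unname(rep@means["psnr"]), 100)  # capped, flagged
  expect_true(rep@psnrCapped)
  expect_equal(unname(rep@means["lpips"]), 0)
  expect_error(evaluateDataset(list(), fx = fx), "empty")
})

test_that("report means equal recomputed column means", {
  pairs <- smallDataset()
  fx <- tinyExtractor()
  rep <- evaluateDataset(pairs, enhancer = NULL, fx = fx)
  pp <- perPairMetrics(rep)
  expect_equal(unname(metricMeans(rep)),
               unname(c(mean(pp$ssi), mean(pp$lncc), mean(pp$psnr),
                        mean(pp$lpips))),
               tolerance = 1e-9)
  expect_true(is.finite(rep@means["psnr"]))
  expect_false(rep@psnrCapped)
})

test_that("one-sided Wilcoxon test matches exact enumeration", {
  b <- as.numeric(1:10)
  a <- b + (1:10) / 20  # distinct positive differences: no ties, exact test
  # all ten differences positive: p = 1 / 2^10
  expect_equal(wilcoxonOneSided(a, b, "greater"), 1 / 1024, tolerance = 1e-12)
  expect_gt(wilcoxonOneSided(a, b, "less"), 0.99)
  expect_warning(p <- wilcoxonOneSided(a, a), "zero")
  expect_true(is.na(p))
  expect_error(wilcoxonOneSided(1:4, 2:5), "5")
  expect_error(wilcoxonOneSided(1:10, 1:9), "paired")
})

test_that("report comparison orients each metric correctly", {
  pairs <- smallDataset()
  fx <- tinyExtractor()
  base <- evaluateDataset(pairs, enhancer = NULL, fx = fx)
  perfect <- evaluateDataset(lapply(pairs, function(p)
    ImagePair(p@id, p@high, p@high, TRUE)), enhancer = NULL, fx = fx)
  cmp <- compareReports(perfect, base)
  expect_identical(cmp$metric, c("ssi", "lncc", "psnr", "lpips"))
  expect_true(all(cmp$pValue < 0.05))
})
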