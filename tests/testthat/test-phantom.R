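test_that("phantom rendering is deterministic and intensity-closed", {
  spec <- tinyPhantomSpec()
  a <- renderPhantom(spec)
  b <- renderPhantom(spec)
  expect_identical(a, b)
  expect_identical(dim(a), c(64L, 64L))
  expect_gte(min(a), 0)
  expect_lte(max(a), 1)
})

test_that("speckle variance vanishes in the many-looks limit", {
  spec <- PhantomSpec(sideLength = 64L, nInclusions = 0L,
                      backgroundEchogenicity = 0.35,
                      speckleLooksHigh = 1e6, seed = 3L)
  img <- renderPhantom(spec)
  expect_lt(max(abs(img - 0.35)), 0.01)

  flat <- matrix(0.4, 32, 32)
  out <- applySpeckle(flat, looks = 1e6, seed = 11L)
  expect_lt(max(abs(out - flat)), 0.01)
})

test_that("multiplicative speckle preserves zero and rejects bad looks", {
  z <- matrix(0, 16, 16)
  expect_identical(applySpeckle(z, looks = 4, seed = 1L), z)
  expect_error(applySpeckle(z, looks = 0), "looks")
  expect_error(applySpeckle(z, looks = -2), "looks")
})

test_that("speckle field has unit mean and variance 1/looks", {
  f <- speckleField(256, 256, looks = 4, seed = 21L)
  expect_lt(abs(mean(f) - 1), 0.02)
  expect_lt(abs(var(as.numeric(f)) - 0.25), 0.02)
})

test_that("echogenicity map carries at least two distinct modes", {
  spec <- tinyPhantomSpec(seed = 7L)
  # oracle: the noiseless map rendered without speckle
  oracle <- echoGAN:::renderEchogenicityMap(spec)
  modes <- unique(as.numeric(oracle))
  expect_gte(length(modes), 2L)
  # the speckled image keeps the mode separation in its conditional means
  img <- renderPhantom(spec)
  inside <- oracle != spec@backgroundEchogenicity
  expect_gt(mean(img[inside]), mean(img[!inside]) + 0.05)
})

test_that("identity degradation configuration passes the image through", {
  high <- renderPhantom(tinyPhantomSpec())
  low <- degradeImage(high, identityDegradationSpec())
  expect_lt(max(abs(low - high)), 0.01)
})

test_that("increasing blur strictly decreases fidelity", {
  high <- renderPhantom(tinyPhantomSpec())
  vals <- vapply(c(0.5, 1, 2, 4), function(s) {
    d <- identityDegradationSpec()
    d@psfSigma <- s
    psnr(high, degradeImage(high, d))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("degradation respects the registration contract and divisibility", {
  spec <- tinyDegradationSpec()
  spec@warpAmplitude <- 0
  pairs <- makeDataset(2, tinyPhantomSpec(), spec, seed = 1L)
  expect_true(all(vapply(pairs, function(p) p@registered, logical(1))))
  pairs2 <- makeDataset(2, tinyPhantomSpec(), tinyDegradationSpec(), seed = 1L)
  expect_false(any(vapply(pairs2, function(p) p@registered, logical(1))))

  bad <- tinyDegradationSpec()
  bad@downsampleFactor <- 3L
  expect_error(degradeImage(renderPhantom(tinyPhantomSpec()), bad),
               "does not divide")
})

test_that("datasets have unique identifiers and reproduce under a seed", {
  a <- makeDataset(10, tinyPhantomSpec(), tinyDegradationSpec(), seed = 42L)
  expect_length(a, 10L)
  ids <- vapply(a, function(p) p@id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  b <- makeDataset(10, tinyPhantomSpec(), tinyDegradationSpec(), seed = 42L)
  expect_identical(lapply(a, function(p) p@low), lapply(b, function(p) p@low))
  expect_identical(lapply(a, function(p) p@high), lapply(b, function(p) p@high))
  expect_error(makeDataset(0, tinyPhantomSpec(), tinyDegradationSpec()), "nPairs")
  rng <- range(unlist(lapply(a, function(p) c(p@low, p@high))))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
})

test_that("invalid specification fields are reported by name", {
  expect_error(PhantomSpec(sideLength = 48L), "sideLength")
  expect_error(PhantomSpec(backgroundEchogenicity = 1.2), "backgroundEchogenicity")
  expect_error(PhantomSpec(inclusionAxisRange = c(10, 5)), "inclusionAxisRange")
  expect_error(PhantomSpec(speckleLooksHigh = 0), "speckleLooksHigh")
  expect_error(DegradationSpec(psfSigma = -1), "psfSigma")
  expect_error(DegradationSpec(contrastGamma = 0), "contrastGamma")
})

test_that("degradation hurts: mean PSNR below the identity case", {
  pairs <- smallDataset()
  base <- mean(vapply(pairs, function(p) psnr(p@high, p@low), numeric(1)))
  expect_true(is.finite(base))
  expect_lt(base, 100)
})
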