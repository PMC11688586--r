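test_that("generator preserves shape and emits tanh-bounded values", {
  g <- buildGenerator(tinyGeneratorSpec(), seed = 1L)
  x <- array(runif(64 * 64 * 2) * 2 - 1, c(64, 64, 2, 1))
  out <- generatorForward(g, x)
  expect_identical(dim(out), dim(x))
  expect_gte(min(out), -1)
  expect_lte(max(out), 1)
  # default-depth UNet on the paper-scale input
  gd <- buildGenerator(GeneratorSpec(baseChannels = 4L), seed = 1L)
  xb <- array(0.1, c(256, 256, 1, 1))
  expect_identical(dim(generatorForward(gd, xb)), dim(xb))
})

test_that("first encoder stage of the default generator emits 64 channels", {
  g <- buildGenerator(GeneratorSpec(), seed = 1L)
  expect_identical(dim(g@params$enc[[1]]$w$val)[4], 64L)
})

test_that("generator forward is deterministic in evaluation mode", {
  g <- buildGenerator(tinyGeneratorSpec(), seed = 9L)
  x <- array(runif(64 * 64) * 2 - 1, c(64, 64, 1, 1))
  expect_identical(generatorForward(g, x), generatorForward(g, x))
})

test_that("generator rejects indivisible sizes and wrong channel counts", {
  g <- buildGenerator(tinyGeneratorSpec(depth = 6L), seed = 1L)
  expect_error(generatorForward(g, array(0, c(48, 48, 1, 1))), "2\\^depth = 64")
  expect_error(generatorForward(g, array(0, c(64, 64, 1, 2))), "channels")
})

test_that("patch discriminator produces the documented score-map sizes", {
  d <- buildDiscriminator(DiscriminatorSpec(), seed = 1L)
  s256 <- discriminatorForward(d, array(0, c(256, 256, 1, 1)))
  expect_identical(dim(s256), c(30L, 30L, 1L, 1L))
  s128 <- discriminatorForward(d, array(0, c(128, 128, 1, 1)))
  expect_identical(dim(s128)[1:2], c(14L, 14L))
  s70 <- discriminatorForward(d, array(0, c(70, 70, 1, 1)))
  expect_identical(dim(s70)[1:2], c(6L, 6L))
})

test_that("spectral normalization matches the exact SVD oracle", {
  w <- diag(c(2, 0.5))
  expect_equal(spectralNormalize(w, 30L), diag(c(1, 0.25)), tolerance = 1e-6)

  q <- qr.Q(qr(matrix(rnorm(25), 5)))  # orthogonal: already 1-Lipschitz
  expect_equal(spectralNormalize(q, 30L), q, tolerance = 1e-3)

  set.seed(31)
  for (i in 1:5) {
    m <- matrix(rnorm(64), 8, 8)
    s <- svd(spectralNormalize(m, 30L))$d[1]
    expect_gte(s, 0.999)
    expect_lte(s, 1.001)
  }
  expect_warning(out <- spectralNormalize(matrix(0, 3, 3)), "all-zero")
  expect_identical(out, matrix(0, 3, 3))
  expect_error(spectralNormalize(matrix(1, 2, 2), 0L), "nPowerIterations")
})

test_that("every discriminator kernel is 1-Lipschitz after normalization", {
  d <- buildDiscriminator(tinyDiscriminatorSpec(), seed = 6L)
  invisible(discriminatorForward(d, array(0.2, c(32, 32, 1, 1)), train = TRUE))
  for (ly in d@params$layers) {
    wn <- spectralNormalize(ly$w$val, 30L)
    s <- svd(matrix(wn, ncol = dim(ly$w$val)[4]))$d[1]
    expect_lte(s, 1 + 1e-3)
  }
})

test_that("paired networks share an architecture but not parameters", {
  m <- tinyModels()
  expect_identical(nParameters(m$G_H), nParameters(m$G_L))
  expect_identical(nParameters(m$D_H), nParameters(m$D_L))
  expect_false(identical(m$G_H@params$enc[[1]]$w$val,
                         m$G_L@params$enc[[1]]$w$val))
})
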