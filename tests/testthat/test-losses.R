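identityG <- function(x) x

test_that("perceptual distance is a symmetric pre-metric", {
  fx <- tinyExtractor()
  set.seed(4)
  X <- array(runif(32 * 32) * 2 - 1, c(32, 32, 1, 1))
  Y <- array(runif(32 * 32) * 2 - 1, c(32, 32, 1, 1))
  expect_identical(lpipsDistance(fx, X, X), 0)
  expect_gte(lpipsDistance(fx, X, Y), 0)
  expect_equal(lpipsDistance(fx, X, Y), lpipsDistance(fx, Y, X),
               tolerance = 1e-12)
  expect_error(lpipsDistance(fx, X, array(0, c(16, 16, 1, 1))), "shape")
})

test_that("degenerate one-pixel extractor reproduces the analytic distance", {
  # channel normalization maps +a and -b to +1 and -1: distance (1-(-1))^2 = 4
  fx <- identityFeatureExtractor()
  X <- array(0.7, c(1, 1, 1, 1))
  Y <- array(-0.3, c(1, 1, 1, 1))
  expect_equal(lpipsDistance(fx, X, Y), 4, tolerance = 1e-6)
  # both generator directions contribute: 4 + 4
  expect_equal(perceptualTerm(X, Y, identityG, identityG, fx), 8,
               tolerance = 1e-5)
  expect_equal(perceptualTerm(X, X, identityG, identityG, fx), 0)
})

test_that("adversarial term matches its constant-map values", {
  ones <- matrix(1, 6, 6)
  expect_identical(adversarialTerm(ones, ones), 0)
  expect_identical(adversarialTerm(ones * 0, ones * 0), 2)
  expect_identical(adversarialTerm(ones * 0.5, ones * 0.5), 0.5)
  expect_error(adversarialTerm(numeric(0), ones), "non-empty")
})

test_that("cycle term vanishes for inverse pairs and matches the shift stub", {
  L <- array(runif(16 * 16), c(16, 16, 1, 1))
  expect_identical(cycleTerm(L, L, identityG, identityG), 0)
  plus <- function(x) x + 0.3; minus <- function(x) x - 0.3
  expect_lt(cycleTerm(L, L, minus, plus), 1e-12)
  # identity-plus-0.1 in both directions on zero images: each round trip
  # shifts by 0.2, so the term is 0.2 + 0.2
  z <- array(0, c(8, 8, 1, 1))
  shift <- function(x) x + 0.1
  expect_equal(cycleTerm(z, z, shift, shift), 0.4, tolerance = 1e-12)
})

test_that("L1 term matches constant offsets and the one-direction flag", {
  L <- array(runif(16 * 16), c(16, 16, 1, 1))
  H <- L + 0.2
  expect_identical(l1Term(L, L, identityG, identityG), 0)
  expect_equal(l1Term(L, H, identityG, identityG), 0.4, tolerance = 1e-12)
  plus <- function(x) x + 0.2
  expect_equal(l1Term(L, H, identityG, plus), 0.2, tolerance = 1e-12)
  expect_equal(l1Term(L, H, identityG, plus, bothDirections = FALSE), 0,
               tolerance = 1e-12)
})

test_that("aggregate loss recombines with the default weights", {
  expect_identical(totalGeneratorLoss(0, 0, 0, 0), 0)
  expect_identical(totalGeneratorLoss(1, 1, 1, 1), 23)
  expect_identical(totalGeneratorLoss(2, 0, 0, 0), 2)
  expect_error(totalGeneratorLoss(1, NaN, 0, 0), "cycle")
  expect_error(totalGeneratorLoss(Inf, 0, 0, 0), "adv")
})

test_that("aggregate loss is linear in its lambda weights", {
  set.seed(8)
  comp <- runif(4)
  w1 <- LossWeights(0.5, 3, 1, 7)
  w2 <- LossWeights(2, 1, 4, 0.5)
  wsum <- LossWeights(2.5, 4, 5, 7.5)
  expect_equal(totalGeneratorLoss(comp[1], comp[2], comp[3], comp[4], w1) +
                 totalGeneratorLoss(comp[1], comp[2], comp[3], comp[4], w2),
               totalGeneratorLoss(comp[1], comp[2], comp[3], comp[4], wsum),
               tolerance = 1e-12)
})

test_that("label smoothing rule follows the score-mean condition", {
  expect_identical(realLabel(0.5, 0.3), 1.0)
  expect_identical(realLabel(0.95, 0.92), 0.9)
  expect_identical(realLabel(0.9, 0.9), 0.9)   # strict inequality
  expect_identical(realLabel(0.95, 0.5), 0.9)
  expect_identical(realLabel(0.5, 0.95), 0.9)
})

test_that("discriminator term matches analytic constant-map cases", {
  m <- function(v) matrix(v, 5, 5)
  expect_identical(discriminatorTerm(m(0.9), m(0), 0.9), 0)
  expect_identical(discriminatorTerm(m(0), m(1), 1.0), 2)
  expect_equal(discriminatorTerm(m(0.8), m(0.1), 0.9), 0.02, tolerance = 1e-12)
})

test_that("generator gradients are finite and not identically zero", {
  m <- tinyModels()
  fx <- tinyExtractor()
  pairs <- smallDataset()[1:2]
  ab <- echoGAN:::pairsToArrays(pairs)
  tape <- echoGAN:::tapeNew()
  L <- echoGAN:::agLeaf(tape, 2 * ab$low - 1)
  H <- echoGAN:::agLeaf(tape, 2 * ab$high - 1)
  fakeH <- echoGAN:::unetForward(tape, m$G_H, L)
  sFH <- discriminatorForward(m$D_H, fakeH, tape = tape)
  total <- echoGAN:::agWeightedSum(tape, list(
    echoGAN:::agMseToConst(tape, sFH, 1),
    echoGAN:::agMeanAbsDiff(tape, fakeH, H),
    lpipsDistance(fx, H, fakeH, tape = tape)), c(1, 2, 10))
  echoGAN:::agBackward(tape, total)
  grads <- lapply(echoGAN:::parameterList(m$G_H), function(p) p$grad)
  expect_true(all(vapply(grads, function(g) is.null(g) || all(is.finite(g)),
                         logical(1))))
  gnorm <- sum(vapply(grads, function(g) if (is.null(g)) 0 else sum(g^2),
                      numeric(1)))
  expect_gt(gnorm, 0)
})
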