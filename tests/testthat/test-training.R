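test_that("split sizes follow the floor rule with remainder to training", {
  pairs1050 <- as.list(seq_len(1050))
  sp <- splitDataset(pairs1050, SplitSpec(seed = 2L))
  expect_identical(lengths(sp), c(train = 735L, val = 105L, test = 210L))
  sp10 <- splitDataset(as.list(1:10), SplitSpec(seed = 2L))
  expect_identical(lengths(sp10), c(train = 7L, val = 1L, test = 2L))
  expect_error(splitDataset(as.list(1:2)), "fewer")
})

test_that("splits are seed-reproducible, disjoint and exhaustive", {
  pairs <- as.list(1:37)
  a <- splitDataset(pairs, SplitSpec(seed = 5L))
  b <- splitDataset(pairs, SplitSpec(seed = 5L))
  expect_identical(a, b)
  all <- c(unlist(a$train), unlist(a$val), unlist(a$test))
  expect_identical(sort(all), 1:37)
  expect_identical(anyDuplicated(all), 0L)
})

test_that("learning rate follows the step-decay schedule", {
  cfg <- TrainConfig()
  expect_identical(lrAtEpoch(cfg, 0), 3e-4)
  expect_identical(lrAtEpoch(cfg, 150), 1.5e-4)
  expect_identical(lrAtEpoch(cfg, 299), 7.5e-5)
  expect_error(lrAtEpoch(cfg, -1), "non-negative")
  trace <- lrAtEpoch(cfg, 0:299)
  expect_true(all(diff(trace) <= 0))
  expect_identical(which(diff(trace) < 0), c(100L, 200L))
})

test_that("a training step moves every network and records consistent losses", {
  m <- tinyModels()
  fx <- tinyExtractor()
  ab <- echoGAN:::pairsToArrays(smallDataset()[1:2])
  before <- lapply(m, copyParamValues)
  set.seed(1)
  rec <- trainStep(m, 2 * ab$low - 1, 2 * ab$high - 1, fx)
  expect_true(all(is.finite(rec)))
  w <- LossWeights()
  expect_equal(rec[["total"]],
               w@lambdaAdv * rec[["adv"]] + w@lambdaCycle * rec[["cycle"]] +
                 w@lambdaL1 * rec[["l1"]] + w@lambdaPer * rec[["perceptual"]],
               tolerance = 1e-6)
  for (nm in names(m)) {
    after <- copyParamValues(m[[nm]])
    moved <- any(mapply(function(a, b) any(a != b), before[[nm]], after))
    expect_true(moved, label = paste("parameters of", nm, "moved"))
  }
})

test_that("zero loss weights leave the generators untouched", {
  m <- tinyModels()
  fx <- tinyExtractor()
  ab <- echoGAN:::pairsToArrays(smallDataset()[1:2])
  before <- lapply(m[c("G_H", "G_L")], copyParamValues)
  set.seed(1)
  trainStep(m, 2 * ab$low - 1, 2 * ab$high - 1, fx,
            weights = LossWeights(0, 0, 0, 0))
  for (nm in c("G_H", "G_L"))
    expect_identical(copyParamValues(m[[nm]]), before[[nm]])
})

test_that("the generator update never touches discriminator parameters", {
  m <- tinyModels()
  fx <- tinyExtractor()
  ab <- echoGAN:::pairsToArrays(smallDataset()[1:2])
  discBefore <- lapply(m[c("D_H", "D_L")], copyParamValues)
  tape <- echoGAN:::tapeNew()
  L <- echoGAN:::agLeaf(tape, 2 * ab$low - 1)
  H <- echoGAN:::agLeaf(tape, 2 * ab$high - 1)
  fakeH <- echoGAN:::unetForward(tape, m$G_H, L)
  sFH <- discriminatorForward(m$D_H, fakeH, train = TRUE, tape = tape)
  loss <- echoGAN:::agMseToConst(tape, sFH, 1)
  echoGAN:::agBackward(tape, loss)
  echoGAN:::adamStep(c(echoGAN:::parameterList(m$G_H)), 3e-4)
  for (nm in c("D_H", "D_L"))
    expect_identical(copyParamValues(m[[nm]]), discBefore[[nm]])
})

test_that("the feature extractor stays frozen across training steps", {
  m <- tinyModels()
  fx <- tinyExtractor()
  ab <- echoGAN:::pairsToArrays(smallDataset()[1:2])
  before <- lapply(fx@stages, function(s) list(w = s$w$val, b = s$b$val))
  set.seed(1)
  trainStep(m, 2 * ab$low - 1, 2 * ab$high - 1, fx)
  after <- lapply(fx@stages, function(s) list(w = s$w$val, b = s$b$val))
  expect_identical(before, after)
})

test_that("identical seeds reproduce the first training step bit-for-bit", {
  runOnce <- function() {
    m <- tinyModels()
    fx <- tinyExtractor()
    ab <- echoGAN:::pairsToArrays(smallDataset()[1:2])
    set.seed(77)
    trainStep(m, 2 * ab$low - 1, 2 * ab$high - 1, fx)
  }
  expect_identical(runOnce(), runOnce())
})

test_that("fitting runs end to end with history, schedule and checkpoints", {
  pairs <- smallDataset()
  out <- withr::local_tempdir()
  fit <- fitModel(pairs[1:6], pairs[7:8],
                  config = TrainConfig(epochs = 2L, batchSize = 4L,
                                       lossScaling = TRUE, seed = 3L),
                  generatorSpec = tinyGeneratorSpec(),
                  discriminatorSpec = tinyDiscriminatorSpec(),
                  fx = tinyExtractor(), outDir = out)
  expect_identical(nrow(fit$history), 2L)
  expect_identical(fit$history$lr,
                   lrAtEpoch(TrainConfig(epochs = 2L), 0:1))
  expect_true(all(is.finite(unlist(fit$history[, c("total", "val_psnr")]))))
  expect_true(file.exists(file.path(out, "checkpoint_latest.rds")))
  expect_true(file.exists(file.path(out, "checkpoint_best.rds")))
  log <- read.csv(file.path(out, "training_log.csv"))
  expect_identical(nrow(log), 4L)  # 2 epochs x ceil(6/4) batches
  expect_identical(names(log), c("epoch", "iter", "adv", "cycle", "l1",
                                 "perceptual", "total", "disc_H", "disc_L",
                                 "lr"))

  # checkpoint round trip preserves the enhancer exactly
  restored <- loadCheckpoint(file.path(out, "checkpoint_latest.rds"))
  low <- pairs[[1]]@low
  expect_identical(enhanceImages(fit$models, low), enhanceImages(restored, low))
  expect_error(fitModel(list(), pairs[7:8]), "empty")
})

test_that("enhancement preserves shape, range and eval-mode determinism", {
  g <- buildGenerator(tinyGeneratorSpec(), seed = 5L)
  low <- renderPhantom(tinyPhantomSpec())
  e1 <- enhanceImages(g, low)
  e2 <- enhanceImages(g, low)
  expect_identical(e1, e2)
  expect_identical(dim(e1), dim(low))
  expect_gte(min(e1), 0)
  expect_lte(max(e1), 1)
  named <- enhanceImages(g, list(a = low, b = low * 0.5))
  expect_identical(names(named), c("a", "b"))
})
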