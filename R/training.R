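#' Training and inference
#'
#' Alternating optimization of the two generators (jointly, on the weighted
#' adversarial + cycle + L1 + perceptual objective) and the two
#' discriminators (each on its own MSE term under the conditional
#' label-smoothing rule), with a step-decay learning-rate schedule and
#' checkpointing.
#'
#' @name training
NULL

#' Split a paired dataset into train/validation/test
#'
#' Deterministic seeded shuffle, then sizes \code{floor(fraction * n)} for
#' validation and test with the remainder assigned to training: a disjoint,
#' exhaustive partition.
#'
#' @param pairs list of \linkS4class{ImagePair} (at least 3).
#' @param spec a \linkS4class{SplitSpec}.
#' @return named list with elements \code{train}, \code{val}, \code{test}.
#' @export
splitDataset <- function(pairs, spec = SplitSpec()) {
  validObject(spec)
  n <- length(pairs)
  if (n < 3L) stop("fewer pairs than 3")
  nVal <- floor(spec@valFraction * n)
  nTest <- floor(spec@testFraction * n)
  nTrain <- n - nVal - nTest
  ord <- withr::with_seed(spec@seed, sample.int(n))
  list(train = pairs[ord[seq_len(nTrain)]],
       val = pairs[ord[nTrain + seq_len(nVal)]],
       test = pairs[ord[nTrain + nVal + seq_len(nTest)]])
}

#' Learning rate at a given epoch
#'
#' Step decay: \code{lrInitial * lrGamma^floor(epoch / lrStep)} (epochs are
#' 0-based). At defaults the rate halves every 100 epochs.
#'
#' @param cfg a \linkS4class{TrainConfig}.
#' @param epoch 0-based epoch index.
#' @return learning rate.
#' @export
lrAtEpoch <- function(cfg, epoch) {
  if (any(epoch < 0)) stop("epoch must be non-negative")
  cfg@lrInitial * cfg@lrGamma^floor(epoch / cfg@lrStep)
}

pairsToArrays <- function(pairs) {
  d <- dim(pairs[[1]]@low)
  n <- length(pairs)
  low <- array(unlist(lapply(pairs, function(p) p@low)), c(d, n, 1L))
  high <- array(unlist(lapply(pairs, function(p) p@high)), c(d, n, 1L))
  list(low = low, high = high)
}

allParameters <- function(models)
  c(parameterList(models$G_H), parameterList(models$G_L),
    parameterList(models$D_H), parameterList(models$D_L))

#' One alternating optimization step
#'
#' Performs one generator update (both generators jointly on the aggregate
#' weighted loss) followed by one update of each discriminator on its own
#' term, scoring detached copies of the current fakes, with the real-image
#' label chosen per discriminator from this step's mean scores. When
#' \code{lossScaling} the objective is multiplied by \code{scaleFactor}
#' before the backward pass and gradients are rescaled before the update.
#'
#' @param models named list with elements \code{G_H}, \code{G_L}, \code{D_H},
#'   \code{D_L}.
#' @param xL,xH paired batches, arrays (H, W, N, C) in [-1, 1].
#' @param fx frozen \linkS4class{FeatureExtractor}.
#' @param weights a \linkS4class{LossWeights}.
#' @param lr,beta1,beta2 Adam settings for this step.
#' @param lossScaling logical; \code{scaleFactor} the static scale.
#' @param l1BothDirections include the G_L(H) vs L direction in the L1 term.
#' @return named numeric loss record: adv, cycle, l1, perceptual, total,
#'   disc_H, disc_L.
#' @export
trainStep <- function(models, xL, xH, fx, weights = LossWeights(),
                      lr = 3e-4, beta1 = 0.9, beta2 = 0.999,
                      lossScaling = FALSE, scaleFactor = 1024,
                      l1BothDirections = TRUE) {
  scale <- if (lossScaling) scaleFactor else 1
  tape <- tapeNew()
  L <- agLeaf(tape, xL)
  H <- agLeaf(tape, xH)
  fakeH <- unetForward(tape, models$G_H, L, train = TRUE)
  fakeL <- unetForward(tape, models$G_L, H, train = TRUE)
  cycL <- unetForward(tape, models$G_L, fakeH, train = TRUE)
  cycH <- unetForward(tape, models$G_H, fakeL, train = TRUE)
  sFH <- discriminatorForward(models$D_H, fakeH, train = TRUE, tape = tape)
  sFL <- discriminatorForward(models$D_L, fakeL, train = TRUE, tape = tape)
  adv <- agWeightedSum(tape, list(agMseToConst(tape, sFH, 1),
                                  agMseToConst(tape, sFL, 1)))
  cyc <- agWeightedSum(tape, list(agMeanAbsDiff(tape, cycL, L),
                                  agMeanAbsDiff(tape, cycH, H)))
  l1terms <- list(agMeanAbsDiff(tape, fakeH, H))
  if (l1BothDirections) l1terms <- c(l1terms, list(agMeanAbsDiff(tape, fakeL, L)))
  l1 <- agWeightedSum(tape, l1terms)
  per <- agWeightedSum(tape, list(lpipsDistance(fx, H, fakeH, tape = tape),
                                  lpipsDistance(fx, L, fakeL, tape = tape)))
  lam <- c(weights@lambdaAdv, weights@lambdaCycle, weights@lambdaL1,
           weights@lambdaPer)
  total <- agWeightedSum(tape, list(adv, cyc, l1, per), lam)
  if (!is.finite(total$val)) {
    comp <- c(adv = adv$val, cycle = cyc$val, l1 = l1$val, perceptual = per$val)
    stop("non-finite loss component: ",
         paste(names(comp)[!is.finite(comp)], collapse = ", "))
  }
  agBackward(tape, total, seed = scale)
  genParams <- c(parameterList(models$G_H), parameterList(models$G_L))
  adamStep(genParams, lr, beta1, beta2, gradScale = scale)
  zeroGrads(allParameters(models))
  zeroGrads(unlist(lapply(fx@stages, function(s) list(s$w, s$b)),
                   recursive = FALSE))

  updateDisc <- function(disc, real, fakeDetached) {
    t2 <- tapeNew()
    sReal <- discriminatorForward(disc, real, train = TRUE, tape = t2)
    sFake <- discriminatorForward(disc, fakeDetached, train = TRUE, tape = t2)
    label <- realLabel(mean(sReal$val), mean(sFake$val))
    lossD <- agWeightedSum(t2, list(agMseToConst(t2, sReal, label),
                                    agMseToConst(t2, sFake, 0)))
    agBackward(t2, lossD, seed = scale)
    adamStep(parameterList(disc), lr, beta1, beta2, gradScale = scale)
    zeroGrads(parameterList(disc))
    lossD$val
  }
  dH <- updateDisc(models$D_H, xH, fakeH$val)
  dL <- updateDisc(models$D_L, xL, fakeL$val)
  c(adv = adv$val, cycle = cyc$val, l1 = l1$val, perceptual = per$val,
    total = total$val, disc_H = dH, disc_L = dL)
}

serializeParams <- function(obj) {
  lapply(parameterList(obj), function(p)
    list(val = p$val, m = p$m, v = p$v, t = p$t, u = p$u))
}

restoreParams <- function(obj, state) {
  pl <- parameterList(obj)
  stopifnot(length(pl) == length(state))
  for (i in seq_along(pl)) {
    # copies: optimizer updates are in place and must not touch the archive
    pl[[i]]$val <- state[[i]]$val + 0
    pl[[i]]$m <- state[[i]]$m + 0
    pl[[i]]$v <- state[[i]]$v + 0
    pl[[i]]$t <- state[[i]]$t
    if (!is.null(state[[i]]$u)) pl[[i]]$u <- state[[i]]$u
  }
  obj
}

#' Save / load a training checkpoint
#'
#' A checkpoint archives the two architecture specifications, all four
#' parameter sets with their optimizer state and power-iteration vectors,
#' the epoch counter and the training seed, under a version tag.
#'
#' @param models named list G_H, G_L, D_H, D_L.
#' @param file path of the checkpoint file.
#' @param epoch epochs completed.
#' @param seed training seed.
#' @export
saveCheckpoint <- function(models, file, epoch = 0L, seed = NA_integer_) {
  ck <- list(version = "echoGAN-checkpoint-1",
             generatorSpec = models$G_H@spec,
             discriminatorSpec = models$D_H@spec,
             epoch = as.integer(epoch), seed = seed,
             params = lapply(models[c("G_H", "G_L", "D_H", "D_L")],
                             serializeParams))
  saveRDS(ck, file)
  invisible(file)
}

#' @rdname saveCheckpoint
#' @return \code{loadCheckpoint}: a named list with the four rebuilt
#'   networks plus \code{epoch} and \code{seed}.
#' @export
loadCheckpoint <- function(file) {
  ck <- readRDS(file)
  if (!identical(ck$version, "echoGAN-checkpoint-1"))
    stop("unrecognized checkpoint version")
  models <- list(
    G_H = restoreParams(buildGenerator(ck$generatorSpec, "G_H"), ck$params$G_H),
    G_L = restoreParams(buildGenerator(ck$generatorSpec, "G_L"), ck$params$G_L),
    D_H = restoreParams(buildDiscriminator(ck$discriminatorSpec, "D_H"),
                        ck$params$D_H),
    D_L = restoreParams(buildDiscriminator(ck$discriminatorSpec, "D_L"),
                        ck$params$D_L))
  c(models, list(epoch = ck$epoch, seed = ck$seed))
}

#' Fit the enhancement model
#'
#' Runs the full alternating optimization over the training pairs with the
#' step-decay learning-rate schedule, evaluating the enhancer (G_H) on the
#' validation pairs after every epoch. When \code{outDir} is given, writes a
#' per-iteration CSV loss log, the latest checkpoint and the checkpoint with
#' the best validation value of \code{selectBy}.
#'
#' @param trainPairs,valPairs lists of \linkS4class{ImagePair}.
#' @param config a \linkS4class{TrainConfig}.
#' @param generatorSpec,discriminatorSpec architecture specifications.
#' @param fx frozen \linkS4class{FeatureExtractor} (perceptual backbone).
#' @param metricConfig \linkS4class{MetricConfig} for validation metrics.
#' @param outDir output directory (NULL keeps everything in memory).
#' @param selectBy validation metric for best-checkpoint selection.
#' @param verbose print per-epoch progress.
#' @return list with \code{models} (the four networks), \code{history}
#'   (per-epoch data.frame of mean losses, validation means and the learning
#'   rate) and \code{bestEpoch}.
#' @export
fitModel <- function(trainPairs, valPairs, config = TrainConfig(),
                     generatorSpec = GeneratorSpec(),
                     discriminatorSpec = DiscriminatorSpec(),
                     fx = randomFeatureExtractor(),
                     metricConfig = MetricConfig(), outDir = NULL,
                     selectBy = "psnr", verbose = FALSE) {
  if (length(trainPairs) == 0L) stop("empty training set")
  validObject(config)
  seeds <- withr::with_seed(config@seed, sample.int(2^30, 5L))
  models <- list(G_H = buildGenerator(generatorSpec, "G_H", seed = seeds[1]),
                 G_L = buildGenerator(generatorSpec, "G_L", seed = seeds[2]),
                 D_H = buildDiscriminator(discriminatorSpec, "D_H", seed = seeds[3]),
                 D_L = buildDiscriminator(discriminatorSpec, "D_L", seed = seeds[4]))
  nTrain <- length(trainPairs)
  nBatches <- ceiling(nTrain / config@batchSize)
  logPath <- if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    file.path(outDir, "training_log.csv")
  }
  if (!is.null(logPath))
    cat("epoch,iter,adv,cycle,l1,perceptual,total,disc_H,disc_L,lr\n",
        file = logPath)
  history <- NULL
  best <- -Inf
  bestEpoch <- NA_integer_
  lowerBetter <- selectBy == "lpips"
  withr::with_seed(seeds[5], {
    for (epoch in seq_len(config@epochs) - 1L) {
      lr <- lrAtEpoch(config, epoch)
      ord <- sample.int(nTrain)
      recs <- matrix(NA_real_, nBatches, 7L)
      for (b in seq_len(nBatches)) {
        idx <- ord[((b - 1L) * config@batchSize + 1L):min(b * config@batchSize, nTrain)]
        ab <- pairsToArrays(trainPairs[idx])
        rec <- trainStep(models, 2 * ab$low - 1, 2 * ab$high - 1, fx,
                         weights = config@lossWeights, lr = lr,
                         beta1 = config@beta1, beta2 = config@beta2,
                         lossScaling = config@lossScaling)
        recs[b, ] <- rec
        if (!is.null(logPath))
          cat(sprintf("%d,%d,%s,%g\n", epoch, b,
                      paste(sprintf("%.6g", rec), collapse = ","), lr),
              file = logPath, append = TRUE)
      }
      epochMeans <- colMeans(recs)
      names(epochMeans) <- c("adv", "cycle", "l1", "perceptual", "total",
                             "disc_H", "disc_L")
      valMeans <- c(ssi = NA_real_, lncc = NA_real_, psnr = NA_real_,
                    lpips = NA_real_)
      if (length(valPairs) > 0L) {
        rep <- evaluateDataset(valPairs, enhancer = models$G_H,
                               cfg = metricConfig, fx = fx)
        valMeans <- rep@means
      }
      history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                           t(epochMeans),
                                           val_ssi = valMeans["ssi"],
                                           val_lncc = valMeans["lncc"],
                                           val_psnr = valMeans["psnr"],
                                           val_lpips = valMeans["lpips"],
                                           row.names = NULL))
      score <- valMeans[[selectBy]]
      if (!is.na(score)) {
        score <- if (lowerBetter) -score else score
        if (score > best) {
          best <- score
          bestEpoch <- epoch
          if (!is.null(outDir))
            saveCheckpoint(models, file.path(outDir, "checkpoint_best.rds"),
                           epoch = epoch + 1L, seed = config@seed)
        }
      }
      if (!is.null(outDir))
        saveCheckpoint(models, file.path(outDir, "checkpoint_latest.rds"),
                       epoch = epoch + 1L, seed = config@seed)
      if (verbose)
        message(sprintf("epoch %d/%d  total %.4f  val PSNR %.2f", epoch + 1L,
                        config@epochs, epochMeans["total"], valMeans["psnr"]))
    }
  })
  list(models = models, history = history, bestEpoch = bestEpoch)
}

#' Enhance low-quality images
#'
#' Applies the trained enhancer G_H in evaluation mode (dropout disabled,
#' power-iteration vectors untouched) and maps outputs from [-1, 1] back to
#' [0, 1]. Identifiers and dimensions are preserved.
#'
#' @param models a model list from \code{\link{fitModel}} or
#'   \code{\link{loadCheckpoint}}, or a single \linkS4class{Generator}.
#' @param lows a matrix, or a named list of matrices, in [0, 1].
#' @return object of the same structure with enhanced images.
#' @export
enhanceImages <- function(models, lows) {
  g <- if (inherits(models, "Generator")) models else models$G_H
  one <- function(m) {
    out <- generatorForward(g, 2 * m - 1, train = FALSE)
    matrix(pmin(pmax((out + 1) / 2, 0), 1), nrow(m), ncol(m))
  }
  if (is.matrix(lows)) one(lows) else lapply(lows, one)
}
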