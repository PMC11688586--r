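#' @import methods
#' @importFrom stats rgamma rnorm runif setNames
#' @importFrom utils read.csv write.csv
#' @useDynLib echoGAN, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Phantom specification
#'
#' Parameters of the synthetic B-mode phantom: a piecewise-elliptical
#' echogenicity map (background plus elliptical inclusions) multiplied by
#' unit-mean multiplicative speckle whose variance is \code{1/speckleLooksHigh}.
#'
#' @slot sideLength image side in pixels (power of two).
#' @slot nInclusions number of elliptical inclusions.
#' @slot backgroundEchogenicity background intensity in [0,1].
#' @slot inclusionEchogenicityRange range of inclusion intensities in [0,1].
#' @slot inclusionAxisRange range of ellipse semi-axes in pixels.
#' @slot speckleLooksHigh number of looks of the clean (high-quality) member.
#' @slot seed integer seed making rendering deterministic.
#' @export
setClass("PhantomSpec", representation(
  sideLength = "integer", nInclusions = "integer",
  backgroundEchogenicity = "numeric", inclusionEchogenicityRange = "numeric",
  inclusionAxisRange = "numeric", speckleLooksHigh = "numeric",
  seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  s <- object@sideLength
  if (length(s) != 1L || s < 32L || bitwAnd(s, s - 1L) != 0L)
    msg <- c(msg, "sideLength must be a single power of two >= 32")
  if (object@nInclusions < 0L)
    msg <- c(msg, "nInclusions must be non-negative")
  if (object@backgroundEchogenicity < 0 || object@backgroundEchogenicity > 1)
    msg <- c(msg, "backgroundEchogenicity must lie in [0,1]")
  r <- object@inclusionEchogenicityRange
  if (length(r) != 2L || any(r < 0) || any(r > 1) || r[1] > r[2])
    msg <- c(msg, "inclusionEchogenicityRange must be an increasing pair in [0,1]")
  a <- object@inclusionAxisRange
  if (length(a) != 2L || any(a <= 0) || a[1] > a[2] || a[2] > s / 2)
    msg <- c(msg, "inclusionAxisRange must be positive, increasing, and fit inside the image")
  if (object@speckleLooksHigh <= 0)
    msg <- c(msg, "speckleLooksHigh must be positive")
  if (length(msg)) msg else TRUE
})

#' @param sideLength,nInclusions,backgroundEchogenicity,inclusionEchogenicityRange,inclusionAxisRange,speckleLooksHigh,seed see slots.
#' @rdname PhantomSpec-class
#' @export
PhantomSpec <- function(sideLength = 64L, nInclusions = 3L,
                        backgroundEchogenicity = 0.35,
                        inclusionEchogenicityRange = c(0.55, 0.9),
                        inclusionAxisRange = c(5, 14),
                        speckleLooksHigh = 4, seed = 1L) {
  new("PhantomSpec", sideLength = as.integer(sideLength),
      nInclusions = as.integer(nInclusions),
      backgroundEchogenicity = backgroundEchogenicity,
      inclusionEchogenicityRange = inclusionEchogenicityRange,
      inclusionAxisRange = inclusionAxisRange,
      speckleLooksHigh = speckleLooksHigh, seed = as.integer(seed))
}

#' Degradation specification
#'
#' How a high-quality phantom becomes its low-quality counterpart: a smooth
#' random warp (misregistration), Gaussian blur of the point-spread function,
#' resolution loss by down/up-sampling, gamma contrast compression and
#' re-speckling with fewer looks. Stages apply in that order.
#'
#' @slot psfSigma Gaussian blur standard deviation in pixels.
#' @slot downsampleFactor integer resolution-loss factor (must divide the side).
#' @slot speckleLooksLow number of looks of the re-speckling field.
#' @slot contrastGamma exponent of the intensity compression.
#' @slot warpAmplitude peak smooth displacement in pixels; 0 means the pair
#'   stays pixel-registered.
#' @slot warpScale smoothness (coarse-grid spacing) of the displacement field,
#'   in pixels.
#' @slot seed integer seed.
#' @export
setClass("DegradationSpec", representation(
  psfSigma = "numeric", downsampleFactor = "integer",
  speckleLooksLow = "numeric", contrastGamma = "numeric",
  warpAmplitude = "numeric", warpScale = "numeric", seed = "integer"))

setValidity("DegradationSpec", function(object) {
  msg <- character()
  if (object@psfSigma < 0) msg <- c(msg, "psfSigma must be non-negative")
  if (object@downsampleFactor < 1L)
    msg <- c(msg, "downsampleFactor must be a positive integer")
  if (object@speckleLooksLow <= 0)
    msg <- c(msg, "speckleLooksLow must be positive")
  if (object@contrastGamma <= 0)
    msg <- c(msg, "contrastGamma must be positive")
  if (object@warpAmplitude < 0) msg <- c(msg, "warpAmplitude must be non-negative")
  if (object@warpScale <= 0) msg <- c(msg, "warpScale must be positive")
  if (length(msg)) msg else TRUE
})

#' @param psfSigma,downsampleFactor,speckleLooksLow,contrastGamma,warpAmplitude,warpScale,seed see slots.
#' @rdname DegradationSpec-class
#' @export
DegradationSpec <- function(psfSigma = 2, downsampleFactor = 2L,
                            speckleLooksLow = 2, contrastGamma = 1.5,
                            warpAmplitude = 1, warpScale = 16, seed = 1L) {
  new("DegradationSpec", psfSigma = psfSigma,
      downsampleFactor = as.integer(downsampleFactor),
      speckleLooksLow = speckleLooksLow, contrastGamma = contrastGamma,
      warpAmplitude = warpAmplitude, warpScale = warpScale,
      seed = as.integer(seed))
}

#' A paired low/high-quality image
#'
#' One anatomically paired observation: the low-quality and the high-quality
#' rendering of the same scene, sharing an identifier. \code{registered}
#' records whether the two members are pixel-aligned.
#'
#' @slot id character identifier.
#' @slot low,high numeric matrices with intensities in [0,1], same dimensions.
#' @slot registered logical.
#' @export
setClass("ImagePair", representation(
  id = "character", low = "matrix", high = "matrix", registered = "logical"))

setValidity("ImagePair", function(object) {
  msg <- character()
  if (!identical(dim(object@low), dim(object@high)))
    msg <- c(msg, "low and high must have identical dimensions")
  rng <- range(object@low, object@high)
  if (rng[1] < 0 || rng[2] > 1)
    msg <- c(msg, "all intensities must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @param id,low,high,registered see slots.
#' @rdname ImagePair-class
#' @export
ImagePair <- function(id, low, high, registered = FALSE) {
  new("ImagePair", id = as.character(id), low = low, high = high,
      registered = registered)
}

setMethod("show", "ImagePair", function(object) {
  cat(sprintf("ImagePair '%s': %dx%d, %s\n", object@id,
              nrow(object@low), ncol(object@low),
              if (object@registered) "registered" else "non-registered"))
})

#' Generator architecture specification
#'
#' Hyperparameters fully determining the UNet generator: strided-convolution
#' encoder (instance normalization + leaky ReLU, widths doubling from
#' \code{baseChannels} and capped at eight times it) mirrored by a
#' transposed-convolution decoder (instance normalization + ReLU) with skip
#' concatenations and a final tanh.
#'
#' @slot inChannels input/output channel count.
#' @slot baseChannels width of the first encoder stage.
#' @slot depth number of down-sampling stages; input sides must be divisible
#'   by \code{2^depth}.
#' @slot dropoutRate dropout probability on the configured decoder stages.
#' @slot dropoutStages decoder stage indices (counted from the bottleneck,
#'   \code{depth} = innermost) that carry dropout.
#' @export
setClass("GeneratorSpec", representation(
  inChannels = "integer", baseChannels = "integer", depth = "integer",
  dropoutRate = "numeric", dropoutStages = "integer"))

setValidity("GeneratorSpec", function(object) {
  msg <- character()
  if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
  if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    msg <- c(msg, "dropoutRate must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @param inChannels,baseChannels,depth,dropoutRate,dropoutStages see slots.
#' @rdname GeneratorSpec-class
#' @export
GeneratorSpec <- function(inChannels = 1L, baseChannels = 64L, depth = 8L,
                          dropoutRate = 0.5,
                          dropoutStages = as.integer(depth - 0:2)) {
  new("GeneratorSpec", inChannels = as.integer(inChannels),
      baseChannels = as.integer(baseChannels), depth = as.integer(depth),
      dropoutRate = dropoutRate,
      dropoutStages = as.integer(dropoutStages))
}

#' Discriminator architecture specification
#'
#' Hyperparameters of the spectrally normalized patch discriminator:
#' \code{nStridedLayers} stride-2 convolutions doubling the width (capped at
#' eight times \code{baseChannels}), one stride-1 widening convolution and a
#' stride-1 single-channel scoring convolution; every convolution kernel is
#' spectrally normalized. The output is a patch-level score map (spatial
#' extent greater than one), e.g. 30x30 for a 256x256 input at defaults.
#'
#' @slot inChannels input channels.
#' @slot baseChannels width of the first layer.
#' @slot nStridedLayers number of stride-2 layers.
#' @slot kernelSize convolution kernel side.
#' @slot leakySlope negative slope of the leaky ReLU.
#' @export
setClass("DiscriminatorSpec", representation(
  inChannels = "integer", baseChannels = "integer", nStridedLayers = "integer",
  kernelSize = "integer", leakySlope = "numeric"))

setValidity("DiscriminatorSpec", function(object) {
  msg <- character()
  if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
  if (object@nStridedLayers < 1L) msg <- c(msg, "nStridedLayers must be >= 1")
  if (object@kernelSize < 2L) msg <- c(msg, "kernelSize must be >= 2")
  if (length(msg)) msg else TRUE
})

#' @param inChannels,baseChannels,nStridedLayers,kernelSize,leakySlope see slots.
#' @rdname DiscriminatorSpec-class
#' @export
DiscriminatorSpec <- function(inChannels = 1L, baseChannels = 64L,
                              nStridedLayers = 3L, kernelSize = 4L,
                              leakySlope = 0.2) {
  new("DiscriminatorSpec", inChannels = as.integer(inChannels),
      baseChannels = as.integer(baseChannels),
      nStridedLayers = as.integer(nStridedLayers),
      kernelSize = as.integer(kernelSize), leakySlope = leakySlope)
}

#' Loss weights
#'
#' The four lambda constants weighting the aggregate generator objective:
#' adversarial, cycle-consistency, paired L1 and perceptual terms. Defaults
#' are 1, 10, 2 and 10.
#'
#' @slot lambdaAdv,lambdaCycle,lambdaL1,lambdaPer non-negative reals.
#' @export
setClass("LossWeights", representation(
  lambdaAdv = "numeric", lambdaCycle = "numeric", lambdaL1 = "numeric",
  lambdaPer = "numeric"))

setValidity("LossWeights", function(object) {
  w <- c(object@lambdaAdv, object@lambdaCycle, object@lambdaL1, object@lambdaPer)
  if (any(w < 0) || any(!is.finite(w))) "all lambda weights must be finite and >= 0" else TRUE
})

#' @param lambdaAdv,lambdaCycle,lambdaL1,lambdaPer see slots.
#' @rdname LossWeights-class
#' @export
LossWeights <- function(lambdaAdv = 1, lambdaCycle = 10, lambdaL1 = 2,
                        lambdaPer = 10) {
  new("LossWeights", lambdaAdv = lambdaAdv, lambdaCycle = lambdaCycle,
      lambdaL1 = lambdaL1, lambdaPer = lambdaPer)
}

#' Metric configuration
#'
#' Settings of the full-reference metrics. \code{ssiMode} selects the
#' Gaussian-windowed mean of the local structural-similarity map
#' (\code{"windowed"}) or the single-window whole-image formula
#' (\code{"global"}); the stabilizers are \code{C1 = (0.01 dataRange)^2} and
#' \code{C2 = (0.03 dataRange)^2}.
#'
#' @slot ssiMode \code{"windowed"} or \code{"global"}.
#' @slot windowSide,windowSigma Gaussian window of the windowed mode.
#' @slot lnccWindow side of the local correlation patch.
#' @slot dataRange maximum possible intensity MAX_I.
#' @slot epsilon denominator stabilizer of the local correlation.
#' @slot psnrCap value reported in aggregate means when the error is zero.
#' @export
setClass("MetricConfig", representation(
  ssiMode = "character", windowSide = "integer", windowSigma = "numeric",
  lnccWindow = "integer", dataRange = "numeric", epsilon = "numeric",
  psnrCap = "numeric"))

setValidity("MetricConfig", function(object) {
  msg <- character()
  if (!object@ssiMode %in% c("windowed", "global"))
    msg <- c(msg, "ssiMode must be 'windowed' or 'global'")
  if (object@windowSide < 3L || object@windowSide %% 2L == 0L)
    msg <- c(msg, "windowSide must be odd and >= 3")
  if (object@lnccWindow < 3L || object@lnccWindow %% 2L == 0L)
    msg <- c(msg, "lnccWindow must be odd and >= 3")
  if (object@dataRange <= 0) msg <- c(msg, "dataRange must be positive")
  if (length(msg)) msg else TRUE
})

#' @param ssiMode,windowSide,windowSigma,lnccWindow,dataRange,epsilon,psnrCap see slots.
#' @rdname MetricConfig-class
#' @export
MetricConfig <- function(ssiMode = "windowed", windowSide = 11L,
                         windowSigma = 1.5, lnccWindow = 9L, dataRange = 1,
                         epsilon = 1e-8, psnrCap = 100) {
  new("MetricConfig", ssiMode = ssiMode, windowSide = as.integer(windowSide),
      windowSigma = windowSigma, lnccWindow = as.integer(lnccWindow),
      dataRange = dataRange, epsilon = epsilon, psnrCap = psnrCap)
}

#' Dataset split specification
#'
#' Fractions of the train/validation/hold-out-test partition (defaults
#' 70/10/20) and the seed of the deterministic shuffle.
#'
#' @slot trainFraction,valFraction,testFraction fractions summing to one.
#' @slot seed integer seed.
#' @export
setClass("SplitSpec", representation(
  trainFraction = "numeric", valFraction = "numeric", testFraction = "numeric",
  seed = "integer"))

setValidity("SplitSpec", function(object) {
  f <- c(object@trainFraction, object@valFraction, object@testFraction)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
    "fractions must be non-negative and sum to 1" else TRUE
})

#' @param trainFraction,valFraction,testFraction,seed see slots.
#' @rdname SplitSpec-class
#' @export
SplitSpec <- function(trainFraction = 0.70, valFraction = 0.10,
                      testFraction = 0.20, seed = 1L) {
  new("SplitSpec", trainFraction = trainFraction, valFraction = valFraction,
      testFraction = testFraction, seed = as.integer(seed))
}

#' Training configuration
#'
#' Optimization settings: Adam with learning rate \code{lrInitial} and
#' moment decays \code{beta1}/\code{beta2}, halved (\code{lrGamma = 0.5})
#' every \code{lrStep} epochs; \code{lossScaling} multiplies the objective
#' before the backward pass and rescales gradients before the update.
#'
#' @slot epochs,batchSize counts.
#' @slot lrInitial,beta1,beta2,lrGamma,lrStep optimizer schedule.
#' @slot lossWeights a \linkS4class{LossWeights}.
#' @slot lossScaling logical; scale the loss before backpropagation.
#' @slot seed integer seed.
#' @export
setClass("TrainConfig", representation(
  epochs = "integer", batchSize = "integer", lrInitial = "numeric",
  beta1 = "numeric", beta2 = "numeric", lrGamma = "numeric",
  lrStep = "integer", lossWeights = "LossWeights", lossScaling = "logical",
  seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@lrGamma <= 0 || object@lrGamma > 1)
    msg <- c(msg, "lrGamma must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param epochs,batchSize,lrInitial,beta1,beta2,lrGamma,lrStep,lossWeights,lossScaling,seed see slots.
#' @rdname TrainConfig-class
#' @export
TrainConfig <- function(epochs = 300L, batchSize = 4L, lrInitial = 3e-4,
                        beta1 = 0.9, beta2 = 0.999, lrGamma = 0.5,
                        lrStep = 100L, lossWeights = LossWeights(),
                        lossScaling = TRUE, seed = 1L) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), lrInitial = lrInitial,
      beta1 = beta1, beta2 = beta2, lrGamma = lrGamma,
      lrStep = as.integer(lrStep), lossWeights = lossWeights,
      lossScaling = lossScaling, seed = as.integer(seed))
}

#' Per-pair metric report
#'
#' Per-pair values of the four metrics plus their means. Infinite PSNR
#' values (zero error) are kept per-pair but capped in the aggregate mean,
#' with \code{psnrCapped} flagging when the cap fired.
#'
#' @slot perPair data.frame with columns id, ssi, lncc, psnr, lpips.
#' @slot means named numeric of the four column means.
#' @slot n pair count.
#' @slot psnrCapped logical.
#' @export
setClass("MetricReport", representation(
  perPair = "data.frame", means = "numeric", n = "integer",
  psnrCapped = "logical"))

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport over %d pairs\n", object@n))
  cat(sprintf("  mean SSI   %.4f\n  mean LNCC  %.4f\n  mean PSNR  %.4f dB%s\n  mean LPIPS %.4f\n",
              object@means["ssi"], object@means["lncc"], object@means["psnr"],
              if (object@psnrCapped) " (capped)" else "",
              object@means["lpips"]))
})

#' @rdname MetricReport-class
#' @param object a \code{MetricReport}.
#' @export
perPairMetrics <- function(object) object@perPair

#' @rdname MetricReport-class
#' @export
metricMeans <- function(object) object@means
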