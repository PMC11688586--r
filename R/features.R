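#' Convolutional feature extractor for the perceptual distance
#'
#' An ordered stack of frozen convolutional stages whose activations are the
#' substrate of the perceptual (deep feature) distance. Each stage holds a
#' kernel, a stride and an activation; features are taken after the
#' activation. Per-stage weights scale each stage's contribution to the
#' distance. Parameters are never updated during enhancement training.
#'
#' @slot stages list of stages, each a list with elements \code{w}
#'   (kernel array (k, k, Cin, Cout)), \code{b} (bias), \code{stride},
#'   \code{activation} ("relu" or "linear").
#' @slot layerWeights non-negative per-stage weights.
#' @slot frozen logical; must be TRUE during training.
#' @export
setClass("FeatureExtractor", representation(
  stages = "list", layerWeights = "numeric", frozen = "logical"))

setValidity("FeatureExtractor", function(object) {
  msg <- character()
  if (length(object@stages) < 1L) msg <- c(msg, "at least one stage required")
  if (length(object@layerWeights) != length(object@stages))
    msg <- c(msg, "one layerWeight per stage required")
  if (any(!is.finite(object@layerWeights)) || any(object@layerWeights < 0))
    msg <- c(msg, "layerWeights must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FeatureExtractor", function(object) {
  ch <- vapply(object@stages, function(s) dim(s$w)[4], numeric(1))
  cat(sprintf("FeatureExtractor: %d stages (channels %s), %s\n",
              length(object@stages), paste(ch, collapse = ", "),
              if (object@frozen) "frozen" else "trainable"))
})

#' Seeded random convolutional feature extractor
#'
#' Builds the default perceptual backbone: a fixed-seed stack of stride-2
#' 3x3 convolutions with He-scaled Gaussian weights and ReLU activations.
#' Random convolutional features preserve enough multi-scale structure to
#' act as a perceptual distance without any pretrained weights; a pretrained
#' backbone can be supplied by constructing a \linkS4class{FeatureExtractor}
#' directly.
#'
#' @param seed weight seed (fixed default so every session agrees).
#' @param channels per-stage channel counts.
#' @param inChannels image channels.
#' @param kernel kernel side.
#' @param layerWeights per-stage distance weights (default all one).
#' @return a frozen \linkS4class{FeatureExtractor}.
#' @export
randomFeatureExtractor <- function(seed = 17L,
                                   channels = c(16L, 32L, 64L, 96L, 128L),
                                   inChannels = 1L, kernel = 3L,
                                   layerWeights = rep(1, length(channels))) {
  cins <- c(inChannels, channels[-length(channels)])
  stages <- withr::with_seed(as.integer(seed), lapply(seq_along(channels), function(i) {
    sd <- sqrt(2 / (kernel * kernel * cins[i]))
    list(w = agParam(array(rnorm(kernel^2 * cins[i] * channels[i], sd = sd),
                           c(kernel, kernel, cins[i], channels[i]))),
         b = agParam(numeric(channels[i])),
         stride = 2L, activation = "relu")
  }))
  new("FeatureExtractor", stages = stages,
      layerWeights = layerWeights, frozen = TRUE)
}

#' Single-stage identity extractor
#'
#' A degenerate one-stage extractor whose feature map is the image itself
#' (1x1 kernel of weight one, linear activation). Useful for analytic checks
#' of the perceptual distance.
#'
#' @param inChannels image channels.
#' @param weight stage weight.
#' @return a frozen \linkS4class{FeatureExtractor}.
#' @export
identityFeatureExtractor <- function(inChannels = 1L, weight = 1) {
  w <- agParam(array(diag(inChannels), c(1L, 1L, inChannels, inChannels)))
  new("FeatureExtractor",
      stages = list(list(w = w, b = agParam(numeric(inChannels)),
                         stride = 1L, activation = "linear")),
      layerWeights = weight, frozen = TRUE)
}

featureStages <- function(tape, fx, x) {
  h <- x
  out <- vector("list", length(fx@stages))
  for (i in seq_along(fx@stages)) {
    st <- fx@stages[[i]]
    h <- agConv2d(tape, h, st$w, st$b, stride = st$stride,
                  pad = (dim(st$w$val)[1] - 1L) %/% 2L)
    if (identical(st$activation, "relu")) h <- agRelu(tape, h)
    out[[i]] <- h
  }
  out
}

#' Perceptual (deep feature) distance between image batches
#'
#' For each extractor stage, channel vectors are unit-normalized at every
#' spatial location; the squared difference is averaged over space and
#' batch, summed over channels, weighted by the stage weight and summed over
#' stages. Zero for identical inputs and symmetric in its arguments.
#'
#' @param fx a frozen \linkS4class{FeatureExtractor}.
#' @param X,Y arrays of dim (H, W, N, C), matrices, or graph nodes of equal
#'   shape.
#' @param tape internal gradient tape.
#' @return non-negative scalar (a graph node under a tape).
#' @export
lpipsDistance <- function(fx, X, Y, tape = NULL) {
  if (!fx@frozen) stop("feature extractor must be frozen")
  node <- !is.null(tape)
  if (is.null(tape)) tape <- tapeNew()
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L, 1L))
  if (is.matrix(Y)) Y <- array(Y, c(dim(Y), 1L, 1L))
  if (!identical(dim(agValue(X)), dim(agValue(Y))))
    stop("X and Y must have identical shapes")
  if (!inherits(X, "agNode")) X <- agLeaf(tape, X)
  if (!inherits(Y, "agNode")) Y <- agLeaf(tape, Y)
  fX <- featureStages(tape, fx, X)
  fY <- featureStages(tape, fx, Y)
  terms <- lapply(seq_along(fX), function(i) {
    nx <- agChannelNormalize(tape, fX[[i]])
    ny <- agChannelNormalize(tape, fY[[i]])
    agStageDistance(tape, nx, ny, wgt = fx@layerWeights[i])
  })
  total <- agWeightedSum(tape, terms)
  if (node) total else total$val
}
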