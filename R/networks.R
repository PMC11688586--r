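#' Generator and discriminator networks
#'
#' \code{Generator} wraps a UNet translator between the low- and high-quality
#' domains; \code{Discriminator} wraps a spectrally normalized patch critic.
#' Parameters live in an environment so optimizer updates happen in place;
#' the two generators (and the two discriminators) share one architecture but
#' never share parameters.
#'
#' @slot spec the architecture specification.
#' @slot params environment holding the trainable arrays.
#' @slot role one of \code{"G_H"}/\code{"G_L"} (or \code{"D_H"}/\code{"D_L"}).
#' @name networks
NULL

#' @rdname networks
#' @export
setClass("Generator", representation(
  spec = "GeneratorSpec", params = "environment", role = "character"))

#' @rdname networks
#' @export
setClass("Discriminator", representation(
  spec = "DiscriminatorSpec", params = "environment", role = "character"))

setMethod("show", "Generator", function(object) {
  cat(sprintf("Generator %s: UNet depth %d, base %d channels, %d parameters\n",
              object@role, object@spec@depth, object@spec@baseChannels,
              nParameters(object)))
})

setMethod("show", "Discriminator", function(object) {
  cat(sprintf("Discriminator %s: %d strided layers, base %d channels, %d parameters\n",
              object@role, object@spec@nStridedLayers, object@spec@baseChannels,
              nParameters(object)))
})

initKernel <- function(k, cin, cout, sd = 0.02) {
  agParam(array(rnorm(k * k * cin * cout, sd = sd), c(k, k, cin, cout)))
}

encoderChannels <- function(spec)
  pmin(spec@baseChannels * 2^(seq_len(spec@depth) - 1L), 8L * spec@baseChannels)

#' Build a UNet generator
#'
#' Encoder: stride-2 4x4 convolutions with instance normalization (omitted on
#' the first stage and wherever the spatial extent collapses to one pixel)
#' and leaky ReLU, widths doubling from \code{baseChannels} capped at eight
#' times it. Decoder: stride-2 4x4 transposed convolutions with instance
#' normalization and ReLU, each stage concatenated with its mirrored encoder
#' stage; dropout on the configured innermost decoder stages; final tanh so
#' outputs lie in [-1, 1].
#'
#' @param spec a \linkS4class{GeneratorSpec}.
#' @param role \code{"G_H"} (enhancer) or \code{"G_L"}.
#' @param seed seed for the Gaussian (sd 0.02) weight initialization.
#' @return a \linkS4class{Generator}.
#' @export
buildGenerator <- function(spec, role = c("G_H", "G_L"), seed = 1L) {
  validObject(spec)
  role <- match.arg(role)
  depth <- spec@depth
  ech <- encoderChannels(spec)
  env <- new.env(parent = emptyenv())
  withr::with_seed(as.integer(seed), {
    env$enc <- lapply(seq_len(depth), function(i) {
      cin <- if (i == 1L) spec@inChannels else ech[i - 1L]
      list(w = initKernel(4L, cin, ech[i]), b = agParam(numeric(ech[i])))
    })
    env$dec <- lapply(seq_len(depth), function(j) {
      cin <- if (j == depth) ech[depth] else decOutCh(spec)[j + 1L] + ech[j]
      cout <- decOutCh(spec)[j]
      # transposed kernels are stored (k, k, Cout, Cin)
      list(w = agParam(array(rnorm(16L * cout * cin, sd = 0.02),
                             c(4L, 4L, cout, cin))),
           b = agParam(numeric(cout)))
    })
  })
  new("Generator", spec = spec, params = env, role = role)
}

decOutCh <- function(spec) {
  ech <- encoderChannels(spec)
  c(spec@inChannels, ech[seq_len(spec@depth - 1L)])
}

#' Number of trainable parameters
#'
#' @param object a Generator or Discriminator.
#' @return count of trainable scalars.
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

#' @rdname nParameters
#' @export
setMethod("nParameters", "Generator", function(object)
  sum(vapply(parameterList(object), function(p) length(p$val), numeric(1))))

#' @rdname nParameters
#' @export
setMethod("nParameters", "Discriminator", function(object)
  sum(vapply(parameterList(object), function(p) length(p$val), numeric(1))))

parameterList <- function(object) {
  env <- object@params
  if (inherits(object, "Generator"))
    unlist(lapply(c(env$enc, env$dec), function(l) list(l$w, l$b)),
           recursive = FALSE)
  else
    unlist(lapply(env$layers, function(l) list(l$w, l$b)), recursive = FALSE)
}

#' Run a generator on an image batch
#'
#' @param g a \linkS4class{Generator}.
#' @param x numeric array of dim (H, W, N, C) with values in [-1, 1], or a
#'   single matrix (promoted to a one-image batch).
#' @param train logical; enables dropout.
#' @param tape internal tape for gradient recording (NULL for inference).
#' @return array of the same dimensions with values in [-1, 1] (a graph node
#'   when \code{tape} is given).
#' @export
generatorForward <- function(g, x, train = FALSE, tape = NULL) {
  node <- !is.null(tape)
  if (is.null(tape)) tape <- tapeNew()
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (!inherits(x, "agNode")) {
    d <- dim(x)
    div <- 2L^g@spec@depth
    if (d[1] %% div != 0L || d[2] %% div != 0L)
      stop(sprintf("input sides (%d x %d) must be divisible by 2^depth = %d",
                   d[1], d[2], div))
    if (d[4] != g@spec@inChannels)
      stop(sprintf("input has %d channels but the generator expects %d",
                   d[4], g@spec@inChannels))
    x <- agLeaf(tape, x)
  }
  out <- unetForward(tape, g, x, train = train)
  if (node) out else out$val
}

unetForward <- function(tape, g, x, train = FALSE) {
  spec <- g@spec
  depth <- spec@depth
  env <- g@params
  e <- vector("list", depth)
  h <- x
  for (i in seq_len(depth)) {
    h <- agConv2d(tape, h, env$enc[[i]]$w, env$enc[[i]]$b, stride = 2L, pad = 1L)
    if (i > 1L && dim(h$val)[1] > 1L) h <- agInstanceNorm(tape, h)
    h <- agLeakyRelu(tape, h, 0.2)
    e[[i]] <- h
  }
  d <- e[[depth]]
  for (j in seq(depth, 1L)) {
    if (j < depth) d <- agConcatChannels(tape, d, e[[j]])
    d <- agConvT2d(tape, d, env$dec[[j]]$w, env$dec[[j]]$b, stride = 2L, pad = 1L)
    if (j > 1L) {
      d <- agInstanceNorm(tape, d)
      if (j %in% spec@dropoutStages)
        d <- agDropout(tape, d, spec@dropoutRate, train = train)
      d <- agRelu(tape, d)
    } else {
      d <- agTanh(tape, d)
    }
  }
  d
}

#' Build a spectrally normalized patch discriminator
#'
#' Layer stack at defaults: 4x4 convolutions with padding 1 and strides
#' 2, 2, 2, 1, 1; widths 1x, 2x, 4x, 8x \code{baseChannels} then a single
#' scoring channel; leaky ReLU between layers; no normalization other than
#' spectral normalization, which is applied to every kernel. On a 256x256
#' input the score map is 30x30.
#'
#' @param spec a \linkS4class{DiscriminatorSpec}.
#' @param role \code{"D_H"} or \code{"D_L"}.
#' @param seed weight initialization seed.
#' @return a \linkS4class{Discriminator}.
#' @export
buildDiscriminator <- function(spec, role = c("D_H", "D_L"), seed = 1L) {
  validObject(spec)
  role <- match.arg(role)
  ns <- spec@nStridedLayers
  widths <- pmin(spec@baseChannels * 2^(0:ns), 8L * spec@baseChannels)
  cins <- c(spec@inChannels, widths)
  couts <- c(widths, 1L)
  env <- new.env(parent = emptyenv())
  withr::with_seed(as.integer(seed), {
    env$layers <- lapply(seq_along(couts), function(i)
      list(w = initKernel(spec@kernelSize, cins[i], couts[i]),
           b = agParam(numeric(couts[i])),
           stride = if (i <= ns) 2L else 1L))
  })
  new("Discriminator", spec = spec, params = env, role = role)
}

#' Run a discriminator on an image batch
#'
#' @param d a \linkS4class{Discriminator}.
#' @param x array of dim (H, W, N, C) in [-1, 1] or a single matrix.
#' @param train logical; updates the persistent power-iteration vectors.
#' @param tape internal gradient tape.
#' @return patch score map array (Ho, Wo, N, 1), or a graph node under a tape.
#' @export
discriminatorForward <- function(d, x, train = FALSE, tape = NULL) {
  node <- !is.null(tape)
  if (is.null(tape)) tape <- tapeNew()
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (!inherits(x, "agNode")) x <- agLeaf(tape, x)
  spec <- d@spec
  h <- x
  nl <- length(d@params$layers)
  for (i in seq_len(nl)) {
    ly <- d@params$layers[[i]]
    h <- agConv2d(tape, h, ly$w, ly$b, stride = ly$stride, pad = 1L,
                  spectral = TRUE, nPower = 1L, updateU = train)
    if (i < nl) h <- agLeakyRelu(tape, h, spec@leakySlope)
  }
  if (prod(dim(h$val)[1:2]) <= 1L)
    warning("discriminator score map has spatial extent <= 1; input too small for patch-level judgment")
  if (node) h else h$val
}

#' Spectrally normalize a weight
#'
#' Divides a weight by a power-iteration estimate of its largest singular
#' value, so the result is 1-Lipschitz as a linear map. With at least 20
#' iterations the largest singular value of the result is within 1e-3 of one
#' for non-degenerate weights. Convolution kernels of dim (k, k, Cin, Cout)
#' are treated as (k*k*Cin) x Cout matrices.
#'
#' @param weight numeric matrix or 4-d kernel array.
#' @param nPowerIterations number of power iterations (>= 1).
#' @return the normalized weight with the shape of the input. An all-zero
#'   weight is returned unchanged with a warning (its norm is undefined).
#' @export
spectralNormalize <- function(weight, nPowerIterations = 20L) {
  if (nPowerIterations < 1L) stop("nPowerIterations must be >= 1")
  if (length(weight) == 0L) stop("weight must be non-empty")
  if (all(weight == 0)) {
    warning("all-zero weight: spectral norm undefined, returned unchanged")
    return(weight)
  }
  d <- dim(weight)
  Wmat <- if (is.matrix(weight)) weight else matrix(weight, ncol = d[length(d)])
  dummy <- new.env(parent = emptyenv())
  # run at least the requested iterations, then continue until the singular
  # value estimate stabilizes (slow convergence when the top two singular
  # values are close)
  sn <- snNormalize(Wmat, dummy, nPower = as.integer(nPowerIterations),
                    updateU = TRUE)
  for (i in seq_len(500L)) {
    prev <- sn$sigma
    sn <- snNormalize(Wmat, dummy, nPower = 5L, updateU = TRUE)
    if (abs(sn$sigma - prev) < 1e-7 * max(1, prev)) break
  }
  out <- sn$Wbar
  if (!is.matrix(weight)) out <- array(out, d)
  out
}
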