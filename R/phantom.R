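#' Synthetic speckle-phantom data
#'
#' Paired low/high-quality B-mode-like images with the statistical structure
#' the enhancement framework assumes: a piecewise-elliptical echogenicity
#' map multiplied by unit-mean gamma speckle gives the high-quality member;
#' the low-quality member is a warped, blurred, resolution-reduced,
#' contrast-compressed, re-speckled version of it.
#'
#' @name phantom
NULL

# Noiseless echogenicity map: background plus elliptical inclusions drawn in
# order (later inclusions overwrite earlier ones).
renderEchogenicityMap <- function(spec) {
  validObject(spec)
  s <- spec@sideLength
  img <- matrix(spec@backgroundEchogenicity, s, s)
  if (spec@nInclusions == 0L) return(img)
  withr::with_seed(spec@seed, {
    rows <- matrix(rep(seq_len(s), s), s, s)
    cols <- matrix(rep(seq_len(s), each = s), s, s)
    for (i in seq_len(spec@nInclusions)) {
      ax <- runif(2, spec@inclusionAxisRange[1], spec@inclusionAxisRange[2])
      marg <- max(ax)
      cy <- runif(1, 1 + marg, s - marg)
      cx <- runif(1, 1 + marg, s - marg)
      th <- runif(1, 0, pi)
      echo <- runif(1, spec@inclusionEchogenicityRange[1],
                    spec@inclusionEchogenicityRange[2])
      dy <- rows - cy; dx <- cols - cx
      u <- (dy * cos(th) + dx * sin(th)) / ax[1]
      v <- (-dy * sin(th) + dx * cos(th)) / ax[2]
      img[u^2 + v^2 <= 1] <- echo
    }
  })
  img
}

#' Unit-mean multiplicative speckle field
#'
#' Gamma-distributed field with shape \code{looks} and mean one, so its
#' variance is \code{1/looks}: the fully developed speckle model after
#' \code{looks}-fold incoherent averaging.
#'
#' @param nrow,ncol field dimensions.
#' @param looks positive number of looks.
#' @param seed integer seed.
#' @return numeric matrix (not clipped).
#' @export
speckleField <- function(nrow, ncol, looks, seed = 1L) {
  if (!is.finite(looks) || looks <= 0) stop("looks must be positive")
  withr::with_seed(as.integer(seed),
    matrix(rgamma(nrow * ncol, shape = looks, rate = looks), nrow, ncol))
}

#' Apply multiplicative speckle to an image
#'
#' Pixel-wise product with a unit-mean gamma field of shape \code{looks},
#' clipped to [0, 1]. In the many-looks limit the field variance vanishes
#' and the image passes through unchanged.
#'
#' @param image matrix with intensities in [0, 1].
#' @param looks positive number of looks.
#' @param seed integer seed.
#' @return matrix in [0, 1].
#' @export
applySpeckle <- function(image, looks, seed = 1L) {
  if (min(image) < 0 || max(image) > 1) stop("image must lie in [0,1]")
  f <- speckleField(nrow(image), ncol(image), looks, seed)
  pmin(pmax(image * f, 0), 1)
}

#' Render a high-quality phantom
#'
#' Piecewise-elliptical echogenicity map multiplied by unit-mean speckle at
#' \code{speckleLooksHigh} looks, clipped to [0, 1]. Deterministic for a
#' fixed seed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return matrix of dim sideLength x sideLength in [0, 1].
#' @export
renderPhantom <- function(spec) {
  echo <- renderEchogenicityMap(spec)
  applySpeckle(echo, spec@speckleLooksHigh, seed = spec@seed + 104729L)
}

# Smooth random displacement field: Gaussian offsets on a coarse grid
# (spacing warpScale), bilinearly upsampled and rescaled so the peak
# displacement equals warpAmplitude.
warpDisplacement <- function(side, amplitude, scale, seed) {
  nc <- max(2L, as.integer(ceiling(side / scale)) + 1L)
  withr::with_seed(as.integer(seed), {
    gy <- matrix(rnorm(nc * nc), nc, nc)
    gx <- matrix(rnorm(nc * nc), nc, nc)
  })
  dy <- EBImage::resize(gy, w = side, h = side)
  dx <- EBImage::resize(gx, w = side, h = side)
  peak <- max(abs(c(dy, dx)))
  if (peak > 0) {
    dy <- dy * amplitude / peak
    dx <- dx * amplitude / peak
  }
  list(dy = dy, dx = dx)
}

warpImage <- function(image, amplitude, scale, seed) {
  if (amplitude <= 0) return(image)
  s <- nrow(image)
  d <- warpDisplacement(s, amplitude, scale, seed)
  rows <- matrix(rep(seq_len(s), s), s, s)
  cols <- matrix(rep(seq_len(s), each = s), s, s)
  out <- .bilinearSample(image, as.numeric(rows + d$dy), as.numeric(cols + d$dx))
  matrix(out, s, s)
}

#' Degrade a high-quality image into its low-quality counterpart
#'
#' Applies, in order: smooth random warp (scene-level misregistration),
#' Gaussian blur of width \code{psfSigma}, resolution loss by
#' downsample-then-upsample, gamma contrast compression and re-speckling at
#' \code{speckleLooksLow} looks. Deterministic for a fixed seed.
#'
#' @param high matrix in [0, 1].
#' @param dspec a \linkS4class{DegradationSpec}.
#' @return matrix in [0, 1].
#' @export
degradeImage <- function(high, dspec) {
  validObject(dspec)
  s <- nrow(high)
  f <- dspec@downsampleFactor
  if (s %% f != 0L)
    stop(sprintf("downsampleFactor %d does not divide the image side %d", f, s))
  img <- warpImage(high, dspec@warpAmplitude, dspec@warpScale, dspec@seed)
  if (dspec@psfSigma > 0) img <- EBImage::gblur(img, sigma = dspec@psfSigma)
  if (f > 1L) {
    img <- EBImage::resize(img, w = s %/% f, h = s %/% f)
    img <- EBImage::resize(img, w = s, h = s)
  }
  img <- pmin(pmax(img, 0), 1)
  img <- img^dspec@contrastGamma
  applySpeckle(img, dspec@speckleLooksLow, seed = dspec@seed + 15485863L)
}

#' Generate a paired synthetic dataset
#'
#' \code{nPairs} phantom pairs with distinct identifiers; the per-pair seeds
#' derive deterministically from the master seed, so the same seed
#' reproduces the dataset bit-identically.
#'
#' @param nPairs number of pairs (>= 1).
#' @param pspec a \linkS4class{PhantomSpec}.
#' @param dspec a \linkS4class{DegradationSpec}.
#' @param seed master seed.
#' @return list of \linkS4class{ImagePair}.
#' @export
makeDataset <- function(nPairs, pspec = PhantomSpec(),
                        dspec = DegradationSpec(), seed = 1L) {
  if (nPairs < 1L) stop("nPairs must be >= 1")
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(2^30, 2L * nPairs, replace = FALSE))
  registered <- dspec@warpAmplitude == 0
  lapply(seq_len(nPairs), function(i) {
    ps <- pspec; ps@seed <- seeds[2L * i - 1L]
    ds <- dspec; ds@seed <- seeds[2L * i]
    high <- renderPhantom(ps)
    ImagePair(id = sprintf("p%05d", i), low = degradeImage(high, ds),
              high = high, registered = registered)
  })
}
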