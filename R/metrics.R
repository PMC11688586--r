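#' Full-reference image-quality metrics
#'
#' Structural similarity (SSI), locally normalized cross-correlation (LNCC),
#' peak signal-to-noise ratio (PSNR) and the perceptual feature distance
#' (LPIPS style), plus paired one-sided significance comparison between two
#' evaluations.
#'
#' @name metrics
NULL

gaussianWindow <- function(side, sigma) {
  r <- seq_len(side) - (side + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  w <- outer(g, g)
  as.numeric(w / sum(w))
}

# Weighted local means of every valid k x k patch, one column per center.
localPatches <- function(img, k) {
  .im2col(array(img, c(dim(img), 1L, 1L)), nrow(img), ncol(img), 1L, 1L,
          as.integer(k), 1L, 0L)
}

checkShapes <- function(H, Hp) {
  if (!identical(dim(H), dim(Hp)))
    stop("images must have identical dimensions")
}

#' Structural similarity index
#'
#' Windowed mode (default): mean over all valid window positions of the
#' local SSI computed with Gaussian-weighted moments. Global mode: the
#' single-window formula evaluated with whole-image moments,
#' \deqn{SSI = \frac{(2\mu_H\mu_{H'}+C_1)(2\sigma_{HH'}+C_2)}
#'   {(\mu_H^2+\mu_{H'}^2+C_1)(\sigma_H^2+\sigma_{H'}^2+C_2)}}
#' with \eqn{C_1 = (0.01\,MAX_I)^2}, \eqn{C_2 = (0.03\,MAX_I)^2}.
#'
#' @param H,Hp images (matrices) with intensities in [0, dataRange].
#' @param cfg a \linkS4class{MetricConfig}.
#' @return scalar in [-1, 1]; 1 for identical images.
#' @export
ssi <- function(H, Hp, cfg = MetricConfig()) {
  checkShapes(H, Hp)
  C1 <- (0.01 * cfg@dataRange)^2
  C2 <- (0.03 * cfg@dataRange)^2
  if (cfg@ssiMode == "global") {
    n <- length(H)
    m1 <- mean(H); m2 <- mean(Hp)
    v1 <- mean((H - m1)^2); v2 <- mean((Hp - m2)^2)
    cv <- mean((H - m1) * (Hp - m2))
    return(((2 * m1 * m2 + C1) * (2 * cv + C2)) /
             ((m1^2 + m2^2 + C1) * (v1 + v2 + C2)))
  }
  k <- cfg@windowSide
  if (nrow(H) < k || ncol(H) < k)
    stop(sprintf("images smaller than the %dx%d window", k, k))
  w <- gaussianWindow(k, cfg@windowSigma)
  p1 <- localPatches(H, k); p2 <- localPatches(Hp, k)
  m1 <- drop(crossprod(w, p1)); m2 <- drop(crossprod(w, p2))
  e11 <- drop(crossprod(w, p1^2)); e22 <- drop(crossprod(w, p2^2))
  e12 <- drop(crossprod(w, p1 * p2))
  v1 <- e11 - m1^2; v2 <- e22 - m2^2; cv <- e12 - m1 * m2
  mean(((2 * m1 * m2 + C1) * (2 * cv + C2)) /
         ((m1^2 + m2^2 + C1) * (v1 + v2 + C2)))
}

symmetricPad <- function(img, p) {
  idx <- function(n) c(rev(seq_len(p)), seq_len(n), n - seq_len(p) + 1L)
  img[idx(nrow(img)), idx(ncol(img))]
}

#' Locally normalized cross-correlation
#'
#' Mean over all patch centers (stride 1, symmetric boundary padding) of the
#' local Pearson correlation: the patch cross-covariance divided by the
#' product of the local standard deviations plus a small stabilizer.
#' Affine-invariant: \code{lncc(H, a*H + b) = 1} for \code{a > 0}.
#'
#' @inheritParams ssi
#' @return scalar clipped to [-1, 1].
#' @export
lncc <- function(H, Hp, cfg = MetricConfig()) {
  checkShapes(H, Hp)
  k <- cfg@lnccWindow
  p <- (k - 1L) %/% 2L
  a <- symmetricPad(H, p); b <- symmetricPad(Hp, p)
  pa <- localPatches(a, k); pb <- localPatches(b, k)
  ma <- colMeans(pa); mb <- colMeans(pb)
  va <- pmax(colMeans(pa^2) - ma^2, 0)
  vb <- pmax(colMeans(pb^2) - mb^2, 0)
  cv <- colMeans(pa * pb) - ma * mb
  r <- cv / (sqrt(va) * sqrt(vb) + cfg@epsilon)
  mean(pmin(pmax(r, -1), 1))
}

#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(MAX_I^2 / MSE)} in decibels; \code{Inf} when the error
#' is zero (capped at \code{cfg@psnrCap} in aggregate means).
#'
#' @inheritParams ssi
#' @return non-negative scalar (dB) for in-range images, or \code{Inf}.
#' @export
psnr <- function(H, Hp, cfg = MetricConfig()) {
  checkShapes(H, Hp)
  mse <- mean((H - Hp)^2)
  if (mse == 0) return(Inf)
  10 * log10(cfg@dataRange^2 / mse)
}

#' Perceptual metric between two images
#'
#' Feature distance of \code{\link{lpipsDistance}} on a single pair, with
#' intensities mapped from [0, 1] to the network range [-1, 1]. Lower values
#' indicate higher perceptual similarity.
#'
#' @inheritParams ssi
#' @param fx a frozen \linkS4class{FeatureExtractor}.
#' @return non-negative scalar.
#' @export
lpipsMetric <- function(H, Hp, fx) {
  checkShapes(H, Hp)
  lpipsDistance(fx, 2 * H - 1, 2 * Hp - 1)
}

applyEnhancer <- function(enhancer, low) {
  if (is.null(enhancer)) return(low)
  if (inherits(enhancer, "Generator")) {
    out <- generatorForward(enhancer, 2 * low - 1, train = FALSE)
    return(matrix(pmin(pmax((out + 1) / 2, 0), 1), nrow(low), ncol(low)))
  }
  enhancer(low)
}

#' Evaluate an enhancer over a paired dataset
#'
#' Computes the four metrics of (enhanced low vs high) for every pair. With
#' the identity enhancer (\code{enhancer = NULL}) this is the reference-low
#' baseline: low-quality images compared directly to their high-quality
#' counterparts without enhancement.
#'
#' @param pairs non-empty list of \linkS4class{ImagePair}.
#' @param enhancer \code{NULL} (identity), a \linkS4class{Generator}, or a
#'   function mapping a [0,1] matrix to a [0,1] matrix.
#' @param cfg a \linkS4class{MetricConfig}.
#' @param fx a frozen \linkS4class{FeatureExtractor}.
#' @return a \linkS4class{MetricReport}.
#' @export
evaluateDataset <- function(pairs, enhancer = NULL, cfg = MetricConfig(),
                            fx = randomFeatureExtractor()) {
  if (length(pairs) == 0L) stop("empty pair list")
  rows <- lapply(pairs, function(pr) {
    enh <- applyEnhancer(enhancer, pr@low)
    data.frame(id = pr@id,
               ssi = ssi(pr@high, enh, cfg),
               lncc = lncc(pr@high, enh, cfg),
               psnr = psnr(pr@high, enh, cfg),
               lpips = lpipsMetric(pr@high, enh, fx))
  })
  perPair <- do.call(rbind, rows)
  capped <- any(is.infinite(perPair$psnr))
  psnrForMean <- pmin(perPair$psnr, cfg@psnrCap)
  means <- c(ssi = mean(perPair$ssi), lncc = mean(perPair$lncc),
             psnr = mean(psnrForMean), lpips = mean(perPair$lpips))
  new("MetricReport", perPair = perPair, means = means,
      n = length(pairs), psnrCapped = capped)
}

#' One-sided Wilcoxon signed-rank test on paired scores
#'
#' Tests whether the paired scores in \code{scoresA} are shifted above
#' (\code{alternative = "greater"}) or below (\code{"less"}) those in
#' \code{scoresB}. Exact distribution for small samples without ties,
#' normal approximation otherwise (the behavior of
#' \code{\link[stats]{wilcox.test}}). When every difference is zero the
#' test is undefined and \code{NA} is returned with a warning.
#'
#' @param scoresA,scoresB equal-length paired score vectors (n >= 5).
#' @param alternative direction of the claim about \code{scoresA}.
#' @return p-value, or \code{NA} when undefined.
#' @export
wilcoxonOneSided <- function(scoresA, scoresB,
                             alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(scoresA) != length(scoresB))
    stop("scores must be paired (equal lengths)")
  if (length(scoresA) < 5L) stop("at least 5 pairs required")
  d <- scoresA - scoresB
  if (all(d == 0)) {
    warning("all paired differences are zero: test undefined")
    return(NA_real_)
  }
  suppressWarnings(stats::wilcox.test(scoresA, scoresB, paired = TRUE,
                                      alternative = alternative)$p.value)
}

#' Compare two metric reports
#'
#' Per-metric paired one-sided Wilcoxon test that report A improves on
#' report B, with the metric's own orientation (higher-better for SSI, LNCC
#' and PSNR; lower-better for LPIPS). Pairs are matched by identifier.
#'
#' @param reportA,reportB \linkS4class{MetricReport}s over the same pairs.
#' @return data.frame with columns metric, meanA, meanB, pValue.
#' @export
compareReports <- function(reportA, reportB) {
  a <- reportA@perPair; b <- reportB@perPair
  common <- intersect(a$id, b$id)
  if (length(common) < 5L) stop("fewer than 5 shared identifiers")
  a <- a[match(common, a$id), ]; b <- b[match(common, b$id), ]
  orient <- c(ssi = "greater", lncc = "greater", psnr = "greater",
              lpips = "less")
  do.call(rbind, lapply(names(orient), function(mtr) {
    av <- pmin(a[[mtr]], 1e6); bv <- pmin(b[[mtr]], 1e6)
    data.frame(metric = mtr, meanA = mean(av), meanB = mean(bv),
               pValue = wilcoxonOneSided(av, bv, orient[[mtr]]))
  }))
}
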