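#' Training losses
#'
#' The adversarial, cycle-consistency, paired L1 and perceptual terms of the
#' generator objective, the conditional label-smoothing rule and the
#' discriminator term. The user-facing functions below evaluate each term on
#' plain arrays (translators may be \linkS4class{Generator} objects or plain
#' functions, which makes analytic stub checks possible); the training loop
#' composes the same underlying operations on a gradient tape.
#'
#' @name losses
NULL

applyTranslator <- function(gen, x) {
  if (inherits(gen, "Generator")) generatorForward(gen, x, train = FALSE)
  else gen(x)
}

asBatch <- function(x) if (is.matrix(x)) array(x, c(dim(x), 1L, 1L)) else x

#' Adversarial term of the generator loss
#'
#' Mean squared deviation of each discriminator's score map on generated
#' images from an all-ones target (the target is materialized at the score
#' map's own shape), summed over the two domains.
#'
#' @param scoresFakeH,scoresFakeL score maps from D_H on G_H(L) and D_L on
#'   G_L(H).
#' @return non-negative scalar.
#' @export
adversarialTerm <- function(scoresFakeH, scoresFakeL) {
  if (length(scoresFakeH) == 0L || length(scoresFakeL) == 0L)
    stop("score maps must be non-empty")
  mean((scoresFakeH - 1)^2) + mean((scoresFakeL - 1)^2)
}

#' Cycle-consistency term
#'
#' Mean absolute error of the round trips G_L(G_H(L)) vs L and G_H(G_L(H))
#' vs H: translating to the other domain and back must reproduce the
#' original image.
#'
#' @param L,H aligned image batches (arrays (H, W, N, C) or matrices).
#' @param gL,gH the two translators (Generators or plain functions).
#' @return non-negative scalar.
#' @export
cycleTerm <- function(L, H, gL, gH) {
  L <- asBatch(L); H <- asBatch(H)
  if (!identical(dim(L), dim(H))) stop("L and H must have identical shapes")
  mean(abs(applyTranslator(gL, applyTranslator(gH, L)) - L)) +
    mean(abs(applyTranslator(gH, applyTranslator(gL, H)) - H))
}

#' Paired L1 term
#'
#' Mean absolute error of G_H(L) vs H plus, by default, of G_L(H) vs L.
#' \code{bothDirections = FALSE} restricts the term to the enhancement
#' direction only.
#'
#' @inheritParams cycleTerm
#' @param bothDirections include the G_L(H) vs L direction.
#' @return non-negative scalar.
#' @export
l1Term <- function(L, H, gL, gH, bothDirections = TRUE) {
  L <- asBatch(L); H <- asBatch(H)
  if (!identical(dim(L), dim(H))) stop("L and H must have identical shapes")
  out <- mean(abs(applyTranslator(gH, L) - H))
  if (bothDirections) out <- out + mean(abs(applyTranslator(gL, H) - L))
  out
}

#' Perceptual term
#'
#' Perceptual distance between the real high-quality batch and the enhanced
#' batch, plus between the real low-quality batch and the degraded batch:
#' lpips(H, G_H(L)) + lpips(L, G_L(H)).
#'
#' @inheritParams cycleTerm
#' @param fx a frozen \linkS4class{FeatureExtractor}.
#' @return non-negative scalar.
#' @export
perceptualTerm <- function(L, H, gL, gH, fx) {
  L <- asBatch(L); H <- asBatch(H)
  lpipsDistance(fx, H, applyTranslator(gH, L)) +
    lpipsDistance(fx, L, applyTranslator(gL, H))
}

#' Aggregate generator loss
#'
#' Weighted recombination lambda_adv * adv + lambda_cycle * cycle +
#' lambda_L1 * l1 + lambda_per * perceptual.
#'
#' @param adv,cycle,l1,perceptual finite scalar components.
#' @param weights a \linkS4class{LossWeights}.
#' @return scalar.
#' @export
totalGeneratorLoss <- function(adv, cycle, l1, perceptual,
                               weights = LossWeights()) {
  comp <- c(adv = adv, cycle = cycle, l1 = l1, perceptual = perceptual)
  bad <- names(comp)[!is.finite(comp)]
  if (length(bad))
    stop("non-finite loss component: ", paste(bad, collapse = ", "))
  weights@lambdaAdv * adv + weights@lambdaCycle * cycle +
    weights@lambdaL1 * l1 + weights@lambdaPer * perceptual
}

#' Conditional label-smoothing rule for real images
#'
#' When the mean discriminator scores of both the real and the generated
#' batch are strictly below \code{threshold}, the hard label 1.0 is used;
#' otherwise the smoothed label (default 0.9) tempers discriminator
#' overconfidence.
#'
#' @param meanRealScore,meanFakeScore batch means of the score maps.
#' @param threshold,smooth rule constants (both default 0.9).
#' @return 1.0 or \code{smooth}.
#' @export
realLabel <- function(meanRealScore, meanFakeScore, threshold = 0.9,
                      smooth = 0.9) {
  stopifnot(is.finite(meanRealScore), is.finite(meanFakeScore))
  if (meanRealScore < threshold && meanFakeScore < threshold) 1.0 else smooth
}

#' Discriminator term for one domain
#'
#' MSE of the real score map against \code{label} plus MSE of the fake score
#' map against zero. The total discriminator loss is this term summed over
#' the high- and low-quality domains.
#'
#' @param realScores,fakeScores score maps.
#' @param label target for real images (from \code{\link{realLabel}}).
#' @return non-negative scalar.
#' @export
discriminatorTerm <- function(realScores, fakeScores, label) {
  if (length(realScores) == 0L || length(fakeScores) == 0L)
    stop("score maps must be non-empty")
  mean((realScores - label)^2) + mean(fakeScores^2)
}
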