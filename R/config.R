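#' Run configuration
#'
#' A nested key-value configuration mirroring the specification objects:
#' sections \code{phantom}, \code{degradation}, \code{generator},
#' \code{discriminator}, \code{losses}, \code{metrics}, \code{training},
#' \code{split}, \code{data}, plus a top-level \code{seed}. Every field has
#' a default; unknown keys are rejected; the effective configuration is
#' echoed to the run directory by the command-line tools.
#'
#' @return \code{defaultRunConfig}: the complete default configuration as a
#'   nested list.
#' @export
defaultRunConfig <- function() {
  list(
    phantom = list(side_length = 64L, n_inclusions = 3L,
                   background_echogenicity = 0.35,
                   inclusion_echogenicity_range = c(0.55, 0.9),
                   inclusion_axis_range = c(5, 14),
                   speckle_looks_high = 4),
    degradation = list(psf_sigma = 2, downsample_factor = 2L,
                       speckle_looks_low = 2, contrast_gamma = 1.5,
                       warp_amplitude = 1, warp_scale = 16),
    generator = list(in_channels = 1L, base_channels = 64L, depth = 8L,
                     dropout_rate = 0.5),
    discriminator = list(in_channels = 1L, base_channels = 64L,
                         n_strided_layers = 3L, kernel_size = 4L,
                         leaky_slope = 0.2),
    losses = list(lambda_adv = 1, lambda_cycle = 10, lambda_l1 = 2,
                  lambda_per = 10),
    metrics = list(ssi_mode = "windowed", window_side = 11L,
                   window_sigma = 1.5, lncc_window = 9L, data_range = 1,
                   epsilon = 1e-8),
    training = list(epochs = 300L, batch_size = 4L, lr_initial = 3e-4,
                    beta1 = 0.9, beta2 = 0.999, lr_gamma = 0.5,
                    lr_step = 100L, loss_scaling = TRUE),
    split = list(train_fraction = 0.70, val_fraction = 0.10,
                 test_fraction = 0.20),
    data = list(n_pairs = 16L),
    features = list(seed = 17L, channels = c(16L, 32L, 64L, 96L, 128L)),
    seed = 1L)
}

mergeConfig <- function(base, override, path = "") {
  for (key in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", here)
    if (is.list(base[[key]])) {
      if (!is.list(override[[key]]))
        stop("configuration section expected at: ", here)
      base[[key]] <- mergeConfig(base[[key]], override[[key]], here)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' @rdname defaultRunConfig
#' @param path a YAML configuration file; missing fields fall back to the
#'   defaults.
#' @export
readRunConfig <- function(path) {
  if (is.null(path)) return(defaultRunConfig())
  if (!file.exists(path)) stop("configuration file does not exist: ", path)
  mergeConfig(defaultRunConfig(), yaml::read_yaml(path))
}

#' @rdname defaultRunConfig
#' @param config a configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Builders from configuration sections to the S4 specification objects.
configPhantomSpec <- function(cfg, seed = cfg$seed) {
  p <- cfg$phantom
  PhantomSpec(sideLength = p$side_length, nInclusions = p$n_inclusions,
              backgroundEchogenicity = p$background_echogenicity,
              inclusionEchogenicityRange = p$inclusion_echogenicity_range,
              inclusionAxisRange = p$inclusion_axis_range,
              speckleLooksHigh = p$speckle_looks_high, seed = seed)
}

configDegradationSpec <- function(cfg, seed = cfg$seed) {
  d <- cfg$degradation
  DegradationSpec(psfSigma = d$psf_sigma, downsampleFactor = d$downsample_factor,
                  speckleLooksLow = d$speckle_looks_low,
                  contrastGamma = d$contrast_gamma,
                  warpAmplitude = d$warp_amplitude, warpScale = d$warp_scale,
                  seed = seed)
}

configGeneratorSpec <- function(cfg) {
  g <- cfg$generator
  GeneratorSpec(inChannels = g$in_channels, baseChannels = g$base_channels,
                depth = g$depth, dropoutRate = g$dropout_rate)
}

configDiscriminatorSpec <- function(cfg) {
  d <- cfg$discriminator
  DiscriminatorSpec(inChannels = d$in_channels, baseChannels = d$base_channels,
                    nStridedLayers = d$n_strided_layers,
                    kernelSize = d$kernel_size, leakySlope = d$leaky_slope)
}

configLossWeights <- function(cfg) {
  l <- cfg$losses
  LossWeights(lambdaAdv = l$lambda_adv, lambdaCycle = l$lambda_cycle,
              lambdaL1 = l$lambda_l1, lambdaPer = l$lambda_per)
}

configMetricConfig <- function(cfg) {
  m <- cfg$metrics
  MetricConfig(ssiMode = m$ssi_mode, windowSide = m$window_side,
               windowSigma = m$window_sigma, lnccWindow = m$lncc_window,
               dataRange = m$data_range, epsilon = m$epsilon)
}

configTrainConfig <- function(cfg, seed = cfg$seed) {
  t <- cfg$training
  TrainConfig(epochs = t$epochs, batchSize = t$batch_size,
              lrInitial = t$lr_initial, beta1 = t$beta1, beta2 = t$beta2,
              lrGamma = t$lr_gamma, lrStep = t$lr_step,
              lossWeights = configLossWeights(cfg),
              lossScaling = t$loss_scaling, seed = seed)
}

configSplitSpec <- function(cfg, seed = cfg$seed) {
  s <- cfg$split
  SplitSpec(trainFraction = s$train_fraction, valFraction = s$val_fraction,
            testFraction = s$test_fraction, seed = seed)
}

configFeatureExtractor <- function(cfg) {
  randomFeatureExtractor(seed = cfg$features$seed,
                         channels = cfg$features$channels,
                         inChannels = cfg$generator$in_channels)
}
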