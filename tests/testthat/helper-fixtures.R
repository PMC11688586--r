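# Shared small fixtures; everything is generated in code with fixed seeds.

tinyPhantomSpec <- function(seed = 5L)
  PhantomSpec(sideLength = 64L, speckleLooksHigh = 4, seed = seed)

tinyDegradationSpec <- function(seed = 5L)
  DegradationSpec(psfSigma = 2, downsampleFactor = 2L, speckleLooksLow = 2,
                  contrastGamma = 1.5, warpAmplitude = 1, warpScale = 16,
                  seed = seed)

identityDegradationSpec <- function(seed = 5L)
  DegradationSpec(psfSigma = 0, downsampleFactor = 1L, speckleLooksLow = 1e6,
                  contrastGamma = 1, warpAmplitude = 0, warpScale = 16,
                  seed = seed)

tinyGeneratorSpec <- function(base = 8L, depth = 6L, dropoutRate = 0.5)
  GeneratorSpec(baseChannels = base, depth = depth, dropoutRate = dropoutRate)

tinyDiscriminatorSpec <- function(base = 8L)
  DiscriminatorSpec(baseChannels = base)

tinyModels <- function(gspec = tinyGeneratorSpec(), dspec = tinyDiscriminatorSpec()) {
  list(G_H = buildGenerator(gspec, "G_H", seed = 1L),
       G_L = buildGenerator(gspec, "G_L", seed = 2L),
       D_H = buildDiscriminator(dspec, "D_H", seed = 3L),
       D_L = buildDiscriminator(dspec, "D_L", seed = 4L))
}

tinyExtractor <- function() randomFeatureExtractor(channels = c(8L, 16L))

# Cache a small paired dataset across tests within one run.
.fixtureEnv <- new.env()
smallDataset <- function(n = 8L) {
  key <- paste0("ds", n)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- makeDataset(n, tinyPhantomSpec(), tinyDegradationSpec(),
                                      seed = 99L)
  .fixtureEnv[[key]]
}

# force copies: optimizer updates are in place
copyParamValues <- function(net)
  lapply(echoGAN:::parameterList(net), function(p) p$val + 0)
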