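#' Simulate one crystal/exposure sub-dataset
#'
#' Wedge partiality is abstracted as a random subset of the unique
#' reflections; intensities follow
#' `I = scale * exp(-B_cryst * s^2 / 2) * |F|^2` with Gaussian counting
#' noise, `sigI = sqrt(quantum * I_true + sig0^2)`. Negative simulated
#' intensities are retained, as in real integration output.
#'
#' @param structure the (damaged) [ToyStructure-class] at this exposure's
#'   dose, used to compute structure factors unless `sf` is supplied.
#' @param crystal list with crystalId, exposure, dose, cell (jittered
#'   [UnitCell-class]), scale, bOffset, and optionally `nisoFactor`, a
#'   per-reflection multiplicative non-isomorphism factor.
#' @param completeness fraction of unique reflections observed, in (0, 1].
#' @param noise list with `quantum` (counts per intensity unit) and `sig0`
#'   (additive noise floor); both 0 gives the noise-free limit.
#' @param seed integer seed; simulation is deterministic per seed.
#' @param dMin resolution limit used when `sf` must be computed.
#' @param sf optional precomputed structure-factor table from
#'   [calcStructureFactors()].
#' @param biasFraction optional orientation-bias strength in [0, 1): the
#'   inclusion probability of reflections near the bias cone axis (c*) is
#'   reduced by this factor.
#' @return a [SubDataset-class].
#' @export
simulateSubDataset <- function(structure, crystal, completeness, noise,
                               seed, dMin = 2, sf = NULL,
                               biasFraction = 0) {
  stopifnot(completeness > 0, completeness <= 1)
  if (is.null(sf)) sf <- calcStructureFactors(structure, dMin = dMin)
  n <- nrow(sf)
  if (!n) stop("degenerate configuration: empty reflection list")
  withSeed(seed, {
    nPick <- max(1L, round(completeness * n))
    prob <- rep(1, n)
    if (biasFraction > 0) {
      ## bias against reflections close to the l (c*) axis
      lfrac <- abs(sf$l) / pmax(1, sqrt(sf$h^2 + sf$k^2 + sf$l^2))
      prob <- 1 - biasFraction * lfrac
    }
    pick <- sort(sample.int(n, nPick, prob = prob))
    s2 <- 1 / sf$d[pick]^2
    Itrue <- crystal$scale * exp(-crystal$bOffset * s2 / 2) *
      sf$Fmod[pick]^2
    if (!is.null(crystal$nisoFactor))
      Itrue <- Itrue * crystal$nisoFactor[pick]
    sigI <- sqrt(noise$quantum * pmax(Itrue, 0) + noise$sig0^2)
    I <- Itrue + rnorm(nPick) * sigI
    sigI <- pmax(sigI, 1e-9)
    obs <- data.frame(h = sf$h[pick], k = sf$k[pick], l = sf$l[pick],
                      I = I, sigI = sigI, d = sf$d[pick])
    new("SubDataset", crystalId = as.integer(crystal$crystalId),
        exposure = as.integer(crystal$exposure),
        dose = as.numeric(crystal$dose), cell = crystal$cell,
        scaleOffset = crystal$scale, bOffset = crystal$bOffset,
        observations = obs)
  })
}

#' Default generator configuration
#'
#' @param ... named overrides of the default fields.
#' @return configuration list for [generateExperiment()].
#' @export
generatorConfig <- function(...) {
  cfg <- list(
    nCrystals = 10L, nExposures = 6L, dosePerExposure = 0.58,
    nAtoms = 150L, nSSites = 6L,
    cell = c(33, 35, 31), cellAngles = c(90, 90, 90),
    spacegroup = "P212121", solventFraction = 0.5,
    dHalf = 2.63, relocFraction = 0, relocDistance = 1.5,
    globalBRate = 0, scaleDecayRate = 0,
    completeness = 0.55, targetIsig = 15, quantum = NA_real_, sig0rel = 0.02,
    cellJitter = 0.002, scaleSd = 0.1, bOffsetSd = 2, nisoSd = 0.03,
    biasFraction = 0, dMin = 2.0)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown generator fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Generate a full serial dose-series experiment pool
#'
#' Builds the ground-truth structure, damages it at each cumulative dose
#' `k * dosePerExposure`, and simulates `nCrystals * nExposures` partial
#' sub-datasets with per-crystal non-isomorphism (cell jitter, overall scale
#' and B offsets, and a fixed per-crystal random intensity modulation) and
#' counting noise. The noise quantum is calibrated once, from the undamaged
#' intensity median, so that the merged single-observation `<I/sigma>` is
#' near `targetIsig`. Ground-truth phases per dose are stored for
#' evaluation only.
#'
#' @param config list from [generatorConfig()].
#' @param seed master seed; every stochastic draw derives from it.
#' @return an [ExperimentPool-class].
#' @export
generateExperiment <- function(config = generatorConfig(), seed = 1) {
  stopifnot(config$nCrystals >= 1, config$nExposures >= 2,
            config$dosePerExposure > 0)
  cell <- unitCell(config$cell[1], config$cell[2], config$cell[3],
                   config$cellAngles[1], config$cellAngles[2],
                   config$cellAngles[3])
  sg <- spaceGroup(config$spacegroup)
  structure <- makeToyStructure(deriveSeed(seed, "structure"),
                                config$nAtoms, config$nSSites, cell, sg,
                                config$solventFraction)
  damage <- damageModel(config$dHalf, config$relocFraction,
                        config$relocDistance, config$globalBRate,
                        config$scaleDecayRate)
  doses <- config$dosePerExposure * seq_len(config$nExposures)
  ## structure factors and ground-truth phases per dose point
  sfs <- vector("list", config$nExposures)
  truePhases <- vector("list", config$nExposures)
  for (k in seq_len(config$nExposures)) {
    stK <- applyDamage(structure, damage, doses[k])
    sf <- calcStructureFactors(stK, dMin = config$dMin)
    decay <- exp(-config$scaleDecayRate * doses[k])
    sf$Fmod <- sf$Fmod * sqrt(decay)
    sf$F <- sf$F * sqrt(decay)
    sfs[[k]] <- sf
    truePhases[[k]] <- sf[, c("h", "k", "l", "Fmod", "phase", "d", "centric")]
  }
  quantum <- config$quantum
  if (is.na(quantum)) {
    medI <- median(sfs[[1]]$Fmod^2)
    quantum <- medI / config$targetIsig^2
  }
  sig0 <- config$sig0rel * sqrt(median(sfs[[1]]$Fmod^2) * quantum)
  noise <- list(quantum = quantum, sig0 = sig0)
  nRefl <- nrow(sfs[[1]])
  subs <- vector("list", config$nCrystals * config$nExposures)
  i <- 0L
  for (cr in seq_len(config$nCrystals)) {
    crSeed <- deriveSeed(seed, paste0("crystal-", cr))
    crys <- withSeed(crSeed, {
      jit <- 1 + rnorm(3, 0, config$cellJitter)
      list(cell = unitCell(cell@a * jit[1], cell@b * jit[2],
                           cell@c * jit[3], cell@alpha, cell@beta,
                           cell@gamma),
           scale = exp(rnorm(1, 0, config$scaleSd)),
           bOffset = rnorm(1, 0, config$bOffsetSd),
           nisoFactor = exp(rnorm(nRefl, 0, config$nisoSd)))
    })
    for (k in seq_len(config$nExposures)) {
      i <- i + 1L
      crystal <- c(crys, list(crystalId = cr, exposure = k, dose = doses[k]))
      subs[[i]] <- simulateSubDataset(
        structure, crystal, config$completeness, noise,
        seed = deriveSeed(seed, paste0("obs-", cr, "-", k)),
        sf = sfs[[k]], biasFraction = config$biasFraction)
    }
  }
  new("ExperimentPool", subdatasets = subs, structure = structure,
      damage = damage, doses = doses, truePhases = truePhases,
      seed = as.integer(seed),
      config = {
        cfg <- config
        cfg$quantum <- quantum
        c(cfg, list(noiseSig0 = sig0))
      })
}

#' Bundled experiment presets
#'
#' Two presets mirror the two experimental regimes the pipeline targets:
#' `"uv-rip"` — strong specific damage only (6 S sites losing 60% occupancy
#' at the final dose, no global damage, no relocation), the high-signal
#' UV-illumination regime; `"xray-rip"` — weaker specific damage with
#' partial relocation to displaced partner sites plus global damage
#' (B inflation and scale decay), the X-ray burn regime.
#'
#' @param name `"uv-rip"` or `"xray-rip"`.
#' @param ... overrides passed to [generatorConfig()].
#' @return configuration list for [generateExperiment()].
#' @export
ripPreset <- function(name = c("uv-rip", "xray-rip"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "uv-rip" = generatorConfig(
      nAtoms = 150L, nSSites = 6L, dHalf = 2.63, relocFraction = 0,
      globalBRate = 0, scaleDecayRate = 0, targetIsig = 15),
    "xray-rip" = generatorConfig(
      nAtoms = 170L, nSSites = 9L, dHalf = 4.0, relocFraction = 0.5,
      relocDistance = 1.5, globalBRate = 1.0, scaleDecayRate = 0.03,
      targetIsig = 12))
  over <- list(...)
  if (length(over)) base[names(over)] <- over
  base
}

## Pool accessors -------------------------------------------------------

#' Extract sub-datasets of one exposure index from a pool
#' @param pool an [ExperimentPool-class].
#' @param exposure exposure index.
#' @return list of [SubDataset-class].
#' @export
poolExposure <- function(pool, exposure) {
  Filter(function(s) s@exposure == exposure, pool@subdatasets)
}

#' Ground-truth phase table for one exposure
#' @param pool an [ExperimentPool-class].
#' @param exposure exposure index.
#' @return data.frame h, k, l, Fmod, phase, d, centric.
#' @export
poolTruePhases <- function(pool, exposure) pool@truePhases[[exposure]]
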