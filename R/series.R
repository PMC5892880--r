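## Experiment drivers: before/after merging, the K scan, and the dose and
## multiplicity series.

#' Conventional scaling of one amplitude set onto another
#'
#' Log-linear fit of `log(F_ref^2 / F^2) = log k + B s^2 / 2` over common
#' indices with positive amplitudes, then application of the fitted
#' resolution-dependent factor (in amplitude units). This is the
#' "conventional" scaling step; the deliberate K down-weighting of the
#' after data is applied on top of it by [differenceAmplitudes()].
#'
#' @param x [AmplitudeSet-class] to scale.
#' @param reference [AmplitudeSet-class] to scale onto.
#' @param nMin minimum number of usable common reflections.
#' @return the scaled [AmplitudeSet-class].
#' @export
scaleAmplitudeSets <- function(x, reference, nMin = 20) {
  a <- x@data; r <- reference@data
  a$id <- encodeHKL(a$h, a$k, a$l)
  r$id <- encodeHKL(r$h, r$k, r$l)
  m <- merge(a, r[, c("id", "F")], by = "id", suffixes = c("", ".r"))
  m <- m[m$F > 0 & m$F.r > 0, , drop = FALSE]
  if (nrow(m) < nMin) stop("insufficient overlap for amplitude scaling")
  fit <- lm(log(m$F.r^2 / m$F^2) ~ I(1 / m$d^2))
  k <- exp(coef(fit)[[1]]); B <- 2 * coef(fit)[[2]]
  fac <- sqrt(k) * exp(B * (1 / a$d^2) / 4)
  out <- x
  out@data$F <- a$F * fac
  out@data$sigF <- a$sigF * fac
  out
}

#' Merge one exposure of a pool into an amplitude set
#'
#' Scales and merges the sub-datasets of one exposure index (optionally GA
#' selected) and converts to amplitudes.
#'
#' @param pool an [ExperimentPool-class].
#' @param exposure exposure index.
#' @param ga use [gaSelect()] to choose the sub-datasets to merge.
#' @param gaCfg GA configuration when `ga = TRUE`.
#' @param crystals optional crystal-id subset to restrict to.
#' @return list with `amplitudes` ([AmplitudeSet-class]) and `merged`
#'   ([MergedDataset-class]).
#' @export
mergeExposure <- function(pool, exposure, ga = FALSE, gaCfg = gaConfig(),
                          crystals = NULL) {
  subs <- poolExposure(pool, exposure)
  if (!is.null(crystals))
    subs <- Filter(function(s) s@crystalId %in% crystals, subs)
  if (!length(subs)) stop("no sub-datasets for exposure ", exposure)
  sg <- pool@structure@spacegroup
  cell <- pool@structure@cell
  merged <- if (ga && length(subs) > 1)
    gaSelect(subs, gaCfg, sg, cell)@merged
  else mergePool(subs, sg, cell)
  list(amplitudes = intensitiesToAmplitudes(merged,
                                            paste0("exposure-", exposure)),
       merged = merged)
}

#' Before/after amplitude pair for one dose point
#'
#' The first exposure is the "before" set; exposure `after` is the
#' "after" set, conventionally scaled onto the before set.
#'
#' @param pool an [ExperimentPool-class].
#' @param after after-exposure index (>= 2).
#' @param ... passed to [mergeExposure()].
#' @return list with `before` and `after` [AmplitudeSet-class] objects.
#' @export
beforeAfterPair <- function(pool, after, ...) {
  b <- mergeExposure(pool, 1L, ...)$amplitudes
  a <- mergeExposure(pool, after, ...)$amplitudes
  list(before = b, after = scaleAmplitudeSets(a, b))
}

#' K scan: substructure determination and phasing at each K
#'
#' For every K of the grid, forms the K-scaled differences, runs the
#' dual-space substructure search, scores the substructure against the
#' model-phased 6-sigma reference (the paper-style pseudo-atom
#' reference), and optionally phases (SIR + solvent flattening +
#' signed-site bootstrapping) and reports the weighted mean phase error
#' against the reference phases.
#'
#' @param before,after [AmplitudeSet-class] objects (after conventionally
#'   scaled onto before).
#' @param Ks K grid (default [kGrid()]).
#' @param refPhases reference phase table (h, k, l, phase, Fmod).
#' @param cell,sg cell and space group.
#' @param search a [searchConfig()] list.
#' @param phase run the phasing chain and report wMPE.
#' @param solventFraction solvent fraction for density modification.
#' @param dmCycles density-modification cycles.
#' @param bootstrap run signed-site bootstrapping.
#' @param tolerance correctness match tolerance in Angstrom.
#' @param refThreshold sigma threshold of the reference substructure.
#' @return list with `perK` (data.frame K, ccAll, ccWeak, correctness,
#'   wmpe), `avgCorrectness`, `avgWmpe`, `bestK`, and `reference` (the
#'   pseudo-atom reference [Substructure-class]).
#' @export
runKScan <- function(before, after, Ks = kGrid(), refPhases, cell, sg,
                     search = searchConfig(), phase = TRUE,
                     solventFraction = 0.5, dmCycles = 5,
                     bootstrap = TRUE, tolerance = 1.5,
                     refThreshold = 6) {
  stopifnot(length(Ks) >= 1)
  reference <- referenceSubstructure(before, after, 1, refPhases, cell,
                                     sg, refThreshold)
  rows <- vector("list", length(Ks))
  for (i in seq_along(Ks)) {
    K <- Ks[i]
    row <- data.frame(K = K, ccAll = NA_real_, ccWeak = NA_real_,
                      correctness = NA_real_, wmpe = NA_real_)
    searchK <- search
    searchK$seed <- deriveSeed(search$seed, paste0("K-", i))
    res <- tryCatch({
      ds <- differenceAmplitudes(before, after, K)
      sub <- dualSpaceSearch(ds, searchK, cell, sg)
      row$ccAll <- sub@ccAll; row$ccWeak <- sub@ccWeak
      row$correctness <- substructureCorrectness(sub, reference, cell, sg,
                                                 tolerance)$percent
      if (phase) {
        pe <- initialSirPhases(before, after, sub, cell, sg, K = K)
        if (bootstrap) {
          bs <- bootstrapSites(pe, before, after, K, sub, cell, sg)
          pe <- bs$phases
        }
        dm <- densityModify(pe, before, cell, sg, solventFraction,
                            dmCycles)
        row$wmpe <- wmpe(dm$phases, refPhases, sg)$wmpe
      }
      row
    }, error = function(e) { row$error <- conditionMessage(e); row })
    rows[[i]] <- res[, c("K", "ccAll", "ccWeak", "correctness", "wmpe")]
  }
  perK <- do.call(rbind, rows)
  ok <- !is.na(perK$correctness)
  list(perK = perK,
       avgCorrectness = mean(perK$correctness, na.rm = TRUE),
       avgWmpe = mean(perK$wmpe, na.rm = TRUE),
       bestWmpe = if (any(!is.na(perK$wmpe))) min(perK$wmpe, na.rm = TRUE)
                  else NA_real_,
       bestK = if (any(ok)) perK$K[which.max(perK$correctness)] else NA,
       reference = reference)
}

#' Dose series of model-phased difference-map peak heights
#'
#' For each dose point, pairs exposure 1 ("before") with exposure k
#' ("after"), forms the model-phased difference map for every K of the
#' grid, and reports the mean and standard deviation across the K grid of
#' the maximum (and minimum) peak heights in map sigma units.
#'
#' @param pool an [ExperimentPool-class] (>= 2 exposures).
#' @param Ks K grid.
#' @param refPhases reference phases; defaults to the pool's ground truth
#'   at the before exposure.
#' @param ga use GA selection in the merges.
#' @return data.frame with dose, exposure, meanMaxPeak, sdMaxPeak,
#'   meanMinPeak, sdMinPeak.
#' @export
runDoseSeries <- function(pool, Ks = kGrid(), refPhases = NULL,
                          ga = FALSE) {
  nExpo <- length(pool@doses)
  stopifnot(nExpo >= 2)
  if (is.null(refPhases)) refPhases <- poolTruePhases(pool, 1)
  cell <- pool@structure@cell; sg <- pool@structure@spacegroup
  b <- mergeExposure(pool, 1L, ga = ga)$amplitudes
  rows <- lapply(2:nExpo, function(k) {
    a <- scaleAmplitudeSets(mergeExposure(pool, k, ga = ga)$amplitudes, b)
    mx <- mn <- numeric(length(Ks))
    for (i in seq_along(Ks)) {
      map <- modelPhasedDifferenceMap(b, a, Ks[i], refPhases, cell, sg)
      mx[i] <- max(map@grid)
      mn[i] <- min(map@grid)
    }
    data.frame(dose = pool@doses[k], exposure = k,
               meanMaxPeak = mean(mx), sdMaxPeak = sd(mx),
               meanMinPeak = mean(mn), sdMinPeak = sd(mn))
  })
  do.call(rbind, rows)
}

#' Multiplicity series by nested random omission of sub-datasets
#'
#' Starting from the full pool, removes crystals (each contributing one
#' before and one after sub-dataset at the chosen dose pair) in nested
#' random steps, reducing the sub-dataset count by about 1.5-fold per
#' step, and reports the merged multiplicity and the mean max/min
#' model-phased peak heights across the K grid at every step. The same
#' resolution range is used for all steps.
#'
#' @param pool an [ExperimentPool-class].
#' @param after after-exposure index (default: the last).
#' @param Ks K grid.
#' @param seed seed of the omission order.
#' @param refPhases reference phases (default ground truth, exposure 1).
#' @param minCrystals smallest number of crystals to keep.
#' @param reduction multiplicative reduction per step.
#' @return data.frame with nCrystals, nSubdatasets, multiplicity,
#'   meanMaxPeak, sdMaxPeak, meanMinPeak, sdMinPeak.
#' @export
runMultiplicitySeries <- function(pool, after = length(pool@doses),
                                  Ks = kGrid(), seed = 1,
                                  refPhases = NULL, minCrystals = 1L,
                                  reduction = 1.5) {
  if (is.null(refPhases)) refPhases <- poolTruePhases(pool, 1)
  cell <- pool@structure@cell; sg <- pool@structure@spacegroup
  crystals <- sort(unique(vapply(pool@subdatasets,
                                 function(s) s@crystalId, 0L)))
  n <- length(crystals)
  if (n < minCrystals) stop("infeasible multiplicity step: pool too small")
  ord <- withSeed(deriveSeed(seed, "multiplicity-omission"),
                  sample(crystals))
  counts <- n
  while (tail(counts, 1) > minCrystals)
    counts <- c(counts, max(minCrystals,
                            floor(tail(counts, 1) / reduction)))
  rows <- lapply(counts, function(m) {
    keep <- ord[seq_len(m)]     # nested: each step a subset of the previous
    mb <- mergeExposure(pool, 1L, crystals = keep)
    ma <- mergeExposure(pool, after, crystals = keep)
    a <- scaleAmplitudeSets(ma$amplitudes, mb$amplitudes)
    mx <- mn <- numeric(length(Ks))
    for (i in seq_along(Ks)) {
      map <- modelPhasedDifferenceMap(mb$amplitudes, a, Ks[i], refPhases,
                                      cell, sg)
      mx[i] <- max(map@grid)
      mn[i] <- min(map@grid)
    }
    data.frame(nCrystals = m, nSubdatasets = 2L * m,
               multiplicity = mb$merged@stats$multiplicity,
               meanMaxPeak = mean(mx), sdMaxPeak = sd(mx),
               meanMinPeak = mean(mn), sdMinPeak = sd(mn))
  })
  do.call(rbind, rows)
}

#' End-to-end experiment driver
#'
#' Generates a preset pool and runs the full inference chain at the final
#' dose point: (optionally GA-selected) merging, conventional scaling, the
#' K scan with substructure determination and phasing, and the dose
#' series.
#'
#' @param preset `"uv-rip"` or `"xray-rip"` (or a full generator config
#'   list).
#' @param seed master seed.
#' @param ga use GA selection for the before/after merges of the K scan.
#' @param Ks K grid.
#' @param search a [searchConfig()]; `nFind` defaults to the preset's
#'   number of S sites.
#' @param doseSeries,multiplicitySeries include the corresponding series.
#' @return list with `pool`, `kscan`, `doseSeries`,
#'   `multiplicitySeries`.
#' @export
runExperiment <- function(preset = "uv-rip", seed = 1, ga = FALSE,
                          Ks = kGrid(), search = NULL,
                          doseSeries = TRUE,
                          multiplicitySeries = FALSE) {
  config <- if (is.character(preset)) ripPreset(preset) else preset
  pool <- generateExperiment(config, seed = seed)
  cell <- pool@structure@cell
  sg <- pool@structure@spacegroup
  if (is.null(search))
    search <- searchConfig(ntry = 150L, nFind = config$nSSites,
                           seed = deriveSeed(seed, "search"),
                           stopScore = 68)
  pair <- beforeAfterPair(pool, length(pool@doses), ga = ga)
  truth <- poolTruePhases(pool, 1)
  kscan <- runKScan(pair$before, pair$after, Ks, truth, cell, sg,
                    search = search,
                    solventFraction = config$solventFraction)
  ds <- if (doseSeries) runDoseSeries(pool, Ks, truth) else NULL
  ms <- if (multiplicitySeries)
    runMultiplicitySeries(pool, Ks = Ks, seed = deriveSeed(seed, "mult"))
  else NULL
  list(pool = pool, kscan = kscan, doseSeries = ds,
       multiplicitySeries = ms)
}
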