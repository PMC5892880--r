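## Genetic-algorithm selection of which sub-datasets to merge.

#' GA configuration
#'
#' The target function combines the overall merging statistics of the
#' candidate merge: `w_IsigI * norm(<I/sig>) - w_Rmeas * norm(R_meas) +
#' w_CC * norm(CC1/2) + w_completeness * completeness`. The first three
#' terms are min-max normalized with bounds frozen from the statistics of
#' the initial population, which keeps the target a fixed function of the
#' genome throughout the run (so elitism guarantees a non-decreasing best
#' target) and comparable against an exhaustive search. I/sigma carries the
#' largest default weight and completeness no more than the others.
#'
#' @param populationSize,generations GA size parameters.
#' @param crossoverProb,mutationProb single-point crossover and per-bit
#'   flip probabilities, in [0, 1].
#' @param elitism number of top genomes copied unchanged each generation.
#' @param weights named numeric: wIsigI, wRmeas, wCC, wCompleteness (all
#'   >= 0, not all zero).
#' @param minSize minimum number of selected sub-datasets.
#' @param seed GA seed.
#' @return configuration list.
#' @export
gaConfig <- function(populationSize = 40L, generations = 60L,
                     crossoverProb = 0.8, mutationProb = 0.05,
                     elitism = 2L,
                     weights = c(wIsigI = 2, wRmeas = 1, wCC = 1,
                                 wCompleteness = 1),
                     minSize = 1L, seed = 1L) {
  stopifnot(crossoverProb >= 0, crossoverProb <= 1,
            mutationProb >= 0, mutationProb <= 1,
            all(weights >= 0), any(weights > 0))
  list(populationSize = as.integer(populationSize),
       generations = as.integer(generations),
       crossoverProb = crossoverProb, mutationProb = mutationProb,
       elitism = as.integer(elitism), weights = weights,
       minSize = as.integer(minSize), seed = as.integer(seed))
}

## Overall merging statistics of a pooled observation data.table (fast
## path used inside the GA loop). `nTheory` is the theoretical unique count.
.overallStats <- function(dt, nTheory) {
  o <- order(dt$id, dt$u)
  id <- dt$id[o]; I <- dt$I[o]; w <- 1 / dt$sigI[o]^2
  S <- rowsum(cbind(w, w * I, I, 1), id, reorder = TRUE)
  n <- S[, 4]
  Im <- S[, 2] / S[, 1]
  isig <- Im * sqrt(S[, 1])
  ## rows -> group index (groups are contiguous after the sort)
  gidx <- rep.int(seq_along(n), n)
  mu <- (S[, 3] / n)[gidx]
  sa <- rowsum(abs(I - mu), id, reorder = TRUE)[, 1]
  pos <- sequence(n)
  oddI <- rowsum(cbind(I * (pos %% 2), pos %% 2,
                       I * (1 - pos %% 2), 1 - pos %% 2), id,
                 reorder = TRUE)
  multi <- n >= 2
  rMeas <- ccHalf <- NA_real_
  if (any(multi)) {
    rMeas <- sum(sqrt(n[multi] / (n[multi] - 1)) * sa[multi]) /
      sum(S[multi, 3])
    m1 <- oddI[multi, 1] / oddI[multi, 2]
    m2 <- oddI[multi, 3] / pmax(oddI[multi, 4], 1)
    ccHalf <- if (sum(multi) >= 3 && sd(m1) > 0 && sd(m2) > 0)
      cor(m1, m2) else NA_real_
  }
  c(IsigI = mean(isig), Rmeas = rMeas, CChalf = ccHalf,
    completeness = min(1, length(n) / nTheory))
}

## Target function under frozen bounds. Missing statistics contribute their
## worst normalized value.
.gaTarget <- function(stats, weights, bounds) {
  norm <- function(x, b, worst) {
    if (is.na(x)) return(worst)
    if (b[2] - b[1] < 1e-12) return(0.5)
    min(1, max(0, (x - b[1]) / (b[2] - b[1])))
  }
  weights[["wIsigI"]] * norm(stats[["IsigI"]], bounds$IsigI, 0) -
    weights[["wRmeas"]] * norm(stats[["Rmeas"]], bounds$Rmeas, 1) +
    weights[["wCC"]] * norm(stats[["CChalf"]], bounds$CChalf, 0) +
    weights[["wCompleteness"]] * stats[["completeness"]]
}

#' Evaluate the GA target for an explicit selection
#'
#' Used both by [gaSelect()] and by exhaustive-search cross-checks: computes
#' the overall merging statistics of the selected sub-datasets and applies
#' the target function under the supplied normalization bounds.
#'
#' @param prescaled result of [gaPrescale()].
#' @param selection integer indices of the selected sub-datasets.
#' @param weights,bounds target weights and frozen normalization bounds.
#' @return target value (numeric scalar).
#' @export
gaEvaluate <- function(prescaled, selection, weights, bounds) {
  dt <- rbindlist(prescaled$tables[selection])
  .gaTarget(.overallStats(dt, prescaled$nTheory), weights, bounds)
}

#' Prescale a pool once for repeated GA evaluations
#'
#' @param subs list of [SubDataset-class].
#' @param sg a [SpaceGroup-class].
#' @param cell reference cell (defaults to the reference sub-dataset's).
#' @param splitSeed CC1/2 half-split seed.
#' @return list with per-sub-dataset scaled observation tables, the
#'   reference index and the theoretical unique-reflection count.
#' @export
gaPrescale <- function(subs, sg, cell = NULL, splitSeed = 1) {
  ref <- chooseReference(subs)
  if (is.null(cell)) cell <- subs[[ref]]@cell
  scaled <- lapply(seq_along(subs), function(i)
    if (i == ref || length(subs) == 1) subs[[i]] else
      scaleToReference(subs[[i]], subs[[ref]], sg))
  dt <- poolObservations(scaled, sg, cell, splitSeed)
  dMin <- min(dt$d)
  tables <- split(dt, by = "memberId", sorted = TRUE)
  list(tables = tables, reference = ref, cell = cell, sg = sg,
       nTheory = nrow(uniqueReflections(cell, sg, dMin)),
       splitSeed = splitSeed, scaled = scaled)
}

#' Select sub-datasets to merge with a genetic algorithm
#'
#' Genomes are inclusion bitmasks over the pool. Fitness is the target
#' function of [gaConfig()]; evolution uses tournament selection (k = 2),
#' single-point crossover, per-bit mutation and elitism, and is
#' deterministic for a fixed config seed.
#'
#' @param subs list of [SubDataset-class] (length >= 1).
#' @param config a [gaConfig()] list.
#' @param sg a [SpaceGroup-class].
#' @param cell optional reference [UnitCell-class].
#' @return a [GASelection-class].
#' @export
gaSelect <- function(subs, config = gaConfig(), sg, cell = NULL) {
  n <- length(subs)
  stopifnot(n >= 1)
  pre <- gaPrescale(subs, sg, cell, splitSeed = config$seed)
  if (n == 1) {
    merged <- mergePool(subs, sg, cell)
    return(new("GASelection", chosen = 1L, target = NA_real_,
               merged = merged, bounds = list(), history = numeric(0)))
  }
  cache <- new.env(parent = emptyenv())
  statsOf <- function(genome) {
    key <- paste(which(genome), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- .overallStats(rbindlist(pre$tables[which(genome)]), pre$nTheory)
    cache[[key]] <- s
    s
  }
  fixGenome <- function(g) {
    if (sum(g) < config$minSize) {
      off <- which(!g)
      g[off[sample.int(length(off), config$minSize - sum(g))]] <- TRUE
    }
    g
  }
  withSeed(deriveSeed(config$seed, "ga-select"), {
    pop <- lapply(seq_len(config$populationSize), function(i)
      fixGenome(runif(n) < 0.5))
    statList <- lapply(pop, statsOf)
    statMat <- do.call(rbind, statList)
    rng <- function(col) {
      v <- statMat[, col]
      v <- v[is.finite(v)]
      if (!length(v)) c(0, 1) else range(v)
    }
    bounds <- list(IsigI = rng("IsigI"), Rmeas = rng("Rmeas"),
                   CChalf = rng("CChalf"))
    fit <- vapply(statList, .gaTarget, 0, weights = config$weights,
                  bounds = bounds)
    history <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      ord <- order(-fit)
      newPop <- pop[ord[seq_len(min(config$elitism, config$populationSize))]]
      while (length(newPop) < config$populationSize) {
        pick <- function() {
          c2 <- sample.int(config$populationSize, 2)
          pop[[c2[which.max(fit[c2])]]]
        }
        p1 <- pick(); p2 <- pick()
        if (runif(1) < config$crossoverProb) {
          cut <- sample.int(n - 1, 1)
          child <- c(p1[seq_len(cut)], p2[(cut + 1):n])
        } else child <- p1
        flip <- runif(n) < config$mutationProb
        child[flip] <- !child[flip]
        newPop[[length(newPop) + 1L]] <- fixGenome(child)
      }
      pop <- newPop
      statList <- lapply(pop, statsOf)
      fit <- vapply(statList, .gaTarget, 0, weights = config$weights,
                    bounds = bounds)
      history[gen] <- max(fit)
    }
    best <- which.max(fit)
    chosen <- which(pop[[best]])
    merged <- mergePool(subs[chosen], sg, cell)
    new("GASelection", chosen = as.integer(chosen), target = fit[best],
        merged = merged, bounds = bounds, history = history)
  })
}
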