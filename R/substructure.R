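## Dual-space determination of the damage-site substructure from
## normalized difference amplitudes, with a difference-Patterson synthesis.

#' Search configuration for the dual-space substructure search
#'
#' @param ntry number of random trials.
#' @param dMax,dMin low/high resolution window in Angstrom (the window the
#'   normalized differences are truncated to before searching).
#' @param nFind number of (positive) sites sought per trial.
#' @param nCycles dual-space recycling cycles per trial.
#' @param weakFraction fraction of smallest |E_obs| defining the CC(weak)
#'   subset.
#' @param strongFraction fraction of largest |E_obs| used in the recycling
#'   cycles (maps and greedy selection); the final CC scores always use
#'   the full set.
#' @param stopScore optional early-termination threshold on
#'   CC(all) + CC(weak): trials stop once a trial reaches it (the search
#'   stays deterministic; later trials are simply not run).
#' @param seed search seed; the search is deterministic per seed.
#' @return configuration list.
#' @export
searchConfig <- function(ntry = 200L, dMax = 500, dMin = 2.2, nFind = 6L,
                         nCycles = 6L, weakFraction = 0.3,
                         strongFraction = 0.3, stopScore = Inf,
                         seed = 1L) {
  if (ntry < 1) stop("invalid config: ntry must be >= 1")
  if (nFind < 1) stop("invalid config: nFind must be >= 1")
  stopifnot(dMax > dMin, weakFraction > 0, weakFraction < 1,
            strongFraction > 0, strongFraction <= 1)
  list(ntry = as.integer(ntry), dMax = dMax, dMin = dMin,
       nFind = as.integer(nFind), nCycles = as.integer(nCycles),
       weakFraction = weakFraction, strongFraction = strongFraction,
       stopScore = stopScore, seed = as.integer(seed))
}

#' Difference Patterson synthesis
#'
#' Fourier synthesis with coefficients `|dF|^2` (or `E^2`) and zero phase.
#' The resulting map is centrosymmetric with its maximum at the origin;
#' non-origin peaks are the interatomic vectors of the damage substructure.
#'
#' @param diffset a [DifferenceSet-class].
#' @param cell the [UnitCell-class].
#' @param sg the [SpaceGroup-class].
#' @param gridSize explicit grid dimensions (length 3), or NULL to choose
#'   from the resolution. Spacing coarser than dMin/3 signals an error
#'   (aliasing risk).
#' @param useE use normalized E^2 instead of |dF|^2 coefficients.
#' @return a [RealMap-class].
#' @export
differencePatterson <- function(diffset, cell, sg, gridSize = NULL,
                                useE = FALSE) {
  d <- diffset@data
  if (!nrow(d)) stop("empty difference set")
  dMin <- min(d$d)
  if (is.null(gridSize)) gridSize <- mapGridSize(cell, dMin)
  sp <- c(cell@a, cell@b, cell@c) / gridSize
  if (any(sp > dMin / 3 + 1e-9))
    stop("grid too coarse for d_min = ", round(dMin, 2),
         " A: aliasing risk (spacing must be <= d_min/3)")
  coef <- if (useE) d$E^2 else d$dF^2
  mapFromCoefficients(cell, sg, as.matrix(d[, c("h", "k", "l")]),
                      complex(real = coef), dMin, gridSize)
}

#' Correlation score between observed and calculated normalized amplitudes
#'
#' 100 times the Pearson correlation over the selected subset.
#'
#' @param eObs,eCalc normalized amplitude magnitudes.
#' @param subset optional logical or integer selector (default: all).
#' @return score in percent.
#' @export
scoreCC <- function(eObs, eCalc, subset = NULL) {
  if (!is.null(subset)) { eObs <- eObs[subset]; eCalc <- eCalc[subset] }
  if (length(eObs) < 3) stop("need at least 3 reflections for a CC score")
  if (sd(eObs) == 0 || sd(eCalc) == 0)
    stop("zero-variance input: correlation undefined")
  100 * cor(eObs, eCalc)
}

## Point-atom structure factors from fractional sites (unit scatterers
## with one overall B), summed over all symmetry operators. `occ` may be
## signed. Returns complex vector over the rows of `hkl`.
pointAtomSF <- function(hkl, sites, sg, d, bOverall = 5, occ = NULL) {
  hkl <- rbind(hkl)
  if (is.null(occ)) occ <- rep(1, nrow(sites))
  Fc <- complex(real = numeric(nrow(hkl)))
  xyz <- as.matrix(sites[, c("x", "y", "z"), drop = FALSE])
  for (op in sg@ops) {
    hm <- hkl %*% op$R
    ph <- exp(2i * pi * (hm %*% t(xyz) + as.vector(hkl %*% op$t)))
    Fc <- Fc + as.vector(ph %*% occ)
  }
  Fc * exp(-bOverall / (4 * d^2))
}

## Reject peak candidates closer than minDist to an already accepted site
## (including its symmetry mates) or to their own symmetry image (special
## positions).
.filterPeakSites <- function(peaks, cell, sg, minDist = 1) {
  keep <- logical(nrow(peaks))
  acc <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(peaks))) {
    p <- as.numeric(peaks[i, c("x", "y", "z")])
    special <- FALSE
    for (op in sg@ops[-1]) {
      img <- as.vector(op$R %*% p) + op$t
      if (fracDistance(cell, rbind(img), rbind(p)) < minDist) {
        special <- TRUE; break
      }
    }
    if (special) next
    clash <- FALSE
    if (nrow(acc)) {
      for (op in sg@ops) {
        img <- sweep(acc %*% t(op$R), 2, op$t, "+")
        if (any(fracDistance(cell, img,
                             matrix(p, nrow(img), 3, byrow = TRUE)) <
                minDist)) { clash <- TRUE; break }
      }
    }
    if (clash) next
    keep[i] <- TRUE
    acc <- rbind(acc, p)
  }
  peaks[keep, , drop = FALSE]
}


## Greedy CC-driven selection of nFind mutually compatible candidate
## sites, followed by one swap-improvement pass.
.greedySelect <- function(cand, candF, Dcand, eS, nFind) {
  Fcur <- 0
  chosen <- integer(0)
  for (k in seq_len(nFind)) {
    bestCC <- -Inf; bestI <- NA_integer_
    for (i in setdiff(seq_len(nrow(cand)), chosen)) {
      if (length(chosen) && min(Dcand[chosen, i]) < 1.5) next
      cc <- suppressWarnings(cor(eS, Mod(Fcur + candF[[i]])))
      if (!is.na(cc) && cc > bestCC) { bestCC <- cc; bestI <- i }
    }
    if (is.na(bestI)) break
    chosen <- c(chosen, bestI)
    Fcur <- Fcur + candF[[bestI]]
  }
  if (!length(chosen)) return(chosen)
  cc0 <- suppressWarnings(cor(eS, Mod(Fcur)))
  for (j in seq_along(chosen)) {
    Fwo <- Fcur - candF[[chosen[j]]]
    for (i in setdiff(seq_len(nrow(cand)), chosen)) {
      oth <- chosen[-j]
      if (length(oth) && min(Dcand[oth, i]) < 1.5) next
      cc <- suppressWarnings(cor(eS, Mod(Fwo + candF[[i]])))
      if (!is.na(cc) && cc > cc0 + 0.002) {
        chosen[j] <- i
        Fcur <- Fwo + candF[[i]]
        Fwo <- Fcur - candF[[i]]
        cc0 <- cc
      }
    }
  }
  chosen
}

#' Dual-space substructure search
#'
#' Per trial: seed sites (even trials purely random; odd trials place a
#' random position plus a partner displaced by a top non-origin
#' difference-Patterson vector), then recycling cycles of {point-atom
#' phases from the current sites -> E-map with the strongest normalized
#' differences -> candidate peak list -> greedy re-selection of the
#' `nFind` sites that maximize the correlation with the strong |E_obs|}.
#' The greedy re-selection (rather than blind top-of-list picking) keeps
#' the growing site set internally consistent in hand and origin. Trials
#' are scored by CC(all) and CC(weak) over the full reflection set and
#' the best trial by CC(all) + CC(weak) is returned. Deterministic per
#' seed.
#'
#' @param diffset a [DifferenceSet-class].
#' @param config a [searchConfig()] list.
#' @param cell the [UnitCell-class].
#' @param sg the [SpaceGroup-class].
#' @return a [Substructure-class].
#' @export
dualSpaceSearch <- function(diffset, config = searchConfig(), cell, sg) {
  d <- diffset@data
  d <- d[d$d <= config$dMax & d$d >= config$dMin, , drop = FALSE]
  if (!nrow(d)) stop("no data in the requested resolution window")
  if (nrow(d) < 10 * config$nFind)
    stop("too few reflections in window (need >= 10 * nFind)")
  eObs <- d$E
  hkl <- as.matrix(d[, c("h", "k", "l")])
  weakN <- max(3L, round(config$weakFraction * length(eObs)))
  weakSel <- order(eObs)[seq_len(weakN)]
  strongN <- max(10L * config$nFind,
                 round(config$strongFraction * length(eObs)))
  strongSel <- order(-eObs)[seq_len(min(strongN, length(eObs)))]
  hklS <- hkl[strongSel, , drop = FALSE]
  eS <- eObs[strongSel]
  dS <- d$d[strongSel]
  gridSize <- mapGridSize(cell, config$dMin)
  siteSF <- function(p) pointAtomSF(hklS, data.frame(x = p[1], y = p[2],
                                                     z = p[3]), sg, dS)
  ## Patterson vectors for pair seeding
  pvec <- tryCatch({
    pm <- differencePatterson(diffset, cell, sg, useE = TRUE)
    pk <- gridPeaks(pm, nTop = 16)
    pk[fracDistance(cell, cbind(pk$x, pk$y, pk$z),
                    matrix(0, nrow(pk), 3)) > 1.5, , drop = FALSE]
  }, error = function(e) data.frame())
  best <- NULL
  scoreLog <- data.frame(trial = integer(0), ccAll = numeric(0),
                         ccWeak = numeric(0))
  for (trial in seq_len(config$ntry)) {
    tSeed <- deriveSeed(config$seed, paste0("trial-", trial))
    sites <- withSeed(tSeed, {
      if (trial %% 2 == 0 || !nrow(pvec)) {
        matrix(runif(3), 1, 3)
      } else {
        x0 <- runif(3)
        u <- as.numeric(pvec[sample.int(min(4, nrow(pvec)), 1),
                             c("x", "y", "z")])
        rbind(x0, wrapFrac(x0 + u))
      }
    })
    for (cyc in seq_len(config$nCycles)) {
      Fc <- pointAtomSF(hklS, data.frame(x = sites[, 1], y = sites[, 2],
                                         z = sites[, 3]), sg, dS)
      emap <- mapFromCoefficients(cell, sg, hklS,
                                  complex(modulus = eS,
                                          argument = Arg(Fc)),
                                  config$dMin, gridSize)
      pk <- gridPeaks(emap, nTop = 40L * length(sg@ops), faceOnly = TRUE)
      pk <- .filterPeakSites(pk, cell, sg, minDist = 1.2)
      if (!nrow(pk)) break
      cand <- as.matrix(pk[, c("x", "y", "z")])
      candF <- lapply(seq_len(nrow(cand)), function(i) siteSF(cand[i, ]))
      Dcand <- siteDistanceMatrix(cand, cand, cell, sg)
      sel <- .greedySelect(cand, candF, Dcand, eS, config$nFind)
      if (!length(sel)) break
      sites <- cand[sel, , drop = FALSE]
    }
    eCalc <- Mod(pointAtomSF(hkl, data.frame(x = sites[, 1],
                                             y = sites[, 2],
                                             z = sites[, 3]), sg, d$d))
    if (sd(eCalc) == 0) next
    ccA <- scoreCC(eObs, eCalc)
    ccW <- scoreCC(eObs, eCalc, weakSel)
    scoreLog <- rbind(scoreLog, data.frame(trial = trial, ccAll = ccA,
                                           ccWeak = ccW))
    if (is.null(best) || ccA + ccW > best$ccA + best$ccW)
      best <- list(sites = sites, ccA = ccA, ccW = ccW, trial = trial)
    if (!is.null(best) && best$ccA + best$ccW >= config$stopScore) break
  }
  if (is.null(best)) stop("substructure search failed on every trial")
  sites <- data.frame(x = wrapFrac(best$sites[, 1]),
                      y = wrapFrac(best$sites[, 2]),
                      z = wrapFrac(best$sites[, 3]))
  ## relative occupancy estimate from the final E-map heights
  Fc <- pointAtomSF(hkl, sites, sg, d$d)
  emap <- mapFromCoefficients(cell, sg, hkl,
                              complex(modulus = eObs, argument = Arg(Fc)),
                              config$dMin, gridSize)
  hgt <- mapValueAt(emap, as.matrix(sites)) / sd(as.vector(emap@grid))
  sites$occ <- pmax(hgt, 0.1) / max(pmax(hgt, 0.1))
  sites$height <- hgt
  sites <- sites[order(-abs(sites$height)), , drop = FALSE]
  rownames(sites) <- NULL
  new("Substructure", sites = sites, ccAll = best$ccA, ccWeak = best$ccW,
      meta = list(trial = best$trial, seed = config$seed,
                  config = config, scoreLog = scoreLog))
}

## Trilinear interpolation of map values at fractional positions (n x 3).
mapValueAt <- function(map, xyz) {
  g <- map@grid; n <- dim(g)
  xyz <- rbind(xyz)
  out <- numeric(nrow(xyz))
  for (r in seq_len(nrow(xyz))) {
    p <- xyz[r, ] * n
    i0 <- floor(p); f <- p - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      idx <- (c(i0[1] + dx, i0[2] + dy, i0[3] + dz)) %% n + 1
      wgt <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      acc <- acc + wgt * g[idx[1], idx[2], idx[3]]
    }
    out[r] <- acc
  }
  out
}
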