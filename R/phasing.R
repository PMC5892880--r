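## SIR-style phasing from a damage substructure, solvent-flattening
## density modification, handedness choice and signed-site bootstrapping.

## F_H of a signed substructure: sulfur form factor x signed occupancy x
## one overall B, summed over symmetry.
substructureFH <- function(hkl, sites, sg, d, bSub = 5) {
  f <- formFactor("S", 1 / (4 * d * d))
  Fc <- complex(real = numeric(nrow(rbind(hkl))))
  xyz <- as.matrix(sites[, c("x", "y", "z"), drop = FALSE])
  hkl <- rbind(hkl)
  for (op in sg@ops) {
    hm <- hkl %*% op$R
    ph <- exp(2i * pi * (hm %*% t(xyz) + as.vector(hkl %*% op$t)))
    Fc <- Fc + as.vector(ph %*% sites$occ)
  }
  Fc * f * exp(-bSub / (4 * d^2))
}

#' Initial SIR-style phase estimate from a damage substructure
#'
#' The damaged sites play the heavy-atom role: with
#' `F_after = F_before - F_H`, the lack of closure at trial phase phi is
#' `eps(phi) = |F_a|_obs - |F_b e^(i phi) - F_H|` and the phase
#' probability is `P(phi) ~ exp(-eps^2 / 2 sigma^2)`, evaluated on a 5
#' degree grid (acentric) or on the two allowed phases (centric). The
#' output phase is the probability centroid and the figure of merit
#' `m = |<e^(i phi)>_P|`. The substructure amplitude is put on the
#' difference scale by a single least-squares factor, and sigma combines
#' the propagated measurement errors with a per-shell non-isomorphism term
#' estimated from the minimal lack of closure.
#'
#' @param before,after [AmplitudeSet-class] objects (after on the before
#'   scale).
#' @param substructure a [Substructure-class] with signed occupancies.
#' @param cell,sg cell and space group.
#' @param K extra down-weighting applied to the after amplitudes.
#' @param bSub overall B of the substructure model (A^2).
#' @param gridDeg phase grid step in degrees.
#' @return a [PhaseEstimate-class] for the before dataset.
#' @export
initialSirPhases <- function(before, after, substructure, cell, sg,
                             K = 1, bSub = 5, gridDeg = 5) {
  if (!nrow(substructure@sites)) stop("empty substructure")
  b <- before@data; a <- after@data
  b$id <- encodeHKL(b$h, b$k, b$l); a$id <- encodeHKL(a$h, a$k, a$l)
  m <- merge(b, a[, c("id", "F", "sigF")], by = "id",
             suffixes = c("b", "a"))
  if (!nrow(m)) stop("no common indices")
  hkl <- as.matrix(m[, c("h", "k", "l")])
  FH <- substructureFH(hkl, substructure@sites, sg, m$d, bSub)
  if (all(Mod(FH) < 1e-12)) stop("empty substructure signal: |F_H| = 0")
  Fa <- K * m$Fa; sigFa <- K * m$sigFa
  ## one least-squares scale puts |F_H| on the observed difference scale
  dFobs <- m$Fb - Fa
  alpha <- sum(abs(dFobs) * Mod(FH)) / sum(Mod(FH)^2)
  FH <- FH * max(alpha, 1e-9)
  phiH <- Arg(FH); modH <- Mod(FH)
  sig2meas <- m$sigFb^2 + sigFa^2
  epsAt <- function(phi) {
    ## |F_b e^(i phi) - F_H| for phase grid `phi` (vector): n x g matrix
    co <- cos(outer(-phiH, phi, "+"))
    sqrt(pmax(m$Fb^2 + modH^2 - 2 * m$Fb * modH * co, 0)) - Fa
  }
  phiGrid <- seq(0, 2 * pi - 1e-9, by = gridDeg * pi / 180)
  eps <- epsAt(phiGrid)
  ## two-pass sigma: non-isomorphism term per shell from the minimal
  ## lack of closure
  epsMin2 <- apply(eps, 1, function(r) min(r^2))
  sh <- shellIndex(m$d, 10)
  niso2 <- as.vector(tapply(pmax(epsMin2 - sig2meas, 0), sh,
                            mean)[as.character(sh)])
  sig2 <- sig2meas + niso2
  centric <- m$centric
  phase <- fom <- numeric(nrow(m))
  P <- exp(-(eps^2) / (2 * sig2))
  ## centroid over the acentric grid
  Z <- rowSums(P)
  cvec <- (P %*% exp(1i * phiGrid)) / pmax(Z, 1e-300)
  phase <- Arg(cvec) * 180 / pi
  fom <- pmin(1, Mod(cvec))
  if (any(centric)) {
    phi0 <- centricPhase(hkl[centric, , drop = FALSE], sg) * pi / 180
    epsC <- function(phi) {
      co <- cos(phi - phiH[centric])
      sqrt(pmax(m$Fb[centric]^2 + modH[centric]^2 -
                2 * m$Fb[centric] * modH[centric] * co, 0)) - Fa[centric]
    }
    p1 <- exp(-epsC(phi0)^2 / (2 * sig2[centric]))
    p2 <- exp(-epsC(phi0 + pi)^2 / (2 * sig2[centric]))
    cv <- (p1 * exp(1i * phi0) + p2 * exp(1i * (phi0 + pi))) /
      pmax(p1 + p2, 1e-300)
    phase[centric] <- Arg(cv) * 180 / pi
    fom[centric] <- pmin(1, Mod(cv))
  }
  new("PhaseEstimate",
      data = data.frame(h = m$h, k = m$k, l = m$l, phase = phase,
                        fom = fom, d = m$d, centric = centric))
}

#' Solvent-flattening density modification
#'
#' Per cycle: Fourier map from the figure-of-merit weighted amplitudes
#' and current phases; a solvent mask from the local density variance at
#' the quantile matching the solvent fraction (a smoothed-density
#' envelope is unreliable when the weakly constrained lowest-resolution
#' phases are poor); solvent flipped about its mean (flattened when
#' `flipFactor = 0`); inverse transform; the modified-map phase combined
#' with the input phase distribution, which anchors all cycles; centric
#' phases snap to their allowed values; figures of merit update with a
#' map-consistency weight. `nCycles = 0` returns the input unchanged.
#'
#' @param phases a [PhaseEstimate-class].
#' @param amplitudes the matching [AmplitudeSet-class] (the before set).
#' @param cell,sg cell and space group.
#' @param solventFraction fraction of the cell flattened, in [0, 1).
#' @param nCycles number of cycles.
#' @param bSmooth smoothing B (A^2) of the variance envelope.
#' @param flipFactor solvent flipping factor (0 = classical flattening).
#' @return list with `phases` (updated [PhaseEstimate-class]) and `map`
#'   (the final flattened [RealMap-class]).
#' @export
densityModify <- function(phases, amplitudes, cell, sg, solventFraction,
                          nCycles = 5, bSmooth = 60, flipFactor = 1) {
  if (solventFraction >= 1 || solventFraction < 0)
    stop("solvent fraction must lie in [0, 1)")
  ph <- phases@data
  am <- amplitudes@data
  am$id <- encodeHKL(am$h, am$k, am$l)
  ph$id <- encodeHKL(ph$h, ph$k, ph$l)
  m <- merge(ph, am[, c("id", "F")], by = "id")
  m <- m[order(-m$d), , drop = FALSE]
  hkl <- as.matrix(m[, c("h", "k", "l")])
  dMin <- min(m$d)
  gridSize <- mapGridSize(cell, dMin)
  phi0cen <- centricPhase(hkl, sg)
  ## the input phase distribution anchors every cycle: the flipped-map
  ## phase is combined with it, never allowed to drift freely
  anchorPhi <- m$phase * pi / 180
  anchorFom <- m$fom
  map <- NULL
  fomOut <- anchorFom
  for (cyc in seq_len(max(nCycles, 0))) {
    ## synthesis always uses the anchor figures of merit: feeding the
    ## inflating output foms back into the map degrades it
    coeff <- complex(modulus = anchorFom * m$F,
                     argument = m$phase * pi / 180)
    map <- mapFromCoefficients(cell, sg, hkl, coeff, dMin, gridSize)
    protein <- proteinEnvelope(map@grid, cell, solventFraction, bSmooth)
    g <- map@grid
    mu <- mean(g[!protein])
    g[!protein] <- mu - flipFactor * (g[!protein] - mu)
    flat <- new("RealMap", grid = g, cell = cell)
    G <- structureFactorsFromMap(flat, hkl)
    ## map-consistency weight: strong flipped-map amplitude relative to
    ## its shell mean earns phase influence; the weight ramps up over the
    ## first three cycles so the estimate approaches the blended fixed
    ## point from the anchor side (monotone in practice)
    X <- Mod(G) / pmax(ave(Mod(G), shellIndex(m$d, 10)), 1e-12)
    w <- min(1, cyc / 3) * X / (1 + X)
    v <- anchorFom * exp(1i * anchorPhi) + w * exp(1i * Arg(G))
    newPhase <- Arg(v) * 180 / pi
    ## centric reflections keep their allowed phase pair
    cen <- m$centric
    if (any(cen)) {
      d1 <- abs(wrapDelta((newPhase[cen] - phi0cen[cen]) / 360)) * 360
      newPhase[cen] <- ifelse(d1 <= 90, phi0cen[cen], phi0cen[cen] + 180)
    }
    m$phase <- newPhase
    fomOut <- pmin(0.999, 1 - (1 - anchorFom) * (1 - w))
  }
  m$fom <- fomOut
  if (is.null(map)) {
    coeff <- complex(modulus = m$fom * m$F, argument = m$phase * pi / 180)
    map <- mapFromCoefficients(cell, sg, hkl, coeff, dMin, gridSize)
  }
  out <- phases
  keep <- c("h", "k", "l", "phase", "fom", "d", "centric")
  out@data <- m[, keep]
  rownames(out@data) <- NULL
  list(phases = out, map = map)
}

## Map contrast: variance of a locally averaged map over the protein
## (non-solvent) region.
mapContrast <- function(map, solventFraction, cell, sg, hkl, dMin,
                        bSmooth = 60) {
  protein <- proteinEnvelope(map@grid, cell, solventFraction, bSmooth)
  sm <- smoothMapGrid(map@grid, cell, bSmooth)
  var(as.vector(sm[protein]))
}

#' Choose the substructure hand
#'
#' Phases with the substructure and with its inverted copy (-x, -y, -z;
#' valid in the self-enantiomorphic preset groups) through SIR +
#' density modification, and keeps the hand with the higher map contrast
#' (variance of the locally averaged map over the protein region). Ties
#' break to the original hand.
#'
#' @param before,after [AmplitudeSet-class] objects.
#' @param substructure a [Substructure-class].
#' @param cell,sg cell and space group.
#' @param solventFraction solvent fraction for density modification.
#' @param K after-set down-weighting.
#' @param nCycles density-modification cycles per hand.
#' @return list with `hand` ("original" or "inverted"), `substructure`
#'   (the winning hand's sites), `phases`, `map`, and `contrast` (named
#'   numeric, both hands).
#' @export
chooseHand <- function(before, after, substructure, cell, sg,
                       solventFraction = 0.5, K = 1, nCycles = 5) {
  inv <- substructure
  inv@sites$x <- wrapFrac(-inv@sites$x)
  inv@sites$y <- wrapFrac(-inv@sites$y)
  inv@sites$z <- wrapFrac(-inv@sites$z)
  run <- function(sub) {
    pe <- initialSirPhases(before, after, sub, cell, sg, K = K)
    dm <- densityModify(pe, before, cell, sg, solventFraction, nCycles)
    hkl <- as.matrix(dm$phases@data[, c("h", "k", "l")])
    ctr <- mapContrast(dm$map, solventFraction, cell, sg, hkl,
                       min(dm$phases@data$d))
    list(dm = dm, contrast = ctr)
  }
  r1 <- run(substructure)
  r2 <- run(inv)
  contrast <- c(original = r1$contrast, inverted = r2$contrast)
  pickInv <- r2$contrast > r1$contrast + 1e-12
  list(hand = if (pickInv) "inverted" else "original",
       substructure = if (pickInv) inv else substructure,
       phases = if (pickInv) r2$dm$phases else r1$dm$phases,
       map = if (pickInv) r2$dm$map else r1$dm$map,
       contrast = contrast)
}

#' Bootstrap the full signed substructure from difference Fourier maps
#'
#' Iterates rounds of: sigma-normalized (F_before - K F_after) difference
#' Fourier synthesis with the current phases; addition of map peaks above
#' `+threshold` sigma as positive sites and below `-threshold` sigma as
#' negative sites (deduplicated against the current sites under symmetry);
#' SIR re-phasing with the extended signed substructure. Stops when a
#' round adds no site or `maxRounds` is reached.
#'
#' @param phases current [PhaseEstimate-class].
#' @param before,after [AmplitudeSet-class] objects.
#' @param K after-set down-weighting.
#' @param substructure current [Substructure-class].
#' @param cell,sg cell and space group.
#' @param threshold peak threshold in map sigma units (default 6).
#' @param maxRounds maximum bootstrap rounds.
#' @return list with `substructure` (signed sites), `phases`, and
#'   `rounds` (number of rounds executed).
#' @export
bootstrapSites <- function(phases, before, after, K, substructure, cell,
                           sg, threshold = 6, maxRounds = 4) {
  stopifnot(threshold > 0)
  sub <- substructure
  pe <- phases
  rounds <- 0L
  for (rd in seq_len(maxRounds)) {
    dmap <- differenceFourier(pe, before, after, K, cell, sg)
    g <- dmap@grid
    sdg <- sd(as.vector(g))
    norm <- new("RealMap", grid = (g - mean(g)) / sdg, cell = cell)
    newSites <- list()
    pos <- gridPeaks(norm, nTop = 30, minValue = threshold)
    if (nrow(pos)) newSites$pos <- cbind(pos[, c("x", "y", "z")],
                                         occ = 1, height = pos$value)
    negMap <- new("RealMap", grid = -norm@grid, cell = cell)
    neg <- gridPeaks(negMap, nTop = 30, minValue = threshold)
    if (nrow(neg)) newSites$neg <- cbind(neg[, c("x", "y", "z")],
                                         occ = -1, height = -neg$value)
    if (!length(newSites)) break
    cand <- do.call(rbind, newSites)
    ## drop candidates already present (within 1 A under symmetry)
    fresh <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      p <- as.numeric(cand[i, c("x", "y", "z")])
      dmin <- Inf
      for (op in sg@ops) {
        img <- sweep(as.matrix(sub@sites[, c("x", "y", "z")]) %*%
                     t(op$R), 2, op$t, "+")
        dmin <- min(dmin, fracDistance(cell, img,
                                       matrix(p, nrow(img), 3,
                                              byrow = TRUE)))
      }
      fresh[i] <- dmin > 1
    }
    cand <- cand[fresh, , drop = FALSE]
    cand <- .filterPeakSites(cand, cell, sg, minDist = 1)
    if (!nrow(cand)) break
    rounds <- rounds + 1L
    relH <- abs(cand$height)
    add <- data.frame(x = cand$x, y = cand$y, z = cand$z,
                      occ = cand$occ * relH / max(relH),
                      height = cand$height)
    sub@sites <- rbind(sub@sites, add)
    pe <- initialSirPhases(before, after, sub, cell, sg, K = K)
  }
  list(substructure = sub, phases = pe, rounds = rounds)
}

## Difference Fourier synthesis with current phases:
## (F_b - K F_a) m e^{i phi}.
differenceFourier <- function(phases, before, after, K, cell, sg) {
  b <- before@data; a <- after@data
  p <- phases@data
  b$id <- encodeHKL(b$h, b$k, b$l)
  a$id <- encodeHKL(a$h, a$k, a$l)
  p$id <- encodeHKL(p$h, p$k, p$l)
  m <- merge(merge(p, b[, c("id", "F")], by = "id"),
             a[, c("id", "F")], by = "id", suffixes = c("b", "a"))
  dF <- m$Fb - K * m$Fa
  coeff <- complex(modulus = abs(dF) * m$fom, argument =
                   (m$phase + ifelse(dF < 0, 180, 0)) * pi / 180)
  mapFromCoefficients(cell, sg, as.matrix(m[, c("h", "k", "l")]),
                      coeff, min(m$d))
}
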