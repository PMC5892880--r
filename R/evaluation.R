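## Evaluation battery: model-phased difference maps, peak search,
## substructure correctness under the allowed equivalences, and weighted
## mean phase error.

#' Model-phased isomorphous difference map
#'
#' Fourier synthesis with coefficients `(F_before - K F_after)
#' e^(i phi_ref)` using reference (ground-truth or refined-model) phases,
#' normalized to sigma units (zero mean, unit rms).
#'
#' @param before,after [AmplitudeSet-class] objects on a common scale.
#' @param K after-set down-weighting.
#' @param refPhases reference phase table (data.frame h, k, l, phase) or a
#'   [PhaseEstimate-class].
#' @param cell,sg cell and space group.
#' @param maxMissing error when reference phases are missing for more than
#'   this fraction of the common indices.
#' @return a [RealMap-class] in sigma units.
#' @export
modelPhasedDifferenceMap <- function(before, after, K, refPhases, cell, sg,
                                     maxMissing = 0.2) {
  if (is(refPhases, "PhaseEstimate")) refPhases <- refPhases@data
  b <- before@data; a <- after@data
  b$id <- encodeHKL(b$h, b$k, b$l)
  a$id <- encodeHKL(a$h, a$k, a$l)
  m <- merge(b, a[, c("id", "F")], by = "id", suffixes = c("b", "a"))
  rp <- refPhases
  rp$id <- encodeHKL(rp$h, rp$k, rp$l)
  mm <- merge(m, rp[, c("id", "phase")], by = "id")
  if (nrow(mm) < (1 - maxMissing) * nrow(m))
    stop("insufficient reference phases: missing for more than ",
         round(100 * maxMissing), "% of the common indices")
  dF <- mm$Fb - K * mm$Fa
  coeff <- complex(modulus = abs(dF),
                   argument = (mm$phase + ifelse(dF < 0, 180, 0)) * pi / 180)
  map <- mapFromCoefficients(cell, sg, as.matrix(mm[, c("h", "k", "l")]),
                             coeff, min(mm$d))
  g <- map@grid
  sdg <- sd(as.vector(g))
  if (sdg < 1e-300) sdg <- 1   # null difference map stays flat at zero
  new("RealMap", grid = (g - mean(g)) / sdg, cell = cell)
}

#' Search a sigma-normalized map for peaks
#'
#' Local maxima above `+threshold` and minima below `-threshold` (reported
#' with negative heights), positions refined by per-axis quadratic
#' interpolation, symmetry-equivalent peaks reduced to one representative.
#'
#' @param map a [RealMap-class] (sigma units; normalize first otherwise).
#' @param threshold height threshold in map sigma units.
#' @param cell,sg cell and space group.
#' @param nTop cap on the number of reported peaks per sign.
#' @return data.frame x, y, z, height, sorted by decreasing |height|.
#' @export
peakSearch <- function(map, threshold, cell, sg, nTop = 50) {
  stopifnot(threshold > 0)
  pos <- gridPeaks(map, nTop = nTop, minValue = threshold)
  neg <- gridPeaks(new("RealMap", grid = -map@grid, cell = map@cell),
                   nTop = nTop, minValue = threshold)
  pk <- rbind(
    if (nrow(pos)) data.frame(x = pos$x, y = pos$y, z = pos$z,
                              height = pos$value),
    if (nrow(neg)) data.frame(x = neg$x, y = neg$y, z = neg$z,
                              height = -neg$value))
  if (is.null(pk) || !nrow(pk))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      height = numeric(0)))
  ## deduplicate symmetry mates: canonical representative by orbit
  canon <- vapply(seq_len(nrow(pk)), function(i) {
    p <- as.numeric(pk[i, c("x", "y", "z")])
    orb <- do.call(rbind, lapply(sg@ops, function(op)
      wrapFrac(as.vector(op$R %*% p) + op$t)))
    key <- round(orb, 3)
    scores <- key[, 1] * 1e6 + key[, 2] * 1e3 + key[, 3]
    paste(key[which.min(scores), ], collapse = ",")
  }, "")
  ord <- order(-abs(pk$height))
  pk <- pk[ord, , drop = FALSE]
  canon <- canon[ord]
  pk <- pk[!duplicated(canon), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

## Minimal distance between two site sets under the space group: for each
## row of `a`, the distance to the nearest symmetry image of `b` rows.
## Returns the distance matrix (nrow(a) x nrow(b)).
siteDistanceMatrix <- function(a, b, cell, sg) {
  a <- as.matrix(a); b <- as.matrix(b)
  out <- matrix(Inf, nrow(a), nrow(b))
  for (op in sg@ops) {
    img <- sweep(b %*% t(op$R), 2, op$t, "+")
    for (j in seq_len(nrow(b))) {
      dd <- fracDistance(cell, matrix(img[j, ], nrow(a), 3, byrow = TRUE),
                         a)
      out[, j] <- pmin(out[, j], dd)
    }
  }
  out
}

#' Substructure correctness against a reference
#'
#' Percent of reference sites matched one-to-one by candidate sites within
#' `tolerance` Angstrom, maximized over the allowed origin shifts and hand
#' inversion, with per-site distances minimized over the symmetry
#' operators. Matching is greedy by ascending distance. For polar (P1)
#' axes the continuous origin component is searched over candidate-to-
#' reference difference vectors.
#'
#' @param candidate,reference [Substructure-class] objects or site
#'   data.frames with x, y, z.
#' @param cell,sg cell and space group.
#' @param tolerance match tolerance in Angstrom (default 1.5).
#' @return list with `percent`, `nMatched`, `nReference`, `pairs`
#'   (matched index pairs with distances), `originShift`, `hand`.
#' @export
substructureCorrectness <- function(candidate, reference, cell, sg,
                                    tolerance = 1.5) {
  cs <- if (is(candidate, "Substructure")) candidate@sites else candidate
  rs <- if (is(reference, "Substructure")) reference@sites else reference
  if (!nrow(rs)) stop("empty reference substructure")
  if (!nrow(cs))
    return(list(percent = 0, nMatched = 0L, nReference = nrow(rs),
                pairs = NULL, originShift = c(0, 0, 0), hand = "original"))
  cmat0 <- as.matrix(cs[, c("x", "y", "z")])
  rmat <- as.matrix(rs[, c("x", "y", "z")])
  shifts <- sg@originShifts
  if (any(sg@polarAxes)) {
    ## candidate shifts aligning each candidate site onto each reference
    ## site along the polar axes
    extra <- list()
    for (i in seq_len(min(nrow(cmat0), 4)))
      for (j in seq_len(nrow(rmat))) {
        sft <- (rmat[j, ] - cmat0[i, ]) * sg@polarAxes
        extra[[length(extra) + 1L]] <- sft
      }
    shifts <- rbind(shifts, do.call(rbind, extra))
  }
  best <- list(percent = -1)
  for (hand in c("original", "inverted")) {
    cmat <- if (hand == "inverted") wrapFrac(-cmat0) else cmat0
    for (si in seq_len(nrow(shifts))) {
      cshift <- wrapFrac(sweep(cmat, 2, shifts[si, ], "+"))
      D <- siteDistanceMatrix(rmat, cshift, cell, sg)
      ## greedy one-to-one matching by ascending distance
      pairs <- NULL
      usedR <- logical(nrow(rmat)); usedC <- logical(nrow(cshift))
      ord <- order(D)
      for (o in ord) {
        if (D[o] > tolerance) break
        ri <- (o - 1) %% nrow(rmat) + 1
        ci <- (o - 1) %/% nrow(rmat) + 1
        if (usedR[ri] || usedC[ci]) next
        usedR[ri] <- TRUE; usedC[ci] <- TRUE
        pairs <- rbind(pairs, data.frame(ref = ri, cand = ci,
                                         dist = D[o]))
      }
      nM <- sum(usedR)
      pct <- 100 * nM / nrow(rmat)
      if (pct > best$percent)
        best <- list(percent = pct, nMatched = nM,
                     nReference = nrow(rmat), pairs = pairs,
                     originShift = shifts[si, ], hand = hand)
      if (best$percent >= 100) break
    }
    if (best$percent >= 100) break
  }
  best$tolerance <- tolerance
  best
}

#' Reference pseudo-atom substructure from the model-phased map
#'
#' Peaks of the model-phased difference map above the threshold (6 sigma
#' by convention), positive and negative, as a reference substructure for
#' correctness scoring.
#'
#' @param before,after,K,refPhases,cell,sg as in
#'   [modelPhasedDifferenceMap()].
#' @param threshold sigma threshold for retained peaks.
#' @return a [Substructure-class].
#' @export
referenceSubstructure <- function(before, after, K, refPhases, cell, sg,
                                  threshold = 6) {
  map <- modelPhasedDifferenceMap(before, after, K, refPhases, cell, sg)
  pk <- peakSearch(map, threshold, cell, sg)
  sites <- data.frame(x = pk$x, y = pk$y, z = pk$z,
                      occ = sign(pk$height), height = pk$height)
  new("Substructure", sites = sites, ccAll = NA_real_, ccWeak = NA_real_,
      meta = list(kind = "model-phased reference", threshold = threshold))
}

#' Weighted mean phase error
#'
#' `wMPE = sum(w |dphi|) / sum(w)` with the circular phase difference in
#' [0, 180] degrees and default weights `w = fom * |F|`. When `align` is
#' TRUE the estimate is first aligned to the truth over the allowed origin
#' shifts (phase ramps `-360 h.t`) and hand inversion (phi -> -phi).
#'
#' @param estimate a [PhaseEstimate-class] (or data.frame with h, k, l,
#'   phase and optionally fom).
#' @param truth reference phase table (data.frame h, k, l, phase,
#'   optionally Fmod).
#' @param sg a [SpaceGroup-class] (needed for alignment).
#' @param weights "fomF" (default), "fom", or "equal".
#' @param align search allowed origin shifts and hand inversion.
#' @param nShells shells for the per-shell report.
#' @return list with `wmpe` (degrees), `hand`, `originShift`, `perShell`.
#' @export
wmpe <- function(estimate, truth, sg, weights = c("fomF", "fom", "equal"),
                 align = TRUE, nShells = 5) {
  weights <- match.arg(weights)
  ed <- if (is(estimate, "PhaseEstimate")) estimate@data else estimate
  td <- truth
  ed$id <- encodeHKL(ed$h, ed$k, ed$l)
  td$id <- encodeHKL(td$h, td$k, td$l)
  m <- merge(ed, td[, c("id", "phase",
                        intersect("Fmod", names(td)))],
             by = "id", suffixes = c("", ".true"))
  if (nrow(m) < 10) stop("need at least 10 common indices")
  w <- switch(weights,
              equal = rep(1, nrow(m)),
              fom = if ("fom" %in% names(m)) m$fom else rep(1, nrow(m)),
              fomF = {
                f <- if ("Fmod" %in% names(m)) m$Fmod else 1
                (if ("fom" %in% names(m)) m$fom else 1) * f
              })
  hklm <- as.matrix(m[, c("h", "k", "l")])
  err <- function(est) {
    dphi <- abs(wrapDelta((est - m$phase.true) / 360)) * 360
    sum(w * dphi) / sum(w)
  }
  cands <- list(list(hand = "original", shift = c(0, 0, 0)))
  if (align) {
    cands <- list()
    for (hand in c("original", "inverted"))
      for (si in seq_len(nrow(sg@originShifts)))
        cands[[length(cands) + 1L]] <-
          list(hand = hand, shift = sg@originShifts[si, ])
  }
  best <- NULL
  for (cd in cands) {
    est <- if (cd$hand == "inverted") -m$phase else m$phase
    est <- est + 360 * as.vector(hklm %*% cd$shift)
    e <- err(est)
    if (is.null(best) || e < best$wmpe)
      best <- list(wmpe = e, hand = cd$hand, originShift = cd$shift)
  }
  ## per-shell report under the winning alignment
  est <- if (best$hand == "inverted") -m$phase else m$phase
  est <- est + 360 * as.vector(hklm %*% best$originShift)
  dphi <- abs(wrapDelta((est - m$phase.true) / 360)) * 360
  if ("d" %in% names(m)) {
    sh <- shellIndex(m$d, nShells)
    perShell <- data.frame(
      shell = sort(unique(sh)),
      dHigh = as.vector(tapply(m$d, sh, min)),
      wmpe = as.vector(tapply(w * dphi, sh, sum) / tapply(w, sh, sum)),
      n = as.vector(tapply(w, sh, length)))
  } else perShell <- NULL
  best$perShell <- perShell
  best$n <- nrow(m)
  best$weights <- weights
  best
}
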