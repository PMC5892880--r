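## Merging: scaling to a reference, inverse-variance merging, and the
## standard multi-crystal merging statistics.

#' Pick the reference sub-dataset of a pool
#'
#' The "strongest" sub-dataset, operationalized as the largest summed
#' I/sigma; ties break to the lowest list position.
#'
#' @param subs list of [SubDataset-class].
#' @return index of the reference within `subs`.
#' @export
chooseReference <- function(subs) {
  strength <- vapply(subs, function(s)
    sum(s@observations$I / s@observations$sigI), 0)
  which.max(strength)   # which.max returns the first (lowest id) maximum
}

#' Scale a sub-dataset onto a reference
#'
#' Least-squares fit of `log(I_ref / I_sub) = log k + B s^2 / 2` over the
#' common positive-intensity unique reflections (s = 1/d), then multiplies
#' the sub-dataset's intensities and sigmas by the fitted resolution-
#' dependent factor.
#'
#' @param sub,reference [SubDataset-class] objects.
#' @param sg the [SpaceGroup-class] used to identify common unique
#'   reflections.
#' @param nMin minimum number of common reflections required.
#' @return the scaled [SubDataset-class]; the fitted `k` and `B` are
#'   attached as attributes `"k"` and `"B"` of the observations slot.
#' @export
scaleToReference <- function(sub, reference, sg, nMin = 20) {
  oS <- sub@observations
  oR <- reference@observations
  idS <- asuId(oS, sg); idR <- asuId(oR, sg)
  ## collapse within-dataset duplicates by plain means for the fit
  mS <- rowsum(cbind(oS$I, 1 / oS$d^2), idS)
  nS <- as.vector(rowsum(rep(1, nrow(oS)), idS))
  mR <- rowsum(oR$I, idR)
  nR <- as.vector(rowsum(rep(1, nrow(oR)), idR))
  dfS <- data.frame(id = as.numeric(rownames(mS)), I = mS[, 1] / nS,
                    s2 = mS[, 2] / nS)
  dfR <- data.frame(id = as.numeric(rownames(mR)), I = mR / nR)
  m <- merge(dfS, dfR, by = "id", suffixes = c(".s", ".r"))
  m <- m[m$I.s > 0 & m$I.r > 0, , drop = FALSE]
  if (nrow(m) < nMin)
    stop("insufficient overlap: ", nrow(m), " common reflections (need ",
         nMin, ")")
  y <- log(m$I.r / m$I.s)
  fit <- lm(y ~ m$s2)
  k <- exp(coef(fit)[[1]])
  B <- 2 * coef(fit)[[2]]
  fac <- k * exp(B * (1 / oS$d^2) / 2)
  oS$I <- oS$I * fac
  oS$sigI <- oS$sigI * fac
  attr(oS, "k") <- k
  attr(oS, "B") <- B
  out <- sub
  out@observations <- oS
  out
}

## ASU id per observation row
asuId <- function(obs, sg) {
  m <- mapToAsu(as.matrix(obs[, c("h", "k", "l")]), sg)
  encodeHKL(m$asu[, 1], m$asu[, 2], m$asu[, 3])
}

## Pool the observations of several sub-datasets into one data.table with
## ASU indices, resolution (from `cell`) and a fixed split rank used by the
## half-dataset correlation. `memberId` records provenance.
poolObservations <- function(subs, sg, cell, splitSeed = 1) {
  dts <- lapply(seq_along(subs), function(i) {
    o <- subs[[i]]@observations
    m <- mapToAsu(as.matrix(o[, c("h", "k", "l")]), sg)
    data.table(id = encodeHKL(m$asu[, 1], m$asu[, 2], m$asu[, 3]),
               h = m$asu[, 1], k = m$asu[, 2], l = m$asu[, 3],
               centric = m$centric, I = o$I, sigI = o$sigI,
               d = dSpacing(cell, m$asu), memberId = i)
  })
  dt <- rbindlist(dts)
  dt[, u := withSeed(deriveSeed(splitSeed, "cc-half-split"),
                     runif(nrow(dt)))]
  dt
}

#' Merge scaled observations to unique reflections
#'
#' Inverse-variance weighted mean per ASU index with
#' `sigma = 1/sqrt(sum(1/sigma_i^2))` and recorded multiplicity.
#'
#' @param obs pooled observation data.table/data.frame with columns h, k, l
#'   (ASU representatives), I, sigI, d, centric (e.g. from several scaled
#'   sub-datasets).
#' @return data.frame of merged reflections: h, k, l, I, sigI, mult,
#'   centric, d.
#' @export
mergeObservations <- function(obs) {
  dt <- as.data.table(obs)
  if (!"id" %in% names(dt)) dt[, id := encodeHKL(h, k, l)]
  m <- dt[, {
    w <- 1 / sigI^2
    .(h = h[1], k = k[1], l = l[1], I = sum(w * I) / sum(w),
      sigI = 1 / sqrt(sum(w)), mult = .N, centric = centric[1], d = d[1])
  }, by = id]
  as.data.frame(m[order(-d)][, !"id"])
}

#' Merging statistics per resolution shell
#'
#' `R_merge = sum |I_i - <I>| / sum I_i` over multiplicity >= 2 groups with
#' unweighted group means; `R_meas` weights each group's numerator by
#' `sqrt(n/(n-1))`. `CC1/2` is the Pearson correlation between the means of
#' two fixed-seed random half-splits of every multiplicity >= 2 group.
#' Completeness counts observed unique indices against all theoretical ASU
#' indices to the pool's resolution limit. Shells are equal-volume in
#' 1/d^3.
#'
#' @param obs pooled observations (data.frame with h, k, l ASU indices, I,
#'   sigI, d; a precomputed split rank column `u` is used when present).
#' @param cell the [UnitCell-class] of the merged dataset.
#' @param sg the [SpaceGroup-class].
#' @param nShells number of resolution shells.
#' @param dMin completeness resolution limit; defaults to the pool minimum.
#' @param splitSeed seed of the half-split used by CC1/2.
#' @param theoretical optional precomputed data.frame of theoretical unique
#'   reflections (from [uniqueReflections()]) to speed repeated calls.
#' @return list with `overall` (one-row data.frame) and `shells`
#'   (per-shell data.frame). R values are reported as NA in shells with no
#'   multiplicity >= 2 group.
#' @export
shellStatistics <- function(obs, cell, sg, nShells = 10, dMin = NULL,
                            splitSeed = 1, theoretical = NULL) {
  dt <- as.data.table(obs)
  if (!"id" %in% names(dt)) dt[, id := encodeHKL(h, k, l)]
  if (!"u" %in% names(dt))
    dt[, u := withSeed(deriveSeed(splitSeed, "cc-half-split"),
                       runif(nrow(dt)))]
  if (is.null(dMin)) dMin <- min(dt$d)
  if (is.null(theoretical))
    theoretical <- uniqueReflections(cell, sg, dMin)
  qmax <- 1 / dMin^3
  shellOf <- function(d) pmin(nShells, pmax(1L, ceiling((1 / d^3) / qmax *
                                                        nShells)))
  dt[, shell := shellOf(d)]
  th <- data.table(d = theoretical$d)
  th[, shell := shellOf(d)]
  thCount <- th[, .N, by = shell]
  statsOf <- function(x) {
    ## x: data.table of observations (one shell, or everything)
    merged <- x[, .(Im = sum(I / sigI^2) / sum(1 / sigI^2),
                    sg2 = 1 / sum(1 / sigI^2), .N), by = id]
    grp <- x[, if (.N >= 2) {
      mu <- mean(I)
      o <- order(u)
      h1 <- I[o[seq(1, .N, by = 2)]]
      h2 <- I[o[seq(2, .N, by = 2)]]
      .(num = sum(abs(I - mu)), den = sum(I),
        numMeas = sqrt(.N / (.N - 1)) * sum(abs(I - mu)),
        m1 = mean(h1), m2 = mean(h2))
    }, by = id]
    rMerge <- rMeas <- cc <- NA_real_
    if (nrow(grp)) {
      rMerge <- sum(grp$num) / sum(grp$den)
      rMeas <- sum(grp$numMeas) / sum(grp$den)
      cc <- if (nrow(grp) >= 3 && sd(grp$m1) > 0 && sd(grp$m2) > 0)
        cor(grp$m1, grp$m2) else NA_real_
    }
    data.frame(IsigI = mean(merged$Im / sqrt(merged$sg2)),
               Rmerge = rMerge, Rmeas = rMeas, CChalf = cc,
               nObs = nrow(x), nUnique = nrow(merged),
               multiplicity = nrow(x) / nrow(merged))
  }
  shells <- do.call(rbind, lapply(seq_len(nShells), function(s) {
    xs <- dt[shell == s]
    nTh <- thCount[shell == s, N]
    if (!length(nTh)) nTh <- 0L
    dLim <- (qmax * c(s - 1, s) / nShells)^(-1 / 3)
    base <- data.frame(shell = s, dLow = dLim[1], dHigh = dLim[2])
    if (!nrow(xs))
      return(cbind(base, IsigI = NA, Rmerge = NA, Rmeas = NA, CChalf = NA,
                   nObs = 0L, nUnique = 0L, multiplicity = NA,
                   completeness = 0))
    st <- statsOf(xs)
    st$completeness <- if (nTh > 0) min(1, st$nUnique / nTh) else NA_real_
    cbind(base, st)
  }))
  overall <- statsOf(dt)
  overall$completeness <- min(1, overall$nUnique / nrow(theoretical))
  list(overall = overall, shells = shells)
}

#' Scale and merge a list of sub-datasets
#'
#' Convenience wrapper: chooses the reference ([chooseReference()]), scales
#' every member onto it ([scaleToReference()]), pools, merges and computes
#' statistics.
#'
#' @param subs list of [SubDataset-class].
#' @param sg a [SpaceGroup-class].
#' @param cell reference [UnitCell-class]; defaults to the reference
#'   sub-dataset's cell.
#' @param nShells resolution shells for the statistics.
#' @param scale set FALSE to merge without scaling.
#' @param splitSeed seed of the CC1/2 half split.
#' @return a [MergedDataset-class].
#' @export
mergePool <- function(subs, sg, cell = NULL, nShells = 10, scale = TRUE,
                      splitSeed = 1) {
  stopifnot(length(subs) >= 1)
  ref <- chooseReference(subs)
  if (is.null(cell)) cell <- subs[[ref]]@cell
  if (scale && length(subs) > 1) {
    subs <- lapply(seq_along(subs), function(i)
      if (i == ref) subs[[i]] else
        scaleToReference(subs[[i]], subs[[ref]], sg))
  }
  dt <- poolObservations(subs, sg, cell, splitSeed)
  merged <- mergeObservations(dt)
  st <- shellStatistics(dt, cell, sg, nShells, splitSeed = splitSeed)
  new("MergedDataset", reflections = merged, stats = st$overall,
      shells = st$shells, memberIds = seq_along(subs))
}
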