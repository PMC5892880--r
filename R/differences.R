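## Isomorphous difference amplitudes: intensity-to-amplitude conversion,
## the K scan, error propagation and the d'/sig(d') significance statistic.

#' Convert merged intensities to amplitudes
#'
#' Truncation rule: `F = sqrt(max(I, 0))`; `sigF = sigI / (2 F)` when `F`
#' exceeds the sigma floor, otherwise `sigF = sqrt(sigI)` (the linearized
#' error blows up near F = 0).
#'
#' @param merged a [MergedDataset-class] (or its reflections data.frame).
#' @param sourceId identifier stored with the output.
#' @return an [AmplitudeSet-class].
#' @export
intensitiesToAmplitudes <- function(merged, sourceId = "") {
  r <- if (is(merged, "MergedDataset")) merged@reflections else merged
  if (!nrow(r)) stop("empty merged dataset")
  F <- sqrt(pmax(r$I, 0))
  floorF <- sqrt(pmax(r$sigI, 1e-12))   # sigma floor in amplitude units
  sigF <- ifelse(F > floorF, r$sigI / (2 * pmax(F, 1e-12)), floorF)
  sigF <- pmax(sigF, 1e-12)
  new("AmplitudeSet",
      data = data.frame(h = r$h, k = r$k, l = r$l, F = F, sigF = sigF,
                        d = r$d, centric = r$centric),
      sourceId = as.character(sourceId))
}

#' K-scaled difference amplitudes
#'
#' `dF = F_before - K * F_after` on the common ASU indices (the after set
#' must already be scaled onto the before set by conventional scaling; K is
#' the deliberate extra down-weighting applied on top). Sigmas propagate as
#' `sqrt(sig_b^2 + K^2 sig_a^2)`. Normalized difference magnitudes E are
#' |dF| scaled so the rms over each resolution shell is 1.
#'
#' @param before,after [AmplitudeSet-class] objects on a common indexing.
#' @param K scale applied to the after amplitudes.
#' @param nShells shells for the E normalization.
#' @param dMin optional high-resolution cutoff applied to the differences.
#' @return a [DifferenceSet-class].
#' @export
differenceAmplitudes <- function(before, after, K = 1, nShells = 10,
                                 dMin = NULL) {
  b <- before@data; a <- after@data
  b$id <- encodeHKL(b$h, b$k, b$l)
  a$id <- encodeHKL(a$h, a$k, a$l)
  m <- merge(b, a[, c("id", "F", "sigF")], by = "id",
             suffixes = c("b", "a"))
  nDropped <- (nrow(b) - nrow(m)) + (nrow(a) - nrow(m))
  if (!nrow(m)) stop("disjoint amplitude sets: no common indices")
  if (!is.null(dMin)) m <- m[m$d >= dMin, , drop = FALSE]
  if (!nrow(m)) stop("no reflections left after resolution cutoff")
  dF <- m$Fb - K * m$Fa
  sigdF <- sqrt(m$sigFb^2 + K^2 * m$sigFa^2)
  out <- data.frame(h = m$h, k = m$k, l = m$l, dF = dF, sigdF = sigdF,
                    E = 0, d = m$d, centric = m$centric,
                    Fb = m$Fb, Fa = m$Fa)
  out$E <- normalizeByShellRms(abs(dF), out$d, nShells)
  new("DifferenceSet", data = out[order(-out$d), , drop = FALSE], K = K,
      dMin = if (is.null(dMin)) min(out$d) else dMin,
      nDropped = as.integer(nDropped))
}

## Scale values so their rms is 1 within each equal-volume resolution shell.
normalizeByShellRms <- function(x, d, nShells = 10) {
  sh <- shellIndex(d, nShells)
  rms <- sqrt(tapply(x^2, sh, mean))
  x / rms[as.character(sh)]
}

## Equal-volume (1/d^3) shell index relative to the data's own d range.
shellIndex <- function(d, nShells) {
  q <- 1 / d^3
  qmax <- max(q) * (1 + 1e-9)
  pmin(nShells, pmax(1L, ceiling(q / qmax * nShells)))
}

#' The K grid of the scale-factor scan
#'
#' @param kMin,kMax grid limits.
#' @param step grid increment.
#' @return arithmetic sequence from `kMin` in steps of `step`, not
#'   exceeding `kMax`.
#' @export
kGrid <- function(kMin = 0.97, kMax = 1.01, step = 0.00211) {
  if (step <= 0) stop("invalid K grid: step must be positive")
  stopifnot(kMin < kMax)
  seq(kMin, kMax + 1e-12, by = step)
}

#' Shell-wise difference significance d'/sig(d') and resolution cutoff
#'
#' The statistic is the shell mean of `|dF| / sig(dF)`. The suggested
#' high-resolution cutoff is the low-resolution boundary of the first shell
#' (scanning towards high resolution) whose statistic falls below the
#' threshold; if no shell falls below, the data's own limit is returned.
#'
#' @param diffset a [DifferenceSet-class].
#' @param nShells number of shells.
#' @param threshold significance threshold (default 1.5; values up to
#'   about 2.5 are reasonable when the cutoff proves too optimistic).
#' @return list with `shells` (data.frame dLow, dHigh, stat, n) and
#'   `cutoff` (suggested d_min in Angstrom).
#' @export
dprimeSignificance <- function(diffset, nShells = 10, threshold = 1.5) {
  d <- diffset@data
  if (!nrow(d)) stop("empty difference set")
  sh <- shellIndex(d$d, nShells)
  stat <- tapply(abs(d$dF) / d$sigdF, sh, mean)
  dLow <- tapply(d$d, sh, max)
  dHigh <- tapply(d$d, sh, min)
  n <- tapply(d$d, sh, length)
  shells <- data.frame(shell = as.integer(names(stat)),
                       dLow = as.vector(dLow), dHigh = as.vector(dHigh),
                       stat = as.vector(stat), n = as.vector(n))
  shells <- shells[order(shells$shell), , drop = FALSE]
  below <- which(shells$stat < threshold)
  cutoff <- if (length(below)) shells$dLow[below[1]] else min(d$d)
  list(shells = shells, cutoff = cutoff)
}
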