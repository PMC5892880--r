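#' Construct a unit cell
#'
#' @param a,b,c edge lengths in Angstrom.
#' @param alpha,beta,gamma angles in degrees (default orthorhombic).
#' @return a [UnitCell-class].
#' @examples
#' unitCell(30, 35, 40)
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  new("UnitCell", a = a, b = b, c = c, alpha = alpha, beta = beta,
      gamma = gamma)
}

#' Unit-cell volume in cubic Angstrom
#' @param cell a [UnitCell-class].
#' @export
cellVolume <- function(cell) {
  ca <- cos(cell@alpha * pi / 180)
  cb <- cos(cell@beta * pi / 180)
  cg <- cos(cell@gamma * pi / 180)
  v <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  cell@a * cell@b * cell@c * sqrt(max(v, 0))
}

## Real-space metric tensor G (fractional -> Angstrom^2 via x' G x)
metricTensor <- function(cell) {
  ca <- cos(cell@alpha * pi / 180)
  cb <- cos(cell@beta * pi / 180)
  cg <- cos(cell@gamma * pi / 180)
  a <- cell@a; b <- cell@b; cc <- cell@c
  matrix(c(a * a, a * b * cg, a * cc * cb,
           a * b * cg, b * b, b * cc * ca,
           a * cc * cb, b * cc * ca, cc * cc), 3, 3)
}

## Fractional -> Cartesian orthogonalization matrix (columns are cell axes)
orthoMatrix <- function(cell) {
  ca <- cos(cell@alpha * pi / 180)
  cb <- cos(cell@beta * pi / 180)
  cg <- cos(cell@gamma * pi / 180)
  sg <- sin(cell@gamma * pi / 180)
  v <- sqrt(max(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg, 0))
  matrix(c(cell@a, 0, 0,
           cell@b * cg, cell@b * sg, 0,
           cell@c * cb, cell@c * (ca - cb * cg) / sg, cell@c * v / sg), 3, 3)
}

#' Resolution of Miller indices
#'
#' @param cell a [UnitCell-class].
#' @param hkl integer matrix (n x 3) of Miller indices.
#' @return d-spacings in Angstrom.
#' @export
dSpacing <- function(cell, hkl) {
  hkl <- rbind(hkl)
  Gstar <- solve(metricTensor(cell))
  q <- rowSums((hkl %*% Gstar) * hkl)   # 1/d^2
  1 / sqrt(q)
}

## Cartesian distance between two fractional coordinate sets, minimal image.
## xa: n x 3, xb: n x 3 (paired rows).
fracDistance <- function(cell, xa, xb) {
  d <- wrapDelta(rbind(xb) - rbind(xa))
  M <- orthoMatrix(cell)
  unname(sqrt(rowSums((d %*% t(M))^2)))
}

#' Construct a space group from a preset symbol
#'
#' Presets: `"P1"` (identity only, fully polar origin) and
#' `"P212121"` (also accepted as `"P 21 21 21"`), the generator default,
#' whose 8 allowed origin shifts are the half-cell translations.
#'
#' @param symbol preset symbol.
#' @return a [SpaceGroup-class].
#' @examples
#' spaceGroup("P212121")
#' @export
spaceGroup <- function(symbol = c("P212121", "P1")) {
  sym <- gsub("[ _]", "", symbol[1])
  if (sym == "P1") {
    return(new("SpaceGroup", symbol = "P1",
               ops = list(list(R = diag(3L), t = c(0, 0, 0))),
               originShifts = matrix(0, 1, 3),
               polarAxes = c(TRUE, TRUE, TRUE), enantiomorphSelf = TRUE))
  }
  if (sym == "P212121") {
    ops <- list(
      list(R = diag(c(1L, 1L, 1L)),    t = c(0, 0, 0)),
      list(R = diag(c(-1L, -1L, 1L)),  t = c(0.5, 0, 0.5)),
      list(R = diag(c(-1L, 1L, -1L)),  t = c(0, 0.5, 0.5)),
      list(R = diag(c(1L, -1L, -1L)),  t = c(0.5, 0.5, 0)))
    sh <- as.matrix(expand.grid(c(0, 0.5), c(0, 0.5), c(0, 0.5)))
    dimnames(sh) <- NULL
    return(new("SpaceGroup", symbol = "P21 21 21", ops = ops,
               originShifts = sh, polarAxes = c(FALSE, FALSE, FALSE),
               enantiomorphSelf = TRUE))
  }
  stop("unknown space-group preset: ", symbol)
}

## Closure check used by the validity tests: every composition of two
## operators equals an operator of the group (modulo lattice translations).
opsClosed <- function(sg) {
  key <- function(R, t) paste(c(R, round(wrapFrac(t), 6)), collapse = ",")
  have <- vapply(sg@ops, function(o) key(o$R, o$t), "")
  for (o1 in sg@ops) for (o2 in sg@ops) {
    R <- o1$R %*% o2$R
    t <- as.vector(o1$R %*% o2$t) + o1$t
    if (!key(R, t) %in% have) return(FALSE)
  }
  TRUE
}

#' Map Miller indices to the asymmetric unit
#'
#' All symmetry mates and Friedel mates of each index are mapped to one
#' lexicographically maximal representative (anomalous-free convention);
#' an index is centric when some rotation maps it to its Friedel mate.
#'
#' @param hkl integer matrix (n x 3); the zero index is rejected.
#' @param sg a [SpaceGroup-class].
#' @return list with `asu` (n x 3 matrix) and `centric` (logical).
#' @export
mapToAsu <- function(hkl, sg) {
  hkl <- rbind(hkl)
  if (any(rowSums(hkl != 0L) == 0L)) stop("(0,0,0) is not a valid reflection")
  n <- nrow(hkl)
  best <- NULL; bestScore <- rep(-Inf, n)
  centric <- rep(FALSE, n)
  for (op in sg@ops) {
    for (sgn in c(1L, -1L)) {
      hm <- sgn * (hkl %*% op$R)
      score <- (hm[, 1] * 2001 + hm[, 2]) * 2001 + hm[, 3]
      upd <- score > bestScore
      if (any(upd)) {
        if (is.null(best)) best <- hm else best[upd, ] <- hm[upd, , drop = FALSE]
        bestScore[upd] <- score[upd]
      }
      if (sgn == -1L)
        centric <- centric | rowSums(hm == hkl) == 3L
    }
  }
  storage.mode(best) <- "integer"
  list(asu = best, centric = centric)
}

## For centric reflections, one allowed phase in degrees (the other is +180).
## For acentric indices returns NA.
centricPhase <- function(hkl, sg) {
  hkl <- rbind(hkl)
  out <- rep(NA_real_, nrow(hkl))
  for (op in sg@ops) {
    hm <- hkl %*% op$R
    hit <- rowSums(hm == -hkl) == 3L & is.na(out)
    if (any(hit))
      out[hit] <- (-180 * (hkl[hit, , drop = FALSE] %*% op$t)) %% 180
  }
  out
}

#' Enumerate the unique reflections of a cell to a resolution limit
#'
#' @param cell a [UnitCell-class].
#' @param sg a [SpaceGroup-class].
#' @param dMin high-resolution limit in Angstrom.
#' @param dMax low-resolution limit in Angstrom (default Inf).
#' @return data.frame with columns h, k, l (ASU representatives), d, centric.
#' @export
uniqueReflections <- function(cell, sg, dMin, dMax = Inf) {
  stopifnot(dMin > 0)
  hmax <- floor(cell@a / dMin) + 1L
  kmax <- floor(cell@b / dMin) + 1L
  lmax <- floor(cell@c / dMin) + 1L
  g <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  g <- g[rowSums(g != 0L) > 0L, , drop = FALSE]
  d <- dSpacing(cell, g)
  keep <- d >= dMin - 1e-9 & d <= dMax
  g <- g[keep, , drop = FALSE]; d <- d[keep]
  m <- mapToAsu(g, sg)
  id <- encodeHKL(m$asu[, 1], m$asu[, 2], m$asu[, 3])
  first <- !duplicated(id)
  out <- data.frame(h = m$asu[first, 1], k = m$asu[first, 2],
                    l = m$asu[first, 3], d = d[first],
                    centric = m$centric[first])
  out[order(-out$d, out$h, out$k, out$l), , drop = FALSE]
}

## Expand an ASU coefficient list to the full sphere of reflections.
## Returns data.frame h,k,l and complex column F. F(hR) = F(h) exp(-2pi i h.t)
expandToSphere <- function(hkl, F, sg) {
  hkl <- rbind(hkl)
  hs <- list(); Fs <- list(); i <- 1L
  for (op in sg@ops) {
    hm <- hkl %*% op$R
    ph <- exp(-2i * pi * as.vector(hkl %*% op$t))
    hs[[i]] <- hm;  Fs[[i]] <- F * ph;        i <- i + 1L
    hs[[i]] <- -hm; Fs[[i]] <- Conj(F * ph);  i <- i + 1L
  }
  H <- do.call(rbind, hs); FF <- unlist(Fs)
  id <- encodeHKL(H[, 1], H[, 2], H[, 3])
  first <- !duplicated(id)
  list(hkl = H[first, , drop = FALSE], F = FF[first])
}
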