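## Tabulated 4-Gaussian atomic scattering factor coefficients (a1..a4,
## b1..b4, c) for the elements the toy structures contain. f(stol2) =
## sum_i a_i exp(-b_i stol2) + c with stol2 = (sin(theta)/lambda)^2 = 1/(4 d^2).
.formFactorTable <- list(
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.5290),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900))

#' Atomic scattering factor
#'
#' @param element one of "C", "N", "O", "S".
#' @param stol2 `(sin(theta)/lambda)^2` in inverse square Angstrom, i.e.
#'   `1/(4 d^2)`.
#' @return scattering factor values (electrons).
#' @export
formFactor <- function(element, stol2) {
  ff <- .formFactorTable[[element]]
  if (is.null(ff)) stop("unsupported atom type: ", element)
  out <- rep(ff$c, length(stol2))
  for (i in 1:4) out <- out + ff$a[i] * exp(-ff$b[i] * stol2)
  out
}

## Atomic number lookup for the supported elements (f at zero angle).
.elementZ <- c(C = 6, N = 7, O = 8, S = 16)

#' Structure factors of a toy structure by direct summation
#'
#' Direct Fourier summation over all atoms and symmetry operators with
#' tabulated 4-Gaussian form factors, occupancies and isotropic Debye-Waller
#' factors exp(-B s^2 / 4), s = 1/d. No anomalous scattering, so Friedel's
#' law holds exactly.
#'
#' @param structure a [ToyStructure-class].
#' @param dMin high-resolution limit in Angstrom (ignored when `hkl` given).
#' @param hkl optional integer matrix of indices to evaluate (default: all
#'   unique reflections to `dMin`).
#' @return data.frame h, k, l, d, centric, F (complex), Fmod, phase (deg).
#' @export
calcStructureFactors <- function(structure, dMin = 2, hkl = NULL) {
  cell <- structure@cell; sg <- structure@spacegroup
  if (is.null(hkl)) {
    refl <- uniqueReflections(cell, sg, dMin)
    hkl <- as.matrix(refl[, c("h", "k", "l")])
    d <- refl$d; centric <- refl$centric
  } else {
    hkl <- rbind(hkl)
    d <- dSpacing(cell, hkl)
    centric <- mapToAsu(hkl, sg)$centric
  }
  atoms <- structure@atoms
  stol2 <- 1 / (4 * d * d)
  Fc <- complex(real = numeric(nrow(hkl)), imaginary = numeric(nrow(hkl)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  elements <- unique(atoms$element)
  fmat <- vapply(elements, function(e) formFactor(e, stol2),
                 numeric(length(stol2)))
  colnames(fmat) <- elements
  dw <- exp(-outer(stol2, atoms$B))          # n_refl x n_atom Debye-Waller
  w <- dw * fmat[, atoms$element, drop = FALSE] *
    rep(atoms$occ, each = length(stol2))
  for (op in sg@ops) {
    hm <- hkl %*% op$R
    phase <- exp(2i * pi * (hm %*% t(xyz) +
                            as.vector(hkl %*% op$t)))
    Fc <- Fc + rowSums(phase * w)
  }
  data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3], d = d,
             centric = centric, F = Fc, Fmod = Mod(Fc),
             phase = Arg(Fc) * 180 / pi)
}

## ---- FFT map machinery ------------------------------------------------

## Choose a grid covering the cell at spacing <= dMin/3 along every axis.
mapGridSize <- function(cell, dMin, factor = 3) {
  vapply(c(cell@a, cell@b, cell@c),
         function(len) nextGoodSize(ceiling(len * factor / dMin)), 0L)
}

#' Fourier synthesis of a real-space map from ASU coefficients
#'
#' Expands the coefficients over the space group (and Friedel mates) and
#' inverts with an FFT: rho(x) = (1/V) sum_h F(h) exp(-2 pi i h.x).
#'
#' @param cell a [UnitCell-class].
#' @param sg a [SpaceGroup-class].
#' @param hkl integer matrix of ASU indices.
#' @param F complex coefficients matching `hkl` rows.
#' @param dMin resolution of the coefficient set; sets the grid so that the
#'   spacing is at most `dMin/3`.
#' @param gridSize optional explicit grid dimensions (length 3).
#' @return a [RealMap-class].
#' @export
mapFromCoefficients <- function(cell, sg, hkl, F, dMin, gridSize = NULL) {
  if (is.null(gridSize)) gridSize <- mapGridSize(cell, dMin)
  n <- as.integer(gridSize)
  sp <- expandToSphere(rbind(hkl), F, sg)
  H <- sp$hkl
  if (any(abs(H[, 1]) >= n[1] / 2 | abs(H[, 2]) >= n[2] / 2 |
          abs(H[, 3]) >= n[3] / 2))
    stop("grid too coarse for the resolution of the coefficients")
  arr <- array(0+0i, dim = n)
  idx <- cbind(H[, 1] %% n[1], H[, 2] %% n[2], H[, 3] %% n[3]) + 1L
  arr[idx] <- sp$F
  rho <- Re(fft(arr)) / cellVolume(cell)
  new("RealMap", grid = rho, cell = cell)
}

#' Structure factors from a real-space map (inverse FFT)
#'
#' @param map a [RealMap-class].
#' @param hkl integer matrix of indices to extract.
#' @return complex structure factors `F(h)` for the requested indices.
#' @export
structureFactorsFromMap <- function(map, hkl) {
  n <- dim(map@grid)
  arr <- fft(map@grid, inverse = TRUE) * cellVolume(map@cell) / prod(n)
  hkl <- rbind(hkl)
  idx <- cbind(hkl[, 1] %% n[1], hkl[, 2] %% n[2], hkl[, 3] %% n[3]) + 1L
  arr[idx]
}

## Local maxima of a periodic grid: TRUE where the voxel is >= all 26
## neighbours (strict on at least one to suppress flat plateaus).
.localMaxMask <- function(g, faceOnly = FALSE) {
  n <- dim(g)
  mask <- array(TRUE, n)
  sh <- function(a, s) {
    i1 <- (seq_len(n[1]) - 1 + s[1]) %% n[1] + 1
    i2 <- (seq_len(n[2]) - 1 + s[2]) %% n[2] + 1
    i3 <- (seq_len(n[3]) - 1 + s[3]) %% n[3] + 1
    a[i1, i2, i3]
  }
  offs <- if (faceOnly)
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  else {
    o <- list()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
      if (dx || dy || dz) o[[length(o) + 1L]] <- c(dx, dy, dz)
    o
  }
  for (s in offs) mask <- mask & (g >= sh(g, s))
  mask
}

## Quadratic (per-axis parabolic) interpolation of peak position and height.
## Returns fractional coordinates and interpolated value.
.interpolatePeaks <- function(g, idx) {
  n <- dim(g)
  out <- matrix(0, nrow(idx), 4)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    x <- (i - 1)
    val <- g[i[1], i[2], i[3]]
    corr <- 0
    for (ax in 1:3) {
      ip <- i; im <- i
      ip[ax] <- i[ax] %% n[ax] + 1
      im[ax] <- (i[ax] - 2) %% n[ax] + 1
      fp <- g[ip[1], ip[2], ip[3]]
      fm <- g[im[1], im[2], im[3]]
      den <- 2 * val - fp - fm
      dx <- if (den > 1e-12) 0.5 * (fp - fm) / den else 0
      dx <- max(-0.5, min(0.5, dx))
      x[ax] <- x[ax] + dx
      corr <- corr + 0.25 * (fp - fm) * dx
    }
    out[r, ] <- c(x / n, val + corr)
  }
  out
}

## Raw peak list of a map grid (positive maxima of `g`); height in grid value
## units. Returns data.frame x,y,z (fractional) and value.
gridPeaks <- function(map, nTop = Inf, minValue = -Inf, faceOnly = FALSE) {
  g <- map@grid
  mask <- .localMaxMask(g, faceOnly)
  idx <- which(mask & g > minValue, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(x = numeric(0), y = numeric(0),
                                    z = numeric(0), value = numeric(0)))
  vals <- g[idx]
  ord <- order(-vals)
  idx <- idx[ord, , drop = FALSE]
  if (nrow(idx) > nTop) idx <- idx[seq_len(nTop), , drop = FALSE]
  p <- .interpolatePeaks(g, idx)
  data.frame(x = wrapFrac(p[, 1]), y = wrapFrac(p[, 2]),
             z = wrapFrac(p[, 3]), value = p[, 4])
}

## Reciprocal-space Gaussian smoothing of a periodic grid: multiplies the
## transform by exp(-B s^2 / 4). Used for envelope construction.
smoothMapGrid <- function(g, cell, B) {
  n <- dim(g)
  hs <- lapply(1:3, function(i) {
    v <- 0:(n[i] - 1)
    v[v > n[i] / 2] <- v[v > n[i] / 2] - n[i]
    v
  })
  Gs <- solve(metricTensor(cell))
  s2 <- outer(outer(hs[[1]]^2 * Gs[1, 1], hs[[2]]^2 * Gs[2, 2], "+"),
              hs[[3]]^2 * Gs[3, 3], "+")
  ## cross terms vanish for orthorhombic cells; add them when present
  if (abs(Gs[1, 2]) + abs(Gs[1, 3]) + abs(Gs[2, 3]) > 1e-12) {
    s2 <- s2 + 2 * Gs[1, 2] * outer(outer(hs[[1]], hs[[2]], "*"),
                                    rep(1, n[3]), "*")
    s2 <- s2 + 2 * Gs[1, 3] * outer(outer(hs[[1]], rep(1, n[2]), "*"),
                                    hs[[3]], "*")
    s2 <- s2 + 2 * Gs[2, 3] * outer(outer(rep(1, n[1]), hs[[2]], "*"),
                                    hs[[3]], "*")
  }
  Re(fft(fft(g) * exp(-B * s2 / 4), inverse = TRUE)) / prod(n)
}

## Protein/solvent envelope from the local density variance (a smoothed
## rho^2 minus squared smoothed rho), robust against poorly determined
## low-resolution phases. Returns a logical grid, TRUE on protein.
proteinEnvelope <- function(g, cell, solventFraction, B = 60) {
  mu <- smoothMapGrid(g, cell, B)
  v <- smoothMapGrid(g * g, cell, B) - mu * mu
  v >= quantile(v, solventFraction)
}
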