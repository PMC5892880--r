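test_that("difference Patterson shows interatomic vectors and symmetry", {
  cell <- unitCell(12, 13, 14)
  sg <- spaceGroup("P1")
  u <- c(0.25, 0.1, 0.3)
  sites <- data.frame(x = c(0.1, 0.1 + u[1]), y = c(0.2, 0.2 + u[2]),
                      z = c(0.6, 0.6 + u[3]))
  refl <- uniqueReflections(cell, sg, 2.5)
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  Fc <- serialRIP:::pointAtomSF(hkl, sites, sg, refl$d, bOverall = 10)
  d <- data.frame(h = refl$h, k = refl$k, l = refl$l, dF = Mod(Fc),
                  sigdF = 1, E = Mod(Fc), d = refl$d,
                  centric = refl$centric, Fb = 1, Fa = 1)
  ds <- new("DifferenceSet", data = d, K = 1, dMin = 2.5, nDropped = 0L)
  pm <- differencePatterson(ds, cell, sg)
  ## centrosymmetric: P(u) = P(-u) on the grid
  g <- pm@grid; n <- dim(g)
  ginv <- g[c(1, n[1]:2), c(1, n[2]:2), c(1, n[3]:2)]
  expect_equal(g, ginv, tolerance = 1e-9)
  ## maximum at the origin
  expect_equal(which.max(g), 1L)
  ## non-origin peaks at +-u
  pk <- gridPeaks(pm, nTop = 8)
  away <- pk[serialRIP:::fracDistance(cell, as.matrix(pk[, 1:3]),
                                      matrix(0, nrow(pk), 3)) > 1.5, ]
  away <- head(away[order(-away$value), ], 2)   # the two +-u vectors
  du <- serialRIP:::fracDistance(cell, as.matrix(away[, 1:3]),
                                 matrix(u, nrow(away), 3, byrow = TRUE))
  duNeg <- serialRIP:::fracDistance(cell, as.matrix(away[, 1:3]),
                                    matrix(1 - u, nrow(away), 3,
                                           byrow = TRUE))
  expect_true(all(pmin(du, duNeg) < 0.5))
  ## a single site has no non-origin peak of comparable height
  Fc1 <- serialRIP:::pointAtomSF(hkl, sites[1, ], sg, refl$d,
                                 bOverall = 10)
  d1 <- d; d1$dF <- Mod(Fc1); d1$E <- Mod(Fc1)
  pm1 <- differencePatterson(new("DifferenceSet", data = d1, K = 1,
                                 dMin = 2.5, nDropped = 0L), cell, sg)
  pk1 <- gridPeaks(pm1, nTop = 5)
  origin <- pk1$value[1]
  nonOrigin <- pk1$value[serialRIP:::fracDistance(
    cell, as.matrix(pk1[, 1:3]), matrix(0, nrow(pk1), 3)) > 1.5]
  if (length(nonOrigin)) expect_lt(max(nonOrigin), 0.2 * origin)
  ## coarse grids are refused
  expect_error(differencePatterson(ds, cell, sg,
                                   gridSize = c(6, 6, 6)), "aliasing")
})

test_that("Patterson synthesis equals direct double summation on a 6^3 grid", {
  cell <- unitCell(9, 9, 9)
  sg <- spaceGroup("P1")
  set.seed(6)
  hkl <- as.matrix(expand.grid(h = -1:1, k = -1:1, l = 0:1))
  hkl <- hkl[rowSums(hkl != 0) > 0, ]
  m <- mapToAsu(hkl, sg)
  keep <- !duplicated(encodeHKL(m$asu[, 1], m$asu[, 2], m$asu[, 3]))
  hkl <- m$asu[keep, , drop = FALSE]
  coef <- runif(nrow(hkl), 0, 5)
  d <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                  dF = sqrt(coef), sigdF = 1, E = sqrt(coef),
                  d = dSpacing(cell, hkl), centric = FALSE,
                  Fb = 1, Fa = 1)
  ds <- new("DifferenceSet", data = d, K = 1, dMin = min(d$d),
            nDropped = 0L)
  pm <- differencePatterson(ds, cell, sg, gridSize = c(6, 6, 6))
  ## independent O(N^2) double sum over the expanded sphere
  direct <- array(0, c(6, 6, 6))
  for (i in seq_len(nrow(hkl))) {
    for (sgn in c(1, -1)) {
      hv <- sgn * hkl[i, ]
      for (ix in 0:5) for (iy in 0:5) for (iz in 0:5) {
        ph <- -2 * pi * sum(hv * c(ix, iy, iz) / 6)
        direct[ix + 1, iy + 1, iz + 1] <-
          direct[ix + 1, iy + 1, iz + 1] + coef[i] * cos(ph)
      }
    }
  }
  ## drop double-counted Friedel self-pairs (none here: no centrics kept)
  direct <- direct / cellVolume(cell)
  expect_equal(pm@grid, direct, tolerance = 1e-6)
})

test_that("CC scoring is affine-invariant with a tight null", {
  set.seed(7)
  e <- runif(1000, 0.2, 3)
  expect_equal(scoreCC(e, e), 100)
  expect_equal(scoreCC(e, 2 * e + 3), 100)
  eBig <- runif(10000); eInd <- runif(10000)
  expect_lt(abs(scoreCC(eBig, eInd)), 3)
  expect_error(scoreCC(e, rep(1, length(e))), "zero-variance")
  expect_error(scoreCC(e[1:2], e[1:2]), "at least 3")
})

test_that("dual-space search solves a noise-free two-site P1 problem", {
  cell <- unitCell(10, 11, 12)
  sg <- spaceGroup("P1")
  truth <- data.frame(x = c(0.15, 0.55), y = c(0.35, 0.75),
                      z = c(0.6, 0.22))
  refl <- uniqueReflections(cell, sg, 2.2)
  refl <- refl[seq_len(min(500, nrow(refl))), ]
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  Fc <- serialRIP:::pointAtomSF(hkl, truth, sg, refl$d)
  E <- Mod(Fc) / sqrt(mean(Mod(Fc)^2))
  d <- data.frame(h = refl$h, k = refl$k, l = refl$l, dF = Mod(Fc),
                  sigdF = 0.01, E = E, d = refl$d,
                  centric = refl$centric, Fb = 1, Fa = 1)
  ds <- new("DifferenceSet", data = d, K = 1, dMin = min(d$d),
            nDropped = 0L)
  cfg <- searchConfig(ntry = 10L, dMin = min(d$d) - 1e-6, nFind = 2L,
                      seed = 3L)
  sol <- dualSpaceSearch(ds, cfg, cell, sg)
  expect_gt(sol@ccAll, 95)
  ## sites match truth modulo the continuous P1 origin and hand
  cr <- substructureCorrectness(sol, asSubstructure(as.matrix(truth)),
                                cell, sg, tolerance = 0.5)
  expect_equal(cr$percent, 100)
  ## determinism
  sol2 <- dualSpaceSearch(ds, cfg, cell, sg)
  expect_equal(sol@sites, sol2@sites)
  expect_equal(sol@ccAll, sol2@ccAll)
  ## exhaustive translation-grid oracle: site1 fixed by the P1 origin at
  ## the truth, site2 scanned on a 0.25 A grid
  ng <- c(40, 44, 48)
  grid <- as.matrix(expand.grid((0:(ng[1] - 1)) / ng[1],
                                (0:(ng[2] - 1)) / ng[2],
                                (0:(ng[3] - 1)) / ng[3]))
  F1 <- as.vector(serialRIP:::pointAtomSF(hkl, truth[1, ], sg, refl$d))
  damp <- exp(-5 / (4 * refl$d^2))
  Ec <- E - mean(E)
  denE <- sqrt(sum(Ec^2))
  bestOracle <- -Inf
  for (chunk in split(seq_len(nrow(grid)),
                      ceiling(seq_len(nrow(grid)) / 6000))) {
    Y <- Mod(F1 + exp(2i * pi * (hkl %*% t(grid[chunk, , drop = FALSE])))
             * damp)
    num <- as.vector(crossprod(Y, Ec))
    den <- sqrt(pmax(colSums(Y^2) - nrow(Y) * colMeans(Y)^2, 1e-12)) *
      denE
    bestOracle <- max(bestOracle, 100 * max(num / den))
  }
  expect_gte(sol@ccAll, bestOracle - 2)
})

test_that("the search rejects degenerate configurations", {
  pair <- fxPair()
  ds <- differenceAmplitudes(pair$before, pair$after, K = 1)
  expect_error(dualSpaceSearch(ds, searchConfig(dMin = 0.1, dMax = 0.2),
                               fxPool()@structure@cell,
                               fxPool()@structure@spacegroup),
               "no data")
  expect_error(searchConfig(ntry = 0), "ntry")
  expect_error(searchConfig(nFind = 0), "nFind")
})

test_that("same-dose null differences score no better than randomized ones", {
  ## two disjoint halves of the same exposure: pure-noise differences
  pool <- fxPool()
  sg <- pool@structure@spacegroup
  cell <- pool@structure@cell
  subs <- poolExposure(pool, 2)
  b <- intensitiesToAmplitudes(mergePool(subs[1:2], sg, cell))
  a0 <- intensitiesToAmplitudes(mergePool(subs[3:4], sg, cell))
  a <- scaleAmplitudeSets(a0, b)
  ds <- differenceAmplitudes(b, a, K = 1)
  cfg <- searchConfig(ntry = 6L, dMin = 2.3, nFind = 3L, seed = 5L)
  nullCC <- dualSpaceSearch(ds, cfg, cell, sg)@ccWeak
  ## baseline: the same search on permuted (structure-free) E values
  perm <- sapply(1:10, function(i) {
    d2 <- ds@data
    d2$E <- withSeed(1000 + i, sample(d2$E))
    d2$dF <- withSeed(1000 + i, sample(d2$dF))
    ds2 <- new("DifferenceSet", data = d2, K = 1, dMin = ds@dMin,
               nDropped = 0L)
    dualSpaceSearch(ds2, cfg, cell, sg)@ccWeak
  })
  lo <- mean(perm) - 2 * sd(perm)
  hi <- mean(perm) + 2 * sd(perm)
  expect_gte(nullCC, lo)
  expect_lte(nullCC, hi + 5)
})
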