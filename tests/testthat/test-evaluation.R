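test_that("model-phased difference maps localize damage and normalize", {
  nf <- fxNoiseFree()
  st <- nf$structure
  cell <- st@cell; sg <- st@spacegroup
  ## null difference: flat map, no peaks
  map0 <- modelPhasedDifferenceMap(nf$before, nf$before, 1, nf$truth,
                                   cell, sg)
  expect_lt(max(abs(map0@grid)), 1e-9)
  expect_equal(nrow(peakSearch(map0, 6, cell, sg)), 0L)
  ## damaged pair: normalized map with peaks on the true S sites
  map <- modelPhasedDifferenceMap(nf$before, nf$after, 1, nf$truth,
                                  cell, sg)
  expect_equal(mean(map@grid), 0, tolerance = 1e-9)
  expect_equal(sd(as.vector(map@grid)), 1, tolerance = 1e-6)
  pk <- peakSearch(map, 6, cell, sg)
  expect_gt(nrow(pk), 0)
  ssites <- st@atoms[st@atoms$damageSusceptible, c("x", "y", "z")]
  D <- serialRIP:::siteDistanceMatrix(ssites,
                                      pk[1, c("x", "y", "z")], cell, sg)
  expect_lt(min(D), 0.5)
  ## insufficient reference phases are rejected
  expect_error(modelPhasedDifferenceMap(nf$before, nf$after, 1,
                                        nf$truth[1:10, ], cell, sg),
               "insufficient")
})

test_that("peak search interpolates heights and deduplicates mates", {
  cell <- unitCell(18, 18, 18)
  sg <- spaceGroup("P212121")
  ## flat map plus one inserted Gaussian blob
  n <- c(36, 36, 36)
  g <- array(0, n)
  ctr <- c(0.31, 0.12, 0.57)
  idx <- as.matrix(expand.grid(0:(n[1] - 1), 0:(n[2] - 1), 0:(n[3] - 1)))
  r2 <- (18 * wrapDelta(idx[, 1] / n[1] - ctr[1]))^2 +
        (18 * wrapDelta(idx[, 2] / n[2] - ctr[2]))^2 +
        (18 * wrapDelta(idx[, 3] / n[3] - ctr[3]))^2
  A <- 7
  g[idx + 1] <- A * exp(-r2 / 1.5) + rnorm(nrow(idx), 0, 1e-3)
  g <- g - mean(g)
  map <- new("RealMap", grid = g / sd(as.vector(g)), cell = cell)
  pk <- peakSearch(map, 5, cell, sg)
  expect_equal(nrow(pk), 1L)   # single peak: no symmetry mates in grid
  expect_equal(pk$height[1], max(map@grid), tolerance = 0.05)
  dd <- serialRIP:::fracDistance(cell, as.matrix(pk[, 1:3]),
                                 rbind(ctr))
  expect_lt(dd, 0.3)
  ## symmetry-expanded copies of the blob collapse to one report
  g2 <- array(0, n)
  for (op in sg@ops) {
    c2 <- wrapFrac(as.vector(op$R %*% ctr) + op$t)
    r2 <- (18 * wrapDelta(idx[, 1] / n[1] - c2[1]))^2 +
          (18 * wrapDelta(idx[, 2] / n[2] - c2[2]))^2 +
          (18 * wrapDelta(idx[, 3] / n[3] - c2[3]))^2
    g2[idx + 1] <- g2[idx + 1] + A * exp(-r2 / 1.5)
  }
  g2 <- g2 - mean(g2)
  map2 <- new("RealMap", grid = g2 / sd(as.vector(g2)), cell = cell)
  pk2 <- peakSearch(map2, 5, cell, sg)
  expect_equal(nrow(pk2), 1L)
  ## a threshold above the global maximum yields an empty report
  expect_equal(nrow(peakSearch(map2, max(map2@grid) + 1, cell, sg)), 0L)
})

test_that("substructure correctness is invariant under allowed equivalences", {
  st <- fxStructure()
  cell <- st@cell; sg <- st@spacegroup
  ref <- asSubstructure(as.matrix(
    st@atoms[st@atoms$damageSusceptible, c("x", "y", "z")]))
  expect_equal(substructureCorrectness(ref, ref, cell, sg)$percent, 100)
  ## empty candidate scores zero
  empty <- asSubstructure(matrix(numeric(0), 0, 3))
  expect_equal(substructureCorrectness(empty, ref, cell, sg)$percent, 0)
  ## exhaustive invariance: symmetry op x origin shift x hand
  base <- as.matrix(ref@sites[, c("x", "y", "z")])
  for (op in sg@ops) {
    for (si in seq_len(nrow(sg@originShifts))) {
      for (hand in c(1, -1)) {
        x <- sweep(base %*% t(op$R), 2, op$t, "+")
        x <- wrapFrac(sweep(hand * x, 2, sg@originShifts[si, ], "+"))
        cand <- asSubstructure(x)
        expect_equal(substructureCorrectness(cand, ref, cell,
                                             sg)$percent, 100)
      }
    }
  }
  ## a genuinely displaced candidate does not match
  off <- asSubstructure(wrapFrac(base + 0.13))
  expect_lt(substructureCorrectness(off, ref, cell, sg,
                                    tolerance = 1)$percent, 100)
})

test_that("weighted mean phase error obeys its analytic properties", {
  sg <- spaceGroup("P212121")
  cell <- unitCell(20, 21, 22)
  refl <- uniqueReflections(cell, sg, 2.2)
  n <- nrow(refl)
  truth <- data.frame(h = refl$h, k = refl$k, l = refl$l,
                      phase = withSeed(1, runif(n, -180, 180)),
                      Fmod = withSeed(2, runif(n, 1, 10)))
  est <- data.frame(h = refl$h, k = refl$k, l = refl$l,
                    phase = truth$phase, fom = 1, d = refl$d)
  expect_equal(wmpe(est, truth, sg)$wmpe, 0)
  ## symmetry in the two arguments (equal weights, no alignment)
  est2 <- est; est2$phase <- truth$phase + withSeed(3, rnorm(n, 0, 50))
  t2 <- truth; t2$phase <- est$phase
  e2 <- data.frame(h = refl$h, k = refl$k, l = refl$l,
                   phase = truth$phase + withSeed(3, rnorm(n, 0, 50)),
                   fom = 1, d = refl$d)
  wA <- wmpe(e2, truth, sg, weights = "equal", align = FALSE)$wmpe
  tSwap <- data.frame(h = refl$h, k = refl$k, l = refl$l,
                      phase = e2$phase)
  eSwap <- data.frame(h = refl$h, k = refl$k, l = refl$l,
                      phase = truth$phase, fom = 1, d = refl$d)
  wB <- wmpe(eSwap, tSwap, sg, weights = "equal", align = FALSE)$wmpe
  expect_equal(wA, wB, tolerance = 1e-12)
  ## a pure origin-shift phase ramp aligns back to zero error
  shift <- c(0.5, 0, 0.5)
  ramp <- est
  ramp$phase <- truth$phase + 360 * as.vector(
    as.matrix(refl[, c("h", "k", "l")]) %*% shift)
  expect_lt(wmpe(ramp, truth, sg)$wmpe, 1e-9)
  ## random phases against truth: 90 degrees at large n
  nBig <- 10000
  tBig <- data.frame(h = seq_len(nBig), k = 1, l = 2,
                     phase = withSeed(4, runif(nBig, -180, 180)))
  eBig <- data.frame(h = seq_len(nBig), k = 1, l = 2,
                     phase = withSeed(5, runif(nBig, -180, 180)),
                     fom = 1)
  w <- wmpe(eBig, tBig, spaceGroup("P1"), weights = "equal",
            align = FALSE)
  expect_lt(abs(w$wmpe - 90), 2)
  expect_error(wmpe(est[1:5, ], truth, sg), "at least 10")
})

test_that("peak sigma-heights are invariant under uniform dF scaling", {
  nf <- fxNoiseFree()
  st <- nf$structure
  scaled <- nf$before
  scaled@data$F <- scaled@data$F * 7.3
  scaledA <- nf$after
  scaledA@data$F <- scaledA@data$F * 7.3
  m1 <- modelPhasedDifferenceMap(nf$before, nf$after, 0.99, nf$truth,
                                 st@cell, st@spacegroup)
  m2 <- modelPhasedDifferenceMap(scaled, scaledA, 0.99, nf$truth,
                                 st@cell, st@spacegroup)
  expect_equal(m1@grid, m2@grid, tolerance = 1e-9)
})

test_that("dose series behaves correctly in null and degenerate cases", {
  ## zero damage: peak heights statistically flat across dose
  nullPool <- generateExperiment(generatorConfig(
    nCrystals = 4L, nExposures = 3L, nAtoms = 40L, nSSites = 3L,
    cell = c(24, 25, 23), dHalf = 1e9, completeness = 0.7,
    targetIsig = 15, dMin = 2.4), seed = 33)
  dsNull <- runDoseSeries(nullPool, Ks = c(0.98, 1.0))
  expect_equal(nrow(dsNull), 2L)
  spread <- max(dsNull$meanMaxPeak) - min(dsNull$meanMaxPeak)
  expect_lt(spread, 3 * max(dsNull$sdMaxPeak, 0.5))
  ## two-exposure pool gives a series of length one
  expect_equal(nrow(runDoseSeries(fxPool(), Ks = 1)), 2L)
})

test_that("multiplicity series uses nested deterministic omission", {
  pool <- fxPool()
  ms1 <- runMultiplicitySeries(pool, after = 3, Ks = c(0.99, 1.0),
                               seed = 7)
  ms2 <- runMultiplicitySeries(pool, after = 3, Ks = c(0.99, 1.0),
                               seed = 7)
  expect_equal(ms1, ms2)
  ## first step is the full pool
  expect_equal(ms1$nCrystals[1], 5L)
  full <- runDoseSeries(pool, Ks = c(0.99, 1.0))
  expect_equal(ms1$meanMaxPeak[1],
               full$meanMaxPeak[full$exposure == 3], tolerance = 1e-9)
  ## counts shrink towards one crystal
  expect_equal(tail(ms1$nCrystals, 1), 1L)
  expect_true(all(diff(ms1$nCrystals) < 0))
})
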