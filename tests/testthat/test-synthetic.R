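test_that("structure generation is deterministic, clash-free and flagged", {
  st1 <- makeToyStructure(3, nAtoms = 12, nSSites = 2,
                          cell = unitCell(22, 22, 22))
  st2 <- makeToyStructure(3, nAtoms = 12, nSSites = 2,
                          cell = unitCell(22, 22, 22))
  expect_identical(st1@atoms, st2@atoms)
  expect_equal(sum(st1@atoms$damageSusceptible), 2L)
  expect_true(all(st1@atoms$element[st1@atoms$damageSusceptible] == "S"))
  ## single-atom case: the one atom is the flagged S site
  st3 <- makeToyStructure(1, nAtoms = 1, nSSites = 1)
  expect_equal(nrow(st3@atoms), 1L)
  expect_true(st3@atoms$damageSusceptible)
  ## all pairwise distances >= 1.2 A (exhaustive, including symmetry)
  st <- makeToyStructure(1, nAtoms = 60, nSSites = 6,
                         cell = unitCell(30, 30, 30))
  xyz <- as.matrix(st@atoms[, c("x", "y", "z")])
  sg <- st@spacegroup
  dmin <- Inf
  for (i in seq_len(nrow(xyz) - 1)) {
    rest <- xyz[(i + 1):nrow(xyz), , drop = FALSE]
    for (op in sg@ops) {
      img <- sweep(rest %*% t(op$R), 2, op$t, "+")
      dmin <- min(dmin, serialRIP:::fracDistance(
        st@cell, img, matrix(xyz[i, ], nrow(img), 3, byrow = TRUE)))
    }
  }
  expect_gte(dmin, 1.2)
  ## impossible packing signals generation failure
  expect_error(makeToyStructure(1, nAtoms = 500, nSSites = 1,
                                cell = unitCell(10, 10, 10)),
               "failed")
})

test_that("damage model follows the occupancy decay law and conserves electrons", {
  st <- fxStructure()
  dm <- damageModel(dHalf = 2, relocFraction = 0, globalBRate = 0.5)
  expect_identical(applyDamage(st, dm, 0), st)
  damaged <- applyDamage(st, dm, 2)
  flag <- st@atoms$damageSusceptible
  expect_equal(damaged@atoms$occ[flag], st@atoms$occ[flag] / 2)
  expect_equal(damaged@atoms$occ[!flag], st@atoms$occ[!flag])
  expect_equal(damaged@atoms$B, st@atoms$B + 1)
  ## full relocation conserves electron count at any dose
  dmr <- damageModel(dHalf = 2, relocFraction = 1, relocDistance = 1.5)
  Z <- c(C = 6, N = 7, O = 8, S = 16)
  e0 <- sum(st@atoms$occ * Z[st@atoms$element])
  for (dose in c(0.6, 2, 5.5)) {
    dd <- applyDamage(st, dmr, dose)
    expect_equal(sum(dd@atoms$occ * Z[dd@atoms$element]), e0,
                 tolerance = 1e-9)
  }
  ## partner sites sit at the configured displacement
  dd <- applyDamage(st, dmr, 2)
  partners <- dd@atoms[!is.na(dd@atoms$partnerOf), ]
  parents <- dd@atoms[match(partners$partnerOf, dd@atoms$id), ]
  sep <- serialRIP:::fracDistance(st@cell,
    as.matrix(parents[, c("x", "y", "z")]),
    as.matrix(partners[, c("x", "y", "z")]))
  expect_equal(sep, rep(1.5, nrow(partners)), tolerance = 1e-6)
})

test_that("low-angle intensity change matches the closed-form estimate", {
  st <- fxStructure()
  dm <- damageModel(dHalf = 2.63)
  dose <- 3.48
  sf0 <- calcStructureFactors(st, dMin = 2.5)
  sf1 <- calcStructureFactors(applyDamage(st, dm, dose), dMin = 2.5)
  ## acentric low-resolution reflections: the estimator models acentric
  ## (circular) phasor statistics
  low <- sf0$d > 5 & !sf0$centric
  dI <- sf1$Fmod[low]^2 - sf0$Fmod[low]^2
  rmsFrac <- sqrt(mean((dI / mean(sf0$Fmod[low]^2))^2))
  est <- crickMagdoffEstimate(st, dm, dose)
  expect_lt(abs(rmsFrac - est) / est, 0.2)
})

test_that("noise-free damage signal grows monotonically with dose", {
  st <- fxStructure()
  dm <- damageModel(dHalf = 2.63)
  doses <- c(0.5, 1, 2, 3, 4.5)
  sf0 <- calcStructureFactors(st, dMin = 2.5)
  dFs <- sapply(doses, function(D) {
    sfD <- calcStructureFactors(applyDamage(st, dm, D), dMin = 2.5)
    Mod(sf0$F - sfD$F)
  })
  ## |dF| non-decreasing in dose for every reflection (pure occupancy loss)
  expect_true(all(apply(dFs, 1, function(r) all(diff(r) >= -1e-9))))
  ## |dI| non-decreasing where the damage term dominates
  dIs <- sapply(doses, function(D) {
    sfD <- calcStructureFactors(applyDamage(st, dm, D), dMin = 2.5)
    sf0$Fmod^2 - sfD$Fmod^2
  })
  C <- (sf0$F - calcStructureFactors(applyDamage(st, dm, max(doses)),
                                     dMin = 2.5)$F)
  dominated <- abs(Re(Conj(sf0$F) * C)) > Mod(C)^2
  expect_true(all(apply(abs(dIs[dominated, ]), 1,
                        function(r) all(diff(r) >= -1e-9))))
})

test_that("sub-dataset simulation honors its noise and determinism contracts", {
  st <- fxStructure()
  sf <- calcStructureFactors(st, dMin = 3)
  crystal <- list(crystalId = 1, exposure = 1, dose = 0, cell = st@cell,
                  scale = 1, bOffset = 0)
  noiseless <- simulateSubDataset(st, crystal, completeness = 1,
                                  noise = list(quantum = 0, sig0 = 0),
                                  seed = 4, sf = sf)
  expect_equal(noiseless@observations$I, sf$Fmod^2, tolerance = 1e-12)
  s1 <- simulateSubDataset(st, crystal, 0.5,
                           list(quantum = 1, sig0 = 1), seed = 9, sf = sf)
  s2 <- simulateSubDataset(st, crystal, 0.5,
                           list(quantum = 1, sig0 = 1), seed = 9, sf = sf)
  expect_identical(s1@observations, s2@observations)
  expect_true(all(s1@observations$sigI > 0))
  ## Monte-Carlo convergence of one reflection's mean intensity
  target <- which.max(sf$Fmod)
  Itrue <- sf$Fmod[target]^2
  hklOne <- sf[target, , drop = FALSE]
  sims <- vapply(seq_len(10000), function(i)
    simulateSubDataset(st, crystal, 1, list(quantum = 5, sig0 = 2),
                       seed = i, sf = hklOne)@observations$I, 0)
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - Itrue), 3 * se)
})

test_that("orientation bias depletes reflections near the bias axis", {
  st <- fxStructure()
  sf <- calcStructureFactors(st, dMin = 2.4)
  crystal <- list(crystalId = 1, exposure = 1, dose = 0, cell = st@cell,
                  scale = 1, bOffset = 0)
  lfrac <- function(o) mean(abs(o$l) / pmax(1, sqrt(o$h^2 + o$k^2 +
                                                    o$l^2)))
  fair <- simulateSubDataset(st, crystal, 0.5,
                             list(quantum = 1, sig0 = 1), seed = 3,
                             sf = sf)
  biased <- simulateSubDataset(st, crystal, 0.5,
                               list(quantum = 1, sig0 = 1), seed = 3,
                               sf = sf, biasFraction = 0.9)
  expect_lt(lfrac(biased@observations), lfrac(fair@observations))
})

test_that("experiment pools have the right shape and clean-limit behavior", {
  pool <- fxPool()
  expect_length(pool@subdatasets, 15L)
  ids <- vapply(pool@subdatasets, function(s)
    paste(s@crystalId, s@exposure), "")
  expect_false(anyDuplicated(ids) > 0)
  expect_equal(pool@doses, 1.16 * 1:3)
  exps <- vapply(poolExposure(pool, 2), function(s) s@exposure, 0L)
  expect_true(all(exps == 2L))
  ## clean limit: no jitter, no noise, no damage -> R_meas ~ 0 after scaling
  clean <- generateExperiment(generatorConfig(
    nCrystals = 3L, nExposures = 2L, nAtoms = 30L, nSSites = 2L,
    cell = c(24, 25, 23), dHalf = 1e9, quantum = 0, sig0rel = 0,
    cellJitter = 0, nisoSd = 0, scaleSd = 0.05, bOffsetSd = 0,
    completeness = 0.8, dMin = 2.5), seed = 5)
  md <- mergePool(poolExposure(clean, 1), clean@structure@spacegroup,
                  clean@structure@cell)
  expect_lt(md@stats$Rmeas, 1e-6)
  ## determinism of the full pool
  pool2 <- generateExperiment(pool@config, seed = 21)
  expect_equal(pool2@subdatasets[[7]]@observations,
               pool@subdatasets[[7]]@observations)
})
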