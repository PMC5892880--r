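test_that("SIR phases recover truth on noise-free data with the true sites", {
  nf <- fxNoiseFree()
  st <- nf$structure
  pe <- initialSirPhases(nf$before, nf$after, nf$trueSub, st@cell,
                         st@spacegroup, K = 1)
  d <- pe@data
  expect_true(all(d$fom >= 0 & d$fom <= 1))
  ## centric reflections collapse to the true allowed phase with high fom
  truth <- nf$truth
  id <- encodeHKL(d$h, d$k, d$l)
  tid <- encodeHKL(truth$h, truth$k, truth$l)
  phiT <- truth$phase[match(id, tid)]
  cen <- d$centric & truth$Fmod[match(id, tid)] > 1
  dphi <- abs(wrapDelta((d$phase[cen] - phiT[cen]) / 360)) * 360
  expect_lt(median(dphi), 5)
  expect_gt(mean(d$fom[cen]), 0.8)
  ## overall phase error is small for a noise-free strong case
  w <- wmpe(pe, truth, st@spacegroup, align = FALSE)
  expect_lt(w$wmpe, 25)
  ## acentric centroids lie on the F_H phase line (bimodal symmetry)
  FH <- serialRIP:::substructureFH(as.matrix(d[, c("h", "k", "l")]),
                                   nf$trueSub@sites, st@spacegroup, d$d)
  ace <- !d$centric & Mod(FH) > quantile(Mod(FH), 0.8)
  rel <- abs(wrapDelta((d$phase[ace] - Arg(FH[ace]) * 180 / pi) / 180))
  ## distance to the nearest multiple of 180 degrees, in degrees
  offAxis <- pmin(rel, 1 - rel) * 180
  expect_lt(median(offAxis), 15)
  expect_error(initialSirPhases(nf$before, nf$after,
                                new("Substructure",
                                    sites = nf$trueSub@sites[0, ],
                                    ccAll = NA_real_, ccWeak = NA_real_,
                                    meta = list()),
                                st@cell, st@spacegroup), "empty")
})

test_that("density modification is anchored, stable and fom-bounded", {
  nf <- fxNoiseFree()
  st <- nf$structure
  truth <- nf$truth
  pe0 <- new("PhaseEstimate", data = data.frame(
    h = truth$h, k = truth$k, l = truth$l, phase = truth$phase,
    fom = 0.9, d = truth$d, centric = truth$centric))
  ## zero cycles is the identity
  dm0 <- densityModify(pe0, nf$before, st@cell, st@spacegroup, 0.5, 0)
  expect_equal(dm0$phases@data$phase, pe0@data$phase)
  expect_equal(dm0$phases@data$fom, pe0@data$fom)
  ## the truth is (approximately) a fixed point
  dm5 <- densityModify(pe0, nf$before, st@cell, st@spacegroup, 0.5, 5)
  w <- wmpe(dm5$phases, truth, st@spacegroup, align = FALSE)
  expect_lt(w$wmpe, 5)
  expect_true(all(dm5$phases@data$fom <= 1))
  expect_error(densityModify(pe0, nf$before, st@cell, st@spacegroup,
                             1.2, 1), "solvent")
})

test_that("density modification improves strong SIR starts cycle by cycle", {
  nf <- fxNoiseFree()
  st <- nf$structure
  pe <- initialSirPhases(nf$before, nf$after, nf$trueSub, st@cell,
                         st@spacegroup, K = 1)
  errs <- vapply(0:3, function(nc)
    wmpe(densityModify(pe, nf$before, st@cell, st@spacegroup, 0.5,
                       nc)$phases, nf$truth, st@spacegroup)$wmpe, 0)
  expect_true(all(diff(errs[1:4]) < 0))
})

test_that("hand choice ties on enantiomorph-degenerate data and is reported consistently", {
  nf <- fxNoiseFree()
  st <- nf$structure
  ch <- chooseHand(nf$before, nf$after, nf$trueSub, st@cell,
                   st@spacegroup, solventFraction = 0.5, K = 1,
                   nCycles = 2)
  ## the half-cell operator translations make the inverted substructure an
  ## exact conjugate solution: contrasts tie and the tie breaks to the
  ## original hand
  expect_equal(unname(ch$contrast["original"]),
               unname(ch$contrast["inverted"]), tolerance = 1e-6)
  expect_equal(ch$hand, "original")
  ## reported contrast equals recomputation from the returned map
  hkl <- as.matrix(ch$phases@data[, c("h", "k", "l")])
  ctr <- serialRIP:::mapContrast(ch$map, 0.5, st@cell, st@spacegroup,
                                 hkl, min(ch$phases@data$d))
  expect_equal(unname(ch$contrast[ch$hand]), ctr, tolerance = 1e-9)
})

test_that("bootstrapping is a fixed point when no peak clears the threshold", {
  nf <- fxNoiseFree()
  st <- nf$structure
  pe <- initialSirPhases(nf$before, nf$after, nf$trueSub, st@cell,
                         st@spacegroup, K = 1)
  bs <- bootstrapSites(pe, nf$before, nf$after, 1, nf$trueSub, st@cell,
                       st@spacegroup, threshold = 50, maxRounds = 1)
  expect_equal(bs$rounds, 0L)
  expect_equal(bs$substructure@sites, nf$trueSub@sites)
  expect_equal(bs$phases@data, pe@data)
})

test_that("bootstrapping recovers a planted relocation partner site", {
  ## noise-free pair with 50% relocation: the partner sites are the
  ## negative difference-map peaks the bootstrap must find
  st <- fxStructure()
  dm <- damageModel(dHalf = 2.63, relocFraction = 0.5,
                    relocDistance = 1.5)
  damaged <- applyDamage(st, dm, 3.48)
  sfB <- calcStructureFactors(st, dMin = 2.2)
  sfA <- calcStructureFactors(damaged, dMin = 2.2)
  mk <- function(sf, id) new("AmplitudeSet", data = data.frame(
    h = sf$h, k = sf$k, l = sf$l, F = sf$Fmod,
    sigF = pmax(1e-3, 0.001 * sf$Fmod), d = sf$d,
    centric = sf$centric), sourceId = id)
  before <- mk(sfB, "b"); after <- mk(sfA, "a")
  flag <- st@atoms$damageSusceptible
  occ0 <- st@atoms$occ[flag]
  posSites <- data.frame(x = st@atoms$x[flag], y = st@atoms$y[flag],
                         z = st@atoms$z[flag],
                         occ = occ0 * (1 - 2^(-3.48 / 2.63)),
                         height = NA_real_)
  sub <- new("Substructure", sites = posSites, ccAll = NA_real_,
             ccWeak = NA_real_, meta = list())
  pe <- initialSirPhases(before, after, sub, st@cell, st@spacegroup,
                         K = 1)
  bs <- bootstrapSites(pe, before, after, 1, sub, st@cell,
                       st@spacegroup, threshold = 4, maxRounds = 3)
  neg <- bs$substructure@sites[bs$substructure@sites$occ < 0, ]
  expect_gt(nrow(neg), 0)
  ## at least one planted partner is recovered within 1.0 A
  partners <- applyDamage(st, dm, 3.48)@atoms
  partners <- partners[!is.na(partners$partnerOf), c("x", "y", "z")]
  D <- serialRIP:::siteDistanceMatrix(partners,
                                      neg[, c("x", "y", "z")],
                                      st@cell, st@spacegroup)
  expect_lt(min(D), 1.0)
})

test_that("figure of merit tracks true phase accuracy on a strong case", {
  nf <- fxNoiseFree()
  st <- nf$structure
  pe <- initialSirPhases(nf$before, nf$after, nf$trueSub, st@cell,
                         st@spacegroup, K = 1)
  d <- pe@data
  truth <- nf$truth
  phiT <- truth$phase[match(encodeHKL(d$h, d$k, d$l),
                            encodeHKL(truth$h, truth$k, truth$l))]
  dphi <- abs(wrapDelta((d$phase - phiT) / 360)) * 2 * pi
  bins <- cut(d$fom, quantile(d$fom, seq(0, 1, 0.25)),
              include.lowest = TRUE)
  meanCos <- tapply(cos(dphi), bins, mean)
  expect_true(all(diff(meanCos) > -0.05))
  expect_gt(meanCos[4], meanCos[1])
})

test_that("hand flip mirrors the weighted phase error on P1 fixtures", {
  cell <- unitCell(12, 13, 11)
  sg <- spaceGroup("P1")
  set.seed(31)
  n <- 300
  refl <- uniqueReflections(cell, sg, 2.5)[1:n, ]
  truth <- data.frame(h = refl$h, k = refl$k, l = refl$l,
                      phase = runif(n, -180, 180), Fmod = runif(n, 1, 9))
  est <- data.frame(h = refl$h, k = refl$k, l = refl$l,
                    phase = truth$phase + rnorm(n, 0, 40),
                    fom = runif(n, 0.3, 1))
  invTruth <- truth; invTruth$phase <- -truth$phase
  invEst <- est; invEst$phase <- -est$phase
  w1 <- wmpe(est, truth, sg, align = FALSE)$wmpe
  w2 <- wmpe(invEst, invTruth, sg, align = FALSE)$wmpe
  expect_equal(w1, w2, tolerance = 1e-12)
})
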