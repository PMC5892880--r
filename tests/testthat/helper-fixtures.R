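## Shared fixtures, built once per test run. Everything is generated in
## code; sizes are kept small so the whole suite stays fast.

.fx <- new.env(parent = emptyenv())

fxCached <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

## Small orthorhombic P212121 structure used across module tests.
fxStructure <- function() {
  fxCached("structure", makeToyStructure(11, nAtoms = 60, nSSites = 4,
                                         cell = unitCell(26, 28, 24),
                                         solventFraction = 0.5))
}

## Small uv-like experiment pool: 5 crystals x 3 exposures.
fxPool <- function() {
  fxCached("pool", generateExperiment(
    generatorConfig(nCrystals = 5L, nExposures = 3L,
                    dosePerExposure = 1.16, nAtoms = 60L, nSSites = 4L,
                    cell = c(26, 28, 24), dHalf = 2.63,
                    completeness = 0.7, targetIsig = 15, dMin = 2.2),
    seed = 21))
}

## Conventionally scaled before/after amplitude pair of the pool's final
## dose point.
fxPair <- function() {
  fxCached("pair", beforeAfterPair(fxPool(), 3))
}

## A high-signal noise-free-like pair built by direct structure-factor
## calculation (strong case for the phasing tests): true substructure
## occupancy loss with no measurement noise.
fxNoiseFree <- function() {
  fxCached("noisefree", {
    st <- fxStructure()
    dm <- damageModel(dHalf = 2.63)
    damaged <- applyDamage(st, dm, 3.48)
    sfB <- calcStructureFactors(st, dMin = 2.2)
    sfA <- calcStructureFactors(damaged, dMin = 2.2)
    mk <- function(sf, id) new("AmplitudeSet", data = data.frame(
      h = sf$h, k = sf$k, l = sf$l, F = sf$Fmod,
      sigF = pmax(1e-3, 0.001 * sf$Fmod), d = sf$d,
      centric = sf$centric), sourceId = id)
    lost <- st@atoms$damageSusceptible
    occ0 <- st@atoms$occ[lost]
    sites <- data.frame(x = st@atoms$x[lost], y = st@atoms$y[lost],
                        z = st@atoms$z[lost],
                        occ = occ0 - occ0 * 2^(-3.48 / 2.63),
                        height = NA_real_)
    list(before = mk(sfB, "before"), after = mk(sfA, "after"),
         structure = st, damaged = damaged,
         trueSub = new("Substructure", sites = sites, ccAll = NA_real_,
                       ccWeak = NA_real_, meta = list()),
         truth = sfB[, c("h", "k", "l", "Fmod", "phase", "d", "centric")])
  })
}

## Independent brute-force merging oracle: plain R implementation used to
## cross-check the data.table path.
bruteForceMerge <- function(obs) {
  key <- paste(obs$h, obs$k, obs$l)
  out <- lapply(split(seq_len(nrow(obs)), key), function(ix) {
    w <- 1 / obs$sigI[ix]^2
    data.frame(h = obs$h[ix[1]], k = obs$k[ix[1]], l = obs$l[ix[1]],
               I = sum(w * obs$I[ix]) / sum(w), sigI = 1 / sqrt(sum(w)),
               mult = length(ix))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$h, out$k, out$l), , drop = FALSE]
}

## Substructure wrapper for a bare site table.
asSubstructure <- function(sites) {
  new("Substructure",
      sites = data.frame(x = wrapFrac(sites[, 1]),
                         y = wrapFrac(sites[, 2]),
                         z = wrapFrac(sites[, 3]),
                         occ = rep(1, nrow(sites)),
                         height = rep(NA_real_, nrow(sites))),
      ccAll = NA_real_, ccWeak = NA_real_, meta = list())
}
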