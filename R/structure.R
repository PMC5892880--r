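#' Damage model constructor
#'
#' @param dHalf half-dose of susceptible-site occupancy decay (MGy); the
#'   occupancy of a flagged site after dose D is `occ0 * 2^(-D/dHalf)`.
#' @param relocFraction fraction of the lost occupancy that reappears at a
#'   displaced partner site (0 = pure loss).
#' @param relocDistance partner-site displacement in Angstrom.
#' @param globalBRate isotropic B inflation added to every atom, A^2/MGy.
#' @param scaleDecayRate overall linear intensity-scale decay per MGy.
#' @return a [DamageModel-class].
#' @export
damageModel <- function(dHalf = 2.6, relocFraction = 0, relocDistance = 1.5,
                        globalBRate = 0, scaleDecayRate = 0) {
  new("DamageModel", dHalf = dHalf, relocFraction = relocFraction,
      relocDistance = relocDistance, globalBRate = globalBRate,
      scaleDecayRate = scaleDecayRate)
}

#' Generate a clash-free toy structure
#'
#' Atoms are placed uniformly inside a compact spherical blob whose volume
#' matches the non-solvent fraction of the cell per asymmetric unit, with a
#' minimum inter-site distance of 1.2 Angstrom enforced against all
#' previously placed atoms and their symmetry mates. Exactly `nSSites` S
#' atoms are flagged damage-susceptible; each is assigned a fixed partner
#' direction used by [applyDamage()] when relocation is enabled.
#'
#' @param seed integer seed; the generator is deterministic for a fixed seed.
#' @param nAtoms total number of atoms (including the S sites).
#' @param nSSites number of damage-susceptible S sites, `1 <= nSSites <=
#'   nAtoms`.
#' @param cell a [UnitCell-class].
#' @param sg a [SpaceGroup-class].
#' @param solventFraction nominal solvent fraction in (0.2, 0.8).
#' @param bRange isotropic B-factor range the atoms are drawn from (A^2).
#' @return a [ToyStructure-class].
#' @export
makeToyStructure <- function(seed, nAtoms, nSSites,
                             cell = unitCell(33, 35, 31),
                             sg = spaceGroup("P212121"),
                             solventFraction = 0.5,
                             bRange = c(8, 18)) {
  stopifnot(nAtoms >= nSSites, nSSites >= 1)
  nops <- length(sg@ops)
  vAsu <- cellVolume(cell) * (1 - solventFraction) / nops
  radius <- (3 * vAsu / (4 * pi))^(1 / 3)
  M <- orthoMatrix(cell)
  Minv <- solve(M)
  withSeed(deriveSeed(seed, "toy-structure"), {
    center <- runif(3)
    placed <- matrix(numeric(0), 0, 3)   # fractional coords
    placedCart <- NULL
    maxTries <- 2000L
    for (i in seq_len(nAtoms)) {
      ok <- FALSE
      for (tr in seq_len(maxTries)) {
        ## uniform point in the blob sphere
        v <- rnorm(3); v <- v / sqrt(sum(v * v))
        r <- radius * runif(1)^(1 / 3)
        cart <- as.vector(M %*% center) + r * v
        frac <- wrapFrac(as.vector(Minv %*% cart))
        ## clash check against symmetry expansion of everything placed
        if (nrow(placed)) {
          clash <- FALSE
          for (op in sg@ops) {
            img <- sweep(placed %*% t(op$R), 2, op$t, "+")
            dd <- fracDistance(cell, img,
                               matrix(frac, nrow(img), 3, byrow = TRUE))
            if (any(dd < 1.2)) { clash <- TRUE; break }
          }
          if (clash) next
        }
        ## self special-position check
        selfOK <- TRUE
        for (op in sg@ops[-1]) {
          img <- as.vector(op$R %*% frac) + op$t
          if (fracDistance(cell, rbind(img), rbind(frac)) < 1.2) {
            selfOK <- FALSE; break
          }
        }
        if (!selfOK) next
        placed <- rbind(placed, frac)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("structure generation failed: cannot pack ", nAtoms,
             " atoms at >= 1.2 A in this cell (placed ", i - 1L, ")")
    }
    elems <- sample(c("C", "N", "O"), nAtoms, replace = TRUE,
                    prob = c(0.62, 0.18, 0.20))
    sIdx <- sample(nAtoms, nSSites)
    elems[sIdx] <- "S"
    flag <- seq_len(nAtoms) %in% sIdx
    ## fixed relocation-partner directions (unit vectors, Cartesian)
    pd <- matrix(rnorm(3 * nAtoms), nAtoms, 3)
    pd <- pd / sqrt(rowSums(pd^2))
    pdFrac <- pd %*% t(Minv)     # per-Angstrom fractional displacement
    atoms <- data.frame(
      id = seq_len(nAtoms), element = elems,
      x = placed[, 1], y = placed[, 2], z = placed[, 3],
      occ = 1, B = runif(nAtoms, bRange[1], bRange[2]),
      damageSusceptible = flag,
      pdx = pdFrac[, 1], pdy = pdFrac[, 2], pdz = pdFrac[, 3],
      partnerOf = NA_integer_)
    new("ToyStructure", cell = cell, spacegroup = sg, atoms = atoms,
        solventFraction = solventFraction, center = center)
  })
}

#' Apply radiation damage to a structure
#'
#' Damage-susceptible sites lose occupancy as `occ0 * 2^(-dose/dHalf)`; a
#' fraction `relocFraction` of the lost occupancy reappears at a partner
#' site displaced by `relocDistance` along the site's fixed partner
#' direction (these partner sites become the negative peaks of the
#' before-minus-after difference map's complement). All atoms gain
#' `globalBRate * dose` of isotropic B. Dose 0 is the identity.
#'
#' @param structure a [ToyStructure-class] (undamaged).
#' @param damage a [DamageModel-class].
#' @param dose cumulative dose in MGy.
#' @return the damaged [ToyStructure-class].
#' @export
applyDamage <- function(structure, damage, dose) {
  stopifnot(dose >= 0)
  if (dose == 0) return(structure)
  atoms <- structure@atoms
  flag <- atoms$damageSusceptible
  occ0 <- atoms$occ[flag]
  occD <- occ0 * 2^(-dose / damage@dHalf)
  lost <- occ0 - occD
  atoms$occ[flag] <- occD
  atoms$B <- atoms$B + damage@globalBRate * dose
  if (damage@relocFraction > 0 && any(flag)) {
    src <- atoms[flag, , drop = FALSE]
    partners <- src
    partners$id <- max(atoms$id) + seq_len(nrow(src))
    partners$x <- wrapFrac(src$x + damage@relocDistance * src$pdx)
    partners$y <- wrapFrac(src$y + damage@relocDistance * src$pdy)
    partners$z <- wrapFrac(src$z + damage@relocDistance * src$pdz)
    partners$occ <- pmin(1, damage@relocFraction * lost)
    partners$damageSusceptible <- FALSE
    partners$partnerOf <- src$id
    atoms <- rbind(atoms, partners)
  }
  new("ToyStructure", cell = structure@cell,
      spacegroup = structure@spacegroup, atoms = atoms,
      solventFraction = structure@solventFraction,
      center = structure@center)
}

#' Closed-form low-angle estimate of the damage-induced intensity change
#'
#' Independent of any structure-factor calculation: under a random-phase
#' model at low resolution, write `F = A + S` with `S` the coherent sum
#' over the damage-susceptible sites and `A` the rest. Occupancy loss by
#' the fraction `delta` gives `dI = 2 delta Re(F* S) - delta^2 |S|^2`,
#' and with second and fourth moments of independent phasors
#' (`E|S|^4 = 2 (E|S|^2)^2 - sum f^4`) the expected rms fractional
#' intensity change is computable from the composition alone (atomic
#' numbers standing in for the zero-angle scattering factors). Relocated
#' partner occupancy enters as additional independent scatterers.
#'
#' @param structure undamaged [ToyStructure-class].
#' @param damage a [DamageModel-class].
#' @param dose dose in MGy.
#' @return estimated rms `|dI|/<I>` at low resolution (dimensionless).
#' @export
crickMagdoffEstimate <- function(structure, damage, dose) {
  atoms <- structure@atoms
  Z <- .elementZ[atoms$element]
  flag <- atoms$damageSusceptible
  delta <- 1 - 2^(-dose / damage@dHalf)
  fS <- atoms$occ[flag] * Z[flag]
  fA <- atoms$occ[!flag] * Z[!flag]
  eS <- sum(fS^2)                  # E|S|^2
  eA <- sum(fA^2)                  # E|A|^2
  eS4 <- 2 * eS^2 - sum(fS^4)      # E|S|^4
  ## E[dI^2] for the occupancy-loss term
  m2 <- 4 * delta^2 * (0.5 * eA * eS + eS4) -
    4 * delta^3 * eS4 + delta^4 * eS4
  ## relocated partners: independent phasors of weight r * delta * f
  eP <- sum((damage@relocFraction * delta * fS)^2)
  m2 <- m2 + 2 * (eA + eS) * eP
  sqrt(m2) / (eA + eS)
}
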