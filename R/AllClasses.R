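## S4 classes for the central crystallographic containers.

#' Unit cell
#'
#' Lengths in Angstrom, angles in degrees. The default preset used by the
#' synthetic generator is orthorhombic (all angles 90).
#'
#' @slot a,b,c cell edge lengths in Angstrom.
#' @slot alpha,beta,gamma cell angles in degrees.
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"),
  prototype(alpha = 90, beta = 90, gamma = 90),
  validity = function(object) {
    if (any(c(object@a, object@b, object@c) <= 0))
      return("cell lengths must be positive")
    ang <- c(object@alpha, object@beta, object@gamma)
    if (any(ang <= 0 | ang >= 180)) return("cell angles must lie in (0, 180)")
    v <- try(cellVolume(object), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v) || v <= 0)
      return("cell volume must be positive")
    TRUE
  })

#' Space group
#'
#' Symmetry operators are stored as (rotation, translation) pairs acting on
#' fractional coordinates, x' = R x + t. Allowed origin shifts are the
#' discrete translations under which a substructure solution is equivalent;
#' `polarAxes` marks axes along which the origin is continuous (P1).
#'
#' @slot symbol Hermann-Mauguin style symbol.
#' @slot ops list of `list(R = <3x3 integer matrix>, t = <numeric(3)>)`.
#' @slot originShifts numeric matrix, one allowed origin shift per row.
#' @slot polarAxes logical(3), TRUE where the origin floats continuously.
#' @slot enantiomorphSelf TRUE when the group is its own enantiomorph so a
#'   hand flip only inverts coordinates.
#' @export
setClass("SpaceGroup",
  representation(symbol = "character", ops = "list",
                 originShifts = "matrix", polarAxes = "logical",
                 enantiomorphSelf = "logical"),
  validity = function(object) {
    if (!length(object@ops)) return("at least one operator required")
    for (op in object@ops) {
      if (!is.matrix(op$R) || any(dim(op$R) != c(3L, 3L)))
        return("each operator needs a 3x3 rotation")
      if (length(op$t) != 3L) return("each operator needs a translation(3)")
    }
    if (ncol(object@originShifts) != 3L)
      return("origin shifts must have 3 columns")
    TRUE
  })

#' Damage model
#'
#' Specific damage is occupancy loss at susceptible sites with half-dose
#' `dHalf`; a fraction `relocFraction` of the lost occupancy reappears at a
#' displaced partner site (the future negative-peak site). Global damage is
#' isotropic B inflation plus an overall scale decay, both linear in dose.
#'
#' @slot dHalf half-dose of the susceptible-site occupancy decay, MGy.
#' @slot relocFraction fraction of lost occupancy relocated, in [0, 1].
#' @slot relocDistance displacement of the partner site, Angstrom.
#' @slot globalBRate isotropic B-factor inflation, Angstrom^2 per MGy.
#' @slot scaleDecayRate overall linear scale decay per MGy.
#' @export
setClass("DamageModel",
  representation(dHalf = "numeric", relocFraction = "numeric",
                 relocDistance = "numeric", globalBRate = "numeric",
                 scaleDecayRate = "numeric"),
  prototype(dHalf = 2.6, relocFraction = 0, relocDistance = 1.5,
            globalBRate = 0, scaleDecayRate = 0),
  validity = function(object) {
    if (object@dHalf <= 0) return("dHalf must be positive")
    if (object@relocFraction < 0 || object@relocFraction > 1)
      return("relocFraction must lie in [0, 1]")
    if (object@globalBRate < 0 || object@scaleDecayRate < 0)
      return("global damage rates must be non-negative")
    TRUE
  })

#' Toy crystal structure (ground truth)
#'
#' @slot cell a [UnitCell-class].
#' @slot spacegroup a [SpaceGroup-class].
#' @slot atoms data.frame with columns id, element, x, y, z (fractional),
#'   occ, B, damageSusceptible, pdx, pdy, pdz (fractional displacement of
#'   the relocation partner site for susceptible atoms), partnerOf.
#' @slot solventFraction nominal solvent fraction of the cell.
#' @slot center fractional coordinates of the molecular blob centre.
#' @export
setClass("ToyStructure",
  representation(cell = "UnitCell", spacegroup = "SpaceGroup",
                 atoms = "data.frame", solventFraction = "numeric",
                 center = "numeric"),
  validity = function(object) {
    a <- object@atoms
    need <- c("id", "element", "x", "y", "z", "occ", "B", "damageSusceptible")
    if (!all(need %in% names(a))) return("atoms table incomplete")
    if (any(a$occ < 0 | a$occ > 1)) return("occupancies must lie in [0, 1]")
    if (any(a$B < 0)) return("B factors must be non-negative")
    if (object@solventFraction <= 0.2 || object@solventFraction >= 0.8)
      return("solvent fraction must lie in (0.2, 0.8)")
    if (!any(a$damageSusceptible))
      return("at least one damage-susceptible site required")
    TRUE
  })

#' One crystal/exposure sub-dataset
#'
#' The serial-data atom: a partial set of intensity observations from one
#' crystal position at one exposure, tagged with its cumulative dose.
#'
#' @slot crystalId integer crystal identifier.
#' @slot exposure exposure index (1-based; 1 is the "before" exposure).
#' @slot dose cumulative dose in MGy.
#' @slot cell the crystal's (jittered) cell.
#' @slot scaleOffset,bOffset per-crystal overall scale and B offset.
#' @slot observations data.frame with h, k, l, I, sigI, d.
#' @export
setClass("SubDataset",
  representation(crystalId = "integer", exposure = "integer",
                 dose = "numeric", cell = "UnitCell",
                 scaleOffset = "numeric", bOffset = "numeric",
                 observations = "data.frame"),
  validity = function(object) {
    o <- object@observations
    if (!all(c("h", "k", "l", "I", "sigI") %in% names(o)))
      return("observations table incomplete")
    if (nrow(o) && any(o$sigI <= 0)) return("sigI must be positive")
    if (object@dose < 0) return("dose must be non-negative")
    TRUE
  })

#' Pool of sub-datasets from one simulated experiment
#'
#' Ground truth (structure and phases per dose) is retained for evaluation
#' only; no pipeline stage reads it.
#'
#' @slot subdatasets list of [SubDataset-class].
#' @slot structure the undamaged ground-truth [ToyStructure-class].
#' @slot damage the [DamageModel-class] used.
#' @slot doses cumulative dose per exposure index.
#' @slot truePhases list (one per exposure) of data.frames h, k, l, phase
#'   (degrees), Fmod, d, centric — the ground-truth structure factors.
#' @slot seed master generator seed.
#' @slot config generator configuration snapshot.
#' @export
setClass("ExperimentPool",
  representation(subdatasets = "list", structure = "ToyStructure",
                 damage = "DamageModel", doses = "numeric",
                 truePhases = "list", seed = "integer", config = "list"),
  validity = function(object) {
    ids <- vapply(object@subdatasets,
                  function(s) paste(s@crystalId, s@exposure), "")
    if (anyDuplicated(ids)) return("(crystal, exposure) pairs must be unique")
    TRUE
  })

#' Merged unique-reflection dataset with merging statistics
#'
#' @slot reflections data.frame h, k, l (ASU), I, sigI, mult, centric, d.
#' @slot stats overall merging statistics (one-row data.frame).
#' @slot shells per-shell statistics data.frame.
#' @slot memberIds ids of the contributing sub-datasets.
#' @export
setClass("MergedDataset",
  representation(reflections = "data.frame", stats = "data.frame",
                 shells = "data.frame", memberIds = "integer"),
  validity = function(object) {
    r <- object@reflections
    if (nrow(r)) {
      if (any(r$mult < 1)) return("multiplicity must be >= 1")
      if (any(r$sigI <= 0)) return("sigI must be positive")
      if (anyDuplicated(encodeHKL(r$h, r$k, r$l)))
        return("ASU indices must be unique")
    }
    TRUE
  })

#' Structure-factor amplitude set
#'
#' @slot data data.frame h, k, l, F, sigF, d, centric.
#' @slot sourceId identifier of the originating dataset.
#' @export
setClass("AmplitudeSet",
  representation(data = "data.frame", sourceId = "character"),
  validity = function(object) {
    d <- object@data
    if (!all(c("h", "k", "l", "F", "sigF", "d") %in% names(d)))
      return("amplitude table incomplete")
    if (nrow(d) && (any(d$F < 0) || any(d$sigF <= 0)))
      return("F must be >= 0 and sigF > 0")
    TRUE
  })

#' K-scaled isomorphous difference amplitudes
#'
#' dF = F_before - K * F_after on the common ASU indices, with propagated
#' sigma and shell-rms normalized magnitudes E.
#'
#' @slot data data.frame h, k, l, dF, sigdF, E, d, centric, Fb, Fa.
#' @slot K the after-dataset scale factor applied.
#' @slot dMin resolution cutoff applied (Angstrom).
#' @slot nDropped number of indices present in only one input set.
#' @export
setClass("DifferenceSet",
  representation(data = "data.frame", K = "numeric", dMin = "numeric",
                 nDropped = "integer"),
  validity = function(object) {
    d <- object@data
    if (nrow(d) && any(d$sigdF <= 0)) return("sigdF must be positive")
    TRUE
  })

#' Damage-site substructure
#'
#' @slot sites data.frame x, y, z (fractional, wrapped to [0,1)), occ
#'   (signed occupancy estimate), height (map sigma units, NA when the site
#'   was not found in a map).
#' @slot ccAll,ccWeak correlation scores in percent.
#' @slot meta list of search metadata (trial index, seed, config).
#' @export
setClass("Substructure",
  representation(sites = "data.frame", ccAll = "numeric", ccWeak = "numeric",
                 meta = "list"),
  validity = function(object) {
    s <- object@sites
    if (!all(c("x", "y", "z", "occ") %in% names(s)))
      return("site table incomplete")
    if (nrow(s) && any(s$x < 0 | s$x >= 1 | s$y < 0 | s$y >= 1 |
                       s$z < 0 | s$z >= 1))
      return("site coordinates must be wrapped to [0, 1)")
    ok <- function(v) !length(v) || !is.finite(v) || (v >= -100 && v <= 100)
    if (!ok(object@ccAll) || !ok(object@ccWeak))
      return("CC scores are percentages in [-100, 100]")
    TRUE
  })

#' Per-reflection phase estimate with figures of merit
#'
#' @slot data data.frame h, k, l, phase (degrees), fom in [0,1], d, centric.
#' @export
setClass("PhaseEstimate",
  representation(data = "data.frame"),
  validity = function(object) {
    d <- object@data
    if (!all(c("h", "k", "l", "phase", "fom") %in% names(d)))
      return("phase table incomplete")
    if (nrow(d) && any(d$fom < 0 | d$fom > 1 + 1e-9))
      return("figures of merit must lie in [0, 1]")
    TRUE
  })

#' Real-space density map over one unit cell
#'
#' @slot grid 3-d numeric array of density values.
#' @slot cell the [UnitCell-class] the grid spans.
#' @export
setClass("RealMap",
  representation(grid = "array", cell = "UnitCell"),
  validity = function(object) {
    if (length(dim(object@grid)) != 3L) return("grid must be 3-dimensional")
    TRUE
  })

#' Result of genetic-algorithm sub-dataset selection
#'
#' @slot chosen integer ids of the selected sub-datasets.
#' @slot target target-function value of the selection (under the frozen
#'   normalization bounds in `bounds`).
#' @slot merged the resulting [MergedDataset-class].
#' @slot bounds normalization bounds (min/max per statistic) frozen from the
#'   initial population.
#' @slot history best target per generation.
#' @export
setClass("GASelection",
  representation(chosen = "integer", target = "numeric",
                 merged = "MergedDataset", bounds = "list",
                 history = "numeric"),
  validity = function(object) {
    if (!length(object@chosen)) return("chosen set must be non-empty")
    TRUE
  })

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              object@a, object@b, object@c,
              object@alpha, object@beta, object@gamma))
})

setMethod("show", "SpaceGroup", function(object) {
  cat(sprintf("SpaceGroup %s: %d operators, %d allowed origin shifts%s\n",
              object@symbol, length(object@ops), nrow(object@originShifts),
              if (any(object@polarAxes)) " (polar axes present)" else ""))
})

setMethod("show", "ToyStructure", function(object) {
  a <- object@atoms
  cat(sprintf("ToyStructure: %d sites (%d damage-susceptible S), %s, solvent %.2f\n",
              nrow(a), sum(a$damageSusceptible), object@spacegroup@symbol,
              object@solventFraction))
})

setMethod("show", "SubDataset", function(object) {
  cat(sprintf("SubDataset crystal %d exposure %d (%.2f MGy): %d observations\n",
              object@crystalId, object@exposure, object@dose,
              nrow(object@observations)))
})

setMethod("show", "ExperimentPool", function(object) {
  cat(sprintf("ExperimentPool: %d sub-datasets, doses %s MGy\n",
              length(object@subdatasets),
              paste(sprintf("%.2f", object@doses), collapse = "/")))
})

setMethod("show", "MergedDataset", function(object) {
  s <- object@stats
  cat(sprintf("MergedDataset: %d unique reflections from %d sub-datasets\n",
              nrow(object@reflections), length(object@memberIds)))
  if (nrow(s))
    cat(sprintf("  <I/sig>=%.2f Rmeas=%s CC1/2=%s compl=%.1f%% mult=%.1f\n",
                s$IsigI, format(round(s$Rmeas, 4)), format(round(s$CChalf, 3)),
                100 * s$completeness, s$multiplicity))
})

setMethod("show", "DifferenceSet", function(object) {
  cat(sprintf("DifferenceSet: %d differences, K=%.5f, d_min=%.2f A (%d unpaired dropped)\n",
              nrow(object@data), object@K, object@dMin, object@nDropped))
})

setMethod("show", "Substructure", function(object) {
  cat(sprintf("Substructure: %d sites (%d negative), CCall=%.1f CCweak=%.1f\n",
              nrow(object@sites), sum(object@sites$occ < 0),
              object@ccAll, object@ccWeak))
})

setMethod("show", "PhaseEstimate", function(object) {
  cat(sprintf("PhaseEstimate: %d reflections, <fom>=%.3f\n",
              nrow(object@data), mean(object@data$fom)))
})

setMethod("show", "RealMap", function(object) {
  g <- dim(object@grid)
  cat(sprintf("RealMap: %dx%dx%d grid, mean=%.4g rms=%.4g\n",
              g[1], g[2], g[3], mean(object@grid), sd(as.vector(object@grid))))
})

setMethod("show", "GASelection", function(object) {
  cat(sprintf("GASelection: %d sub-datasets chosen, target=%.4f\n",
              length(object@chosen), object@target))
})
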