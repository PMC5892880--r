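## File formats: SHELX HKLF4 reflection text, PDB-style site records,
## delimited result tables, structured configs and run records.

#' Write observations in HKLF4 fixed-width format
#'
#' Three 4-character integer fields (h, k, l) followed by two 8-character
#' fixed-point fields (I, sigI), terminated by an all-zero record. Values
#' too large for the 8-character fields are uniformly scaled down and the
#' scale is returned invisibly.
#'
#' @param obs data.frame with h, k, l, I, sigI.
#' @param path output file.
#' @return invisibly, the scale applied to I and sigI on writing.
#' @export
writeHklf4 <- function(obs, path) {
  scale <- 1
  maxV <- max(abs(c(obs$I, obs$sigI)), 0)
  if (maxV > 9999.99) scale <- 9999.99 / maxV
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f", obs$h, obs$k, obs$l,
                   obs$I * scale, obs$sigI * scale)
  bad <- nchar(lines) != 28L
  if (any(bad)) stop("HKLF4 field overflow on line ", which(bad)[1])
  writeLines(c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0)),
             path)
  invisible(scale)
}

#' Read an HKLF4 reflection file
#'
#' Strict fixed-width parsing (columns 1-4, 5-8, 9-12 integers; 13-20,
#' 21-28 fixed-point). Parsing stops at the all-zero terminator record; a
#' missing terminator parses to end of file with a warning.
#'
#' @param path input file.
#' @return data.frame with h, k, l, I, sigI.
#' @export
readHklf4 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- matrix(NA_real_, length(lines), 5)
  terminated <- FALSE
  nRec <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (nchar(ln) < 28) stop("HKLF4 parse error at line ", i,
                             ": record shorter than 28 columns")
    fields <- c(substr(ln, 1, 4), substr(ln, 5, 8), substr(ln, 9, 12),
                substr(ln, 13, 20), substr(ln, 21, 28))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop("HKLF4 parse error at line ", i, ": non-numeric field")
    if (any(vals[1:3] != round(vals[1:3])))
      stop("HKLF4 parse error at line ", i, ": non-integer index")
    if (all(vals[1:3] == 0)) { terminated <- TRUE; break }
    nRec <- nRec + 1L
    out[nRec, ] <- vals
  }
  if (!terminated)
    warning("HKLF4 file has no all-zero terminator; parsed to end of file")
  out <- out[seq_len(nRec), , drop = FALSE]
  data.frame(h = as.integer(out[, 1]), k = as.integer(out[, 2]),
             l = as.integer(out[, 3]), I = out[, 4], sigI = out[, 5])
}

#' Write a sub-dataset pool to a directory
#'
#' One HKLF4 file per sub-dataset plus a tab-delimited manifest mapping
#' file to crystal id, exposure and dose, the ground-truth structure as
#' PDB-style ATOM records, and the ground-truth phases as delimited text.
#'
#' @param pool an [ExperimentPool-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data.frame.
#' @export
writePool <- function(pool, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(pool@subdatasets, function(s) {
    fn <- sprintf("crystal%03d_expo%02d.hkl", s@crystalId, s@exposure)
    sc <- writeHklf4(s@observations, file.path(dir, fn))
    data.frame(file = fn, crystalId = s@crystalId, exposure = s@exposure,
               dose = s@dose, cellA = s@cell@a, cellB = s@cell@b,
               cellC = s@cell@c, scale = sc)
  })
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  writeStructurePdb(pool@structure, file.path(dir, "ground_truth.pdb"))
  writePhaseTable(poolTruePhases(pool, 1),
                  file.path(dir, "true_phases_expo1.tsv"))
  cellCfg <- list(cell = c(pool@structure@cell@a, pool@structure@cell@b,
                           pool@structure@cell@c),
                  spacegroup = pool@structure@spacegroup@symbol,
                  doses = pool@doses, seed = pool@seed)
  yaml::write_yaml(cellCfg, file.path(dir, "pool.yaml"))
  invisible(manifest)
}

#' Read a sub-dataset pool from a directory written by [writePool()]
#'
#' Ground truth is not reloaded: the returned list carries only what the
#' pipeline stages may see.
#'
#' @param dir directory with manifest.tsv and HKLF4 files.
#' @param cell a [UnitCell-class]; defaults to the cell in pool.yaml.
#' @param sg a [SpaceGroup-class]; defaults to the group in pool.yaml.
#' @return list of [SubDataset-class].
#' @export
readPool <- function(dir, cell = NULL, sg = NULL) {
  mf <- read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                   header = TRUE)
  meta <- if (file.exists(file.path(dir, "pool.yaml")))
    yaml::read_yaml(file.path(dir, "pool.yaml")) else NULL
  lapply(seq_len(nrow(mf)), function(i) {
    obs <- readHklf4(file.path(dir, mf$file[i]))
    if ("scale" %in% names(mf) && is.finite(mf$scale[i]) &&
        mf$scale[i] > 0) {
      obs$I <- obs$I / mf$scale[i]
      obs$sigI <- obs$sigI / mf$scale[i]
    }
    cl <- unitCell(mf$cellA[i], mf$cellB[i], mf$cellC[i])
    obs$d <- dSpacing(cl, as.matrix(obs[, c("h", "k", "l")]))
    new("SubDataset", crystalId = as.integer(mf$crystalId[i]),
        exposure = as.integer(mf$exposure[i]), dose = mf$dose[i],
        cell = cl, scaleOffset = 1, bOffset = 0, observations = obs)
  })
}

#' Write a structure or substructure as PDB-style ATOM records
#'
#' Fractional coordinates are orthogonalized; occupancy carries the
#' (signed) occupancy estimate.
#'
#' @param x a [ToyStructure-class] or [Substructure-class].
#' @param path output file.
#' @export
writeStructurePdb <- function(x, path) {
  if (is(x, "ToyStructure")) {
    at <- x@atoms
    elems <- at$element
    occ <- at$occ
    b <- at$B
    xyzf <- as.matrix(at[, c("x", "y", "z")])
    cell <- x@cell
  } else {
    at <- x@sites
    elems <- rep("S", nrow(at))
    occ <- at$occ
    b <- rep(20, nrow(at))
    xyzf <- as.matrix(at[, c("x", "y", "z")])
    cell <- attr(x, "cell")
    if (is.null(cell)) cell <- unitCell(1, 1, 1)
  }
  xyz <- xyzf %*% t(orthoMatrix(cell))
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)),
                   resno = seq_len(nrow(at)),
                   resid = rep("UNK", nrow(at)),
                   elety = elems, o = occ, b = b,
                   chain = rep("A", nrow(at)))
  invisible(path)
}

#' Read site records from a PDB-style file
#'
#' @param path PDB file.
#' @param cell a [UnitCell-class] for fractionalization.
#' @return a [Substructure-class] (occupancy from the occupancy column).
#' @export
readSitesPdb <- function(path, cell) {
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  frac <- wrapFrac(xyz %*% t(solve(orthoMatrix(cell))))
  new("Substructure",
      sites = data.frame(x = frac[, 1], y = frac[, 2], z = frac[, 3],
                         occ = pdb$atom$o,
                         height = rep(NA_real_, nrow(frac))),
      ccAll = NA_real_, ccWeak = NA_real_, meta = list(source = path))
}

#' Write a phase table as delimited text
#' @param phases data.frame with h, k, l, phase (and more) or a
#'   [PhaseEstimate-class].
#' @param path output file.
#' @export
writePhaseTable <- function(phases, path) {
  d <- if (is(phases, "PhaseEstimate")) phases@data else phases
  write.table(format(d, digits = 7), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a phase table written by [writePhaseTable()]
#' @param path input file.
#' @return data.frame.
#' @export
readPhaseTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE)
}

#' Write a merged dataset as delimited text
#' @param merged a [MergedDataset-class].
#' @param path output file for the reflections; the per-shell statistics
#'   go to `<path>.stats`.
#' @export
writeMergedData <- function(merged, path) {
  write.table(merged@reflections, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(merged@shells, paste0(path, ".stats"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a merged dataset written by [writeMergedData()]
#' @param path reflections file.
#' @return a [MergedDataset-class] (statistics reloaded when present).
#' @export
readMergedData <- function(path) {
  refl <- read.table(path, sep = "\t", header = TRUE)
  statsPath <- paste0(path, ".stats")
  shells <- if (file.exists(statsPath))
    read.table(statsPath, sep = "\t", header = TRUE) else data.frame()
  new("MergedDataset", reflections = refl, stats = data.frame(),
      shells = shells, memberIds = integer(0))
}

## ---- run configuration -------------------------------------------------

.configSchema <- function() list(
  generator = names(generatorConfig()),
  merging = c("ga", "populationSize", "generations", "crossoverProb",
              "mutationProb", "elitism", "weights", "minSize", "seed",
              "nShells"),
  differences = c("kMin", "kMax", "kStep", "cutoffThreshold", "nShells"),
  substructure = c("ntry", "dMax", "dMin", "nFind", "nCycles",
                   "weakFraction", "strongFraction", "stopScore", "seed"),
  phasing = c("solventFraction", "dmCycles", "bootstrapThreshold",
              "maxBootstrapRounds", "flipFactor"),
  evaluation = c("tolerance", "refThreshold", "doseSeries",
                 "multiplicitySeries"))

#' Read and validate a pipeline run configuration
#'
#' YAML file with blocks generator, merging, differences, substructure,
#' phasing, evaluation; every block is validated against the known keys
#' before any stage runs, and unknown keys are rejected.
#'
#' @param path YAML configuration file.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- .configSchema()
  unknownBlocks <- setdiff(names(cfg), names(schema))
  if (length(unknownBlocks))
    stop("config error: unknown block '", unknownBlocks[1], "'")
  for (blk in names(cfg)) {
    unknown <- setdiff(names(cfg[[blk]]), schema[[blk]])
    if (length(unknown))
      stop("config error: unknown key '", unknown[1], "' in block '",
           blk, "'")
  }
  cfg
}

#' Write a run record
#'
#' Config snapshot, seeds, stage timings, output inventory and package
#' version, sufficient to re-execute the deterministic stages
#' bit-identically.
#'
#' @param path output YAML file.
#' @param config configuration list used.
#' @param seed master seed.
#' @param timings named numeric vector of stage timings (seconds).
#' @param outputs character vector of produced files.
#' @export
writeRunRecord <- function(path, config, seed, timings = numeric(0),
                           outputs = character(0)) {
  rec <- list(config = config, seed = seed,
              timings = as.list(timings), outputs = as.list(outputs),
              package = as.character(packageVersion("serialRIP")),
              rversion = R.version.string)
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' Write the per-trial score log of a substructure search
#'
#' Delimited table of (trial, CC(all), CC(weak)) supporting scatter-plot
#' style diagnostics of the search.
#'
#' @param substructure a [Substructure-class] from [dualSpaceSearch()].
#' @param path output file.
#' @export
writeScoreLog <- function(substructure, path) {
  log <- substructure@meta$scoreLog
  if (is.null(log)) stop("substructure carries no score log")
  write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a real-space map as a portable text grid container
#'
#' Plain-text format: a header line `dims nx ny nz`, a `cell` line with
#' the six cell parameters, then the grid values in Fortran (x fastest)
#' order, ten per line.
#'
#' @param map a [RealMap-class].
#' @param path output file.
#' @export
writeMapGrid <- function(map, path) {
  n <- dim(map@grid)
  con <- file(path, "w")
  on.exit(close(con))
  cat("dims", n, "\n", file = con)
  cat("cell", map@cell@a, map@cell@b, map@cell@c, map@cell@alpha,
      map@cell@beta, map@cell@gamma, "\n", file = con)
  writeLines(apply(matrix(c(sprintf("%.6g", map@grid),
                            rep("", (10 - length(map@grid) %% 10) %% 10)),
                          nrow = 10), 2, paste, collapse = " "), con)
  invisible(path)
}

#' Read a map written by [writeMapGrid()]
#' @param path input file.
#' @return a [RealMap-class].
#' @export
readMapGrid <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][-1])
  cl <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]][-1])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:2)]), "\\s+")))
  vals <- vals[seq_len(prod(dims))]
  new("RealMap", grid = array(vals, dims),
      cell = unitCell(cl[1], cl[2], cl[3], cl[4], cl[5], cl[6]))
}
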