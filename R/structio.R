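# Structure/trajectory I/O and atom selection. PDB parsing is delegated to
# bio3d; multi-model PDB and DCD trajectory *writing* are implemented here
# (bio3d reads but does not write DCD).

#' Read a reference structure from a PDB file
#'
#' Reads all ATOM records of the first model. Alternate locations are
#' resolved by highest occupancy, ties broken by file order. HETATM records
#' are ignored.
#'
#' @param path Path to a PDB file.
#' @param chain Optional chain id to restrict to (required for multi-chain
#'   input used in single-chain analyses).
#' @return A \code{\link{Structure}}.
#' @examples
#' pdb <- system.file("extdata", "toy_twodomain_synthetic.pdb",
#'                    package = "DomainDynamics")
#' s <- readStructure(pdb)
#' @export
readStructure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  .checkPDBCoordinates(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          verbose = FALSE, rm.alt = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  if (!is.null(chain)) {
    at <- at[at$chain %in% chain, , drop = FALSE]
    if (!nrow(at)) stop("no ATOM records for chain ", chain, " in ", path)
  } else if (length(unique(at$chain)) > 1) {
    stop("multi-chain input: specify a chain id (chains: ",
         paste(unique(at$chain), collapse = ", "), ")")
  }
  at <- .resolveAltLoc(at)
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- substr(trimws(at$elety[is.na(elem) | elem == ""]), 1, 1)
  atoms <- data.frame(elety = trimws(at$elety), resno = at$resno,
                      resid = trimws(at$resid), chain = at$chain,
                      elem = trimws(elem), stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  Structure(atoms, cbind(at$x, at$y, at$z))
}

## Error with the line number if an ATOM record has unparsable coordinates.
.checkPDBCoordinates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  idx <- which(startsWith(lines, "ATOM"))
  for (i in idx) {
    fields <- substring(lines[i], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stop(sprintf("malformed coordinate fields at line %d of %s", i, path))
  }
  invisible(TRUE)
}

.resolveAltLoc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  key <- paste(at$chain, at$resno, trimws(at$elety))
  occ <- at$o
  occ[is.na(occ)] <- 1
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, unique(key))),
                        function(ii) ii[which.max(occ[ii])]))
  at[sort(keep), , drop = FALSE]
}

#' Read a coordinate trajectory (DCD or multi-model PDB)
#'
#' Frames are returned in file order. Time metadata is taken from the
#' arguments (normally from an \code{\link{AnalysisConfig}}), never from DCD
#' headers, which are unreliable across writers.
#'
#' @param topology A \code{\link{Structure}} with the trajectory's atom table.
#' @param path DCD file or multi-model PDB.
#' @param frameInterval Time between frames in ps (NA if unknown).
#' @param productionLength Production length in ns (NA if unknown).
#' @param format "auto" (by extension), "dcd" or "pdb".
#' @return A \code{\link{Trajectory}}.
#' @export
readTrajectory <- function(topology, path, frameInterval = NA_real_,
                           productionLength = NA_real_,
                           format = c("auto", "dcd", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
      error = function(e) stop("cannot parse multi-model PDB ", path,
                               " (truncated or malformed): ",
                               conditionMessage(e), call. = FALSE))
    keep <- which(pdb$atom$type == "ATOM")
    if (!length(keep)) stop("no ATOM records in ", path)
    if (ncol(pdb$xyz) < 3 * nrow(pdb$atom))
      stop(sprintf("trajectory file %s appears truncated: %d coordinates per frame for %d atoms",
                   path, ncol(pdb$xyz), nrow(pdb$atom)))
    xyz <- pdb$xyz[, as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep)),
                   drop = FALSE]
  }
  found <- ncol(xyz) / 3
  if (found != nAtoms(topology))
    stop(sprintf("atom-count mismatch: topology has %d atoms, trajectory has %g",
                 nAtoms(topology), found))
  nfr <- nrow(xyz)
  coords <- aperm(array(t(xyz), dim = c(3, nAtoms(topology), nfr)),
                  c(2, 1, 3))
  traj <- Trajectory(topology, coords, frameInterval, productionLength)
  checkBookkeeping(traj)
  traj
}

#' Write a trajectory to multi-model PDB or DCD
#'
#' @param traj A \code{\link{Trajectory}}.
#' @param path Output path.
#' @param format "pdb" (multi-model, text) or "dcd" (CHARMM-style binary).
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(traj, path, format = c("pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "dcd") return(.writeDCD(coords(traj), path))
  a <- atoms(traj)
  con <- file(path, "w")
  on.exit(close(con))
  nfr <- nFrames(traj)
  for (f in seq_len(nfr)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj@coords[, , f]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(.pdbAtomLines(a, xyz), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a single structure to a PDB file
#'
#' @param structure A \code{\link{Structure}}.
#' @param path Output path.
#' @export
writeStructure <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.pdbAtomLines(atoms(structure), coords(structure)), con)
  writeLines("END", con)
  invisible(path)
}

.pdbAtomLines <- function(a, xyz) {
  name <- ifelse(nchar(a$elety) < 4, sprintf(" %-3s", a$elety),
                 sprintf("%-4s", a$elety))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(a)) %% 100000, name, a$resid, a$chain, a$resno,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$elem)
}

## Minimal CHARMM-format DCD writer (little-endian, no unit cell). bio3d's
## read.dcd serves as the independent reader in round-trip tests.
.writeDCD <- function(coords, path) {
  natoms <- dim(coords)[1]
  nfr <- dim(coords)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  icntrl <- integer(20)
  icntrl[1] <- nfr; icntrl[2] <- 1; icntrl[3] <- 1; icntrl[4] <- nfr
  icntrl[20] <- 24  # CHARMM version flag
  wInt(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  wInt(icntrl)
  wInt(84)
  title <- sprintf("%-80s", "written by DomainDynamics")
  wInt(4 + 80)
  wInt(1)
  writeChar(title, con, nchars = 80, eos = NULL)
  wInt(4 + 80)
  wInt(4); wInt(natoms); wInt(4)
  for (f in seq_len(nfr)) {
    for (k in 1:3) {
      wInt(4 * natoms)
      writeBin(as.numeric(coords[, k, f]), con, size = 4, endian = "little")
      wInt(4 * natoms)
    }
  }
  invisible(path)
}

#' Select C-alpha atom indices for an inclusive residue range
#'
#' Returns one atom index per residue in \code{range} that has a CA atom,
#' in residue order. A residue present in the range but lacking a CA is an
#' error (analyses here are CA-based).
#'
#' @param structure A \code{\link{Structure}}.
#' @param range Inclusive residue interval \code{c(first, last)}.
#' @return Integer vector of atom indices.
#' @export
selectCalpha <- function(structure, range) {
  stopifnot(length(range) == 2, range[1] <= range[2])
  a <- atoms(structure)
  inRange <- a$resno >= range[1] & a$resno <= range[2]
  if (!any(inRange))
    stop(sprintf("no residues in range %d-%d", range[1], range[2]))
  present <- unique(a$resno[inRange])
  idx <- which(inRange & a$elety == "CA")
  missing <- setdiff(present, a$resno[idx])
  if (length(missing))
    stop("residue(s) without a CA atom in range: ",
         paste(missing, collapse = ", "))
  idx
}

# ---------------------------------------------------------------------------
# Analysis configuration.
# ---------------------------------------------------------------------------

.defaultParams <- list(
  distance_bin_width = 0.5,     # Angstrom (distance histograms)
  angle_bin_width = 2,          # degrees (angle histograms)
  kde_bandwidth = "silverman",
  shell_cutoff = 10,            # Angstrom, coordination shell
  anticorrelation_threshold = 0.1,
  anticorrelation_margin = 0.05,
  distance_change_windows = c(4, 10),  # Angstrom, |delta| window
  distance_change_mode = "strict",     # or "saturating"
  salt_bridge_threshold = 4.5,  # Angstrom, COM distance for "formed"
  min_prominence_fraction = 0.05,
  fes_bins = 50,
  combined_pca = TRUE)

#' Construct an analysis configuration
#'
#' @param domains Named list of inclusive residue ranges, e.g.
#'   \code{list(cyclophilin = c(1, 183), linker = c(184, 213),
#'   TPR = c(216, 362))}.
#' @param helices Named list of inclusive helix ranges.
#' @param saltBridges data.frame with columns \code{acidic}, \code{basic}
#'   (residue numbers).
#' @param pcaRange Inclusive residue range used for superposition and PCA.
#' @param temperature Temperature in K (default 310).
#' @param chain Chain id for multi-chain input (NA = single chain).
#' @param frameInterval Time per stored frame in ps.
#' @param productionLength Production run length in ns.
#' @param nReplicas Number of independent production runs per system.
#' @param params Named list of descriptor parameters; unset entries take
#'   package defaults (each default is logged).
#' @return A validated \code{AnalysisConfig}.
#' @export
AnalysisConfig <- function(domains, helices = list(),
                           saltBridges = data.frame(acidic = integer(),
                                                    basic = integer()),
                           pcaRange = numeric(), temperature = 310,
                           chain = NA_character_, frameInterval = NA_real_,
                           productionLength = NA_real_, nReplicas = 1,
                           params = list()) {
  filled <- .defaultParams
  for (nm in names(params)) filled[[nm]] <- params[[nm]]
  defaulted <- setdiff(names(.defaultParams), names(params))
  if (length(defaulted))
    message("using default parameter(s): ",
            paste(sprintf("%s=%s", defaulted,
                          vapply(filled[defaulted],
                                 function(v) paste(format(v), collapse = ","),
                                 character(1))), collapse = ", "))
  domains <- lapply(domains, as.numeric)
  helices <- lapply(helices, as.numeric)
  new("AnalysisConfig", domains = domains, helices = helices,
      saltBridges = as.data.frame(saltBridges), pcaRange = as.numeric(pcaRange),
      temperature = temperature, chain = as.character(chain),
      frameInterval = as.numeric(frameInterval),
      productionLength = as.numeric(productionLength),
      nReplicas = as.numeric(nReplicas), params = filled)
}

#' Load an analysis configuration from YAML
#'
#' Required keys: \code{domains}. Optional: \code{helices},
#' \code{salt_bridges} (list of \code{[acidic, basic]} pairs),
#' \code{pca_residue_range}, \code{temperature} (default 310 K, logged),
#' \code{chain}, \code{frame_interval_ps}, \code{production_length_ns},
#' \code{n_replicas}, \code{parameters}. Every defaulted parameter is logged
#' via \code{message()}.
#'
#' @param path YAML file.
#' @param structure Optional \code{\link{Structure}}; when given, all residue
#'   ranges are validated against its residue span.
#' @return A validated \code{\link{AnalysisConfig}}.
#' @export
loadConfig <- function(path, structure = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$domains)) stop("config must define 'domains'")
  sb <- y$salt_bridges
  sb <- if (length(sb)) {
    m <- do.call(rbind, lapply(sb, as.integer))
    data.frame(acidic = m[, 1], basic = m[, 2])
  } else data.frame(acidic = integer(), basic = integer())
  if (is.null(y$temperature))
    message("using default temperature = 310 K")
  cfg <- AnalysisConfig(
    domains = y$domains, helices = y$helices %||% list(), saltBridges = sb,
    pcaRange = as.numeric(y$pca_residue_range %||% numeric()),
    temperature = y$temperature %||% 310, chain = y$chain %||% NA_character_,
    frameInterval = y$frame_interval_ps %||% NA_real_,
    productionLength = y$production_length_ns %||% NA_real_,
    nReplicas = y$n_replicas %||% 1, params = y$parameters %||% list())
  if (!is.null(structure)) validateConfig(cfg, structure)
  cfg
}

#' Validate a configuration against a structure
#'
#' Checks that every domain, helix, salt-bridge and PCA residue range lies
#' within the structure's residue span.
#'
#' @param config An \code{\link{AnalysisConfig}}.
#' @param structure A \code{\link{Structure}}.
#' @return \code{TRUE} invisibly; errors otherwise.
#' @export
validateConfig <- function(config, structure) {
  span <- range(atoms(structure)$resno)
  chk <- function(r, what) {
    if (r[1] < span[1] || r[2] > span[2])
      stop(sprintf("%s range %g-%g outside structure residue span %d-%d",
                   what, r[1], r[2], span[1], span[2]))
  }
  for (nm in names(config@domains)) chk(config@domains[[nm]], paste("domain", nm))
  for (nm in names(config@helices)) chk(config@helices[[nm]], paste("helix", nm))
  if (length(config@pcaRange)) chk(config@pcaRange, "pca_residue_range")
  if (nrow(config@saltBridges)) {
    rs <- unlist(config@saltBridges)
    if (any(rs < span[1] | rs > span[2]))
      stop("salt-bridge residue outside structure residue span")
  }
  invisible(TRUE)
}

#' Frame/time bookkeeping of a configuration
#'
#' Reproduces the trajectory arithmetic of a production setup: frames per
#' run = production length (ns) x 1000 / frame interval (ps); total sampling
#' = runs x production length.
#'
#' @param config An \code{\link{AnalysisConfig}}.
#' @param nSystems Number of simulated systems sharing the setup.
#' @return List with \code{framesPerRun}, \code{totalNs},
#'   \code{totalMicroseconds}.
#' @examples
#' cfg <- AnalysisConfig(domains = list(d1 = c(1, 10)), frameInterval = 50,
#'                       productionLength = 720, nReplicas = 2)
#' bookkeeping(cfg, nSystems = 4)  # 14400 frames/run, 5.76 us total
#' @export
bookkeeping <- function(config, nSystems = 1) {
  fi <- config@frameInterval
  pl <- config@productionLength
  frames <- if (is.na(fi) || is.na(pl)) NA_real_ else pl * 1000 / fi
  if (!is.na(frames) && abs(frames - round(frames)) > 1e-9)
    warning(sprintf("production length (%g ns) is not a whole number of frame intervals (%g ps)",
                    pl, fi))
  totalNs <- if (is.na(pl)) NA_real_ else pl * config@nReplicas * nSystems
  list(framesPerRun = frames, totalNs = totalNs,
       totalMicroseconds = totalNs / 1000)
}

#' Check a trajectory's frame count against its time metadata
#'
#' @param traj A \code{\link{Trajectory}}.
#' @return \code{TRUE} if consistent (or metadata absent), invisibly;
#'   warns on mismatch or non-integral frame arithmetic.
#' @export
checkBookkeeping <- function(traj) {
  fi <- traj@frameInterval
  pl <- traj@productionLength
  if (is.na(fi) || is.na(pl)) return(invisible(TRUE))
  expected <- pl * 1000 / fi
  if (abs(expected - round(expected)) > 1e-9) {
    warning(sprintf("production length (%g ns) not an integral number of %g ps frames",
                    pl, fi))
    return(invisible(FALSE))
  }
  if (round(expected) != nFrames(traj)) {
    warning(sprintf("frame count %d does not match %g ns @ %g ps (%d expected)",
                    nFrames(traj), pl, fi, as.integer(round(expected))))
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
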