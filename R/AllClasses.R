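#' @import methods
#' @importFrom stats density dist rnorm runif sd var
NULL

## Boltzmann constant in kcal/mol/K
.kB <- 0.0019872

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return kT in kcal/mol (k = 0.0019872 kcal/mol/K).
#' @examples
#' thermalEnergy(310)  # ~0.616 kcal/mol
#' @export
thermalEnergy <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB * temperature
}

# ---------------------------------------------------------------------------
# Structure: an atom table plus one coordinate set (the reference frame for
# alignment and domain definitions). Coordinates are in Angstrom.
# ---------------------------------------------------------------------------

#' @rdname Structure
#' @export
setClass("Structure",
  representation(atoms = "data.frame", xyz = "matrix"))

setValidity("Structure", function(object) {
  a <- object@atoms
  msg <- character()
  required <- c("elety", "resno", "resid", "chain", "elem")
  if (!all(required %in% names(a)))
    msg <- c(msg, paste("atoms must have columns:",
                        paste(required, collapse = ", ")))
  if (nrow(a) != nrow(object@xyz) || ncol(object@xyz) != 3)
    msg <- c(msg, "xyz must be an n_atoms x 3 matrix")
  if (nrow(object@xyz) && !all(is.finite(object@xyz)))
    msg <- c(msg, "all coordinates must be finite")
  if (nrow(a) && all(required %in% names(a))) {
    for (ch in unique(a$chain)) {
      rn <- a$resno[a$chain == ch]
      if (is.unsorted(rn))
        msg <- c(msg, sprintf("residue numbers must be non-decreasing within chain '%s'", ch))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Structure: atoms plus one coordinate set
#'
#' A light-weight container for a protein structure: an ordered atom table
#' (atom name \code{elety}, 1-based residue number \code{resno}, residue name
#' \code{resid}, chain id \code{chain}, element \code{elem}) and an
#' \code{n x 3} coordinate matrix in Angstrom.
#'
#' @param atoms data.frame with columns elety, resno, resid, chain, elem.
#' @param xyz numeric n x 3 matrix of coordinates (Angstrom).
#' @return A \code{Structure} object.
#' @examples
#' s <- Structure(
#'   atoms = data.frame(elety = "CA", resno = 1L, resid = "GLY",
#'                      chain = "A", elem = "C"),
#'   xyz = matrix(c(1, 2, 3), 1, 3))
#' nAtoms(s)
#' @export
Structure <- function(atoms, xyz) {
  atoms$resno <- as.integer(atoms$resno)
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- NULL
  storage.mode(xyz) <- "double"
  new("Structure", atoms = atoms, xyz = xyz)
}

# ---------------------------------------------------------------------------
# Trajectory: ordered frames of coordinates over a fixed atom table.
# ---------------------------------------------------------------------------

#' @rdname Trajectory
#' @export
setClass("Trajectory",
  representation(topology = "Structure", coords = "array",
                 frameInterval = "numeric", productionLength = "numeric",
                 aligned = "logical"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  msg <- character()
  if (length(d) != 3 || d[2] != 3)
    msg <- c(msg, "coords must be an n_atoms x 3 x n_frames array")
  else if (d[1] != nAtoms(object@topology))
    msg <- c(msg, sprintf("frame atom count (%d) does not match topology (%d)",
                          d[1], nAtoms(object@topology)))
  if (length(object@frameInterval) != 1 ||
      (!is.na(object@frameInterval) && object@frameInterval <= 0))
    msg <- c(msg, "frameInterval must be a single positive value (ps) or NA")
  if (length(msg)) msg else TRUE
})

#' Trajectory: frames of coordinates over a fixed topology
#'
#' @param topology A \code{Structure} giving the atom table.
#' @param coords n_atoms x 3 x n_frames array (Angstrom), frames in file order.
#' @param frameInterval Time between stored frames in ps (NA if unknown).
#'   Taken from configuration, never guessed from binary file headers.
#' @param productionLength Production run length in ns (NA if unknown).
#' @param aligned Logical flag set by \code{\link{alignTrajectory}}.
#' @return A \code{Trajectory} object.
#' @export
Trajectory <- function(topology, coords, frameInterval = NA_real_,
                       productionLength = NA_real_, aligned = FALSE) {
  storage.mode(coords) <- "double"
  new("Trajectory", topology = topology, coords = coords,
      frameInterval = as.numeric(frameInterval),
      productionLength = as.numeric(productionLength), aligned = aligned)
}

# ---------------------------------------------------------------------------
# AnalysisConfig: domains, helices, salt bridges, bookkeeping, parameters.
# ---------------------------------------------------------------------------

#' @rdname AnalysisConfig
#' @export
setClass("AnalysisConfig",
  representation(domains = "list", helices = "list", saltBridges = "data.frame",
                 pcaRange = "numeric", temperature = "numeric",
                 chain = "character", frameInterval = "numeric",
                 productionLength = "numeric", nReplicas = "numeric",
                 params = "list"))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  chkRange <- function(r, what) {
    if (!is.numeric(r) || length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      sprintf("%s must be an inclusive range c(start, end)", what)
    else character()
  }
  for (nm in names(object@domains))
    msg <- c(msg, chkRange(object@domains[[nm]], paste("domain", nm)))
  for (nm in names(object@helices))
    msg <- c(msg, chkRange(object@helices[[nm]], paste("helix", nm)))
  if (!length(msg) && length(object@domains) > 1) {
    rr <- do.call(rbind, object@domains)
    o <- order(rr[, 1])
    rr <- rr[o, , drop = FALSE]
    if (any(rr[-1, 1] <= rr[-nrow(rr), 2]))
      msg <- c(msg, "domain ranges must not overlap")
  }
  if (length(object@temperature) != 1 || object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive value (K)")
  if (length(object@pcaRange))
    msg <- c(msg, chkRange(object@pcaRange, "pca_residue_range"))
  if (nrow(object@saltBridges) &&
      !all(c("acidic", "basic") %in% names(object@saltBridges)))
    msg <- c(msg, "saltBridges must have columns 'acidic' and 'basic'")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SyntheticSpec / GroundTruth: the two-state trajectory generator.
# ---------------------------------------------------------------------------

#' @rdname SyntheticSpec
#' @export
setClass("SyntheticSpec",
  representation(nResDomain1 = "numeric", nResDomain2 = "numeric",
                 nResLinker = "numeric", nHelices = "numeric",
                 extendedDistance = "numeric", compactDistance = "numeric",
                 pEC = "numeric", pCE = "numeric", noiseSigma = "numeric",
                 linkerNoiseScale = "numeric", nFrames = "numeric",
                 seed = "numeric", acidLinkerOffsets = "numeric",
                 baseDomain2Offsets = "numeric"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nResDomain1 < 1 || object@nResDomain2 < 1)
    msg <- c(msg, "both domains must have at least one residue")
  if (object@nResLinker < 0) msg <- c(msg, "linker length must be >= 0")
  if (object@extendedDistance <= 0 || object@compactDistance <= 0)
    msg <- c(msg, "basin interdomain distances must be positive")
  if (object@pEC < 0 || object@pEC > 1 || object@pCE < 0 || object@pCE > 1)
    msg <- c(msg, "switch probabilities must lie in [0, 1]")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@linkerNoiseScale < 1)
    msg <- c(msg, "linkerNoiseScale must be >= 1")
  if (object@nFrames < 1) msg <- c(msg, "nFrames must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Specification for the synthetic two-state trajectory generator
#'
#' Defines a two-domain C-alpha toy protein (globular domain 1, extended
#' linker, helix-bundle domain 2 with proxy side-chain atoms for salt-bridge
#' descriptors) and a per-frame two-state Markov chain switching between an
#' extended and a compact basin that differ by a rigid interdomain
#' translation. Defaults mirror the study conditions the generator emulates:
#' basin centroid distances 43.8 and 34.0 Angstrom, per-atom isotropic noise
#' 1.5 Angstrom, linker noise scale 3, switch probabilities 0.003
#' (extended to compact) and 0.007 (compact to extended), and 14400 frames
#' (720 ns sampled every 50 ps).
#'
#' @param nResDomain1,nResDomain2,nResLinker Residue counts of the globular
#'   domain, the helix-bundle domain and the connecting linker.
#' @param nHelices Number of ideal alpha-helices in domain 2.
#' @param extendedDistance,compactDistance Target interdomain centroid
#'   distances (Angstrom) of the two basins.
#' @param pEC,pCE Per-frame switch probabilities extended->compact and
#'   compact->extended. The stationary compact fraction is pEC/(pEC+pCE).
#' @param noiseSigma Isotropic Gaussian positional noise per atom per frame
#'   (Angstrom).
#' @param linkerNoiseScale Multiplier (>= 1) applied to noiseSigma for
#'   linker atoms, emulating the elevated linker B-factors of flexible
#'   interdomain tethers.
#' @param nFrames Number of frames to generate.
#' @param seed RNG seed; all generator randomness is derived from it.
#' @param acidLinkerOffsets 0-based offsets into the linker of residues that
#'   carry proxy acidic side-chain oxygens.
#' @param baseDomain2Offsets 0-based offsets into domain 2 of residues that
#'   carry a proxy basic side-chain nitrogen.
#' @return A validated \code{SyntheticSpec}.
#' @export
SyntheticSpec <- function(nResDomain1 = 60, nResDomain2 = 60, nResLinker = 10,
                          nHelices = 2, extendedDistance = 43.8,
                          compactDistance = 34.0, pEC = 0.003, pCE = 0.007,
                          noiseSigma = 1.5, linkerNoiseScale = 3,
                          nFrames = 14400, seed = 1,
                          acidLinkerOffsets = c(4, 6),
                          baseDomain2Offsets = c(2, 5)) {
  new("SyntheticSpec", nResDomain1 = nResDomain1, nResDomain2 = nResDomain2,
      nResLinker = nResLinker, nHelices = nHelices,
      extendedDistance = extendedDistance, compactDistance = compactDistance,
      pEC = pEC, pCE = pCE, noiseSigma = noiseSigma,
      linkerNoiseScale = linkerNoiseScale, nFrames = nFrames, seed = seed,
      acidLinkerOffsets = acidLinkerOffsets,
      baseDomain2Offsets = baseDomain2Offsets)
}

#' @rdname GroundTruth
#' @export
setClass("GroundTruth",
  representation(labels = "character", occupancy = "numeric",
                 basinRefs = "list"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!all(object@labels %in% c("extended", "compact")))
    msg <- c(msg, "labels must be 'extended' or 'compact'")
  if (abs(sum(object@occupancy) - 1) > 1e-12)
    msg <- c(msg, "occupancies must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic two-state trajectory
#'
#' Per-frame basin labels, realized occupancy fractions and the noise-free
#' basin reference structures.
#'
#' @param labels character vector of per-frame labels.
#' @param occupancy named numeric, realized fractions (sum 1).
#' @param basinRefs named list of \code{Structure} basin references.
#' @export
GroundTruth <- function(labels, occupancy, basinRefs) {
  new("GroundTruth", labels = labels, occupancy = occupancy,
      basinRefs = basinRefs)
}

# ---------------------------------------------------------------------------
# CovarianceModel / FreeEnergySurface (essential dynamics).
# ---------------------------------------------------------------------------

#' @rdname CovarianceModel
#' @export
setClass("CovarianceModel",
  representation(selection = "integer", mean = "numeric", matrix = "matrix",
                 components = "matrix", variances = "numeric"))

setValidity("CovarianceModel", function(object) {
  msg <- character()
  C <- object@matrix
  if (nrow(C) != ncol(C)) msg <- c(msg, "covariance must be square")
  if (nrow(C) != 3 * length(object@selection))
    msg <- c(msg, "covariance dimension must be 3 x selection length")
  if (length(object@mean) != nrow(C))
    msg <- c(msg, "mean length must match covariance dimension")
  if (nrow(C) && max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    msg <- c(msg, "covariance must be symmetric")
  if (length(object@variances)) {
    if (any(object@variances < 0)) msg <- c(msg, "variances must be >= 0")
    if (is.unsorted(rev(object@variances)))
      msg <- c(msg, "variances must be in descending order")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FreeEnergySurface
#' @export
setClass("FreeEnergySurface",
  representation(pcIndices = "integer", edges = "list", density = "array",
                 energy = "array", kT = "numeric"))

setValidity("FreeEnergySurface", function(object) {
  msg <- character()
  if (length(object@pcIndices) != length(object@edges))
    msg <- c(msg, "one edge vector per axis required")
  if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
  if (object@kT <= 0) msg <- c(msg, "kT must be positive")
  bad <- (object@density == 0) != is.infinite(object@energy)
  if (any(bad)) msg <- c(msg, "energy must be infinite exactly on empty bins")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Descriptor containers.
# ---------------------------------------------------------------------------

#' @rdname DescriptorSeries
#' @export
setClass("DescriptorSeries",
  representation(name = "character", values = "numeric", units = "character",
                 provenance = "list"))

setValidity("DescriptorSeries", function(object) {
  if (length(object@values) && !all(is.finite(object@values)))
    "descriptor values must be finite" else TRUE
})

#' Per-frame scalar descriptor series
#'
#' @param name Descriptor name.
#' @param values Per-frame values.
#' @param units "Angstrom" or "degrees".
#' @param provenance list recording the definition and residue sets.
#' @export
DescriptorSeries <- function(name, values, units, provenance = list()) {
  new("DescriptorSeries", name = name, values = as.numeric(values),
      units = units, provenance = provenance)
}

#' @rdname FluctuationProfile
#' @export
setClass("FluctuationProfile",
  representation(resno = "integer", rmsf = "numeric", bfactor = "numeric",
                 context = "character"))

setValidity("FluctuationProfile", function(object) {
  msg <- character()
  if (length(object@rmsf) != length(object@resno) ||
      length(object@bfactor) != length(object@resno))
    msg <- c(msg, "rmsf/bfactor lengths must match resno")
  if (any(object@rmsf < 0)) msg <- c(msg, "rmsf must be >= 0")
  if (length(object@rmsf) &&
      max(abs(object@bfactor - (8 * pi^2 / 3) * object@rmsf^2)) >
        1e-8 * max(1, max(object@bfactor)))
    msg <- c(msg, "bfactor must equal (8*pi^2/3) * rmsf^2")
  if (length(msg)) msg else TRUE
})

#' @rdname CoordinationShellProfile
#' @export
setClass("CoordinationShellProfile",
  representation(resno = "integer", radius = "numeric",
                 nNeighbors = "numeric", average = "numeric",
                 cutoff = "numeric"))

#' @rdname HelixAxis
#' @export
setClass("HelixAxis",
  representation(axis = "numeric", anchor = "numeric", name = "character"))

setValidity("HelixAxis", function(object) {
  msg <- character()
  if (length(object@axis) != 3 || abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    msg <- c(msg, "axis must be a unit 3-vector")
  if (length(object@anchor) != 3) msg <- c(msg, "anchor must be a 3-vector")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Comparative containers.
# ---------------------------------------------------------------------------

#' @rdname MeanDistanceMatrix
#' @export
setClass("MeanDistanceMatrix",
  representation(resno = "integer", matrix = "matrix"))

setValidity("MeanDistanceMatrix", function(object) {
  msg <- character()
  M <- object@matrix
  if (nrow(M) != length(object@resno) || ncol(M) != length(object@resno))
    msg <- c(msg, "matrix dimension must match residue list")
  if (nrow(M)) {
    if (max(abs(M - t(M))) > 1e-9) msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(M)) > 1e-9)) msg <- c(msg, "diagonal must be zero")
    if (any(M < 0)) msg <- c(msg, "distances must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CorrelationMatrix
#' @export
setClass("CorrelationMatrix",
  representation(resno = "integer", matrix = "matrix", context = "character",
                 undefined = "integer"))

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  M <- object@matrix
  if (nrow(M) != length(object@resno) || ncol(M) != length(object@resno))
    msg <- c(msg, "matrix dimension must match residue list")
  ok <- is.finite(M)
  if (any(M[ok] > 1 + 1e-9) || any(M[ok] < -1 - 1e-9))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (nrow(M) && max(abs(M - t(M)), na.rm = TRUE) > 1e-9)
    msg <- c(msg, "matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' @rdname DifferenceMap
#' @export
setClass("DifferenceMap",
  representation(resno = "integer", delta = "matrix", classification = "matrix",
                 thresholds = "list", kind = "character"))

setValidity("DifferenceMap", function(object) {
  msg <- character()
  if (!identical(dim(object@delta), dim(object@classification)))
    msg <- c(msg, "delta and class must have the same dimension")
  if (nrow(object@delta) != length(object@resno))
    msg <- c(msg, "matrix dimension must match residue list")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# State classification containers.
# ---------------------------------------------------------------------------

#' @rdname DistributionEstimate
#' @export
setClass("DistributionEstimate",
  representation(grid = "numeric", density = "numeric", estimator = "character",
                 width = "numeric", n = "integer"))

setValidity("DistributionEstimate", function(object) {
  msg <- character()
  if (length(object@grid) != length(object@density))
    msg <- c(msg, "grid and density lengths must match")
  if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
  if (length(object@grid) > 1) {
    dx <- diff(object@grid)
    if (max(abs(dx - dx[1])) > 1e-8 * abs(dx[1]))
      msg <- c(msg, "grid must be regular")
    if (abs(sum(object@density) * dx[1] - 1) > 1e-6)
      msg <- c(msg, "density must integrate to 1")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname StateAssignment
#' @export
setClass("StateAssignment",
  representation(labels = "character", boundary = "numeric",
                 fractionCompact = "numeric", peaks = "numeric",
                 descriptor = "character"))

setValidity("StateAssignment", function(object) {
  msg <- character()
  if (!all(object@labels %in% c("extended", "compact")))
    msg <- c(msg, "labels must be 'extended' or 'compact'")
  f <- mean(object@labels == "compact")
  if (abs(f - object@fractionCompact) > 1e-12)
    msg <- c(msg, "fractionCompact must equal the compact label fraction")
  if (length(object@peaks) == 2 && is.finite(object@boundary)) {
    if (object@boundary <= min(object@peaks) ||
        object@boundary >= max(object@peaks))
      msg <- c(msg, "boundary must lie strictly between the two peaks")
  }
  if (length(msg)) msg else TRUE
})
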