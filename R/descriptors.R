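# Per-frame geometric descriptors: interdomain centroid distance,
# salt-bridge center-of-mass distance, helix axes and interhelix angles,
# RMSF/B-factors, coordination-shell radii.

.sideChainO <- c("OD1", "OD2", "OE1", "OE2")
.sideChainN <- c("NZ", "NH1", "NH2", "NE", "ND1", "NE2")

#' Interdomain centroid distance series
#'
#' Per-frame Euclidean distance between the unweighted CA centroids of two
#' domains. Invariant under global rigid motion, so no alignment is needed.
#'
#' @param traj A \code{\link{Trajectory}} (or \code{\link{Structure}} for a
#'   single frame).
#' @param domainA,domainB Inclusive residue ranges.
#' @return A \code{\link{DescriptorSeries}} in Angstrom (a single number
#'   for a \code{Structure}).
#' @export
interdomainDistance <- function(traj, domainA, domainB) {
  if (is(traj, "Structure")) {
    iA <- selectCalpha(traj, domainA); iB <- selectCalpha(traj, domainB)
    xyz <- coords(traj)
    return(sqrt(sum((.centroid(xyz[iA, , drop = FALSE]) -
                     .centroid(xyz[iB, , drop = FALSE]))^2)))
  }
  top <- topology(traj)
  iA <- selectCalpha(top, domainA); iB <- selectCalpha(top, domainB)
  cA <- apply(traj@coords[iA, , , drop = FALSE], c(2, 3), mean)  # 3 x T
  cB <- apply(traj@coords[iB, , , drop = FALSE], c(2, 3), mean)
  DescriptorSeries("interdomain_distance", sqrt(colSums((cA - cB)^2)),
                   "Angstrom",
                   provenance = list(definition = "CA centroid distance",
                                     domainA = domainA, domainB = domainB))
}

#' Salt-bridge center-of-mass distance series
#'
#' Per-frame distance between the center of mass of the side-chain oxygens
#' of an acidic residue (OD1/OD2/OE1/OE2) and the center of mass of the
#' side-chain nitrogens of a basic residue (NZ/NH1/NH2/NE/ND1/NE2). All-O
#' and all-N sets make the mass weighting an unweighted mean.
#'
#' @param traj A \code{\link{Trajectory}} (or \code{\link{Structure}}).
#' @param acidic,basic Residue numbers.
#' @return A \code{\link{DescriptorSeries}} in Angstrom (single number for
#'   a \code{Structure}).
#' @export
saltBridgeDistance <- function(traj, acidic, basic) {
  top <- if (is(traj, "Structure")) traj else topology(traj)
  a <- atoms(top)
  iO <- which(a$resno == acidic & a$elety %in% .sideChainO)
  iN <- which(a$resno == basic & a$elety %in% .sideChainN)
  if (!length(iO))
    stop("residue ", acidic, " has no acidic side-chain oxygens")
  if (!length(iN))
    stop("residue ", basic, " has no basic side-chain nitrogens")
  if (is(traj, "Structure")) {
    xyz <- coords(traj)
    return(sqrt(sum((.centroid(xyz[iO, , drop = FALSE]) -
                     .centroid(xyz[iN, , drop = FALSE]))^2)))
  }
  cO <- apply(traj@coords[iO, , , drop = FALSE], c(2, 3), mean)
  cN <- apply(traj@coords[iN, , , drop = FALSE], c(2, 3), mean)
  DescriptorSeries(sprintf("salt_bridge_%d_%d", acidic, basic),
                   sqrt(colSums((cO - cN)^2)), "Angstrom",
                   provenance = list(definition = "COM(O acid) - COM(N base)",
                                     acidic = acidic, basic = basic))
}

#' Helix axis of a single frame
#'
#' The axis is the first principal component of the helix's CA coordinates
#' within the frame (3 x 3 positional covariance), with sign fixed so the
#' axis points from the N- to the C-terminal end. When the first two
#' positional variances are nearly equal the axis direction is ambiguous
#' and a warning is raised.
#'
#' @param structure A \code{\link{Structure}}, or a \code{\link{Trajectory}}
#'   together with \code{frame}.
#' @param helixRange Inclusive residue range of the helix (>= 4 residues).
#' @param frame Frame index when a trajectory is given.
#' @param name Helix name stored in the result.
#' @return A \code{\link{HelixAxis}}.
#' @export
helixAxis <- function(structure, helixRange, frame = NULL, name = "") {
  if (is(structure, "Trajectory")) {
    stopifnot(!is.null(frame))
    xyz <- structure@coords[, , frame]
    top <- topology(structure)
  } else {
    xyz <- coords(structure)
    top <- structure
  }
  idx <- selectCalpha(top, helixRange)
  if (length(idx) < 4) stop("helix must have at least 4 residues")
  P <- xyz[idx, , drop = FALSE]
  Pc <- sweep(P, 2, colMeans(P))
  C3 <- crossprod(Pc) / nrow(Pc)
  e <- eigen(C3, symmetric = TRUE)
  if (e$values[1] > 0 && (e$values[1] - e$values[2]) / e$values[1] < 1e-6)
    warning("ambiguous helix axis: first two positional variances nearly equal")
  ax <- e$vectors[, 1]
  nc <- P[nrow(P), ] - P[1, ]            # N -> C direction
  if (sum(ax * nc) < 0) ax <- -ax
  new("HelixAxis", axis = ax / sqrt(sum(ax^2)), anchor = colMeans(P),
      name = name)
}

#' Angle between two helix axes
#'
#' theta = atan2(||a x b||, a . b) in degrees, the numerically stable
#' equivalent of acos of the dot product; lies in [0, 180). Both axes must
#' come from the same frame (angles are only rotation-invariant within a
#' frame).
#'
#' @param a,b \code{\link{HelixAxis}} objects or unit 3-vectors.
#' @return Angle in degrees.
#' @examples
#' interhelixAngle(c(0, 0, 1), c(1, 0, 0))  # 90
#' @export
interhelixAngle <- function(a, b) {
  va <- if (is(a, "HelixAxis")) axisVector(a) else as.numeric(a)
  vb <- if (is(b, "HelixAxis")) axisVector(b) else as.numeric(b)
  if (sqrt(sum(va^2)) < 1e-12 || sqrt(sum(vb^2)) < 1e-12)
    stop("zero-length axis vector")
  cr <- c(va[2] * vb[3] - va[3] * vb[2],
          va[3] * vb[1] - va[1] * vb[3],
          va[1] * vb[2] - va[2] * vb[1])
  ang <- atan2(sqrt(sum(cr^2)), sum(va * vb)) * 180 / pi
  if (ang >= 180) ang <- 0               # anti-parallel rounding guard
  ang
}

#' Interhelix angle series over a trajectory
#'
#' @param traj A \code{\link{Trajectory}}.
#' @param helixA,helixB Inclusive residue ranges; both axes are computed
#'   from the same frame.
#' @param name Descriptor name.
#' @return A \code{\link{DescriptorSeries}} in degrees.
#' @export
interhelixAngleSeries <- function(traj, helixA, helixB, name = "helix_angle") {
  vals <- vapply(seq_len(nFrames(traj)), function(f)
    interhelixAngle(helixAxis(traj, helixA, frame = f),
                    helixAxis(traj, helixB, frame = f)), numeric(1))
  DescriptorSeries(name, vals, "degrees",
                   provenance = list(definition = "angle between per-frame helix PC1 axes",
                                     helixA = helixA, helixB = helixB))
}

#' Per-residue RMSF and B-factors
#'
#' RMSF_i = <|R_i - <R_i>|^2>^0.5 over the frames; B_i = (8 pi^2 / 3)
#' RMSF_i^2, the crystallographic temperature-factor relation.
#'
#' @param traj An aligned \code{\link{Trajectory}} (>= 2 frames); a warning
#'   is raised when the alignment flag is unset.
#' @param selection CA atom indices (default: all CA atoms).
#' @param context Label stored with the profile ("global" or "domain").
#' @return A \code{\link{FluctuationProfile}}.
#' @export
rmsf <- function(traj, selection = NULL, context = "global") {
  if (nFrames(traj) < 2) stop("need at least 2 frames")
  if (!isAligned(traj))
    warning("trajectory is not flagged as aligned; RMSF includes rigid-body motion")
  top <- topology(traj)
  if (is.null(selection)) selection <- which(atoms(top)$elety == "CA")
  sub <- traj@coords[selection, , , drop = FALSE]
  mu <- apply(sub, c(1, 2), mean)
  msf <- apply((sub - as.vector(mu))^2, 1, sum) / dim(sub)[3]
  r <- sqrt(msf)
  new("FluctuationProfile", resno = atoms(top)$resno[selection],
      rmsf = r, bfactor = (8 * pi^2 / 3) * r^2, context = context)
}

#' Domain-average fluctuation
#'
#' Arithmetic mean of the per-residue RMSF over a domain. Note the average
#' is taken over the fluctuation (Angstrom), not over B.
#'
#' @param profile A \code{\link{FluctuationProfile}}.
#' @param domain Inclusive residue range.
#' @return Mean RMSF in Angstrom.
#' @export
domainAverageBfactor <- function(profile, domain) {
  sel <- profile@resno >= domain[1] & profile@resno <= domain[2]
  if (!any(sel)) stop("empty domain: no profiled residues in range")
  mean(profile@rmsf[sel])
}

#' Coordination-shell radius profile
#'
#' For each residue i, neighbors are the other CA atoms within
#' \code{cutoff}; the shell radius is R_g,i = (sum_j R_ij^2 / n_i)^0.5.
#' The protein average is taken over residues with at least one neighbor;
#' isolated residues are flagged (NaN radius) and excluded. By default the
#' radius is computed per frame and then averaged over frames; set
#' \code{perFrame = FALSE} to compute it on the mean structure instead.
#'
#' @param traj A \code{\link{Trajectory}} or \code{\link{Structure}}.
#' @param selection CA atom indices (default all CA atoms).
#' @param cutoff Neighbor cutoff in Angstrom (default 10).
#' @param perFrame Average per-frame radii (default) or use mean structure.
#' @return A \code{\link{CoordinationShellProfile}}.
#' @export
coordinationShellRadius <- function(traj, selection = NULL, cutoff = 10,
                                    perFrame = TRUE) {
  stopifnot(cutoff > 0)
  top <- if (is(traj, "Structure")) traj else topology(traj)
  if (is.null(selection)) selection <- which(atoms(top)$elety == "CA")
  if (length(selection) < 2) stop("need at least 2 residues")
  resno <- atoms(top)$resno[selection]
  shellOne <- function(xyz) {
    D <- as.matrix(dist(xyz))
    nb <- D <= cutoff & upper.tri(D, diag = FALSE)
    nb <- nb | t(nb)
    n <- rowSums(nb)
    rg <- sqrt(rowSums((D^2) * nb) / n)  # NaN where n = 0
    list(rg = rg, n = n)
  }
  if (is(traj, "Structure")) {
    s <- shellOne(coords(traj)[selection, , drop = FALSE])
    rg <- s$rg; nn <- s$n
  } else if (perFrame) {
    T <- nFrames(traj)
    rgSum <- numeric(length(selection)); rgCnt <- numeric(length(selection))
    nnSum <- numeric(length(selection))
    for (f in seq_len(T)) {
      s <- shellOne(traj@coords[selection, , f])
      ok <- s$n > 0
      rgSum[ok] <- rgSum[ok] + s$rg[ok]
      rgCnt[ok] <- rgCnt[ok] + 1
      nnSum <- nnSum + s$n
    }
    rg <- ifelse(rgCnt > 0, rgSum / rgCnt, NaN)
    nn <- nnSum / T
  } else {
    mu <- apply(traj@coords[selection, , , drop = FALSE], c(1, 2), mean)
    s <- shellOne(mu)
    rg <- s$rg; nn <- s$n
  }
  new("CoordinationShellProfile", resno = as.integer(resno), radius = rg,
      nNeighbors = nn, average = mean(rg[is.finite(rg)]), cutoff = cutoff)
}
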