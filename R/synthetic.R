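# Synthetic two-domain trajectory generator. The toy protein is a CA-only
# chain (globular domain 1, extended linker, ideal-helix bundle domain 2)
# with proxy side-chain atoms for salt-bridge descriptors. Frames switch
# between an extended and a compact basin via a per-frame two-state Markov
# chain; positional noise is iid isotropic Gaussian, so every downstream
# estimator's sampling error is analytic.

# Proxy side-chain geometry (fixed so center-of-mass distances are closed
# form): acid = two O atoms at +-1.2 A about a virtual centroid 2.5 A off
# the CA along +y; base = one N atom 3.5 A off the CA along +y.
.proxyAcidOffset <- 2.5
.proxyAcidSplit <- 1.2
.proxyBaseOffset <- 3.5

#' Build the two-domain toy protein of a synthetic specification
#'
#' Domain 1 is a compact cluster of CA atoms on a 3.8-Angstrom cubic
#' lattice; the linker is an extended strand (3.5 Angstrom rise); domain 2
#' is a bundle of ideal alpha-helices (rise 1.5 Angstrom/residue, 100
#' degrees/residue, radius 2.3 Angstrom, antiparallel, 10 Angstrom apart).
#' Designated linker residues carry two proxy acidic oxygens and designated
#' domain-2 residues one proxy basic nitrogen. Domain 2 is placed so the
#' interdomain CA centroid distance equals \code{extendedDistance} exactly.
#' The construction is deterministic.
#'
#' @param spec A \code{\link{SyntheticSpec}}.
#' @return A \code{\link{Structure}} (the extended-basin reference).
#' @export
buildToyProtein <- function(spec) {
  validObject(spec)
  n1 <- as.integer(spec@nResDomain1)
  nl <- as.integer(spec@nResLinker)
  n2 <- as.integer(spec@nResDomain2)
  if (n1 < 1 || n2 < 1) stop("zero-length domain in spec")

  # domain 1: cubic lattice, centered at the origin
  k <- ceiling(n1^(1 / 3))
  g <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))
  d1 <- as.matrix(g[seq_len(n1), ]) * 3.8
  d1 <- sweep(d1, 2, colMeans(d1))

  # linker: extended strand along +x from the domain-1 edge
  x0 <- max(d1[, 1])
  lk <- if (nl > 0) cbind(x0 + 3.5 * seq_len(nl), 0, 0) else
    matrix(0, 0, 3)

  # domain 2: antiparallel ideal-helix bundle, axes along z
  nh <- max(1L, as.integer(spec@nHelices))
  per <- diff(round(seq(0, n2, length.out = nh + 1)))
  helixList <- vector("list", nh)
  xD2 <- x0 + 3.5 * (nl + 1) + 10
  for (h in seq_len(nh)) {
    m <- per[h]
    t <- seq_len(m) - 1
    theta <- t * 100 * pi / 180
    pts <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * t)
    # antiparallel packing: rotate every other helix 180 deg about x,
    # which preserves helical chirality
    if (h %% 2 == 0) pts <- pts %*% diag(c(1, -1, -1))
    pts[, 3] <- pts[, 3] - mean(pts[, 3])
    helixList[[h]] <- cbind(xD2 + pts[, 1], (h - 1) * 10 + pts[, 2],
                            pts[, 3])
  }
  d2 <- do.call(rbind, helixList)
  d2 <- sweep(d2, 2, c(0, mean(d2[, 2]), 0))  # center bundle on y = 0

  ca <- rbind(d1, lk, d2)
  nres <- nrow(ca)
  acidRes <- if (nl > 0) n1 + 1 + spec@acidLinkerOffsets else integer()
  acidRes <- acidRes[acidRes >= n1 + 1 & acidRes <= n1 + nl]
  baseRes <- n1 + nl + 1 + spec@baseDomain2Offsets
  baseRes <- baseRes[baseRes <= nres]

  rows <- vector("list", nres)
  xyzs <- vector("list", nres)
  u <- c(0, 1, 0); v <- c(0, 0, 1)
  for (r in seq_len(nres)) {
    resid <- if (r %in% acidRes) "GLU" else if (r %in% baseRes) "LYS" else "ALA"
    elety <- "CA"; elem <- "C"; xyz <- ca[r, , drop = FALSE]
    if (r %in% acidRes) {
      c0 <- ca[r, ] + .proxyAcidOffset * u
      xyz <- rbind(xyz, c0 + .proxyAcidSplit * v, c0 - .proxyAcidSplit * v)
      elety <- c(elety, "OE1", "OE2"); elem <- c(elem, "O", "O")
    } else if (r %in% baseRes) {
      xyz <- rbind(xyz, ca[r, ] + .proxyBaseOffset * u)
      elety <- c(elety, "NZ"); elem <- c(elem, "N")
    }
    rows[[r]] <- data.frame(elety = elety, resno = r, resid = resid,
                            chain = "A", elem = elem,
                            stringsAsFactors = FALSE)
    xyzs[[r]] <- xyz
  }
  s <- Structure(do.call(rbind, rows), do.call(rbind, xyzs))
  makeBasin(s, spec@extendedDistance, domainRanges(spec)$domain1,
            domainRanges(spec)$domain2, domainRanges(spec)$linker)
}

#' Residue ranges implied by a synthetic specification
#'
#' @param spec A \code{\link{SyntheticSpec}}.
#' @return List with inclusive ranges \code{domain1}, \code{linker},
#'   \code{domain2} (linker is NULL when absent).
#' @export
domainRanges <- function(spec) {
  n1 <- spec@nResDomain1; nl <- spec@nResLinker; n2 <- spec@nResDomain2
  list(domain1 = c(1, n1),
       linker = if (nl > 0) c(n1 + 1, n1 + nl) else NULL,
       domain2 = c(n1 + nl + 1, n1 + nl + n2))
}

#' Helix residue ranges of the synthetic toy protein
#'
#' @param spec A \code{\link{SyntheticSpec}}.
#' @return Named list of inclusive residue ranges, one per helix.
#' @export
syntheticHelices <- function(spec) {
  nh <- max(1L, as.integer(spec@nHelices))
  per <- diff(round(seq(0, spec@nResDomain2, length.out = nh + 1)))
  start <- spec@nResDomain1 + spec@nResLinker + cumsum(c(1, per[-nh]))
  stats::setNames(lapply(seq_len(nh), function(h)
    c(start[h], start[h] + per[h] - 1)),
    paste0("H", seq_len(nh)))
}

#' Set the interdomain centroid distance of a two-domain structure
#'
#' Rigidly translates all atoms of domain 2 along the domain centroid axis
#' so that the CA centroid distance equals \code{targetDistance}; linker CA
#' atoms are then re-laid by linear interpolation between their anchors
#' (the last domain-1 CA and the first domain-2 CA), with proxy side-chain
#' atoms keeping their offsets. Domain 1 is untouched.
#'
#' @param reference A \code{\link{Structure}}.
#' @param targetDistance Target centroid distance in Angstrom (> 0).
#' @param domain1,domain2 Inclusive residue ranges of the two domains.
#' @param linker Inclusive linker residue range, or NULL.
#' @return A \code{\link{Structure}} at the requested separation.
#' @export
makeBasin <- function(reference, targetDistance, domain1, domain2,
                      linker = NULL) {
  stopifnot(targetDistance > 0)
  a <- atoms(reference)
  xyz <- coords(reference)
  ca1 <- selectCalpha(reference, domain1)
  ca2 <- selectCalpha(reference, domain2)
  c1 <- .centroid(xyz[ca1, , drop = FALSE])
  c2 <- .centroid(xyz[ca2, , drop = FALSE])
  sep <- c2 - c1
  d0 <- sqrt(sum(sep^2))
  if (d0 < 1e-9) stop("coincident domain centroids: translation axis undefined")
  axis <- sep / d0
  inD2 <- a$resno >= domain2[1] & a$resno <= domain2[2]
  xyz[inD2, ] <- sweep(xyz[inD2, , drop = FALSE], 2,
                       (targetDistance - d0) * axis, `+`)
  if (!is.null(linker) && linker[2] >= linker[1]) {
    a1 <- xyz[ca1[length(ca1)], ]
    a2 <- xyz[which(inD2 & a$elety == "CA")[1], ]
    L <- linker[2] - linker[1] + 1
    for (i in seq_len(L)) {
      res <- linker[1] + i - 1
      inRes <- which(a$resno == res)
      caIdx <- inRes[a$elety[inRes] == "CA"]
      newCA <- a1 + (a2 - a1) * i / (L + 1)
      shift <- newCA - xyz[caIdx, ]
      xyz[inRes, ] <- sweep(xyz[inRes, , drop = FALSE], 2, shift, `+`)
    }
  }
  Structure(a, xyz)
}

#' Stationary compact fraction of the generator's Markov chain
#'
#' @param spec A \code{\link{SyntheticSpec}}.
#' @return pEC / (pEC + pCE); NA when both probabilities are zero.
#' @export
stationaryCompactFraction <- function(spec) {
  s <- spec@pEC + spec@pCE
  if (s == 0) return(NA_real_)
  spec@pEC / s
}

#' Generate a synthetic two-state trajectory with ground truth
#'
#' Per-frame basin labels follow a two-state Markov chain (initial state
#' drawn from the stationary distribution unless fixed); frame coordinates
#' are the labeled basin reference plus iid isotropic Gaussian noise
#' (\code{noiseSigma}; linker atoms get \code{noiseSigma *
#' linkerNoiseScale}). Fully reproducible given \code{spec@seed}.
#'
#' @param spec A \code{\link{SyntheticSpec}}.
#' @param initialState "stationary" (default), "extended" or "compact".
#' @return List with elements \code{trajectory} (a
#'   \code{\link{Trajectory}}, 50 ps frame interval) and \code{truth}
#'   (a \code{\link{GroundTruth}}).
#' @examples
#' spec <- SyntheticSpec(nResDomain1 = 20, nResDomain2 = 20, nResLinker = 4,
#'                       nFrames = 200, seed = 7)
#' run <- generateTwoStateTrajectory(spec)
#' occupancy(run$truth)
#' @export
generateTwoStateTrajectory <- function(spec,
                                       initialState = c("stationary",
                                                        "extended",
                                                        "compact")) {
  validObject(spec)
  initialState <- match.arg(initialState)
  rg <- domainRanges(spec)
  refE <- buildToyProtein(spec)
  refC <- makeBasin(refE, spec@compactDistance, rg$domain1, rg$domain2,
                    rg$linker)
  if (spec@pEC + spec@pCE == 0 && initialState == "stationary")
    stop("both switch probabilities are zero and no initial label was given")

  n <- as.integer(spec@nFrames)
  natoms <- nAtoms(refE)
  a <- atoms(refE)
  sigma <- rep(spec@noiseSigma, natoms)
  if (!is.null(rg$linker)) {
    inLinker <- a$resno >= rg$linker[1] & a$resno <= rg$linker[2]
    sigma[inLinker] <- spec@noiseSigma * spec@linkerNoiseScale
  }

  out <- .withSeed(spec@seed, {
    piC <- stationaryCompactFraction(spec)
    state <- integer(n)  # 1 = extended, 2 = compact
    state[1] <- switch(initialState,
                       stationary = if (runif(1) < piC) 2L else 1L,
                       extended = 1L, compact = 2L)
    if (n > 1) {
      u <- runif(n - 1)
      for (t in 2:n) {
        p <- if (state[t - 1] == 1L) spec@pEC else 1 - spec@pCE
        state[t] <- if (u[t - 1] < p) 2L else 1L
      }
    }
    refs <- array(c(coords(refE), coords(refC)), dim = c(natoms, 3, 2))
    coordsArr <- refs[, , state, drop = FALSE]
    dim(coordsArr) <- c(natoms, 3, n)
    if (spec@noiseSigma > 0)
      coordsArr <- coordsArr + array(rnorm(natoms * 3 * n) * sigma,
                                     dim = c(natoms, 3, n))
    list(state = state, coordsArr = coordsArr)
  })

  labels <- c("extended", "compact")[out$state]
  occ <- c(extended = mean(out$state == 1L), compact = mean(out$state == 2L))
  traj <- Trajectory(refE, out$coordsArr, frameInterval = 50,
                     productionLength = n * 50 / 1000)
  truth <- GroundTruth(labels, occ,
                       list(extended = refE, compact = refC))
  list(trajectory = traj, truth = truth)
}

#' Write ground-truth labels to TSV
#'
#' @param truth A \code{\link{GroundTruth}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  .writeTSV(data.frame(frame = seq_along(truth@labels), label = truth@labels),
            path,
            meta = list(occupancy_extended = truth@occupancy["extended"],
                        occupancy_compact = truth@occupancy["compact"]))
}
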