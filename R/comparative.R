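# Cross-system comparisons: trajectory-averaged CA-CA distance matrices
# and distance-change maps, normalized dynamic cross-correlation matrices
# and anticorrelation-difference maps, and per-domain-aligned intradomain
# correlation/fluctuation analysis.

#' Trajectory-averaged CA-CA distance matrix
#'
#' d_ij = (1/T) sum_t |r_i(t) - r_j(t)|. Distances are invariant under
#' rigid motion, so no alignment is required.
#'
#' @param traj A \code{\link{Trajectory}}.
#' @param selection CA atom indices (default all CA atoms).
#' @return A \code{\link{MeanDistanceMatrix}}.
#' @export
meanDistanceMatrix <- function(traj, selection = NULL) {
  top <- topology(traj)
  if (is.null(selection)) selection <- which(atoms(top)$elety == "CA")
  if (!length(selection)) stop("empty selection")
  T <- nFrames(traj)
  n <- length(selection)
  acc <- matrix(0, n, n)
  for (f in seq_len(T))
    acc <- acc + as.matrix(dist(traj@coords[selection, , f]))
  M <- acc / T
  M <- (M + t(M)) / 2
  diag(M) <- 0
  new("MeanDistanceMatrix", resno = as.integer(atoms(top)$resno[selection]),
      matrix = M)
}

#' Residue-pair distance-change map between two systems
#'
#' Delta_ij = d_ij(mutant) - d_ij(wildtype). Pairs are classified
#' "decrease" when Delta lies in [-window2, -window1] and "increase" when
#' in [window1, window2] (both ends inclusive); everything else is
#' "unclassified". With \code{mode = "saturating"} the outer bound is read
#' as a saturation limit and |Delta| > window2 falls into the same class.
#'
#' @param mutant,wildtype \code{\link{MeanDistanceMatrix}} objects over the
#'   same residue list.
#' @param windows \code{c(inner, outer)} window in Angstrom (default
#'   \code{c(4, 10)}).
#' @param mode "strict" (default) or "saturating".
#' @return A \code{\link{DifferenceMap}} of kind "distance_change".
#' @export
distanceChangeMap <- function(mutant, wildtype, windows = c(4, 10),
                              mode = c("strict", "saturating")) {
  mode <- match.arg(mode)
  if (!identical(mutant@resno, wildtype@resno))
    stop("residue lists differ between the two systems")
  delta <- mutant@matrix - wildtype@matrix
  hi <- if (mode == "strict") windows[2] else Inf
  cls <- matrix("unclassified", nrow(delta), ncol(delta))
  cls[delta <= -windows[1] & delta >= -hi] <- "decrease"
  cls[delta >= windows[1] & delta <= hi] <- "increase"
  diag(cls) <- "unclassified"
  new("DifferenceMap", resno = mutant@resno, delta = delta, classification = cls,
      thresholds = list(windows = windows, mode = mode),
      kind = "distance_change")
}

#' Normalized dynamic cross-correlation matrix
#'
#' c_ij = <dR_i . dR_j> / (<dR_i^2> <dR_j^2>)^0.5 computed from the 3 x 3
#' residue blocks of the positional covariance: the numerator is the block
#' trace, the denominator the product of per-residue RMSFs. Residues with
#' zero variance get undefined (NA) rows/columns and are flagged.
#'
#' @param model A \code{\link{CovarianceModel}} (decomposition not
#'   required).
#' @param resno Residue numbers of the selection (default: 1-based index).
#' @param context Alignment context label stored with the matrix.
#' @return A \code{\link{CorrelationMatrix}}.
#' @export
correlationMatrix <- function(model, resno = NULL, context = "global") {
  C <- model@matrix
  n <- nrow(C) / 3
  ii <- 3 * (seq_len(n) - 1)
  tr <- matrix(0, n, n)
  for (k in 1:3) tr <- tr + C[ii + k, ii + k]   # block traces
  msf <- diag(tr)
  bad <- which(msf <= 0)
  denom <- sqrt(outer(msf, msf))
  M <- tr / denom
  M[bad, ] <- NA_real_; M[, bad] <- NA_real_
  d <- diag(M); d[setdiff(seq_len(n), bad)] <- 1; diag(M) <- d
  M <- pmin(pmax(M, -1), 1)
  if (is.null(resno)) resno <- seq_len(n)
  new("CorrelationMatrix", resno = as.integer(resno), matrix = M,
      context = context, undefined = as.integer(bad))
}

#' Anticorrelation-difference map between two systems
#'
#' Considers only residue pairs anticorrelated (c < -threshold) in at least
#' one system. A pair is "less_anticorrelated" when c_mut - c_wt exceeds
#' +margin and "more_anticorrelated" when below -margin; other eligible
#' pairs are "unclassified", ineligible pairs "excluded".
#'
#' @param wt,mut \code{\link{CorrelationMatrix}} objects over the same
#'   residue list.
#' @param threshold Anticorrelation threshold (default 0.1).
#' @param margin Significance margin on the change (default 0.05).
#' @return A \code{\link{DifferenceMap}} of kind
#'   "anticorrelation_difference".
#' @export
anticorrelationDifferenceMap <- function(wt, mut, threshold = 0.1,
                                         margin = 0.05) {
  if (!identical(wt@resno, mut@resno))
    stop("residue lists differ between the two systems")
  delta <- mut@matrix - wt@matrix
  elig <- (wt@matrix < -threshold) | (mut@matrix < -threshold)
  elig[is.na(elig)] <- FALSE
  cls <- matrix("excluded", nrow(delta), ncol(delta))
  cls[elig] <- "unclassified"
  cls[elig & delta > margin] <- "less_anticorrelated"
  cls[elig & delta < -margin] <- "more_anticorrelated"
  diag(cls) <- "excluded"
  new("DifferenceMap", resno = wt@resno, delta = delta, classification = cls,
      thresholds = list(threshold = threshold, margin = margin),
      kind = "anticorrelation_difference")
}

#' Per-domain-aligned intradomain correlation and fluctuation analysis
#'
#' Aligns every frame on the domain's CA atoms only, then computes the
#' domain's covariance, its normalized correlation matrix and the
#' RMSF/B-factor profile from the covariance diagonal. Rigid-body motion
#' of the domain is removed, isolating internal dynamics.
#'
#' @param traj A \code{\link{Trajectory}}.
#' @param domain Inclusive residue range.
#' @param reference A \code{\link{Structure}} to align onto.
#' @return List with \code{correlation} (a \code{\link{CorrelationMatrix}},
#'   context "domain"), \code{fluctuations} (a
#'   \code{\link{FluctuationProfile}}) and \code{aligned} (the
#'   domain-aligned \code{\link{Trajectory}}).
#' @export
intradomainAnalysis <- function(traj, domain, reference) {
  sel <- selectCalpha(topology(traj), domain)
  aligned <- alignTrajectory(traj, reference, sel)
  model <- computeCovariance(aligned, sel)
  resno <- atoms(topology(traj))$resno[sel]
  corr <- correlationMatrix(model, resno = resno, context = "domain")
  msf <- diag(model@matrix)
  msfRes <- msf[3 * (seq_along(sel) - 1) + 1] +
    msf[3 * (seq_along(sel) - 1) + 2] + msf[3 * (seq_along(sel) - 1) + 3]
  r <- sqrt(msfRes)
  prof <- new("FluctuationProfile", resno = as.integer(resno), rmsf = r,
              bfactor = (8 * pi^2 / 3) * r^2, context = "domain")
  list(correlation = corr, fluctuations = prof, aligned = aligned)
}
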