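# Essential dynamics: positional covariance of the aligned CA configuration
# vectors, its eigendecomposition into principal components, projections of
# frames onto PCs, and Boltzmann-inversion free-energy surfaces.

## Frames-by-3N configuration matrix of a selection.
.configMatrix <- function(traj, selection) {
  sub <- traj@coords[selection, , , drop = FALSE]  # n x 3 x T
  n <- length(selection); T <- dim(sub)[3]
  # rows = frames, columns = (x1, y1, z1, x2, ...)
  t(matrix(aperm(sub, c(2, 1, 3)), nrow = 3 * n, ncol = T))
}

#' Positional covariance of an aligned trajectory
#'
#' Builds the 3N x 3N population covariance (divide by the number of
#' frames, matching the ensemble average) of the configuration vectors of
#' the selected atoms, C = <(R - <R>)(R - <R>)^T>, and stores the mean
#' configuration.
#'
#' @param traj An aligned \code{\link{Trajectory}} (>= 2 frames). A warning
#'   is issued if the trajectory has not been aligned.
#' @param selection Atom indices defining the configuration vector.
#' @return A \code{\link{CovarianceModel}} (components empty until
#'   \code{\link{eigenDecompose}}).
#' @export
computeCovariance <- function(traj, selection) {
  if (nFrames(traj) < 2) stop("need at least 2 frames")
  if (!isAligned(traj))
    warning("trajectory is not flagged as aligned; covariance mixes rigid-body and internal motion")
  X <- .configMatrix(traj, selection)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nrow(Xc)          # population (1/n) covariance
  C <- (C + t(C)) / 2
  new("CovarianceModel", selection = as.integer(selection), mean = mu,
      matrix = C, components = matrix(0, nrow(C), 0), variances = numeric())
}

#' Eigendecomposition of a covariance model
#'
#' Decomposes C into descending-variance orthonormal principal components.
#' Eigenvalues more negative than -1e-8 x trace(C) are an error; small
#' negative values (numerical noise) are clamped to zero. Each component's
#' sign is fixed so its largest-magnitude entry is positive, making
#' projections reproducible.
#'
#' @param model A \code{\link{CovarianceModel}}.
#' @return The model with \code{components} and \code{variances} filled.
#' @export
eigenDecompose <- function(model) {
  C <- model@matrix
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("covariance matrix is not symmetric")
  e <- eigen(C, symmetric = TRUE)        # eigenvalues already descending
  tr <- sum(diag(C))
  if (any(e$values < -1e-8 * max(tr, 1)))
    stop("covariance has significantly negative eigenvalues")
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (i in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, i]))
    if (vecs[j, i] < 0) vecs[, i] <- -vecs[, i]
  }
  initialize(model, components = vecs, variances = vals)
}

#' Project trajectory frames onto principal components
#'
#' score_i(t) = p_i . (R(t) - <R>), in Angstrom. The trajectory must be
#' aligned to the same reference with the same selection as the model.
#'
#' @param traj An aligned \code{\link{Trajectory}}.
#' @param model A decomposed \code{\link{CovarianceModel}}.
#' @param pcs Integer PC indices (default 1:2).
#' @return Frames x length(pcs) matrix of scores; column names "PC1", ...
#' @export
projectFrames <- function(traj, model, pcs = 1:2) {
  if (!ncol(model@components)) stop("model has no components; run eigenDecompose first")
  if (max(pcs) > ncol(model@components)) stop("PC index out of range")
  X <- .configMatrix(traj, model@selection)
  if (ncol(X) != length(model@mean))
    stop("selection mismatch between trajectory and model")
  S <- sweep(X, 2, model@mean) %*% model@components[, pcs, drop = FALSE]
  colnames(S) <- paste0("PC", pcs)
  S
}

#' Boltzmann-inversion free-energy surface of PC scores
#'
#' Histograms the scores (one or two PCs), normalizes the density and sets
#' A = -kT ln f, shifted so the minimum finite energy is zero. Empty bins
#' have infinite energy (never capped).
#'
#' @param scores Numeric vector (1-D) or 2-column matrix (2-D) of PC scores.
#' @param bins Number of bins per axis (default 50).
#' @param kT Thermal energy in kcal/mol (see \code{\link{thermalEnergy}}).
#' @param pcIndices PC indices the axes refer to (metadata).
#' @return A \code{\link{FreeEnergySurface}}.
#' @examples
#' s <- rnorm(5000)
#' fes <- freeEnergySurface(s, bins = 40, kT = thermalEnergy(310))
#' min(energyValues(fes))  # 0
#' @export
freeEnergySurface <- function(scores, bins = 50, kT, pcIndices = NULL) {
  stopifnot(kT > 0, bins >= 1)
  scores <- if (is.null(dim(scores))) matrix(scores, ncol = 1) else
    as.matrix(scores)
  if (!nrow(scores)) stop("no scores given")
  ndim <- ncol(scores)
  if (!ndim %in% 1:2) stop("scores must be 1- or 2-dimensional")
  if (is.null(pcIndices)) pcIndices <- seq_len(ndim)
  bins <- as.integer(rep_len(bins, ndim))
  edges <- lapply(seq_len(ndim), function(k) {
    r <- range(scores[, k])
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)   # all-identical scores
    seq(r[1], r[2], length.out = bins[k] + 1)
  })
  idx <- vapply(seq_len(ndim), function(k) {
    i <- findInterval(scores[, k], edges[[k]], rightmost.closed = TRUE)
    pmin(pmax(i, 1L), bins[k])
  }, integer(nrow(scores)))
  idx <- matrix(idx, ncol = ndim)
  counts <- array(0, dim = bins)
  tt <- table(factor(idx[, 1], levels = seq_len(bins[1])),
              if (ndim == 2) factor(idx[, 2], levels = seq_len(bins[2])) else
                factor(rep(1, nrow(idx))))
  counts[] <- as.numeric(tt)
  binVol <- prod(vapply(edges, function(e) diff(e[1:2]), numeric(1)))
  f <- counts / (nrow(scores) * binVol)
  A <- -kT * log(f)
  A <- A - min(A[is.finite(A)])
  new("FreeEnergySurface", pcIndices = as.integer(pcIndices), edges = edges,
      density = f, energy = A, kT = kT)
}
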