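# Kabsch least-squares rigid superposition and trajectory alignment.
# Alignment is single-pass onto a fixed reference (the crystal structure),
# not iterative mean-alignment.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' selected atoms, and applies the transformation to all atoms of
#' \code{mobile}.
#'
#' @param mobile n x 3 coordinate matrix to transform.
#' @param reference n x 3 coordinate matrix (same atom order).
#' @param selection Atom indices used to fit the transformation (default:
#'   all atoms). At least 3 non-collinear atoms are required.
#' @return List with \code{rotation} (3 x 3, det = +1), \code{translation}
#'   (length-3), \code{coords} (all atoms transformed, i.e.
#'   \code{mobile \%*\% rotation} then shifted) and \code{rmsd} (Angstrom,
#'   over the selection).
#' @examples
#' ref <- matrix(rnorm(30), 10, 3)
#' th <- pi / 3
#' Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
#' fit <- kabschSuperpose(ref %*% Rz + 5, ref)
#' fit$rmsd  # ~0
#' @export
kabschSuperpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3) stop("need at least 3 selection atoms")
  M <- mobile[selection, , drop = FALSE]
  R <- reference[selection, , drop = FALSE]
  cm <- colMeans(M); cr <- colMeans(R)
  M0 <- sweep(M, 2, cm); R0 <- sweep(R, 2, cr)
  sv <- svd(crossprod(M0, R0))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear) selection: superposition is not unique")
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  rot <- sv$u %*% D %*% t(sv$v)        # applied as x %*% rot
  trans <- cr - as.vector(cm %*% rot)
  out <- sweep(mobile %*% rot, 2, trans, `+`)
  rmsd <- sqrt(mean(rowSums((out[selection, , drop = FALSE] - R)^2)))
  list(rotation = rot, translation = trans, coords = out, rmsd = rmsd)
}

#' Align every trajectory frame onto a fixed reference
#'
#' Each frame is superposed onto \code{reference} using the selection atoms
#' (single-pass, never onto an iterated mean).
#'
#' @param traj A \code{\link{Trajectory}}.
#' @param reference A \code{\link{Structure}} (or n x 3 matrix) with the
#'   same atom table as the trajectory.
#' @param selection Atom indices used for the fit (e.g. from
#'   \code{\link{selectCalpha}}); default all atoms.
#' @return An aligned \code{\link{Trajectory}} (flag set).
#' @export
alignTrajectory <- function(traj, reference, selection = NULL) {
  refxyz <- if (is(reference, "Structure")) coords(reference) else
    as.matrix(reference)
  if (nrow(refxyz) != nAtoms(traj))
    stop(sprintf("reference has %d atoms, trajectory has %d",
                 nrow(refxyz), nAtoms(traj)))
  out <- traj@coords
  for (f in seq_len(nFrames(traj))) {
    fit <- tryCatch(
      kabschSuperpose(out[, , f], refxyz, selection),
      error = function(e) stop(sprintf("frame %d: %s", f, conditionMessage(e)),
                               call. = FALSE))
    out[, , f] <- fit$coords
  }
  Trajectory(traj@topology, out, traj@frameInterval, traj@productionLength,
             aligned = TRUE)
}

#' Selection RMSD of each frame to a reference
#'
#' @param traj A \code{\link{Trajectory}}.
#' @param reference \code{\link{Structure}} or n x 3 matrix.
#' @param selection Atom indices (default all).
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
frameRMSD <- function(traj, reference, selection = NULL) {
  refxyz <- if (is(reference, "Structure")) coords(reference) else
    as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nAtoms(traj))
  R <- refxyz[selection, , drop = FALSE]
  vapply(seq_len(nFrames(traj)), function(f) {
    M <- traj@coords[selection, , f]
    sqrt(mean(rowSums((M - R)^2)))
  }, numeric(1))
}
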