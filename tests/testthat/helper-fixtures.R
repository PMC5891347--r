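# Fixtures built in code: small synthetic specs, random trajectories and
# ad-hoc structures used across the suite.

smallSpec <- function(nFrames = 500, seed = 11, ...) {
  args <- utils::modifyList(
    list(nResDomain1 = 30, nResDomain2 = 30, nResLinker = 6,
         nFrames = nFrames, seed = seed), list(...))
  do.call(SyntheticSpec, args)
}

# CA-only structure with one atom per residue at given coordinates
caStructure <- function(xyz, resno = seq_len(nrow(xyz))) {
  Structure(data.frame(elety = "CA", resno = resno, resid = "ALA",
                       chain = "A", elem = "C", stringsAsFactors = FALSE),
            xyz)
}

# trajectory of iid Gaussian coordinates around a base structure
randomTrajectory <- function(natoms = 10, nframes = 20, seed = 1, sd = 1,
                             aligned = TRUE) {
  set.seed(seed)
  base <- matrix(rnorm(natoms * 3, sd = 10), natoms, 3)
  coords <- array(rep(base, nframes) + rnorm(natoms * 3 * nframes, sd = sd),
                  dim = c(natoms, 3, nframes))
  Trajectory(caStructure(base), coords, aligned = aligned)
}

randomRotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr.Q(qr(M)) * sign(det(qr.Q(qr(M))))
}

# proper random rotation via QR with det fixed
properRotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# ideal alpha-helix CA coordinates along +z (same parametrization a text
# book would give: radius 2.3 A, rise 1.5 A/residue, 100 deg/residue)
idealHelix <- function(n, radius = 2.3, rise = 1.5, twist = 100) {
  t <- seq_len(n) - 1
  th <- t * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), t * rise)
}

writeLinesTo <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

pdbAtomLine <- function(serial, name, resid, resno, x, y, z,
                        record = "ATOM", elem = substr(name, 1, 1)) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, nm, resid, resno, x, y, z, elem)
}
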