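# Geometric descriptors: distances, helix axes/angles, fluctuations,
# coordination shells.

test_that("interdomainDistance equals the explicit centroid computation", {
  two <- caStructure(rbind(c(0, 0, 0), c(0, 0, 10)), resno = 1:2)
  expect_equal(interdomainDistance(two, c(1, 1), c(2, 2)), 10)

  set.seed(12)
  xyz <- matrix(rnorm(100 * 3, sd = 8), 100, 3)
  s <- caStructure(xyz)
  d <- interdomainDistance(s, c(1, 50), c(51, 100))
  oracle <- sqrt(sum((colMeans(xyz[1:50, ]) - colMeans(xyz[51:100, ]))^2))
  expect_equal(d, oracle, tolerance = 1e-10)

  # invariance under global rigid transforms
  for (i in 1:5) {
    moved <- caStructure(sweep(xyz %*% properRotation(), 2,
                               rnorm(3, sd = 20), `+`))
    expect_equal(interdomainDistance(moved, c(1, 50), c(51, 100)), d,
                 tolerance = 1e-9)
  }

  expect_error(interdomainDistance(s, c(200, 210), c(51, 100)), "no residues")
})

test_that("saltBridgeDistance uses side-chain O/N centers of mass", {
  mk <- function(xyzO, xyzN) {
    nO <- nrow(xyzO)
    Structure(data.frame(
      elety = c("CA", rep(c("OE1", "OE2"), length.out = nO), "CA", "NZ"),
      resno = c(rep(1L, nO + 1), 2L, 2L),
      resid = c(rep("GLU", nO + 1), "LYS", "LYS"),
      chain = "A", elem = c("C", rep("O", nO), "C", "N")),
      rbind(c(0, 0, -5), xyzO, c(5, 5, 5), xyzN))
  }
  s1 <- mk(matrix(c(0, 0, 0), 1, 3), matrix(c(3, 4, 0), 1, 3))
  expect_equal(saltBridgeDistance(s1, 1, 2), 5)

  s2 <- mk(rbind(c(1, 0, 0), c(-1, 0, 0)), matrix(c(0, 0, 3), 1, 3))
  expect_equal(saltBridgeDistance(s2, 1, 2), 3)

  expect_error(saltBridgeDistance(s1, 2, 2), "oxygens")
  expect_error(saltBridgeDistance(s1, 1, 1), "nitrogens")

  # synthetic proxy geometry: COM distance is the closed form
  # |(CA_acid + 2.5 y) - (CA_base + 3.5 y)| from the placement rules
  spec <- smallSpec()
  s <- buildToyProtein(spec)
  a <- atoms(s)
  acid <- unique(a$resno[a$elety == "OE1"])[1]
  base <- unique(a$resno[a$elety == "NZ"])[1]
  caA <- coords(s)[a$resno == acid & a$elety == "CA", ]
  caB <- coords(s)[a$resno == base & a$elety == "CA", ]
  expected <- sqrt(sum(((caA + c(0, 2.5, 0)) - (caB + c(0, 3.5, 0)))^2))
  expect_equal(saltBridgeDistance(s, acid, base), expected, tolerance = 1e-10)
})

test_that("helixAxis is the frame's dominant positional direction, N->C", {
  # finite helices tilt PC1 slightly off the true axis (the z-to-phase
  # cross moment decays with length); 30 residues is comfortably < 1 deg
  h <- caStructure(idealHelix(30))
  ax <- helixAxis(h, c(1, 30))
  expect_lt(interhelixAngle(axisVector(ax), c(0, 0, 1)), 1)

  # reversing the residue order flips the geometric PC1, but the N->C
  # convention flips it back
  rev30 <- caStructure(idealHelix(30)[30:1, ])
  axRev <- helixAxis(rev30, c(1, 30))
  expect_lt(interhelixAngle(axisVector(axRev), -axisVector(ax)), 1)

  # bent helix: axis equals the dominant eigenvector of the 3x3 moment
  # matrix computed by an explicit power-iteration oracle
  bent <- idealHelix(20)
  bent[11:20, ] <- bent[11:20, ] %*% matrix(
    c(cos(0.4), 0, -sin(0.4), 0, 1, 0, sin(0.4), 0, cos(0.4)), 3, 3)
  sB <- caStructure(bent)
  axB <- axisVector(helixAxis(sB, c(1, 20)))
  P <- sweep(bent, 2, colMeans(bent))
  M3 <- crossprod(P) / nrow(P)
  v <- c(1, 1, 1)
  for (i in 1:500) { v <- M3 %*% v; v <- v / sqrt(sum(v^2)) }
  expect_equal(abs(sum(axB * v)), 1, tolerance = 1e-8)

  expect_error(helixAxis(h, c(1, 3)), "4 residues")
})

test_that("interhelixAngle matches the arccos oracle and its invariants", {
  expect_equal(interhelixAngle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(interhelixAngle(c(0, 0, 1), c(1, 0, 0)), 90)
  expect_error(interhelixAngle(c(0, 0, 0), c(1, 0, 0)), "zero")

  set.seed(13)
  for (i in 1:50) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    b <- rnorm(3); b <- b / sqrt(sum(b^2))
    th <- interhelixAngle(a, b)
    oracle <- acos(max(-1, min(1, sum(a * b)))) * 180 / pi
    expect_equal(th, oracle, tolerance = 1e-9)
    expect_equal(th, interhelixAngle(b, a))
    expect_true(th >= 0 && th < 180)
  }
})

test_that("rmsf and B-factors satisfy the temperature-factor relation", {
  base <- matrix(rnorm(18), 6, 3)
  d <- 0.8
  arr <- array(rep(base, 2), c(6, 3, 2))
  arr[3, 1, ] <- base[3, 1] + c(d, -d)
  traj <- Trajectory(caStructure(base), arr, aligned = TRUE)
  prof <- rmsf(traj)
  expect_equal(unname(rmsfValues(prof)[3]), d, tolerance = 1e-12)
  expect_equal(unname(rmsfValues(prof)[-3]), rep(0, 5))

  # B = (8 pi^2 / 3) RMSF^2; 1 A fluctuation -> 26.32 A^2
  expect_equal(unname(bfactors(prof)), (8 * pi^2 / 3) * unname(rmsfValues(prof))^2)
  expect_equal((8 * pi^2 / 3) * 1^2, 26.32, tolerance = 1e-3)

  # sum of squared RMSF equals the covariance trace
  traj2 <- randomTrajectory(5, 30, seed = 14)
  prof2 <- rmsf(traj2)
  model <- computeCovariance(traj2, 1:5)
  expect_equal(sum(rmsfValues(prof2)^2), sum(diag(covarianceMatrix(model))),
               tolerance = 1e-8)
})

test_that("domainAverageBfactor averages the fluctuation, not B", {
  prof <- new("FluctuationProfile", resno = 1:10, rmsf = rep(0.5, 10),
              bfactor = (8 * pi^2 / 3) * rep(0.25, 10), context = "global")
  expect_equal(domainAverageBfactor(prof, c(1, 10)), 0.5)
  expect_equal(domainAverageBfactor(prof, c(3, 3)), 0.5)
  expect_error(domainAverageBfactor(prof, c(11, 12)), "empty domain")
})

test_that("coordination shell radius matches enumeration oracles", {
  pair <- caStructure(rbind(c(0, 0, 0), c(5, 0, 0)), resno = 1:2)
  sh <- coordinationShellRadius(pair, cutoff = 6)
  expect_equal(unname(shellRadii(sh)), c(5, 5))
  expect_equal(averageShellRadius(sh), 5)

  # simple cubic lattice: the interior point has 6 neighbors at spacing a
  a <- 3.8
  g <- as.matrix(expand.grid(0:2, 0:2, 0:2)) * a
  lat <- caStructure(g)
  shl <- coordinationShellRadius(lat, cutoff = 1.1 * a)
  interior <- which(rowSums(g == a) == 3)  # center of the 3x3x3 block
  expect_equal(unname(shellRadii(shl)[interior]), a, tolerance = 1e-12)
  expect_equal(unname(shl@nNeighbors[interior]), 6)

  # random cloud vs O(N^2) double loop
  set.seed(15)
  xyz <- matrix(rnorm(40 * 3, sd = 6), 40, 3)
  cl <- caStructure(xyz)
  sh2 <- coordinationShellRadius(cl, cutoff = 8)
  oracle <- vapply(1:40, function(i) {
    r2 <- numeric()
    for (j in setdiff(1:40, i)) {
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dij <= 8) r2 <- c(r2, dij^2)
    }
    if (length(r2)) sqrt(sum(r2) / length(r2)) else NaN
  }, numeric(1))
  expect_equal(unname(shellRadii(sh2)), oracle, tolerance = 1e-10)
  expect_equal(averageShellRadius(sh2), mean(oracle[is.finite(oracle)]),
               tolerance = 1e-10)

  # average radius is monotone non-decreasing in the cutoff
  avgs <- vapply(c(5, 8, 11, 14), function(ct)
    averageShellRadius(coordinationShellRadius(cl, cutoff = ct)), numeric(1))
  expect_true(all(diff(avgs) >= -1e-12))
})

test_that("compact ensembles have larger average shell radii", {
  spec <- smallSpec()
  rg <- domainRanges(spec)
  ext <- buildToyProtein(spec)
  comp <- makeBasin(ext, spec@compactDistance, rg$domain1, rg$domain2,
                    rg$linker)
  # the cutoff must span the compact form's interdomain gap (the smallest
  # cross-domain CA-CA distance) for cross-domain neighbors to register
  caIdx <- selectCalpha(comp, c(1, spec@nResDomain1))
  caIdx2 <- selectCalpha(comp, rg$domain2)
  gap <- min(as.matrix(dist(coords(comp)[c(caIdx, caIdx2), ]))[
    seq_along(caIdx), length(caIdx) + seq_along(caIdx2)])
  ct <- gap + 5
  rgE <- averageShellRadius(coordinationShellRadius(ext, cutoff = ct))
  rgC <- averageShellRadius(coordinationShellRadius(comp, cutoff = ct))
  expect_gte(rgC, rgE)
})

test_that("per-basin interdomain distances recover generator targets", {
  spec <- smallSpec(nFrames = 4000, seed = 16, pEC = 0.01, pCE = 0.01)
  run <- generateTwoStateTrajectory(spec)
  rg <- domainRanges(spec)
  d <- values(interdomainDistance(run$trajectory, rg$domain1, rg$domain2))
  lab <- stateLabels(run$truth)
  # standard error of a basin mean: centroid noise sigma*sqrt(2*3/(nAtoms))
  # per frame is ~0.27 A, over n frames /sqrt(n)
  for (basin in c("extended", "compact")) {
    target <- if (basin == "extended") spec@extendedDistance else
      spec@compactDistance
    n <- sum(lab == basin)
    se <- 1.5 * sqrt(2 / 30) / sqrt(n)
    expect_lt(abs(mean(d[lab == basin]) - target), 3 * se + 0.02)
  }
})
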