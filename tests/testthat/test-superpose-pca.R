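# Kabsch superposition, covariance/PCA and free-energy surfaces.

test_that("kabschSuperpose recovers exact rigid transforms", {
  set.seed(1)
  ref <- matrix(rnorm(30, sd = 5), 10, 3)

  idFit <- kabschSuperpose(ref, ref)
  expect_equal(idFit$rotation, diag(3), tolerance = 1e-10)
  expect_lt(idFit$rmsd, 1e-10)

  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  mobile <- sweep(ref %*% Rz, 2, c(5, 0, 0), `+`)
  fit <- kabschSuperpose(mobile, ref)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$coords, ref, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line + 1), "collinear|degenerate")
})

test_that("kabschSuperpose beats 10000 random rigid transforms", {
  set.seed(2)
  ref <- matrix(rnorm(30, sd = 5), 10, 3)
  mobile <- ref + rnorm(30, sd = 0.5)
  best <- kabschSuperpose(mobile, ref)$rmsd
  oracle <- min(vapply(1:10000, function(i) {
    Q <- properRotation()
    tr <- rnorm(3, sd = 2)
    moved <- sweep(mobile %*% Q, 2, tr, `+`)
    # optimal translation for this rotation: align centroids
    moved <- sweep(moved, 2, colMeans(ref) - colMeans(moved), `+`)
    sqrt(mean(rowSums((moved - ref)^2)))
  }, numeric(1)))
  expect_lte(best, oracle + 1e-12)
})

test_that("alignTrajectory superposes each frame onto the fixed reference", {
  set.seed(3)
  base <- matrix(rnorm(36, sd = 5), 12, 3)
  ref <- caStructure(base)
  nfr <- 8
  arr <- array(0, c(12, 3, nfr))
  for (f in seq_len(nfr))
    arr[, , f] <- sweep(base %*% properRotation(), 2, rnorm(3, sd = 10), `+`)
  traj <- Trajectory(ref, arr)

  al <- alignTrajectory(traj, ref)
  for (f in seq_len(nfr))
    expect_lt(max(abs(coords(al, frame = f) - base)), 1e-6)

  # idempotence
  al2 <- alignTrajectory(al, ref)
  expect_lt(max(abs(coords(al2) - coords(al))), 1e-8)

  # optimality: post-alignment RMSD never exceeds pre-alignment RMSD
  noisy <- Trajectory(ref, arr + rnorm(length(arr), sd = 0.3))
  alN <- alignTrajectory(noisy, ref)
  expect_true(all(frameRMSD(alN, ref) <= frameRMSD(noisy, ref) + 1e-12))
})

test_that("computeCovariance matches closed forms and a brute-force oracle", {
  base <- matrix(rnorm(15), 5, 3)
  const <- Trajectory(caStructure(base),
                      array(rep(base, 4), c(5, 3, 4)), aligned = TRUE)
  m0 <- computeCovariance(const, 1:5)
  expect_true(all(covarianceMatrix(m0) == 0))

  # two frames, atom 2 displaced +-d along x
  d <- 1.7
  arr <- array(rep(base, 2), c(5, 3, 2))
  arr[2, 1, 1] <- base[2, 1] + d
  arr[2, 1, 2] <- base[2, 1] - d
  m2 <- computeCovariance(Trajectory(caStructure(base), arr, aligned = TRUE),
                          1:5)
  expected <- matrix(0, 15, 15)
  expected[4, 4] <- d^2
  expect_equal(covarianceMatrix(m2), expected, tolerance = 1e-12)

  # brute-force double loop over 50 random frames
  traj <- randomTrajectory(4, 50, seed = 7)
  m <- computeCovariance(traj, 1:4)
  X <- sapply(1:50, function(f) as.vector(t(coords(traj, frame = f))))
  mu <- rowMeans(X)
  O <- matrix(0, 12, 12)
  for (f in 1:50) O <- O + tcrossprod(X[, f] - mu)
  O <- O / 50
  expect_lt(max(abs(covarianceMatrix(m) - O)), 1e-10)
  expect_equal(meanConfiguration(m), mu, tolerance = 1e-12)

  one <- Trajectory(caStructure(base), array(base, c(5, 3, 1)),
                    aligned = TRUE)
  expect_error(computeCovariance(one, 1:5), "2 frames")
  expect_warning(computeCovariance(randomTrajectory(4, 5, aligned = FALSE),
                                   1:4), "aligned")
})

test_that("eigenDecompose sorts, sign-fixes and reconstructs the spectrum", {
  mdl <- new("CovarianceModel", selection = 1L, mean = rep(0, 3),
             matrix = diag(c(2, 3, 1)), components = matrix(0, 3, 0),
             variances = numeric())
  e <- eigenDecompose(mdl)
  expect_equal(variances(e), c(3, 2, 1))
  expect_equal(abs(principalComponents(e)),
               cbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)), tolerance = 1e-12)
  # sign convention: largest-magnitude entry positive
  expect_true(all(apply(principalComponents(e), 2,
                        function(p) p[which.max(abs(p))] > 0)))

  # random PSD: reconstruction and orthonormality
  set.seed(4)
  A <- matrix(rnorm(36), 6, 6)
  C <- crossprod(A)
  mdl6 <- new("CovarianceModel", selection = 1:2, mean = rep(0, 6),
              matrix = C, components = matrix(0, 6, 0),
              variances = numeric())
  e6 <- eigenDecompose(mdl6)
  P <- principalComponents(e6)
  expect_lt(max(abs(P %*% diag(variances(e6)) %*% t(P) - C)), 1e-8)
  expect_lt(max(abs(crossprod(P) - diag(6))), 1e-8)
  expect_equal(sum(variances(e6)), sum(diag(C)), tolerance = 1e-10)

  # spectrum agrees with characteristic-polynomial root finding
  # (Faddeev-LeVerrier coefficients, polyroot as the independent oracle)
  cp <- numeric(7)  # coefficients of lambda^6 ... lambda^0
  M <- diag(6); cp[1] <- 1
  for (k in 1:6) {
    M <- C %*% M
    ck <- -sum(diag(M)) / k
    cp[k + 1] <- ck
    M <- M + ck * diag(6)
  }
  roots <- sort(Re(polyroot(rev(cp))), decreasing = TRUE)
  expect_equal(variances(e6), roots, tolerance = 1e-6)

  asym <- mdl6
  asym@matrix[1, 2] <- asym@matrix[1, 2] + 1  # force asymmetry unchecked
  expect_error(eigenDecompose(asym), "symmetric")

  neg <- new("CovarianceModel", selection = 1L, mean = rep(0, 3),
             matrix = diag(c(1, 1, -1)), components = matrix(0, 3, 0),
             variances = numeric())
  expect_error(eigenDecompose(neg), "negative")
})

test_that("projections satisfy their defining identities", {
  traj <- randomTrajectory(5, 40, seed = 9)
  model <- eigenDecompose(computeCovariance(traj, 1:5))

  # frame = mean gives zero scores; mean + 2 p1 scores (2, 0, ...)
  mu <- matrix(meanConfiguration(model), ncol = 3, byrow = TRUE)
  p1 <- matrix(principalComponents(model)[, 1], ncol = 3, byrow = TRUE)
  special <- Trajectory(topology(traj),
                        array(c(mu, mu + 2 * p1), c(5, 3, 2)),
                        aligned = TRUE)
  S <- projectFrames(special, model, 1:15)
  expect_equal(as.vector(S[1, ]), rep(0, 15), tolerance = 1e-10)
  expect_equal(as.vector(S[2, ]), c(2, rep(0, 14)), tolerance = 1e-10)

  # score variance over the model's own trajectory equals sigma_i
  Sown <- projectFrames(traj, model, 1:15)
  popVar <- apply(Sown, 2, function(s) mean((s - mean(s))^2))
  expect_equal(unname(popVar), variances(model), tolerance = 1e-8)

  # isometry: sum of squared scores = squared displacement per frame
  X <- sapply(1:40, function(f) as.vector(t(coords(traj, frame = f))))
  disp2 <- colSums((X - meanConfiguration(model))^2)
  expect_equal(unname(rowSums(Sown^2)), unname(disp2), tolerance = 1e-8)
})

test_that("free-energy surfaces follow Boltzmann inversion", {
  kT <- thermalEnergy(310)
  expect_equal(kT, 0.616032, tolerance = 1e-6)

  # two occupied bins at 70%/30%
  s <- c(rep(0.25, 700), rep(0.75, 300))
  fes <- freeEnergySurface(s, bins = 2, kT = kT)
  A <- energyValues(fes)
  expect_equal(A[2] - A[1], kT * log(70 / 30), tolerance = 1e-10)
  expect_equal(min(A), 0)

  # exactly uniform occupancy is flat at zero
  u <- rep(seq(0.05, 0.95, by = 0.1), each = 10)
  fesU <- freeEnergySurface(u, bins = 10, kT = kT)
  expect_true(all(abs(energyValues(fesU)) < 1e-10))

  # Gaussian scores: quadratic energy with curvature kT / sigma^2
  set.seed(10)
  sig <- 1.4
  g <- rnorm(2e5, sd = sig)
  fesG <- freeEnergySurface(g, bins = 60, kT = kT)
  ctr <- (binEdges(fesG)[[1]][-1] + binEdges(fesG)[[1]][-61]) / 2
  sel <- abs(ctr) < 2 * sig & is.finite(energyValues(fesG))
  fitq <- lm(energyValues(fesG)[sel] ~ poly(ctr[sel], 2, raw = TRUE))
  curv <- 2 * coef(fitq)[[3]]
  expect_equal(curv, kT / sig^2, tolerance = 0.05)

  # density normalization and empty-bin handling
  fes2 <- freeEnergySurface(cbind(g[1:5000], rnorm(5000)), bins = 20, kT = kT)
  w <- prod(vapply(binEdges(fes2), function(e) diff(e[1:2]), numeric(1)))
  expect_equal(sum(fes2@density) * w, 1, tolerance = 1e-8)
  expect_true(any(is.infinite(energyValues(fes2))))

  # all-identical scores occupy a single bin
  fes3 <- freeEnergySurface(rep(2.5, 10), bins = 5, kT = kT)
  expect_equal(sum(fes3@density > 0), 1)
})

test_that("superposition and PCA agree with bio3d's independent routines", {
  traj <- randomTrajectory(8, 25, seed = 30)
  ref <- topology(traj)

  # per-frame fitted RMSD vs bio3d::fit.xyz
  al <- alignTrajectory(traj, ref)
  xyzmat <- t(apply(coords(traj), 3, function(m) as.vector(t(m))))
  fitted <- bio3d::fit.xyz(as.vector(t(coords(ref))), xyzmat,
                           fixed.inds = 1:24, mobile.inds = 1:24)
  oursRMSD <- frameRMSD(al, ref)
  b3dRMSD <- sqrt(rowMeans((sweep(fitted, 2, as.vector(t(coords(ref)))))^2) * 3)
  expect_equal(oursRMSD, unname(b3dRMSD), tolerance = 1e-6)

  # PCA spectrum vs bio3d::pca.xyz on pre-aligned coordinates
  alMat <- t(apply(coords(al), 3, function(m) as.vector(t(m))))
  b3dPCA <- bio3d::pca.xyz(alMat, use.svd = FALSE)
  ours <- eigenDecompose(computeCovariance(al, 1:8))
  # bio3d uses the 1/(n-1) covariance; rescale to the population convention
  expect_equal(variances(ours), b3dPCA$L * (25 - 1) / 25, tolerance = 1e-8)
  # leading subspace agrees up to sign
  for (k in 1:3)
    expect_equal(abs(sum(principalComponents(ours)[, k] * b3dPCA$U[, k])), 1,
                 tolerance = 1e-6)
})
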