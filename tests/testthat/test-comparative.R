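# Mean distance matrices, difference maps, correlation matrices and
# per-domain-aligned intradomain analysis.

test_that("meanDistanceMatrix equals the per-frame double-loop oracle", {
  set.seed(17)
  xyz <- matrix(rnorm(18, sd = 5), 6, 3)
  s <- caStructure(xyz)
  one <- Trajectory(s, array(xyz, c(6, 3, 1)))
  M1 <- distanceMatrix(meanDistanceMatrix(one))
  expect_equal(M1, as.matrix(dist(xyz)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(diag(M1) == 0))

  traj <- randomTrajectory(6, 20, seed = 18)
  M <- distanceMatrix(meanDistanceMatrix(traj))
  O <- matrix(0, 6, 6)
  for (f in 1:20) {
    x <- coords(traj, frame = f)
    for (i in 1:6) for (j in 1:6)
      O[i, j] <- O[i, j] + sqrt(sum((x[i, ] - x[j, ])^2))
  }
  O <- O / 20
  expect_lt(max(abs(M - O)), 1e-10)
  expect_equal(M, t(M))
})

test_that("distanceChangeMap classifies inclusively within the windows", {
  # two well-separated clusters along x
  set.seed(19)
  base <- rbind(matrix(rnorm(12, sd = 2), 4, 3),
                sweep(matrix(rnorm(12, sd = 2), 4, 3), 2, c(30, 0, 0), `+`))
  arr <- array(rep(base, 10), c(8, 3, 10)) + rnorm(240, sd = 0.1)
  traj <- Trajectory(caStructure(base), arr)
  mdm <- meanDistanceMatrix(traj)
  same <- distanceChangeMap(mdm, mdm)
  expect_true(all(classMatrix(same) == "unclassified"))
  expect_true(all(deltaMatrix(same) == 0))

  # rigid +7 A translation of the far cluster: every interdomain pair
  # grows by ~7 A (inside the window), intradomain pairs stay put
  arr2 <- arr
  arr2[5:8, 1, ] <- arr2[5:8, 1, ] + 7
  shifted <- Trajectory(topology(traj), arr2)
  mdm2 <- meanDistanceMatrix(shifted)
  map <- distanceChangeMap(mdm2, mdm)
  cls <- classMatrix(map)
  intra <- cls[1:4, 1:4][upper.tri(matrix(0, 4, 4))]
  expect_true(all(intra == "unclassified"))
  inter <- cls[1:4, 5:8]
  expect_true(all(inter == "increase"))

  # boundary convention: delta = -4 exactly is a decrease
  A <- new("MeanDistanceMatrix", resno = 1:2,
           matrix = matrix(c(0, 10, 10, 0), 2, 2))
  B <- new("MeanDistanceMatrix", resno = 1:2,
           matrix = matrix(c(0, 6, 6, 0), 2, 2))
  expect_equal(classMatrix(distanceChangeMap(B, A))[1, 2], "decrease")
  # |delta| beyond the outer window: strict drops it, saturating keeps it
  Bfar <- new("MeanDistanceMatrix", resno = 1:2,
              matrix = matrix(c(0, 22, 22, 0), 2, 2))
  expect_equal(classMatrix(distanceChangeMap(Bfar, A))[1, 2], "unclassified")
  expect_equal(classMatrix(distanceChangeMap(Bfar, A,
                                             mode = "saturating"))[1, 2],
               "increase")

  C <- new("MeanDistanceMatrix", resno = 1:3, matrix = matrix(0, 3, 3))
  expect_error(distanceChangeMap(C, A), "residue lists")
})

test_that("correlationMatrix matches the direct time-average oracle", {
  # identical / opposite displacement of two atoms
  base <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0), 3, 3, byrow = TRUE)
  nfr <- 20
  set.seed(20)
  disp <- rnorm(nfr)
  arr <- array(rep(base, nfr), c(3, 3, nfr))
  arr[1, 1, ] <- arr[1, 1, ] + disp
  arr[2, 1, ] <- arr[2, 1, ] + disp   # identical motion
  arr[3, 1, ] <- arr[3, 1, ] - disp   # opposite motion
  traj <- Trajectory(caStructure(base), arr, aligned = TRUE)
  cc <- correlationValues(correlationMatrix(computeCovariance(traj, 1:3)))
  expect_equal(diag(cc), rep(1, 3))
  expect_equal(cc[1, 2], 1, tolerance = 1e-12)
  expect_equal(cc[1, 3], -1, tolerance = 1e-12)

  # random trajectory vs explicit time averages
  traj2 <- randomTrajectory(5, 40, seed = 21)
  cc2 <- correlationValues(correlationMatrix(computeCovariance(traj2, 1:5)))
  X <- coords(traj2)
  mu <- apply(X, c(1, 2), mean)
  O <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    num <- mean(vapply(1:40, function(f)
      sum((X[i, , f] - mu[i, ]) * (X[j, , f] - mu[j, ])), numeric(1)))
    di <- mean(vapply(1:40, function(f)
      sum((X[i, , f] - mu[i, ])^2), numeric(1)))
    dj <- mean(vapply(1:40, function(f)
      sum((X[j, , f] - mu[j, ])^2), numeric(1)))
    O[i, j] <- num / sqrt(di * dj)
  }
  expect_lt(max(abs(cc2 - O)), 1e-9)
  expect_true(all(cc2 >= -1 - 1e-9 & cc2 <= 1 + 1e-9))

  # zero-variance residue is flagged undefined
  arrC <- coords(traj2)
  arrC[2, , ] <- 0
  still <- Trajectory(topology(traj2), arrC, aligned = TRUE)
  ccU <- correlationMatrix(computeCovariance(still, 1:5))
  expect_equal(ccU@undefined, 2L)
  expect_true(all(is.na(correlationValues(ccU)[2, ])))
})

test_that("anticorrelationDifferenceMap applies eligibility and margins", {
  mk <- function(v12) {
    M <- diag(2); M[1, 2] <- M[2, 1] <- v12
    new("CorrelationMatrix", resno = 1:2, matrix = M, context = "global",
        undefined = integer())
  }
  same <- anticorrelationDifferenceMap(mk(-0.5), mk(-0.5))
  expect_false(any(classMatrix(same) %in%
                   c("less_anticorrelated", "more_anticorrelated")))

  less <- anticorrelationDifferenceMap(mk(-0.5), mk(-0.1),
                                       threshold = 0.1, margin = 0.1)
  expect_equal(classMatrix(less)[1, 2], "less_anticorrelated")

  more <- anticorrelationDifferenceMap(mk(-0.2), mk(-0.6))
  expect_equal(classMatrix(more)[1, 2], "more_anticorrelated")

  # pair never anticorrelated is excluded
  excl <- anticorrelationDifferenceMap(mk(0.3), mk(0.1))
  expect_equal(classMatrix(excl)[1, 2], "excluded")
})

test_that("intradomain alignment removes rigid-body motion", {
  set.seed(22)
  base <- matrix(rnorm(30, sd = 6), 10, 3)
  ref <- caStructure(base)
  nfr <- 15
  arr <- array(0, c(10, 3, nfr))
  for (f in seq_len(nfr))
    arr[, , f] <- sweep(base %*% properRotation(), 2, rnorm(3, sd = 15), `+`)
  traj <- Trajectory(ref, arr)

  res <- intradomainAnalysis(traj, c(1, 10), ref)
  expect_lt(max(rmsfValues(res$fluctuations)), 1e-6)
  globalProf <- suppressWarnings(rmsf(traj))
  expect_gt(mean(rmsfValues(globalProf)), 1)

  # on two-state data, domain-aligned RMSF of the domain is not larger
  # than globally-aligned RMSF of the same residues
  spec <- smallSpec(nFrames = 800, seed = 23, pEC = 0.01, pCE = 0.01)
  run <- generateTwoStateTrajectory(spec)
  top <- topology(run$trajectory)
  rg <- domainRanges(spec)
  glob <- alignTrajectory(run$trajectory, top,
                          selectCalpha(top, c(1, rg$domain2[2])))
  gProf <- rmsf(glob, selectCalpha(top, rg$domain2))
  dom <- intradomainAnalysis(run$trajectory, rg$domain2, top)
  expect_lte(mean(rmsfValues(dom$fluctuations)),
             mean(rmsfValues(gProf)) + 1e-9)

  # hinging two-domain motion: interdomain anticorrelation along the
  # separation axis, intradomain positive correlation
  sel <- selectCalpha(top, c(1, rg$domain2[2]))
  al <- alignTrajectory(run$trajectory, top, sel)
  cc <- correlationValues(correlationMatrix(computeCovariance(al, sel)))
  n1 <- 30; n2 <- 30
  interBlock <- cc[1:n1, (length(sel) - n2 + 1):length(sel)]
  expect_lt(mean(interBlock), 0)
})
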