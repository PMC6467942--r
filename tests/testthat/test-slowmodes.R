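# Dihedral features, tICA, k-means, representative extraction.

# Single-frame trajectory holding one Ca quadruplet in a helix segment.
quadTraj <- function(p, nFrames = 1) {
  top <- Topology(data.frame(name = "CA", resname = "ALA", resid = 1:4,
                             chain = "A"),
                  data.frame(chain = "A", first = 1, last = 4, kind = "helix"))
  co <- array(rep(t(p), each = nFrames), dim = c(nFrames, 4, 3))
  for (i in seq_len(nFrames)) co[i, , ] <- p
  Trajectory(top, co)
}

test_that("pseudo-dihedral features: planar trans and cis quadruplets", {
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  f <- values(dihedralFeatures(quadTraj(trans)))
  expect_equal(unname(f[1, ]), c(0, -1), tolerance = 1e-10)  # (sin, cos) of 180
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  f2 <- values(dihedralFeatures(quadTraj(cis)))
  expect_equal(unname(f2[1, ]), c(0, 1), tolerance = 1e-10)  # (sin, cos) of 0
})

test_that("90-degree dihedral sign matches textbook and bio3d oracles", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  f <- values(dihedralFeatures(quadTraj(p)))
  ang <- atan2(f[1, 1], f[1, 2])
  expect_equal(abs(ang), pi / 2, tolerance = 1e-10)
  expect_equal(ang, oracleDihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
               tolerance = 1e-10)
  bio <- bio3d::torsion.xyz(as.numeric(t(p)), atm.inc = 4) * pi / 180
  expect_equal(ang, unname(bio[1]), tolerance = 1e-8)
})

test_that("random quadruplets agree with both oracles; sin^2+cos^2 = 1", {
  set.seed(1)
  for (i in 1:25) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    f <- values(dihedralFeatures(quadTraj(p)))
    expect_equal(sum(f[1, ]^2), 1, tolerance = 1e-12)
    ang <- atan2(f[1, 1], f[1, 2])
    expect_equal(ang, oracleDihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-8)
    bio <- bio3d::torsion.xyz(as.numeric(t(p)), atm.inc = 4) * pi / 180
    expect_equal(ang, unname(bio[1]), tolerance = 1e-6)
  }
})

test_that("features on a real template: labels unique, unit circle, per segment", {
  tpl <- makeDimerTemplate(8, 10)
  h <- simulateHarmonic(tpl, 0.2, 20, seed = 2)$trajectory
  fm <- dihedralFeatures(h)
  v <- values(fm)
  expect_false(anyDuplicated(fm@labels) > 0)
  expect_true(all(is.finite(v)))
  s2 <- v[, seq(1, ncol(v), 2)]^2 + v[, seq(2, ncol(v), 2)]^2
  expect_lt(max(abs(s2 - 1)), 1e-12)
})

test_that("phi_psi mode errors list residues with missing backbone atoms", {
  top <- Topology(data.frame(name = "CA", resname = "ALA", resid = 1:5,
                             chain = "A"),
                  data.frame(chain = "A", first = 1, last = 5, kind = "helix"))
  traj <- Trajectory(top, array(rnorm(2 * 5 * 3), dim = c(2, 5, 3)))
  expect_error(dihedralFeatures(traj, mode = "phi_psi"), "resid")
})

test_that("tICA degenerate limit: lag-periodic input gives eigenvalues 1", {
  set.seed(3)
  lag <- 4L
  block <- matrix(rnorm(4 * 3), 4, 3)
  X <- do.call(rbind, replicate(10, block, simplify = FALSE))
  r <- tica(X, lag = lag, regularization = 0)
  expect_equal(r@eigenvalues, rep(1, 3), tolerance = 1e-8)
})

test_that("tICA eigenvalues are bounded and invariant to feature remixing", {
  sf <- simulateSlowFastFeatures(4, slowTau = 50, nFrames = 5000, seed = 4)
  X <- values(sf$features)
  r1 <- tica(X, lag = 25, regularization = 0)
  expect_true(all(abs(r1@eigenvalues) <= 1 + 1e-6))
  set.seed(5)
  A <- matrix(rnorm(16), 4, 4)         # invertible remix w.p. 1
  r2 <- tica(X %*% A, lag = 25, regularization = 0)
  expect_equal(r1@eigenvalues, r2@eigenvalues, tolerance = 1e-6)
})

test_that("tICA recovers the planted OU slow mode", {
  # the +-0.05 recovery band is stated at n = 5e4 (sd of a lag-50
  # autocorrelation estimate for this process is ~5/sqrt(n))
  sf <- simulateSlowFastFeatures(10, slowTau = 100, nFrames = 50000, seed = 6)
  r <- tica(values(sf$features), lag = 50)
  expect_equal(r@eigenvalues[1], exp(-0.5), tolerance = 0.05)
  expect_gt(abs(cor(projections(r)[, 1], sf$truth@slowCoordinate)), 0.9)
  expect_error(tica(values(sf$features)[1:40, ], lag = 50), "lag")
})

test_that("kmeansCluster: k = 1, planted blobs, determinism, inertia", {
  set.seed(7)
  pts <- rbind(matrix(rnorm(200, sd = 0.5), ncol = 2),
               sweep(matrix(rnorm(200, sd = 0.5), ncol = 2), 2, c(20, 0), "+"),
               sweep(matrix(rnorm(200, sd = 0.5), ncol = 2), 2, c(0, 20), "+"))
  truth <- rep(1:3, each = 100)
  k1 <- kmeansCluster(pts, k = 1, seed = 1)
  expect_equal(as.numeric(k1@centroids), colMeans(pts), tolerance = 1e-10)
  d2 <- rowSums(sweep(pts, 2, colMeans(pts))^2)
  expect_equal(representatives(k1), which.min(d2))
  k3 <- kmeansCluster(pts, k = 3, seed = 1)
  expect_gte(labelAgreement(assignments(k3), truth), 0.99)
  # determinism
  k3b <- kmeansCluster(pts, k = 3, seed = 1)
  expect_identical(assignments(k3), assignments(k3b))
  expect_identical(k3@centroids, k3b@centroids)
  # inertia non-increasing across Lloyd iterations
  expect_true(all(diff(k3@inertiaHistory) <= 1e-12))
  # representatives belong to their own cluster
  expect_equal(assignments(k3)[representatives(k3)],
               seq_len(nrow(k3@centroids)))
})

test_that("kmeansCluster agrees with stats::kmeans from the same start", {
  set.seed(8)
  pts <- rbind(matrix(rnorm(160, sd = 0.4), ncol = 2),
               sweep(matrix(rnorm(160, sd = 0.4), ncol = 2), 2, c(10, 5), "+"))
  ours <- kmeansCluster(pts, k = 2, seed = 2)
  ref <- stats::kmeans(pts, centers = ours@centroids, algorithm = "Lloyd",
                       iter.max = 100)
  expect_equal(labelAgreement(assignments(ours), ref$cluster), 1)
  expect_equal(ours@inertia, ref$tot.withinss, tolerance = 1e-8)
})

test_that("extractRepresentatives returns k aligned frames", {
  tpl <- makeDimerTemplate(8, 10)
  m <- simulateMetastable(tpl, 3, sigma = 0.3, nFrames = 200, seed = 9)
  feats <- dihedralFeatures(m$trajectory)
  r <- tica(feats, lag = 2)
  km <- kmeansCluster(r, k = 3, seed = 1)
  reps <- extractRepresentatives(m$trajectory, km)
  expect_equal(nFrames(reps), 3)
  # frames equal the originals up to a rigid motion
  for (j in 1:3)
    expect_lt(rmsdPair(coords(reps)[j, , ],
                       coords(m$trajectory)[representatives(km)[j], , ]),
              1e-8)
  # k = 1: single aligned frame
  km1 <- kmeansCluster(r, k = 1, seed = 1)
  reps1 <- extractRepresentatives(m$trajectory, km1)
  expect_equal(nFrames(reps1), 1)
})
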