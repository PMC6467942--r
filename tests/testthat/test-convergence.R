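# Convergence battery: RMSD series, all-to-all matrix, cluster counting,
# plateau, GROMOS clustering, PCA.

test_that("rmsdToReference: trivial cases and raw harmonic closed form", {
  tpl <- makeDimerTemplate(10, 12.5)
  flat <- simulateHarmonic(tpl, 0, 5, seed = 1)$trajectory
  expect_equal(values(rmsdToReference(flat)), rep(0, 5), tolerance = 1e-12)
  h <- simulateHarmonic(tpl, 0.5, 2000, seed = 2)$trajectory
  s <- rmsdToReference(h, reference = 1L)
  expect_equal(values(s)[1], 0, tolerance = 1e-12)
  expect_true(all(values(s) >= 0))
  expect_equal(frameTimes(s), frameTimes(h))
  # raw RMSD to the noiseless template: E[RMSD] -> sigma*sqrt(3)
  idx <- resolveSelection(topology(tpl), AtomSelection())
  raw <- rmsdToReference(h, reference = coords(tpl)[idx, , drop = FALSE],
                         superpose = FALSE)
  expect_equal(mean(values(raw)), 0.5 * sqrt(3), tolerance = 0.01)
})

test_that("allToAllRmsd matches pairwise rmsdPair and stride submatrix", {
  tpl <- makeDimerTemplate(8, 10)
  traj <- simulateMetastable(tpl, 3, sigma = 0.3, nFrames = 10,
                             seed = 3)$trajectory
  m <- allToAllRmsd(traj)
  idx <- resolveSelection(topology(tpl), AtomSelection())
  co <- coords(traj)
  for (i in 1:10) for (j in 1:10)
    expect_equal(values(m)[i, j], rmsdPair(co[i, idx, ], co[j, idx, ]),
                 tolerance = 1e-10)
  expect_equal(values(m), t(values(m)), tolerance = 1e-10)
  expect_lt(max(abs(diag(values(m)))), 1e-10)
  m2 <- allToAllRmsd(traj, stride = 2L)
  expect_equal(values(m2), values(m)[c(1, 3, 5, 7, 9), c(1, 3, 5, 7, 9)],
               tolerance = 1e-10)
  # trivial: two identical frames
  two <- Trajectory(topology(tpl), coords(traj)[c(1, 1), , , drop = FALSE])
  expect_lt(max(values(allToAllRmsd(two))), 1e-10)
  # guards
  one <- Trajectory(topology(tpl), coords(traj)[1, , , drop = FALSE])
  expect_error(allToAllRmsd(one))
})

test_that("memory guard refuses oversized matrices unless forced", {
  tpl <- makeDimerTemplate(8, 10)
  traj <- simulateHarmonic(tpl, 0.1, 30, seed = 4)$trajectory
  expect_error(allToAllRmsd(traj, maxFrames = 20L), "stride")
  expect_s4_class(allToAllRmsd(traj, maxFrames = 20L, force = TRUE),
                  "RmsdMatrix")
})

test_that("leader counting: identical frames and planted A,B,A,B", {
  tpl <- makeDimerTemplate(10, 12.5)
  flat <- simulateHarmonic(tpl, 0, 6, seed = 1)$trajectory
  ct <- leaderClusterCount(flat, cutoff = 2)
  expect_equal(countCurve(ct), rep(1L, 6))
  expect_equal(representatives(ct), 1L)
  # two planted conformers, alternating (built from the state offsets)
  m <- simulateMetastable(tpl, 2, sigma = 0, nFrames = 4, seed = 5,
                          rmsdFloor = 5)
  conf <- lapply(m$truth@stateOffsets, function(o) coords(tpl) + o)
  co <- array(0, dim = c(4, nAtoms(tpl), 3))
  for (i in 1:4) co[i, , ] <- conf[[c(1, 2, 1, 2)[i]]]
  abab <- Trajectory(topology(tpl), co)
  ct2 <- leaderClusterCount(abab, cutoff = 2)
  expect_equal(countCurve(ct2), c(1L, 2L, 2L, 2L))
  expect_equal(assignments(ct2), c(1L, 2L, 1L, 2L))
  expect_equal(representatives(ct2), c(1L, 2L))
})

test_that("leader counting recovers planted metastable states", {
  tpl <- makeDimerTemplate(10, 12.5)
  m <- simulateMetastable(tpl, 4, sigma = 0.3, nFrames = 800, seed = 6,
                          rmsdFloor = 6)
  ct <- leaderClusterCount(m$trajectory, cutoff = 2)
  expect_equal(max(assignments(ct)), 4L)
  expect_gte(labelAgreement(assignments(ct), m$truth@stateLabels), 0.99)
  # invariant under per-frame rigid corruption
  corr <- applyRandomRigidMotion(m$trajectory, seed = 7)
  ct2 <- leaderClusterCount(corr$trajectory, cutoff = 2)
  expect_equal(assignments(ct2), assignments(ct))
  # c(t) structural invariants
  cc <- countCurve(ct)
  expect_true(all(diff(cc) >= 0))
  expect_true(all(cc >= 1 & cc <= seq_along(cc)))
})

test_that("plateauTime reads the founding time of the last cluster", {
  tpl <- makeDimerTemplate(10, 12.5)
  m <- simulateMetastable(tpl, 3, sigma = 0, nFrames = 12, seed = 8,
                          rmsdFloor = 6)
  conf <- lapply(m$truth@stateOffsets, function(o) coords(tpl) + o)
  pick <- c(1, 2, 2, 3, 3, 3)
  co <- array(0, dim = c(6, nAtoms(tpl), 3))
  for (i in 1:6) co[i, , ] <- conf[[pick[i]]]
  traj <- Trajectory(topology(tpl), co, times = 0:5)
  ct <- leaderClusterCount(traj, cutoff = 2)
  expect_equal(countCurve(ct), c(1L, 2L, 2L, 3L, 3L, 3L))
  expect_equal(plateauTime(ct), 3)
  # single cluster: plateau at the first frame's time
  flat <- simulateHarmonic(tpl, 0, 4, seed = 1)$trajectory
  expect_equal(plateauTime(leaderClusterCount(flat, cutoff = 2)), 0)
  # metastable: plateau equals the last first-visit time from truth
  m2 <- simulateMetastable(tpl, 4, sigma = 0.3, nFrames = 800, seed = 6)
  ct2 <- leaderClusterCount(m2$trajectory, cutoff = 2)
  lastFirst <- max(vapply(unique(m2$truth@stateLabels),
                          function(s) which(m2$truth@stateLabels == s)[1], 1L))
  expect_equal(plateauTime(ct2), frameTimes(m2$trajectory)[lastFirst])
})

test_that("degenerate cutoffs bound the cluster count", {
  tpl <- makeDimerTemplate(8, 10)
  traj <- simulateHarmonic(tpl, 0.3, 50, seed = 9)$trajectory
  expect_equal(max(assignments(leaderClusterCount(traj, cutoff = 1e6))), 1L)
  expect_equal(max(assignments(leaderClusterCount(traj, cutoff = 1e-6))), 50L)
})

test_that("gromosCluster: trivial cases and brute-force oracle", {
  # A, A, B with RMSD(A,B) > cutoff
  m3 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3, 3)
  rm3 <- new("RmsdMatrix", frames = 1:3, times = 0:2, values = m3)
  g <- gromosCluster(rm3, cutoff = 2)
  expect_equal(g$members, list(c(1L, 2L), 3L))
  expect_equal(g$centers, c(1L, 3L))
  # all within cutoff -> one cluster
  g1 <- gromosCluster(rm3, cutoff = 10)
  expect_equal(g1$members, list(1:3))
  # 200-frame dual-implementation oracle
  tpl <- makeDimerTemplate(10, 12.5)
  traj <- simulateMetastable(tpl, 5, sigma = 0.5, nFrames = 200,
                             seed = 10)$trajectory
  mat <- allToAllRmsd(traj)
  got <- gromosCluster(mat, cutoff = 2)
  oracle <- bruteGromos(values(mat), 2)
  expect_equal(lapply(got$members, as.integer), oracle$members)
  expect_equal(got$centers, oracle$centers)
  # partition property
  expect_equal(sort(unlist(got$members)), 1:200)
})

test_that("coordinatePca: rank-1 motion, conservation, projection moments", {
  tpl <- makeDimerTemplate(8, 10)
  fx <- plantedTwoModeTrajectory(tpl, varHigh = 4, varLow = 0, nFrames = 400,
                                 seed = 11)
  sel <- AtomSelection(atomNames = NULL, segmentKinds = NULL)
  # align = FALSE keeps the planted rank exactly 1
  expect_warning(pr <- coordinatePca(fx$trajectory, sel, nComponents = 2L,
                                     align = FALSE),
                 "rank")
  expect_true(pr@rankDeficient)
  expect_equal(pr@explainedVariance[1], 1, tolerance = 1e-8)
  # two planted modes, 9:1
  fx2 <- plantedTwoModeTrajectory(tpl, 9, 1, nFrames = 4000, seed = 12)
  pr2 <- coordinatePca(fx2$trajectory, sel, nComponents = 2L)
  expect_equal(pr2@explainedVariance, c(0.9, 0.1), tolerance = 0.03)
  # orthonormal components
  expect_equal(crossprod(pr2@vectors), diag(2), tolerance = 1e-8)
  # projections: zero mean, variance = eigenvalue (1/n convention)
  pj <- projections(pr2)
  n <- nrow(pj)
  expect_lt(max(abs(colMeans(pj))), 1e-8)
  empVar <- colSums(sweep(pj, 2, colMeans(pj))^2) / n
  expect_equal(unname(empVar), pr2@eigenvalues, tolerance = 1e-8)
  # trace conservation over the full spectrum
  prAll <- suppressWarnings(coordinatePca(fx2$trajectory, sel,
                                          nComponents = 3L * nAtoms(tpl)))
  expect_equal(sum(prAll@eigenvalues), prAll@totalVariance,
               tolerance = 1e-8)
})
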