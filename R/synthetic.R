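#' Idealized helical dimer template
#'
#' Builds a deterministic coarse model of a homodimeric helix-bundle
#' scaffold: each chain is a Ca trace of two idealized alpha-helices
#' (rise 1.5 Angstrom, radius 2.3 Angstrom, 100 degrees per residue) joined
#' by a short loop. One residue at the middle of each chain's inner helix is
#' tagged (resname TRP) and the pair of their alpha-carbons is the pore
#' gauge; chain B is the C2 image of chain A, translated along the gauge
#' axis so the gauge Ca-Ca distance equals `gaugeSeparation` exactly.
#'
#' @param nResPerHelix residues per helix (>= 4; default 10)
#' @param gaugeSeparation desired gauge Ca-Ca distance, Angstrom (default
#'   12.5, an "open pore" geometry; ~8 corresponds to a closed pore)
#' @param nLoopRes residues in the connecting loop (default 3)
#' @return a [DimerTemplate-class]
#' @examples
#' tpl <- makeDimerTemplate(10, 12.5)
#' @export
makeDimerTemplate <- function(nResPerHelix = 10, gaugeSeparation = 12.5,
                              nLoopRes = 3) {
  n <- as.integer(nResPerHelix)
  if (n < 4) .stopf("nResPerHelix must be >= 4")
  if (gaugeSeparation <= 0) .stopf("gaugeSeparation must be > 0")
  step <- 100 * pi / 180
  helix <- function(n, phase, yc, reverse = FALSE) {
    i <- 0:(n - 1)
    z <- 1.5 * i
    if (reverse) z <- rev(z)
    cbind(2.3 * cos(step * i + phase), yc + 2.3 * sin(step * i + phase), z)
  }
  gIdx <- n %/% 2 + 1L                      # gauge residue within inner helix
  phase2 <- pi / 2 - step * (gIdx - 1)      # its Ca points inward (+y)
  h1 <- helix(n, 0, -12)
  h2 <- helix(n, phase2, -5, reverse = TRUE)
  # loop: semicircular arc over the helix ends, keeping Ca spacing realistic
  p0 <- h1[n, ]; p1 <- h2[1, ]
  span <- p1 - p0
  L <- sqrt(sum(span^2))
  u <- span / L
  mid <- (p0 + p1) / 2
  tt <- seq_len(nLoopRes) / (nLoopRes + 1)
  loop <- t(vapply(tt, function(t)
    mid - (L / 2) * cos(pi * t) * u + c(0, 0, (L / 2) * sin(pi * t)),
    numeric(3)))
  chainA <- rbind(h1, loop, h2)
  chainB <- chainA %*% diag(c(-1, -1, 1))   # C2 rotation about z
  nres <- nrow(chainA)
  gaugeA <- n + nLoopRes + gIdx
  gaugeB <- nres + gaugeA
  xyz <- rbind(chainA, chainB)
  g <- xyz[gaugeB, ] - xyz[gaugeA, ]
  u <- g / sqrt(sum(g^2))
  shift <- (gaugeSeparation - sqrt(sum(g^2))) * u
  xyz[(nres + 1):(2 * nres), ] <- sweep(xyz[(nres + 1):(2 * nres), ], 2, shift, "+")
  resname <- rep("ALA", nres); resname[gaugeA] <- "TRP"
  atomsDf <- data.frame(
    serial = seq_len(2 * nres), name = "CA",
    resname = rep(resname, 2), resid = rep(seq_len(nres), 2),
    chain = rep(c("A", "B"), each = nres))
  seg <- function(ch) data.frame(
    chain = ch, first = c(1L, n + 1L, n + nLoopRes + 1L),
    last = c(n, n + nLoopRes, nres),
    kind = c("helix", "loop", "helix"))
  top <- Topology(atomsDf, rbind(seg("A"), seg("B")))
  new("DimerTemplate", topology = top, coords = unname(xyz),
      gaugePair = as.integer(c(gaugeA, gaugeB)))
}

# per-atom sigma vector from scalar or vector input
.sigmaVec <- function(sigma, nAtoms) {
  if (any(sigma < 0)) .stopf("sigma must be >= 0")
  if (length(sigma) == 1) rep(as.numeric(sigma), nAtoms)
  else if (length(sigma) == nAtoms) as.numeric(sigma)
  else .stopf("sigma must be a scalar or one value per atom")
}

# iid Gaussian displacement array, per-atom per-coordinate std sigma
.noiseArray <- function(nFrames, sigma) {
  n <- length(sigma)
  noise <- array(stats::rnorm(nFrames * n * 3), dim = c(nFrames, n, 3))
  if (any(sigma != sigma[1])) {
    noise <- sweep(noise, 2, sigma, "*")
  } else noise <- noise * sigma[1]
  noise
}

.truth <- function(labels = integer(0), offsets = list(), sigma = numeric(0),
                   gate = numeric(0), motions = list(),
                   P = matrix(numeric(0), 0, 0), slow = numeric(0)) {
  new("SyntheticTruth", stateLabels = as.integer(labels),
      stateOffsets = offsets, sigma = sigma, gateDistance = gate,
      rigidMotions = motions, transitionMatrix = P,
      visitedStates = sort(unique(as.integer(labels))),
      slowCoordinate = slow)
}

#' Harmonic-fluctuation trajectory
#'
#' Every frame is the template plus iid Gaussian displacement with
#' per-coordinate standard deviation `sigma[i]` for atom i -- the simplest
#' emulation of equilibrium fluctuation about a single basin. The planted
#' amplitudes give closed-form recovery targets (E[RMSF_i^2] = 3 sigma_i^2).
#'
#' @param template a [DimerTemplate-class]
#' @param sigma per-coordinate fluctuation std, Angstrom (scalar or per-atom)
#' @param nFrames number of frames (>= 1)
#' @param seed integer seed
#' @param dt ns per frame (default 1)
#' @return list with `trajectory` ([Trajectory-class]) and `truth`
#'   ([SyntheticTruth-class])
#' @export
simulateHarmonic <- function(template, sigma, nFrames, seed, dt = 1) {
  nFrames <- as.integer(nFrames)
  if (nFrames < 1) .stopf("nFrames must be >= 1")
  sig <- .sigmaVec(sigma, nAtoms(template))
  coordsArr <- .withSeed(seed, .noiseArray(nFrames, sig))
  coordsArr <- sweep(coordsArr, c(2, 3), template@coords, "+")
  list(trajectory = Trajectory(template@topology, coordsArr, dt = dt),
       truth = .truth(labels = rep(1L, nFrames),
                      offsets = list(matrix(0, nAtoms(template), 3)),
                      sigma = sig, P = matrix(1, 1, 1)))
}

#' Persistent cyclic Markov transition matrix
#'
#' State i stays with probability `1 - switchProb` and advances to
#' `i + 1 (mod K)` otherwise: the simplest persistent chain guaranteed to
#' visit every state once roughly `K / switchProb` frames have elapsed.
#'
#' @param K number of states
#' @param switchProb per-frame switching probability (default 0.01)
#' @return row-stochastic `K x K` matrix
#' @export
cyclicTransitionMatrix <- function(K, switchProb = 0.01) {
  P <- diag(1 - switchProb, K)
  if (K > 1) for (i in seq_len(K)) P[i, i %% K + 1] <- switchProb
  else P[1, 1] <- 1
  P
}

#' Metastable-state trajectory with planted sub-states
#'
#' A hidden first-order Markov chain over K states; frame t is the template
#' plus the current state's displacement field plus iid Gaussian noise.
#' State 1 has a zero offset; the other fields are random smooth
#' (low-frequency sinusoidal over atom index) displacements, rescaled until
#' every pair of states differs by at least `rmsdFloor` in superposed RMSD
#' over `floorSelection` -- so states remain separated after optimal
#' superposition, which arbitrary random vectors would not guarantee.
#'
#' @param template a [DimerTemplate-class]
#' @param K number of metastable states
#' @param transitionMatrix row-stochastic `K x K`; default
#'   `cyclicTransitionMatrix(K)`.
#' @param sigma within-state noise std, Angstrom
#' @param nFrames frames to generate
#' @param seed integer seed
#' @param rmsdFloor minimum pairwise superposed state RMSD, Angstrom
#' @param floorSelection selection on which the floor is enforced (default:
#'   helix alpha-carbons, the selection the downstream analyses use)
#' @param dt ns per frame
#' @return list with `trajectory` and `truth`; `truth` records labels,
#'   offsets, sigma and the transition matrix. States never visited under
#'   the chain are reported in `truth@visitedStates`, not as an error.
#' @export
simulateMetastable <- function(template, K, transitionMatrix = NULL,
                               sigma = 0.3, nFrames = 2000, seed = 1,
                               rmsdFloor = 6,
                               floorSelection = AtomSelection(), dt = 1) {
  K <- as.integer(K)
  if (K < 1) .stopf("K must be >= 1")
  if (is.null(transitionMatrix)) transitionMatrix <- cyclicTransitionMatrix(K)
  if (nrow(transitionMatrix) != K || ncol(transitionMatrix) != K ||
      max(abs(rowSums(transitionMatrix) - 1)) > 1e-12)
    .stopf("transitionMatrix must be row-stochastic %d x %d", K, K)
  n <- nAtoms(template)
  sig <- .sigmaVec(sigma, n)
  selIdx <- resolveSelection(template@topology, floorSelection)
  out <- .withSeed(seed, {
    offsets <- .plantedOffsets(template, K, selIdx, rmsdFloor)
    labels <- rep(1L, nFrames)
    # K = 1 draws no labels, so the generator reduces bit-exactly to
    # simulateHarmonic at the same seed.
    if (K > 1 && nFrames > 1) for (t in 2:nFrames)
      labels[t] <- sample.int(K, 1L, prob = transitionMatrix[labels[t - 1], ])
    noise <- .noiseArray(nFrames, sig)
    list(offsets = offsets, labels = labels, noise = noise)
  })
  coordsArr <- out$noise
  for (t in seq_len(nFrames))
    coordsArr[t, , ] <- coordsArr[t, , ] + template@coords + out$offsets[[out$labels[t]]]
  list(trajectory = Trajectory(template@topology, coordsArr, dt = dt),
       truth = .truth(labels = out$labels, offsets = out$offsets, sigma = sig,
                      P = transitionMatrix))
}

# Smooth random displacement fields for states 2..K, rescaled so that all
# pairwise superposed RMSDs over selIdx reach rmsdFloor. State 1 is zero.
.plantedOffsets <- function(template, K, selIdx, rmsdFloor) {
  n <- nAtoms(template)
  offsets <- vector("list", K)
  offsets[[1]] <- matrix(0, n, 3)
  if (K == 1) return(offsets)
  u <- seq_len(n) / n
  for (k in 2:K) {
    f <- matrix(0, n, 3)
    for (d in 1:3) for (h in 1:3)
      f[, d] <- f[, d] + stats::rnorm(1) * sin(2 * pi * h * u + stats::runif(1, 0, 2 * pi))
    f <- f / sqrt(mean(f^2))      # unit per-coordinate RMS
    offsets[[k]] <- f
  }
  base <- template@coords[selIdx, , drop = FALSE]
  scale <- rmsdFloor               # a reasonable starting magnitude
  minR <- -Inf
  for (iter in 1:40) {
    minR <- Inf
    for (i in 1:(K - 1)) for (j in (i + 1):K) {
      a <- base + scale * offsets[[i]][selIdx, , drop = FALSE]
      b <- base + scale * offsets[[j]][selIdx, , drop = FALSE]
      minR <- min(minR, rmsdPair(a, b, superpose = TRUE))
    }
    if (minR >= rmsdFloor) break
    scale <- scale * max(rmsdFloor / minR, 1.05)
  }
  if (minR < rmsdFloor)
    .stopf("could not separate planted states to %.2f Angstrom", rmsdFloor)
  for (k in 2:K) offsets[[k]] <- scale * offsets[[k]]
  offsets
}

#' Two-state pore gate trajectory
#'
#' A hidden two-state chain (state 1 = open at `dOpen`, state 2 = closed at
#' `dClosed`) drives a rigid translation of chain B along the gauge axis.
#' After iid per-atom noise is applied, chain B is translated along the
#' realized gauge axis so the gauge Ca-Ca distance equals the planted state
#' value plus a mean-zero axial Gaussian fluctuation of std
#' `sqrt(2) * sigma` (the distance noise two independently noised endpoints
#' carry). Planting the gauge coordinate this way keeps the planted values
#' recoverable as conditional means: naive 3-D endpoint noise would bias the
#' measured distance upward by ~`2 sigma^2 / d`. With `sigma = 0` the
#' measured gauge distance equals the planted value exactly.
#'
#' @param template a [DimerTemplate-class]
#' @param dOpen,dClosed planted open/closed gauge distances, Angstrom
#'   (`dOpen > dClosed > 0`)
#' @param switchProb per-frame probability of switching state (default 0.01)
#' @param sigma per-atom noise std, Angstrom
#' @param nFrames frames to generate
#' @param seed integer seed
#' @param dt ns per frame
#' @return list with `trajectory` and `truth`; `truth@gateDistance` holds the
#'   planted (two-valued) distance per frame, `truth@stateLabels` the hidden
#'   state (1 = open, 2 = closed).
#' @export
simulateGate <- function(template, dOpen = 12.5, dClosed = 8.0,
                         switchProb = 0.01, sigma = 0.3, nFrames = 5000,
                         seed = 1, dt = 1) {
  if (!(dOpen > dClosed && dClosed > 0)) .stopf("need dOpen > dClosed > 0")
  n <- nAtoms(template)
  sig <- .sigmaVec(sigma, n)
  chainB <- which(template@topology@atoms$chain ==
                  template@topology@atoms$chain[template@gaugePair[2]])
  gA <- template@gaugePair[1]; gB <- template@gaugePair[2]
  out <- .withSeed(seed, {
    switches <- stats::runif(nFrames) < switchProb
    noise <- .noiseArray(nFrames, sig)
    axial <- stats::rnorm(nFrames, sd = sqrt(2) * mean(sig))
    list(switches = switches, noise = noise, axial = axial)
  })
  labels <- integer(nFrames); labels[1] <- 1L
  if (nFrames > 1) for (t in 2:nFrames)
    labels[t] <- if (out$switches[t]) 3L - labels[t - 1] else labels[t - 1]
  planted <- ifelse(labels == 1L, dOpen, dClosed)
  coordsArr <- out$noise
  if (all(sig == 0)) out$axial <- rep(0, nFrames)
  for (t in seq_len(nFrames)) {
    fr <- coordsArr[t, , ] + template@coords
    g <- fr[gB, ] - fr[gA, ]
    cur <- sqrt(sum(g^2))
    target <- planted[t] + out$axial[t]
    fr[chainB, ] <- sweep(fr[chainB, , drop = FALSE], 2,
                          (target - cur) * g / cur, "+")
    coordsArr[t, , ] <- fr
  }
  P <- matrix(c(1 - switchProb, switchProb, switchProb, 1 - switchProb), 2, 2,
              byrow = TRUE)
  list(trajectory = Trajectory(template@topology, coordsArr, dt = dt),
       truth = .truth(labels = labels, sigma = sig, gate = planted, P = P))
}

#' Corrupt a trajectory with random per-frame rigid motions
#'
#' Each frame is independently rotated (rotation drawn uniformly from SO(3)
#' via normalized quaternions) and translated (components uniform in
#' [-20, 20] Angstrom). Used to test that superposed analyses are invariant
#' to how the trajectory happens to drift or be imaged.
#'
#' @param traj a [Trajectory-class]
#' @param seed integer seed
#' @return list with `trajectory` (corrupted) and `truth` whose
#'   `rigidMotions` records the applied [RigidTransform-class] per frame.
#' @export
applyRandomRigidMotion <- function(traj, seed) {
  nf <- nFrames(traj)
  motions <- .withSeed(seed, lapply(seq_len(nf), function(i) {
    R <- .randomRotation()
    new("RigidTransform", rotation = R,
        translation = stats::runif(3, -20, 20))
  }))
  coordsArr <- traj@coords
  for (i in seq_len(nf))
    coordsArr[i, , ] <- applyTransform(.frame(traj, i), motions[[i]])
  list(trajectory = new("Trajectory", topology = traj@topology,
                        coords = coordsArr, times = traj@times),
       truth = .truth(motions = motions))
}

#' Undo recorded rigid motions
#'
#' Analytically inverts the per-frame transforms recorded by
#' [applyRandomRigidMotion()], recovering the original coordinates.
#'
#' @param traj the corrupted [Trajectory-class]
#' @param truth the [SyntheticTruth-class] carrying `rigidMotions`
#' @return the restored [Trajectory-class]
#' @export
undoRigidMotions <- function(traj, truth) {
  if (length(truth@rigidMotions) != nFrames(traj))
    .stopf("truth records %d motions for %d frames",
           length(truth@rigidMotions), nFrames(traj))
  coordsArr <- traj@coords
  for (i in seq_len(nFrames(traj)))
    coordsArr[i, , ] <- applyTransform(.frame(traj, i),
                                       invertTransform(truth@rigidMotions[[i]]))
  new("Trajectory", topology = traj@topology, coords = coordsArr,
      times = traj@times)
}

#' Slow-plus-fast feature matrix
#'
#' Feature 1 is a discretized Ornstein-Uhlenbeck process with autocorrelation
#' time `slowTau` frames and unit stationary variance (lag-tau
#' autocorrelation `exp(-tau / slowTau)`); features `2..nFeatures` are iid
#' standard white noise. The planted slow coordinate is the recovery target
#' for tICA.
#'
#' @param nFeatures total number of features (>= 1)
#' @param slowTau autocorrelation time of the slow feature, frames
#' @param nFrames frames to generate
#' @param seed integer seed
#' @return list with `features` (a [FeatureMatrix-class]) and `truth` whose
#'   `slowCoordinate` is the planted slow process.
#' @export
simulateSlowFastFeatures <- function(nFeatures, slowTau, nFrames, seed) {
  if (slowTau < 1) .stopf("slowTau must be >= 1")
  rho <- exp(-1 / slowTau)
  m <- .withSeed(seed, {
    x0 <- stats::rnorm(1)
    e <- stats::rnorm(nFrames, sd = sqrt(1 - rho^2))
    slow <- as.numeric(stats::filter(e, rho, method = "recursive",
                                     init = x0))
    rest <- if (nFeatures > 1)
      matrix(stats::rnorm(nFrames * (nFeatures - 1)), nrow = nFrames)
    else NULL
    cbind(slow, rest, deparse.level = 0)
  })
  labels <- c("slow", if (nFeatures > 1) paste0("noise", seq_len(nFeatures - 1)))
  feats <- new("FeatureMatrix", values = unname(m), labels = labels,
               times = as.numeric(seq_len(nFrames) - 1))
  list(features = feats, truth = .truth(slow = m[, 1]))
}
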