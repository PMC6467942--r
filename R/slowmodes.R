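#' Dihedral-angle featurization
#'
#' Computes backbone dihedrals and encodes each as a (sin, cos) pair --
#' never the raw angle, which would carry a +/-180 degree wrap
#' discontinuity into the covariance estimates. Angles follow the IUPAC
#' sign convention (trans = 180 degrees, cis = 0).
#'
#' Modes:
#' * `"ca_pseudo"`: pseudo-dihedrals over consecutive Ca quadruplets within
#'   each annotated segment (never across chain breaks or segment gaps).
#'   Works for Ca-only models.
#' * `"phi_psi"`: backbone phi/psi; requires N, CA and C atoms per residue.
#'
#' @param traj a [Trajectory-class]
#' @param mode `"ca_pseudo"` (default) or `"phi_psi"`
#' @return a [FeatureMatrix-class] with two columns (sin, cos) per dihedral
#' @export
dihedralFeatures <- function(traj, mode = c("ca_pseudo", "phi_psi")) {
  mode <- match.arg(mode)
  quads <- if (mode == "ca_pseudo") .caPseudoQuads(traj@topology)
           else .phiPsiQuads(traj@topology)
  if (!nrow(quads$idx)) .stopf("no dihedrals found for mode '%s'", mode)
  nf <- nFrames(traj)
  nd <- nrow(quads$idx)
  vals <- matrix(NA_real_, nf, 2 * nd)
  labs <- character(2 * nd)
  for (d in seq_len(nd)) {
    ang <- .dihedralSeries(traj@coords, quads$idx[d, ])
    vals[, 2 * d - 1] <- sin(ang)
    vals[, 2 * d] <- cos(ang)
    labs[2 * d - 1] <- paste("sin", quads$label[d])
    labs[2 * d] <- paste("cos", quads$label[d])
  }
  new("FeatureMatrix", values = vals, labels = labs, times = traj@times)
}

# Dihedral angle (radians, IUPAC sign) for one atom quadruplet, all frames.
# coords: frames x atoms x 3 array; q: 4 atom indices.
.dihedralSeries <- function(coords, q) {
  p1 <- coords[, q[1], , drop = FALSE]; dim(p1) <- dim(p1)[c(1, 3)]
  p2 <- coords[, q[2], , drop = FALSE]; dim(p2) <- dim(p2)[c(1, 3)]
  p3 <- coords[, q[3], , drop = FALSE]; dim(p3) <- dim(p3)[c(1, 3)]
  p4 <- coords[, q[4], , drop = FALSE]; dim(p4) <- dim(p4)[c(1, 3)]
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross(n1, n2) * b2n)
  atan2(y, x)
}

.caPseudoQuads <- function(top) {
  a <- top@atoms
  seg <- top@segments
  if (!nrow(seg)) {
    # no annotation: treat each chain's contiguous residue runs as segments
    seg <- do.call(rbind, lapply(unique(a$chain), function(ch) {
      r <- sort(unique(a$resid[a$chain == ch]))
      brk <- c(0, which(diff(r) != 1), length(r))
      data.frame(chain = ch, first = r[utils::head(brk, -1) + 1],
                 last = r[brk[-1]], kind = "loop")
    }))
  }
  idx <- NULL; label <- character(0)
  for (i in seq_len(nrow(seg))) {
    ca <- which(a$chain == seg$chain[i] & a$name == "CA" &
                a$resid >= seg$first[i] & a$resid <= seg$last[i])
    ca <- ca[order(a$resid[ca])]
    if (length(ca) < 4) next
    for (s in seq_len(length(ca) - 3)) {
      idx <- rbind(idx, ca[s:(s + 3)])
      label <- c(label, sprintf("ca_pseudo chain%s resid%d",
                                seg$chain[i], a$resid[ca[s]]))
    }
  }
  list(idx = if (is.null(idx)) matrix(integer(0), 0, 4) else idx,
       label = label)
}

.phiPsiQuads <- function(top) {
  a <- top@atoms
  idx <- NULL; label <- character(0)
  missing <- character(0)
  for (ch in unique(a$chain)) {
    res <- sort(unique(a$resid[a$chain == ch]))
    at <- function(r, nm) {
      i <- which(a$chain == ch & a$resid == r & a$name == nm)
      if (length(i) != 1) NA_integer_ else i
    }
    N <- vapply(res, at, integer(1), nm = "N")
    CA <- vapply(res, at, integer(1), nm = "CA")
    C <- vapply(res, at, integer(1), nm = "C")
    bad <- res[is.na(N) | is.na(CA) | is.na(C)]
    if (length(bad))
      missing <- c(missing, sprintf("%s:%d", ch, bad))
    for (i in seq_along(res)) {
      if (res[i] %in% bad) next
      if (i > 1 && res[i - 1] == res[i] - 1 && !(res[i - 1] %in% bad)) {
        idx <- rbind(idx, c(C[i - 1], N[i], CA[i], C[i]))
        label <- c(label, sprintf("phi chain%s resid%d", ch, res[i]))
      }
      if (i < length(res) && res[i + 1] == res[i] + 1 && !(res[i + 1] %in% bad)) {
        idx <- rbind(idx, c(N[i], CA[i], C[i], N[i + 1]))
        label <- c(label, sprintf("psi chain%s resid%d", ch, res[i]))
      }
    }
  }
  if (length(missing))
    .stopf("phi_psi mode needs N/CA/C backbone atoms; missing for residues: %s",
           paste(missing, collapse = ", "))
  list(idx = if (is.null(idx)) matrix(integer(0), 0, 4) else idx,
       label = label)
}

#' Time-lagged independent component analysis
#'
#' Estimates the instantaneous covariance C0 and the lag-tau covariance Ct
#' over all valid frame pairs `(t, t + lag)` of a single contiguous
#' trajectory, symmetrizes Ct as `(Ct + Ct')/2`, ridge-regularizes C0, and
#' solves the generalized symmetric eigenproblem `Ct v = lambda C0 v`.
#' Leading components are the slowest-decorrelating linear combinations of
#' the features: their eigenvalues are lag-tau autocorrelations, so for a
#' planted Ornstein-Uhlenbeck mode with timescale tau0 the top eigenvalue
#' approaches `exp(-lag / tau0)`.
#'
#' C0 is averaged over the head and tail frame sets, which together with the
#' symmetrization keeps all eigenvalues in [-1, 1] on finite samples.
#'
#' @param features a [FeatureMatrix-class] or plain `frames x features`
#'   matrix
#' @param lag lag in frames (`n_frames > lag + 1`)
#' @param nComponents components to return (default: all)
#' @param regularization ridge added to C0; default `1e-6 * trace(C0)/dim`
#' @return a [TicaResult-class]
#' @export
tica <- function(features, lag, nComponents = NULL, regularization = NULL) {
  X <- if (is(features, "FeatureMatrix")) features@values else as.matrix(features)
  lag <- as.integer(lag)
  n <- nrow(X); p <- ncol(X)
  if (n <= lag + 1) .stopf("need n_frames > lag + 1 (n = %d, lag = %d)", n, lag)
  if (is.null(nComponents)) nComponents <- p
  m <- n - lag
  X0 <- X[seq_len(m), , drop = FALSE]
  Xl <- X[(lag + 1):n, , drop = FALSE]
  mu <- colMeans(rbind(X0, Xl))
  X0 <- sweep(X0, 2, mu); Xl <- sweep(Xl, 2, mu)
  C0 <- (crossprod(X0) + crossprod(Xl)) / (2 * m)
  Ct <- crossprod(X0, Xl) / m
  Ct <- (Ct + t(Ct)) / 2
  if (is.null(regularization)) regularization <- 1e-6 * sum(diag(C0)) / p
  C0r <- C0 + diag(regularization, p)
  e0 <- eigen(C0r, symmetric = TRUE)
  if (min(e0$values) <= 1e-12 * max(e0$values))
    .stopf("C0 is singular beyond the ridge; increase regularization or reduce features")
  W <- e0$vectors %*% diag(1 / sqrt(e0$values), p) %*% t(e0$vectors)
  M <- W %*% Ct %*% W
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  k <- as.integer(nComponents)
  vecs <- W %*% em$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  proj <- sweep(X, 2, mu) %*% vecs
  new("TicaResult", eigenvalues = em$values[seq_len(k)], vectors = vecs,
      projections = proj, lag = lag, regularization = regularization)
}

#' k-means clustering with representative frames
#'
#' k-means++ seeding under the given seed, then Lloyd iterations until the
#' relative inertia change falls below `tol` or `maxIter` is reached. A
#' cluster that empties during iteration is re-seeded at the point currently
#' farthest from its assigned centroid. Each cluster's representative frame
#' is its member nearest the centroid (ties to the lowest frame index).
#'
#' @param points `frames x d` matrix (e.g. tICA projections) or a
#'   [TicaResult-class]
#' @param k number of clusters (`k <= n_frames`); no automatic selection --
#'   the choice of k is the user's.
#' @param seed integer seed for the initialization
#' @param maxIter maximum Lloyd iterations (default 100)
#' @param tol relative inertia-change convergence threshold (default 1e-8)
#' @return a [ClusterRepresentatives-class]
#' @export
kmeansCluster <- function(points, k, seed, maxIter = 100L, tol = 1e-8) {
  P <- if (is(points, "TicaResult")) points@projections else as.matrix(points)
  k <- as.integer(k)
  n <- nrow(P)
  if (k < 1 || k > n) .stopf("need 1 <= k <= n_frames (k = %d, n = %d)", k, n)
  centers <- .withSeed(seed, .kmeansppInit(P, k))
  pn2 <- rowSums(P^2)
  assign <- integer(n); inertiaHist <- numeric(0); inertia <- Inf
  for (it in seq_len(maxIter)) {
    d2 <- .sqDistToCenters(P, centers, pn2)
    assign <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters at the farthest point
    repeat {
      sizes <- tabulate(assign, k)
      empty <- which(sizes == 0)
      if (!length(empty)) break
      near <- d2[cbind(seq_len(n), assign)]
      far <- which.max(near)
      centers[empty[1], ] <- P[far, ]
      d2 <- .sqDistToCenters(P, centers, pn2)
      assign <- max.col(-d2, ties.method = "first")
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(P[assign == j, , drop = FALSE])
    d2 <- .sqDistToCenters(P, centers, pn2)
    assign <- max.col(-d2, ties.method = "first")
    newInertia <- sum(d2[cbind(seq_len(n), assign)])
    inertiaHist <- c(inertiaHist, newInertia)
    if (is.finite(inertia) && (inertia - newInertia) <= tol * max(inertia, 1e-300)) {
      inertia <- newInertia
      break
    }
    inertia <- newInertia
  }
  d2 <- .sqDistToCenters(P, centers, pn2)
  reps <- vapply(seq_len(k), function(j) {
    memb <- which(assign == j)
    memb[which.min(d2[memb, j])]     # ties -> lowest frame index
  }, integer(1))
  new("ClusterRepresentatives", centroids = centers, assignments = assign,
      representatives = reps, inertia = inertia, inertiaHistory = inertiaHist)
}

.sqDistToCenters <- function(P, centers, pn2 = rowSums(P^2)) {
  d2 <- outer(pn2, rowSums(centers^2), "+") - 2 * P %*% t(centers)
  pmax(d2, 0)
}

.kmeansppInit <- function(P, k) {
  n <- nrow(P)
  centers <- matrix(NA_real_, k, ncol(P))
  centers[1, ] <- P[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums(sweep(P, 2, centers[1, ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) i <- sample.int(n, 1)
      else i <- sample.int(n, 1, prob = d2)
      centers[j, ] <- P[i, ]
      d2 <- pmin(d2, rowSums(sweep(P, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Extract representative frames as an aligned ensemble
#'
#' Builds a new trajectory containing each cluster's representative frame in
#' cluster order, rigid-body aligned to the first representative. Because
#' the ensemble is not a time series, frames are restamped 0, 1, 2, ... .
#'
#' @param traj the source [Trajectory-class]
#' @param reps a [ClusterRepresentatives-class]
#' @param sel selection used for the alignment (default: all atoms)
#' @return a [Trajectory-class] with one frame per cluster
#' @export
extractRepresentatives <- function(traj, reps,
                                   sel = AtomSelection(atomNames = NULL,
                                                       segmentKinds = NULL)) {
  idx <- reps@representatives
  if (any(idx < 1 | idx > nFrames(traj))) .stopf("representative index out of range")
  sub <- new("Trajectory", topology = traj@topology,
             coords = traj@coords[idx, , , drop = FALSE],
             times = as.numeric(seq_along(idx) - 1))
  alignTrajectory(sub, sel, reference = 1L)
}
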