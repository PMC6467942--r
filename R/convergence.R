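#' RMSD against a reference structure
#'
#' The classic first look at a trajectory: superposed RMSD of the selection
#' against a fixed reference (by default the starting structure) per frame.
#'
#' @param traj a [Trajectory-class]
#' @param sel an [AtomSelection-class]
#' @param reference a frame index (default 1) or an external `n x 3`
#'   coordinate matrix matching the selected atom count.
#' @param superpose optimally superpose each frame onto the reference first
#'   (default TRUE). `FALSE` gives the raw per-atom deviation, useful when
#'   frames are already aligned.
#' @return an [RmsdSeries-class]
#' @export
rmsdToReference <- function(traj, sel = AtomSelection(), reference = 1L,
                            superpose = TRUE) {
  idx <- resolveSelection(traj@topology, sel)
  if (is.matrix(reference)) {
    ref <- reference
    refDesc <- "external coordinates"
  } else {
    ref <- .frame(traj, as.integer(reference))[idx, , drop = FALSE]
    refDesc <- sprintf("frame %d", as.integer(reference))
  }
  if (nrow(ref) != length(idx))
    .stopf("reference has %d atoms but selection resolves to %d",
           nrow(ref), length(idx))
  vals <- vapply(seq_len(nFrames(traj)), function(i)
    rmsdPair(.frame(traj, i)[idx, , drop = FALSE], ref, superpose = superpose),
    numeric(1))
  new("RmsdSeries", times = traj@times, values = vals,
      selection = .describeSelection(sel), reference = refDesc)
}

.describeSelection <- function(sel) {
  fmt <- function(x) if (length(x)) paste(x, collapse = "+") else "*"
  sprintf("chains=%s names=%s kinds=%s", fmt(sel@chains), fmt(sel@atomNames),
          fmt(sel@segmentKinds))
}

#' All-to-all RMSD matrix
#'
#' The pairwise superposed RMSD between every pair of (strided) frames. Its
#' block structure exposes the sub-states a trajectory dwells in, which a
#' single-reference RMSD series cannot show. Only the upper triangle is
#' computed and mirrored. The matrix is O(frames^2): more than `maxFrames`
#' strided frames is refused with a suggested stride unless `force = TRUE`.
#'
#' @param traj a [Trajectory-class]
#' @param sel an [AtomSelection-class]
#' @param stride keep every stride-th frame (default 1)
#' @param maxFrames memory guard (default 20000)
#' @param force override the guard
#' @return an [RmsdMatrix-class]
#' @export
allToAllRmsd <- function(traj, sel = AtomSelection(), stride = 1L,
                         maxFrames = 20000L, force = FALSE) {
  idx <- resolveSelection(traj@topology, sel)
  keep <- seq(1L, nFrames(traj), by = as.integer(stride))
  m <- length(keep)
  if (m < 2) .stopf("all-to-all RMSD needs >= 2 frames after stride")
  if (m > maxFrames && !force)
    .stopf("%d frames would give a %dx%d matrix; use stride >= %d or force = TRUE",
           m, m, m, ceiling(nFrames(traj) / maxFrames))
  # precentred selected coordinates per frame
  fr <- lapply(keep, function(i) {
    x <- .frame(traj, i)[idx, , drop = FALSE]
    sweep(x, 2, colMeans(x))
  })
  n <- length(idx)
  mat <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    A <- fr[[i]]
    for (j in (i + 1):m) {
      B <- fr[[j]]
      s <- svd(crossprod(A, B))
      d <- sign(det(s$u) * det(s$v))
      R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
      mat[i, j] <- mat[j, i] <- sqrt(sum((A %*% R - B)^2) / n)
    }
  }
  new("RmsdMatrix", frames = keep, times = traj@times[keep], values = mat)
}

#' Sequential (leader) cluster counting
#'
#' Frames are processed in time order. Each frame computes its superposed
#' RMSD to the representative (founding frame) of every existing cluster; if
#' the minimum is within the cutoff it joins the nearest cluster (ties go to
#' the lowest cluster id), otherwise it founds a new cluster and becomes its
#' representative. Representatives are never updated, so the cumulative
#' count curve c(t) records first visits to new conformational sub-states;
#' its plateau indicates sampling saturation.
#'
#' Assignment uses the nearest representative within the cutoff (not the
#' first found), making the result robust to cluster founding order; cutoff
#' comparisons use `<=`.
#'
#' @param traj a [Trajectory-class]
#' @param sel an [AtomSelection-class]
#' @param cutoff RMSD cutoff in Angstrom (default 2.0)
#' @return a [ClusterTrace-class]
#' @export
leaderClusterCount <- function(traj, sel = AtomSelection(), cutoff = 2.0) {
  if (cutoff <= 0) .stopf("cutoff must be > 0")
  idx <- resolveSelection(traj@topology, sel)
  nf <- nFrames(traj)
  n <- length(idx)
  fr <- lapply(seq_len(nf), function(i) {
    x <- .frame(traj, i)[idx, , drop = FALSE]
    sweep(x, 2, colMeans(x))
  })
  assignments <- integer(nf)
  reps <- integer(0)
  counts <- integer(nf)
  for (t in seq_len(nf)) {
    if (length(reps)) {
      B <- fr[[t]]
      d <- vapply(reps, function(r) {
        A <- fr[[r]]
        s <- svd(crossprod(A, B))
        dd <- sign(det(s$u) * det(s$v))
        R <- s$u %*% diag(c(1, 1, dd)) %*% t(s$v)
        sqrt(sum((A %*% R - B)^2) / n)
      }, numeric(1))
      best <- which.min(d)     # ties -> lowest cluster id
      if (d[best] <= cutoff) {
        assignments[t] <- best
      } else {
        reps <- c(reps, t)
        assignments[t] <- length(reps)
      }
    } else {
      reps <- t
      assignments[t] <- 1L
    }
    counts[t] <- length(reps)
  }
  new("ClusterTrace", assignments = assignments, representatives = reps,
      countCurve = counts, cutoff = cutoff, times = traj@times)
}

#' Plateau time of a cluster-count curve
#'
#' The timestamp of the founding frame of the last-founded cluster: after
#' this time no new conformational sub-state appears, the operational
#' definition of sampling saturation used with cluster counting.
#'
#' @param trace a [ClusterTrace-class]
#' @return time in ns
#' @export
plateauTime <- function(trace) {
  trace@times[max(trace@representatives)]
}

#' GROMOS-style neighbour clustering
#'
#' The post-hoc clustering of Daura and colleagues: repeatedly take the frame
#' with the most neighbours within the cutoff (ties to the lowest frame
#' index) as a cluster centre, remove it and its neighbours, and continue
#' until no frames remain. Operates on a precomputed [RmsdMatrix-class].
#'
#' @param mat an [RmsdMatrix-class]
#' @param cutoff RMSD cutoff in Angstrom (comparisons use `<=`)
#' @return list with `members` (list of integer vectors, frame indices into
#'   the matrix, in extraction order) and `centers` (integer vector of the
#'   central frames).
#' @export
gromosCluster <- function(mat, cutoff = 2.0) {
  nb <- mat@values <= cutoff
  alive <- rep(TRUE, nrow(nb))
  members <- list(); centers <- integer(0)
  while (any(alive)) {
    counts <- rowSums(nb[, alive, drop = FALSE]) * alive
    center <- which.max(counts)   # ties -> lowest frame index
    grp <- which(nb[center, ] & alive)
    members[[length(members) + 1]] <- grp
    centers <- c(centers, center)
    alive[grp] <- FALSE
  }
  list(members = members, centers = centers)
}

#' Cartesian-coordinate principal component analysis (essential dynamics)
#'
#' Frames are aligned to the mean structure (two-pass, see
#' [alignTrajectory()]), selected coordinates flattened to a `3n` vector per
#' frame, mean-centred, and the population covariance (1/n normalization)
#' diagonalized. Leading components capture the largest-amplitude collective
#' motions; scattered projections show whether new regions of conformational
#' space keep appearing. Eigenvector signs are fixed by making each vector's
#' largest-magnitude coefficient positive, so output is deterministic across
#' linear-algebra backends.
#'
#' @param traj a [Trajectory-class]
#' @param sel an [AtomSelection-class]
#' @param nComponents components to return (default 2)
#' @param align align to the mean structure first (default TRUE; set FALSE
#'   only if frames are already aligned)
#' @return a [ProjectionResult-class]; if `nComponents` exceeds the data
#'   rank the trailing ~0-eigenvalue components are returned and
#'   `rankDeficient` is flagged (with a warning).
#' @export
coordinatePca <- function(traj, sel = AtomSelection(), nComponents = 2L,
                          align = TRUE) {
  idx <- resolveSelection(traj@topology, sel)
  nComponents <- as.integer(nComponents)
  if (nComponents < 1) .stopf("nComponents must be >= 1")
  if (nComponents > 3 * length(idx))
    .stopf("nComponents (%d) exceeds 3 x selected atoms (%d)",
           nComponents, 3 * length(idx))
  if (align) traj <- alignTrajectory(traj, sel, reference = "mean")
  X <- .flattenCoords(traj@coords[, idx, , drop = FALSE])
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nrow(Xc)
  e <- eigen(C, symmetric = TRUE)
  evals <- pmax(e$values, 0)
  vecs <- e$vectors[, seq_len(nComponents), drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  total <- sum(evals)
  rank <- sum(evals > max(evals[1], .Machine$double.eps) * 1e-10)
  rankDef <- nComponents > rank
  if (rankDef)
    warning(sprintf("requested %d components but data rank is ~%d; trailing eigenvalues are ~0",
                    nComponents, rank), call. = FALSE)
  new("ProjectionResult",
      vectors = vecs,
      eigenvalues = evals[seq_len(nComponents)],
      projections = Xc %*% vecs,
      explainedVariance = evals[seq_len(nComponents)] / total,
      totalVariance = total,
      rankDeficient = rankDef)
}
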