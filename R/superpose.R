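#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `mobile`
#' onto `reference` via singular value decomposition of the cross-covariance,
#' with the determinant sign correction that excludes reflections. All atoms
#' carry unit weight.
#'
#' The returned transform applies to row-vector coordinates:
#' `aligned = mobile %*% rotation + translation`.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`.
#' @return list with elements `transform` (a [RigidTransform-class]) and
#'   `rmsd` (the minimized RMSD, Angstrom).
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' kabsch(x, x)$rmsd   # 0
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    .stopf("mobile is %dx%d but reference is %dx%d",
           nrow(mobile), ncol(mobile), nrow(reference), ncol(reference))
  n <- nrow(mobile)
  if (n < 3) .stopf("superposition needs at least 3 atoms, got %d", n)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  s <- svd(H)
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    warning("near-collinear coordinates: rotation is rank-deficient",
            call. = FALSE)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- A %*% R
  rmsd <- sqrt(sum((aligned - B)^2) / n)
  tr <- new("RigidTransform", rotation = R, translation = as.numeric(cr - cm %*% R))
  list(transform = tr, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param coords `n x 3` matrix
#' @param transform a [RigidTransform-class]
#' @return transformed `n x 3` matrix
#' @export
applyTransform <- function(coords, transform) {
  sweep(coords %*% transform@rotation, 2, transform@translation, "+")
}

#' Invert a rigid transform
#' @param transform a [RigidTransform-class]
#' @return the inverse [RigidTransform-class]
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  new("RigidTransform", rotation = Rt,
      translation = as.numeric(-transform@translation %*% Rt))
}

#' RMSD between two coordinate sets
#'
#' With `superpose = TRUE` (default) the Kabsch-minimized RMSD; otherwise the
#' raw root-mean-square deviation of corresponding atoms.
#'
#' @param a,b `n x 3` coordinate matrices
#' @param superpose optimally superpose first?
#' @return RMSD in Angstrom
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
#' rmsdPair(sq, sweep(sq, 2, c(3, 4, 0), "+"), superpose = FALSE)  # 5
#' rmsdPair(sq, sweep(sq, 2, c(3, 4, 0), "+"))                     # ~0
#' @export
rmsdPair <- function(a, b, superpose = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    .stopf("coordinate sets differ in shape: %dx%d vs %dx%d",
           nrow(a), ncol(a), nrow(b), ncol(b))
  if (superpose) return(kabsch(a, b)$rmsd)
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Align every frame of a trajectory to a reference
#'
#' The Kabsch transform is computed on the selection only, then applied to
#' all atoms of the frame. `reference = "mean"` uses the documented two-pass
#' procedure: align to frame 1, compute the mean selection structure,
#' re-align to that mean (exactly one refinement pass, so results are
#' bit-reproducible).
#'
#' @param traj a [Trajectory-class]
#' @param sel an [AtomSelection-class] (needs >= 3 atoms)
#' @param reference a frame index (default 1) or `"mean"`
#' @return the aligned [Trajectory-class]
#' @export
alignTrajectory <- function(traj, sel = AtomSelection(), reference = 1L) {
  idx <- resolveSelection(traj@topology, sel)
  if (length(idx) < 3) .stopf("alignment selection has %d atoms; need >= 3",
                              length(idx))
  if (identical(reference, "mean")) {
    pass1 <- .alignToCoords(traj, idx, .frame(traj, 1)[idx, , drop = FALSE])
    mref <- apply(pass1@coords[, idx, , drop = FALSE], c(2, 3), mean)
    return(.alignToCoords(pass1, idx, mref))
  }
  ref <- .frame(traj, as.integer(reference))[idx, , drop = FALSE]
  .alignToCoords(traj, idx, ref)
}

# Hot path: same Kabsch rotation as kabsch(), without per-frame S4 object
# construction (validity checks on tens of thousands of frames dominate
# otherwise).
.alignToCoords <- function(traj, idx, refSel) {
  out <- traj@coords
  cr <- colMeans(refSel)
  B <- sweep(refSel, 2, cr)
  for (i in seq_len(nFrames(traj))) {
    fr <- out[i, , ]
    sel <- fr[idx, , drop = FALSE]
    cm <- colMeans(sel)
    s <- svd(crossprod(sweep(sel, 2, cm), B))
    if (det(s$u) * det(s$v) < 0) s$u[, 3] <- -s$u[, 3]
    R <- tcrossprod(s$u, s$v)
    out[i, , ] <- sweep(fr %*% R, 2, cr - cm %*% R, "+")
  }
  new("Trajectory", topology = traj@topology, coords = out, times = traj@times)
}
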