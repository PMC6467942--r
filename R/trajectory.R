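#' Construct a Trajectory
#'
#' @param topology a [Topology-class]
#' @param coords numeric array `frames x atoms x 3` (Angstrom), or a single
#'   `atoms x 3` matrix for a one-frame trajectory.
#' @param times per-frame timestamps in ns; defaults to `0, dt, 2 dt, ...`.
#' @param dt default timestep in ns used when `times` is not given (default 1,
#'   i.e. frame units; the frame-to-ns mapping is always user-supplied, never
#'   inferred).
#' @return a [Trajectory-class]
#' @export
Trajectory <- function(topology, coords, times = NULL, dt = 1) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, dim(coords)))
  if (is.null(times)) times <- (seq_len(dim(coords)[1]) - 1) * dt
  new("Trajectory", topology = topology, coords = coords,
      times = as.numeric(times))
}

#' Remove solvent residues from a trajectory
#'
#' Drops every atom whose residue name is in `solventResnames`, preserving
#' the order of the remaining atoms. Periodic reimaging is not performed
#' here: inputs are required to be pre-imaged/whole (see
#' [checkImagingArtifacts()]).
#'
#' @param traj a [Trajectory-class]
#' @param solventResnames character vector of residue names to strip
#'   (e.g. `c("HOH", "WAT", "NA", "CL")`).
#' @return a [Trajectory-class] without the solvent atoms
#' @export
stripSolvent <- function(traj, solventResnames = c("HOH", "WAT")) {
  keep <- !(traj@topology@atoms$resname %in% solventResnames)
  if (!any(keep))
    .stopf("stripping {%s} would remove every atom",
           paste(solventResnames, collapse = ", "))
  if (all(keep)) return(traj)
  top <- traj@topology
  top@atoms <- top@atoms[keep, , drop = FALSE]
  rownames(top@atoms) <- NULL
  validObject(top)
  new("Trajectory", topology = top,
      coords = traj@coords[, keep, , drop = FALSE], times = traj@times)
}

#' Subsample a trajectory by a fixed stride
#'
#' Keeps frames `1, 1+stride, 1+2*stride, ...` with their original
#' timestamps.
#'
#' @param traj a [Trajectory-class]
#' @param stride integer >= 1
#' @return a [Trajectory-class]
#' @export
subsampleTrajectory <- function(traj, stride) {
  stride <- as.integer(stride)
  if (stride < 1) .stopf("stride must be >= 1")
  keep <- seq(1L, nFrames(traj), by = stride)
  new("Trajectory", topology = traj@topology,
      coords = traj@coords[keep, , , drop = FALSE], times = traj@times[keep])
}

#' Flag probable periodic-imaging artifacts
#'
#' Reimaging is out of scope here (it needs box and bond data), so inputs
#' must arrive pre-imaged. This validator flags any atom that jumps by more
#' than half a declared box length between consecutive frames -- the
#' signature of a molecule wrapping across the periodic boundary.
#'
#' @param traj a [Trajectory-class]
#' @param box numeric length-3 declared box lengths (Angstrom)
#' @return invisibly, a data.frame of offending `(frame, atom, jump_A)` rows
#'   (zero rows when clean); a warning is raised when any are found.
#' @export
checkImagingArtifacts <- function(traj, box) {
  stopifnot(length(box) == 3, all(box > 0))
  n <- nFrames(traj)
  bad <- list()
  lim <- 0.5 * min(box)
  if (n > 1) {
    for (i in 2:n) {
      d <- sqrt(rowSums((.frame(traj, i) - .frame(traj, i - 1))^2))
      hit <- which(d > lim)
      if (length(hit))
        bad[[length(bad) + 1]] <- data.frame(frame = i, atom = hit,
                                             jump_A = d[hit])
    }
  }
  out <- if (length(bad)) do.call(rbind, bad) else
    data.frame(frame = integer(0), atom = integer(0), jump_A = numeric(0))
  if (nrow(out))
    warning(sprintf("%d inter-frame jumps exceed half the box length; input may not be reimaged",
                    nrow(out)), call. = FALSE)
  invisible(out)
}

# Subset a trajectory to an atom-index vector (keeps segment table).
.subsetAtoms <- function(traj, idx) {
  top <- traj@topology
  top@atoms <- top@atoms[idx, , drop = FALSE]
  rownames(top@atoms) <- NULL
  new("Trajectory", topology = top,
      coords = traj@coords[, idx, , drop = FALSE], times = traj@times)
}
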