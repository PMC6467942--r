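#' Read a topology plus coordinate trajectory
#'
#' Supported dialects:
#' * `"pdb"` -- multi-model PDB (MODEL/ENDMDL). The topology is taken from
#'   `topologySource`; coordinates from `trajectorySource` (which may be the
#'   same file).
#' * `"xyz"` -- plain XYZ-per-frame text: per frame one line `n_atoms`, one
#'   comment line `t=<ns>`, then `n_atoms` lines `name x y z`. Topology from
#'   a PDB `topologySource`.
#' * `"dcd"` -- CHARMM/NAMD binary DCD (read-only), topology from PDB.
#' * `"xtc"` -- not supported by this build; a clear error is raised.
#'
#' PDB and DCD carry no time metadata, so frame times default to
#' `0, dt, 2 dt, ...`; the frame-to-ns mapping is user-supplied via `dt`,
#' never inferred. XYZ frame times are read from the `t=` comment lines.
#'
#' @param topologySource path to a PDB file defining the atoms.
#' @param trajectorySource path to the coordinate file; defaults to
#'   `topologySource` (multi-model PDB case).
#' @param dialect one of `"pdb"`, `"xyz"`, `"dcd"`, `"xtc"`.
#' @param segments optional segment annotation data.frame
#'   (`chain`, `first`, `last`, `kind`) attached to the topology.
#' @param dt default timestep (ns per frame) when the file has no times.
#' @return a [Trajectory-class]
#' @export
readTrajectory <- function(topologySource, trajectorySource = topologySource,
                           dialect = c("pdb", "xyz", "dcd", "xtc"),
                           segments = NULL, dt = 1) {
  dialect <- match.arg(dialect)
  if (dialect == "xtc")
    .stopf("dialect 'xtc' is not supported by this build; convert to pdb, xyz or dcd")
  if (!file.exists(topologySource)) .stopf("no such file: %s", topologySource)
  if (!file.exists(trajectorySource)) .stopf("no such file: %s", trajectorySource)
  top <- .readPdbTopology(topologySource, segments)
  n <- nAtoms(top)
  if (dialect == "pdb") {
    .checkPdbModels(trajectorySource, n)
    pdb <- bio3d::read.pdb(trajectorySource, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    coordsArr <- .xyzToArray(xyz, n, trajectorySource)
    return(Trajectory(top, coordsArr, dt = dt))
  }
  if (dialect == "dcd") {
    xyz <- bio3d::read.dcd(trajectorySource, verbose = FALSE)
    coordsArr <- .xyzToArray(unclass(xyz), n, trajectorySource)
    return(Trajectory(top, coordsArr, dt = dt))
  }
  .readXyzTrajectory(trajectorySource, top)
}

#' Write a trajectory
#'
#' `"pdb"` writes a multi-model PDB (coordinates at the format's 1e-3
#' Angstrom precision, serials preserved); `"xyz"` writes the plain
#' XYZ-per-frame dialect described in [readTrajectory()] (1e-6 precision,
#' including frame times).
#'
#' @param traj a [Trajectory-class]
#' @param file output path
#' @param dialect `"pdb"` or `"xyz"`
#' @return the path, invisibly
#' @export
writeTrajectory <- function(traj, file, dialect = c("pdb", "xyz")) {
  dialect <- match.arg(dialect)
  a <- traj@topology@atoms
  if (dialect == "pdb") {
    xyz <- .flattenCoords(traj@coords)
    bio3d::write.pdb(file = file, xyz = xyz, resno = a$resid, resid = a$resname,
                     eleno = a$serial, elety = a$name, chain = a$chain)
  } else {
    n <- nAtoms(traj)
    con <- file(file, "w")
    on.exit(close(con))
    for (i in seq_len(nFrames(traj))) {
      writeLines(c(as.character(n), sprintf("t=%.9g", traj@times[i])), con)
      fr <- .frame(traj, i)
      writeLines(sprintf("%s %.6f %.6f %.6f", a$name, fr[, 1], fr[, 2], fr[, 3]),
                 con)
    }
  }
  invisible(file)
}

# ---- internals ------------------------------------------------------------

.readPdbTopology <- function(path, segments = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) .stopf("cannot parse PDB %s: %s",
                                             path, conditionMessage(e)))
  a <- pdb$atom
  Topology(data.frame(serial = a$eleno, name = a$elety, resname = a$resid,
                      resid = a$resno,
                      chain = ifelse(is.na(a$chain), "A", a$chain)),
           segments)
}

# Pre-scan a multi-model PDB: per-model atom counts must equal `n`; errors
# name the offending frame (model) and carry the line number when a record
# is unparseable.
.checkPdbModels <- function(path, n) {
  lines <- readLines(path)
  isAtom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  bad <- which(isAtom & nchar(lines) < 54)
  if (length(bad))
    .stopf("unparseable ATOM record at line %d of %s", bad[1], path)
  modelStarts <- which(startsWith(lines, "MODEL"))
  if (!length(modelStarts)) {
    cnt <- sum(isAtom)
    if (cnt != n)
      .stopf("frame 1 of %s has %d atoms but topology has %d", path, cnt, n)
    return(invisible(1L))
  }
  modelEnds <- which(startsWith(lines, "ENDMDL"))
  if (length(modelEnds) != length(modelStarts))
    .stopf("unbalanced MODEL/ENDMDL records in %s", path)
  for (m in seq_along(modelStarts)) {
    cnt <- sum(isAtom[modelStarts[m]:modelEnds[m]])
    if (cnt != n)
      .stopf("frame %d of %s has %d atoms but topology has %d", m, path, cnt, n)
  }
  invisible(length(modelStarts))
}

.xyzToArray <- function(xyz, n, path) {
  if (ncol(xyz) != 3 * n)
    .stopf("%s has %d coordinates per frame but topology has %d atoms",
           path, ncol(xyz), n)
  .unflattenCoords(xyz, n)
}

.readXyzTrajectory <- function(path, top) {
  lines <- readLines(path)
  n <- nAtoms(top)
  framesPer <- n + 2L
  if (length(lines) %% framesPer != 0)
    .stopf("%s: %d lines is not a multiple of %d (n_atoms + 2)",
           path, length(lines), framesPer)
  nf <- length(lines) %/% framesPer
  coordsArr <- array(NA_real_, dim = c(nf, n, 3))
  times <- numeric(nf)
  for (f in seq_len(nf)) {
    off <- (f - 1L) * framesPer
    cnt <- suppressWarnings(as.integer(lines[off + 1L]))
    if (is.na(cnt))
      .stopf("%s: unparseable atom count at line %d", path, off + 1L)
    if (cnt != n)
      .stopf("frame %d of %s has %d atoms but topology has %d", f, path, cnt, n)
    tl <- lines[off + 2L]
    if (!startsWith(tl, "t="))
      .stopf("%s: missing 't=' comment at line %d", path, off + 2L)
    times[f] <- as.numeric(substring(tl, 3))
    for (i in seq_len(n)) {
      parts <- strsplit(trimws(lines[off + 2L + i]), "[[:space:]]+")[[1]]
      if (length(parts) != 4)
        .stopf("%s: unparseable atom record at line %d", path, off + 2L + i)
      coordsArr[f, i, ] <- as.numeric(parts[2:4])
    }
  }
  if (any(!is.finite(coordsArr)))
    .stopf("%s: non-numeric coordinates", path)
  Trajectory(top, coordsArr, times = times)
}

#' Write the synthetic ground truth as JSON
#'
#' @param truth a [SyntheticTruth-class]
#' @param file output path
#' @return the path, invisibly
#' @export
writeTruth <- function(truth, file) {
  x <- list(
    state_labels = truth@stateLabels,
    sigma = truth@sigma,
    gate_distance = truth@gateDistance,
    transition_matrix = truth@transitionMatrix,
    visited_states = truth@visitedStates,
    state_offsets = lapply(truth@stateOffsets, unname),
    slow_coordinate = truth@slowCoordinate)
  jsonlite::write_json(x, file, digits = NA, auto_unbox = FALSE)
  invisible(file)
}
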