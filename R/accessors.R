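#' @describeIn nFrames frames in a trajectory
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' @describeIn nFrames frames covered by an RMSD matrix
#' @export
setMethod("nFrames", "RmsdMatrix", function(x) nrow(x@values))

#' @describeIn nFrames rows of a feature matrix
#' @export
setMethod("nFrames", "FeatureMatrix", function(x) nrow(x@values))

#' @describeIn nAtoms atoms in a topology
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @describeIn nAtoms atoms in a trajectory
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[2])

#' @describeIn nAtoms atoms in a dimer template
#' @export
setMethod("nAtoms", "DimerTemplate", function(x) nrow(x@coords))

#' @describeIn frameTimes trajectory timestamps
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @describeIn frameTimes series timestamps
#' @export
setMethod("frameTimes", "RmsdSeries", function(x) x@times)

#' @describeIn frameTimes gauge timestamps
#' @export
setMethod("frameTimes", "GaugeSeries", function(x) x@times)

#' @describeIn frameTimes cluster-trace timestamps
#' @export
setMethod("frameTimes", "ClusterTrace", function(x) x@times)

#' @describeIn coords trajectory coordinate array
#' @export
setMethod("coords", "Trajectory", function(x) x@coords)

#' @describeIn coords template coordinates
#' @export
setMethod("coords", "DimerTemplate", function(x) x@coords)

#' @describeIn topology of a trajectory
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @describeIn topology of a dimer template
#' @export
setMethod("topology", "DimerTemplate", function(x) x@topology)

#' @describeIn eigenvalues PCA eigenvalues (Angstrom^2)
#' @export
setMethod("eigenvalues", "ProjectionResult", function(x) x@eigenvalues)

#' @describeIn eigenvalues tICA eigenvalues (autocorrelations)
#' @export
setMethod("eigenvalues", "TicaResult", function(x) x@eigenvalues)

#' @describeIn projections PCA projections
#' @export
setMethod("projections", "ProjectionResult", function(x) x@projections)

#' @describeIn projections tICA projections
#' @export
setMethod("projections", "TicaResult", function(x) x@projections)

#' @describeIn values RMSD series values (Angstrom)
#' @export
setMethod("values", "RmsdSeries", function(x) x@values)

#' @describeIn values RMSD matrix (Angstrom)
#' @export
setMethod("values", "RmsdMatrix", function(x) x@values)

#' @describeIn values RMSF per residue (Angstrom)
#' @export
setMethod("values", "RmsfProfile", function(x) x@values)

#' @describeIn values gauge distances (Angstrom)
#' @export
setMethod("values", "GaugeSeries", function(x) x@values)

#' @describeIn values feature matrix values
#' @export
setMethod("values", "FeatureMatrix", function(x) x@values)

#' @describeIn assignments leader-cluster assignment per frame
#' @export
setMethod("assignments", "ClusterTrace", function(x) x@assignments)

#' @describeIn assignments k-means assignment per frame
#' @export
setMethod("assignments", "ClusterRepresentatives", function(x) x@assignments)

#' @describeIn representatives founding frames of leader clusters
#' @export
setMethod("representatives", "ClusterTrace", function(x) x@representatives)

#' @describeIn representatives frames nearest each k-means centroid
#' @export
setMethod("representatives", "ClusterRepresentatives", function(x) x@representatives)

#' @describeIn countCurve cumulative cluster count after each frame
#' @export
setMethod("countCurve", "ClusterTrace", function(x) x@countCurve)

#' @export
setMethod("show", "Topology", function(object) {
  cat(sprintf("Topology: %d atoms, %d chains, %d segments\n",
              nrow(object@atoms), length(unique(object@atoms$chain)),
              nrow(object@segments)))
})

#' @export
setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %.4g..%.4g ns\n",
              d[1], d[2], object@times[1], object@times[d[1]]))
})

#' @export
setMethod("show", "AtomSelection", function(object) {
  fmt <- function(x) if (length(x)) paste(x, collapse = ",") else "*"
  cat(sprintf("AtomSelection: chains=%s names=%s kinds=%s ranges=%d\n",
              fmt(object@chains), fmt(object@atomNames),
              fmt(object@segmentKinds), nrow(object@residRanges)))
})

#' @export
setMethod("show", "DimerTemplate", function(object) {
  cat(sprintf("DimerTemplate: %d Ca atoms, gauge pair (%d, %d) at %.3f Angstrom\n",
              nrow(object@coords), object@gaugePair[1], object@gaugePair[2],
              sqrt(sum((object@coords[object@gaugePair[1], ] -
                        object@coords[object@gaugePair[2], ])^2))))
})

#' @export
setMethod("show", "RmsdSeries", function(object) {
  cat(sprintf("RmsdSeries: %d frames, mean %.3f Angstrom (ref: %s)\n",
              length(object@values), mean(object@values), object@reference))
})

#' @export
setMethod("show", "RmsdMatrix", function(object) {
  cat(sprintf("RmsdMatrix: %d x %d, max %.3f Angstrom\n",
              nrow(object@values), ncol(object@values), max(object@values)))
})

#' @export
setMethod("show", "ClusterTrace", function(object) {
  cat(sprintf("ClusterTrace: %d frames, %d clusters (cutoff %.2f Angstrom), plateau %.4g ns\n",
              length(object@assignments), max(object@assignments),
              object@cutoff, plateauTime(object)))
})

#' @export
setMethod("show", "ProjectionResult", function(object) {
  cat(sprintf("ProjectionResult: %d components, explained %s\n",
              length(object@eigenvalues),
              paste(sprintf("%.3f", object@explainedVariance), collapse = " ")))
})

#' @export
setMethod("show", "RmsfProfile", function(object) {
  cat(sprintf("RmsfProfile: %d residues, mean %.3f Angstrom\n",
              length(object@values), mean(object@values)))
})

#' @export
setMethod("show", "TicaResult", function(object) {
  cat(sprintf("TicaResult: lag %d, eigenvalues %s\n", object@lag,
              paste(sprintf("%.3f", utils::head(object@eigenvalues, 5)),
                    collapse = " ")))
})

#' @export
setMethod("show", "ClusterRepresentatives", function(object) {
  cat(sprintf("ClusterRepresentatives: k=%d, inertia %.4g\n",
              nrow(object@centroids), object@inertia))
})

#' @export
setMethod("show", "GaugeSeries", function(object) {
  cat(sprintf("GaugeSeries [%s]: %d frames, mean %.3f Angstrom\n",
              object@definition, length(object@values), mean(object@values)))
})

#' @export
setMethod("show", "ReportBundle", function(object) {
  ok <- vapply(object@stages, function(s) !(is.list(s) && isTRUE(s$skipped)),
               logical(1))
  cat(sprintf("ReportBundle: %d/%d stages completed\n", sum(ok), length(ok)))
  for (k in names(object@summary))
    cat(sprintf("  %s: %s\n", k, paste(format(object@summary[[k]]), collapse = " ")))
})

#' Tabular views of result objects
#'
#' `as.data.frame` methods matching the CSV schemas the report writer uses.
#' @param x a result object
#' @param ... ignored
#' @return data.frame
#' @name as.data.frame-methods
NULL

#' @rdname as.data.frame-methods
#' @export
as.data.frame.RmsdSeries <- function(x, ...)
  data.frame(time_ns = x@times, rmsd_A = x@values)

#' @rdname as.data.frame-methods
#' @export
as.data.frame.ClusterTrace <- function(x, ...) {
  isNew <- seq_along(x@assignments) %in% x@representatives
  data.frame(frame = seq_along(x@assignments), time_ns = x@times,
             cluster_id = x@assignments, is_new = isNew,
             cumulative_count = x@countCurve)
}

#' @rdname as.data.frame-methods
#' @export
as.data.frame.RmsfProfile <- function(x, ...)
  data.frame(chain = x@chain, resid = x@resid, rmsf_A = x@values)

#' @rdname as.data.frame-methods
#' @export
as.data.frame.GaugeSeries <- function(x, ...)
  data.frame(time_ns = x@times, distance_A = x@values)
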