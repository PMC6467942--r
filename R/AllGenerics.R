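#' Number of frames
#' @param x a [Trajectory-class], [RmsdMatrix-class] or [FeatureMatrix-class]
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms
#' @param x a [Trajectory-class], [Topology-class] or [DimerTemplate-class]
#' @return integer
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Per-frame timestamps (ns)
#' @param x an object with a time axis
#' @return numeric vector
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Coordinates
#' @param x a [Trajectory-class] (returns `frames x atoms x 3`) or
#'   [DimerTemplate-class] (returns `atoms x 3`)
#' @return numeric array or matrix, Angstrom
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Topology of an object
#' @param x a [Trajectory-class] or [DimerTemplate-class]
#' @return a [Topology-class]
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Eigenvalues of a decomposition
#' @param x a [ProjectionResult-class] or [TicaResult-class]
#' @return numeric vector, descending
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' Per-frame projections of a decomposition
#' @param x a [ProjectionResult-class] or [TicaResult-class]
#' @return `frames x components` matrix
#' @export
setGeneric("projections", function(x) standardGeneric("projections"))

#' Values carried by a result object
#' @param x a series, matrix or profile result object
#' @return numeric vector or matrix
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Cluster assignments
#' @param x a [ClusterTrace-class] or [ClusterRepresentatives-class]
#' @return integer vector, one cluster id per frame
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' Representative frame indices
#' @param x a [ClusterTrace-class] or [ClusterRepresentatives-class]
#' @return integer vector, one frame per cluster
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' Cumulative new-cluster count curve c(t)
#' @param x a [ClusterTrace-class]
#' @return integer vector
#' @export
setGeneric("countCurve", function(x) standardGeneric("countCurve"))
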