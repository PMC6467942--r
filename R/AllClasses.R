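#' @import methods
NULL

#' Topology: atoms and annotated secondary-structure segments
#'
#' A minimal molecular topology: an ordered atom table (serial, name, residue
#' name/number, chain) plus a table of annotated segments (helix, sheet or
#' loop residue ranges per chain). Segment annotation is supplied explicitly
#' in the configuration, mirroring the common practice of fixing the analysis
#' selection (e.g. the alpha-carbons of the alpha-helices) a priori rather
#' than recomputing secondary structure per frame.
#'
#' @slot atoms data.frame with columns `serial` (integer, unique, strictly
#'   increasing), `name`, `resname`, `resid` (integer), `chain`.
#' @slot segments data.frame with columns `chain`, `first`, `last`, `kind`
#'   (one of `"helix"`, `"sheet"`, `"loop"`). Ranges are inclusive residue
#'   numbers, non-empty, present in `atoms`, and non-overlapping per chain.
#' @export
setClass("Topology",
  representation(atoms = "data.frame", segments = "data.frame"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "resname", "resid", "chain")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0) return("topology has no atoms")
  if (anyDuplicated(a$serial) || any(diff(a$serial) <= 0))
    return("atom serials must be unique and strictly increasing")
  s <- object@segments
  if (nrow(s)) {
    needs <- c("chain", "first", "last", "kind")
    if (!all(needs %in% names(s)))
      return(paste("segments must have columns:", paste(needs, collapse = ", ")))
    if (!all(s$kind %in% c("helix", "sheet", "loop")))
      return("segment kind must be helix, sheet or loop")
    if (any(s$last < s$first)) return("segment residue ranges must be non-empty")
    for (i in seq_len(nrow(s))) {
      hit <- a$chain == s$chain[i] & a$resid >= s$first[i] & a$resid <= s$last[i]
      if (!any(hit))
        return(sprintf("segment %d (%s %d-%d) matches no atoms",
                       i, s$chain[i], s$first[i], s$last[i]))
    }
    for (ch in unique(s$chain)) {
      ss <- s[s$chain == ch, , drop = FALSE]
      ss <- ss[order(ss$first), , drop = FALSE]
      if (nrow(ss) > 1 && any(ss$first[-1] <= ss$last[-nrow(ss)]))
        return(sprintf("overlapping segments on chain %s", ch))
    }
  }
  TRUE
})

#' Trajectory: frames of coordinates over a fixed topology
#'
#' @slot topology a [Topology-class].
#' @slot coords numeric array `frames x atoms x 3`, lengths in Angstrom.
#' @slot times numeric vector of per-frame timestamps in nanoseconds,
#'   strictly increasing.
#' @export
setClass("Trajectory",
  representation(topology = "Topology", coords = "array", times = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3)
    return("coords must be a frames x atoms x 3 array")
  if (d[2] != nrow(object@topology@atoms))
    return(sprintf("coords have %d atoms but topology has %d",
                   d[2], nrow(object@topology@atoms)))
  if (length(object@times) != d[1])
    return("times length must equal frame count")
  if (any(!is.finite(object@coords))) return("non-finite coordinates")
  if (d[1] > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  TRUE
})

#' Atom selection by chain, residue range, atom name and segment kind
#'
#' All clauses are conjunctive; a zero-length slot means "no filter on this
#' attribute". The default selects alpha-carbons of annotated helix segments,
#' the selection used for all distance-based analyses here.
#'
#' @slot chains character; chains to keep (empty = all).
#' @slot residRanges integer matrix with columns `first`, `last`
#'   (0 rows = all residues).
#' @slot atomNames character; atom names to keep (default `"CA"`).
#' @slot segmentKinds character; segment kinds to keep (default `"helix"`).
#' @export
setClass("AtomSelection",
  representation(chains = "character", residRanges = "matrix",
                 atomNames = "character", segmentKinds = "character"))

setValidity("AtomSelection", function(object) {
  r <- object@residRanges
  if (nrow(r) && (ncol(r) != 2 || any(r[, 2] < r[, 1])))
    return("residRanges must be a matrix of inclusive (first, last) pairs")
  TRUE
})

#' Analysis configuration
#'
#' @slot rmsdCutoff RMSD cluster cutoff in Angstrom (default 2.0).
#' @slot nPcaComponents number of PCA components (default 2).
#' @slot ticaLag tICA lag in frames (`NA` = tICA stage skipped).
#' @slot kmeansK number of k-means clusters (`NA` = skipped).
#' @slot stride frame stride for the all-to-all matrix (default 1).
#' @slot seed integer seed for the stochastic stages.
#' @export
setClass("AnalysisConfig",
  representation(rmsdCutoff = "numeric", nPcaComponents = "integer",
                 ticaLag = "integer", kmeansK = "integer",
                 stride = "integer", seed = "integer"))

setValidity("AnalysisConfig", function(object) {
  if (object@rmsdCutoff <= 0) return("rmsdCutoff must be > 0")
  if (object@nPcaComponents < 1) return("nPcaComponents must be >= 1")
  if (!is.na(object@ticaLag) && object@ticaLag < 1) return("ticaLag must be >= 1")
  if (!is.na(object@kmeansK) && object@kmeansK < 1) return("kmeansK must be >= 1")
  if (object@stride < 1) return("stride must be >= 1")
  TRUE
})

#' Rigid-body transform (proper rotation plus translation)
#'
#' Applied to row-vector coordinates as `x' = x %*% rotation + translation`.
#'
#' @slot rotation 3x3 proper orthogonal matrix.
#' @slot translation length-3 numeric, Angstrom.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-10) return("rotation not orthogonal")
  if (abs(det(R) - 1) > 1e-10) return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3) return("translation must have length 3")
  TRUE
})

#' Hidden ground truth of a synthetic trajectory
#'
#' Everything the generator planted, recorded so downstream analyses can be
#' scored against it: per-frame state labels, per-state displacement fields,
#' per-atom fluctuation amplitudes, the planted gauge distance, any rigid
#' motions applied, and the Markov transition matrix.
#'
#' @slot stateLabels integer per frame, in `1..K`.
#' @slot stateOffsets list of `atoms x 3` matrices, one per state (Angstrom).
#' @slot sigma per-atom isotropic per-coordinate noise std (Angstrom).
#' @slot gateDistance planted gauge distance per frame (Angstrom; length 0 if
#'   the generator plants none).
#' @slot rigidMotions list of per-frame [RigidTransform-class] (may be empty).
#' @slot transitionMatrix row-stochastic K x K matrix.
#' @slot visitedStates sorted integer vector of states actually visited.
#' @slot slowCoordinate the planted slow feature (length 0 unless produced by
#'   [simulateSlowFastFeatures()]).
#' @export
setClass("SyntheticTruth",
  representation(stateLabels = "integer", stateOffsets = "list",
                 sigma = "numeric", gateDistance = "numeric",
                 rigidMotions = "list", transitionMatrix = "matrix",
                 visitedStates = "integer", slowCoordinate = "numeric"))

setValidity("SyntheticTruth", function(object) {
  K <- nrow(object@transitionMatrix)
  if (K) {
    if (ncol(object@transitionMatrix) != K) return("transition matrix must be square")
    if (max(abs(rowSums(object@transitionMatrix) - 1)) > 1e-12)
      return("transition matrix rows must sum to 1")
    if (length(object@stateLabels) &&
        (min(object@stateLabels) < 1 || max(object@stateLabels) > K))
      return("state labels must lie in 1..K")
  }
  if (any(object@sigma < 0)) return("sigma must be >= 0")
  TRUE
})

#' Idealized two-chain helical template with a tagged gauge pair
#'
#' A coarse dimer emulating the architecture of a homodimeric
#' helix-bundle scaffold: each chain is a Ca trace of two idealized helices
#' (rise 1.5 Angstrom, radius 2.3 Angstrom, 100 degrees per residue) joined
#' by a loop, with one tagged residue per chain whose Ca pair serves as the
#' pore open/close gauge.
#'
#' @slot topology a [Topology-class] (Ca-only).
#' @slot coords `atoms x 3` reference coordinates (Angstrom).
#' @slot gaugePair integer length-2 atom indices of the gauge Ca pair.
#' @export
setClass("DimerTemplate",
  representation(topology = "Topology", coords = "matrix", gaugePair = "integer"))

setValidity("DimerTemplate", function(object) {
  if (length(object@gaugePair) != 2) return("gaugePair must have two atom indices")
  n <- nrow(object@coords)
  if (any(object@gaugePair < 1 | object@gaugePair > n))
    return("gaugePair indices out of range")
  if (any(!is.finite(object@coords))) return("non-finite template coordinates")
  d <- stats::dist(object@coords)
  if (min(d) < 2) return("template self-intersects at 2 Angstrom resolution")
  TRUE
})

#' Per-frame RMSD series against a reference
#' @slot times ns; @slot values Angstrom; @slot selection,reference descriptions.
#' @export
setClass("RmsdSeries",
  representation(times = "numeric", values = "numeric",
                 selection = "character", reference = "character"))

setValidity("RmsdSeries", function(object) {
  if (length(object@times) != length(object@values)) return("length mismatch")
  if (any(object@values < 0)) return("RMSD values must be >= 0")
  TRUE
})

#' All-to-all superposed RMSD matrix over (strided) frames
#' @slot frames original frame indices after stride; @slot times ns;
#' @slot values symmetric matrix, Angstrom.
#' @export
setClass("RmsdMatrix",
  representation(frames = "integer", times = "numeric", values = "matrix"))

setValidity("RmsdMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (nrow(v) != length(object@frames)) return("frames length mismatch")
  if (max(abs(v - t(v))) > 1e-8) return("matrix must be symmetric")
  if (max(abs(diag(v))) > 1e-10) return("diagonal must be zero")
  if (any(v < -1e-12)) return("entries must be >= 0")
  TRUE
})

#' Sequential (leader) cluster-counting trace
#'
#' @slot assignments cluster id per frame (dense `1..C` in founding order).
#' @slot representatives founding frame index per cluster.
#' @slot countCurve cumulative number of clusters after each frame.
#' @slot cutoff Angstrom; @slot times ns.
#' @export
setClass("ClusterTrace",
  representation(assignments = "integer", representatives = "integer",
                 countCurve = "integer", cutoff = "numeric", times = "numeric"))

setValidity("ClusterTrace", function(object) {
  n <- length(object@assignments)
  if (length(object@countCurve) != n || length(object@times) != n)
    return("assignments, countCurve and times must have equal length")
  if (n == 0) return("empty trace")
  if (any(diff(object@countCurve) < 0)) return("count curve must be non-decreasing")
  if (any(object@countCurve < 1 | object@countCurve > seq_len(n)))
    return("count curve must satisfy 1 <= c(t) <= t")
  C <- max(object@assignments)
  if (!identical(sort(unique(object@assignments)), seq_len(C)))
    return("cluster ids must be dense 1..C")
  if (length(object@representatives) != C) return("one representative per cluster")
  if (any(object@assignments[object@representatives] != seq_len(C)))
    return("representatives must found their own cluster")
  TRUE
})

#' Principal component decomposition of Cartesian fluctuations
#'
#' @slot vectors orthonormal component vectors, one column per component,
#'   dimension `3 * n_selected`.
#' @slot eigenvalues Angstrom^2, descending.
#' @slot projections `frames x components` matrix (Angstrom).
#' @slot explainedVariance fraction of total variance per component.
#' @slot totalVariance Angstrom^2.
#' @slot rankDeficient TRUE when trailing requested components exceed the
#'   data rank (their eigenvalues are ~0).
#' @export
setClass("ProjectionResult",
  representation(vectors = "matrix", eigenvalues = "numeric",
                 projections = "matrix", explainedVariance = "numeric",
                 totalVariance = "numeric", rankDeficient = "logical"))

setValidity("ProjectionResult", function(object) {
  if (any(object@eigenvalues < -1e-10)) return("eigenvalues must be >= 0")
  if (sum(object@explainedVariance) > 1 + 1e-10)
    return("explained fractions must sum to <= 1")
  k <- ncol(object@vectors)
  if (k) {
    g <- crossprod(object@vectors)
    if (max(abs(g - diag(k))) > 1e-8) return("component vectors must be orthonormal")
  }
  TRUE
})

#' Per-residue root-mean-square fluctuation profile
#' @slot chain,resid residue keys; @slot values RMSF in Angstrom;
#' @slot selection,reference descriptions.
#' @export
setClass("RmsfProfile",
  representation(chain = "character", resid = "integer", values = "numeric",
                 selection = "character", reference = "character"))

setValidity("RmsfProfile", function(object) {
  n <- length(object@values)
  if (length(object@chain) != n || length(object@resid) != n)
    return("chain, resid and values must have equal length")
  if (any(object@values < 0)) return("RMSF values must be >= 0")
  TRUE
})

#' Feature matrix for time-lagged analyses
#' @slot values `frames x features` matrix; @slot labels unique feature
#'   labels; @slot times ns.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", labels = "character", times = "numeric"))

setValidity("FeatureMatrix", function(object) {
  if (any(!is.finite(object@values))) return("non-finite feature values")
  if (length(object@labels) != ncol(object@values)) return("one label per feature")
  if (anyDuplicated(object@labels)) return("feature labels must be unique")
  if (length(object@times) != nrow(object@values)) return("one time per frame")
  TRUE
})

#' tICA decomposition
#' @slot eigenvalues descending, dimensionless autocorrelations;
#' @slot vectors one column per component; @slot projections
#'   `frames x components`; @slot lag frames; @slot regularization ridge used.
#' @export
setClass("TicaResult",
  representation(eigenvalues = "numeric", vectors = "matrix",
                 projections = "matrix", lag = "integer",
                 regularization = "numeric"))

setValidity("TicaResult", function(object) {
  if (length(object@eigenvalues) &&
      max(abs(object@eigenvalues)) > 1 + 1e-6)
    return("|eigenvalues| must be <= 1 for symmetrized estimation")
  if (any(!is.finite(object@projections))) return("non-finite projections")
  TRUE
})

#' k-means partition with representative frames
#' @slot centroids `k x d`; @slot assignments cluster per frame;
#' @slot representatives frame index nearest each centroid;
#' @slot inertia final within-cluster sum of squares;
#' @slot inertiaHistory inertia after each Lloyd iteration.
#' @export
setClass("ClusterRepresentatives",
  representation(centroids = "matrix", assignments = "integer",
                 representatives = "integer", inertia = "numeric",
                 inertiaHistory = "numeric"))

setValidity("ClusterRepresentatives", function(object) {
  k <- nrow(object@centroids)
  if (length(object@representatives) != k) return("one representative per cluster")
  if (any(object@assignments < 1 | object@assignments > k))
    return("assignments out of range")
  if (any(object@assignments[object@representatives] != seq_len(k)))
    return("each representative must belong to its own cluster")
  TRUE
})

#' Scalar structural gauge tracked over time
#' @slot times ns; @slot values Angstrom; @slot definition human-readable
#'   gauge definition; @slot stats named summary (mean, sd, min, max).
#' @export
setClass("GaugeSeries",
  representation(times = "numeric", values = "numeric",
                 definition = "character", stats = "numeric"))

setValidity("GaugeSeries", function(object) {
  if (length(object@times) != length(object@values)) return("length mismatch")
  if (any(object@values <= 0)) return("distance gauge values must be > 0")
  TRUE
})

#' Full analysis report bundle
#'
#' @slot provenance list: effective config, seed, software version, input
#'   digests.
#' @slot stages named list of stage outputs; a failed or skipped stage is
#'   recorded as `list(skipped = TRUE, reason = ...)`.
#' @slot summary named list of headline metrics.
#' @export
setClass("ReportBundle",
  representation(provenance = "list", stages = "list", summary = "list"))
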