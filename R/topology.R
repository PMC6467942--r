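#' Construct a Topology
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `resid`,
#'   `chain` (a missing `serial` column is filled with `1:n`).
#' @param segments data.frame with columns `chain`, `first`, `last`, `kind`;
#'   defaults to no annotated segments.
#' @return a [Topology-class]
#' @examples
#' top <- Topology(data.frame(name = "CA", resname = "ALA",
#'                            resid = 1:3, chain = "A"))
#' @export
Topology <- function(atoms, segments = NULL) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  atoms$name <- as.character(atoms$name)
  atoms$resname <- as.character(atoms$resname)
  atoms$chain <- as.character(atoms$chain)
  rownames(atoms) <- NULL
  if (is.null(segments))
    segments <- data.frame(chain = character(0), first = integer(0),
                           last = integer(0), kind = character(0))
  segments <- as.data.frame(segments)
  if (nrow(segments)) {
    segments$chain <- as.character(segments$chain)
    segments$first <- as.integer(segments$first)
    segments$last <- as.integer(segments$last)
    segments$kind <- as.character(segments$kind)
  }
  rownames(segments) <- NULL
  new("Topology", atoms = atoms, segments = segments)
}

#' Atom table of a Topology
#' @param top a [Topology-class]
#' @return data.frame of atoms
#' @export
atoms <- function(top) top@atoms

#' Segment table of a Topology
#' @param top a [Topology-class]
#' @return data.frame of segments
#' @export
segments <- function(top) top@segments

#' Construct an AtomSelection
#'
#' The default selection keeps alpha-carbons belonging to annotated helix
#' segments, the selection used throughout for distance-based analyses
#' (flexible loops and termini are thereby excluded).
#'
#' @param chains chains to keep, or `NULL` for all.
#' @param residRanges list of `c(first, last)` pairs or a two-column matrix,
#'   or `NULL` for all residues.
#' @param atomNames atom names to keep; `NULL` disables the name filter.
#'   Default `"CA"`.
#' @param segmentKinds segment kinds to keep; `NULL` disables the segment
#'   filter. Default `"helix"`.
#' @return an [AtomSelection-class]
#' @examples
#' AtomSelection()                          # helix Ca atoms
#' AtomSelection(segmentKinds = NULL)       # all Ca atoms
#' @export
AtomSelection <- function(chains = NULL, residRanges = NULL,
                          atomNames = "CA", segmentKinds = "helix") {
  if (is.list(residRanges)) residRanges <- do.call(rbind, residRanges)
  if (is.null(residRanges)) residRanges <- matrix(integer(0), ncol = 2)
  storage.mode(residRanges) <- "integer"
  colnames(residRanges) <- c("first", "last")
  new("AtomSelection",
      chains = as.character(chains %||% character(0)),
      residRanges = residRanges,
      atomNames = as.character(atomNames %||% character(0)),
      segmentKinds = as.character(segmentKinds %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an AnalysisConfig
#'
#' @param rmsdCutoff cluster-counting RMSD cutoff in Angstrom (default 2.0).
#' @param nPcaComponents PCA components to report (default 2).
#' @param ticaLag tICA lag in frames; `NA` skips the tICA stage (no silent
#'   default: the lag is a scientific choice the user must make).
#' @param kmeansK k for k-means in tICA space; `NA` skips.
#' @param stride frame stride for the all-to-all matrix (default 1).
#' @param seed integer seed for stochastic stages (default 1).
#' @return an [AnalysisConfig-class]
#' @export
AnalysisConfig <- function(rmsdCutoff = 2.0, nPcaComponents = 2L,
                           ticaLag = NA_integer_, kmeansK = NA_integer_,
                           stride = 1L, seed = 1L) {
  new("AnalysisConfig", rmsdCutoff = as.numeric(rmsdCutoff),
      nPcaComponents = as.integer(nPcaComponents),
      ticaLag = as.integer(ticaLag), kmeansK = as.integer(kmeansK),
      stride = as.integer(stride), seed = as.integer(seed))
}

#' Resolve an AtomSelection against a Topology
#'
#' Applies all filter clauses conjunctively and returns the (strictly
#' increasing, 1-based) indices of matching atoms. Resolution is
#' deterministic and independent of clause order.
#'
#' @param top a [Topology-class]
#' @param sel an [AtomSelection-class]
#' @return integer vector of atom indices
#' @examples
#' top <- Topology(data.frame(name = "CA", resname = "ALA", resid = 1:10,
#'                            chain = "A"),
#'                 data.frame(chain = "A", first = 2, last = 5, kind = "helix"))
#' resolveSelection(top, AtomSelection())   # atoms 2..5
#' @export
resolveSelection <- function(top, sel = AtomSelection()) {
  a <- top@atoms
  keep <- rep(TRUE, nrow(a))
  clauses <- list()
  if (length(sel@chains))
    clauses$chains <- a$chain %in% sel@chains
  if (nrow(sel@residRanges)) {
    hit <- rep(FALSE, nrow(a))
    for (i in seq_len(nrow(sel@residRanges)))
      hit <- hit | (a$resid >= sel@residRanges[i, 1] &
                    a$resid <= sel@residRanges[i, 2])
    clauses$residRanges <- hit
  }
  if (length(sel@atomNames))
    clauses$atomNames <- a$name %in% sel@atomNames
  if (length(sel@segmentKinds)) {
    s <- top@segments
    s <- s[s$kind %in% sel@segmentKinds, , drop = FALSE]
    hit <- rep(FALSE, nrow(a))
    for (i in seq_len(nrow(s)))
      hit <- hit | (a$chain == s$chain[i] & a$resid >= s$first[i] &
                    a$resid <= s$last[i])
    clauses$segmentKinds <- hit
  }
  for (nm in names(clauses)) {
    keep <- keep & clauses[[nm]]
    if (!any(keep))
      .stopf("selection resolves to no atoms (first empty at clause '%s')", nm)
  }
  which(keep)
}

# Find one atom by (chain, resid, name); errors name the key.
.findAtom <- function(top, chain, resid, name = "CA") {
  a <- top@atoms
  i <- which(a$chain == chain & a$resid == as.integer(resid) & a$name == name)
  if (length(i) != 1)
    .stopf("atom key %s:%s:%s matches %d atoms (need exactly 1)",
           chain, resid, name, length(i))
  i
}
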