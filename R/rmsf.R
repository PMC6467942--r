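#' Per-residue root-mean-square fluctuation
#'
#' Aligns the trajectory to its mean structure (two-pass, see
#' [alignTrajectory()]) and reports, for each selected atom,
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)`. Computed on the selection's
#' atoms (alpha-carbons by default) and reported per residue through the
#' selected atom. RMSF localizes the flexible regions (loops, termini,
#' fraying helix ends) whose exclusion from distance-based analyses the
#' helix-Ca selection encodes.
#'
#' @param traj a [Trajectory-class] with >= 2 frames
#' @param sel atoms to report RMSF for (default helix alpha-carbons)
#' @param alignSel atoms used for the alignment (defaults to `sel`; supply a
#'   rigid selection here to report fluctuation of flexible regions measured
#'   in a stable frame, e.g. align on helices, report loops)
#' @return an [RmsfProfile-class]
#' @export
rmsf <- function(traj, sel = AtomSelection(), alignSel = sel) {
  if (nFrames(traj) < 2) .stopf("RMSF needs >= 2 frames")
  idx <- resolveSelection(traj@topology, sel)
  aligned <- alignTrajectory(traj, alignSel, reference = "mean")
  sub <- aligned@coords[, idx, , drop = FALSE]
  mu <- apply(sub, c(2, 3), mean)
  dev2 <- sweep(sub, c(2, 3), mu)^2
  vals <- sqrt(apply(dev2, 2, sum) / dim(sub)[1])
  a <- traj@topology@atoms[idx, ]
  new("RmsfProfile", chain = a$chain, resid = a$resid, values = vals,
      selection = .describeSelection(sel), reference = "mean structure")
}

#' Mean RMSF per chain
#'
#' Arithmetic mean of the per-residue RMSF over each chain, the summary used
#' to compare overall chain mobility between systems.
#'
#' @param profile an [RmsfProfile-class]
#' @return named numeric vector, one mean per chain (Angstrom)
#' @export
meanRmsfByChain <- function(profile) {
  if (!length(profile@values)) .stopf("empty RMSF profile")
  tapply(profile@values, profile@chain, mean)[unique(profile@chain)]
}
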