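#' Run the full convergence and plasticity report
#'
#' Executes the complete analysis battery on one trajectory: solvent
#' stripping, selection, RMSD-to-reference series, all-to-all RMSD matrix,
#' sequential cluster counting with plateau time, Cartesian PCA, per-residue
#' RMSF, dihedral tICA with k-means representative extraction (when `ticaLag`
#' and `kmeansK` are set in the config), and any configured distance gauges.
#' Stage outputs are written as CSV/JSON (plus a multi-model PDB of
#' representative structures) under `outDir`, and a [ReportBundle-class] is
#' returned. Given the same inputs, config and seed the run is
#' bit-reproducible; a failing stage is recorded with its reason and the
#' remaining independent stages still run.
#'
#' @param traj a [Trajectory-class]
#' @param config an [AnalysisConfig-class]
#' @param sel an [AtomSelection-class] used by all distance-based stages
#' @param gauges optional list of gauge definitions, each a list with
#'   elements `a` and `b` (atom keys, see [pairDistanceSeries()]) and an
#'   optional `threshold` for [bimodalitySummary()].
#' @param solventResnames residue names stripped before analysis
#' @param outDir output directory (created if needed); `NULL` skips writing
#' @param inputPaths optional character vector of source file paths recorded
#'   (with md5 digests) in the provenance block
#' @return a [ReportBundle-class]
#' @export
runReport <- function(traj, config = AnalysisConfig(), sel = AtomSelection(),
                      gauges = NULL, solventResnames = c("HOH", "WAT"),
                      outDir = NULL, inputPaths = NULL) {
  stages <- list()
  run <- function(expr) tryCatch(expr, error = function(e)
    list(skipped = TRUE, reason = conditionMessage(e)))
  skipped <- function(reason) list(skipped = TRUE, reason = reason)

  traj <- stripSolvent(traj, solventResnames)
  digests <- if (!is.null(inputPaths)) as.list(tools::md5sum(inputPaths))
             else list()
  provenance <- list(
    package = "mdconverge",
    version = as.character(utils::packageVersion("mdconverge")),
    seed = config@seed,
    config = list(rmsd_cutoff_A = config@rmsdCutoff,
                  n_pca_components = config@nPcaComponents,
                  tica_lag_frames = config@ticaLag,
                  kmeans_k = config@kmeansK,
                  stride = config@stride),
    selection = .describeSelection(sel),
    input = list(n_frames = nFrames(traj), n_atoms = nAtoms(traj),
                 coord_checksum = sprintf("%.10e", sum(traj@coords)),
                 files = digests))

  stages$rmsd_series <- run(rmsdToReference(traj, sel, reference = 1L))
  stages$rmsd_matrix <- run(allToAllRmsd(traj, sel, stride = config@stride))
  stages$clusters <- run(leaderClusterCount(traj, sel, cutoff = config@rmsdCutoff))
  stages$pca <- run(coordinatePca(traj, sel, nComponents = config@nPcaComponents))
  stages$rmsf <- run(rmsf(traj, sel))
  if (is.na(config@ticaLag) || is.na(config@kmeansK)) {
    stages$tica <- skipped("ticaLag and kmeansK are required for the tICA stage")
  } else {
    stages$tica <- run({
      feats <- dihedralFeatures(traj, mode = "ca_pseudo")
      tr <- tica(feats, lag = config@ticaLag,
                 nComponents = min(2L, ncol(feats@values)))
      km <- kmeansCluster(tr, k = config@kmeansK, seed = config@seed)
      list(tica = tr, kmeans = km,
           representatives = extractRepresentatives(traj, km))
    })
  }
  if (is.null(gauges) || !length(gauges)) {
    stages$gauges <- skipped("no gauges configured")
  } else {
    stages$gauges <- run(lapply(gauges, function(g) {
      s <- pairDistanceSeries(traj, g$a, g$b)
      out <- list(series = s)
      if (!is.null(g$threshold))
        out$bimodality <- bimodalitySummary(s, g$threshold)
      out
    }))
  }

  summary <- list()
  if (!.isSkipped(stages$clusters)) {
    summary$final_cluster_count <- max(stages$clusters@assignments)
    summary$plateau_time_ns <- plateauTime(stages$clusters)
  }
  if (!.isSkipped(stages$pca))
    summary$pca_explained_variance <- stages$pca@explainedVariance
  if (!.isSkipped(stages$rmsf))
    summary$mean_rmsf_by_chain_A <- as.list(meanRmsfByChain(stages$rmsf))
  if (!.isSkipped(stages$rmsd_series))
    summary$mean_rmsd_to_start_A <- mean(stages$rmsd_series@values)
  if (!.isSkipped(stages$tica))
    summary$tica_top_eigenvalue <- stages$tica$tica@eigenvalues[1]
  if (!.isSkipped(stages$gauges))
    summary$gauge_mean_A <- lapply(stages$gauges, function(g)
      unname(g$series@stats["mean"]))

  bundle <- new("ReportBundle", provenance = provenance, stages = stages,
                summary = summary)
  if (!is.null(outDir)) writeReport(bundle, outDir)
  bundle
}

#' Write a report bundle to disk
#'
#' One CSV per tabular stage output, a multi-model PDB of tICA/k-means
#' representative structures when present, and `report.json` carrying the
#' provenance, stage status and summary metrics (schema in
#' `system.file("schema", "report-schema.json", package = "mdconverge")`).
#' Outputs contain no timestamps, so identical runs are byte-identical.
#'
#' @param bundle a [ReportBundle-class]
#' @param outDir output directory
#' @return `outDir`, invisibly
#' @export
writeReport <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(outDir, name),
                                           row.names = FALSE)
  st <- bundle@stages
  if (!.isSkipped(st$rmsd_series))
    w(as.data.frame(st$rmsd_series), "rmsd_series.csv")
  if (!.isSkipped(st$rmsd_matrix)) {
    m <- st$rmsd_matrix@values
    df <- data.frame(frame = st$rmsd_matrix@frames, m)
    names(df) <- c("frame", paste0("f", st$rmsd_matrix@frames))
    w(df, "rmsd_matrix.csv")
  }
  if (!.isSkipped(st$clusters))
    w(as.data.frame(st$clusters), "cluster_trace.csv")
  if (!.isSkipped(st$pca)) {
    w(data.frame(component = seq_along(st$pca@eigenvalues),
                 eigenvalue_A2 = st$pca@eigenvalues,
                 explained_fraction = st$pca@explainedVariance),
      "pca_eigenvalues.csv")
    pr <- as.data.frame(st$pca@projections)
    names(pr) <- paste0("pc", seq_len(ncol(pr)))
    w(cbind(frame = seq_len(nrow(pr)), pr), "pca_projections.csv")
  }
  if (!.isSkipped(st$rmsf)) {
    w(as.data.frame(st$rmsf), "rmsf.csv")
    mbc <- meanRmsfByChain(st$rmsf)
    w(data.frame(chain = names(mbc), mean_rmsf_A = as.numeric(mbc)),
      "rmsf_by_chain.csv")
  }
  if (!.isSkipped(st$tica)) {
    w(data.frame(component = seq_along(st$tica$tica@eigenvalues),
                 eigenvalue = st$tica$tica@eigenvalues),
      "tica_eigenvalues.csv")
    km <- st$tica$kmeans
    w(data.frame(frame = seq_along(km@assignments), cluster = km@assignments,
                 is_representative = seq_along(km@assignments) %in%
                   km@representatives),
      "tica_clusters.csv")
    writeTrajectory(st$tica$representatives,
                    file.path(outDir, "representatives.pdb"), "pdb")
  }
  if (!.isSkipped(st$gauges)) {
    for (i in seq_along(st$gauges))
      w(as.data.frame(st$gauges[[i]]$series), sprintf("gauge_%d.csv", i))
  }
  stageStatus <- lapply(st, function(s)
    if (.isSkipped(s)) list(completed = FALSE, reason = s$reason)
    else list(completed = TRUE))
  jsonlite::write_json(
    list(provenance = bundle@provenance, stages = stageStatus,
         summary = bundle@summary),
    file.path(outDir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Validate a written report against the shipped schema
#'
#' Structural validation (required keys and JSON types) of `report.json`
#' against `inst/schema/report-schema.json`.
#'
#' @param file path to a `report.json`
#' @return TRUE invisibly; errors describe the first violation
#' @export
validateReport <- function(file) {
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                            package = "mdconverge"))
  doc <- jsonlite::read_json(file)
  .checkSchema(doc, schema, "$")
  invisible(TRUE)
}

.checkSchema <- function(doc, schema, path) {
  type <- schema$type
  ok <- switch(type,
    object = is.list(doc) && (is.null(names(doc)) == (length(doc) == 0)),
    array = is.list(doc) || is.vector(doc),
    string = is.character(doc),
    number = is.numeric(doc),
    integer = is.numeric(doc) && all(doc == round(doc)),
    boolean = is.logical(doc),
    TRUE)
  if (!isTRUE(ok)) .stopf("%s: expected %s", path, type)
  if (type == "object") {
    for (req in schema$required)
      if (!req %in% names(doc)) .stopf("%s: missing required key '%s'", path, req)
    for (nm in names(schema$properties))
      if (nm %in% names(doc))
        .checkSchema(doc[[nm]], schema$properties[[nm]],
                     paste0(path, ".", nm))
  }
  invisible(TRUE)
}

#' Compare several report bundles side by side
#'
#' Produces a table of headline metrics (cluster count, plateau time,
#' explained-variance fractions, per-chain mean RMSF, gauge means) with one
#' row per bundle -- the cross-system view used to rank scaffold plasticity.
#' Bundles must share the same selection.
#'
#' @param bundles list of [ReportBundle-class] objects (>= 2)
#' @param labels optional row labels
#' @return data.frame, one row per bundle
#' @export
compareReports <- function(bundles, labels = NULL) {
  if (length(bundles) < 2) .stopf("need at least 2 bundles to compare")
  sels <- vapply(bundles, function(b) b@provenance$selection, character(1))
  if (length(unique(sels)) != 1)
    .stopf("bundles use incompatible selections: %s",
           paste(unique(sels), collapse = " vs "))
  if (is.null(labels)) labels <- paste0("system", seq_along(bundles))
  getn <- function(b, key, i = NULL) {
    v <- b@summary[[key]]
    if (is.null(v)) return(NA_real_)
    v <- unlist(v)
    if (!is.null(i)) { if (i > length(v)) NA_real_ else v[i] } else v[1]
  }
  chains <- unique(unlist(lapply(bundles, function(b)
    names(b@summary$mean_rmsf_by_chain_A))))
  out <- data.frame(
    label = labels,
    final_cluster_count = vapply(bundles, getn, numeric(1),
                                 key = "final_cluster_count"),
    plateau_time_ns = vapply(bundles, getn, numeric(1), key = "plateau_time_ns"),
    pca_var_1 = vapply(bundles, getn, numeric(1),
                       key = "pca_explained_variance", i = 1),
    pca_var_2 = vapply(bundles, getn, numeric(1),
                       key = "pca_explained_variance", i = 2),
    mean_rmsd_to_start_A = vapply(bundles, getn, numeric(1),
                                  key = "mean_rmsd_to_start_A"))
  for (ch in chains)
    out[[paste0("mean_rmsf_", ch, "_A")]] <- vapply(bundles, function(b) {
      v <- b@summary$mean_rmsf_by_chain_A[[ch]]
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
  ng <- max(vapply(bundles, function(b) length(b@summary$gauge_mean_A),
                   integer(1)))
  for (i in seq_len(ng))
    out[[sprintf("gauge_%d_mean_A", i)]] <- vapply(bundles, function(b) {
      v <- b@summary$gauge_mean_A
      if (length(v) >= i) v[[i]] else NA_real_
    }, numeric(1))
  out
}

# A stage result is "skipped" when it is a plain list carrying skipped = TRUE
# (S4 stage outputs are always completed results).
.isSkipped <- function(s) is.list(s) && isTRUE(s$skipped)
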