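#' Assemble and validate a run configuration
#'
#' All overrides are validated against the class invariants before any
#' computation starts, so a bad flag fails fast.
#'
#' @param pdb input multi-model PDB path (not needed by `annotate`).
#' @param chains the two declared dimer chain ids.
#' @param scheme a [RegionScheme-class].
#' @param thresholds a [ContactThresholds-class].
#' @param clusterCutoff nm, see [gromosCluster()].
#' @param frames equilibrated frame window (integer vector), `NULL` = all.
#' @param out output directory (created if missing).
#' @param seed integer seed for any randomized step.
#' @param verbose emit per-stage counts on stderr.
#' @return validated config list.
#' @export
runConfig <- function(pdb = NULL, chains = NULL,
                      scheme = defaultRegionScheme(),
                      thresholds = contactThresholds(),
                      clusterCutoff = 0.2, frames = NULL, out = ".",
                      seed = 1L, verbose = TRUE) {
  validObject(scheme)
  validObject(thresholds)
  stopifnot(clusterCutoff > 0)
  if (!is.null(pdb) && !file.exists(pdb))
    stop(ecError(paste("input PDB not found:", pdb), "io_error"))
  list(pdb = pdb, chains = chains, scheme = scheme, thresholds = thresholds,
       clusterCutoff = clusterCutoff, frames = frames, out = out,
       seed = as.integer(seed), verbose = isTRUE(verbose))
}

.log <- function(config, ...) {
  if (config$verbose) message(...)
}

.loadInput <- function(config) {
  ens <- readPDBModels(config$pdb)
  chains <- sort(unique(ens@atoms$chain_id))
  if (!is.null(config$chains)) {
    missing <- setdiff(config$chains, chains)
    if (length(missing))
      stop(ecError(paste("unknown chain:",
                         paste(missing, collapse = ",")), "chain_error"))
    keep <- ens@atoms$chain_id %in% config$chains
    ens <- new("StructuralEnsemble", atoms = ens@atoms[keep, , drop = FALSE],
               coords = ens@coords[keep, , , drop = FALSE])
  }
  .log(config, "loaded ", nFrames(ens), " frame(s), ", nAtoms(ens), " atoms")
  ens
}

.outPath <- function(config, name) {
  if (!dir.exists(config$out))
    dir.create(config$out, recursive = TRUE)
  file.path(config$out, name)
}

#' Run the contact-profiling stage
#'
#' Detectors over every frame of the window, occupancy aggregation,
#' interface assignment and the asymmetry summary; writes `profile.tsv` and
#' `profile_summary.json` into the output directory.
#'
#' @param config a [runConfig()] list.
#' @param table a [ChemistryTable-class].
#' @return the profile data.frame, invisibly; summary attached as attribute
#'   `"summary"`.
#' @export
runProfile <- function(config, table = defaultChemistry()) {
  ens <- .loadInput(config)
  prof <- interfaceProfile(ens, config$scheme, table, config$thresholds,
                           config$frames)
  .log(config, "profile: ", nrow(prof), " occupancy record(s)")
  summary <- writeProfileReport(prof, tsv = .outPath(config, "profile.tsv"),
                                json = .outPath(config,
                                                "profile_summary.json"))
  attr(prof, "summary") <- summary
  invisible(prof)
}

#' Run the clustering stage
#'
#' GROMOS clustering over the configured frame window; writes
#' `clusters.tsv` (frame, cluster) and the representative frame as a
#' single-model PDB `representative.pdb`.
#'
#' @param config a [runConfig()] list.
#' @return the [ClusterResult-class], invisibly.
#' @export
runCluster <- function(config) {
  ens <- .loadInput(config)
  frames <- .resolveFrames(ens, config$frames)
  if (!length(frames))
    stop(ecError("empty frame-range selection", "frame_error"))
  sub <- new("StructuralEnsemble", atoms = ens@atoms,
             coords = ens@coords[, , frames, drop = FALSE])
  cl <- gromosCluster(sub, cutoff = config$clusterCutoff)
  rep <- representativeStructure(cl)
  .log(config, "cluster: ", length(cl@sizes), " cluster(s), coverage ",
       sprintf("%.3f", cl@coverage))
  utils::write.table(
    data.frame(frame = frames, cluster = cl@membership),
    .outPath(config, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  repi <- frames[rep$frame]
  writePDBModels(new("StructuralEnsemble", atoms = ens@atoms,
                     coords = ens@coords[, , repi, drop = FALSE]),
                 .outPath(config, "representative.pdb"))
  jsonlite::write_json(
    list(representative_frame = repi, coverage = rep$coverage,
         sizes = cl@sizes, cutoff_nm = cl@cutoff),
    .outPath(config, "cluster_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(cl)
}

#' Run the convergence-diagnostics stage
#'
#' Backbone RMSD series, covariance modes and cosine content over the
#' configured window; writes `convergence.tsv` (frame, rmsd_nm, p1, p2, ...)
#' and `convergence_summary.json`.
#'
#' @param config a [runConfig()] list.
#' @param n_modes modes to report.
#' @return the [ConvergenceReport-class], invisibly.
#' @export
runConverge <- function(config, n_modes = 2L) {
  ens <- .loadInput(config)
  frames <- .resolveFrames(ens, config$frames)
  sub <- new("StructuralEnsemble", atoms = ens@atoms,
             coords = ens@coords[, , frames, drop = FALSE])
  rep <- convergenceReport(sub, n_modes = n_modes)
  .log(config, "converge: cosine content ",
       paste(sprintf("%.3f", rep@cosineContent), collapse = ", "))
  tab <- data.frame(frame = frames, rmsd_nm = rep@rmsd)
  for (i in seq_len(ncol(rep@projections)))
    tab[[paste0("p", i)]] <- rep@projections[, i]
  utils::write.table(tab, .outPath(config, "convergence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(cosine_content = rep@cosineContent,
         eigenvalues_nm2 = rep@eigenvalues[seq_len(n_modes)],
         total_variance_nm2 = sum(rep@eigenvalues),
         final_rmsd_nm = utils::tail(rep@rmsd, 1)),
    .outPath(config, "convergence_summary.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(rep)
}

#' Run the variant-annotation stage
#'
#' Annotates a variant TSV (or the built-in table) and writes
#' `variants_annotated.tsv` plus a JSON report. Out-of-range positions are
#' flagged and the run continues.
#'
#' @param config a [runConfig()] list.
#' @param variants path to a variant TSV or a data.frame; default the
#'   built-in table.
#' @return the annotated data.frame, invisibly.
#' @export
runAnnotate <- function(config, variants = NULL) {
  v <- if (is.null(variants)) stat5aVariants()
       else if (is.character(variants)) stat5aVariants(variants)
       else variants
  catalog <- defaultInterfaceCatalog(config$scheme)
  ann <- annotateVariants(v, catalog, config$scheme)
  .log(config, "annotate: ", nrow(ann), " row(s), ",
       sum(ann$region == "out_of_range"), " out of range")
  utils::write.table(ann, .outPath(config, "variants_annotated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ann, .outPath(config, "variants_annotated.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(ann)
}

#' Run the synthetic-ensemble stage
#'
#' Generates a designed-contact ensemble, writes it as a multi-model PDB
#' plus its ground-truth schedule TSV.
#'
#' @param config a [runConfig()] list (uses `out` and `seed`).
#' @param spec a [contactScheduleSpec()]; a small symmetric-dimer default is
#'   used when omitted.
#' @return list as from [generateContactEnsemble()], invisibly.
#' @export
runSimulate <- function(config, spec = NULL) {
  if (is.null(spec)) {
    spec <- contactScheduleSpec(100L, config$seed, list(
      designedPair("salt_bridge", "A", 694L, "B", 618L, p = 0.8),
      designedPair("salt_bridge", "B", 694L, "A", 618L, p = 0.8),
      designedPair("hydrophobic", "A", 706L, "A", 633L, p = 0.55)))
  }
  gen <- generateContactEnsemble(spec)
  writePDBModels(gen$ensemble, .outPath(config, "synthetic.pdb"))
  utils::write.table(gen$truth, .outPath(config, "synthetic_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log(config, "simulate: ", nFrames(gen$ensemble), " frame(s), ",
       nrow(gen$designed), " designed schedule(s)")
  invisible(gen)
}
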