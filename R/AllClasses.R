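#' @import methods
NULL

#' StructuralEnsemble: an ordered set of conformations over a fixed topology
#'
#' Holds one topology (the atom identity table) and the coordinates of every
#' frame. All analyses in the package consume this container. Coordinates are
#' stored in nanometres.
#'
#' @slot atoms data.frame with one row per atom and columns `serial`, `name`,
#'   `element`, `alt_loc`, `res_name`, `chain_id`, `res_seq`, `i_code`,
#'   `occupancy_field`, `is_hetatm`. The row order is the shared atom order of
#'   every frame.
#' @slot coords numeric array of dimension `c(n_atoms, 3, n_frames)`, nm.
#'
#' @seealso [readPDBModels()], [nFrames()], [frameCoords()]
#' @export
setClass("StructuralEnsemble",
  representation(atoms = "data.frame", coords = "array"))

setValidity("StructuralEnsemble", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "alt_loc", "res_name", "chain_id",
            "res_seq", "i_code", "occupancy_field", "is_hetatm")
  if (!all(need %in% names(a)))
    return(paste("atoms is missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1] != nrow(a))
    return("coords first dimension must equal nrow(atoms)")
  if (d[3] < 1L)
    return("an ensemble needs at least one frame")
  if (any(!is.finite(object@coords)))
    return("all coordinates must be finite")
  if (any(!nzchar(a$element)))
    return("every atom needs a non-empty element after inference")
  TRUE
})

#' ChemistryTable: per-residue-type interaction chemistry
#'
#' Declares, per 3-letter residue code, the hydrogen-bond donor pairs
#' (heavy atom + bonded hydrogens), acceptor atoms, side-chain heavy atoms,
#' positive/negative charge-group atoms and aromatic ring atoms, plus atomic
#' masses per element. The default table covers the 20 standard amino acids
#' and phosphotyrosine (PTR).
#'
#' @slot entries data.frame with columns `res_name`, `role` (one of `donor`,
#'   `acceptor`, `sidechain`, `pos_charge`, `neg_charge`, `aromatic`),
#'   `atom`, `partner_hydrogens` (pipe-separated, donors only).
#' @slot masses named numeric vector, element symbol -> mass (Da).
#'
#' @seealso [defaultChemistry()], [residueChemistry()]
#' @export
setClass("ChemistryTable",
  representation(entries = "data.frame", masses = "numeric"))

setValidity("ChemistryTable", function(object) {
  e <- object@entries
  need <- c("res_name", "role", "atom", "partner_hydrogens")
  if (!all(need %in% names(e)))
    return("entries needs columns res_name, role, atom, partner_hydrogens")
  ok <- c("donor", "acceptor", "sidechain", "pos_charge", "neg_charge",
          "aromatic")
  if (!all(e$role %in% ok))
    return(paste("unknown role:", paste(setdiff(e$role, ok), collapse = ",")))
  if (is.null(names(object@masses)) || any(!nzchar(names(object@masses))))
    return("masses must be a named numeric vector")
  TRUE
})

#' RegionScheme: named residue-number ranges
#'
#' Maps region labels to inclusive residue-number ranges, applied on each
#' chain of the dimer. The default scheme is the STAT5A fragment numbering:
#' SH2 589-687, L (linker) 688-693, PTM (phosphotyrosine motif) 694-706,
#' nTAD 707-714.
#'
#' @slot regions data.frame with columns `label`, `start`, `end` (inclusive).
#' @seealso [defaultRegionScheme()], [selectRegion()], [assignInterface()]
#' @export
setClass("RegionScheme", representation(regions = "data.frame"))

setValidity("RegionScheme", function(object) {
  r <- object@regions
  if (!all(c("label", "start", "end") %in% names(r)))
    return("regions needs columns label, start, end")
  if (any(r$end < r$start)) return("region end must be >= start")
  if (anyDuplicated(r$label)) return("region labels must be unique")
  o <- r[order(r$start), , drop = FALSE]
  if (nrow(o) > 1L && any(o$start[-1L] <= o$end[-nrow(o)]))
    return("regions overlap")
  TRUE
})

#' ContactThresholds: geometric cut-offs for the four detectors
#'
#' Defaults are the simulation-analysis criteria used throughout:
#' a hydrogen bond requires donor-acceptor distance below 0.35 nm and a
#' hydrogen-donor-acceptor angle below 30 degrees; a hydrophobic contact
#' requires side-chain centre-of-mass distance below 0.5 nm; a salt bridge
#' requires a minimum N+/O- heavy-atom distance below 0.4 nm
#' (Barlow-Thornton convention). All inequalities are strict.
#'
#' @slot hbondDist nm, default 0.35
#' @slot hbondAngle degrees, default 30
#' @slot hydrophobicDist nm, default 0.5
#' @slot saltBridgeDist nm, default 0.4
#' @seealso [contactThresholds()]
#' @export
setClass("ContactThresholds",
  representation(hbondDist = "numeric", hbondAngle = "numeric",
                 hydrophobicDist = "numeric", saltBridgeDist = "numeric"))

setValidity("ContactThresholds", function(object) {
  v <- c(object@hbondDist, object@hbondAngle, object@hydrophobicDist,
         object@saltBridgeDist)
  if (length(v) != 4L || any(!is.finite(v)) || any(v <= 0))
    return("all thresholds must be single, finite, strictly positive values")
  TRUE
})

#' ClusterResult: outcome of conformational clustering
#'
#' @slot cutoff nm, the pairwise-RMSD neighbour cutoff used.
#' @slot membership integer vector, frame -> cluster id (1 = largest).
#' @slot sizes integer vector of cluster sizes, descending.
#' @slot centroids integer vector, centroid frame index per cluster.
#' @slot coverage fraction of frames in the largest cluster.
#' @seealso [gromosCluster()], [representativeStructure()]
#' @export
setClass("ClusterResult",
  representation(cutoff = "numeric", membership = "integer",
                 sizes = "integer", centroids = "integer",
                 coverage = "numeric"))

setValidity("ClusterResult", function(object) {
  if (sum(object@sizes) != length(object@membership))
    return("cluster sizes must sum to the frame count")
  if (length(object@centroids) != length(object@sizes))
    return("one centroid per cluster required")
  if (any(object@membership[object@centroids] != seq_along(object@centroids)))
    return("each centroid frame must belong to its own cluster")
  TRUE
})

#' ConvergenceReport: sampling diagnostics for an ensemble
#'
#' @slot eigenvalues numeric, descending positional-covariance eigenvalues
#'   (nm^2).
#' @slot projections matrix, frames x modes: projections of each frame's
#'   deviation from the mean structure onto the top modes.
#' @slot cosineContent numeric in \[0,1\] per reported mode (Hess criterion;
#'   near 1 = random-diffusion-like, near 0 = sampling about an equilibrium).
#' @slot rmsd numeric, per-frame backbone RMSD (nm) versus the reference.
#' @seealso [covarianceModes()], [cosineContent()], [rmsdSeries()]
#' @export
setClass("ConvergenceReport",
  representation(eigenvalues = "numeric", projections = "matrix",
                 cosineContent = "numeric", rmsd = "numeric"))

setValidity("ConvergenceReport", function(object) {
  if (any(object@eigenvalues < -1e-9))
    return("eigenvalues must be non-negative")
  cc <- object@cosineContent
  if (length(cc) && any(cc < -1e-9 | cc > 1 + 1e-9))
    return("cosine content must lie in [0,1]")
  TRUE
})

#' InterfaceCatalog: named residue pockets of the dimer interface
#'
#' Residue sets (STAT5A numbering) used to annotate variants:
#' the phosphotyrosine-binding pocket, the pY+1 (V695) pocket and the
#' intramolecular hydrophobic acceptor interface for F706.
#'
#' @slot pyPocket integer residue numbers.
#' @slot v695Pocket integer residue numbers.
#' @slot hydrophobicInterface integer residue numbers.
#' @slot scheme the [RegionScheme-class] the catalog refers to.
#' @seealso [defaultInterfaceCatalog()], [annotateVariant()]
#' @export
setClass("InterfaceCatalog",
  representation(pyPocket = "integer", v695Pocket = "integer",
                 hydrophobicInterface = "integer", scheme = "RegionScheme"))

setValidity("InterfaceCatalog", function(object) {
  sh2 <- object@scheme@regions
  sh2 <- sh2[sh2$label == "SH2", , drop = FALSE]
  if (nrow(sh2) != 1L) return("catalog scheme must define an SH2 region")
  all_res <- c(object@pyPocket, object@v695Pocket,
               object@hydrophobicInterface)
  if (any(all_res < sh2$start | all_res > sh2$end))
    return("all catalog residues must fall inside the SH2 range")
  TRUE
})
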