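#' Number of frames in an ensemble
#' @param x a [StructuralEnsemble-class]
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms in the shared topology
#' @param x a [StructuralEnsemble-class]
#' @return integer
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom identity table of an ensemble
#' @param x a [StructuralEnsemble-class]
#' @return data.frame, one row per atom in the shared order
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Coordinates of one frame
#' @param x a [StructuralEnsemble-class]
#' @param i frame index (1-based)
#' @return n_atoms x 3 numeric matrix, nm
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "StructuralEnsemble", function(x) dim(x@coords)[3])

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "StructuralEnsemble", function(x) dim(x@coords)[1])

#' @rdname atomTable
#' @export
setMethod("atomTable", "StructuralEnsemble", function(x) x@atoms)

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "StructuralEnsemble", function(x, i) {
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > nFrames(x))
    stop(ecError("frame index out of range", "frame_error"))
  x@coords[, , i, drop = TRUE]
})

setMethod("show", "StructuralEnsemble", function(object) {
  a <- object@atoms
  key <- paste(a$chain_id, a$res_seq, a$i_code)
  cat("StructuralEnsemble:", nFrames(object), "frame(s),",
      nAtoms(object), "atoms,", length(unique(key)), "residues on chain(s)",
      paste(sort(unique(a$chain_id)), collapse = ","), "\n")
})

setMethod("show", "ChemistryTable", function(object) {
  cat("ChemistryTable:", length(unique(object@entries$res_name)),
      "residue types,", nrow(object@entries), "role entries\n")
})

setMethod("show", "RegionScheme", function(object) {
  r <- object@regions
  cat("RegionScheme:",
      paste(sprintf("%s=%d-%d", r$label, r$start, r$end), collapse = ", "),
      "\n")
})

setMethod("show", "ContactThresholds", function(object) {
  cat(sprintf(paste0("ContactThresholds: hbond < %.3g nm & < %.3g deg; ",
                     "hydrophobic COM < %.3g nm; salt bridge < %.3g nm\n"),
              object@hbondDist, object@hbondAngle, object@hydrophobicDist,
              object@saltBridgeDist))
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@sizes), "cluster(s) at cutoff",
      object@cutoff, "nm; sizes", paste(object@sizes, collapse = ","),
      sprintf("; coverage %.3f\n", object@coverage))
})

setMethod("show", "ConvergenceReport", function(object) {
  cat("ConvergenceReport:", length(object@eigenvalues), "modes;",
      "cosine content", paste(sprintf("%.3f", object@cosineContent),
                              collapse = ", "),
      sprintf("; final RMSD %.4f nm\n", utils::tail(object@rmsd, 1)))
})

setMethod("show", "InterfaceCatalog", function(object) {
  cat("InterfaceCatalog: pY pocket {",
      paste(object@pyPocket, collapse = ","), "}, V695 pocket {",
      paste(object@v695Pocket, collapse = ","), "}, hydrophobic interface {",
      paste(object@hydrophobicInterface, collapse = ","), "}\n")
})

# internal structured-condition helper: all package errors carry a class so
# callers and tests can distinguish I/O, topology, region, ... failures
ecError <- function(msg, class) {
  structure(class = c(paste0("ec_", class), "ec_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
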