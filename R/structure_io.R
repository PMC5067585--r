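#' Construct a StructuralEnsemble from an atom table and coordinates
#'
#' @param atoms data.frame with the atom-identity columns (see
#'   [StructuralEnsemble-class]); missing bookkeeping columns are filled with
#'   defaults.
#' @param coords either an `n_atoms x 3 x n_frames` array or a list of
#'   `n_atoms x 3` matrices (nm).
#' @return a [StructuralEnsemble-class]
#' @export
structuralEnsemble <- function(atoms, coords) {
  if (is.list(coords) && !is.array(coords))
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1L]]), 3L, length(coords)))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  n <- dim(coords)[1L]
  defaults <- list(serial = seq_len(n), name = NULL, element = NULL,
                   alt_loc = "", res_name = NULL, chain_id = "A",
                   res_seq = NULL, i_code = "", occupancy_field = 1,
                   is_hetatm = FALSE)
  for (col in names(defaults)) {
    if (is.null(atoms[[col]])) {
      if (is.null(defaults[[col]]))
        stop(ecError(paste("atoms must provide column", col), "input_error"))
      atoms[[col]] <- defaults[[col]]
    }
  }
  new("StructuralEnsemble", atoms = atoms, coords = coords)
}

# fixed-width PDB v3.3 column extraction for ATOM/HETATM lines
.parseAtomLines <- function(lines, lineno) {
  sub2 <- function(a, b) trimws(substring(lines, a, b))
  xyz <- cbind(suppressWarnings(as.numeric(substring(lines, 31, 38))),
               suppressWarnings(as.numeric(substring(lines, 39, 46))),
               suppressWarnings(as.numeric(substring(lines, 47, 54))))
  res_seq <- suppressWarnings(as.integer(sub2(23, 26)))
  bad <- which(!stats::complete.cases(xyz) | is.na(res_seq))
  if (length(bad))
    stop(ecError(sprintf("unparseable fixed-width record at line %d: %s",
                         lineno[bad[1L]], lines[bad[1L]]), "parse_error"))
  occ <- suppressWarnings(as.numeric(sub2(55, 60)))
  occ[is.na(occ)] <- 1
  data.frame(serial = suppressWarnings(as.integer(sub2(7, 11))),
             name = sub2(13, 16), alt_loc = sub2(17, 17),
             res_name = sub2(18, 20), chain_id = sub2(22, 22),
             res_seq = res_seq, i_code = sub2(27, 27),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy_field = occ, element = sub2(77, 78),
             is_hetatm = startsWith(lines, "HETATM"),
             stringsAsFactors = FALSE)
}

# infer the element from the atom name when column 77-78 is blank
# (common in simulation-written PDBs); validated against the mass table
.inferElement <- function(element, name, masses) {
  blank <- !nzchar(element)
  if (any(blank)) {
    stripped <- gsub("[0-9']", "", name[blank])
    # names like 1HB1 put the digit first; after stripping, first letter wins
    guess <- toupper(substring(stripped, 1L, 1L))
    element[blank] <- guess
  }
  unknown <- !(element %in% names(masses))
  if (any(unknown))
    stop(ecError(paste("cannot infer element for atom name(s):",
                       paste(unique(name[unknown]), collapse = ", ")),
                 "parse_error"))
  element
}

#' Read a multi-model PDB file into a StructuralEnsemble
#'
#' One frame per `MODEL`/`ENDMDL` block; a file without MODEL records gives a
#' single frame. Coordinates are converted from Angstrom to nm. PTR
#' (phosphotyrosine) is accepted from either ATOM or HETATM records. Alt-loc
#' policy: only blank or 'A' locations are kept (simulation frames carry no
#' alternates; crystal inputs get a deterministic rule). Hydrogen-name
#' variants are normalized (`1HH1` -> `HH11`, `HN` -> `H`). Blank element
#' fields are inferred from the atom-name columns.
#'
#' The topology (the `(chain, res_seq, res_name, name)` sequence) must be
#' identical across models; the first divergent model is reported otherwise.
#'
#' @param path PDB file path.
#' @return a [StructuralEnsemble-class] (coordinates in nm).
#' @seealso [writePDBModels()], [selectRegion()]
#' @export
readPDBModels <- function(path) {
  if (!file.exists(path))
    stop(ecError(paste("file not found:", path), "io_error"))
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  if (!any(is_atom))
    stop(ecError(paste("no ATOM/HETATM records in", path), "parse_error"))
  model_lines <- which(startsWith(lines, "MODEL"))
  atom_idx <- which(is_atom)
  a <- .parseAtomLines(lines[atom_idx], atom_idx)
  # model id per atom record: 0 when the file has no MODEL blocks
  model_of <- if (length(model_lines)) findInterval(atom_idx, model_lines)
              else rep(1L, length(atom_idx))
  if (length(model_lines) && any(model_of == 0L))
    stop(ecError("ATOM records found before the first MODEL record",
                 "parse_error"))
  keep <- a$alt_loc %in% c("", "A")
  a <- a[keep, , drop = FALSE]
  model_of <- model_of[keep]
  a$alt_loc <- ""
  hy <- grepl("^[0-9]?H", a$name)
  a$name[hy] <- normalizeHydrogenName(a$name[hy])
  a$element <- .inferElement(a$element, a$name, proteinMasses())

  ids <- paste(a$chain_id, a$res_seq, a$i_code, a$res_name, a$name)
  split_ids <- split(ids, model_of)
  ref <- split_ids[[1L]]
  for (m in seq_along(split_ids)) {
    if (!identical(split_ids[[m]], ref)) {
      stop(ecError(sprintf(
        "topology mismatch: model %d has %d atoms / differing identities (model 1 has %d)",
        m, length(split_ids[[m]]), length(ref)), "topology_error"))
    }
  }
  n_frames <- length(split_ids)
  n_atoms <- length(ref)
  xyz <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
  coords <- array(NA_real_, c(n_atoms, 3L, n_frames))
  for (m in seq_len(n_frames))
    coords[, , m] <- xyz[model_of == m, , drop = FALSE]
  atoms <- a[model_of == 1L,
             c("serial", "name", "element", "alt_loc", "res_name",
               "chain_id", "res_seq", "i_code", "occupancy_field",
               "is_hetatm"), drop = FALSE]
  rownames(atoms) <- NULL
  new("StructuralEnsemble", atoms = atoms, coords = coords)
}

#' Write a StructuralEnsemble as a multi-model PDB file
#'
#' Coordinates are converted back from nm to Angstrom at 3 decimals.
#' Ensembles with more than one frame are wrapped in MODEL/ENDMDL blocks;
#' a round-trip through [readPDBModels()] reproduces coordinates to the
#' format precision (1e-4 nm).
#'
#' @param ensemble a [StructuralEnsemble-class]
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePDBModels <- function(ensemble, path) {
  stopifnot(is(ensemble, "StructuralEnsemble"))
  a <- ensemble@atoms
  nf <- nFrames(ensemble)
  # PDB name column: 1-char elements start in column 14 unless 4 chars long
  fmt_name <- ifelse(nchar(a$name) >= 4L | nchar(a$element) == 2L,
                     sprintf("%-4s", a$name),
                     sprintf(" %-3s", a$name))
  rec <- ifelse(a$is_hetatm, "HETATM", "ATOM  ")
  out <- character(0)
  for (m in seq_len(nf)) {
    xyz <- ensemble@coords[, , m, drop = TRUE] * 10
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    block <- sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, a$serial %% 100000L, fmt_name, a$alt_loc,
                     a$res_name, a$chain_id, a$res_seq, a$i_code,
                     xyz[, 1], xyz[, 2], xyz[, 3], a$occupancy_field, 0,
                     a$element)
    if (nf > 1L)
      block <- c(sprintf("MODEL     %4d", m), block, "ENDMDL")
    out <- c(out, block)
  }
  out <- c(out, "END")
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop(ecError(paste("cannot write PDB file:", path), "io_error"))
  invisible(path)
}

#' Construct a region scheme
#'
#' @param labels character region labels.
#' @param start,end integer inclusive residue-number bounds per label.
#' @return a [RegionScheme-class]
#' @export
regionScheme <- function(labels, start, end) {
  new("RegionScheme",
      regions = data.frame(label = labels, start = as.integer(start),
                           end = as.integer(end), stringsAsFactors = FALSE))
}

#' The default STAT5A-fragment region scheme
#'
#' SH2 domain 589-687, linker (L) 688-693, phosphotyrosine motif (PTM)
#' 694-706, nTAD 707-714 (STAT5A numbering, applied on both chains).
#'
#' @return a [RegionScheme-class]
#' @export
defaultRegionScheme <- function() {
  regionScheme(c("SH2", "L", "PTM", "nTAD"),
               c(589L, 688L, 694L, 707L),
               c(687L, 693L, 706L, 714L))
}

#' Label residue numbers with their region
#'
#' @param res_seq integer residue numbers.
#' @param scheme a [RegionScheme-class].
#' @return character vector of region labels, `"other"` where uncovered.
#' @export
regionOf <- function(res_seq, scheme) {
  stopifnot(is(scheme, "RegionScheme"))
  r <- scheme@regions
  out <- rep("other", length(res_seq))
  for (i in seq_len(nrow(r)))
    out[res_seq >= r$start[i] & res_seq <= r$end[i]] <- r$label[i]
  out
}

#' Select the atoms of one region on one chain
#'
#' Returns the sub-ensemble of atoms whose residue number falls in the
#' inclusive range of `region` on `chain`. Residues missing from the range
#' are simply absent; an empty intersection yields an empty selection, not
#' an error.
#'
#' @param ensemble a [StructuralEnsemble-class]
#' @param chain chain identifier.
#' @param region region label defined in `scheme`.
#' @param scheme a [RegionScheme-class].
#' @return a [StructuralEnsemble-class] view (zero atoms when the
#'   intersection is empty).
#' @export
selectRegion <- function(ensemble, chain, region, scheme = defaultRegionScheme()) {
  stopifnot(is(ensemble, "StructuralEnsemble"), is(scheme, "RegionScheme"))
  r <- scheme@regions
  hit <- r[r$label == region, , drop = FALSE]
  if (nrow(hit) != 1L)
    stop(ecError(paste("unknown region label:", region), "region_error"))
  if (!chain %in% ensemble@atoms$chain_id)
    stop(ecError(paste("unknown chain:", chain), "region_error"))
  keep <- ensemble@atoms$chain_id == chain &
    ensemble@atoms$res_seq >= hit$start & ensemble@atoms$res_seq <= hit$end
  atoms <- ensemble@atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  new("StructuralEnsemble", atoms = atoms,
      coords = ensemble@coords[keep, , , drop = FALSE])
}
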