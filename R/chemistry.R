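#' Read a chemistry table from TSV
#'
#' The TSV has columns `res_name`, `role`, `atom`, `partner_hydrogens`.
#' Roles are `donor` (with pipe-separated candidate hydrogen names),
#' `acceptor`, `sidechain` (heavy atoms), `pos_charge`, `neg_charge`
#' and `aromatic`.
#'
#' @param path path to a TSV file.
#' @param masses named numeric vector of atomic masses (Da) per element
#'   symbol; the default covers the elements found in proteins.
#' @return a [ChemistryTable-class]
#' @export
readChemistryTable <- function(path, masses = proteinMasses()) {
  if (!file.exists(path))
    stop(ecError(paste("chemistry table not found:", path), "io_error"))
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character", na.strings = NULL,
                         quote = "", comment.char = "#")
  e$partner_hydrogens[is.na(e$partner_hydrogens)] <- ""
  new("ChemistryTable", entries = e, masses = masses)
}

#' Atomic masses of protein elements
#'
#' @return named numeric vector (Da)
#' @export
proteinMasses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974)
}

#' The built-in residue chemistry table
#'
#' Covers the 20 standard amino acids plus phosphotyrosine (PTR: acceptors
#' O1P/O2P/O3P, negative charge group \{O1P, O2P, O3P, P\}, aromatic ring
#' CG..CZ, no side-chain hydroxyl donor). The table ships as an editable TSV
#' under `inst/extdata/chemistry.tsv`.
#'
#' Histidine is listed as potential donor and acceptor at ND1/NE2; it only
#' contributes a positive charge group when `protonatedHis = TRUE`
#' (protonation states are an input assumption, not predicted here).
#'
#' @param protonatedHis logical; treat histidine as positively charged.
#' @return a [ChemistryTable-class]
#' @export
defaultChemistry <- function(protonatedHis = FALSE) {
  tab <- readChemistryTable(system.file("extdata", "chemistry.tsv",
                                        package = "EnsembleContacts",
                                        mustWork = TRUE))
  if (protonatedHis) {
    e <- tab@entries
    add <- data.frame(res_name = "HIS", role = "pos_charge",
                      atom = c("ND1", "NE2"), partner_hydrogens = "")
    tab@entries <- rbind(e, add)
    validObject(tab)
  }
  tab
}

#' Chemistry entry for one residue type
#'
#' Soft-fails by contract: an unknown residue code returns a marker entry
#' (`known = FALSE`) so detectors can skip it with a warning rather than
#' abort a whole ensemble.
#'
#' @param res_name 3-letter residue code.
#' @param table a [ChemistryTable-class].
#' @return list with elements `res_name`, `known`, `donors` (data.frame
#'   `atom`, `hydrogens` pipe-separated), `acceptors`, `sidechain`,
#'   `pos_charge`, `neg_charge`, `aromatic` (character vectors).
#' @examples
#' residueChemistry("ARG", defaultChemistry())$pos_charge
#' @export
residueChemistry <- function(res_name, table) {
  stopifnot(is(table, "ChemistryTable"))
  e <- table@entries[table@entries$res_name == res_name, , drop = FALSE]
  if (nrow(e) == 0L)
    return(list(res_name = res_name, known = FALSE,
                donors = data.frame(atom = character(),
                                    hydrogens = character()),
                acceptors = character(), sidechain = character(),
                pos_charge = character(), neg_charge = character(),
                aromatic = character()))
  don <- e[e$role == "donor", , drop = FALSE]
  list(res_name = res_name, known = TRUE,
       donors = data.frame(atom = don$atom, hydrogens = don$partner_hydrogens,
                           stringsAsFactors = FALSE),
       acceptors = e$atom[e$role == "acceptor"],
       sidechain = e$atom[e$role == "sidechain"],
       pos_charge = e$atom[e$role == "pos_charge"],
       neg_charge = e$atom[e$role == "neg_charge"],
       aromatic = e$atom[e$role == "aromatic"])
}

#' Restrict a chemistry table to a subset of residue types
#'
#' Mostly useful for testing: dropping a residue code removes every event
#' that residue type could produce.
#'
#' @param table a [ChemistryTable-class]
#' @param res_names residue codes to keep (or drop).
#' @param drop if `TRUE`, `res_names` are removed instead of kept.
#' @return a [ChemistryTable-class]
#' @export
subsetChemistry <- function(table, res_names, drop = FALSE) {
  keep <- table@entries$res_name %in% res_names
  if (drop) keep <- !keep
  new("ChemistryTable", entries = table@entries[keep, , drop = FALSE],
      masses = table@masses)
}

# Hydrogens are assigned to the side chain by the PDB position-letter
# convention: names whose letter part is H followed by B/G/D/E/Z/H
# (HB2, HG11, HH11, ...) sit on side-chain heavy atoms; H, HN, H1-3 and HA*
# are backbone. Works on names already normalized by normalizeHydrogenName().
isSidechainHydrogen <- function(name) {
  grepl("^H[BGDEZH]", name)
}

# Normalize hydrogen-name variants: rotate a leading digit to the end
# (1HH1 -> HH11, 2HB -> HB2) and map HN -> H.
normalizeHydrogenName <- function(name) {
  rot <- grepl("^[0-9]H", name)
  name[rot] <- paste0(substring(name[rot], 2L), substring(name[rot], 1L, 1L))
  name[name == "HN"] <- "H"
  name
}
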