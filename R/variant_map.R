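#' The default interface catalog of the STAT5A dimer
#'
#' Named residue pockets (STAT5A numbering) on the SH2 domain:
#' * `pY_pocket` - phosphotyrosine coordination: R618 (invariant arginine),
#'   the transient hydrogen-bond partners K600, S620, S622, T628, and the
#'   betaD residues N642 (betaD5) and K644 (betaD7) that pack against the
#'   phosphotyrosine ring;
#' * `v695_pocket` - hydrophobic pocket accepting the pY+1 valine: W631,
#'   W641, L643;
#' * `hydrophobic_interface` - the intramolecular acceptor of F706: W631,
#'   F633, W641, L663, Y665, L666.
#'
#' @param scheme a [RegionScheme-class]; catalog residues must fall in its
#'   SH2 range.
#' @return an [InterfaceCatalog-class]
#' @export
defaultInterfaceCatalog <- function(scheme = defaultRegionScheme()) {
  new("InterfaceCatalog",
      pyPocket = c(618L, 600L, 620L, 622L, 628L, 642L, 644L),
      v695Pocket = c(631L, 641L, 643L),
      hydrophobicInterface = c(631L, 633L, 641L, 663L, 665L, 666L),
      scheme = scheme)
}

#' Built-in STAT5A variant table
#'
#' Point mutations of the modeled STAT5A fragment with, where published,
#' cohort carrier counts; shipped as an editable TSV under
#' `inst/extdata/stat5a_variants.tsv`. Counts are stored rather than the
#' printed percentages so frequencies are always recomputable; one printed
#' frequency (I699L, "2.0%") is inconsistent with its counts and the
#' discrepancy is flagged in the `note` column rather than resolved.
#'
#' @param path alternative TSV path (same columns).
#' @return data.frame: `position`, `wt`, `mut`, `cohort_label`, `carriers`,
#'   `total`, `note`.
#' @export
stat5aVariants <- function(path = system.file("extdata",
                                              "stat5a_variants.tsv",
                                              package = "EnsembleContacts",
                                              mustWork = TRUE)) {
  v <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         na.strings = "NA", stringsAsFactors = FALSE)
  v$position <- as.integer(v$position)
  v$carriers <- as.integer(v$carriers)
  v$total <- as.integer(v$total)
  v
}

#' Cohort frequency from carrier counts
#'
#' `100 * carriers / total`, rounded half-up to one decimal (the convention
#' used when such frequencies are printed).
#'
#' @param carriers,total non-negative integers, `carriers <= total`,
#'   `total >= 1`. Vectorized.
#' @return percent, one decimal.
#' @examples
#' variantFrequency(7, 21)   # 33.3
#' variantFrequency(3, 50)   # 6.0
#' @export
variantFrequency <- function(carriers, total) {
  if (any(total < 1L, na.rm = FALSE) || any(is.na(total)) ||
      any(is.na(carriers)))
    stop(ecError("total must be >= 1 and counts non-missing", "input_error"))
  if (any(carriers < 0L | carriers > total))
    stop(ecError("carriers must lie in [0, total]", "input_error"))
  floor(1000 * carriers / total + 0.5) / 10
}

#' Annotate a variant position with its region and interface membership
#'
#' Attaches the region label (SH2/L/PTM/nTAD), any catalog pocket
#' memberships, and the interface the position participates in:
#' pY-pocket and V695-pocket residues sit in interface 1; PTM positions
#' pY+1..pY+11 except the C-terminal F706 belong to interface 2 (the motif/
#' motif interface); hydrophobic-interface residues and F706 (the donor)
#' belong to interface 3; the phosphotyrosine itself anchors interface 1.
#'
#' @param position residue number (STAT5A numbering), within the modeled
#'   range 589-714.
#' @param catalog an [InterfaceCatalog-class].
#' @param scheme a [RegionScheme-class].
#' @return list: `position`, `region`, `pockets` (character vector),
#'   `interface` (`"1"`, `"2"`, `"3"`, `"3 donor"` or `NA`).
#' @examples
#' annotateVariant(642)$interface  # "1"
#' annotateVariant(701)$interface  # "2"
#' @export
annotateVariant <- function(position, catalog = defaultInterfaceCatalog(),
                            scheme = defaultRegionScheme()) {
  position <- as.integer(position)
  lo <- min(scheme@regions$start)
  hi <- max(scheme@regions$end)
  if (position < lo || position > hi)
    stop(ecError(sprintf("position %d outside the modeled range %d-%d",
                         position, lo, hi), "range_error"))
  region <- regionOf(position, scheme)
  pockets <- character(0)
  if (position %in% catalog@pyPocket) pockets <- c(pockets, "pY_pocket")
  if (position %in% catalog@v695Pocket) pockets <- c(pockets, "v695_pocket")
  if (position %in% catalog@hydrophobicInterface)
    pockets <- c(pockets, "hydrophobic_interface")
  ptm <- scheme@regions[scheme@regions$label == "PTM", , drop = FALSE]
  interface <- NA_character_
  if ("hydrophobic_interface" %in% pockets) {
    interface <- "3"
  } else if (length(pockets)) {
    interface <- "1"
  } else if (region == "PTM") {
    py <- ptm$start  # the phosphotyrosine anchors the motif
    interface <- if (position == py || position == py + 1L) "1"
                 else if (position == ptm$end) "3 donor"
                 else "2"
  }
  list(position = position, region = region, pockets = pockets,
       interface = interface)
}

#' Annotate a whole variant table
#'
#' Applies [annotateVariant()] to every row and computes cohort frequencies
#' where counts are available. Out-of-range positions are flagged in the
#' `region` column rather than aborting the run.
#'
#' @param variants data.frame as returned by [stat5aVariants()].
#' @param catalog an [InterfaceCatalog-class].
#' @param scheme a [RegionScheme-class].
#' @return the input with added `region`, `pockets` (comma-separated),
#'   `interface`, `frequency_pct` columns.
#' @export
annotateVariants <- function(variants, catalog = defaultInterfaceCatalog(),
                             scheme = defaultRegionScheme()) {
  n <- nrow(variants)
  region <- pockets <- interface <- rep(NA_character_, n)
  freq <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ann <- tryCatch(annotateVariant(variants$position[i], catalog, scheme),
                    ec_range_error = function(e) NULL)
    if (is.null(ann)) {
      region[i] <- "out_of_range"
      next
    }
    region[i] <- ann$region
    pockets[i] <- paste(ann$pockets, collapse = ",")
    interface[i] <- ann$interface
    if (!is.na(variants$carriers[i]) && !is.na(variants$total[i]))
      freq[i] <- variantFrequency(variants$carriers[i], variants$total[i])
  }
  cbind(variants, data.frame(region = region, pockets = pockets,
                             interface = interface, frequency_pct = freq,
                             stringsAsFactors = FALSE))
}
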