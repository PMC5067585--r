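#' Aggregate per-frame events into residue-pair occupancies
#'
#' One record per distinct (canonical residue pair, kind). A pair detected
#' several times in one frame (e.g. two simultaneous hydrogen bonds) counts
#' that frame once. Pairs never present are not enumerated (the candidate
#' universe is unbounded). Occupancy is the percentage of frames in which
#' the pair satisfies its geometric criterion; the persistence label splits
#' it at `persistenceCutoff` into `persistent` / `transient`.
#'
#' @param events event data.frame from the detectors.
#' @param n_frames total number of frames the events were detected over.
#' @param persistenceCutoff percent; default 25.
#' @return data.frame with the pair key columns, `kind`, `n_present`,
#'   `n_frames`, `occupancy_pct`, `label`.
#' @export
accumulateOccupancy <- function(events, n_frames, persistenceCutoff = 25) {
  stopifnot(n_frames >= 1L)
  if (nrow(events) && any(events$frame > n_frames))
    stop(ecError("event frame index exceeds n_frames", "frame_error"))
  if (!nrow(events))
    return(data.frame(kind = character(), chain_a = character(),
                      res_a = integer(), icode_a = character(),
                      resname_a = character(), chain_b = character(),
                      res_b = integer(), icode_b = character(),
                      resname_b = character(), n_present = integer(),
                      n_frames = integer(), occupancy_pct = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  key_cols <- c("kind", "chain_a", "res_a", "icode_a", "resname_a",
                "chain_b", "res_b", "icode_b", "resname_b")
  key <- do.call(paste, c(events[key_cols], sep = "\r"))
  uf <- !duplicated(paste(key, events$frame))
  n_present <- table(key[uf])
  first <- events[match(names(n_present), key), key_cols, drop = FALSE]
  out <- cbind(first,
               data.frame(n_present = as.integer(n_present),
                          n_frames = as.integer(n_frames)))
  out$occupancy_pct <- 100 * out$n_present / out$n_frames
  out$label <- ifelse(out$occupancy_pct >= persistenceCutoff,
                      "persistent", "transient")
  out <- out[order(-out$occupancy_pct, out$chain_a, out$res_a, out$chain_b,
                   out$res_b, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a residue pair to a dimer interface
#'
#' The three-interface scheme of the SH2-mediated dimer:
#' * interface `1`: different chains, one residue in PTM or nTAD, the other
#'   in the SH2 domain (intermolecular phosphotyrosine-motif/SH2);
#' * interface `2`: different chains, both residues in PTM or nTAD
#'   (intermolecular motif/motif);
#' * interface `3`: same chain, one residue in PTM or nTAD, the other in SH2
#'   (intramolecular motif/SH2);
#' * `linker` when either residue falls in L; `other` otherwise.
#'
#' nTAD is grouped with the PTM because the C-terminal tail acts as one
#' percolating unit across the interface.
#'
#' @param chain_a,res_a,chain_b,res_b residue pair (vectors allowed).
#' @param scheme a [RegionScheme-class].
#' @param chains the two declared chain ids of the dimer.
#' @return data.frame with `interface` (`"1"`, `"2"`, `"3"`, `"linker"`,
#'   `"other"`) and `orientation` (the chain donating the PTM/nTAD side for
#'   interfaces 1 and 3, `NA` otherwise).
#' @export
assignInterface <- function(chain_a, res_a, chain_b, res_b,
                            scheme = defaultRegionScheme(),
                            chains = sort(unique(c(chain_a, chain_b)))) {
  if (length(chains) > 2L ||
      !all(c(chain_a, chain_b) %in% chains))
    stop(ecError("residue chain not among the declared dimer chains",
                 "chain_error"))
  ra <- regionOf(res_a, scheme)
  rb <- regionOf(res_b, scheme)
  tail_a <- ra %in% c("PTM", "nTAD")
  tail_b <- rb %in% c("PTM", "nTAD")
  sh2_a <- ra == "SH2"
  sh2_b <- rb == "SH2"
  inter <- chain_a != chain_b
  interface <- rep("other", length(ra))
  orientation <- rep(NA_character_, length(ra))
  i1 <- inter & ((tail_a & sh2_b) | (tail_b & sh2_a))
  i2 <- inter & tail_a & tail_b
  i3 <- !inter & ((tail_a & sh2_b) | (tail_b & sh2_a))
  lk <- ra == "L" | rb == "L"
  interface[i1] <- "1"
  interface[i2] <- "2"
  interface[i3] <- "3"
  interface[lk & !(i1 | i2 | i3)] <- "linker"
  donates <- ifelse(tail_a, chain_a, chain_b)
  orientation[i1 | i3] <- donates[i1 | i3]
  data.frame(interface = interface, orientation = orientation,
             stringsAsFactors = FALSE)
}

#' Full interface occupancy profile of a dimer ensemble
#'
#' Runs all four detectors over every frame, aggregates occupancies and
#' attaches the interface assignment to every record. Records are sorted by
#' interface, then occupancy descending.
#'
#' @param ensemble a two-chain [StructuralEnsemble-class].
#' @param scheme a [RegionScheme-class].
#' @param table a [ChemistryTable-class].
#' @param thresholds a [ContactThresholds-class].
#' @param frames integer frame window, default all.
#' @param persistenceCutoff percent, see [accumulateOccupancy()].
#' @return occupancy data.frame with added `interface` and `orientation`.
#' @export
interfaceProfile <- function(ensemble, scheme = defaultRegionScheme(),
                             table = defaultChemistry(),
                             thresholds = contactThresholds(),
                             frames = NULL, persistenceCutoff = 25) {
  frames <- .resolveFrames(ensemble, frames)
  chains <- sort(unique(ensemble@atoms$chain_id))
  if (max(apply(ensemble@coords, 2, max) - apply(ensemble@coords, 2, min)) >
        200)
    warning("ensemble extent exceeds 200 nm; coordinates may be wrapped or ",
            "in the wrong unit", call. = FALSE)
  ev <- detectAllContacts(ensemble, table, thresholds, frames)
  # occupancy is over the selected window, with frame indices re-based
  ev$frame <- match(ev$frame, frames)
  occ <- accumulateOccupancy(ev, length(frames), persistenceCutoff)
  asg <- assignInterface(occ$chain_a, occ$res_a, occ$chain_b, occ$res_b,
                         scheme, chains)
  occ$interface <- asg$interface
  occ$orientation <- asg$orientation
  occ <- occ[order(occ$interface, -occ$occupancy_pct, occ$kind), ,
             drop = FALSE]
  rownames(occ) <- NULL
  occ
}

#' Asymmetry of a reciprocal interface
#'
#' The dimer is nominally symmetric: interfaces 1 and 3 exist once per
#' orientation (each monomer donates its phosphotyrosine motif once).
#' The score matches records across the two orientations by (kind,
#' tail-residue number, SH2-residue number) and returns the mean absolute
#' occupancy difference over the union of matched pairs, a missing partner
#' counting as 0%. 0 means a perfectly symmetric profile.
#'
#' @param profile output of [interfaceProfile()].
#' @param interface which reciprocal interface to score (`"1"` or `"3"`).
#' @param scheme the [RegionScheme-class] the profile was built with.
#' @return percent (mean |occupancy difference|).
#' @export
asymmetryScore <- function(profile, interface = "1",
                           scheme = defaultRegionScheme()) {
  p <- profile[profile$interface == interface, , drop = FALSE]
  orientations <- sort(unique(stats::na.omit(p$orientation)))
  if (!nrow(p) || length(orientations) == 0L)
    stop(ecError("no records in either orientation: asymmetry undefined",
                 "undefined_score_error"))
  # orientation-free pair key: (kind, tail residue, partner residue)
  tail_first <- regionOf(p$res_a, scheme) %in% c("PTM", "nTAD")
  tail_res <- ifelse(tail_first, p$res_a, p$res_b)
  part_res <- ifelse(tail_first, p$res_b, p$res_a)
  key <- paste(p$kind, tail_res, part_res)
  keys <- unique(key)
  occ_of <- function(orient) {
    v <- stats::setNames(rep(0, length(keys)), keys)
    sel <- p$orientation == orient
    v[key[sel]] <- p$occupancy_pct[sel]
    v
  }
  if (length(orientations) == 1L)
    return(mean(abs(occ_of(orientations[1L]))))
  mean(abs(occ_of(orientations[1L]) - occ_of(orientations[2L])))
}

#' Write an interface profile as TSV and a JSON summary
#'
#' @param profile output of [interfaceProfile()].
#' @param tsv,json output paths (`NULL` to skip either).
#' @return invisibly, a list with per-interface record counts and the
#'   asymmetry scores that are defined.
#' @export
writeProfileReport <- function(profile, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(profile, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  counts <- as.list(table(profile$interface))
  asym <- list()
  for (i in c("1", "3")) {
    asym[[paste0("interface", i)]] <-
      tryCatch(asymmetryScore(profile, i), ec_error = function(e) NA_real_)
  }
  summary <- list(n_records = nrow(profile), records_per_interface = counts,
                  asymmetry_pct = asym)
  if (!is.null(json))
    jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(summary)
}
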