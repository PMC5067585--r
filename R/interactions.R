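#' Construct contact-detection thresholds
#'
#' @param hbondDist donor-acceptor heavy-atom distance cutoff, nm.
#' @param hbondAngle hydrogen-donor-acceptor angle cutoff at the donor
#'   vertex, degrees.
#' @param hydrophobicDist side-chain centre-of-mass distance cutoff, nm.
#' @param saltBridgeDist minimum N+/O- heavy-atom distance cutoff, nm.
#' @return a [ContactThresholds-class]
#' @export
contactThresholds <- function(hbondDist = 0.35, hbondAngle = 30,
                              hydrophobicDist = 0.5, saltBridgeDist = 0.4) {
  new("ContactThresholds", hbondDist = hbondDist, hbondAngle = hbondAngle,
      hydrophobicDist = hydrophobicDist, saltBridgeDist = saltBridgeDist)
}

#' Hydrogen-bond geometry of a donor/hydrogen/acceptor triple
#'
#' @param donor,hydrogen,acceptor finite 3-vectors (nm).
#' @return named numeric: `distance` = |donor - acceptor| (nm) and `angle` =
#'   the angle at the donor vertex between donor->hydrogen and
#'   donor->acceptor, degrees in \[0, 180\].
#' @examples
#' hbondGeometry(c(0, 0, 0), c(0.1, 0, 0), c(0.3, 0, 0))  # 0.3 nm, 0 deg
#' @export
hbondGeometry <- function(donor, hydrogen, acceptor) {
  stopifnot(length(donor) == 3L, length(hydrogen) == 3L,
            length(acceptor) == 3L,
            all(is.finite(c(donor, hydrogen, acceptor))))
  u <- hydrogen - donor
  v <- acceptor - donor
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0)
    stop(ecError("degenerate geometry: donor and hydrogen coincide",
                 "geometry_error"))
  ang <- if (nv == 0) 0 else {
    ct <- sum(u * v) / (nu * nv)
    acos(min(1, max(-1, ct))) * 180 / pi
  }
  c(distance = nv, angle = ang)
}

# all-pairs Euclidean distances between two point sets (rows), nm
.crossDist <- function(P, Q) {
  d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
  sqrt(pmax(d2, 0))
}

# Per-ensemble role index: resolves the ChemistryTable against the topology
# once, so per-frame detection is pure geometry. Unknown residue codes are
# excluded with one warning.
.roleIndex <- function(ensemble, table, strict = FALSE) {
  a <- ensemble@atoms
  rid <- paste(a$chain_id, a$res_seq, a$i_code, sep = "\r")
  ures <- !duplicated(rid)
  residues <- data.frame(rid = rid[ures], chain = a$chain_id[ures],
                         res_seq = a$res_seq[ures], i_code = a$i_code[ures],
                         res_name = a$res_name[ures],
                         stringsAsFactors = FALSE)
  unknown <- vapply(unique(residues$res_name),
                    function(r) !residueChemistry(r, table)$known,
                    logical(1))
  if (any(unknown))
    warning("excluding unknown residue type(s): ",
            paste(names(unknown)[unknown], collapse = ", "), call. = FALSE)
  donors <- list(); acceptors <- integer(); acc_res <- character()
  sc <- list(); pos <- list(); neg <- list(); ring <- list()
  masses <- table@masses
  for (k in seq_len(nrow(residues))) {
    rk <- residues$rid[k]
    chem <- residueChemistry(residues$res_name[k], table)
    if (!chem$known) next
    idx <- which(rid == rk)
    nm <- a$name[idx]
    # donor triples: heavy atom + each present candidate hydrogen
    if (nrow(chem$donors)) {
      for (j in seq_len(nrow(chem$donors))) {
        d_i <- idx[nm == chem$donors$atom[j]]
        if (!length(d_i)) next
        hyd <- strsplit(chem$donors$hydrogens[j], "|", fixed = TRUE)[[1L]]
        h_i <- idx[nm %in% hyd]
        if (!length(h_i)) {
          msg <- sprintf("donor %s of %s %s has no resolvable hydrogen",
                         chem$donors$atom[j], residues$res_name[k],
                         sub("\r", ":", sub("\r$", "", rk)))
          if (strict) stop(ecError(msg, "chemistry_error"))
          warning(msg, call. = FALSE)
          next
        }
        donors[[length(donors) + 1L]] <-
          data.frame(rid = rk, d = d_i[1L], h = h_i)
      }
    }
    acc_i <- idx[nm %in% chem$acceptors]
    acceptors <- c(acceptors, acc_i)
    acc_res <- c(acc_res, rep(rk, length(acc_i)))
    sc_i <- idx[nm %in% chem$sidechain |
                  (a$element[idx] == "H" & isSidechainHydrogen(nm))]
    if (length(sc_i)) sc[[rk]] <- sc_i
    p_i <- idx[nm %in% chem$pos_charge & a$element[idx] == "N"]
    if (length(p_i)) pos[[rk]] <- p_i
    n_i <- idx[nm %in% chem$neg_charge & a$element[idx] == "O"]
    if (length(n_i)) neg[[rk]] <- n_i
    r_i <- idx[nm %in% chem$aromatic]
    if (length(r_i) >= 3L) ring[[rk]] <- r_i
  }
  donors <- if (length(donors)) do.call(rbind, donors)
            else data.frame(rid = character(), d = integer(), h = integer())
  list(residues = residues, donors = donors,
       acceptors = data.frame(rid = acc_res, i = acceptors,
                              stringsAsFactors = FALSE),
       sidechain = sc, pos = pos, neg = neg, ring = ring,
       mass = masses[a$element])
}

# empty event table with the canonical column set
.emptyEvents <- function() {
  data.frame(frame = integer(), kind = character(),
             chain_a = character(), res_a = integer(), icode_a = character(),
             resname_a = character(), name_a = character(),
             chain_b = character(), res_b = integer(), icode_b = character(),
             resname_b = character(), name_b = character(),
             hydrogen = character(), distance_nm = numeric(),
             angle_deg = numeric(), stringsAsFactors = FALSE)
}

# order every event's residue pair canonically (chain, res_seq, i_code)
# and sort rows so the event multiset has a unique representation
.canonicalizeEvents <- function(ev) {
  if (!nrow(ev)) return(ev)
  swap <- (ev$chain_b < ev$chain_a) |
    (ev$chain_b == ev$chain_a & (ev$res_b < ev$res_a |
      (ev$res_b == ev$res_a & ev$icode_b < ev$icode_a)))
  if (any(swap)) {
    for (cols in list(c("chain_a", "chain_b"), c("res_a", "res_b"),
                      c("icode_a", "icode_b"), c("resname_a", "resname_b"),
                      c("name_a", "name_b"))) {
      tmp <- ev[[cols[1L]]][swap]
      ev[[cols[1L]]][swap] <- ev[[cols[2L]]][swap]
      ev[[cols[2L]]][swap] <- tmp
    }
  }
  o <- order(ev$frame, ev$kind, ev$chain_a, ev$res_a, ev$icode_a,
             ev$chain_b, ev$res_b, ev$icode_b, ev$name_a, ev$name_b,
             ev$hydrogen)
  ev <- ev[o, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

.ridParts <- function(res_df, rid) {
  m <- match(rid, res_df$rid)
  res_df[m, c("chain", "res_seq", "i_code", "res_name"), drop = FALSE]
}

.resolveFrames <- function(ensemble, frames) {
  if (is.null(frames)) return(seq_len(nFrames(ensemble)))
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > nFrames(ensemble)))
    stop(ecError("frame selection out of range", "frame_error"))
  frames
}

#' Detect hydrogen bonds
#'
#' One event per (donor heavy atom, bonded hydrogen, acceptor) triple with
#' donor-acceptor distance strictly below `hbondDist` and
#' hydrogen-donor-acceptor angle strictly below `hbondAngle`. Intra-residue
#' pairs are excluded; both intra- and inter-chain bonds are reported.
#' Donors whose hydrogen cannot be resolved in the topology are skipped with
#' a warning (`strict = TRUE` turns this into an error).
#'
#' @param ensemble a [StructuralEnsemble-class] with explicit hydrogens.
#' @param table a [ChemistryTable-class].
#' @param thresholds a [ContactThresholds-class].
#' @param frames integer frame indices, default all.
#' @param strict error (rather than warn) on unresolvable donor hydrogens.
#' @return data.frame of events: `frame`, `kind`, canonical residue pair
#'   columns (`chain_a`, `res_a`, `icode_a`, `resname_a`, `name_a`, same for
#'   b), `hydrogen`, `distance_nm`, `angle_deg`.
#' @export
detectHBonds <- function(ensemble, table = defaultChemistry(),
                         thresholds = contactThresholds(), frames = NULL,
                         strict = FALSE) {
  frames <- .resolveFrames(ensemble, frames)
  ri <- .roleIndex(ensemble, table, strict = strict)
  don <- ri$donors
  acc <- ri$acceptors
  if (!nrow(don) || !nrow(acc)) return(.emptyEvents())
  a <- ensemble@atoms
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    X <- ensemble@coords[, , frames[fi], drop = TRUE]
    D <- .crossDist(X[don$d, , drop = FALSE], X[acc$i, , drop = FALSE])
    cand <- which(D < thresholds@hbondDist &
                    outer(don$rid, acc$rid, "!="), arr.ind = TRUE)
    if (!nrow(cand)) next
    keep <- logical(nrow(cand))
    ang <- numeric(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      g <- hbondGeometry(X[don$d[cand[k, 1L]], ],
                         X[don$h[cand[k, 1L]], ],
                         X[acc$i[cand[k, 2L]], ])
      ang[k] <- g["angle"]
      keep[k] <- g["angle"] < thresholds@hbondAngle
    }
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]
    pa <- .ridParts(ri$residues, don$rid[cand[, 1L]])
    pb <- .ridParts(ri$residues, acc$rid[cand[, 2L]])
    out[[fi]] <- data.frame(frame = frames[fi], kind = "hbond",
      chain_a = pa$chain, res_a = pa$res_seq, icode_a = pa$i_code,
      resname_a = pa$res_name, name_a = a$name[don$d[cand[, 1L]]],
      chain_b = pb$chain, res_b = pb$res_seq, icode_b = pb$i_code,
      resname_b = pb$res_name, name_b = a$name[acc$i[cand[, 2L]]],
      hydrogen = a$name[don$h[cand[, 1L]]],
      distance_nm = D[cand], angle_deg = ang[keep],
      stringsAsFactors = FALSE)
  }
  .canonicalizeEvents(do.call(rbind, c(out, list(.emptyEvents()))))
}

#' Side-chain centre of mass of one residue in one frame
#'
#' Mass-weighted mean position of the residue's side-chain atoms present in
#' the frame; hydrogens on side-chain heavy atoms are included when present.
#'
#' @param ensemble a [StructuralEnsemble-class].
#' @param chain,res_seq,i_code residue identity.
#' @param frame frame index.
#' @param table a [ChemistryTable-class].
#' @return 3-vector, nm.
#' @export
sidechainCOM <- function(ensemble, chain, res_seq, frame = 1L,
                         i_code = "", table = defaultChemistry()) {
  ri <- .roleIndex(ensemble, table)
  rk <- paste(chain, res_seq, i_code, sep = "\r")
  idx <- ri$sidechain[[rk]]
  if (is.null(idx))
    stop(ecError(sprintf("residue %s:%s has no side-chain atoms",
                         chain, res_seq), "no_sidechain_error"))
  X <- ensemble@coords[idx, , .resolveFrames(ensemble, frame), drop = FALSE]
  w <- ri$mass[idx]
  colSums(matrix(X, ncol = 3) * w) / sum(w)
}

# side-chain COM matrix for all residues with a non-empty side chain
.comMatrix <- function(ri, X) {
  rk <- names(ri$sidechain)
  com <- t(vapply(rk, function(r) {
    idx <- ri$sidechain[[r]]
    w <- ri$mass[idx]
    colSums(X[idx, , drop = FALSE] * w) / sum(w)
  }, numeric(3)))
  rownames(com) <- rk
  com
}

.pairEvents <- function(frame, kind, res_df, rid_a, rid_b, dist,
                        name_a = "COM", name_b = "COM") {
  pa <- .ridParts(res_df, rid_a)
  pb <- .ridParts(res_df, rid_b)
  data.frame(frame = frame, kind = kind,
             chain_a = pa$chain, res_a = pa$res_seq, icode_a = pa$i_code,
             resname_a = pa$res_name, name_a = name_a,
             chain_b = pb$chain, res_b = pb$res_seq, icode_b = pb$i_code,
             resname_b = pb$res_name, name_b = name_b,
             hydrogen = "", distance_nm = dist, angle_deg = NA_real_,
             stringsAsFactors = FALSE)
}

#' Detect hydrophobic (side-chain packing) contacts
#'
#' One event per unordered residue pair whose side-chain centres of mass lie
#' strictly below `hydrophobicDist` apart. Applies to every residue type
#' with a non-empty side chain (polar and charged side chains can and do
#' appear in such contacts); glycine never participates.
#'
#' @inheritParams detectHBonds
#' @return event data.frame (see [detectHBonds()]); `name_a`/`name_b` are
#'   `"COM"`.
#' @export
detectHydrophobic <- function(ensemble, table = defaultChemistry(),
                              thresholds = contactThresholds(),
                              frames = NULL) {
  frames <- .resolveFrames(ensemble, frames)
  ri <- .roleIndex(ensemble, table)
  if (length(ri$sidechain) < 2L) return(.emptyEvents())
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    X <- ensemble@coords[, , frames[fi], drop = TRUE]
    com <- .comMatrix(ri, X)
    D <- .crossDist(com, com)
    cand <- which(upper.tri(D) & D < thresholds@hydrophobicDist,
                  arr.ind = TRUE)
    if (!nrow(cand)) next
    out[[fi]] <- .pairEvents(frames[fi], "hydrophobic", ri$residues,
                             rownames(com)[cand[, 1L]],
                             rownames(com)[cand[, 2L]], D[cand])
  }
  .canonicalizeEvents(do.call(rbind, c(out, list(.emptyEvents()))))
}

#' Detect salt bridges
#'
#' One event per (positively charged, negatively charged) residue pair whose
#' minimum distance between any positive-group nitrogen and any
#' negative-group oxygen is strictly below `saltBridgeDist`
#' (Barlow-Thornton convention). The reported atoms are the closest N/O
#' pair.
#'
#' @inheritParams detectHBonds
#' @return event data.frame (see [detectHBonds()]).
#' @export
detectSaltBridges <- function(ensemble, table = defaultChemistry(),
                              thresholds = contactThresholds(),
                              frames = NULL) {
  frames <- .resolveFrames(ensemble, frames)
  ri <- .roleIndex(ensemble, table)
  if (!length(ri$pos) || !length(ri$neg)) return(.emptyEvents())
  a <- ensemble@atoms
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    X <- ensemble@coords[, , frames[fi], drop = TRUE]
    rows <- list()
    for (rp in names(ri$pos)) {
      for (rn in names(ri$neg)) {
        if (rp == rn) next
        D <- .crossDist(X[ri$pos[[rp]], , drop = FALSE],
                        X[ri$neg[[rn]], , drop = FALSE])
        m <- which.min(D)
        if (D[m] < thresholds@saltBridgeDist) {
          ij <- arrayInd(m, dim(D))
          rows[[length(rows) + 1L]] <- .pairEvents(
            frames[fi], "salt_bridge", ri$residues, rp, rn, D[m],
            name_a = a$name[ri$pos[[rp]][ij[1L]]],
            name_b = a$name[ri$neg[[rn]][ij[2L]]])
        }
      }
    }
    if (length(rows)) out[[fi]] <- do.call(rbind, rows)
  }
  .canonicalizeEvents(do.call(rbind, c(out, list(.emptyEvents()))))
}

#' Detect aromatic contacts
#'
#' The subset of hydrophobic-criterion contacts in which both residues carry
#' an aromatic ring (Phe, Tyr, Trp, His, phosphotyrosine), relabelled
#' `aromatic`; the pair additionally has to satisfy the same cutoff on the
#' distance between the two ring-atom centroids, which is the distance
#' reported. No ring-plane angle term is applied.
#'
#' @inheritParams detectHBonds
#' @return event data.frame (see [detectHBonds()]); `name_a`/`name_b` are
#'   `"RING"`.
#' @export
detectAromatic <- function(ensemble, table = defaultChemistry(),
                           thresholds = contactThresholds(), frames = NULL) {
  frames <- .resolveFrames(ensemble, frames)
  ri <- .roleIndex(ensemble, table)
  if (length(ri$ring) < 2L) return(.emptyEvents())
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    X <- ensemble@coords[, , frames[fi], drop = TRUE]
    com <- .comMatrix(ri, X)
    rk <- names(ri$ring)
    cen <- t(vapply(rk, function(r)
      colMeans(X[ri$ring[[r]], , drop = FALSE]), numeric(3)))
    Dc <- .crossDist(cen, cen)
    Dm <- .crossDist(com[rk, , drop = FALSE], com[rk, , drop = FALSE])
    cand <- which(upper.tri(Dc) & Dc < thresholds@hydrophobicDist &
                    Dm < thresholds@hydrophobicDist, arr.ind = TRUE)
    if (!nrow(cand)) next
    out[[fi]] <- .pairEvents(frames[fi], "aromatic", ri$residues,
                             rk[cand[, 1L]], rk[cand[, 2L]], Dc[cand],
                             name_a = "RING", name_b = "RING")
  }
  .canonicalizeEvents(do.call(rbind, c(out, list(.emptyEvents()))))
}

#' Run all four contact detectors
#'
#' @inheritParams detectHBonds
#' @return combined event data.frame across kinds.
#' @export
detectAllContacts <- function(ensemble, table = defaultChemistry(),
                              thresholds = contactThresholds(),
                              frames = NULL) {
  rbind(detectHBonds(ensemble, table, thresholds, frames),
        detectSaltBridges(ensemble, table, thresholds, frames),
        detectHydrophobic(ensemble, table, thresholds, frames),
        detectAromatic(ensemble, table, thresholds, frames))
}

#' Write an event table as TSV
#'
#' @param events event data.frame from the detectors.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEventsTSV <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
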