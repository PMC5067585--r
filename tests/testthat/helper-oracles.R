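# Independent brute-force oracles: plain nested loops over all atom/residue
# combinations, sharing only the ChemistryTable *data* with the package.
# Each returns a sorted character vector of event keys for set comparison.

oracle_dist <- function(p, q) sqrt(sum((p - q)^2))

oracle_residues <- function(ens) {
  a <- atomTable(ens)
  split(seq_len(nrow(a)), paste(a$chain_id, a$res_seq, a$i_code, sep = "|"))
}

oracle_pair_key <- function(kind, id1, id2, extra = "") {
  ids <- sort(c(id1, id2))
  paste(kind, ids[1], ids[2], extra)
}

oracle_hbonds <- function(ens, frame, table, th) {
  a <- atomTable(ens)
  X <- frameCoords(ens, frame)
  res <- oracle_residues(ens)
  keys <- character(0)
  for (r1 in names(res)) for (r2 in names(res)) {
    if (r1 == r2) next
    i_d <- res[[r1]]; i_a <- res[[r2]]
    chem_d <- residueChemistry(a$res_name[i_d[1]], table)
    chem_a <- residueChemistry(a$res_name[i_a[1]], table)
    if (!chem_d$known || !chem_a$known) next
    for (j in seq_len(nrow(chem_d$donors))) {
      d <- i_d[a$name[i_d] == chem_d$donors$atom[j]]
      if (!length(d)) next
      hyds <- strsplit(chem_d$donors$hydrogens[j], "|", fixed = TRUE)[[1]]
      for (h in i_d[a$name[i_d] %in% hyds]) {
        for (acc in i_a[a$name[i_a] %in% chem_a$acceptors]) {
          dist <- oracle_dist(X[d, ], X[acc, ])
          if (dist >= th@hbondDist) next
          u <- X[h, ] - X[d, ]; v <- X[acc, ] - X[d, ]
          ang <- acos(max(-1, min(1, sum(u * v) /
            (sqrt(sum(u^2)) * sqrt(sum(v^2)))))) * 180 / pi
          if (ang < th@hbondAngle)
            keys <- c(keys, paste("hbond", r1, a$name[d], a$name[h],
                                  r2, a$name[acc]))
        }
      }
    }
  }
  sort(keys)
}

oracle_sidechain_com <- function(ens, idx, frame, table) {
  a <- atomTable(ens)
  X <- frameCoords(ens, frame)
  chem <- residueChemistry(a$res_name[idx[1]], table)
  if (!chem$known) return(NULL)
  sel <- idx[a$name[idx] %in% chem$sidechain |
               (a$element[idx] == "H" & grepl("^H[BGDEZH]", a$name[idx]))]
  if (!length(sel)) return(NULL)
  w <- table@masses[a$element[sel]]
  colSums(X[sel, , drop = FALSE] * w) / sum(w)
}

oracle_hydrophobic <- function(ens, frame, table, th) {
  res <- oracle_residues(ens)
  coms <- lapply(res, oracle_sidechain_com, ens = ens, frame = frame,
                 table = table)
  keys <- character(0)
  nm <- names(res)
  for (i in seq_along(res)) for (j in seq_along(res)) {
    if (i >= j) next
    if (is.null(coms[[i]]) || is.null(coms[[j]])) next
    if (oracle_dist(coms[[i]], coms[[j]]) < th@hydrophobicDist)
      keys <- c(keys, oracle_pair_key("hydrophobic", nm[i], nm[j]))
  }
  sort(keys)
}

oracle_salt <- function(ens, frame, table, th) {
  a <- atomTable(ens)
  X <- frameCoords(ens, frame)
  res <- oracle_residues(ens)
  nm <- names(res)
  keys <- character(0)
  for (i in seq_along(res)) for (j in seq_along(res)) {
    if (i == j) next
    ci <- residueChemistry(a$res_name[res[[i]][1]], table)
    cj <- residueChemistry(a$res_name[res[[j]][1]], table)
    if (!ci$known || !cj$known) next
    pos <- res[[i]][a$name[res[[i]]] %in% ci$pos_charge &
                      a$element[res[[i]]] == "N"]
    neg <- res[[j]][a$name[res[[j]]] %in% cj$neg_charge &
                      a$element[res[[j]]] == "O"]
    if (!length(pos) || !length(neg)) next
    dmin <- Inf
    for (p in pos) for (q in neg)
      dmin <- min(dmin, oracle_dist(X[p, ], X[q, ]))
    if (dmin < th@saltBridgeDist)
      keys <- c(keys, oracle_pair_key("salt_bridge", nm[i], nm[j]))
  }
  sort(unique(keys))
}

oracle_aromatic <- function(ens, frame, table, th) {
  a <- atomTable(ens)
  X <- frameCoords(ens, frame)
  res <- oracle_residues(ens)
  nm <- names(res)
  coms <- lapply(res, oracle_sidechain_com, ens = ens, frame = frame,
                 table = table)
  rings <- lapply(res, function(idx) {
    chem <- residueChemistry(a$res_name[idx[1]], table)
    sel <- idx[a$name[idx] %in% chem$aromatic]
    if (length(sel) < 3) NULL else colMeans(X[sel, , drop = FALSE])
  })
  keys <- character(0)
  for (i in seq_along(res)) for (j in seq_along(res)) {
    if (i >= j) next
    if (is.null(rings[[i]]) || is.null(rings[[j]])) next
    if (is.null(coms[[i]]) || is.null(coms[[j]])) next
    if (oracle_dist(coms[[i]], coms[[j]]) < th@hydrophobicDist &&
        oracle_dist(rings[[i]], rings[[j]]) < th@hydrophobicDist)
      keys <- c(keys, oracle_pair_key("aromatic", nm[i], nm[j]))
  }
  sort(keys)
}

# event data.frames -> comparable key sets
event_keys_hbond <- function(ev) {
  if (!nrow(ev)) return(character(0))
  # donor side is whichever side carries the hydrogen's residue; keys built
  # directly from both orderings and matched against the oracle's donor-first
  # form by trying both
  k1 <- paste("hbond", paste(ev$chain_a, ev$res_a, ev$icode_a, sep = "|"),
              ev$name_a, ev$hydrogen,
              paste(ev$chain_b, ev$res_b, ev$icode_b, sep = "|"), ev$name_b)
  k2 <- paste("hbond", paste(ev$chain_b, ev$res_b, ev$icode_b, sep = "|"),
              ev$name_b, ev$hydrogen,
              paste(ev$chain_a, ev$res_a, ev$icode_a, sep = "|"), ev$name_a)
  list(k1 = k1, k2 = k2)
}

event_keys_pair <- function(ev, kind) {
  ev <- ev[ev$kind == kind, , drop = FALSE]
  if (!nrow(ev)) return(character(0))
  sort(vapply(seq_len(nrow(ev)), function(i)
    oracle_pair_key(kind,
                    paste(ev$chain_a[i], ev$res_a[i], ev$icode_a[i],
                          sep = "|"),
                    paste(ev$chain_b[i], ev$res_b[i], ev$icode_b[i],
                          sep = "|")), character(1)))
}

# match hydrogen-bond events against oracle keys allowing either pair order
expect_hbond_set_equal <- function(ev, oracle_keys) {
  ks <- event_keys_hbond(ev)
  if (is.character(ks) && !length(ks)) {
    testthat::expect_length(oracle_keys, 0)
    return(invisible(TRUE))
  }
  chosen <- ifelse(ks$k1 %in% oracle_keys, ks$k1, ks$k2)
  testthat::expect_setequal(chosen, oracle_keys)
  testthat::expect_equal(length(chosen), length(oracle_keys))
  invisible(TRUE)
}

# brute-force optimal-rotation RMSD: minimize over Euler angles after
# removing centroids (multi-start BFGS)
oracle_fit_rmsd <- function(ref, mob) {
  A <- sweep(ref, 2, colMeans(ref))
  B <- sweep(mob, 2, colMeans(mob))
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    matrix(c(cy * cz, cy * sz, -sy,
             sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
             cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
           3, 3, byrow = TRUE)
  }
  f <- function(ang) sqrt(mean(rowSums((B %*% t(rot(ang)) - A)^2)))
  best <- Inf
  set.seed(42)
  for (s in 1:12) {
    start <- stats::runif(3, -pi, pi)
    o <- stats::optim(start, f, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
    best <- min(best, o$value)
  }
  best
}
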