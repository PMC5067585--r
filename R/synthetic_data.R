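# Minimal residue templates used by the generators. Each template is the
# smallest atom set that triggers exactly the intended detector(s); local
# coordinates are nm relative to the residue anchor, with the interaction
# atom (donor N, acceptor O, charged atom, ring centroid, side-chain COM
# carrier) at the anchor itself so designed anchor distances equal the
# detector-relevant distances.
.pairTemplates <- function(kind) {
  hexagon <- function() {
    th <- seq(0, by = pi / 3, length.out = 6)
    r <- 0.139
    data.frame(name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
               x = 0, y = r * cos(th), z = r * sin(th))
  }
  tpl <- function(res, het, df) list(res_name = res, hetatm = het, atoms = df)
  switch(kind,
    hbond = list(
      a = tpl("GLY", FALSE, data.frame(name = c("N", "H"),
                                       x = c(0, 0.1), y = 0, z = 0)),
      b = tpl("GLY", FALSE, data.frame(name = "O", x = 0, y = 0, z = 0))),
    salt_bridge = list(
      # HH11 perpendicular to the bridge axis: the N-H...O angle stays near
      # 90 deg, so the pair can never double as a hydrogen bond
      a = tpl("ARG", FALSE, data.frame(name = c("NH1", "HH11"),
                                       x = 0, y = c(0, 0.1), z = 0)),
      b = tpl("PTR", TRUE, data.frame(name = c("O1P", "P"),
                                      x = c(0, 0.15), y = 0, z = 0))),
    hydrophobic = list(
      a = tpl("ALA", FALSE, data.frame(name = "CB", x = 0, y = 0, z = 0)),
      b = tpl("LEU", FALSE, data.frame(name = "CB", x = 0, y = 0, z = 0))),
    aromatic = list(
      a = tpl("PHE", FALSE, hexagon()),
      b = tpl("PHE", FALSE, hexagon())),
    stop(ecError(paste("unknown designed-pair kind:", kind), "input_error")))
}

# distances (nm) placed for present/absent frames: present at 80% of the
# governing threshold, absent at 150%, so jitter can never flip a detection
# (the induced hydrophobic contact of a salt/aromatic pair keeps a >=120%
# margin as well: the charged-pair COM sits ~0.1 nm beyond the N-O axis)
.designDistances <- function(kind, th) {
  gov <- switch(kind, hbond = th@hbondDist, salt_bridge = th@saltBridgeDist,
                hydrophobic = th@hydrophobicDist,
                aromatic = th@hydrophobicDist)
  c(present = 0.8 * gov, absent = 1.5 * gov)
}

#' Describe one designed contact pair
#'
#' @param kind one of `hbond`, `salt_bridge`, `hydrophobic`, `aromatic`.
#' @param chain_a,res_a,chain_b,res_b residue identities the pair will carry.
#' @param p Bernoulli per-frame presence probability (realized once from the
#'   spec seed), or
#' @param schedule explicit logical presence vector (length `n_frames`).
#' @return list describing the pair, for [contactScheduleSpec()].
#' @export
designedPair <- function(kind, chain_a, res_a, chain_b, res_b, p = NULL,
                         schedule = NULL) {
  if (is.null(p) == is.null(schedule))
    stop(ecError("give exactly one of p or schedule", "input_error"))
  list(kind = kind, chain_a = chain_a, res_a = as.integer(res_a),
       chain_b = chain_b, res_b = as.integer(res_b), p = p,
       schedule = schedule)
}

#' Specify a synthetic contact ensemble
#'
#' @param n_frames number of frames.
#' @param seed RNG seed for Bernoulli schedules and positional jitter.
#' @param pairs list of [designedPair()] descriptions.
#' @param jitter nm of rigid per-residue positional noise per frame; kept
#'   small enough (relative to the placement margins) that designed
#'   presence/absence is preserved exactly.
#' @param thresholds the [ContactThresholds-class] the geometry is designed
#'   against.
#' @return validated spec list for [generateContactEnsemble()].
#' @export
contactScheduleSpec <- function(n_frames, seed, pairs, jitter = 0.005,
                                thresholds = contactThresholds()) {
  stopifnot(n_frames >= 1L, length(pairs) >= 1L)
  if (jitter < 0 || jitter * 2 >= 0.1 * thresholds@hbondDist)
    stop(ecError("jitter too large for the placement margins",
                 "input_error"))
  for (p in pairs) {
    if (!is.null(p$schedule) && length(p$schedule) != n_frames)
      stop(ecError("schedule length must equal n_frames", "input_error"))
  }
  ids <- unlist(lapply(pairs, function(p)
    c(paste(p$chain_a, p$res_a), paste(p$chain_b, p$res_b))))
  if (anyDuplicated(ids))
    stop(ecError(paste("conflicting constraints: residue(s)",
                       paste(unique(ids[duplicated(ids)]), collapse = ", "),
                       "appear in more than one designed pair"),
                 "construction_error"))
  list(n_frames = as.integer(n_frames), seed = as.integer(seed),
       pairs = pairs, jitter = jitter, thresholds = thresholds)
}

#' Generate a two-chain ensemble with exact contact ground truth
#'
#' Builds a minimal multi-model system in which every designed pair sits at
#' its own spatial station (stations 5 nm apart): present frames place the
#' pair at 80% of the governing threshold, absent frames at 150% of the
#' hydrophobic cutoff, so the margin bands guarantee that the detectors
#' reproduce the designed schedules exactly despite the positional jitter.
#' Salt-bridge pairs (single-atom side chains below 0.4 nm) and aromatic
#' pairs (ring centroid = side-chain COM) necessarily also satisfy the
#' hydrophobic criterion; the truth table lists those induced hydrophobic
#' schedules explicitly.
#'
#' @param spec output of [contactScheduleSpec()].
#' @return list with `ensemble` (a [StructuralEnsemble-class]), `truth`
#'   (long data.frame: `kind`, canonical pair columns, `frame`, `present`)
#'   and `designed` (per pair+kind: `n_present`, `occupancy_pct`).
#' @export
generateContactEnsemble <- function(spec) {
  set.seed(spec$seed)
  nf <- spec$n_frames
  atoms <- list()
  place <- list()  # per pair: template coords, indices, schedule
  serial <- 0L
  for (k in seq_along(spec$pairs)) {
    p <- spec$pairs[[k]]
    tpl <- .pairTemplates(p$kind)
    sched <- if (!is.null(p$schedule)) as.logical(p$schedule)
             else stats::runif(nf) < p$p
    jit_a <- matrix(stats::runif(nf * 3, -1, 1), nf, 3) *
      spec$jitter / sqrt(3)
    jit_b <- matrix(stats::runif(nf * 3, -1, 1), nf, 3) *
      spec$jitter / sqrt(3)
    station <- c(5 * (k - 1L), 0, 0)
    mk <- function(side, tp, chain, res) {
      n <- nrow(tp$atoms)
      data.frame(serial = serial + seq_len(n), name = tp$atoms$name,
                 element = "", alt_loc = "", res_name = tp$res_name,
                 chain_id = chain, res_seq = res, i_code = "",
                 occupancy_field = 1, is_hetatm = tp$hetatm,
                 stringsAsFactors = FALSE)
    }
    at_a <- mk("a", tpl$a, p$chain_a, p$res_a)
    serial <- serial + nrow(at_a)
    at_b <- mk("b", tpl$b, p$chain_b, p$res_b)
    serial <- serial + nrow(at_b)
    atoms[[k]] <- rbind(at_a, at_b)
    place[[k]] <- list(kind = p$kind, sched = sched, station = station,
                       local_a = as.matrix(tpl$a$atoms[c("x", "y", "z")]),
                       local_b = as.matrix(tpl$b$atoms[c("x", "y", "z")]),
                       jit_a = jit_a, jit_b = jit_b)
  }
  atoms <- do.call(rbind, atoms)
  atoms$element <- .inferElement(atoms$element, atoms$name, proteinMasses())
  n_atoms <- nrow(atoms)
  coords <- array(NA_real_, c(n_atoms, 3L, nf))
  row0 <- 0L
  dists <- lapply(place, function(pl)
    .designDistances(pl$kind, spec$thresholds))
  for (k in seq_along(place)) {
    pl <- place[[k]]
    na <- nrow(pl$local_a); nb <- nrow(pl$local_b)
    d <- ifelse(pl$sched, dists[[k]]["present"], dists[[k]]["absent"])
    for (f in seq_len(nf)) {
      anchor_a <- pl$station + pl$jit_a[f, ]
      anchor_b <- pl$station + c(d[f], 0, 0) + pl$jit_b[f, ]
      coords[row0 + seq_len(na), , f] <-
        pl$local_a + rep(anchor_a, each = na)
      coords[row0 + na + seq_len(nb), , f] <-
        pl$local_b + rep(anchor_b, each = nb)
    }
    row0 <- row0 + na + nb
  }
  ensemble <- new("StructuralEnsemble", atoms = atoms, coords = coords)
  truth <- list()
  for (k in seq_along(spec$pairs)) {
    p <- spec$pairs[[k]]
    kinds <- switch(p$kind, salt_bridge = c("salt_bridge", "hydrophobic"),
                    aromatic = c("aromatic", "hydrophobic"), p$kind)
    # canonical (chain, res) order, as the detectors report pairs
    swap <- (p$chain_b < p$chain_a) |
      (p$chain_b == p$chain_a & p$res_b < p$res_a)
    ca <- if (swap) p$chain_b else p$chain_a
    ra <- if (swap) p$res_b else p$res_a
    cb <- if (swap) p$chain_a else p$chain_b
    rb <- if (swap) p$res_a else p$res_b
    for (kind in kinds) {
      truth[[length(truth) + 1L]] <-
        data.frame(kind = kind, chain_a = ca, res_a = ra, chain_b = cb,
                   res_b = rb, frame = seq_len(nf),
                   present = place[[k]]$sched, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  key <- paste(truth$kind, truth$chain_a, truth$res_a, truth$chain_b,
               truth$res_b, sep = "\r")
  designed <- do.call(rbind, lapply(split(truth, key), function(g) {
    data.frame(kind = g$kind[1L], chain_a = g$chain_a[1L],
               res_a = g$res_a[1L], chain_b = g$chain_b[1L],
               res_b = g$res_b[1L], n_present = sum(g$present),
               n_frames = nf,
               occupancy_pct = 100 * sum(g$present) / nf,
               stringsAsFactors = FALSE)
  }))
  rownames(designed) <- NULL
  list(ensemble = ensemble, truth = truth, designed = designed)
}

#' Generate a two-conformer clustering fixture
#'
#' `n_a` frames wobble around conformer A and `n_b` around conformer B; the
#' two conformers differ by an internal (rigid-motion-free) distortion of
#' post-fit backbone RMSD `separation`, and per-frame wobble keeps
#' within-group pairwise RMSD below `2 * wobble`.
#'
#' @param n_a,n_b frames per conformer (A frames come first).
#' @param separation nm, post-fit RMSD between the conformers.
#' @param wobble nm; must be `< separation / 4` (when `n_b > 0`).
#' @param seed RNG seed.
#' @return a [StructuralEnsemble-class] of `n_a + n_b` frames over 8
#'   backbone atoms.
#' @export
generateClusterFixture <- function(n_a, n_b, separation, wobble, seed) {
  if (n_b > 0L && wobble >= separation / 4)
    stop(ecError("wobble must be below separation / 4", "input_error"))
  stopifnot(n_a >= 1L)
  set.seed(seed)
  atoms <- data.frame(serial = 1:8,
                      name = rep(c("N", "CA", "C", "O"), 2),
                      element = rep(c("N", "C", "C", "O"), 2),
                      alt_loc = "", res_name = "GLY", chain_id = "A",
                      res_seq = rep(1:2, each = 4), i_code = "",
                      occupancy_field = 1, is_hetatm = FALSE,
                      stringsAsFactors = FALSE)
  A <- matrix(stats::runif(24, 0, 1), 8, 3)
  B <- A
  if (n_b > 0L) {
    # distortion projected free of rigid motion by refitting, then scaled to
    # the requested post-fit RMSD by fixed-point iteration
    B <- A + matrix(stats::rnorm(24), 8, 3)
    for (it in 1:5) {
      k <- .kabsch(A, B)
      B <- B %*% t(k$rotation) + rep(k$translation, each = 8)
      B <- A + (B - A) * separation / k$rmsd
    }
  }
  nf <- n_a + n_b
  coords <- array(NA_real_, c(8, 3, nf))
  sdw <- wobble / 2.5
  for (f in seq_len(nf)) {
    base <- if (f <= n_a) A else B
    coords[, , f] <- base + matrix(stats::rnorm(24, sd = sdw), 8, 3)
  }
  new("StructuralEnsemble", atoms = atoms, coords = coords)
}

#' Generate a test projection series
#'
#' @param kind `cosine` (`cos(mode * pi * t/T)`), `constant` (all ones) or
#'   `random_walk` (cumulative sum of unit Gaussian steps).
#' @param n series length (>= 2).
#' @param mode half-period count for `cosine`.
#' @param seed RNG seed (random walk only).
#' @return numeric series of length `n`.
#' @export
generateProjectionSeries <- function(kind = c("cosine", "constant",
                                              "random_walk"),
                                     n, mode = 1L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 2L)
  t <- seq(0, 1, length.out = n)
  switch(kind,
         cosine = cos(mode * pi * t),
         constant = rep(1, n),
         random_walk = { set.seed(seed); cumsum(stats::rnorm(n)) })
}

#' Generate a random frame for detector stress-testing
#'
#' Scatters `n_residues` residues (drawn from GLY/SER/ARG/GLU/PHE/LEU/PTR
#' minimal builds with explicit polar hydrogens) uniformly in a cubic box,
#' with random internal atom offsets. No designed contacts: the frame is
#' meant to be compared against an exhaustive brute-force scan.
#'
#' @param n_residues number of residues (alternating between two chains).
#' @param seed RNG seed.
#' @param box box edge, nm (default 2 gives a realistic contact density).
#' @return a single-frame [StructuralEnsemble-class]
#' @export
generateRandomFrame <- function(n_residues, seed, box = 2) {
  set.seed(seed)
  palette <- list(
    GLY = c("N", "H", "O"),
    SER = c("N", "H", "O", "CB", "OG", "HG"),
    ARG = c("N", "H", "O", "CB", "NE", "HE", "CZ", "NH1", "HH11", "HH12",
            "NH2", "HH21", "HH22"),
    GLU = c("N", "H", "O", "CB", "CG", "CD", "OE1", "OE2"),
    PHE = c("N", "H", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    LEU = c("N", "H", "O", "CB", "CG", "CD1", "CD2"),
    PTR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "P", "O1P",
            "O2P", "O3P"))
  res_names <- sample(names(palette), n_residues, replace = TRUE)
  atoms <- list(); xyz <- list(); serial <- 0L
  for (i in seq_len(n_residues)) {
    nm <- palette[[res_names[i]]]
    n <- length(nm)
    anchor <- stats::runif(3, 0, box)
    xyz[[i]] <- matrix(stats::rnorm(n * 3, sd = 0.08), n, 3) +
      rep(anchor, each = n)
    atoms[[i]] <- data.frame(serial = serial + seq_len(n), name = nm,
                             element = "", alt_loc = "",
                             res_name = res_names[i],
                             chain_id = c("A", "B")[1L + i %% 2L],
                             res_seq = i, i_code = "", occupancy_field = 1,
                             is_hetatm = res_names[i] == "PTR",
                             stringsAsFactors = FALSE)
    serial <- serial + n
  }
  atoms <- do.call(rbind, atoms)
  atoms$element <- .inferElement(atoms$element, atoms$name, proteinMasses())
  new("StructuralEnsemble", atoms = atoms,
      coords = array(do.call(rbind, xyz), c(nrow(atoms), 3L, 1L)))
}
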