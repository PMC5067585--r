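th <- contactThresholds()

test_that("hydrogen-bond geometry: collinear, right-angle and random triples", {
  expect_equal(hbondGeometry(c(0, 0, 0), c(0.1, 0, 0), c(0.3, 0, 0)),
               c(distance = 0.3, angle = 0))
  expect_equal(hbondGeometry(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.3, 0)),
               c(distance = 0.3, angle = 90))
  expect_error(hbondGeometry(c(0, 0, 0), c(0, 0, 0), c(0.3, 0, 0)),
               class = "ec_geometry_error")
  set.seed(101)
  for (k in 1:1000) {
    D <- rnorm(3); H <- D + rnorm(3, sd = 0.05); A <- rnorm(3)
    g <- hbondGeometry(D, H, A)
    u <- H - D; v <- A - D
    expect_equal(unname(g["distance"]), sqrt(sum(v^2)), tolerance = 1e-9)
    ref_ang <- acos(max(-1, min(1, sum(u * v) /
      sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    expect_equal(unname(g["angle"]), ref_ang, tolerance = 1e-9)
  }
})

test_that("hydrogen-bond detection respects strict distance and angle cuts", {
  ev <- detectHBonds(ser_gly_frame(0.30))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "hbond")
  expect_equal(ev$distance_nm, 0.30, tolerance = 1e-9)
  expect_equal(ev$hydrogen, "HG")
  # stretched past the cutoff: nothing
  expect_equal(nrow(detectHBonds(ser_gly_frame(0.36))), 0L)
  # at the cutoff exactly: strict inequality excludes it
  expect_equal(nrow(detectHBonds(ser_gly_frame(0.35))), 0L)
  # off-axis beyond 30 degrees: rejected by the angle term
  expect_equal(nrow(detectHBonds(ser_gly_frame(0.30, angle_deg = 40))), 0L)
  expect_equal(nrow(detectHBonds(ser_gly_frame(0.30, angle_deg = 20))), 1L)
})

test_that("donors without a resolvable hydrogen are skipped (or error in strict mode)", {
  df <- data.frame(name = c("OG", "O"), element = "O",
                   res_name = c("SER", "GLY"), chain_id = "A",
                   res_seq = 1:2, x = c(0, 0.3), y = 0, z = 0)
  ens <- frame_from_atoms(df)
  expect_warning(ev <- detectHBonds(ens), "no resolvable hydrogen")
  expect_equal(nrow(ev), 0L)
  expect_error(suppressWarnings(detectHBonds(ens, strict = TRUE)),
               class = "ec_chemistry_error")
})

test_that("side-chain centre of mass is mass-weighted over present atoms", {
  df <- data.frame(name = c("CB", "CA"), element = "C", res_name = "ALA",
                   chain_id = "A", res_seq = 1L,
                   x = c(1, 9), y = c(1, 9), z = c(1, 9))
  expect_equal(sidechainCOM(frame_from_atoms(df), "A", 1), c(1, 1, 1))
  # two equal-mass atoms -> midpoint
  df2 <- data.frame(name = c("CG1", "CG2"), element = "C",
                    res_name = "VAL", chain_id = "A", res_seq = 1L,
                    x = 0, y = 0, z = c(0, 2))
  expect_equal(sidechainCOM(frame_from_atoms(df2), "A", 1), c(0, 0, 1))
  # leucine side chain with hydrogens vs hand-computed weighted mean
  nm <- c("CB", "CG", "CD1", "CD2", "HB2")
  el <- c("C", "C", "C", "C", "H")
  xyz <- matrix(c(0, 0, 0,  .15, 0, 0,  .3, .1, 0,  .3, -.1, 0, 0, .1, 0),
                ncol = 3, byrow = TRUE)
  df3 <- data.frame(name = nm, element = el, res_name = "LEU",
                    chain_id = "A", res_seq = 1L,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  w <- proteinMasses()[el]
  expect_equal(sidechainCOM(frame_from_atoms(df3), "A", 1),
               colSums(xyz * w) / sum(w), tolerance = 1e-9)
  # glycine has no side chain
  dfg <- data.frame(name = "CA", element = "C", res_name = "GLY",
                    chain_id = "A", res_seq = 1L, x = 0, y = 0, z = 0)
  expect_error(sidechainCOM(frame_from_atoms(dfg), "A", 1),
               class = "ec_no_sidechain_error")
})

test_that("hydrophobic contacts: adjacency on a line, glycine excluded", {
  # 5 single-CB residues at 0.3 nm spacing: only the 4 adjacent pairs hit
  df <- data.frame(name = "CB", element = "C", res_name = "ALA",
                   chain_id = "A", res_seq = 1:5,
                   x = 0.3 * (0:4), y = 0, z = 0)
  ev <- detectHydrophobic(frame_from_atoms(df))
  expect_equal(nrow(ev), 4L)
  expect_true(all(ev$res_b - ev$res_a == 1L))
  # threshold boundaries
  mk <- function(d) frame_from_atoms(data.frame(
    name = "CB", element = "C", res_name = c("ALA", "LEU"),
    chain_id = "A", res_seq = 1:2, x = c(0, d), y = 0, z = 0))
  expect_equal(nrow(detectHydrophobic(mk(0.45))), 1L)
  expect_equal(nrow(detectHydrophobic(mk(0.55))), 0L)
  # glycine never appears in any event
  dfg <- rbind(df, data.frame(name = "CA", element = "C", res_name = "GLY",
                              chain_id = "A", res_seq = 6L, x = 0.3, y = 0.1,
                              z = 0))
  evg <- detectHydrophobic(frame_from_atoms(dfg))
  expect_false(any(evg$resname_a == "GLY" | evg$resname_b == "GLY"))
})

test_that("salt bridges use the minimum N+/O- distance under 0.4 nm", {
  mk <- function(d) frame_from_atoms(data.frame(
    name = c("NH1", "O1P"), element = c("N", "O"),
    res_name = c("ARG", "PTR"), chain_id = c("A", "B"),
    res_seq = c(618L, 694L), is_hetatm = c(FALSE, TRUE),
    x = c(0, d), y = 0, z = 0))
  ev <- suppressWarnings(detectSaltBridges(mk(0.35)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "salt_bridge")
  expect_equal(sort(c(ev$name_a, ev$name_b)), c("NH1", "O1P"))
  expect_equal(nrow(suppressWarnings(detectSaltBridges(mk(0.45)))), 0L)
  # 3x3 charged grid equals the exhaustive oracle
  set.seed(7)
  rows <- list()
  for (i in 1:3) rows[[i]] <- data.frame(
    name = c("NE", "NH1"), element = "N", res_name = "ARG", chain_id = "A",
    res_seq = i, x = runif(2), y = runif(2), z = runif(2))
  for (i in 4:6) rows[[i]] <- data.frame(
    name = c("OE1", "OE2"), element = "O", res_name = "GLU", chain_id = "B",
    res_seq = i, x = runif(2), y = runif(2), z = runif(2))
  ens <- frame_from_atoms(do.call(rbind, rows))
  ev <- suppressWarnings(detectSaltBridges(ens))
  expect_setequal(event_keys_pair(ev, "salt_bridge"),
                  oracle_salt(ens, 1, defaultChemistry(), th))
})

test_that("aromatic contacts need two rings and stay within hydrophobic pairs", {
  hexagon <- function(cx) data.frame(
    name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), element = "C",
    x = cx, y = 0.139 * cos(seq(0, by = pi / 3, length.out = 6)),
    z = 0.139 * sin(seq(0, by = pi / 3, length.out = 6)))
  phe_phe <- function(d) {
    a <- cbind(hexagon(0), res_name = "PHE", chain_id = "A", res_seq = 1L)
    b <- cbind(hexagon(d), res_name = "PHE", chain_id = "A", res_seq = 2L)
    frame_from_atoms(rbind(a, b))
  }
  ev <- detectAromatic(phe_phe(0.45))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$distance_nm, 0.45, tolerance = 1e-9)
  expect_equal(nrow(detectAromatic(phe_phe(0.55))), 0L)
  # Phe vs Leu at contact distance: hydrophobic yes, aromatic no
  mixed <- frame_from_atoms(rbind(
    cbind(hexagon(0), res_name = "PHE", chain_id = "A", res_seq = 1L),
    data.frame(name = "CB", element = "C", x = 0.45, y = 0, z = 0,
               res_name = "LEU", chain_id = "A", res_seq = 2L)))
  expect_equal(nrow(detectHydrophobic(mixed)), 1L)
  expect_equal(nrow(detectAromatic(mixed)), 0L)
})

test_that("every detector matches the exhaustive oracle on random frames", {
  tab <- defaultChemistry()
  for (seed in 1:25) {
    ens <- generateRandomFrame(n_residues = sample(5:20, 1), seed = seed)
    ev <- suppressWarnings(detectAllContacts(ens, tab, th))
    expect_hbond_set_equal(ev[ev$kind == "hbond", , drop = FALSE],
                           oracle_hbonds(ens, 1, tab, th))
    expect_setequal(event_keys_pair(ev, "hydrophobic"),
                    oracle_hydrophobic(ens, 1, tab, th))
    expect_setequal(event_keys_pair(ev, "salt_bridge"),
                    oracle_salt(ens, 1, tab, th))
    expect_setequal(event_keys_pair(ev, "aromatic"),
                    oracle_aromatic(ens, 1, tab, th))
  }
})

test_that("detection is order-independent and canonical", {
  ens <- generateRandomFrame(12, seed = 99)
  ev <- suppressWarnings(detectAllContacts(ens))
  perm <- sample(nAtoms(ens))
  shuffled <- structuralEnsemble(atomTable(ens)[perm, , drop = FALSE],
                                 ens@coords[perm, , , drop = FALSE])
  ev2 <- suppressWarnings(detectAllContacts(shuffled))
  rownames(ev) <- rownames(ev2) <- NULL
  expect_equal(ev2, ev, tolerance = 1e-12)
  # canonical pair ordering holds
  expect_true(all(ev$chain_a < ev$chain_b |
                    (ev$chain_a == ev$chain_b & ev$res_a <= ev$res_b)))
})

test_that("events are monotone in the thresholds", {
  ens <- generateRandomFrame(15, seed = 5)
  ev <- suppressWarnings(detectAllContacts(ens, thresholds = th))
  bigger <- contactThresholds(0.45, 45, 0.65, 0.55)
  smaller <- contactThresholds(0.25, 20, 0.35, 0.3)
  ev_big <- suppressWarnings(detectAllContacts(ens, thresholds = bigger))
  ev_small <- suppressWarnings(detectAllContacts(ens, thresholds = smaller))
  key <- function(e) paste(e$kind, e$chain_a, e$res_a, e$name_a, e$chain_b,
                           e$res_b, e$name_b, e$hydrogen)
  expect_true(all(key(ev) %in% key(ev_big)))
  expect_true(all(key(ev_small) %in% key(ev)))
})
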