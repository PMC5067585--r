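rand_coords <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * 3), n, 3)
}

rotz <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

test_that("Kabsch superposition recovers rigid motions exactly", {
  A <- rand_coords(6, 1)
  fit <- kabschSuperpose(A, A)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  B <- A %*% t(rotz(90)) + rep(c(1, -2, 3), each = 6)
  fit <- kabschSuperpose(A, B)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # the returned transform actually maps mobile onto reference
  expect_equal(B %*% t(fit$rotation) + rep(fit$translation, each = 6), A,
               tolerance = 1e-9)
  expect_error(kabschSuperpose(A[1:2, ], B[1:2, ]),
               class = "ec_selection_error")
  collinear <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabschSuperpose(collinear, collinear),
               class = "ec_selection_error")
})

test_that("Kabsch RMSD equals brute-force rotation search and bio3d", {
  for (seed in 1:5) {
    A <- rand_coords(5, seed)
    B <- rand_coords(5, seed + 100)
    ours <- kabschSuperpose(A, B)$rmsd
    expect_equal(ours, oracle_fit_rmsd(A, B), tolerance = 1e-6)
  }
  skip_if_not_installed("bio3d")
  A <- rand_coords(8, 7); B <- rand_coords(8, 8)
  ref <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)), fit = TRUE)
  # bio3d reports RMSD rounded to 3 decimals
  expect_equal(round(kabschSuperpose(A, B)$rmsd, 3), ref)
})

test_that("RMSD series is zero for identical or rigidly moved frames", {
  base <- rand_coords(8, 3)
  atoms <- data.frame(name = rep(c("N", "CA", "C", "O"), 2),
                      res_name = "GLY", res_seq = rep(1:2, each = 4),
                      element = rep(c("N", "C", "C", "O"), 2))
  frames <- list(base, base + rep(c(5, 0, 0), each = 8),
                 base %*% t(rotz(37)) + rep(c(0, 1, 2), each = 8))
  ens <- structuralEnsemble(atoms, frames)
  expect_equal(rmsdSeries(ens), rep(0, 3), tolerance = 1e-9)
  # designed increasing internal distortion gives a monotone series
  grow <- lapply(0:4, function(k) {
    set.seed(50)
    base + k * 0.05 * matrix(rnorm(24), 8, 3)
  })
  ens2 <- structuralEnsemble(atoms, grow)
  s <- rmsdSeries(ens2)
  expect_equal(s[1], 0, tolerance = 1e-9)
  expect_true(all(diff(s) > 0))
})

test_that("GROMOS clustering resolves the designed two-conformer fixture", {
  ens <- generateClusterFixture(30, 20, 1.0, 0.02, seed = 1)
  cl <- gromosCluster(ens, cutoff = 0.2)
  expect_equal(cl@sizes, c(30L, 20L))
  expect_equal(cl@coverage, 0.6)
  expect_equal(sum(cl@sizes), nFrames(ens))
  expect_true(all(cl@membership[1:30] == 1L))
  expect_true(all(cl@membership[31:50] == 2L))
  rep <- representativeStructure(cl)
  expect_lte(rep$frame, 30L)
  expect_equal(rep$coverage, 0.6)
  expect_gt(rep$coverage, 0.5)
  # single cluster cases
  one <- generateClusterFixture(10, 0, 1.0, 0.02, seed = 2)
  cl1 <- gromosCluster(one, cutoff = 0.2)
  expect_equal(cl1@sizes, 10L)
  expect_equal(cl1@coverage, 1.0)
  big <- gromosCluster(ens, cutoff = 5)
  expect_length(big@sizes, 1L)
  expect_error(generateClusterFixture(5, 5, 0.4, 0.2, seed = 1),
               class = "ec_input_error")
})

test_that("clustering of identical frames and tie-breaks are deterministic", {
  base <- rand_coords(8, 11)
  atoms <- data.frame(name = rep(c("N", "CA", "C", "O"), 2),
                      res_name = "GLY", res_seq = rep(1:2, each = 4),
                      element = rep(c("N", "C", "C", "O"), 2))
  ens <- structuralEnsemble(atoms, replicate(5, base, simplify = FALSE))
  cl <- gromosCluster(ens, 0.1)
  expect_equal(cl@sizes, 5L)
  expect_equal(cl@centroids, 1L)  # lowest-index tie-break
  expect_equal(cl@coverage, 1.0)
})

test_that("clustering is invariant to global rigid motion and frame order", {
  ens <- generateClusterFixture(8, 6, 1.0, 0.02, seed = 4)
  cl <- gromosCluster(ens, 0.2)
  moved <- ens
  for (f in seq_len(nFrames(ens)))
    moved@coords[, , f] <- ens@coords[, , f] %*% t(rotz(65)) +
      rep(c(3, -1, 2), each = 8)
  cl2 <- gromosCluster(moved, 0.2)
  expect_equal(cl2@membership, cl@membership)
  perm <- c(9, 2, 14, 1, 7, 3, 11, 5, 13, 4, 10, 6, 12, 8)
  permuted <- structuralEnsemble(atomTable(ens),
                                 ens@coords[, , perm, drop = FALSE])
  cl3 <- gromosCluster(permuted, 0.2)
  expect_equal(sort(cl3@sizes), sort(cl@sizes))
  expect_equal(cl3@membership, cl@membership[perm])
})

test_that("covariance analysis: degenerate motions and trace conservation", {
  base <- rand_coords(4, 21)
  atoms <- data.frame(name = c("N", "CA", "C", "O"), res_name = "GLY",
                      res_seq = 1L, element = c("N", "C", "C", "O"))
  same <- structuralEnsemble(atoms, replicate(6, base, simplify = FALSE))
  cm <- covarianceModes(same, n_modes = 2L)
  expect_equal(cm$eigenvalues, rep(0, 12), tolerance = 1e-12)
  # one atom oscillating along x: a single mode along the x unit direction
  osc <- lapply(seq(0, 1, length.out = 9), function(a) {
    b <- base; b[1, 1] <- b[1, 1] + 0.2 * cos(pi * a); b
  })
  cm1 <- covarianceModes(structuralEnsemble(atoms, osc),
                         selection = 1:4, n_modes = 1L, superpose = FALSE)
  expect_equal(sum(cm1$eigenvalues > 1e-12), 1L)
  expect_equal(abs(cm1$modes[1, 1]), 1, tolerance = 1e-9)
  expect_error(covarianceModes(same, n_modes = 50L),
               class = "ec_selection_error")
  # trace conservation on a noisy ensemble
  set.seed(31)
  noisy <- structuralEnsemble(atoms, lapply(1:40, function(i)
    base + matrix(rnorm(12, sd = 0.05), 4, 3)))
  cmn <- covarianceModes(noisy, n_modes = 3L)
  expect_equal(sum(cmn$eigenvalues), cmn$total_variance, tolerance = 1e-9)
})

test_that("known planar Gaussian spectrum is recovered within sampling error", {
  set.seed(77)
  S <- matrix(c(0.04, 0.012, 0.012, 0.01), 2, 2)
  L <- chol(S)
  base <- rand_coords(4, 5)
  frames <- lapply(1:600, function(i) {
    b <- base
    b[1, 1:2] <- b[1, 1:2] + as.numeric(matrix(rnorm(2), 1) %*% L)
    b
  })
  atoms <- data.frame(name = c("N", "CA", "C", "O"), res_name = "GLY",
                      res_seq = 1L, element = c("N", "C", "C", "O"))
  cm <- covarianceModes(structuralEnsemble(atoms, frames),
                        selection = 1:4, n_modes = 2L, superpose = FALSE)
  expect_equal(cm$eigenvalues[1:2], sort(eigen(S)$values, decreasing = TRUE),
               tolerance = 0.15)
  expect_lt(cm$eigenvalues[3], 1e-12)
})

test_that("cosine content matches the analytic values for designed series", {
  expect_equal(cosineContent(generateProjectionSeries("cosine", 1000, 1), 1),
               1.0, tolerance = 1e-3)
  expect_equal(cosineContent(generateProjectionSeries("constant", 500), 1),
               0.0, tolerance = 1e-12)
  p2 <- generateProjectionSeries("cosine", 2000, 2)
  expect_equal(cosineContent(p2, 2), 1.0, tolerance = 1e-3)
  expect_lt(cosineContent(p2, 1), 0.01)
  expect_error(cosineContent(rep(0, 10), 1), class = "ec_input_error")
  expect_error(cosineContent(numeric(1), 1), class = "ec_input_error")
})

test_that("cosine content is bounded in [0,1] for arbitrary series", {
  for (seed in 1:50) {
    set.seed(seed)
    p <- rnorm(200)
    for (i in 1:3) {
      cc <- cosineContent(p, i)
      expect_gte(cc, 0)
      expect_lte(cc, 1)
    }
  }
})

test_that("random walks look cosine-like while white noise does not", {
  walk_cc <- vapply(1:50, function(s)
    cosineContent(generateProjectionSeries("random_walk", 400, seed = s), 1),
    numeric(1))
  noise_cc <- vapply(1:50, function(s) {
    set.seed(s + 1000)
    cosineContent(rnorm(400), 1)
  }, numeric(1))
  expect_gt(mean(walk_cc), 5 * mean(noise_cc))
})
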