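#' Indices of the backbone atoms (N, CA, C, O)
#'
#' @param ensemble a [StructuralEnsemble-class].
#' @return integer atom indices.
#' @export
backboneSelection <- function(ensemble) {
  which(ensemble@atoms$name %in% c("N", "CA", "C", "O"))
}

# core Kabsch on two n x 3 matrices; returns list(R, t, rmsd)
.kabsch <- function(ref, mob) {
  n <- nrow(ref)
  cr <- colMeans(ref)
  cm <- colMeans(mob)
  A <- sweep(ref, 2, cr)
  B <- sweep(mob, 2, cm)
  s <- svd(t(B) %*% A)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  list(rotation = R, translation = cr - as.numeric(R %*% cm), rmsd = rmsd)
}

#' Optimal rigid superposition (Kabsch) of two frames
#'
#' Least-squares optimal proper rotation (det = +1) and translation mapping
#' the mobile selection onto the reference, with the post-fit RMSD.
#'
#' @param reference,mobile n x 3 coordinate matrices (nm) or
#'   [StructuralEnsemble-class] frames via `frame_ref`/`frame_mob`.
#' @param selection integer atom indices (1:1 between the two frames),
#'   at least 3 non-collinear atoms.
#' @return list with `rotation` (3x3), `translation` (3-vector; the fit is
#'   `x %*% t(rotation) + translation`) and `rmsd` (nm).
#' @export
kabschSuperpose <- function(reference, mobile, selection = NULL) {
  if (is(reference, "StructuralEnsemble")) reference <- frameCoords(reference, 1L)
  if (is(mobile, "StructuralEnsemble")) mobile <- frameCoords(mobile, 1L)
  if (!is.null(selection)) {
    reference <- reference[selection, , drop = FALSE]
    mobile <- mobile[selection, , drop = FALSE]
  }
  if (nrow(reference) != nrow(mobile))
    stop(ecError("selection must map 1:1 between frames", "selection_error"))
  if (nrow(reference) < 3L)
    stop(ecError("superposition needs at least 3 atoms", "selection_error"))
  C <- sweep(reference, 2, colMeans(reference))
  if (sum(svd(C)$d > 1e-12) < 2L)
    stop(ecError("degenerate (collinear) selection", "selection_error"))
  .kabsch(reference, mobile)
}

#' Per-frame RMSD versus a reference frame
#'
#' Every frame is optimally superposed onto the reference over `selection`
#' before the RMSD is taken (so global rigid motions contribute nothing).
#'
#' @param ensemble a [StructuralEnsemble-class].
#' @param reference reference frame index (default 1) or an n x 3 matrix.
#' @param selection integer atom indices; default the backbone (N, CA, C, O).
#' @return numeric vector, one RMSD (nm) per frame.
#' @export
rmsdSeries <- function(ensemble, reference = 1L, selection = NULL) {
  if (is.null(selection)) selection <- backboneSelection(ensemble)
  ref <- if (is.matrix(reference)) reference[selection, , drop = FALSE]
         else frameCoords(ensemble, reference)[selection, , drop = FALSE]
  vapply(seq_len(nFrames(ensemble)), function(i) {
    kabschSuperpose(ref, ensemble@coords[selection, , i, drop = TRUE])$rmsd
  }, numeric(1))
}

# pairwise post-fit RMSD matrix over a selection
.rmsdMatrix <- function(ensemble, selection) {
  n <- nFrames(ensemble)
  X <- lapply(seq_len(n), function(i)
    ensemble@coords[selection, , i, drop = TRUE])
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    D[i, j] <- D[j, i] <- .kabsch(X[[i]], X[[j]])$rmsd
  }
  D
}

#' Conformational clustering by iterative neighbour counting
#'
#' The GROMOS scheme: compute all pairwise post-fit RMSDs; the frame with
#' the most neighbours within `cutoff` becomes the centroid of the first
#' cluster; it and its neighbours are removed and the procedure repeats on
#' the remainder. Ties are broken toward the lowest frame index, so the
#' result is deterministic.
#'
#' @param ensemble a [StructuralEnsemble-class].
#' @param cutoff neighbour RMSD cutoff, nm (default 0.2 on backbone atoms).
#' @param selection integer atom indices; default the backbone.
#' @return a [ClusterResult-class]; cluster ids are ordered by size
#'   (1 = largest; equal sizes keep discovery order).
#' @export
gromosCluster <- function(ensemble, cutoff = 0.2, selection = NULL) {
  stopifnot(cutoff > 0)
  if (is.null(selection)) selection <- backboneSelection(ensemble)
  n <- nFrames(ensemble)
  D <- .rmsdMatrix(ensemble, selection)
  remaining <- rep(TRUE, n)
  membership <- integer(n)
  centroids <- integer(0)
  sizes <- integer(0)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    idx <- which(remaining)
    # neighbour count includes the frame itself
    counts <- vapply(idx, function(i) sum(D[i, idx] <= cutoff), integer(1))
    centre <- idx[which.max(counts)]  # which.max = lowest index on ties
    members <- idx[D[centre, idx] <= cutoff]
    membership[members] <- cl
    centroids[cl] <- centre
    sizes[cl] <- length(members)
    remaining[members] <- FALSE
  }
  o <- order(-sizes, seq_along(sizes))
  relabel <- integer(length(sizes))
  relabel[o] <- seq_along(sizes)
  new("ClusterResult", cutoff = cutoff,
      membership = relabel[membership],
      sizes = sizes[o], centroids = centroids[o],
      coverage = sizes[o][1L] / n)
}

#' Representative structure of an ensemble
#'
#' The centroid frame of the largest cluster, with the fraction of all
#' frames that cluster covers (so a "more than half of the sampled
#' conformations" claim is checkable).
#'
#' @param result a [ClusterResult-class].
#' @return list with `frame` (index) and `coverage` (fraction).
#' @export
representativeStructure <- function(result) {
  stopifnot(is(result, "ClusterResult"), length(result@sizes) >= 1L)
  list(frame = result@centroids[1L], coverage = result@coverage)
}

#' Positional covariance analysis (essential dynamics)
#'
#' Frames are superposed to the ensemble mean (one fit-to-mean iteration
#' after an initial fit to the first frame), the 3N x 3N positional
#' covariance over `selection` is diagonalized, and each frame's deviation
#' from the mean is projected onto the top modes.
#'
#' @param ensemble a [StructuralEnsemble-class].
#' @param selection integer atom indices; default the backbone.
#' @param n_modes number of modes to report.
#' @param superpose fit frames to the ensemble mean first (default); turn
#'   off for inputs that are already aligned or have fewer than 3 atoms.
#' @return list with `eigenvalues` (all 3N, descending, nm^2),
#'   `modes` (3N x n_modes), `projections` (frames x n_modes) and
#'   `total_variance` (the trace).
#' @export
covarianceModes <- function(ensemble, selection = NULL, n_modes = 2L,
                            superpose = TRUE) {
  if (is.null(selection)) selection <- backboneSelection(ensemble)
  n <- nFrames(ensemble)
  p <- 3L * length(selection)
  if (n_modes > p)
    stop(ecError("n_modes exceeds 3N coordinates", "selection_error"))
  fit_all <- function(ref) {
    t(vapply(seq_len(n), function(i) {
      k <- .kabsch(ref, ensemble@coords[selection, , i, drop = TRUE])
      as.numeric(ensemble@coords[selection, , i, drop = TRUE] %*%
                   t(k$rotation) + rep(k$translation, each = length(selection)))
    }, numeric(p)))
  }
  if (superpose) {
    M <- fit_all(frameCoords(ensemble, 1L)[selection, , drop = FALSE])
    mean_xyz <- matrix(colMeans(M), ncol = 3L)
    M <- fit_all(mean_xyz)
  } else {
    M <- t(vapply(seq_len(n), function(i)
      as.numeric(ensemble@coords[selection, , i, drop = FALSE]), numeric(p)))
  }
  mu <- colMeans(M)
  Dev <- sweep(M, 2, mu)
  C <- crossprod(Dev) / n
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  modes <- eig$vectors[, seq_len(n_modes), drop = FALSE]
  list(eigenvalues = ev, modes = modes,
       projections = Dev %*% modes, total_variance = sum(diag(C)))
}

#' Cosine content of a principal-component projection (Hess criterion)
#'
#' Compares a projection time series with the half-cosines expected for
#' random diffusion:
#' `c_i = (2/T) * (integral p(t) cos(i pi t / T) dt)^2 / integral p(t)^2 dt`
#' with trapezoidal integration over the uniformly spaced series. Values
#' near 1 indicate random-diffusion-like (unconverged) sampling, values near
#' 0 indicate sampling about an equilibrium position.
#'
#' @param projection numeric series p(t), length >= 2, not all zero.
#' @param mode_index i, the cosine half-period count (default: 1).
#' @return value in \[0, 1\].
#' @examples
#' t <- seq(0, 1, length.out = 1000)
#' cosineContent(cos(pi * t), 1)  # ~1
#' @export
cosineContent <- function(projection, mode_index = 1L) {
  n <- length(projection)
  if (n < 2L)
    stop(ecError("projection series needs at least 2 points", "input_error"))
  if (all(projection == 0))
    stop(ecError("cosine content undefined for an all-zero series",
                 "input_error"))
  t <- seq(0, 1, length.out = n)  # t/T on [0,1]
  num <- 2 * pracma::trapz(t, projection * cos(mode_index * pi * t))^2
  den <- pracma::trapz(t, projection^2)
  min(1, max(0, num / den))
}

#' Convergence diagnostics of an ensemble
#'
#' Bundles [rmsdSeries()], [covarianceModes()] and [cosineContent()] into a
#' single report over an (optionally windowed) ensemble.
#'
#' @param ensemble a [StructuralEnsemble-class].
#' @param selection atom indices; default the backbone.
#' @param n_modes modes to report cosine content for.
#' @param reference reference frame index for the RMSD series.
#' @return a [ConvergenceReport-class]
#' @export
convergenceReport <- function(ensemble, selection = NULL, n_modes = 2L,
                              reference = 1L) {
  if (is.null(selection)) selection <- backboneSelection(ensemble)
  cm <- covarianceModes(ensemble, selection, n_modes)
  cc <- vapply(seq_len(n_modes), function(i) {
    p <- cm$projections[, i]
    if (all(p == 0)) 0 else cosineContent(p, i)
  }, numeric(1))
  new("ConvergenceReport", eigenvalues = cm$eigenvalues,
      projections = cm$projections, cosineContent = cc,
      rmsd = rmsdSeries(ensemble, reference, selection))
}
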