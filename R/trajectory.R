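# Trajectory container and extraction of the local fluctuation variables:
# aligned on-residue displacement magnitudes (1R) and residue-pair
# distances (2R).

#' Construct a Trajectory
#'
#' @param coords frames × residues × 3 numeric array (Å).
#' @param frame0 residues × 3 reference structure; defaults to the first
#'   frame (but note frame0 is a reference only, never an observation — by
#'   default the supplied frames are all kept as observations and frame0 is
#'   a copy of the first one).
#' @param ids integer residue indices (default 1..nResidues).
#' @param frameInterval time between frames in ps (default 50).
#' @return a [Trajectory-class].
#' @export
trajectory <- function(coords, frame0 = NULL, ids = NULL,
                       frameInterval = 50) {
  coords <- unname(coords)
  if (is.null(frame0)) frame0 <- coords[1L, , , drop = TRUE]
  frame0 <- matrix(as.numeric(frame0), ncol = 3L)
  if (is.null(ids)) ids <- seq_len(dim(coords)[2L])
  new("Trajectory", coords = coords, frame0 = unname(frame0),
      ids = as.integer(ids), frameInterval = as.numeric(frameInterval))
}

#' @describeIn nFrames frame count of the coordinate array.
#' @export
setMethod("nFrames", "Trajectory", function(object) dim(object@coords)[1L])

#' @describeIn nResidues residue count.
#' @export
setMethod("nResidues", "Trajectory", function(object) dim(object@coords)[2L])

#' @describeIn residueIds residue index vector.
#' @export
setMethod("residueIds", "Trajectory", function(object) object@ids)

#' @describeIn coords the frames × residues × 3 array.
#' @export
setMethod("coords", "Trajectory", function(object) object@coords)

#' @describeIn frame0 the reference structure.
#' @export
setMethod("frame0", "Trajectory", function(object) object@frame0)

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nFrames(object), "frames x", nResidues(object),
      "residues,", object@frameInterval, "ps/frame\n")
})

# ---- rigid-body superposition ----------------------------------------------

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Rotates and translates `mobile` onto `reference` minimising the RMSD
#' over proper rigid transforms; reflections are not permitted (the
#' rotation determinant is constrained to +1). Equal weights on all Cα
#' positions.
#'
#' @param mobile residues × 3 coordinate matrix (Å).
#' @param reference residues × 3 coordinate matrix, or a [Trajectory-class]
#'   whose frame0 is used.
#' @return residues × 3 matrix of superposed coordinates.
#' @export
superpose <- function(mobile, reference) {
  if (is(reference, "Trajectory")) reference <- frame0(reference)
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have the same dimensions")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm); Q <- sweep(reference, 2L, cr)
  C <- crossprod(P, Q)
  sv <- svd(C)
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sweep(P %*% R, 2L, cr, "+")
}

.rmsdPair <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Align all frames of a trajectory onto a reference structure
#'
#' Superposes every frame (rigid-body least squares) onto `reference`;
#' self-alignment uses the trajectory's own frame0, mean-alignment an
#' average reference from [makeMeanReference()].
#'
#' @param traj a [Trajectory-class].
#' @param reference residues × 3 matrix; default the trajectory's frame0.
#' @return the aligned [Trajectory-class] (frame0 also superposed).
#' @export
alignTrajectory <- function(traj, reference = NULL) {
  if (is.null(reference)) reference <- frame0(traj)
  reference <- as.matrix(reference)
  x <- coords(traj)
  for (f in seq_len(dim(x)[1L]))
    x[f, , ] <- superpose(x[f, , ], reference)
  initialize(traj, coords = x, frame0 = superpose(frame0(traj), reference))
}

#' Iterative mean reference structure
#'
#' Superposes all input structures onto the first, averages, re-superposes
#' onto the average and repeats until the mean coordinates change by less
#' than `tol` Å. Used for mean-alignment, where one average of the
#' trajectories' frame0 structures aligns all runs.
#'
#' @param structures list of residues × 3 coordinate matrices.
#' @param tol convergence tolerance on the mean coordinates (Å).
#' @return residues × 3 mean reference matrix.
#' @export
makeMeanReference <- function(structures, tol = 1e-6) {
  if (!length(structures)) stop("empty structure list")
  structures <- lapply(structures, as.matrix)
  nr <- unique(vapply(structures, nrow, integer(1)))
  if (length(nr) != 1L) stop("structures must have equal residue counts")
  ref <- structures[[1L]]
  for (it in seq_len(1000L)) {
    aligned <- lapply(structures, superpose, reference = ref)
    newref <- Reduce(`+`, aligned) / length(aligned)
    if (max(abs(newref - ref)) < tol) return(newref)
    ref <- newref
  }
  warning("mean reference did not converge to ", tol, " A")
  ref
}

# ---- frame halving ----------------------------------------------------------

#' Split a trajectory into two contiguous half blocks
#'
#' The first and second halves of the frames define samples 1 and 2 (e.g.
#' 2000 frames → two blocks of 1000). frame0 is a reference only and is not
#' a member of either block. Odd frame counts drop the final frame with a
#' warning.
#'
#' @param traj a [Trajectory-class].
#' @return list of two [Trajectory-class] blocks sharing frame0 and ids.
#' @export
splitHalves <- function(traj) {
  nf <- nFrames(traj)
  if (nf %% 2L == 1L) {
    warning("odd frame count: dropping the final frame")
    nf <- nf - 1L
  }
  if (nf < 4L) stop("need at least 4 frames to form two blocks")
  h <- nf / 2L
  x <- coords(traj)
  list(
    initialize(traj, coords = x[seq_len(h), , , drop = FALSE]),
    initialize(traj, coords = x[h + seq_len(h), , , drop = FALSE])
  )
}

# ---- 1R: displacement magnitudes --------------------------------------------

#' On-residue displacement magnitudes
#'
#' For each frame t and residue k the 1R variable is
#' v_k(t) = |r_k(t) − μ_k|, the magnitude of the displacement from the
#' residue's average position. With local averaging each block uses its own
#' empirical mean position μ_b; with global averaging both blocks share
#' μ = (μ1 + μ2)/2. Frames must already be superposed onto a common
#' reference.
#'
#' @param block1,block2 aligned [Trajectory-class] half blocks (block2 may
#'   be NULL with local averaging).
#' @param averaging "local" or "global".
#' @return list of per-block matrices (frames × residues) of displacement
#'   magnitudes in Å, residue ids as column names.
#' @export
displacementMagnitudes <- function(block1, block2 = NULL,
                                   averaging = c("local", "global")) {
  averaging <- match.arg(averaging)
  blocks <- if (is.null(block2)) list(block1) else list(block1, block2)
  if (averaging == "global" && length(blocks) != 2L)
    stop("global averaging needs both blocks")
  mus <- lapply(blocks, function(b) apply(coords(b), c(2L, 3L), mean))
  if (averaging == "global")
    mus <- list((mus[[1L]] + mus[[2L]]) / 2, (mus[[1L]] + mus[[2L]]) / 2)
  out <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    x <- coords(blocks[[i]])
    dev <- sweep(x, c(2L, 3L), mus[[i]])
    mag <- sqrt(dev[, , 1L]^2 + dev[, , 2L]^2 + dev[, , 3L]^2)
    mag <- matrix(mag, nrow = dim(x)[1L])
    colnames(mag) <- residueIds(blocks[[i]])
    out[[i]] <- mag
  }
  names(out) <- paste0("block", seq_along(blocks))
  out
}

#' Root mean square fluctuation of a displacement sample
#'
#' Default convention is the root of the mean squared displacement
#' magnitude (`type = "rms"`); the empirical standard deviation of the
#' magnitudes is available as `type = "sd"` since the two readings of
#' "standard deviation of the sample" differ for non-centred magnitudes.
#'
#' @param sample numeric vector of displacement magnitudes (Å).
#' @param type "rms" (default) or "sd".
#' @return nonnegative scalar (Å).
#' @export
rmsf <- function(sample, type = c("rms", "sd")) {
  type <- match.arg(type)
  if (!length(sample)) stop("empty sample")
  if (type == "rms") sqrt(mean(sample^2)) else stats::sd(sample)
}

# ---- 2R: residue-pair distances ---------------------------------------------

#' Residue-pair distance samples within a neighbour cutoff
#'
#' Two residues are nearest neighbours if their Cα distance is ≤ `cutoff`
#' in at least one frame of the entire trajectory (membership is decided on
#' all frames, before any halving). Distance samples are rotationally
#' invariant, so no alignment is required. Cutoffs below 8 Å give sparse
#' neighbourhoods and a warning (4 Å is not robust, 6 Å marginal).
#'
#' @param traj a [Trajectory-class].
#' @param cutoff neighbour cutoff in Å (default 12).
#' @return list with `neighbors` (data.frame k, j with k < j, residue ids)
#'   and `distances` (frames × pairs matrix, columns named "k|j").
#' @export
pairDistances <- function(traj, cutoff = 12) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (cutoff < 8) warning("cutoffs below 8 A give insufficient local ",
                          "spatial averaging; 6 A is marginal, 4 A is ",
                          "not robust")
  x <- coords(traj)
  nf <- dim(x)[1L]; nr <- dim(x)[2L]
  ids <- residueIds(traj)
  if (nr < 2L)
    return(list(neighbors = data.frame(k = integer(), j = integer()),
                distances = matrix(numeric(), nrow = nf, ncol = 0L)))
  minD <- matrix(Inf, nr, nr)
  for (f in seq_len(nf)) {
    D <- as.matrix(stats::dist(x[f, , ]))
    minD <- pmin(minD, D)
  }
  sel <- which(upper.tri(minD) & minD <= cutoff, arr.ind = TRUE)
  ord <- order(sel[, 1L], sel[, 2L])
  sel <- sel[ord, , drop = FALSE]
  neighbors <- data.frame(k = ids[sel[, 1L]], j = ids[sel[, 2L]])
  dists <- matrix(0, nrow = nf, ncol = nrow(sel))
  for (p in seq_len(nrow(sel))) {
    dv <- x[, sel[p, 1L], ] - x[, sel[p, 2L], ]
    dists[, p] <- sqrt(rowSums(matrix(dv, nrow = nf)^2))
  }
  colnames(dists) <- paste(neighbors$k, neighbors$j, sep = "|")
  list(neighbors = neighbors, distances = dists)
}

# ---- shifting ----------------------------------------------------------------

#' Shift a sample and its density so the density mean is exactly zero
#'
#' The first moment of the fitted density (by quadrature) is subtracted
#' from both the sample values and the density's support. The shifted
#' distribution characterises fluctuations about the mean with the average
#' structural information (the equilibrium length of a distance pair)
#' removed; all means after the shift are zero to quadrature accuracy.
#'
#' @param sample numeric vector the estimate was fitted to.
#' @param estimate a [MaxEntDensity-class] fitted to `sample`.
#' @return list with `sample` (shifted values) and `estimate` (shifted
#'   density).
#' @export
shiftDistribution <- function(sample, estimate) {
  m <- densityMean(estimate)
  shifted <- initialize(estimate, support = estimate@support - m)
  # recompute lambda0 offset: the affine support shift leaves the shape and
  # normalisation untouched, so lambdas carry over unchanged
  list(sample = as.numeric(sample) - m, estimate = shifted)
}

# ---- convergence utility -----------------------------------------------------

#' Per-frame RMSD relative to frame0
#'
#' Least-squares-fitted RMSD of every frame against the initial reference
#' structure; a simple convergence trace.
#'
#' @param traj a [Trajectory-class].
#' @return numeric vector, one RMSD (Å) per frame.
#' @export
rmsdTrace <- function(traj) {
  ref <- frame0(traj)
  x <- coords(traj)
  vapply(seq_len(dim(x)[1L]), function(f)
    .rmsdPair(superpose(x[f, , ], ref), ref), numeric(1))
}
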