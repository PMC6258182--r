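# Synthetic mock trajectories: per-residue Gaussian position fluctuations
# (optionally AR(1)-correlated in time), deterministic or random parameter
# perturbations between the two members of a pair, frame shuffling, and
# toy geometries for neighbour-set fixtures.

#' Specification of a Gaussian mock trajectory pair
#'
#' Defines per-residue per-axis Gaussian means and standard deviations for
#' trajectory A and the perturbation rules producing trajectory B: a mean
#' shift expressed as a multiple of the per-axis sd and a multiplicative sd
#' scale. Frames are iid by default; a nonzero AR(1) coefficient adds
#' stationary time correlation (unit marginal variance preserved).
#'
#' @param nResidues number of residues (default 263).
#' @param nFrames frames per trajectory (default 2000, i.e. two blocks of
#'   1000).
#' @param means residues × 3 matrix of mean positions (Å); default a helix
#'   from [toyStructure()].
#' @param sds residues × 3 matrix of per-axis sds (Å); default heterogeneous
#'   across residues, drawn once from Uniform(0.3, 0.9) under `seed`.
#' @param meanShift perturbation of B's means, in units of the per-axis sd
#'   (default 0 = identically distributed pair).
#' @param sdScale multiplicative perturbation of B's sds (default 1).
#' @param randomPerturb logical; FALSE (default) applies the perturbation
#'   identically to all residues, TRUE draws per-residue perturbations
#'   uniformly from \[0, meanShift\] and \[1, sdScale\].
#' @param ar AR(1) coefficient in \[0, 1) (default 0 = iid frames).
#' @param frameInterval ps between frames (default 50).
#' @param seed integer seed.
#' @return a list of class "MockSpec".
#' @export
mockSpec <- function(nResidues = 263L, nFrames = 2000L, means = NULL,
                     sds = NULL, meanShift = 0, sdScale = 1,
                     randomPerturb = FALSE, ar = 0, frameInterval = 50,
                     seed = 1L) {
  nResidues <- as.integer(nResidues); nFrames <- as.integer(nFrames)
  if (ar < 0 || ar >= 1) stop("AR coefficient must lie in [0, 1)")
  if (is.null(means)) means <- toyStructure(nResidues, "helix")
  means <- matrix(as.numeric(means), ncol = 3L)
  if (is.null(sds))
    sds <- .withSeed(seed, matrix(stats::runif(nResidues * 3L, 0.3, 0.9),
                                  ncol = 3L))
  sds <- matrix(as.numeric(sds), ncol = 3L)
  if (any(sds <= 0)) stop("sds must be positive")
  if (nrow(means) != nResidues || nrow(sds) != nResidues)
    stop("means and sds must have one row per residue")
  structure(list(nResidues = nResidues, nFrames = nFrames, means = means,
                 sds = sds, meanShift = meanShift, sdScale = sdScale,
                 randomPerturb = randomPerturb, ar = ar,
                 frameInterval = frameInterval, seed = as.integer(seed)),
            class = "MockSpec")
}

# One trajectory: frames x residues x 3 of AR(1) Gaussians with the given
# per-residue/axis means and sds; ar = 0 gives iid frames.
.simulateGaussian <- function(nFrames, means, sds, ar) {
  nr <- nrow(means)
  x <- array(0, dim = c(nFrames, nr, 3L))
  for (ax in 1:3) {
    eps <- matrix(stats::rnorm(nFrames * nr), nFrames, nr)
    if (ar > 0) {
      # stationary AR(1) with unit marginal variance
      z <- matrix(0, nFrames, nr)
      z[1L, ] <- eps[1L, ]
      s <- sqrt(1 - ar^2)
      for (f in 2:nFrames) z[f, ] <- ar * z[f - 1L, ] + s * eps[f, ]
      eps <- z
    }
    x[, , ax] <- sweep(sweep(eps, 2L, sds[, ax], "*"), 2L, means[, ax], "+")
  }
  x
}

#' Generate a mock Gaussian trajectory pair
#'
#' Trajectory A is drawn from the spec's base Gaussian parameters;
#' trajectory B from the perturbed parameters (means shifted by
#' `meanShift`·sd per axis, sds scaled by `sdScale`). With zero
#' perturbation the two trajectories are identically distributed — the
#' null-calibration control. frame0 of each trajectory is its mean
#' structure. Output is bitwise reproducible for a fixed spec.
#'
#' @param spec a [mockSpec()].
#' @return list of two [Trajectory-class] objects, named A and B.
#' @export
gaussianMockPair <- function(spec) {
  stopifnot(inherits(spec, "MockSpec"))
  .withSeed(spec$seed + 7L, {
    meansB <- spec$means
    sdsB <- spec$sds
    if (spec$randomPerturb) {
      shift <- stats::runif(spec$nResidues, 0, spec$meanShift)
      scale <- stats::runif(spec$nResidues, 1, max(1, spec$sdScale))
    } else {
      shift <- rep(spec$meanShift, spec$nResidues)
      scale <- rep(spec$sdScale, spec$nResidues)
    }
    meansB <- meansB + spec$sds * shift
    sdsB <- sdsB * scale
    A <- .simulateGaussian(spec$nFrames, spec$means, spec$sds, spec$ar)
    B <- .simulateGaussian(spec$nFrames, meansB, sdsB, spec$ar)
    list(A = trajectory(A, frame0 = spec$means,
                        frameInterval = spec$frameInterval),
         B = trajectory(B, frame0 = meansB,
                        frameInterval = spec$frameInterval))
  })
}

#' Shuffle the frame order of a trajectory
#'
#' Uniformly random permutation of the frames; the multiset of frames (and
#' hence every per-residue value distribution) is unchanged, but all time
#' correlation is destroyed. Used as the control that converts an
#' autocorrelated trajectory into an exchangeable one.
#'
#' @param traj a [Trajectory-class].
#' @param seed integer seed.
#' @return the shuffled [Trajectory-class].
#' @export
shuffleFrames <- function(traj, seed = 1L) {
  perm <- .withSeed(seed, sample.int(nFrames(traj)))
  initialize(traj, coords = coords(traj)[perm, , , drop = FALSE])
}

#' Deterministic toy backbone geometries
#'
#' Line geometry places residue k at ((k−1)·spacing, 0, 0), so the pair
#' (k, j) distance is exactly |k−j|·spacing — convenient for neighbour-set
#' arithmetic. Helix geometry uses ideal α-helix Cα parameters (2.3 Å
#' radius, 1.5 Å rise, 100° per residue), giving ~3.8 Å between sequential
#' residues.
#'
#' @param nResidues number of residues.
#' @param geometry "helix" (default) or "line".
#' @param spacing Å between sequential residues for the line geometry
#'   (default 3.8).
#' @return residues × 3 coordinate matrix (Å).
#' @export
toyStructure <- function(nResidues, geometry = c("helix", "line"),
                         spacing = 3.8) {
  geometry <- match.arg(geometry)
  if (spacing <= 0) stop("spacing must be positive")
  k <- seq_len(nResidues) - 1L
  if (geometry == "line") {
    cbind(k * spacing, 0, 0)
  } else {
    theta <- k * 100 * pi / 180
    cbind(2.3 * cos(theta), 2.3 * sin(theta), k * 1.5)
  }
}
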