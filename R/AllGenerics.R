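#' Evaluate a density at points
#'
#' @param object a [Density-class] object.
#' @param points numeric vector of evaluation points.
#' @return numeric vector of non-negative density values; points outside
#'   the support evaluate to exactly 0.
#' @export
setGeneric("evaluatePdf", function(object, points)
  standardGeneric("evaluatePdf"))

#' Evaluate the cumulative distribution function of a density
#'
#' @param object a [Density-class] object.
#' @param points numeric vector of evaluation points.
#' @return numeric vector in \[0, 1\], nondecreasing in the points; 0 at or
#'   below the support lower bound, 1 at or above the upper bound.
#' @export
setGeneric("evaluateCdf", function(object, points)
  standardGeneric("evaluateCdf"))

#' Support interval of a density
#'
#' @param object a [Density-class] object.
#' @return numeric length-2 vector c(lo, hi).
#' @export
setGeneric("supportInterval", function(object)
  standardGeneric("supportInterval"))

#' Lagrange multipliers of a maximum-entropy estimate
#'
#' @param object a [MaxEntDensity-class].
#' @return numeric vector c(lambda0, lambda1, ..., lambdaD).
#' @export
setGeneric("lambdas", function(object) standardGeneric("lambdas"))

#' Basis dimension of a maximum-entropy estimate
#'
#' @param object a [MaxEntDensity-class].
#' @return integer D, the number of active basis functions.
#' @export
setGeneric("basisDim", function(object) standardGeneric("basisDim"))

#' Mean (first moment) of a density by quadrature
#'
#' @param object a [Density-class] object.
#' @return numeric scalar mean in data units.
#' @export
setGeneric("densityMean", function(object) standardGeneric("densityMean"))

#' Number of frames in a trajectory
#' @param object a [Trajectory-class].
#' @return integer frame count (excluding frame0, which is a reference).
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' Number of residues in a trajectory
#' @param object a [Trajectory-class].
#' @return integer residue count.
#' @export
setGeneric("nResidues", function(object) standardGeneric("nResidues"))

#' Residue ids of a trajectory
#' @param object a [Trajectory-class].
#' @return integer vector of residue indices.
#' @export
setGeneric("residueIds", function(object) standardGeneric("residueIds"))

#' Coordinate array of a trajectory
#' @param object a [Trajectory-class].
#' @return frames × residues × 3 numeric array (Å).
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' Reference (frame0) structure of a trajectory
#' @param object a [Trajectory-class].
#' @return residues × 3 numeric matrix (Å).
#' @export
setGeneric("frame0", function(object) standardGeneric("frame0"))
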