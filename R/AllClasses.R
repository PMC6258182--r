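#' @import methods
NULL

#' Cα coordinate trajectory
#'
#' Container for a Cα-resolution molecular dynamics trajectory: a
#' frames × residues × 3 coordinate array in Ångström, the reference
#' structure `frame0` (the final equilibration snapshot, used for alignment
#' and never treated as an observation), the residue index vector and the
#' time between frames in picoseconds.
#'
#' @slot coords numeric array, frames × residues × 3 (Å).
#' @slot frame0 numeric matrix, residues × 3 (Å); alignment reference.
#' @slot ids integer vector of 1-based residue indices.
#' @slot frameInterval numeric scalar, time between frames (ps).
#'
#' @seealso [trajectory()], [splitHalves()], [alignTrajectory()]
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    coords = "array",
    frame0 = "matrix",
    ids = "integer",
    frameInterval = "numeric"
  )
)

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a frames x residues x 3 array")
  if (d[1] < 2L)
    return("a trajectory needs at least 2 frames")
  if (!all(is.finite(object@coords)))
    return("coords contain non-finite values")
  if (!identical(dim(object@frame0), c(d[2], 3L)) &&
      !identical(dim(object@frame0), c(as.integer(d[2]), 3L)))
    return("frame0 must be a residues x 3 matrix matching coords")
  if (length(object@ids) != d[2])
    return("ids length must equal the residue dimension of coords")
  if (any(duplicated(object@ids)))
    return("residue ids must be unique")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    return("frameInterval must be a single positive number (ps)")
  TRUE
})

#' Virtual parent for probability densities on an interval
#'
#' Both the fitted maximum-entropy estimates ([MaxEntDensity-class]) and
#' analytic reference densities ([FunctionDensity-class]) answer the same
#' generics ([evaluatePdf()], [evaluateCdf()], [supportInterval()]), so the
#' similarity measures accept either.
#'
#' @exportClass Density
setClass("Density", representation("VIRTUAL"))

#' Maximum-entropy density estimate
#'
#' Exponential-family density exp(λ0 − 1 + Σ_j λ_j T_j(t)) on a closed
#' support interval, with Chebyshev polynomials of the first kind T_j
#' evaluated on the support affinely mapped to \[−1, 1\]. λ0 carries the
#' normalisation so that the density integrates to one over the support;
#' outside the support the density is defined as exactly zero.
#'
#' @slot lambdas numeric vector λ0..λD (λ0 first).
#' @slot dimension integer D ≥ 0, number of active basis functions.
#' @slot support numeric length-2, closed support interval in data units.
#' @slot basis character, basis identifier ("chebyshev").
#' @slot n integer, size of the fitting sample.
#' @slot seed integer seed the fit was run under.
#' @slot surd [SurdScore-class] of the fit against its own sample.
#'
#' @seealso [estimateDensity()], [evaluatePdf()], [densityMean()]
#' @exportClass MaxEntDensity
setClass("MaxEntDensity",
  contains = "Density",
  representation(
    lambdas = "numeric",
    dimension = "integer",
    support = "numeric",
    basis = "character",
    n = "integer",
    seed = "integer",
    surd = "ANY"
  )
)

setValidity("MaxEntDensity", function(object) {
  if (length(object@support) != 2L || diff(object@support) <= 0)
    return("support must be an interval [lo, hi] with lo < hi")
  if (length(object@lambdas) != object@dimension + 1L)
    return("lambdas must have length dimension + 1 (lambda0 first)")
  if (!all(is.finite(object@lambdas)))
    return("lambdas must be finite")
  TRUE
})

#' Analytic density wrapper
#'
#' Wraps arbitrary pdf/cdf functions (e.g. a truncated Gaussian used as an
#' oracle in tests, or a known reference distribution) so they can be fed
#' to the similarity measures alongside fitted estimates.
#'
#' @slot pdf vectorised density function of one numeric argument.
#' @slot cdf vectorised distribution function, or NULL to integrate pdf.
#' @slot support numeric length-2 support interval.
#'
#' @seealso [functionDensity()]
#' @exportClass FunctionDensity
setClass("FunctionDensity",
  contains = "Density",
  representation(pdf = "function", cdf = "ANY", support = "numeric")
)

#' Goodness score of a trial density from sampled uniform random data
#'
#' Result of scoring a CDF-mapped (SURD) sample through single order
#' statistics: the log-likelihood under the Beta(k, n+1−k) order-statistic
#' densities, standardised by the Monte-Carlo null mean and standard
#' deviation at the same sample size so that the scale is stable in n.
#'
#' @slot score numeric, standardised (size-stable) score.
#' @slot raw numeric, raw order-statistic log-likelihood.
#' @slot accept logical, TRUE if score is above the calibrated null
#'   quantile threshold.
#' @slot threshold numeric, acceptance threshold on the standardised scale.
#' @slot n integer sample size.
#'
#' @seealso [scoreSurd()]
#' @exportClass SurdScore
setClass("SurdScore",
  representation(score = "numeric", raw = "numeric", accept = "logical",
                 threshold = "numeric", n = "integer")
)

#' Comparison group definition
#'
#' A named bundle of trajectory comparisons: the description mode (on-residue
#' displacement magnitudes "1R" or residue-pair distances "2R"), the frame
#' alignment strategy, the sample averaging strategy, and the list of
#' trajectory-label pairs to compare.
#'
#' @slot name character group label (e.g. "1R-self-1", "2R-mt-wt-2").
#' @slot mode "1R" or "2R".
#' @slot alignment "self", "mean" or "none" (2R needs no alignment).
#' @slot averaging "local", "global" or "shifting".
#' @slot pairs list of length-2 character vectors of trajectory labels;
#'   identical labels denote a self (first-half vs second-half) comparison.
#'
#' @seealso [comparisonGroup()], [enumerateComparisons()], [runGroup()]
#' @exportClass ComparisonGroup
setClass("ComparisonGroup",
  representation(name = "character", mode = "character",
                 alignment = "character", averaging = "character",
                 pairs = "list")
)

setValidity("ComparisonGroup", function(object) {
  if (!object@mode %in% c("1R", "2R")) return("mode must be '1R' or '2R'")
  if (!object@alignment %in% c("self", "mean", "none"))
    return("alignment must be 'self', 'mean' or 'none'")
  if (!object@averaging %in% c("local", "global", "shifting"))
    return("averaging must be 'local', 'global' or 'shifting'")
  if ((object@alignment == "none") != (object@mode == "2R"))
    return("alignment 'none' is used exactly when mode is '2R'")
  if (object@averaging == "shifting" && object@mode != "2R")
    return("averaging 'shifting' only applies to 2R distance pairs")
  if (!length(object@pairs)) return("pairs must be non-empty")
  ok <- vapply(object@pairs, function(p)
    is.character(p) && length(p) == 2L, logical(1))
  if (!all(ok)) return("each pair must be two trajectory labels")
  TRUE
})

#' Result of running a comparison group
#'
#' Holds the per-comparison measure panels (one row per residue or residue
#' pair per block pairing), the collapsed per-residue profiles averaged over
#' the four block pairings, and the significance profile (per-residue
#' log10 p-values from the symmetrised one-sample Kolmogorov-Smirnov test).
#'
#' @slot group [ComparisonGroup-class] that was run.
#' @slot panels data.frame of raw measure panels.
#' @slot profiles data.frame of per-residue block-averaged measures and
#'   log10 p-values, one row per (pair, residue).
#' @slot cutoff numeric Å neighbour cutoff used (2R; NA for 1R).
#' @slot seed integer master seed.
#'
#' @seealso [runGroup()], [writeResultTSV()]
#' @exportClass ComparisonResult
setClass("ComparisonResult",
  representation(group = "ComparisonGroup", panels = "data.frame",
                 profiles = "data.frame", cutoff = "numeric",
                 seed = "integer")
)
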