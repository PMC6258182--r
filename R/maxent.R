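# Nonparametric maximum-entropy density estimation.
#
# The estimate has the exponential-family form
#   P(v) = exp(lambda0 - 1 + sum_j lambda_j T_j(t(v))),  t(v) in [-1, 1],
# with Chebyshev polynomials of the first kind as the orthogonal level
# functions. The multipliers are found by penalized maximum likelihood
# (convex in lambda, BFGS with analytic gradient), the dimension D is grown
# from 1 until the fit is accepted by the SURD order-statistic score, and a
# five-member restart ensemble supplies the candidates from which a
# representative is selected.

# ---- Chebyshev basis --------------------------------------------------------

# T_1..T_D at points t in [-1,1]; length(t) x D matrix.
.chebBasis <- function(t, D) {
  n <- length(t)
  B <- matrix(0, n, D)
  if (D >= 1L) B[, 1L] <- t
  if (D >= 2L) B[, 2L] <- 2 * t * t - 1
  if (D >= 3L) for (j in 3:D) B[, j] <- 2 * t * B[, j - 1L] - B[, j - 2L]
  B
}

.toUnit <- function(x, support) {
  2 * (x - support[1L]) / (support[2L] - support[1L]) - 1
}

# ---- caches -----------------------------------------------------------------

.trajcompareCache <- new.env(parent = emptyenv())

.glQuad <- function(nQuad) {
  key <- paste0("gl", nQuad)
  q <- .trajcompareCache[[key]]
  if (is.null(q)) {
    q <- pracma::gaussLegendre(nQuad, -1, 1)
    .trajcompareCache[[key]] <- q
  }
  q
}

# Evaluate an expression under a temporary RNG state, restoring the caller's.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# ---- SURD scoring -----------------------------------------------------------

# Raw order-statistic log-likelihood: sum_k log Beta(u_(k); k, n+1-k).
.surdRaw <- function(u) {
  n <- length(u)
  k <- seq_len(n)
  sum(stats::dbeta(u, k, n + 1 - k, log = TRUE))
}

# Null calibration at sample size n: mean, sd and lower quantile of the raw
# score under genuinely uniform samples. Monte-Carlo with a fixed internal
# seed so results are reproducible regardless of the caller's RNG; cached
# per n for the session.
.surdNull <- function(n, reps = 10000L, acceptQuantile = 0.005) {
  key <- paste0("null", n, "_", reps)
  cal <- .trajcompareCache[[key]]
  if (is.null(cal)) {
    cal <- .withSeed(1000003L + n, {
      k <- seq_len(n)
      scores <- numeric(reps)
      chunk <- max(1L, min(reps, floor(2e6 / n)))
      done <- 0L
      while (done < reps) {
        m <- min(chunk, reps - done)
        U <- matrix(stats::runif(n * m), nrow = n)
        U <- apply(U, 2L, sort)
        if (n == 1L) U <- matrix(U, nrow = 1L)
        LB <- stats::dbeta(U, k, n + 1 - k, log = TRUE)
        scores[done + seq_len(m)] <- colSums(LB)
        done <- done + m
      }
      list(mean = mean(scores), sd = stats::sd(scores),
           q = stats::quantile(scores, acceptQuantile, names = FALSE))
    })
    cal$z <- (cal$q - cal$mean) / cal$sd
    .trajcompareCache[[key]] <- cal
  }
  cal
}

#' Score a CDF-mapped sample against sampled uniform random data
#'
#' A sample mapped through the cumulative distribution of a trial density is
#' uniform on \[0, 1\] exactly when the trial density is the truth. The k-th
#' order statistic of n uniforms follows Beta(k, n+1−k); the score is the
#' log-likelihood of the sorted mapped sample under those beta densities,
#' standardised by its Monte-Carlo null mean and standard deviation at size
#' n so the scale is stable across sample sizes. The fit is accepted when
#' the standardised score exceeds the calibrated lower null quantile.
#'
#' @param uniformSample sorted numeric vector in \[0, 1\] (the SURD candidate).
#' @param acceptQuantile lower null quantile defining acceptance
#'   (default 0.005).
#' @param nullReps Monte-Carlo replicates for the null calibration
#'   (default 10000; cached per sample size).
#' @return a [SurdScore-class] object.
#' @examples
#' n <- 10
#' scoreSurd(seq_len(n) / (n + 1))    # order-statistic means: accepted
#' @export
scoreSurd <- function(uniformSample, acceptQuantile = 0.005,
                      nullReps = 10000L) {
  u <- uniformSample
  if (length(u) == 0L) stop("empty SURD sample")
  if (is.unsorted(u)) stop("SURD sample must be sorted")
  if (any(u < 0 | u > 1)) stop("SURD sample must lie in [0, 1]")
  n <- length(u)
  cal <- .surdNull(n, reps = nullReps, acceptQuantile = acceptQuantile)
  raw <- .surdRaw(u)
  z <- (raw - cal$mean) / cal$sd
  new("SurdScore", score = z, raw = raw, accept = is.finite(z) && z >= cal$z,
      threshold = cal$z, n = as.integer(n))
}

#' Map a sample through a density's CDF onto \[0, 1\]
#'
#' The sorted CDF-transformed sample is the SURD (sampled uniform random
#' data) candidate: uniform exactly when the density matches the sample's
#' true distribution.
#'
#' @param estimate a [Density-class] object.
#' @param sample numeric vector of observations.
#' @return sorted numeric vector in \[0, 1\].
#' @export
mapToUniform <- function(estimate, sample) {
  sort(evaluateCdf(estimate, sample))
}

#' Select the representative estimate from a candidate ensemble
#'
#' Among candidates accepted by the SURD score, the one with the median
#' standardised score is returned (rank ceiling(m/2) of m after sorting by
#' score) — a robust notion of "most representative" fit.
#'
#' @param candidates list of [MaxEntDensity-class] objects with SURD scores.
#' @return a single [MaxEntDensity-class].
#' @export
selectRepresentative <- function(candidates) {
  if (!length(candidates)) stop("empty candidate list")
  sc <- vapply(candidates, function(e) e@surd@score, numeric(1))
  ord <- order(sc)
  candidates[[ord[ceiling(length(candidates) / 2)]]]
}

# ---- control ----------------------------------------------------------------

#' Control settings for maximum-entropy estimation
#'
#' @param maxD largest basis dimension tried (default 40).
#' @param nRestarts ensemble size: optimisation restarts per dimension
#'   (default 5).
#' @param nQuad Gauss-Legendre nodes for normalisation quadrature
#'   (default 256).
#' @param penalty L2 penalty weight on the multipliers (default 1e-4);
#'   stabilises the fit and pulls inactive multipliers to zero.
#' @param acceptQuantile SURD acceptance quantile (default 0.005).
#' @param nullReps Monte-Carlo replicates for SURD null calibration.
#' @param supportPad tail padding factor: the support extends
#'   `supportPad * IQR / n^(1/3)` beyond the sample extremes (default 3),
#'   so rare events beyond the observed range keep non-zero density.
#' @return list of settings for [estimateDensity()].
#' @export
maxentControl <- function(maxD = 40L, nRestarts = 5L, nQuad = 256L,
                          penalty = 1e-4, acceptQuantile = 0.005,
                          nullReps = 10000L, supportPad = 3) {
  list(maxD = as.integer(maxD), nRestarts = as.integer(nRestarts),
       nQuad = as.integer(nQuad), penalty = penalty,
       acceptQuantile = acceptQuantile, nullReps = as.integer(nullReps),
       supportPad = supportPad)
}

# Default support rule: sample range padded by pad*IQR/n^(1/3) on each side,
# floored at zero for intrinsically nonnegative variables.
.defaultSupport <- function(x, nonnegative, pad) {
  n <- length(x)
  w <- stats::IQR(x)
  if (w <= 0) w <- stats::sd(x)
  margin <- pad * w / n^(1 / 3)
  lo <- min(x) - margin
  hi <- max(x) + margin
  if (nonnegative) lo <- max(0, lo)
  c(lo, hi)
}

# ---- fitting ----------------------------------------------------------------

# Penalized MLE for fixed D. Returns list(lambda, logZ) in t-space.
.fitLambda <- function(Bs, Bq, gw, D, start, penalty) {
  Bs <- Bs[, seq_len(D), drop = FALSE]
  Bq <- Bq[, seq_len(D), drop = FALSE]
  bbar <- colMeans(Bs)
  logZ <- function(lam) {
    e <- drop(Bq %*% lam)
    m <- max(e)
    m + log(sum(gw * exp(e - m)))
  }
  fn <- function(lam) logZ(lam) - sum(bbar * lam) + penalty * sum(lam^2)
  gr <- function(lam) {
    e <- drop(Bq %*% lam)
    m <- max(e)
    we <- gw * exp(e - m)
    Eg <- drop(crossprod(Bq, we)) / sum(we)
    Eg - bbar + 2 * penalty * lam
  }
  fit <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(maxit = 400L, reltol = 1e-12))
  list(lambda = fit$par, logZ = logZ(fit$par))
}

.makeEstimate <- function(lambda, logZ, support, n, seed, surd = NULL) {
  # lambda0 chosen so that P(v) = exp(lambda0 - 1 + sum lambda_j T_j(t(v)))
  # is the normalized density on the original scale.
  lambda0 <- 1 - logZ + log(2 / diff(support))
  new("MaxEntDensity",
      lambdas = c(lambda0, lambda), dimension = length(lambda),
      support = as.numeric(support), basis = "chebyshev",
      n = as.integer(n), seed = as.integer(seed),
      surd = if (is.null(surd)) NULL else surd)
}

#' Estimate a probability density by nonparametric maximum entropy
#'
#' Fits exp(λ0 − 1 + Σ λ_j T_j) with Chebyshev level functions by penalized
#' maximum likelihood, growing the dimension D from 1 until the fit is
#' accepted by the SURD order-statistic score ([scoreSurd()]) or D reaches
#' `control$maxD`. At the accepting dimension an ensemble of restarts
#' provides candidates; the representative (median SURD score among
#' accepted) is returned.
#'
#' @param sample numeric vector of at least 2 distinct finite observations.
#' @param support optional fixed support interval c(lo, hi); by default the
#'   sample range padded by 3·IQR/n^(1/3) each side (floored at 0 when
#'   `nonnegative`).
#' @param nonnegative logical; TRUE for intrinsically nonnegative variables
#'   (displacement magnitudes, distances), flooring the default support at 0.
#' @param seed integer seed controlling the restart ensemble; identical
#'   sample and seed give an identical estimate.
#' @param control see [maxentControl()].
#' @return a [MaxEntDensity-class] with its SURD score attached.
#' @examples
#' est <- estimateDensity(rnorm(500), seed = 7)
#' integrate(function(z) evaluatePdf(est, z),
#'           supportInterval(est)[1], supportInterval(est)[2])
#' @export
estimateDensity <- function(sample, support = NULL, nonnegative = FALSE,
                            seed = 1L, control = maxentControl()) {
  x <- as.numeric(sample)
  if (length(x) < 2L) stop("need at least 2 observations")
  if (!all(is.finite(x))) stop("sample contains non-finite values")
  if (length(unique(x)) < 2L) stop("degenerate sample: all values identical")
  if (is.null(support))
    support <- .defaultSupport(x, nonnegative, control$supportPad)
  support <- as.numeric(support)
  if (diff(support) <= 0) stop("support must satisfy lo < hi")
  if (any(x < support[1L] | x > support[2L]))
    stop("sample values outside the fixed support")

  n <- length(x)
  t <- .toUnit(x, support)
  q <- .glQuad(control$nQuad)
  Bq <- .chebBasis(q$x, control$maxD)
  Bs <- .chebBasis(t, control$maxD)

  .withSeed(seed, {
    best <- NULL
    for (D in seq_len(control$maxD)) {
      accepted <- list()
      for (r in seq_len(control$nRestarts)) {
        start <- if (r == 1L) numeric(D) else stats::rnorm(D, 0, 0.5)
        fit <- .fitLambda(Bs, Bq, q$w, D, start, control$penalty)
        est <- .makeEstimate(fit$lambda, fit$logZ, support, n, seed)
        u <- mapToUniform(est, x)
        sc <- scoreSurd(u, acceptQuantile = control$acceptQuantile,
                        nullReps = control$nullReps)
        est@surd <- sc
        if (sc@accept) accepted[[length(accepted) + 1L]] <- est
        if (is.null(best) || sc@score > best@surd@score) best <- est
      }
      if (length(accepted)) return(selectRepresentative(accepted))
    }
    warning("no fit reached SURD acceptance up to D = ", control$maxD,
            "; returning the best-scoring estimate")
    best
  })
}

# ---- Density methods --------------------------------------------------------

#' @describeIn evaluatePdf maximum-entropy estimate: exp of the λ-weighted
#'   Chebyshev expansion; exactly 0 outside the support.
#' @export
setMethod("evaluatePdf", "MaxEntDensity", function(object, points) {
  v <- as.numeric(points)
  out <- numeric(length(v))
  inside <- v >= object@support[1L] & v <= object@support[2L]
  if (any(inside)) {
    t <- .toUnit(v[inside], object@support)
    D <- object@dimension
    g <- if (D > 0L) drop(.chebBasis(t, D) %*% object@lambdas[-1L]) else 0
    out[inside] <- exp(object@lambdas[1L] - 1 + g)
  }
  out
})

# Fine-grid cumulative table for a MaxEnt estimate (trapezoid, renormalised).
.cdfTable <- function(object, nGrid = 4001L) {
  grid <- seq(object@support[1L], object@support[2L], length.out = nGrid)
  p <- evaluatePdf(object, grid)
  cdf <- c(0, cumsum((p[-1L] + p[-nGrid]) / 2 * diff(grid)))
  cdf <- cdf / cdf[nGrid]
  list(grid = grid, cdf = cdf)
}

#' @describeIn evaluateCdf maximum-entropy estimate: cumulative trapezoid
#'   integral of the pdf on a fine grid, interpolated; clipped to \[0, 1\].
#' @export
setMethod("evaluateCdf", "MaxEntDensity", function(object, points) {
  v <- as.numeric(points)
  tab <- .cdfTable(object)
  out <- stats::approx(tab$grid, tab$cdf, xout = v, rule = 2)$y
  out[v <= object@support[1L]] <- 0
  out[v >= object@support[2L]] <- 1
  pmin(pmax(out, 0), 1)
})

#' @describeIn supportInterval support of a maximum-entropy estimate.
#' @export
setMethod("supportInterval", "MaxEntDensity", function(object) object@support)

#' @describeIn lambdas multipliers c(λ0, λ1, ..., λD).
#' @export
setMethod("lambdas", "MaxEntDensity", function(object) object@lambdas)

#' @describeIn basisDim active basis dimension D.
#' @export
setMethod("basisDim", "MaxEntDensity", function(object) object@dimension)

#' @describeIn densityMean first moment by Gauss-Legendre quadrature.
#' @export
setMethod("densityMean", "Density", function(object) {
  s <- supportInterval(object)
  q <- .glQuad(256L)
  v <- (q$x + 1) / 2 * diff(s) + s[1L]
  sum(q$w * v * evaluatePdf(object, v)) * diff(s) / 2
})

#' Wrap analytic pdf/cdf functions as a density object
#'
#' @param pdf vectorised density function.
#' @param support numeric c(lo, hi) support interval.
#' @param cdf optional vectorised distribution function; when omitted the
#'   pdf is integrated numerically on a fine grid.
#' @return a [FunctionDensity-class].
#' @examples
#' tn <- functionDensity(function(z) dnorm(z) / (pnorm(6) - pnorm(-6)),
#'                       support = c(-6, 6))
#' @export
functionDensity <- function(pdf, support, cdf = NULL) {
  new("FunctionDensity", pdf = pdf, cdf = cdf, support = as.numeric(support))
}

#' @describeIn evaluatePdf analytic density: the wrapped pdf, 0 outside the
#'   support.
#' @export
setMethod("evaluatePdf", "FunctionDensity", function(object, points) {
  v <- as.numeric(points)
  out <- numeric(length(v))
  inside <- v >= object@support[1L] & v <= object@support[2L]
  if (any(inside)) out[inside] <- object@pdf(v[inside])
  pmax(out, 0)
})

#' @describeIn evaluateCdf analytic density: the wrapped cdf if given, else
#'   a fine-grid cumulative integral of the pdf.
#' @export
setMethod("evaluateCdf", "FunctionDensity", function(object, points) {
  v <- as.numeric(points)
  if (!is.null(object@cdf)) {
    out <- object@cdf(v)
  } else {
    nGrid <- 4001L
    grid <- seq(object@support[1L], object@support[2L], length.out = nGrid)
    p <- evaluatePdf(object, grid)
    cdf <- c(0, cumsum((p[-1L] + p[-nGrid]) / 2 * diff(grid)))
    cdf <- cdf / cdf[nGrid]
    out <- stats::approx(grid, cdf, xout = v, rule = 2)$y
  }
  out[v <= object@support[1L]] <- 0
  out[v >= object@support[2L]] <- 1
  pmin(pmax(out, 0), 1)
})

#' @describeIn supportInterval support of an analytic density.
#' @export
setMethod("supportInterval", "FunctionDensity", function(object)
  object@support)

#' Draw random values from a density by inverse-CDF sampling
#'
#' Inverts the fine-grid CDF table by interpolation; used for
#' self-coherence checks (a sample drawn from an estimate, mapped back
#' through its CDF, is uniform).
#'
#' @param object a [Density-class] object.
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of length n inside the support.
#' @export
sampleDensity <- function(object, n, seed = 1L) {
  s <- supportInterval(object)
  grid <- seq(s[1L], s[2L], length.out = 4001L)
  cdf <- evaluateCdf(object, grid)
  u <- .withSeed(seed, stats::runif(n))
  stats::approx(cdf, grid, xout = u, rule = 2, ties = "ordered")$y
}

# ---- serialization ----------------------------------------------------------

#' Serialize a maximum-entropy estimate to JSON
#'
#' @param estimate a [MaxEntDensity-class].
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON string, invisibly when written to file.
#' @export
densityToJSON <- function(estimate, path = NULL) {
  stopifnot(is(estimate, "MaxEntDensity"))
  obj <- list(basis = estimate@basis, dimension = estimate@dimension,
              support = estimate@support, lambdas = estimate@lambdas,
              n = estimate@n, seed = estimate@seed)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a maximum-entropy estimate from JSON
#'
#' @param path file path or JSON string produced by [densityToJSON()].
#' @return a [MaxEntDensity-class].
#' @export
densityFromJSON <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new("MaxEntDensity", lambdas = as.numeric(obj$lambdas),
      dimension = as.integer(obj$dimension),
      support = as.numeric(obj$support), basis = obj$basis,
      n = as.integer(obj$n), seed = as.integer(obj$seed), surd = NULL)
}

# ---- show -------------------------------------------------------------------

setMethod("show", "MaxEntDensity", function(object) {
  cat("MaxEntDensity (", object@basis, " basis)\n", sep = "")
  cat("  dimension D =", object@dimension, "\n")
  cat(sprintf("  support     = [%.4g, %.4g]\n",
              object@support[1L], object@support[2L]))
  cat("  fitted on n =", object@n, "observations\n")
  if (!is.null(object@surd))
    cat(sprintf("  SURD score  = %.3f (%s)\n", object@surd@score,
                if (object@surd@accept) "accepted" else "rejected"))
})

setMethod("show", "SurdScore", function(object) {
  cat(sprintf("SurdScore: %.3f (raw %.2f, n = %d, threshold %.3f) -> %s\n",
              object@score, object@raw, object@n, object@threshold,
              if (object@accept) "accept" else "reject"))
})
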