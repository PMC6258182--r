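# The eight non-negative similarity measures between two fluctuation
# samples a, b and their density estimates p(z|a), p(z|b):
#   dRMSF, JS, dP (L1), KLmin/KLave/KLmax, KS1 (symmetrised 1-sample),
#   KS0 (0-sample on the two estimated CDFs), plus conversion of KS
#   statistics to p-values via the asymptotic Kolmogorov distribution.

.DENSITY_FLOOR <- 1e-12

# Quadrature over [lo, hi]: adaptive Gauss-Kronrod, trapezoid fallback for
# integrands with kinks the adaptive rule cannot localise.
.qintegrate <- function(f, lo, hi, nFallback = 1e5) {
  val <- tryCatch(
    stats::integrate(f, lo, hi, rel.tol = 1e-8, abs.tol = 1e-10,
                     subdivisions = 4000L, stop.on.error = TRUE)$value,
    error = function(e) NA_real_)
  if (is.finite(val)) return(val)
  z <- seq(lo, hi, length.out = nFallback)
  pracma::trapz(z, f(z))
}

.unionSupport <- function(pa, pb) {
  sa <- supportInterval(pa); sb <- supportInterval(pb)
  c(min(sa[1L], sb[1L]), max(sa[2L], sb[2L]))
}

#' Absolute RMSF difference between two samples
#'
#' @param a,b numeric displacement-magnitude samples (Å).
#' @param type RMSF convention, see [rmsf()].
#' @return |RMSF(a) − RMSF(b)| in Å.
#' @export
deltaRmsf <- function(a, b, type = "rms") {
  if (!length(a) || !length(b)) stop("empty sample")
  abs(rmsf(a, type) - rmsf(b, type))
}

#' Jensen-Shannon divergence between two estimated densities
#'
#' JS(a,b) = ½ KL(pa‖q) + ½ KL(pb‖q) with the mixture q = ½(pa + pb)
#' standing in for the unknown true density. Bounded: 0 ≤ JS ≤ ln 2, with
#' ln 2 attained for disjoint supports. Integration over the union of
#' supports.
#'
#' @param pa,pb [Density-class] objects.
#' @return divergence in nats.
#' @export
jsDivergence <- function(pa, pb) {
  u <- .unionSupport(pa, pb)
  term <- function(z, p, q) ifelse(p > 0 & q > 0, p * log(p / q), 0)
  f <- function(z) {
    fa <- evaluatePdf(pa, z); fb <- evaluatePdf(pb, z)
    q <- (fa + fb) / 2
    (term(z, fa, q) + term(z, fb, q)) / 2
  }
  max(0, .qintegrate(f, u[1L], u[2L]))
}

#' L1 distance between two estimated densities
#'
#' ∫ |p(z|a) − p(z|b)| dz over the union of supports; in \[0, 2\], with 2 for
#' disjoint supports.
#'
#' @param pa,pb [Density-class] objects.
#' @return unitless distance in \[0, 2\].
#' @export
deltaP <- function(pa, pb) {
  u <- .unionSupport(pa, pb)
  f <- function(z) abs(evaluatePdf(pa, z) - evaluatePdf(pb, z))
  min(2, max(0, .qintegrate(f, u[1L], u[2L])))
}

#' Kullback-Leibler band: KLmin, KLave, KLmax
#'
#' Weighted integrals of the non-negative deviation |ln p(z|a)/p(z|b)|,
#' with the unknown true density represented by the pointwise minimum, the
#' geometric mean, and the pointwise maximum of the two estimates. The
#' pointwise weight ordering min ≤ √(pa·pb) ≤ max makes
#' KLmin ≤ KLave ≤ KLmax. KLmin suppresses outliers; KLmax emphasises them
#' (rare events). Densities are floored at 1e-12 inside the log ratio, so
#' regions where one estimate vanishes contribute a capped |ln| at the
#' floor ratio.
#'
#' @param pa,pb [Density-class] objects.
#' @return named numeric c(kl_min, kl_ave, kl_max) in nats, with attribute
#'   `weights` = c(int_min, int_geo, int_max), the integrals of the three
#'   weight functions (∫min ≤ 1, ∫√(pa·pb) ≤ 1, ∫max ≥ 1).
#' @export
klBand <- function(pa, pb) {
  u <- .unionSupport(pa, pb)
  parts <- function(z) {
    fa <- evaluatePdf(pa, z); fb <- evaluatePdf(pb, z)
    lr <- abs(log(pmax(fa, .DENSITY_FLOOR) / pmax(fb, .DENSITY_FLOOR)))
    lr[fa <= .DENSITY_FLOOR & fb <= .DENSITY_FLOOR] <- 0
    list(lr = lr, wmin = pmin(fa, fb), wgeo = sqrt(fa * fb),
         wmax = pmax(fa, fb))
  }
  int <- function(pick) .qintegrate(function(z) {
    p <- parts(z); pick(p)
  }, u[1L], u[2L])
  out <- c(kl_min = int(function(p) p$lr * p$wmin),
           kl_ave = int(function(p) p$lr * p$wgeo),
           kl_max = int(function(p) p$lr * p$wmax))
  attr(out, "weights") <- c(int_min = int(function(p) p$wmin),
                            int_geo = int(function(p) p$wgeo),
                            int_max = int(function(p) p$wmax))
  out
}

# One-sided 1-sample KS statistic: empirical CDF of x vs estimated CDF of
# `est`; exact sup over the step discontinuities.
.ks1OneSided <- function(x, est) {
  n <- length(x)
  u <- evaluateCdf(est, sort(x))
  i <- seq_len(n)
  max(max(i / n - u), max(u - (i - 1) / n), 0)
}

#' Symmetrised one-sample Kolmogorov-Smirnov statistic
#'
#' KS1(a|b) = sup |F_n(a) − F(z|b)| compares the empirical CDF of sample a
#' with the estimated CDF of sample b (and vice versa); the symmetric
#' statistic is the geometric mean √(KS1(a|b)·KS1(b|a)). Each one-sided sup
#' is taken exactly over the empirical-CDF step discontinuities.
#'
#' @param a,b numeric samples.
#' @param pa,pb [Density-class] estimates for a and b.
#' @return statistic in \[0, 1\].
#' @export
ks1Sym <- function(a, pa, b, pb) {
  if (!length(a) || !length(b)) stop("empty sample")
  sqrt(.ks1OneSided(a, pb) * .ks1OneSided(b, pa))
}

#' Zero-sample Kolmogorov-Smirnov statistic between two estimated CDFs
#'
#' sup_z |F(z|a) − F(z|b)| over the union of supports, located on a dense
#' grid (≥ 10^4 points) and refined around the maximum.
#'
#' @param pa,pb [Density-class] objects.
#' @param nGrid grid size (default 20001).
#' @return statistic in \[0, 1\].
#' @export
ks0 <- function(pa, pb, nGrid = 20001L) {
  u <- .unionSupport(pa, pb)
  z <- seq(u[1L], u[2L], length.out = nGrid)
  d <- abs(evaluateCdf(pa, z) - evaluateCdf(pb, z))
  i <- which.max(d)
  lo <- z[max(1L, i - 1L)]; hi <- z[min(nGrid, i + 1L)]
  ref <- stats::optimize(function(v)
    abs(evaluateCdf(pa, v) - evaluateCdf(pb, v)),
    interval = c(lo, hi), maximum = TRUE)
  min(1, max(d[i], ref$objective))
}

#' Convert a Kolmogorov-Smirnov statistic to a p-value
#'
#' Complement Q(λ) of the asymptotic Kolmogorov distribution with the
#' standard finite-n correction λ = (√n + 0.12 + 0.11/√n)·D. The log10
#' p-value is computed directly from the series, so values down to 10^−250
#' and far below are represented without underflow.
#'
#' @param statistic KS statistic in \[0, 1\].
#' @param n effective sample size (block size for the symmetrised KS1; also
#'   used, as a descriptive non-calibrated device, for KS0).
#' @return list with `p` (p-value, 0 if below double precision) and
#'   `log10p` (log10 of the p-value, always finite for statistic < 1).
#' @export
ksToPValue <- function(statistic, n) {
  if (n < 1L) stop("n must be >= 1")
  if (statistic < 0 || statistic > 1)
    stop("KS statistic must lie in [0, 1]")
  if (statistic == 0) return(list(p = 1, log10p = 0))
  lam <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * statistic
  if (lam < 1.18) {
    # small-lambda branch: P(K <= lam) via the theta-function form
    w <- exp(-pi^2 / (8 * lam^2))
    cdf <- sqrt(2 * pi) / lam * (w + w^9 + w^25)
    p <- max(0, min(1, 1 - cdf))
    return(list(p = p, log10p = if (p > 0) log10(p) else -.Machine$double.xmax))
  }
  # large-lambda branch: Q = 2(w - w^4 + w^9 - ...), w = exp(-2 lam^2),
  # evaluated in log space
  e <- -2 * lam^2
  corr <- -exp(3 * e) + exp(8 * e) - exp(15 * e)
  log10p <- (log(2) + e + log1p(corr)) / log(10)
  list(p = 10^max(log10p, -323), log10p = log10p)
}

#' Full eight-measure similarity panel for one comparison
#'
#' Computes ΔRMSF, JS, Δp, the KL band, KS1 (symmetrised) and KS0 between
#' two fluctuation samples and their density estimates, plus p-values for
#' the KS statistics (effective n = block size; the KS0 conversion is a
#' descriptive, non-calibrated device and is flagged as such in the TSV
#' writer).
#'
#' @param a,b numeric samples.
#' @param pa,pb [Density-class] estimates fitted to a and b.
#' @return one-row data.frame with columns delta_rmsf, js, delta_p, kl_min,
#'   kl_ave, kl_max, ks1, ks0, pv_ks1, log10pv_ks1, pv_ks0, log10pv_ks0,
#'   n_a, n_b, and attribute `weights` from [klBand()].
#' @export
measurePanel <- function(a, pa, b, pb) {
  kl <- klBand(pa, pb)
  s1 <- ks1Sym(a, pa, b, pb)
  s0 <- ks0(pa, pb)
  neff <- min(length(a), length(b))
  p1 <- ksToPValue(s1, neff)
  p0 <- ksToPValue(s0, neff)
  out <- data.frame(
    delta_rmsf = deltaRmsf(a, b),
    js = jsDivergence(pa, pb),
    delta_p = deltaP(pa, pb),
    kl_min = kl[["kl_min"]], kl_ave = kl[["kl_ave"]],
    kl_max = kl[["kl_max"]],
    ks1 = s1, ks0 = s0,
    pv_ks1 = p1$p, log10pv_ks1 = p1$log10p,
    pv_ks0 = p0$p, log10pv_ks0 = p0$log10p,
    n_a = length(a), n_b = length(b))
  attr(out, "weights") <- attr(kl, "weights")
  out
}
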