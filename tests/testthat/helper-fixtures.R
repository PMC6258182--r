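# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own integration/sup code paths: plain 10^6-point trapezoid sums
# and dense-grid suprema over explicit function evaluations.

# -- analytic densities -------------------------------------------------------

uniformDensity <- function(lo, hi) {
  functionDensity(function(z) rep(1 / (hi - lo), length(z)),
                  support = c(lo, hi),
                  cdf = function(z) pmin(pmax((z - lo) / (hi - lo), 0), 1))
}

truncNormalDensity <- function(mu, sigma, lo, hi) {
  zc <- stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma)
  functionDensity(function(z) stats::dnorm(z, mu, sigma) / zc,
                  support = c(lo, hi),
                  cdf = function(z) pmin(pmax(
                    (stats::pnorm(z, mu, sigma) -
                       stats::pnorm(lo, mu, sigma)) / zc, 0), 1))
}

# piecewise-constant density 1/2 on [0, 1/2), 3/2 on [1/2, 1]
stepDensity <- function() {
  functionDensity(function(z) ifelse(z < 0.5, 0.5, 1.5),
                  support = c(0, 1),
                  cdf = function(z) {
                    out <- ifelse(z < 0.5, 0.5 * z, 0.25 + 1.5 * (z - 0.5))
                    pmin(pmax(out, 0), 1)
                  })
}

# flat maximum-entropy estimate (D = 0) on [lo, hi]
uniformMaxEnt <- function(lo, hi) {
  new("MaxEntDensity", lambdas = 1 - log(hi - lo), dimension = 0L,
      support = c(lo, hi), basis = "chebyshev", n = 2L, seed = 1L,
      surd = NULL)
}

# -- brute-force integral / sup oracles ---------------------------------------

trapzOracle <- function(f, lo, hi, n = 1e6 + 1) {
  z <- seq(lo, hi, length.out = n)
  y <- f(z)
  sum((y[-1] + y[-length(y)]) / 2) * (hi - lo) / (n - 1)
}

jsOracle <- function(pa, pb, lo, hi) {
  term <- function(p, q) ifelse(p > 0 & q > 0, p * log(p / q), 0)
  trapzOracle(function(z) {
    fa <- evaluatePdf(pa, z); fb <- evaluatePdf(pb, z)
    q <- (fa + fb) / 2
    (term(fa, q) + term(fb, q)) / 2
  }, lo, hi)
}

l1Oracle <- function(pa, pb, lo, hi) {
  trapzOracle(function(z) abs(evaluatePdf(pa, z) - evaluatePdf(pb, z)),
              lo, hi)
}

klBandOracle <- function(pa, pb, lo, hi, floor = 1e-12) {
  w <- function(z, pick) {
    fa <- evaluatePdf(pa, z); fb <- evaluatePdf(pb, z)
    lr <- abs(log(pmax(fa, floor) / pmax(fb, floor)))
    lr[fa <= floor & fb <= floor] <- 0
    lr * pick(fa, fb)
  }
  c(kl_min = trapzOracle(function(z) w(z, pmin), lo, hi),
    kl_ave = trapzOracle(function(z) w(z, function(a, b) sqrt(a * b)),
                         lo, hi),
    kl_max = trapzOracle(function(z) w(z, pmax), lo, hi))
}

ks0Oracle <- function(pa, pb, lo, hi, n = 2e5 + 1) {
  z <- seq(lo, hi, length.out = n)
  max(abs(evaluateCdf(pa, z) - evaluateCdf(pb, z)))
}

# one-sided empirical-vs-reference KS statistic, written out directly
ks1Oracle <- function(x, ref) {
  n <- length(x)
  u <- evaluateCdf(ref, sort(x))
  i <- seq_len(n)
  max(max(i / n - u), max(u - (i - 1) / n), 0)
}

# -- toy trajectories ---------------------------------------------------------

rotationMatrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# rigid-fit RMSD by direct minimisation over Euler angles (coarse grid +
# Nelder-Mead refinement); independent of the SVD solution
rmsdGridOracle <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  obj <- function(ang) {
    R <- rotationMatrix(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  g <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- c(0, 0, 0); bestv <- obj(best)
  for (a in g) for (b in g) for (cc in g) {
    v <- obj(c(a, b, cc))
    if (v < bestv) { bestv <- v; best <- c(a, b, cc) }
  }
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

.rmsdHelper <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# static trajectory: the same structure in every frame
staticTrajectory <- function(struct, nf = 2) {
  x <- array(0, dim = c(nf, nrow(struct), 3))
  for (f in seq_len(nf)) x[f, , ] <- struct
  trajectory(x, frame0 = struct)
}
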