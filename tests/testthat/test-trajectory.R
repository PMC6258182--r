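# Trajectory features: superposition, references, halving, displacement
# magnitudes, pair distances, shifting, RMSD trace.

test_that("superposition exactly recovers rigid transforms", {
  set.seed(2)
  ref <- matrix(rnorm(30, sd = 5), ncol = 3)
  R <- rotationMatrix(0, 0, pi / 2)
  mobile <- sweep(ref %*% t(R), 2, c(5, 5, 5), "+")
  fit <- superpose(mobile, ref)
  expect_lt(.rmsdHelper(fit, ref), 1e-8)
  expect_equal(superpose(ref, ref), ref, tolerance = 1e-10)
  expect_error(superpose(ref[1:5, ], ref), "same dimensions")
})

test_that("superposition RMSD matches direct-rotation-search and bio3d", {
  set.seed(3)
  ref <- matrix(rnorm(12, sd = 3), ncol = 3)   # 4-point toy
  mobile <- ref
  mobile[1, ] <- mobile[1, ] + c(1.5, -0.5, 0.25)
  ours <- .rmsdHelper(superpose(mobile, ref), ref)
  expect_equal(ours, rmsdGridOracle(mobile, ref), tolerance = 1e-3)
  # independent library cross-check
  b3d <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(ref)),
                   mobile = matrix(as.vector(t(mobile)), nrow = 1)))
  expect_equal(ours,
               .rmsdHelper(matrix(b3d, ncol = 3, byrow = TRUE), ref),
               tolerance = 1e-6)
})

test_that("superposition is idempotent", {
  set.seed(4)
  ref <- matrix(rnorm(24, sd = 4), ncol = 3)
  mobile <- ref + matrix(rnorm(24, sd = 0.3), ncol = 3)
  once <- superpose(mobile, ref)
  twice <- superpose(once, ref)
  expect_lt(max(abs(twice - once)), 1e-8)
})

test_that("the mean reference is a fixed point independent of input order", {
  one <- matrix(rnorm(15), ncol = 3)
  expect_equal(makeMeanReference(list(one)), one)

  R <- rotationMatrix(0.3, -0.2, 1.1)
  moved <- sweep(one %*% t(R), 2, c(1, 2, 3), "+")
  m2 <- makeMeanReference(list(one, moved))
  expect_lt(.rmsdHelper(superpose(m2, one), one), 1e-6)

  set.seed(6)
  base <- matrix(rnorm(15, sd = 3), ncol = 3)
  structs <- lapply(1:3, function(i) base + matrix(rnorm(15, sd = 0.4),
                                                   ncol = 3))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  refs <- lapply(perms, function(p) makeMeanReference(structs[p]))
  for (r in refs[-1])
    expect_lt(max(abs(superpose(r, refs[[1]]) - refs[[1]])), 1e-5)

  expect_error(makeMeanReference(list()), "empty")
})

test_that("half splitting is contiguous, equal and excludes frame0", {
  set.seed(7)
  tr <- trajectory(array(rnorm(2000 * 3 * 3), dim = c(2000, 3, 3)))
  blocks <- splitHalves(tr)
  expect_equal(nFrames(blocks[[1]]), 1000)
  expect_equal(nFrames(blocks[[2]]), 1000)
  expect_identical(coords(blocks[[1]]), coords(tr)[1:1000, , , drop = FALSE])
  expect_identical(coords(blocks[[2]]),
                   coords(tr)[1001:2000, , , drop = FALSE])
  expect_identical(frame0(blocks[[1]]), frame0(tr))

  tr4 <- trajectory(array(rnorm(4 * 2 * 3), dim = c(4, 2, 3)))
  b4 <- splitHalves(tr4)
  expect_identical(coords(b4[[1]]), coords(tr4)[1:2, , , drop = FALSE])
  expect_identical(coords(b4[[2]]), coords(tr4)[3:4, , , drop = FALSE])

  tr5 <- trajectory(array(rnorm(5 * 2 * 3), dim = c(5, 2, 3)))
  expect_warning(b5 <- splitHalves(tr5), "dropping")
  expect_identical(coords(b5[[2]]), coords(tr5)[3:4, , , drop = FALSE])
})

test_that("displacement magnitudes match hand enumeration", {
  # 1 residue, 2 frames at (0,0,0) and (2,0,0): local mean (1,0,0)
  x <- array(0, dim = c(2, 1, 3))
  x[2, 1, 1] <- 2
  tr <- trajectory(x)
  m <- displacementMagnitudes(tr)
  expect_equal(unname(m$block1[, 1]), c(1, 1))

  # all frames identical -> all magnitudes zero
  same <- staticTrajectory(matrix(1:9, ncol = 3), nf = 4)
  expect_true(all(displacementMagnitudes(same)$block1 == 0))

  # 2 residues x 4 frames: brute-force arithmetic
  set.seed(8)
  y <- array(rnorm(4 * 2 * 3), dim = c(4, 2, 3))
  tb <- trajectory(y)
  got <- displacementMagnitudes(tb)$block1
  for (r in 1:2) {
    mu <- colMeans(y[, r, ])
    for (f in 1:4)
      expect_equal(unname(got[f, r]), sqrt(sum((y[f, r, ] - mu)^2)))
  }
})

test_that("global and local averaging coincide when block means are equal", {
  set.seed(9)
  a <- array(rnorm(6 * 2 * 3), dim = c(6, 2, 3))
  b <- a
  b[, , ] <- a[rev(1:6), , ]       # same frames, reversed: identical means
  trA <- trajectory(a); trB <- trajectory(b)
  loc <- displacementMagnitudes(trA, trB, averaging = "local")
  glo <- displacementMagnitudes(trA, trB, averaging = "global")
  expect_equal(loc, glo, tolerance = 1e-12)
  expect_error(displacementMagnitudes(trA, averaging = "global"),
               "both blocks")
})

test_that("rmsf follows the RMS convention with SD as an option", {
  expect_equal(rmsf(c(1, 1, 1, 1)), 1)
  expect_equal(rmsf(c(0, 0)), 0)
  expect_equal(rmsf(c(3, 4)), sqrt(12.5))
  expect_equal(rmsf(c(3, 4), type = "sd"), sd(c(3, 4)))
  expect_error(rmsf(numeric(0)), "empty")
})

test_that("neighbour membership uses the at-least-one-frame rule", {
  # two residues fixed at (0,0,0) and (3,4,0): distance exactly 5
  s <- rbind(c(0, 0, 0), c(3, 4, 0))
  pd <- pairDistances(staticTrajectory(s, nf = 3), cutoff = 12)
  expect_equal(nrow(pd$neighbors), 1)
  expect_true(all(pd$distances == 5))

  # always >= 13 apart: excluded
  far <- rbind(c(0, 0, 0), c(13.5, 0, 0))
  pdf_ <- pairDistances(staticTrajectory(far, nf = 3), cutoff = 12)
  expect_equal(nrow(pdf_$neighbors), 0)

  # crosses the cutoff in exactly one frame: included
  x <- array(0, dim = c(3, 2, 3))
  x[, 2, 1] <- c(14, 11.9, 14)
  pd1 <- pairDistances(trajectory(x), cutoff = 12)
  expect_equal(nrow(pd1$neighbors), 1)
})

test_that("pair distances are invariant under per-frame rigid transforms", {
  set.seed(11)
  x <- array(rnorm(8 * 4 * 3, sd = 3), dim = c(8, 4, 3))
  tr <- trajectory(x)
  y <- x
  for (f in 1:8) {
    R <- rotationMatrix(runif(1, 0, 2 * pi), runif(1, 0, pi),
                        runif(1, 0, 2 * pi))
    y[f, , ] <- sweep(x[f, , ] %*% t(R), 2, rnorm(3, sd = 10), "+")
  }
  trR <- trajectory(y, frame0 = frame0(tr))
  a <- pairDistances(tr, cutoff = 20)
  b <- pairDistances(trR, cutoff = 20)
  expect_identical(a$neighbors, b$neighbors)
  expect_equal(sort(as.vector(a$distances)), sort(as.vector(b$distances)),
               tolerance = 1e-9)
})

test_that("shifting zeroes the density mean and moves sample and support", {
  u24 <- uniformMaxEnt(2, 4)
  sh <- shiftDistribution(c(2.5, 3.5), u24)
  expect_equal(supportInterval(sh$estimate), c(-1, 1), tolerance = 1e-9)
  expect_equal(sh$sample, c(-0.5, 0.5), tolerance = 1e-9)
  expect_lt(abs(densityMean(sh$estimate)), 1e-8)

  centred <- uniformMaxEnt(-1, 1)
  sh0 <- shiftDistribution(c(-0.2, 0.2), centred)
  expect_equal(supportInterval(sh0$estimate), c(-1, 1), tolerance = 1e-9)
})

test_that("shifting location-offset pairs cannot worsen density measures", {
  set.seed(12)
  a <- rnorm(500, mean = 5, sd = 1)
  b <- rnorm(500, mean = 5.8, sd = 1)
  pa <- estimateDensity(a, seed = 3)
  pb <- estimateDensity(b, seed = 4)
  sa <- shiftDistribution(a, pa)
  sb <- shiftDistribution(b, pb)
  tol <- 1e-6
  expect_lte(jsDivergence(sa$estimate, sb$estimate),
             jsDivergence(pa, pb) + tol)
  expect_lte(deltaP(sa$estimate, sb$estimate), deltaP(pa, pb) + tol)
  expect_lte(ks0(sa$estimate, sb$estimate), ks0(pa, pb) + tol)
})

test_that("the RMSD trace is zero for copies and matches the oracle", {
  s <- matrix(rnorm(12, sd = 3), ncol = 3)
  expect_equal(rmsdTrace(staticTrajectory(s, nf = 3)), c(0, 0, 0),
               tolerance = 1e-10)

  R <- rotationMatrix(1, 0.5, -0.4)
  x <- array(0, dim = c(2, 4, 3))
  x[1, , ] <- sweep(s %*% t(R), 2, c(3, -2, 1), "+")
  x[2, , ] <- s
  x[2, 1, ] <- x[2, 1, ] + c(2, 0, 0)
  tr <- trajectory(x, frame0 = s)
  trace <- rmsdTrace(tr)
  expect_lt(trace[1], 1e-8)
  expect_equal(trace[2], rmsdGridOracle(x[2, , ], s), tolerance = 1e-3)
})
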