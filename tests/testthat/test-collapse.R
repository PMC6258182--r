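# Comparison orchestration: groups, enumeration, neighbour collapse,
# block averaging, and the end-to-end pipeline.

test_that("neighbour collapse averages pair measures onto residues", {
  pm <- data.frame(k = c(1, 1), j = c(2, 3), value = c(0.2, 0.4))
  out <- neighborCollapse(pm)
  expect_equal(out[["1"]], 0.3)
  expect_equal(out[["2"]], 0.2)   # single neighbour: identity
  expect_equal(out[["3"]], 0.4)

  # 3-residue chain, all pairwise neighbours
  abc <- data.frame(k = c(1, 1, 2), j = c(2, 3, 3),
                    value = c(0.1, 0.5, 0.9))
  got <- neighborCollapse(abc)
  expect_equal(unname(got), c((0.1 + 0.5) / 2, (0.1 + 0.9) / 2,
                              (0.5 + 0.9) / 2))
})

test_that("pairs outside the neighbour intersection never contribute", {
  pm <- data.frame(k = c(1, 1), j = c(2, 3), value = c(10, 2))
  nb <- data.frame(k = 1, j = 3)    # pair 1-2 not in the intersection
  out <- neighborCollapse(pm, nb)
  expect_equal(unname(out), c(2, 2))
  expect_named(out, c("1", "3"))

  # a residue that loses all its pairs is omitted with a warning
  nb2 <- data.frame(k = c(1, 4), j = c(2, 5))
  expect_warning(out2 <- neighborCollapse(pm, nb2), "omitted")
  expect_false("4" %in% names(out2))
})

test_that("block averaging is the elementwise mean over pairings", {
  p <- c("1" = 2, "2" = 4)
  expect_equal(blockAverage(list(p, p, p, p)), p)
  four <- lapply(1:4, function(i) c("7" = i))
  expect_equal(blockAverage(four)[["7"]], 2.5)
  expect_equal(blockAverage(list(p)), p)   # self comparison: passthrough
  # mismatched residue sets intersect
  q <- c("2" = 6, "3" = 1)
  expect_equal(blockAverage(list(p, q)), c("2" = 5))
  expect_error(blockAverage(list()), "no profiles")
})

test_that("comparison enumeration yields 1 task per self, 4 per cross pair", {
  self <- comparisonGroup("1R-self-1")
  tasks <- enumerateComparisons(self)
  expect_equal(nrow(tasks), 6)
  expect_true(all(tasks$blockA == 1 & tasks$blockB == 2))

  wtwt <- comparisonGroup("1R-wt-wt-1")
  expect_equal(nrow(enumerateComparisons(wtwt)), 12)

  mtwt <- comparisonGroup("1R-mt-wt-1")
  t36 <- enumerateComparisons(mtwt)
  expect_equal(nrow(t36), 36)
  expect_equal(unname(table(t36$pair)[["X-A"]]), 4)

  expect_error(comparisonGroup("no-such-group"), "unknown")
  expect_error(comparisonGroup("bad", mode = "1R", alignment = "self",
                               averaging = "shifting",
                               pairs = list(c("A", "B"))),
               "shifting")
})

test_that("comparing a trajectory with itself gives near-null measures", {
  set.seed(23)
  spec <- mockSpec(nResidues = 4, nFrames = 600, seed = 5)
  tr <- gaussianMockPair(spec)$A
  g <- comparisonGroup("same", mode = "1R", alignment = "self",
                       averaging = "local", pairs = list(c("A", "B")))
  res <- runGroup(g, list(A = tr, B = tr), seed = 31)
  same <- res@panels[res@panels$comparison %in% c("A1-B1", "A2-B2"), ]
  expect_true(all(same$delta_rmsf == 0))
  expect_true(all(same$js < 0.05))
  expect_true(all(same$ks0 < 0.1))
  expect_true(all(same$pv_ks1 > 0.05))  # identical samples: deflated KS1
})

test_that("the 2R pipeline collapses pair panels onto residue profiles", {
  set.seed(24)
  spec <- mockSpec(nResidues = 6, nFrames = 120,
                   means = toyStructure(6, "line", spacing = 4),
                   sds = matrix(0.3, 6, 3),
                   meanShift = 0.4, sdScale = 1.2, seed = 9)
  pair <- gaussianMockPair(spec)
  g <- comparisonGroup("2R-toy", mode = "2R", alignment = "none",
                       averaging = "local", pairs = list(c("A", "B")))
  res <- runGroup(g, pair, cutoff = 9, seed = 41)
  # line spacing 4, cutoff 9, small jitter: pairs are |k-j| <= 2
  keys <- unique(res@panels$id)
  kj <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  expect_true(all(abs(as.integer(kj[, 1]) - as.integer(kj[, 2])) <= 2))
  expect_setequal(unique(res@profiles$id), 1:6)
  expect_true(all(c("js", "kl_ave", "pv_ks1") %in% names(res@profiles)))
})

test_that("shifting averaging runs the 2R pipeline on centred samples", {
  set.seed(26)
  spec <- mockSpec(nResidues = 4, nFrames = 120,
                   means = toyStructure(4, "line", spacing = 4),
                   meanShift = 1.0, seed = 13)
  pair <- gaussianMockPair(spec)
  gl <- comparisonGroup("2R-loc", mode = "2R", alignment = "none",
                        averaging = "local", pairs = list(c("A", "B")))
  gs <- comparisonGroup("2R-shift", mode = "2R", alignment = "none",
                        averaging = "shifting", pairs = list(c("A", "B")))
  rl <- runGroup(gl, pair, cutoff = 14, seed = 43)
  rs <- runGroup(gs, pair, cutoff = 14, seed = 43)
  # pure mean perturbation: shifting removes the structural offset, so the
  # density measures can only improve on average
  expect_lte(mean(rs@profiles$js), mean(rl@profiles$js))
  expect_lte(mean(rs@profiles$delta_p), mean(rl@profiles$delta_p))
})

test_that("neighbour collapse reduces replicate variance of the measure", {
  set.seed(27)
  reps <- 6
  js_pair <- numeric(reps); js_collapsed <- numeric(reps)
  for (r in seq_len(reps)) {
    spec <- mockSpec(nResidues = 5, nFrames = 100,
                     means = toyStructure(5, "line", spacing = 4),
                     sds = matrix(0.3, 5, 3),
                     sdScale = 1.15, seed = 100 + r)
    pair <- gaussianMockPair(spec)
    g <- comparisonGroup("2R-var", mode = "2R", alignment = "none",
                         averaging = "local", pairs = list(c("A", "B")))
    res <- runGroup(g, pair, cutoff = 9, seed = 51)
    one <- res@panels[res@panels$comparison == "A1-B1", ]
    js_pair[r] <- one$js[one$id == "2|3"]
    prof <- res@profiles
    js_collapsed[r] <- prof$js[prof$id == 2]
  }
  expect_lte(var(js_collapsed), var(js_pair))
})

test_that("the pipeline is deterministic under a fixed master seed", {
  spec <- mockSpec(nResidues = 3, nFrames = 200, sdScale = 1.2, seed = 6)
  pair <- gaussianMockPair(spec)
  g <- comparisonGroup("det", mode = "1R", alignment = "self",
                       averaging = "local", pairs = list(c("A", "B")))
  r1 <- runGroup(g, pair, seed = 77)
  r2 <- runGroup(g, pair, seed = 77)
  expect_identical(r1@profiles, r2@profiles)
  expect_identical(r1@panels, r2@panels)
})

test_that("KLmax tracks KLave across mixed perturbations", {
  set.seed(28)
  spec <- mockSpec(nResidues = 12, nFrames = 300, meanShift = 0.6,
                   sdScale = 1.4, randomPerturb = TRUE, seed = 15)
  pair <- gaussianMockPair(spec)
  g <- comparisonGroup("scatter", mode = "1R", alignment = "self",
                       averaging = "local", pairs = list(c("A", "B")))
  res <- runGroup(g, pair, seed = 61)
  rho <- cor(res@panels$kl_max, res@panels$kl_ave, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("group runs fail fast on inconsistent inputs", {
  spec <- mockSpec(nResidues = 3, nFrames = 20, seed = 2)
  pair <- gaussianMockPair(spec)
  small <- gaussianMockPair(mockSpec(nResidues = 4, nFrames = 20, seed = 2))
  g <- comparisonGroup("bad", mode = "1R", alignment = "self",
                       averaging = "local", pairs = list(c("A", "B")))
  expect_error(runGroup(g, list(A = pair$A, B = small$B)),
               "residue-count mismatch")
  expect_error(runGroup(g, list(A = pair$A)), "missing")
})
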