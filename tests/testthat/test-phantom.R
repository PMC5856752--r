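test_that("the phantom fixture has the documented topology", {
  ph <- buildPhantom()
  expect_equal(length(nodeLabels(ph)), 16)
  gt <- groundTruthEdges(ph)
  expect_equal(length(unique(gt$bundle)), 7)
  expect_equal(length(unique(colourGroups(ph))), 5)
  expect_equal(nrow(gt), 9)

  key <- paste(gt$from, gt$to, sep = "|")
  expect_true(all(c("P1|P2", "P3|P4", "P5|P7", "P6|P9", "P8|P10", "P9|P12",
                    "P11|P15", "P13|P14", "P15|P16") %in% key))
  expect_false(any(c("P6|P7", "P7|P9", "P8|P9", "P9|P10", "P12|P15",
                     "P11|P16") %in% key))
  # every ground-truth edge stays within one colour group (validity enforces
  # it, but assert through the accessor too)
  grp <- colourGroups(ph)
  expect_true(all(grp[gt$from] == grp[gt$to]))
})

test_that("block design produces the printed block structure", {
  rec0 <- boldRecipe(eventProb = 0)
  tc <- blockDesign(rec0)
  expect_length(tc, 1200)
  expect_equal(sum(tc > 0), 600)                      # 20 blocks x 30 TRs ON
  expect_equal(unique(tc), c(0, 1))                   # exact square wave
  expect_equal(tc[1:30], rep(0, 30))                  # alternating from OFF

  expect_length(blockDesign(boldRecipe(), networkId = 2, seed = 3), 1200)
  # seeded reproducibility
  expect_equal(blockDesign(boldRecipe(), 3, seed = 5),
               blockDesign(boldRecipe(), 3, seed = 5))

  # mean event count ~ Binomial(1200, 0.2) over many seeds
  rec <- boldRecipe()
  counts <- vapply(1:1000, function(s)
    sum(blockDesign(rec, seed = s) - blockDesign(rec0, seed = s)), numeric(1))
  sdBin <- sqrt(1200 * 0.2 * 0.8)
  expect_lt(abs(mean(counts) - 240), 3 * sdBin / sqrt(1000))
})

test_that("per-network block orders are nearly orthogonal", {
  rec0 <- boldRecipe(eventProb = 0)
  for (seed in c(1, 20, 57)) {
    base <- sapply(1:5, function(g) blockDesign(rec0, g, seed))
    cc <- cor(base)
    expect_true(max(abs(cc[upper.tri(cc)])) <= 0.21)
  }
})

test_that("the hemodynamic kernel behaves canonically", {
  expect_equal(hrfConvolve(rep(0, 100), 0.72), rep(0, 100))
  tr <- 0.72
  imp <- c(1, rep(0, 199))
  h <- hrfConvolve(imp, tr)
  peakT <- (which.max(h) - 1) * tr
  expect_gt(peakT, 4); expect_lt(peakT, 7)   # response peak near 5-6 s
  expect_equal(max(h), 1, tolerance = 1e-9)  # unit-peak normalization
  # linearity
  set.seed(4)
  a <- runif(120); b <- runif(120)
  expect_equal(hrfConvolve(a + b, tr),
               hrfConvolve(a, tr) + hrfConvolve(b, tr), tolerance = 1e-10)
  expect_error(hrfConvolve(a, 0), "tr")
})

test_that("Rician corruption is nonnegative with the Rayleigh zero-signal mean", {
  set.seed(8)
  x <- rnorm(500)
  expect_equal(ricianNoise(x, 0), abs(x))
  y <- ricianNoise(x, 0.3)
  expect_true(all(y >= 0))

  sigma <- 0.7
  n <- 20000
  z <- ricianNoise(rep(0, n), sigma)
  rayleighMean <- sigma * sqrt(pi / 2)
  rayleighSd <- sigma * sqrt(2 - pi / 2)
  expect_lt(abs(mean(z) - rayleighMean), 3 * rayleighSd / sqrt(n))
})

test_that("simulated instances share group time courses and are reproducible", {
  ph <- buildPhantom()
  clean <- boldRecipe(ampScaleRange = c(1, 1), ricianSigma = 0)
  ts <- simulateInstance(ph, clean, seed = 2)
  expect_equal(dim(ts), c(16, 1200))
  grp <- colourGroups(ph)
  r <- suppressWarnings(cor(t(ts)))
  mates <- outer(grp, grp, "==") & upper.tri(r)
  expect_equal(unname(r[mates]), rep(1, sum(mates)), tolerance = 1e-12)

  # default recipe: within-group correlation exceeds between-group
  within <- c(); between <- c()
  for (s in 1:5) {
    tsn <- simulateInstance(ph, boldRecipe(), seed = s)
    rn <- cor(t(tsn))
    within <- c(within, abs(rn[outer(grp, grp, "==") & upper.tri(rn)]))
    between <- c(between, abs(rn[outer(grp, grp, "!=") & upper.tri(rn)]))
  }
  expect_gt(mean(within), mean(between))

  expect_identical(simulateInstance(ph, boldRecipe(), seed = 3),
                   simulateInstance(ph, boldRecipe(), seed = 3))
})

test_that("tractography emulation reproduces the documented error patterns", {
  ph <- buildPhantom()
  det <- emulateTractography(ph, "deterministic", seed = 1)
  expect_equal(det@counts["P15", "P16"], 0)       # missed by deterministic
  expect_gt(det@counts["P7", "P9"], 0)            # spurious crossing artifact
  expect_true(isSymmetric(unname(det@counts)))
  expect_true(all(det@counts >= 0))

  gtKey <- paste(nodeLabels(ph)[ph@edges[, 1]],
                 nodeLabels(ph)[ph@edges[, 2]], sep = "|")
  fnKey <- paste(nodeLabels(ph)[det@falseNegatives[, 1]],
                 nodeLabels(ph)[det@falseNegatives[, 2]], sep = "|")
  fpKey <- paste(nodeLabels(ph)[det@falsePositives[, 1]],
                 nodeLabels(ph)[det@falsePositives[, 2]], sep = "|")
  expect_true(all(fnKey %in% gtKey))              # FN subset of ground truth
  expect_length(intersect(fpKey, gtKey), 0)       # FP disjoint from truth

  prob <- emulateTractography(ph, "probabilistic", seed = 1)
  idx <- cbind(ph@edges[, 1], ph@edges[, 2])
  expect_true(all(prob@counts[idx] > 0))          # no missed true edges
  expect_gt(nrow(prob@falsePositives), nrow(det@falsePositives))
})

test_that("source separation recovers the colour groups", {
  ph <- buildPhantom()
  ref <- phantomReferenceMaps(ph)

  # noiseless: maps match groups essentially exactly
  clean <- boldRecipe(ampScaleRange = c(1, 1), ricianSigma = 0)
  ts <- simulateInstance(ph, clean, seed = 6)
  maps <- sourceSeparation(ts, 5, seed = 6)
  mm <- matchModes(maps, ref)
  expect_true(all(abs(mm$r) >= 0.985))
  expect_equal(sort(mm$reference), sort(colnames(ref)))

  # permuting locations permutes maps identically (up to component order)
  perm <- sample(16)
  maps2 <- sourceSeparation(ts[perm, ], 5, seed = 6)
  target <- maps[perm, ]
  align <- apply(abs(cor(maps2, target)), 1, which.max)
  expect_equal(sort(unname(align)), 1:5)  # a one-to-one component matching exists
  expect_equal(unname(maps2), unname(target[, align]), tolerance = 1e-4)

  expect_error(sourceSeparation(ts, 20, seed = 1), "rank|exceeds")
})

test_that("a small enhancement experiment is deterministic and well-formed", {
  ph <- buildPhantom()
  e1 <- runEnhancementExperiment(ph, "deterministic", nInstances = 2L,
                                 seed = 5L)
  e2 <- runEnhancementExperiment(ph, "deterministic", nInstances = 2L,
                                 seed = 5L)
  expect_identical(e1@corrections, e2@corrections)
  expect_identical(e1@flows, e2@flows)
  expect_equal(dim(e1@corrections), c(2, 120))
  expect_equal(dim(e1@flows), c(120, 5, 2))
  expect_true(all(e1@objectives > 0))
  s <- enhancementSummary(e1)
  expect_true(all(c("edge", "meanP", "sdP") %in% names(s)))
})
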