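test_that("pearson network matches hand values and rejects constant rows", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5))
  r <- pearsonNetwork(x)
  expect_equal(r["a", "b"], 6.5 / sqrt(43.75), tolerance = 1e-12)
  expect_equal(diag(r), c(a = 1, b = 1))

  same <- rbind(a = c(1, 3, 2, 5), b = c(1, 3, 2, 5))
  expect_equal(pearsonNetwork(same)["a", "b"], 1)
  neg <- rbind(a = c(1, 3, 2, 5), b = -c(1, 3, 2, 5))
  expect_equal(pearsonNetwork(neg)["a", "b"], -1)

  expect_error(pearsonNetwork(rbind(a = c(1, 2, 3), flat = c(2, 2, 2))),
               "constant.*flat")

  # invariance to positive per-row affine rescaling
  set.seed(3)
  y <- matrix(rnorm(40), 4, 10)
  y2 <- y * c(2, 0.5, 3, 10) + c(-1, 4, 0, 2)
  expect_equal(pearsonNetwork(y), pearsonNetwork(y2), tolerance = 1e-12)
})

test_that("fisher averaging is exact on fixed points and monotone", {
  expect_equal(fisherAverage(c(0.4, 0.4)), 0.4, tolerance = 1e-12)
  expect_equal(fisherAverage(c(0.5, -0.5)), 0, tolerance = 1e-12)
  expect_equal(fisherAverage(c(0.5, 0.9)), 0.7660773415974732,
               tolerance = 1e-9)
  expect_error(fisherAverage(numeric(0)), "empty")
  # monotone in each argument; clipping keeps +/-1 finite
  expect_true(fisherAverage(c(0.5, 0.91)) > fisherAverage(c(0.5, 0.9)))
  expect_true(is.finite(fisherAverage(c(1, 1))))
})

test_that("region activation averages map magnitudes within regions", {
  maps <- matrix(c(3, 3, 1, -1, 0.2, 0.4, 0.9), ncol = 1,
                 dimnames = list(paste0("v", 1:7), "m1"))
  parcel <- setNames(c("u", "u", "pm", "pm", "g", "g", "g"), paste0("v", 1:7))
  act <- regionActivation(maps, parcel)
  v <- activationValues(act)
  expect_equal(v["u", "m1"], 3)
  expect_equal(v["pm", "m1"], 1)      # magnitude before averaging
  expect_equal(v["g", "m1"], 0.5)
  # raw-mean alternative
  raw <- activationValues(regionActivation(maps, parcel, magnitude = FALSE))
  expect_equal(raw["pm", "m1"], 0)
  # permutation of locations within a region commutes
  perm <- c(2, 1, 4, 3, 7, 5, 6)
  act2 <- regionActivation(maps[perm, , drop = FALSE], parcel[perm])
  expect_equal(activationValues(act2)[rownames(v), ], v[, 1])
  expect_error(regionActivation(maps[1:6, , drop = FALSE], parcel),
               "absent.*v7")
})

test_that("activity masking zeroes the low cluster and is idempotent", {
  a <- activationMatrix(matrix(c(0, 0, 0, 10, 10), 5, 1))
  m <- kmeansActivityMask(a)
  expect_equal(as.numeric(activationValues(m)), c(0, 0, 0, 10, 10))

  b <- activationMatrix(matrix(c(0, 1), 2, 1))
  expect_equal(as.numeric(activationValues(kmeansActivityMask(b))), c(0, 1))

  flat <- activationMatrix(matrix(2, 4, 1))
  expect_equal(as.numeric(activationValues(kmeansActivityMask(flat))),
               rep(2, 4))  # all kept active

  set.seed(5)
  x <- activationMatrix(matrix(runif(40), 20, 2))
  m1 <- kmeansActivityMask(x)
  expect_true(all(activationValues(m1) <= activationValues(x)))
  expect_equal(activationValues(kmeansActivityMask(m1)),
               activationValues(m1))  # idempotent
})

test_that("mode matching recovers identity, permutations and noisy copies", {
  set.seed(9)
  ref <- matrix(rnorm(80), 16, 5, dimnames = list(NULL, paste0("ref", 1:5)))
  self <- matchModes(ref, ref)
  expect_equal(self$reference, paste0("ref", 1:5))
  expect_equal(self$r, rep(1, 5), tolerance = 1e-12)

  perm <- c(3, 5, 1, 2, 4)
  shuffled <- ref[, perm]
  colnames(shuffled) <- paste0("mode", 1:5)
  mm <- matchModes(shuffled, ref)
  expect_equal(mm$reference[match(paste0("mode", 1:5), mm$mode)],
               paste0("ref", perm))

  noisy <- -ref + matrix(rnorm(80, sd = 0.1 * sd(ref)), 16, 5)
  colnames(noisy) <- paste0("mode", 1:5)
  mn <- matchModes(noisy, ref)
  expect_equal(mn$reference[match(paste0("mode", 1:5), mn$mode)],
               paste0("ref", 1:5))
  expect_true(all(abs(mn$r) > 0.9))
  expect_true(all(mn$sign == -1L))  # sign of the match is recorded
})

test_that("top-k consistency counts selections with canonical tie-breaks", {
  v1 <- setNames(c(3, 2, 1), c("A|B", "A|C", "B|C"))
  one <- topkConsistency(list(v1), k = 2)
  expect_equal(one$frequency, c(1, 1, 0))

  two <- topkConsistency(list(v1, v1), k = 2)
  expect_true(all(two$frequency %in% c(0, 1)))

  # five subjects; edge A|B always ranks first by construction
  set.seed(2)
  nets <- lapply(1:5, function(i)
    setNames(c(10, runif(2)), c("A|B", "A|C", "B|C")))
  five <- topkConsistency(nets, k = 1)
  expect_equal(five$frequency[five$edge == "A|B"], 1)

  # ties broken by canonical edge order, deterministically
  tied <- setNames(c(1, 1, 1), c("A|B", "A|C", "B|C"))
  t1 <- topkConsistency(list(tied), k = 2)
  expect_equal(t1$frequency, c(1, 1, 0))

  expect_error(topkConsistency(list(v1), k = 5), "exceeds")

  # matrix input converts through the canonical edge order
  m <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  m["A", "B"] <- m["B", "A"] <- 3
  m["A", "C"] <- m["C", "A"] <- 2
  m["B", "C"] <- m["C", "B"] <- 1
  expect_equal(topkConsistency(list(m), k = 2)$frequency, c(1, 1, 0))
})
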