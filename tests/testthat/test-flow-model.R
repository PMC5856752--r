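test_that("graph canonicalization normalizes, floors and rejects bad input", {
  lab <- c("A", "B", "C")
  w <- matrix(0, 3, 3, dimnames = list(lab, lab))
  w["A", "B"] <- w["B", "A"] <- 50
  w["A", "C"] <- w["C", "A"] <- 5
  g <- regionGraph(w, config = flowConfig(capacityFloor = 1e-4))
  expect_equal(unname(capacities(g)), c(1.0, 0.1, 1e-4))
  expect_equal(nrow(g@edges), 3)  # complete candidate set

  w2 <- matrix(c(0, 50, 50, 0), 2, 2)
  expect_equal(max(capacities(regionGraph(w2, c("A", "B")))), 1.0)

  expect_error(regionGraph(matrix(0, 3, 3), lab), "all-zero")
  wAsym <- w; wAsym["A", "B"] <- 49
  expect_error(regionGraph(wAsym), "asymmetric.*[AB].*[AB]")
  wNeg <- w; wNeg["A", "C"] <- wNeg["C", "A"] <- -1
  expect_error(regionGraph(wNeg), "negative or non-finite.*[AC]")
})

test_that("gamma is the largest nodal activation-to-capacity ratio", {
  f <- twoNodeFixture()
  expect_equal(computeGamma(f$graph, f$activation), 1)

  zero <- activationMatrix(matrix(0, 2, 1), "m1", c("A", "B"))
  expect_equal(computeGamma(f$graph, zero), 0)

  g3 <- regionGraphFromEdges(paste0("N", 1:3),
                             rbind(c(1, 2), c(1, 3), c(2, 3)), rep(0.5, 3))
  R3 <- activationMatrix(matrix(c(2, 1, 1), 3, 1))
  expect_equal(computeGamma(g3, R3), 2)
})

test_that("LP assembly has the documented shape", {
  f <- twoNodeFixture()
  lp <- assembleFlowLP(f$graph, f$activation, f$config)
  expect_equal(ncol(lp@constraints), 2)   # f + P
  expect_equal(nrow(lp@constraints), 4)   # 1 capacity + 2 demand + 1 feasibility
  expect_equal(sort(unique(lp@rowFamily)),
               c("capacity", "demand", "feasibility"))

  # complete 16-node graph, 5 modes: L*M + L variables with L = 120
  w <- matrix(1, 16, 16); diag(w) <- 0
  g16 <- regionGraph(w, paste0("P", 1:16))
  R16 <- activationMatrix(matrix(1, 16, 5))
  lp16 <- assembleFlowLP(g16, R16)
  expect_equal(ncol(lp16@constraints), 120 * 5 + 120)
  expect_equal(nrow(lp16@constraints), 120 + 16 * 5 + 120 * 5)

  expect_error(assembleFlowLP(f$graph, f$activation,
                              flowConfig(gamma = 0, rho = 1)),
               "gamma must be positive")
  badR <- f$activation
  badR@values[1] <- NaN
  expect_error(assembleFlowLP(f$graph, badR), "NaN|finite")
})

test_that("an all-zero mode carries no flow and zero activation solves to zero", {
  f <- twoNodeFixture()
  R <- activationMatrix(cbind(m1 = c(1, 0.5), dead = c(0, 0)),
                        regionLabels = c("A", "B"))
  sol <- solveFlow(f$graph, R, f$config)
  expect_equal(unname(flows(sol)[, "dead"]), 0)
  expect_equal(objectiveValue(sol), 1)

  zero <- activationMatrix(matrix(0, 2, 1), "m1", c("A", "B"))
  solz <- solveFlow(f$graph, zero, flowConfig())
  expect_equal(solverStatus(solz), "optimal")
  expect_equal(unname(as.numeric(flows(solz))), 0)
  expect_equal(unname(as.numeric(corrections(solz))), 0)
  expect_equal(objectiveValue(solz), 0)
})

test_that("hand-derived optima are reproduced exactly", {
  f <- twoNodeFixture()
  sol <- solveFlow(f$graph, f$activation, f$config)
  expect_equal(objectiveValue(sol), 1, tolerance = 1e-10)
  expect_equal(unname(as.numeric(flows(sol))), 1, tolerance = 1e-10)
  expect_equal(unname(as.numeric(corrections(sol))), 0, tolerance = 1e-10)

  # three nodes: demand at j forces f1 >= 0.99; pushing the last 0.01 of i's
  # demand through the strong (enhanced) edge beats the weak edge
  t3 <- threeNodeFixture()
  s3 <- solveFlow(t3$graph, t3$activation, t3$config)
  # one-dimensional line-search oracle over p in [0, 0.01], f1 = 0.99 + p
  p <- seq(0, 0.01, length.out = 2001)
  obj <- (0.99 + p) / 0.99 + (0.01 - p) / 0.01 + 1 * (1 + 1 / 0.99) * p
  expect_equal(objectiveValue(s3), min(obj), tolerance = 1e-9)
  expect_equal(objectiveValue(s3), 10199 / 9900, tolerance = 1e-9)
  expect_equal(unname(flows(s3)[, 1]), c(1, 0), tolerance = 1e-8)
  expect_equal(unname(as.numeric(corrections(s3))), c(0.01, 0),
               tolerance = 1e-8)
})

test_that("solution validation passes optima and flags constructed violations", {
  f <- twoNodeFixture()
  zero <- activationMatrix(matrix(0, 2, 1), "m1", c("A", "B"))
  solz <- solveFlow(f$graph, zero, flowConfig())
  expect_equal(max(validateSolution(f$graph, zero, flowConfig(), solz)), 0)

  sol <- solveFlow(f$graph, f$activation, f$config)
  resid <- validateSolution(f$graph, f$activation, f$config, sol)
  expect_true(all(resid <= f$config@solverTolerance))

  # perturb a demand-binding flow downward: demand constraint must trip
  bad <- sol
  bad@flows[1, 1] <- bad@flows[1, 1] - 2 * f$config@solverTolerance
  expect_error(validateSolution(f$graph, f$activation, f$config, bad),
               "demand")
  # perturb upward past the capacity/feasibility bound
  bad2 <- sol
  bad2@flows[1, 1] <- bad2@flows[1, 1] + 2 * f$config@solverTolerance
  expect_error(validateSolution(f$graph, f$activation, f$config, bad2),
               "capacity|feasibility")
})

test_that("circuit extraction thresholds flows and validates the mode", {
  f <- twoNodeFixture()
  sol <- solveFlow(f$graph, f$activation, f$config)
  circ <- extractCircuit(sol, f$graph, "m1")
  expect_s4_class(circ, "CircuitNetwork")
  expect_equal(nrow(circ@edges), 1)
  expect_equal(circ@weights, 1, tolerance = 1e-9)
  expect_equal(edgeTable(circ)$from, "A")

  expect_error(extractCircuit(sol, f$graph, "nope"), "unknown mode")

  zero <- activationMatrix(matrix(0, 2, 1), "m1", c("A", "B"))
  solz <- solveFlow(f$graph, zero, flowConfig())
  expect_equal(nrow(extractCircuit(solz, f$graph, "m1")@edges), 0)
})

test_that("enhanced capacities add corrections to input capacities", {
  f <- twoNodeFixture()
  zero <- activationMatrix(matrix(0, 2, 1), "m1", c("A", "B"))
  solz <- solveFlow(f$graph, zero, flowConfig())
  expect_equal(unname(enhancedCapacities(f$graph, solz)),
               unname(capacities(f$graph)))

  t3 <- threeNodeFixture()
  s3 <- solveFlow(t3$graph, t3$activation, t3$config)
  enh <- enhancedCapacities(t3$graph, s3)
  expect_equal(unname(enh), c(1.00, 0.01), tolerance = 1e-8)
  expect_true(all(enh >= capacities(t3$graph) - 1e-12))
})

test_that("objective matches the independent HiGHS oracle on random instances", {
  set.seed(7)
  lps <- list(); mine <- numeric(0)
  for (t in 1:25) {
    inst <- randomFlowInstance()
    lp <- assembleFlowLP(inst$graph, inst$activation, inst$config)
    sol <- solveFlow(lp, config = inst$config, graph = inst$graph)
    expect_equal(solverStatus(sol), "optimal")
    lps[[t]] <- lp
    mine[t] <- objectiveValue(sol)
  }
  expect_equal(mine, oracleObjectives(lps), tolerance = 1e-6)
})

test_that("scaling, permutation and mode-isolation invariances hold", {
  set.seed(11)
  for (rep in 1:5) {
    inst <- randomFlowInstance(nMax = 5, mMax = 3)
    cfg0 <- flowConfig(rho = 0)  # pure routing

    # scaling: R -> 3 R scales flows and objective by exactly 3 at rho = 0
    sol1 <- solveFlow(inst$graph, inst$activation, cfg0)
    R3 <- activationMatrix(3 * inst$activation@values)
    sol3 <- solveFlow(inst$graph, R3, cfg0)
    expect_equal(objectiveValue(sol3), 3 * objectiveValue(sol1),
                 tolerance = 1e-7)

    # permutation equivariance: relabeling nodes permutes the solution
    n <- length(nodeLabels(inst$graph))
    perm <- sample(n)
    wOrig <- matrix(0, n, n)
    e <- inst$graph@edges
    wOrig[e] <- inst$graph@capacity; wOrig[e[, 2:1, drop = FALSE]] <- inst$graph@capacity
    wPerm <- wOrig[perm, perm]
    gPerm <- regionGraphFromEdges(paste0("Q", seq_len(n)),
                                  allPairsLocal(n), wPerm[allPairsLocal(n)])
    RPerm <- activationMatrix(inst$activation@values[perm, , drop = FALSE])
    solP <- solveFlow(gPerm, RPerm, inst$config)
    solO <- solveFlow(inst$graph, inst$activation, inst$config)
    expect_equal(objectiveValue(solP), objectiveValue(solO), tolerance = 1e-7)

    # mode isolation at rho = 0: zeroing one mode leaves the others' cost
    if (ncol(inst$activation@values) > 1) {
      v <- inst$activation@values
      contrib <- function(sol, m) sum((1 / inst$graph@capacity) * flows(sol)[, m])
      m0 <- 1
      v0 <- v; v0[, m0] <- 0
      solDrop <- solveFlow(inst$graph, activationMatrix(v0), cfg0)
      expect_equal(sum(flows(solDrop)[, m0]), 0, tolerance = 1e-9)
      others <- setdiff(seq_len(ncol(v)), m0)
      expect_equal(sum(vapply(others, function(m) contrib(solDrop, m), 1)),
                   sum(vapply(others, function(m) contrib(sol1, m), 1)),
                   tolerance = 1e-7)
    }
  }
})

test_that("total correction is non-increasing in rho and auto-gamma is feasible", {
  set.seed(13)
  for (rep in 1:4) {
    inst <- randomFlowInstance(nMax = 5, mMax = 2)
    totP <- vapply(c(0.1, 1, 10, 100), function(rho) {
      sol <- solveFlow(inst$graph, inst$activation, flowConfig(rho = rho))
      expect_equal(solverStatus(sol), "optimal")  # feasible under auto-gamma
      sum(corrections(sol))
    }, numeric(1))
    expect_true(all(diff(totP) <= 1e-7))
  }
})
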