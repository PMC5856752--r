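#' @include connectivity.R
NULL

# fixture constants for the tractography emulation: streamline count levels
# and error sets chosen to reproduce the qualitative error patterns of
# deterministic vs probabilistic tractography on the phantom (crossings
# under-estimated, kissing/crossing artifacts spuriously connected)
.phantomCounts <- c(high = 100, underEstimated = 20, spurious = 10, missed = 0)

.detMissed <- c("P1|P2", "P3|P4", "P15|P16")
.detUnder  <- c("P5|P7", "P6|P9", "P8|P10", "P9|P12", "P11|P15")
.detSpurious <- c("P6|P7", "P7|P9", "P8|P9", "P9|P10", "P12|P15")
.probUnder <- c("P5|P7", "P6|P9", "P9|P12", "P11|P15")
.probSpurious <- c(.detSpurious, "P4|P5", "P5|P6", "P11|P16")

#' Build the synthetic Fibercup-like phantom
#'
#' A deterministic fixture of sixteen end-point regions (P1..P16) connected
#' by nine ground-truth region pairs grouped into seven fiber bundles
#' (bundles at crossings contribute a branch, hence two region pairs), with
#' five functional sub-networks (colour groups) whose members share a BOLD
#' activity pattern. The edge list is the package's canonical ground truth,
#' reconstructed from the phantom's documented bundle layout.
#'
#' @param seed unused (the fixture is deterministic); kept for interface
#'   symmetry with the simulators.
#' @return a [PhantomSpec-class].
#' @export
#' @examples
#' buildPhantom()
buildPhantom <- function(seed = 1L) {
  nodes <- paste0("P", 1:16)
  edges <- rbind(c(1, 2), c(3, 4), c(5, 7), c(6, 9), c(8, 10),
                 c(9, 12), c(11, 15), c(13, 14), c(15, 16))
  storage.mode(edges) <- "integer"
  bundles <- c(1L, 2L, 3L, 4L, 5L, 4L, 6L, 7L, 6L)
  groups <- integer(16)
  groups[c(1, 2)] <- 1L
  groups[c(3, 4)] <- 2L
  groups[c(5, 7, 13, 14)] <- 3L
  groups[c(6, 9, 12)] <- 4L
  groups[c(8, 10, 11, 15, 16)] <- 5L
  new("PhantomSpec", nodes = nodes, edges = edges, bundleIds = bundles,
      groups = groups,
      groupColours = c("blue", "green", "orange", "cyan", "red"))
}

#' Reference spatial maps of the phantom sub-networks
#'
#' Indicator maps (one column per colour group) over the sixteen regions,
#' used as the references for ICA mode matching.
#'
#' @param phantom a [PhantomSpec-class].
#' @return 16 x 5 numeric matrix.
#' @export
phantomReferenceMaps <- function(phantom) {
  g <- phantom@groups
  out <- vapply(seq_len(max(g)), function(k) as.numeric(g == k),
                numeric(length(g)))
  dimnames(out) <- list(phantom@nodes, phantom@groupColours)
  out
}

#' BOLD simulation recipe
#'
#' Block-design parameters of the SimTB-style simulation: 20 ON and 20 OFF
#' blocks of 30 TRs (1200 time points), unit events with probability 0.2
#' per TR, per-region uniform amplitude scaling in (0.8, 1.2) and Rician
#' noise. The default TR is 0.72 s (HCP-like; the phantom description's
#' "72 ms" is supported by setting `tr = 0.072` but is read as a typo).
#' When `ricianSigma` is `NA` the noise level is derived from `targetSnr`
#' relative to the mean clean-signal magnitude.
#'
#' @param nOnBlocks,nOffBlocks,blockLen block design shape.
#' @param eventProb per-TR probability of a unique unit event.
#' @param eventAmp event amplitude relative to the task block (1).
#' @param tr repetition time in seconds.
#' @param ampScaleRange per-region amplitude scaling range.
#' @param ricianSigma Rician noise sigma (`NA` = derive from `targetSnr`).
#' @param targetSnr target SNR when `ricianSigma` is `NA`.
#' @return a [BoldRecipe-class].
#' @export
boldRecipe <- function(nOnBlocks = 20L, nOffBlocks = 20L, blockLen = 30L,
                       eventProb = 0.2, eventAmp = 1, tr = 0.72,
                       ampScaleRange = c(0.8, 1.2), ricianSigma = NA_real_,
                       targetSnr = 20) {
  new("BoldRecipe", nOnBlocks = as.integer(nOnBlocks),
      nOffBlocks = as.integer(nOffBlocks), blockLen = as.integer(blockLen),
      eventProb = eventProb, eventAmp = eventAmp, tr = tr,
      ampScaleRange = as.numeric(ampScaleRange),
      ricianSigma = as.numeric(ricianSigma), targetSnr = targetSnr)
}

# seeded ON/OFF block orders for networks 1..networkId; successive networks
# are redrawn until their ON-block overlap with every earlier network stays
# within 2 of the independence expectation, so base designs are guaranteed
# nearly orthogonal (pairwise square-wave correlation bounded by 0.2)
networkBlockOrders <- function(recipe, networkId, seed) {
  nb <- recipe@nOnBlocks + recipe@nOffBlocks
  expectOv <- recipe@nOnBlocks^2 / nb
  alt <- rep(c(FALSE, TRUE), length.out = nb)
  orders <- vector("list", networkId)
  withSeed(as.integer(seed) + 997L, {
    for (g in seq_len(networkId)) {
      repeat {
        cand <- sample(alt)
        dev <- vapply(orders[seq_len(g - 1)],
                      function(o) abs(sum(o & cand) - expectOv), numeric(1))
        if (g == 1 || all(dev <= 2)) break
      }
      orders[[g]] <- cand
    }
  })
  orders[[networkId]]
}

#' Block-design activation time course
#'
#' A square wave of ON/OFF blocks with independent Bernoulli unit events
#' superposed per TR. Without a network id the blocks alternate OFF/ON;
#' with a network id the 20 ON blocks are placed in a seeded per-network
#' random order constrained to near-expected pairwise overlap across
#' networks, so that the base time courses of different sub-networks are
#' nearly uncorrelated (the independence their ICA separation relies on).
#'
#' @param recipe a [BoldRecipe-class].
#' @param networkId optional integer sub-network id.
#' @param seed integer seed.
#' @return numeric activation time course of length
#'   `(nOnBlocks + nOffBlocks) * blockLen`.
#' @export
#' @examples
#' length(blockDesign(boldRecipe(eventProb = 0)))  # 1200
blockDesign <- function(recipe, networkId = NULL, seed = 1L) {
  nb <- recipe@nOnBlocks + recipe@nOffBlocks
  on <- if (is.null(networkId)) rep(c(FALSE, TRUE), length.out = nb)
        else networkBlockOrders(recipe, as.integer(networkId), seed)
  withSeed(as.integer(seed) + 31L * (if (is.null(networkId)) 0L
                                     else as.integer(networkId)), {
    tc <- rep(as.numeric(on), each = recipe@blockLen)
    if (recipe@eventProb > 0) {
      ev <- stats::rbinom(length(tc), 1L, recipe@eventProb)
      tc <- tc + recipe@eventAmp * ev
    }
    tc
  })
}

#' Canonical double-gamma hemodynamic response function
#'
#' `dgamma(t, 6, 1) - dgamma(t, 16, 1)/6`: response peak near 5-6 s,
#' undershoot near 16 s, undershoot ratio 1/6; normalized to unit peak.
#'
#' @param t time points in seconds.
#' @return HRF values.
#' @export
canonicalHrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Convolve an activation time course with the hemodynamic response
#'
#' Linear convolution with the canonical double-gamma HRF sampled at the
#' repetition time, truncated to the input length.
#'
#' @param tc numeric activation time course.
#' @param tr repetition time in seconds.
#' @return BOLD time course of the same length.
#' @export
hrfConvolve <- function(tc, tr) {
  if (tr <= 0) stop("tr must be > 0")
  n <- length(tc)
  h <- canonicalHrf(seq(0, by = tr, length.out = min(n, ceiling(40 / tr))))
  out <- stats::convolve(tc, rev(h), type = "open")
  out[seq_len(n)]
}

#' Apply Rician noise
#'
#' Magnitude-MRI noise model: \eqn{x \to \sqrt{(x+n_1)^2 + n_2^2}} with
#' independent Gaussian \eqn{n_1, n_2 \sim N(0, \sigma^2)}. Output is
#' nonnegative; \eqn{\sigma \to 0} recovers |x|.
#'
#' @param x numeric signal.
#' @param sigma noise standard deviation.
#' @return corrupted signal.
#' @export
ricianNoise <- function(x, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(abs(x))
  n1 <- stats::rnorm(length(x), 0, sigma)
  n2 <- stats::rnorm(length(x), 0, sigma)
  sqrt((x + n1)^2 + n2^2)
}

#' Simulate one fMRI instance for the phantom
#'
#' Each colour group gets a base BOLD time course (seeded block design plus
#' unit events, convolved with the canonical HRF); regions in the same group
#' share their group's course, scaled by an independent uniform amplitude
#' factor, and Rician noise is added. This emulates the phantom simulation:
#' shared activity patterns within sub-networks, structural variability via
#' amplitude scaling, scanner-like magnitude noise.
#'
#' @param phantom a [PhantomSpec-class].
#' @param recipe a [BoldRecipe-class].
#' @param seed integer seed (each instance of the 100-realization experiment
#'   gets its own).
#' @return region x time numeric matrix (16 x 1200 at the default recipe)
#'   with attribute `tr`.
#' @export
simulateInstance <- function(phantom, recipe = boldRecipe(), seed = 1L) {
  g <- phantom@groups
  nG <- max(g)
  len <- (recipe@nOnBlocks + recipe@nOffBlocks) * recipe@blockLen
  base <- matrix(0, nG, len)
  for (k in seq_len(nG))
    base[k, ] <- hrfConvolve(blockDesign(recipe, k, seed), recipe@tr)
  withSeed(as.integer(seed) + 499999L, {
    scales <- stats::runif(length(g), recipe@ampScaleRange[1],
                           recipe@ampScaleRange[2])
    clean <- base[g, , drop = FALSE] * scales
    sigma <- recipe@ricianSigma
    if (is.na(sigma)) sigma <- mean(abs(clean)) / recipe@targetSnr
    out <- matrix(ricianNoise(clean, sigma), nrow(clean), ncol(clean))
  })
  dimnames(out) <- list(phantom@nodes, NULL)
  attr(out, "tr") <- recipe@tr
  out
}

#' Emulate tractography streamline counting on the phantom
#'
#' Produces a streamline-count matrix reproducing the characteristic error
#' patterns of the two tractography families on the phantom: deterministic
#' tractography misses connections entirely (P1-P2, P3-P4, P15-P16),
#' under-estimates links in crossing/bending configurations (P5-P7, P6-P9,
#' P8-P10, P9-P12, P11-P15) and creates spurious crossing artifacts (P6-P7,
#' P7-P9, P8-P9, P9-P10, P12-P15); probabilistic tractography reconstructs
#' every true connection at a nonzero count but adds a wider spurious set.
#' Counts get multiplicative uniform jitter (seeded).
#'
#' @param phantom a [PhantomSpec-class].
#' @param method "deterministic" or "probabilistic".
#' @param seed integer seed for the count jitter.
#' @param counts named count levels (high / underEstimated / spurious /
#'   missed); the defaults are the package's calibrated fixture constants.
#' @param jitter relative jitter half-width (0.2 = +/-20\%).
#' @return a [TractogramEmulation-class].
#' @export
emulateTractography <- function(phantom, method = c("deterministic",
                                                    "probabilistic"),
                                seed = 1L, counts = .phantomCounts,
                                jitter = 0.2) {
  method <- match.arg(method)
  nodes <- phantom@nodes
  n <- length(nodes)
  key <- function(e) paste(nodes[pmin(e[, 1], e[, 2])],
                           nodes[pmax(e[, 1], e[, 2])], sep = "|")
  trueKeys <- key(phantom@edges)

  if (method == "deterministic") {
    missedK <- .detMissed; underK <- .detUnder; spurK <- .detSpurious
  } else {
    missedK <- character(0); underK <- .probUnder; spurK <- .probSpurious
  }

  cnt <- matrix(0, n, n, dimnames = list(nodes, nodes))
  setCount <- function(k, value) {
    ab <- strsplit(k, "|", fixed = TRUE)
    for (p in ab) {
      cnt[p[1], p[2]] <<- value
      cnt[p[2], p[1]] <<- value
    }
  }
  setCount(setdiff(trueKeys, c(missedK, underK)), counts[["high"]])
  setCount(underK, counts[["underEstimated"]])
  setCount(missedK, counts[["missed"]])
  setCount(spurK, counts[["spurious"]])

  withSeed(as.integer(seed) + 77003L, {
    jit <- matrix(stats::runif(n * n, 1 - jitter, 1 + jitter), n, n)
    jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
    cnt <- round(cnt * jit, 1)
  })

  pairIdx <- function(keys) {
    if (!length(keys)) return(matrix(integer(0), 0, 2))
    m <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    cbind(match(m[, 1], nodes), match(m[, 2], nodes))
  }
  new("TractogramEmulation", method = method, counts = cnt,
      falseNegatives = pairIdx(missedK), underEstimated = pairIdx(underK),
      falsePositives = pairIdx(spurK))
}

# symmetric whitening-based FastICA (logcosh contrast, symmetric
# decorrelation); rows of x are variables (regions/voxels), columns samples
fastIcaSym <- function(x, nComp, seed = 1L, maxIter = 500, tol = 1e-8) {
  n <- nrow(x); p <- ncol(x)
  if (nComp > min(n, p)) stop("nComp exceeds data rank bound")
  xc <- x - rowMeans(x)
  cv <- tcrossprod(xc) / p
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values[seq_len(nComp)]
  if (any(pos <= 1e-12 * eg$values[1]))
    stop("data rank below requested component count")
  K <- diag(1 / sqrt(pos), nComp) %*% t(eg$vectors[, seq_len(nComp), drop = FALSE])
  z <- K %*% xc  # whitened, nComp x p

  orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- withSeed(as.integer(seed) + 131L,
                orth(matrix(stats::rnorm(nComp * nComp), nComp)))
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W1 <- orth(g %*% t(z) / p - diag(rowMeans(gp), nComp) %*% W)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("FastICA did not fully converge")
  s <- W %*% z  # sources, nComp x p
  # mixing in original variable space: xc ~ A s
  A <- xc %*% t(s) %*% solve(tcrossprod(s))
  list(S = s, A = A, K = K, W = W)
}

#' Spatial source separation of simulated BOLD data
#'
#' Temporal FastICA on the region (or voxel) time series: independent
#' sources are extracted from the whitened data (symmetric fixed-point
#' iteration with the logcosh contrast) and the per-region mixing columns
#' are returned as spatial maps, each normalized to unit Euclidean norm
#' with its largest-magnitude entry positive. The fixed-point iteration is
#' restarted from `nStarts` seeded initializations and the run with the
#' largest negentropy proxy (squared deviation of `E[log cosh]` from its
#' Gaussian value) is kept, which avoids occasional poor local optima.
#' Sign and permutation indeterminacy is resolved downstream by
#' [matchModes()].
#'
#' @param ts numeric location x time matrix.
#' @param nComponents number of components to extract.
#' @param seed integer seed for the unmixing initialization.
#' @param nStarts number of restarts.
#' @return location x component numeric matrix of spatial maps.
#' @export
sourceSeparation <- function(ts, nComponents, seed = 1L, nStarts = 10L) {
  x <- as.matrix(ts)
  if (nComponents > min(dim(x)))
    stop("nComponents exceeds the data rank bound min(locations, samples)")
  gaussLogCosh <- 0.3745672
  fit <- NULL; bestJ <- -Inf
  for (s in seq_len(nStarts)) {
    cand <- tryCatch(
      suppressWarnings(fastIcaSym(x, nComponents, seed = seed + 7919L * (s - 1L))),
      error = function(e) NULL)
    if (is.null(cand)) next
    J <- sum((apply(cand$S, 1, function(r) mean(log(cosh(r)))) - gaussLogCosh)^2)
    if (J > bestJ) { bestJ <- J; fit <- cand }
  }
  if (is.null(fit)) stop("source separation failed for all restarts")
  A <- fit$A
  for (k in seq_len(ncol(A))) {
    nrm <- sqrt(sum(A[, k]^2))
    if (nrm == 0) stop("degenerate spatial map from decomposition")
    A[, k] <- A[, k] / nrm
    if (A[which.max(abs(A[, k])), k] < 0) A[, k] <- -A[, k]
  }
  rownames(A) <- rownames(ts)
  colnames(A) <- paste0("IC", seq_len(ncol(A)))
  A
}

# one full phantom pipeline pass: simulate -> separate -> activations
# (matched to colour groups, masked) -> LP solve
phantomInstanceSolve <- function(phantom, graph, recipe, config, seed) {
  ts <- simulateInstance(phantom, recipe, seed)
  maps <- sourceSeparation(ts, max(phantom@groups), seed = seed)
  ref <- phantomReferenceMaps(phantom)
  mm <- matchModes(maps, ref)
  ordered <- maps[, match(mm$mode[order(match(mm$reference, colnames(ref)))],
                          colnames(maps)), drop = FALSE]
  colnames(ordered) <- colnames(ref)
  act <- kmeansActivityMask(regionActivation(ordered))
  act <- suppressWarnings(dropDegenerateModes(act))
  sol <- solveFlow(graph, act, config)
  matchR <- abs(mm$r)[order(match(mm$reference, colnames(ref)))]
  list(solution = sol, activation = act, maps = ordered,
       matchQuality = matchR)
}

#' Run the phantom enhancement experiment
#'
#' The full validation pipeline: one tractography emulation defines the
#' structural graph; for each of `nInstances` seeds an fMRI instance is
#' simulated, source-separated, converted to masked regional activations
#' (modes matched one-to-one to the colour groups), and the joint flow LP
#' is solved. Per-edge corrections \eqn{P_l} and per-mode flows are
#' collected across instances.
#'
#' @param phantom a [PhantomSpec-class].
#' @param method tractography emulation method.
#' @param nInstances number of simulated fMRI instances (100 in the
#'   reference experiment).
#' @param recipe a [BoldRecipe-class].
#' @param config a [FlowConfig-class].
#' @param seed integer base seed; instance k uses `seed + k`.
#' @return an [EnhancementExperiment-class].
#' @export
runEnhancementExperiment <- function(phantom = buildPhantom(),
                                     method = "deterministic",
                                     nInstances = 100L,
                                     recipe = boldRecipe(),
                                     config = flowConfig(),
                                     seed = 1L) {
  tract <- emulateTractography(phantom, method, seed = seed)
  graph <- regionGraph(tract@counts, config = config)
  L <- nrow(graph@edges)
  nG <- max(phantom@groups)
  elab <- edgeNames(graph@edges, graph@nodeLabels)

  P <- matrix(0, nInstances, L, dimnames = list(NULL, elab))
  Fm <- array(0, c(L, nG, nInstances),
              dimnames = list(elab, phantom@groupColours, NULL))
  objs <- numeric(nInstances)
  mq <- matrix(NA_real_, nInstances, nG,
               dimnames = list(NULL, phantom@groupColours))

  for (k in seq_len(nInstances)) {
    res <- tryCatch(
      phantomInstanceSolve(phantom, graph, recipe, config, seed + k),
      error = function(e) stop(sprintf("instance %d failed: %s", k,
                                       conditionMessage(e))))
    sol <- res$solution
    if (sol@solverStatus != "optimal")
      stop(sprintf("instance %d: solver status %s", k, sol@solverStatus))
    P[k, ] <- as.numeric(sol@corrections)
    fm <- sol@flows
    Fm[, match(colnames(fm), phantom@groupColours), k] <- fm
    objs[k] <- sol@objectiveValue
    mq[k, ] <- res$matchQuality
  }
  new("EnhancementExperiment", graph = graph, phantom = phantom,
      method = method, corrections = P, flows = Fm, objectives = objs,
      matchQuality = mq, seed = as.integer(seed), config = config)
}

#' Summarize an enhancement experiment
#'
#' Per-edge mean and standard deviation of the capacity correction
#' \eqn{P_l} across instances, plus the mean per-mode flow.
#'
#' @param experiment an [EnhancementExperiment-class].
#' @return data.frame with columns `edge`, `meanP`, `sdP` and mean flow per
#'   colour group.
#' @export
enhancementSummary <- function(experiment) {
  P <- experiment@corrections
  out <- data.frame(edge = colnames(P), meanP = colMeans(P),
                    sdP = apply(P, 2, stats::sd), stringsAsFactors = FALSE)
  mf <- apply(experiment@flows, c(1, 2), mean)
  colnames(mf) <- paste0("meanFlow.", colnames(mf))
  cbind(out, as.data.frame(mf))
}

#' Node-set Jaccard overlap of mode circuits with colour groups
#'
#' For one experiment instance, extracts each mode's circuit and computes
#' the Jaccard index between its node set and the matched colour group's
#' node set.
#'
#' @param experiment an [EnhancementExperiment-class].
#' @param instance instance index.
#' @return named numeric of Jaccard indices per colour group.
#' @export
circuitJaccard <- function(experiment, instance = 1L) {
  phantom <- experiment@phantom
  g <- experiment@graph
  eps <- experiment@config@flowEpsilon
  f <- experiment@flows[, , instance]
  out <- numeric(ncol(f))
  names(out) <- colnames(f)
  for (m in seq_len(ncol(f))) {
    fm <- f[, m]
    keep <- fm > eps * max(fm, 0) & fm > experiment@config@solverTolerance
    nodes <- unique(as.integer(g@edges[keep, , drop = FALSE]))
    grp <- which(phantom@groups == m)
    out[m] <- length(intersect(nodes, grp)) / length(union(nodes, grp))
  }
  out
}
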