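#' @include AllGenerics.R
NULL

# canonical "A|B" edge labels
edgeNames <- function(edges, labels) {
  paste(labels[edges[, 1]], labels[edges[, 2]], sep = "|")
}

# all unordered pairs of 1..n in lexicographic order
allPairs <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
  cbind(i = i, j = j)
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Model configuration
#'
#' Collects the tunable parameters of the joint structural-functional flow
#' model. Defaults define the package's reference study conditions: automatic
#' \eqn{\gamma} (feasibility-guaranteeing), correction weight \eqn{\rho} =
#' 0.1 (mildly favoring recovery of under-estimated links), capacity floor
#' \eqn{\delta} = 0.05 on max-normalized streamline counts, and a scale-free
#' circuit threshold of 20\% of each mode's maximum flow.
#'
#' @param gamma positive number, or `"auto"` (default) to use the largest
#'   nodal activation-to-capacity ratio.
#' @param rho nonnegative correction weight \eqn{\rho}.
#' @param capacityFloor positive capacity floor \eqn{\delta}.
#' @param flowEpsilon circuit inclusion threshold as a fraction of the
#'   mode's maximum flow.
#' @param solverTolerance LP feasibility tolerance.
#' @param seed integer seed recorded in manifests.
#' @return a [FlowConfig-class] object.
#' @export
#' @examples
#' flowConfig(rho = 1)
flowConfig <- function(gamma = "auto", rho = 0.1, capacityFloor = 0.05,
                       flowEpsilon = 0.2, solverTolerance = 1e-8,
                       seed = 1L) {
  g <- if (identical(gamma, "auto")) NA_real_ else as.numeric(gamma)
  new("FlowConfig", gamma = g, rho = as.numeric(rho),
      capacityFloor = as.numeric(capacityFloor),
      flowEpsilon = as.numeric(flowEpsilon),
      solverTolerance = as.numeric(solverTolerance),
      seed = as.integer(seed))
}

#' Build a RegionGraph from a symmetric weight matrix
#'
#' Canonicalizes raw structural connectivity (streamline counts) into the
#' model's link capacities: weights are divided by the maximum off-diagonal
#' entry (max-normalization, bounding capacities in (0, 1]), the candidate
#' edge set is expanded to all unordered region pairs, and every capacity is
#' floored at `capacityFloor` so that fully missed connections keep a uniform
#' small prior and the unit delivery cost \eqn{1/D_l} stays finite.
#'
#' @param rawWeights square symmetric nonnegative matrix of streamline
#'   counts with zero diagonal.
#' @param labels optional region labels (defaults to the matrix dimnames).
#' @param config a [FlowConfig-class]; only `capacityFloor` is used.
#' @param symmetricTol tolerance for the symmetry check.
#' @return a [RegionGraph-class] with all \eqn{(N^2-N)/2} candidate edges.
#' @export
#' @examples
#' w <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
#' w["A", "B"] <- w["B", "A"] <- 50
#' w["A", "C"] <- w["C", "A"] <- 5
#' capacities(regionGraph(w))
regionGraph <- function(rawWeights, labels = NULL, config = flowConfig(),
                        symmetricTol = 1e-8) {
  w <- as.matrix(rawWeights)
  n <- nrow(w)
  if (n != ncol(w)) stop("weight matrix must be square")
  if (is.null(labels)) labels <- rownames(w)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  bad <- which(!is.finite(w) | w < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative or non-finite weight at (%s, %s)",
                 labels[bad[1, 1]], labels[bad[1, 2]]))
  asym <- abs(w - t(w))
  if (max(asym) > symmetricTol * max(1, max(abs(w)))) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetric weights at (%s, %s)",
                 labels[bad[1]], labels[bad[2]]))
  }
  diag(w) <- 0
  mx <- max(w)
  if (mx == 0) stop("all-zero weight matrix: no structural signal")
  w <- w / mx
  e <- allPairs(n)
  raw <- w[e]
  new("RegionGraph", nodeLabels = as.character(labels), edges = e,
      capacity = pmax(raw, config@capacityFloor), rawWeights = raw)
}

#' Low-level RegionGraph constructor from an explicit edge set
#'
#' Builds a graph from given edges and capacities without normalization or
#' flooring; intended for small worked examples and tests where the
#' candidate edge set is written down directly.
#'
#' @param labels character node labels.
#' @param edges two-column matrix of node index pairs.
#' @param capacity numeric capacities (one per edge, already > 0).
#' @return a [RegionGraph-class].
#' @export
regionGraphFromEdges <- function(labels, edges, capacity) {
  e <- as.matrix(edges)
  storage.mode(e) <- "integer"
  flip <- e[, 1] > e[, 2]
  e[flip, ] <- e[flip, 2:1]
  o <- order(e[, 1], e[, 2])
  new("RegionGraph", nodeLabels = as.character(labels), edges = e[o, , drop = FALSE],
      capacity = as.numeric(capacity)[o],
      rawWeights = as.numeric(capacity)[o])
}

#' Construct an ActivationMatrix
#'
#' @param values nonnegative numeric N x M matrix of per-region, per-mode
#'   activations \eqn{R_i^m}.
#' @param modeLabels optional mode labels (defaults to column names).
#' @param regionLabels optional region labels (defaults to row names).
#' @return an [ActivationMatrix-class].
#' @export
activationMatrix <- function(values, modeLabels = NULL, regionLabels = NULL) {
  v <- as.matrix(values)
  if (!is.null(modeLabels)) colnames(v) <- modeLabels
  if (is.null(colnames(v))) colnames(v) <- paste0("mode", seq_len(ncol(v)))
  if (!is.null(regionLabels)) rownames(v) <- regionLabels
  new("ActivationMatrix", values = v)
}

# per-node incident edge index list N(i)
incidentEdges <- function(graph) {
  n <- length(graph@nodeLabels)
  e <- graph@edges
  inc <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    inc[[e[k, 1]]] <- c(inc[[e[k, 1]]], k)
    inc[[e[k, 2]]] <- c(inc[[e[k, 2]]], k)
  }
  inc
}

#' Automatic unit-conversion parameter gamma
#'
#' Returns the largest ratio, over nodes, between total functional activation
#' and total incident structural capacity,
#' \deqn{\gamma = \max_i \frac{\sum_m R_i^m}{\sum_{l \in N(i)} D_l}.}
#' This is the smallest value that keeps the link-capacity constraints
#' compatible with the node demands on every node, guaranteeing feasibility
#' of the LP (with corrections unrestricted). Returns 0 when all activations
#' are zero.
#'
#' @param graph a [RegionGraph-class].
#' @param activation an [ActivationMatrix-class].
#' @return nonnegative scalar \eqn{\gamma}.
#' @export
computeGamma <- function(graph, activation) {
  R <- activation@values
  if (nrow(R) != length(graph@nodeLabels))
    stop("activation rows must match graph nodes")
  tot <- rowSums(R)
  if (all(tot == 0)) return(0)
  inc <- incidentEdges(graph)
  capSum <- vapply(inc, function(ix) sum(graph@capacity[ix]), numeric(1))
  if (any(tot > 0 & capSum <= 0))
    stop("node with positive activation but zero incident capacity")
  max(tot / capSum)
}

#' Assemble the joint structural-functional LP
#'
#' Builds the linear program
#' \deqn{\min_{f \ge 0, P \ge 0} \sum_l \frac{1}{D_l}\sum_m f_l^m +
#'       \rho \sum_l (1 + \frac{1}{D_l}) P_l}
#' subject to, for every link \eqn{l} and mode \eqn{m}: the link-capacity
#' constraint \eqn{\sum_m f_l^m \le \gamma (D_l + P_l)}, the node-demand
#' constraint \eqn{\sum_{l \in N(i)} f_l^m \ge R_i^m}, and the feasibility
#' constraint \eqn{f_l^m \le \max\{R_i^m, R_j^m\}} for \eqn{l = (i, j)}.
#' Flows are stored in activation-equivalent units (the fMRI-to-flow
#' conversion is absorbed into the flow variables).
#'
#' @param graph a [RegionGraph-class].
#' @param activation an [ActivationMatrix-class].
#' @param config a [FlowConfig-class]; `gamma = NA` resolves via
#'   [computeGamma()].
#' @return an [LPSpec-class] with \eqn{L(M+1)} variables and
#'   \eqn{L + NM + LM} inequality rows.
#' @export
assembleFlowLP <- function(graph, activation, config = flowConfig()) {
  R <- activation@values
  n <- length(graph@nodeLabels)
  if (nrow(R) != n) stop("activation rows must match graph nodes")
  if (any(!is.finite(R))) stop("NaN or Inf in activations")
  if (any(!is.finite(graph@capacity))) stop("NaN or Inf in capacities")
  L <- nrow(graph@edges)
  M <- ncol(R)
  gamma <- if (is.na(config@gamma)) computeGamma(graph, activation) else config@gamma
  if (gamma <= 0 && any(R > 0))
    stop("gamma must be positive when any activation is positive")

  D <- graph@capacity
  invD <- 1 / D
  nv <- L * M + L
  # variable order: f[l, m] edge-major within mode, then P[l]
  fIdx <- function(m) (m - 1L) * L + seq_len(L)
  pIdx <- L * M + seq_len(L)

  obj <- c(rep(invD, M), config@rho * (1 + invD))

  nr <- L + n * M + L * M
  A <- matrix(0, nr, nv)
  b <- numeric(nr)
  fam <- character(nr)

  # capacity rows: sum_m f_l^m - gamma P_l <= gamma D_l
  for (m in seq_len(M)) A[cbind(seq_len(L), fIdx(m))] <- 1
  A[cbind(seq_len(L), pIdx)] <- -gamma
  b[seq_len(L)] <- gamma * D
  fam[seq_len(L)] <- "capacity"

  # demand rows: -sum_{l in N(i)} f_l^m <= -R_i^m
  inc <- incidentEdges(graph)
  r0 <- L
  for (m in seq_len(M)) {
    for (i in seq_len(n)) {
      r <- r0 + (m - 1L) * n + i
      A[r, (m - 1L) * L + inc[[i]]] <- -1
      b[r] <- -R[i, m]
      fam[r] <- "demand"
    }
  }

  # feasibility rows: f_l^m <= max(R_i^m, R_j^m)
  r0 <- L + n * M
  upper <- pmax(R[graph@edges[, 1], , drop = FALSE],
                R[graph@edges[, 2], , drop = FALSE])  # L x M
  for (m in seq_len(M)) {
    rows <- r0 + (m - 1L) * L + seq_len(L)
    A[cbind(rows, fIdx(m))] <- 1
    b[rows] <- upper[, m]
    fam[rows] <- "feasibility"
  }

  new("LPSpec", objective = obj, constraints = A, rhs = b, rowFamily = fam,
      nEdges = as.integer(L), nModes = as.integer(M), gamma = gamma,
      modeLabels = colnames(R))
}

#' Solve the flow LP
#'
#' Solves the assembled LP with the package's deterministic dense two-phase
#' primal simplex. Because optimal flow patterns need not be unique (e.g.
#' under symmetric capacities), the objective value is the quantity to
#' compare across implementations. The all-zero activation problem is
#' short-circuited to the all-zero solution.
#'
#' @param lp an [LPSpec-class] (or a [RegionGraph-class], in which case
#'   `activation` must be supplied and the LP is assembled first).
#' @param activation an [ActivationMatrix-class] when `lp` is a graph.
#' @param config a [FlowConfig-class].
#' @param graph the graph used to assemble `lp` (needed to label edges when
#'   `lp` is an LPSpec built separately; optional).
#' @return a [FlowSolution-class].
#' @export
#' @examples
#' g <- regionGraphFromEdges(c("A", "B"), cbind(1, 2), 1)
#' R <- activationMatrix(matrix(c(1, 0.5), 2, 1), "m1", c("A", "B"))
#' sol <- solveFlow(g, R, flowConfig(gamma = 1, rho = 1))
#' objectiveValue(sol)  # 1
solveFlow <- function(lp, activation = NULL, config = flowConfig(),
                      graph = NULL) {
  if (is(lp, "RegionGraph")) {
    graph <- lp
    lp <- assembleFlowLP(graph, activation, config)
  }
  stopifnot(is(lp, "LPSpec"))
  L <- lp@nEdges
  M <- lp@nModes

  edgeLab <- if (!is.null(graph)) edgeNames(graph@edges, graph@nodeLabels)
             else paste0("e", seq_len(L))

  zeroSolution <- function(status) {
    f <- matrix(0, L, M, dimnames = list(edgeLab, lp@modeLabels))
    new("FlowSolution", flows = f, corrections = stats::setNames(numeric(L), edgeLab),
        objectiveValue = 0, solverStatus = status, maxResidual = 0,
        residuals = c(capacity = 0, demand = 0, feasibility = 0),
        gamma = lp@gamma, config = config)
  }

  if (lp@gamma == 0) return(zeroSolution("optimal"))

  res <- .lp_simplex(lp@objective, lp@constraints, lp@rhs,
                     tol = 1e-9, maxit = 0L)
  if (res$status == 1L) {
    viol <- lp@constraints %*% rep(0, ncol(lp@constraints)) - lp@rhs
    worst <- which(lp@rowFamily == "demand")[
      which.max(viol[lp@rowFamily == "demand"])]
    sol <- zeroSolution("infeasible")
    attr(sol, "diagnostic") <- sprintf(
      "LP infeasible; most violated node demand row %d (unmet demand %.6g)",
      worst, viol[worst])
    return(sol)
  }
  if (res$status != 0L) {
    sol <- zeroSolution("error")
    attr(sol, "diagnostic") <- sprintf("solver failure (code %d)", res$status)
    return(sol)
  }

  x <- res$x
  f <- matrix(x[seq_len(L * M)], L, M,
              dimnames = list(edgeLab, lp@modeLabels))
  P <- stats::setNames(x[L * M + seq_len(L)], edgeLab)
  resid <- lpResiduals(lp, x)
  new("FlowSolution", flows = f, corrections = P,
      objectiveValue = res$objective, solverStatus = "optimal",
      maxResidual = max(resid), residuals = resid,
      gamma = lp@gamma, config = config)
}

lpResiduals <- function(lp, x) {
  viol <- as.numeric(lp@constraints %*% x - lp@rhs)
  viol <- pmax(viol, 0)
  viol <- c(viol, pmax(-x, 0))  # nonnegativity
  famAll <- c(lp@rowFamily, rep("nonnegativity", length(x)))
  out <- vapply(c("capacity", "demand", "feasibility"),
                function(f) if (any(famAll == f)) max(viol[famAll == f]) else 0,
                numeric(1))
  out
}

#' Validate a flow solution against the model constraints
#'
#' Recomputes the per-family maximum violation of the link-capacity,
#' node-demand and feasibility constraints for a solved problem and asserts
#' all are within the solver tolerance.
#'
#' @param graph a [RegionGraph-class].
#' @param activation an [ActivationMatrix-class].
#' @param config a [FlowConfig-class].
#' @param solution a [FlowSolution-class] with status "optimal".
#' @return named numeric of per-family maximum violations (invisibly raises
#'   an error when any exceeds `solverTolerance`).
#' @export
validateSolution <- function(graph, activation, config, solution) {
  if (solution@solverStatus != "optimal")
    stop("can only validate an optimal solution")
  lp <- assembleFlowLP(graph, activation,
                       flowConfig(gamma = solution@gamma, rho = config@rho,
                                  capacityFloor = config@capacityFloor,
                                  flowEpsilon = config@flowEpsilon,
                                  solverTolerance = config@solverTolerance,
                                  seed = config@seed))
  x <- c(as.numeric(solution@flows), as.numeric(solution@corrections))
  resid <- lpResiduals(lp, x)
  bad <- resid > config@solverTolerance
  if (any(bad))
    stop(sprintf("constraint family '%s' violated by %.3g (tolerance %.3g)",
                 names(resid)[bad][1], resid[bad][1], config@solverTolerance))
  resid
}

#' Extract the function-specific circuit for one mode
#'
#' The circuit is the sub-network of edges whose optimal flow for the mode
#' exceeds the inclusion threshold, taken as `flowEpsilon` times the mode's
#' maximum flow (a scale-free cut, since flows inherit the data-dependent
#' activation scale).
#'
#' @param solution an optimal [FlowSolution-class].
#' @param graph the [RegionGraph-class] the solution was computed on.
#' @param mode mode label or index.
#' @param config a [FlowConfig-class]; `flowEpsilon` sets the threshold.
#' @return a [CircuitNetwork-class].
#' @export
extractCircuit <- function(solution, graph, mode, config = solution@config) {
  if (solution@solverStatus != "optimal")
    stop("circuits require an optimal solution")
  f <- solution@flows
  if (is.character(mode)) {
    if (!mode %in% colnames(f)) stop("unknown mode label: ", mode)
    m <- match(mode, colnames(f))
  } else m <- as.integer(mode)
  if (is.na(m) || m < 1 || m > ncol(f)) stop("unknown mode: ", mode)
  fm <- f[, m]
  thr <- config@flowEpsilon * max(fm, 0)
  keep <- which(fm > thr & fm > config@solverTolerance)
  e <- graph@edges[keep, , drop = FALSE]
  new("CircuitNetwork", mode = colnames(f)[m], edges = e,
      weights = unname(fm[keep]),
      nodes = sort(unique(as.integer(e))),
      nodeLabels = graph@nodeLabels)
}

#' Enhanced structural capacities
#'
#' Adds the optimal capacity corrections to the input capacities,
#' \eqn{D_l + P_l}: the model's improved estimate of structural
#' connectivity, recovering links under-estimated by tractography.
#'
#' @param graph a [RegionGraph-class].
#' @param solution an optimal [FlowSolution-class] computed on `graph`.
#' @return named numeric vector of \eqn{D_l + P_l} per edge.
#' @export
enhancedCapacities <- function(graph, solution) {
  if (solution@solverStatus != "optimal")
    stop("enhanced capacities require an optimal solution")
  out <- graph@capacity + as.numeric(solution@corrections)
  names(out) <- edgeNames(graph@edges, graph@nodeLabels)
  out
}

#' Drop all-zero activation modes
#'
#' Degenerate modes (all-zero activation, e.g. after active/inactive
#' masking) are removed with a warning rather than kept as trivial columns.
#'
#' @param activation an [ActivationMatrix-class].
#' @return an [ActivationMatrix-class] without all-zero columns.
#' @export
dropDegenerateModes <- function(activation) {
  v <- activation@values
  keep <- colSums(v) > 0
  if (!all(keep)) {
    warning("dropping degenerate (all-zero) mode(s): ",
            paste(colnames(v)[!keep], collapse = ", "))
    v <- v[, keep, drop = FALSE]
  }
  new("ActivationMatrix", values = v)
}
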