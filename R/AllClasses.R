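#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' RegionGraph: a floored, normalized structural connectome
#'
#' Nodes are gray-matter regions; candidate edges are all unordered region
#' pairs. Each edge carries a capacity \eqn{D_l}, the max-normalized
#' streamline count floored at a small positive value so that the unit
#' delivery cost \eqn{1/D_l} stays finite and fully missed connections keep a
#' uniform small prior probability of existence.
#'
#' @slot nodeLabels character vector of region identifiers (length N).
#' @slot edges integer matrix (L x 2) of node index pairs, i < j, in
#'   canonical lexicographic order.
#' @slot capacity numeric vector of edge capacities \eqn{D_l > 0}
#'   (dimensionless normalized streamline counts).
#' @slot rawWeights numeric vector of the pre-floor normalized weights
#'   (kept for reporting; zero where tractography found nothing).
#'
#' @exportClass RegionGraph
setClass("RegionGraph",
  representation(nodeLabels = "character", edges = "matrix",
                 capacity = "numeric", rawWeights = "numeric"))

setValidity("RegionGraph", function(object) {
  e <- object@edges
  msg <- character()
  if (!is.numeric(e) || ncol(e) != 2) msg <- c(msg, "edges must be an L x 2 matrix")
  else {
    if (any(e[, 1] >= e[, 2])) msg <- c(msg, "edges must satisfy i < j (no self-loops)")
    key <- paste(e[, 1], e[, 2])
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
    n <- length(object@nodeLabels)
    if (nrow(e) > n * (n - 1) / 2) msg <- c(msg, "more edges than unordered pairs")
    if (any(e < 1) || any(e > n)) msg <- c(msg, "edge endpoint out of range")
  }
  if (length(object@capacity) != nrow(e)) msg <- c(msg, "capacity length != edge count")
  if (any(!is.finite(object@capacity)) || any(object@capacity <= 0))
    msg <- c(msg, "all capacities must be finite and > 0 after flooring")
  if (length(msg)) msg else TRUE
})

#' ActivationMatrix: nonnegative per-region, per-mode functional activation
#'
#' Rows are regions (matching a [RegionGraph]), columns are functional modes
#' (task contrasts or ICA resting-state components). Entries are the
#' dimensionless average activation \eqn{R_i^m \ge 0}.
#'
#' @slot values numeric N x M matrix with region row names and mode column
#'   names.
#'
#' @exportClass ActivationMatrix
setClass("ActivationMatrix", representation(values = "matrix"))

setValidity("ActivationMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (any(!is.finite(v))) msg <- c(msg, "non-finite activation values")
  else if (any(v < 0)) msg <- c(msg, "negative activation values")
  if (is.null(colnames(v))) msg <- c(msg, "mode labels (column names) required")
  if (length(msg)) msg else TRUE
})

#' FlowConfig: tunable parameters of the flow model
#'
#' @slot gamma unit conversion between capacity and activation-equivalent
#'   flow; `NA` means "auto" (largest nodal activation-to-capacity ratio,
#'   which guarantees feasibility).
#' @slot rho penalty weight trading flow routing cost against capacity
#'   corrections \eqn{P_l}; larger values restrict corrections.
#' @slot capacityFloor floor \eqn{\delta > 0} applied to normalized
#'   capacities.
#' @slot flowEpsilon circuit inclusion threshold, as a fraction of the
#'   mode's maximum flow (scale-free).
#' @slot solverTolerance feasibility tolerance for the LP solver.
#' @slot seed integer seed recorded in run manifests.
#'
#' @exportClass FlowConfig
setClass("FlowConfig",
  representation(gamma = "numeric", rho = "numeric", capacityFloor = "numeric",
                 flowEpsilon = "numeric", solverTolerance = "numeric",
                 seed = "integer"))

setValidity("FlowConfig", function(object) {
  msg <- character()
  if (object@rho < 0) msg <- c(msg, "rho must be >= 0")
  if (object@capacityFloor <= 0) msg <- c(msg, "capacityFloor must be > 0")
  if (object@flowEpsilon < 0) msg <- c(msg, "flowEpsilon must be >= 0")
  if (object@solverTolerance <= 0) msg <- c(msg, "solverTolerance must be > 0")
  if (!is.na(object@gamma) && object@gamma < 0) msg <- c(msg, "gamma must be >= 0 or NA (auto)")
  if (length(msg)) msg else TRUE
})

#' LPSpec: assembled linear program for the joint flow model
#'
#' Variables are ordered `f[l,m]` (edge-major within mode, mode-major
#' overall) followed by `P[l]`. Inequality rows encode the link-capacity,
#' node-demand (negated to <=) and feasibility constraints.
#'
#' @slot objective numeric cost vector (length L*M + L).
#' @slot constraints dense numeric constraint matrix.
#' @slot rhs numeric right-hand side.
#' @slot rowFamily character: "capacity", "demand" or "feasibility" per row.
#' @slot nEdges,nModes integer problem dimensions.
#' @slot gamma numeric resolved unit-conversion parameter.
#' @slot modeLabels character mode labels.
#'
#' @exportClass LPSpec
setClass("LPSpec",
  representation(objective = "numeric", constraints = "matrix", rhs = "numeric",
                 rowFamily = "character", nEdges = "integer", nModes = "integer",
                 gamma = "numeric", modeLabels = "character"))

setValidity("LPSpec", function(object) {
  L <- object@nEdges; M <- object@nModes
  msg <- character()
  if (ncol(object@constraints) != L * M + L) msg <- c(msg, "wrong variable count")
  if (length(object@rhs) != nrow(object@constraints)) msg <- c(msg, "rhs length mismatch")
  if (length(object@objective) != L * M + L) msg <- c(msg, "objective length mismatch")
  if (any(!is.finite(object@objective)) || any(!is.finite(object@constraints)))
    msg <- c(msg, "non-finite LP coefficients")
  if (length(msg)) msg else TRUE
})

#' FlowSolution: optimal flows and capacity corrections
#'
#' @slot flows numeric L x M matrix of optimal information flows
#'   \eqn{f_l^m \ge 0} in activation-equivalent units.
#' @slot corrections numeric vector of capacity corrections \eqn{P_l \ge 0}
#'   (capacity units).
#' @slot objectiveValue numeric optimal cost.
#' @slot solverStatus character: "optimal", "infeasible" or "error".
#' @slot maxResidual numeric largest constraint violation of the returned
#'   solution.
#' @slot residuals numeric per-family maximum violations.
#' @slot gamma numeric gamma used.
#' @slot config the [FlowConfig-class] used.
#'
#' @exportClass FlowSolution
setClass("FlowSolution",
  representation(flows = "matrix", corrections = "numeric",
                 objectiveValue = "numeric", solverStatus = "character",
                 maxResidual = "numeric", residuals = "numeric",
                 gamma = "numeric", config = "FlowConfig"))

setValidity("FlowSolution", function(object) {
  msg <- character()
  tol <- object@config@solverTolerance
  if (object@solverStatus == "optimal") {
    if (any(object@flows < -tol)) msg <- c(msg, "negative flow beyond tolerance")
    if (any(object@corrections < -tol)) msg <- c(msg, "negative correction beyond tolerance")
  }
  if (length(msg)) msg else TRUE
})

#' CircuitNetwork: the anatomical sub-network serving one functional mode
#'
#' @slot mode character mode label.
#' @slot edges integer matrix (k x 2) of node index pairs (subset of the
#'   graph's edges).
#' @slot weights numeric flow weights, all above the inclusion threshold.
#' @slot nodes integer indices of nodes touched by the edges.
#' @slot nodeLabels character labels of the parent graph.
#'
#' @exportClass CircuitNetwork
setClass("CircuitNetwork",
  representation(mode = "character", edges = "matrix", weights = "numeric",
                 nodes = "integer", nodeLabels = "character"))

#' PhantomSpec: ground truth for the synthetic Fibercup-like phantom
#'
#' Sixteen end-point regions P1..P16, nine ground-truth region-pair
#' connections grouped into seven fiber bundles, and five functional
#' sub-networks (colour groups) whose members share a BOLD time course.
#'
#' @slot nodes character region labels P1..P16.
#' @slot edges integer 9 x 2 matrix of ground-truth connections.
#' @slot bundleIds integer bundle id (1..7) per ground-truth edge.
#' @slot groups integer group id (1..5) per node.
#' @slot groupColours character colour name per group.
#'
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(nodes = "character", edges = "matrix", bundleIds = "integer",
                 groups = "integer", groupColours = "character"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@nodes) != 16) msg <- c(msg, "phantom must have 16 nodes")
  if (length(unique(object@bundleIds)) != 7) msg <- c(msg, "phantom must have 7 bundles")
  if (length(unique(object@groups)) != 5) msg <- c(msg, "phantom must have 5 colour groups")
  g <- object@groups
  e <- object@edges
  if (nrow(e) && any(g[e[, 1]] != g[e[, 2]]))
    msg <- c(msg, "every ground-truth edge must lie within one colour group")
  if (length(msg)) msg else TRUE
})

#' BoldRecipe: SimTB-style BOLD simulation parameters
#'
#' @slot nOnBlocks,nOffBlocks,blockLen block-design shape: 20 ON and 20 OFF
#'   blocks of 30 TRs each (1200 time points).
#' @slot eventProb probability of a unique unit event per TR (0.2).
#' @slot eventAmp amplitude of a unit event relative to the task block.
#' @slot tr repetition time in seconds.
#' @slot ampScaleRange per-region uniform amplitude scaling range.
#' @slot ricianSigma Rician noise sigma; `NA` derives it from `targetSnr`.
#' @slot targetSnr target SNR relative to the mean clean signal magnitude.
#'
#' @exportClass BoldRecipe
setClass("BoldRecipe",
  representation(nOnBlocks = "integer", nOffBlocks = "integer",
                 blockLen = "integer", eventProb = "numeric",
                 eventAmp = "numeric", tr = "numeric",
                 ampScaleRange = "numeric", ricianSigma = "numeric",
                 targetSnr = "numeric"))

setValidity("BoldRecipe", function(object) {
  msg <- character()
  if (object@eventProb < 0 || object@eventProb > 1)
    msg <- c(msg, "eventProb must be in [0, 1]")
  if (object@tr <= 0) msg <- c(msg, "tr must be > 0")
  if (length(object@ampScaleRange) != 2 ||
      object@ampScaleRange[1] > object@ampScaleRange[2])
    msg <- c(msg, "ampScaleRange must be (lo, hi)")
  if (length(msg)) msg else TRUE
})

#' TractogramEmulation: streamline-count matrix with declared error pattern
#'
#' @slot method "deterministic" or "probabilistic".
#' @slot counts numeric 16 x 16 symmetric streamline-count matrix.
#' @slot falseNegatives integer matrix of fully missed true edges.
#' @slot underEstimated integer matrix of under-estimated true edges.
#' @slot falsePositives integer matrix of spurious edges.
#'
#' @exportClass TractogramEmulation
setClass("TractogramEmulation",
  representation(method = "character", counts = "matrix",
                 falseNegatives = "matrix", underEstimated = "matrix",
                 falsePositives = "matrix"))

setValidity("TractogramEmulation", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "negative streamline counts")
  if (!isSymmetric(unname(object@counts))) msg <- c(msg, "counts must be symmetric")
  if (length(msg)) msg else TRUE
})

#' GmmModel: six-component joint Gaussian mixture over link features
#'
#' Components model per-link (structural value, functional correlation)
#' pairs; category semantics are the product of anatomical state
#' (connected / not connected) and functional sign (positive / negative /
#' uncorrelated).
#'
#' @slot weights numeric mixing weights (sum 1).
#' @slot means numeric K x 2 component means.
#' @slot covariances numeric 2 x 2 x K positive-definite covariances.
#' @slot logLik numeric log-likelihood trace (non-decreasing under EM).
#' @slot converged logical.
#' @slot categories data.frame mapping component -> connected / sign labels.
#'
#' @exportClass GmmModel
setClass("GmmModel",
  representation(weights = "numeric", means = "matrix",
                 covariances = "array", logLik = "numeric",
                 converged = "logical", categories = "data.frame"))

setValidity("GmmModel", function(object) {
  msg <- character()
  if (abs(sum(object@weights) - 1) > 1e-10) msg <- c(msg, "weights must sum to 1")
  if (any(object@weights < 0)) msg <- c(msg, "negative weight")
  for (k in seq_along(object@weights)) {
    ev <- eigen(object@covariances[, , k], symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) { msg <- c(msg, "covariance not positive definite"); break }
  }
  if (length(msg)) msg else TRUE
})

#' EnhancementExperiment: aggregated phantom enhancement results
#'
#' @slot graph the [RegionGraph-class] built from the tractography emulation.
#' @slot phantom the [PhantomSpec-class] ground truth.
#' @slot method tractography emulation method.
#' @slot corrections numeric nInstances x L matrix of per-instance \eqn{P_l}.
#' @slot flows numeric L x 5 x nInstances array of per-instance flows with
#'   modes matched to colour groups.
#' @slot objectives numeric per-instance LP objective values.
#' @slot matchQuality numeric nInstances x 5 matrix of |spatial r| between
#'   matched ICA maps and group reference maps.
#' @slot seed integer base seed.
#' @slot config the [FlowConfig-class] used.
#'
#' @exportClass EnhancementExperiment
setClass("EnhancementExperiment",
  representation(graph = "RegionGraph", phantom = "PhantomSpec",
                 method = "character", corrections = "matrix",
                 flows = "array", objectives = "numeric",
                 matchQuality = "matrix", seed = "integer",
                 config = "FlowConfig"))
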