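#' @include AllClasses.R
NULL

#' Accessors for flowcircuit classes
#'
#' Small accessor generics for the core S4 classes: node labels, edge tables,
#' capacities, flows, corrections and objective values.
#'
#' @param object a flowcircuit S4 object.
#' @return The requested component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("capacities", function(object) standardGeneric("capacities"))

#' @rdname accessors
#' @export
setGeneric("modeLabels", function(object) standardGeneric("modeLabels"))

#' @rdname accessors
#' @export
setGeneric("activationValues", function(object) standardGeneric("activationValues"))

#' @rdname accessors
#' @export
setGeneric("flows", function(object) standardGeneric("flows"))

#' @rdname accessors
#' @export
setGeneric("corrections", function(object) standardGeneric("corrections"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname accessors
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))

#' @rdname accessors
#' @export
setGeneric("groundTruthEdges", function(object) standardGeneric("groundTruthEdges"))

#' @rdname accessors
#' @export
setGeneric("colourGroups", function(object) standardGeneric("colourGroups"))

setMethod("nodeLabels", "RegionGraph", function(object) object@nodeLabels)
setMethod("nodeLabels", "PhantomSpec", function(object) object@nodes)
setMethod("nodeLabels", "CircuitNetwork", function(object) object@nodeLabels)

setMethod("capacities", "RegionGraph", function(object) {
  stats::setNames(object@capacity, edgeNames(object@edges, object@nodeLabels))
})

setMethod("edgeTable", "RegionGraph", function(object) {
  data.frame(from = object@nodeLabels[object@edges[, 1]],
             to = object@nodeLabels[object@edges[, 2]],
             capacity = object@capacity,
             rawWeight = object@rawWeights,
             stringsAsFactors = FALSE)
})

setMethod("edgeTable", "CircuitNetwork", function(object) {
  data.frame(from = object@nodeLabels[object@edges[, 1]],
             to = object@nodeLabels[object@edges[, 2]],
             flow = object@weights, stringsAsFactors = FALSE)
})

setMethod("modeLabels", "ActivationMatrix", function(object) colnames(object@values))
setMethod("modeLabels", "FlowSolution", function(object) colnames(object@flows))
setMethod("activationValues", "ActivationMatrix", function(object) object@values)

setMethod("flows", "FlowSolution", function(object) object@flows)
setMethod("corrections", "FlowSolution", function(object) object@corrections)
setMethod("objectiveValue", "FlowSolution", function(object) object@objectiveValue)
setMethod("solverStatus", "FlowSolution", function(object) object@solverStatus)

setMethod("groundTruthEdges", "PhantomSpec", function(object) {
  data.frame(from = object@nodes[object@edges[, 1]],
             to = object@nodes[object@edges[, 2]],
             bundle = object@bundleIds, stringsAsFactors = FALSE)
})

setMethod("colourGroups", "PhantomSpec", function(object) {
  stats::setNames(object@groups, object@nodes)
})

setMethod("show", "RegionGraph", function(object) {
  cat("RegionGraph:", length(object@nodeLabels), "regions,",
      nrow(object@edges), "candidate edges\n")
  cat("  capacity range:", format(range(object@capacity), digits = 4), "\n")
  cat("  edges above floor:", sum(object@rawWeights > 0), "\n")
})

setMethod("show", "ActivationMatrix", function(object) {
  cat("ActivationMatrix:", nrow(object@values), "regions x",
      ncol(object@values), "modes\n")
  cat("  modes:", paste(colnames(object@values), collapse = ", "), "\n")
})

setMethod("show", "FlowSolution", function(object) {
  cat("FlowSolution (", object@solverStatus, ")\n", sep = "")
  cat("  objective:", format(object@objectiveValue, digits = 8), "\n")
  cat("  gamma:", format(object@gamma, digits = 6),
      " rho:", format(object@config@rho, digits = 6), "\n")
  cat("  total correction sum(P):",
      format(sum(object@corrections), digits = 6), "\n")
  cat("  max constraint residual:", format(object@maxResidual, digits = 4), "\n")
})

setMethod("show", "CircuitNetwork", function(object) {
  cat("CircuitNetwork for mode", object@mode, ":",
      nrow(object@edges), "edges,", length(object@nodes), "nodes\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", length(object@nodes), "regions,",
      nrow(object@edges), "ground-truth connections in",
      length(unique(object@bundleIds)), "bundles,",
      length(unique(object@groups)), "functional sub-networks\n")
})

setMethod("show", "GmmModel", function(object) {
  cat("GmmModel:", length(object@weights), "bivariate components,",
      "logLik", format(utils::tail(object@logLik, 1), digits = 8),
      if (object@converged) "(converged)" else "(max iterations)", "\n")
})

setMethod("show", "EnhancementExperiment", function(object) {
  cat("EnhancementExperiment:", nrow(object@corrections), "instances,",
      object@method, "tractography\n")
  mp <- colMeans(object@corrections)
  cat("  links with mean correction > 0:", sum(mp > 1e-8), "\n")
})
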