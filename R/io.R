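#' @include gmm.R
NULL

inferSep <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Read a labeled square adjacency matrix (CSV/TSV)
#'
#' Expects a header row and a first column of region labels; row and column
#' labels must match. Ragged rows, duplicate labels and non-numeric cells
#' are rejected with the offending line number.
#'
#' @param path file path (.csv or .tsv).
#' @return numeric square matrix with dimnames.
#' @export
readAdjacency <- function(path) {
  sep <- inferSep(path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("adjacency file has no data rows")
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(cells[[1]])[-1]
  n <- length(header)
  if (anyDuplicated(header))
    stop("duplicate region label: ", header[duplicated(header)][1])
  if (length(cells) - 1 != n)
    stop(sprintf("expected %d data rows, found %d", n, length(cells) - 1))
  out <- matrix(NA_real_, n, n, dimnames = list(character(n), header))
  for (i in seq_len(n)) {
    row <- trimws(cells[[i + 1]])
    if (length(row) != n + 1)
      stop(sprintf("ragged row at line %d (%d cells, expected %d)",
                   i + 1, length(row), n + 1))
    vals <- suppressWarnings(as.numeric(row[-1]))
    if (any(is.na(vals)))
      stop(sprintf("non-numeric cell at line %d", i + 1))
    rownames(out)[i] <- row[1]
    out[i, ] <- vals
  }
  if (!identical(rownames(out), colnames(out)))
    stop("row labels do not match column labels")
  out
}

#' Write a labeled square matrix (CSV/TSV)
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path; extension selects the delimiter.
#' @export
writeAdjacency <- function(mat, path) {
  sep <- inferSep(path)
  lab <- rownames(mat)
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  lines <- c(paste(c("", lab), collapse = sep),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(lab[i], fmt(mat[i, ])), collapse = sep), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 3-column edge list into a dense symmetric matrix
#'
#' Columns: node_i, node_j, count. Nodes default to those appearing in the
#' file (sorted); pass `nodes` to fix the ordering and include isolated
#' regions.
#'
#' @param path TSV/CSV path.
#' @param nodes optional character vector of node labels.
#' @return numeric square matrix (zeros where no edge was listed).
#' @export
readEdgeList <- function(path, nodes = NULL) {
  df <- utils::read.table(path, sep = inferSep(path), header = FALSE,
                          col.names = c("from", "to", "count"),
                          stringsAsFactors = FALSE)
  if (!is.numeric(df$count)) stop("third column must be numeric")
  if (is.null(nodes)) nodes <- sort(unique(c(df$from, df$to)))
  n <- length(nodes)
  out <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(df))) {
    i <- match(df$from[r], nodes); j <- match(df$to[r], nodes)
    if (is.na(i) || is.na(j)) stop("edge references unknown node at row ", r)
    out[i, j] <- out[j, i] <- df$count[r]
  }
  out
}

#' Read / write an activation table (regions x modes CSV)
#'
#' @param path CSV path with a header of mode labels and a first column of
#'   region labels.
#' @return an [ActivationMatrix-class].
#' @export
readActivation <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  activationMatrix(as.matrix(df))
}

#' @rdname readActivation
#' @param activation an [ActivationMatrix-class] to write.
#' @export
writeActivation <- function(activation, path) {
  utils::write.csv(as.data.frame(activation@values), path)
  invisible(path)
}

#' Export a circuit or graph to GraphML
#'
#' Writes node labels and an edge `weight` attribute; empty circuits yield
#' a valid nodes-only graph. The file re-imports with [igraph::read_graph()].
#'
#' @param network a [CircuitNetwork-class] or [RegionGraph-class].
#' @param path output .graphml path.
#' @export
exportGraphML <- function(network, path) {
  if (is(network, "CircuitNetwork")) {
    labels <- network@nodeLabels
    e <- network@edges
    w <- network@weights
  } else if (is(network, "RegionGraph")) {
    labels <- network@nodeLabels
    e <- network@edges
    w <- network@capacity
  } else stop("unsupported network type")
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labels)
  if (nrow(e)) {
    g <- igraph::add_edges(g, t(e))
    g <- igraph::set_edge_attr(g, "weight", value = w)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a flow solution as tidy TSVs plus a JSON manifest
#'
#' Emits `flows.tsv` (edge, mode, flow), `corrections.tsv` (edge,
#' correction, capacity, enhanced) and `manifest.json` (gamma, rho, floor,
#' solver, tolerance, seed, objective) with deterministic row order.
#'
#' @param solution an optimal [FlowSolution-class].
#' @param graph the [RegionGraph-class] solved on.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSolution <- function(solution, graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  f <- solution@flows
  flowsDf <- data.frame(
    edge = rep(rownames(f), times = ncol(f)),
    mode = rep(colnames(f), each = nrow(f)),
    flow = fmt(as.numeric(f)), stringsAsFactors = FALSE)
  utils::write.table(flowsDf, file.path(dir, "flows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  corrDf <- data.frame(edge = names(solution@corrections),
                       correction = fmt(as.numeric(solution@corrections)),
                       capacity = fmt(graph@capacity),
                       enhanced = fmt(graph@capacity +
                                        as.numeric(solution@corrections)),
                       stringsAsFactors = FALSE)
  utils::write.table(corrDf, file.path(dir, "corrections.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "flowcircuit",
    version = as.character(utils::packageVersion("flowcircuit")),
    gamma = solution@gamma, rho = solution@config@rho,
    capacityFloor = solution@config@capacityFloor,
    flowEpsilon = solution@config@flowEpsilon,
    solver = "two-phase dense primal simplex",
    solverTolerance = solution@config@solverTolerance,
    seed = solution@config@seed,
    objective = solution@objectiveValue,
    status = solution@solverStatus,
    maxResidual = solution@maxResidual)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write the phantom specification as JSON
#'
#' @param phantom a [PhantomSpec-class].
#' @param path output .json path.
#' @export
writePhantomJson <- function(phantom, path) {
  obj <- list(nodes = phantom@nodes,
              edges = groundTruthEdges(phantom),
              groups = as.list(stats::setNames(phantom@groups, phantom@nodes)),
              groupColours = phantom@groupColours)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
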