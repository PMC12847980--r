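#' MolecularGraph: a hydrogen-suppressed molecular graph
#'
#' Simple undirected graph whose vertices are heavy (non-hydrogen) atoms and
#' whose edges are bonds. All bonds, whatever their order, count as a single
#' edge. Validity requires a simple graph (no self-loops, no duplicate
#' edges), minimum degree one, and connectivity (a single molecule).
#'
#' Element labels are annotation only; no index computation ever reads them.
#'
#' @slot vertices character vector of distinct vertex identifiers.
#' @slot edges two-column character matrix, one bond per row.
#' @slot elements named character vector mapping vertex ids to atomic
#'   symbols; may be empty.
#' @seealso [buildGraph()], [vertexDegrees()], [edgeDegreePartition()]
#' @export
setClass("MolecularGraph",
         representation(vertices = "character",
                        edges = "matrix",
                        elements = "character"),
         prototype(vertices = character(),
                   edges = matrix(character(), 0, 2),
                   elements = character()))

setValidity("MolecularGraph", function(object) {
  msg <- character()
  e <- object@edges
  v <- object@vertices
  if (!is.character(e) || ncol(e) != 2L)
    return("'edges' must be a two-column character matrix")
  if (nrow(e) == 0L)
    msg <- c(msg, "graph has no edges; molecules have at least one bond")
  if (anyDuplicated(v))
    msg <- c(msg, "duplicate vertex identifiers")
  if (any(e[, 1L] == e[, 2L]))
    msg <- c(msg, "self-loop found; molecular graphs are simple")
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]), sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate edge found; molecular graphs are simple")
  if (!all(e %in% v))
    msg <- c(msg, "edge endpoint not in vertex set")
  if (!all(v %in% e))
    msg <- c(msg, "isolated vertex found; every heavy atom must be bonded")
  if (length(object@elements) &&
      !all(names(object@elements) %in% v))
    msg <- c(msg, "element label for unknown vertex")
  if (length(msg) == 0L && nrow(e) > 0L) {
    ig <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::components(ig)$no > 1L)
      msg <- c(msg, "graph is disconnected; expected a single molecule")
  }
  if (length(msg)) msg else TRUE
})

#' DegreePartition: edge tallies by unordered endpoint-degree pair
#'
#' The multiset of unordered degree pairs \eqn{\{d_u, d_v\}} over the edges
#' of a molecular graph, stored as canonical pairs \eqn{(a, b)} with
#' \eqn{1 \le a \le b} and positive integer counts. Every degree-based,
#' edge-additive topological index is a linear functional of this object, so
#' partitions may also be supplied directly without a realizing graph.
#'
#' @slot pairs two-column integer matrix of distinct degree pairs, rows
#'   ordered lexicographically, each row with `pairs[,1] <= pairs[,2]`.
#' @slot counts positive integer vector of edge counts, parallel to `pairs`.
#' @seealso [partitionFromCounts()], [edgeDegreePartition()],
#'   [computeIndex()]
#' @export
setClass("DegreePartition",
         representation(pairs = "matrix", counts = "integer"),
         prototype(pairs = matrix(integer(), 0, 2), counts = integer()))

setValidity("DegreePartition", function(object) {
  p <- object@pairs
  n <- object@counts
  msg <- character()
  if (!is.numeric(p) || ncol(p) != 2L)
    return("'pairs' must be a two-column integer matrix")
  if (nrow(p) != length(n))
    return("'pairs' and 'counts' lengths differ")
  if (nrow(p) == 0L)
    msg <- c(msg, "empty partition: no edges")
  if (any(p < 1L))
    msg <- c(msg, "degrees must be >= 1")
  if (any(p[, 1L] > p[, 2L]))
    msg <- c(msg, "pairs must satisfy a <= b")
  if (anyDuplicated(paste(p[, 1L], p[, 2L])))
    msg <- c(msg, "duplicate degree pair")
  if (any(n < 1L))
    msg <- c(msg, "counts must be positive integers")
  if (length(msg)) msg else TRUE
})

#' RegressionFit: one single-predictor least-squares fit
#'
#' Holds the coefficients and summary statistics of an ordinary
#' least-squares fit of a property on one topological index under one of
#' three model forms:
#' \describe{
#'   \item{linear}{\eqn{P = \alpha + \beta T}}
#'   \item{quadratic}{\eqn{P = \alpha + \beta T + \gamma T^2}}
#'   \item{logarithmic}{\eqn{P = \alpha + \beta \ln T}}
#' }
#'
#' @slot form `"linear"`, `"quadratic"` or `"logarithmic"`.
#' @slot alpha intercept.
#' @slot beta first-order coefficient.
#' @slot gamma second-order coefficient; `NA` unless quadratic.
#' @slot n number of observations.
#' @slot R correlation coefficient: signed for the single-slope forms, the
#'   positive root of \eqn{R^2} for the quadratic form.
#' @slot R2 coefficient of determination.
#' @slot Fstat overall F statistic (`Inf` for a perfect fit).
#' @slot pValue p-value of the F statistic.
#' @slot residSE residual standard error \eqn{\sqrt{SSE/(n-k-1)}}.
#' @slot residuals raw residuals.
#' @slot xName,yName names of predictor and response, used when rendering
#'   the fitted equation.
#' @seealso [fitModel()], [standardizedResiduals()], [renderFitEquation()]
#' @export
setClass("RegressionFit",
         representation(form = "character", alpha = "numeric",
                        beta = "numeric", gamma = "numeric", n = "integer",
                        R = "numeric", R2 = "numeric", Fstat = "numeric",
                        pValue = "numeric", residSE = "numeric",
                        residuals = "numeric", xName = "character",
                        yName = "character"))

setValidity("RegressionFit", function(object) {
  msg <- character()
  if (!object@form %in% c("linear", "quadratic", "logarithmic"))
    msg <- c(msg, "unknown model form")
  if (object@R2 < -1e-12 || object@R2 > 1 + 1e-12)
    msg <- c(msg, "R2 outside [0, 1]")
  if (is.finite(object@Fstat) && object@Fstat < 0)
    msg <- c(msg, "negative F statistic")
  if (length(msg)) msg else TRUE
})

#' ComparisonReport: best predictors and winning model form per property
#'
#' Summarises, for each physicochemical property, the best topological-index
#' predictor (by coefficient of determination, compared at three decimals so
#' ties are reported, not broken) under each model form, and the winning
#' form.
#'
#' @slot best data.frame with columns `property`, `form`, `predictors`
#'   (comma-joined when tied), `R2`.
#' @slot winner data.frame with columns `property`, `form` (comma-joined
#'   when forms tie), `predictors`, `R2`.
#' @slot grids named list of the three property-by-index \eqn{R^2} matrices
#'   the report was built from.
#' @seealso [compareForms()]
#' @export
setClass("ComparisonReport",
         representation(best = "data.frame", winner = "data.frame",
                        grids = "list"))
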