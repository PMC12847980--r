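#' @import methods
NULL

#' Vertex degrees of a molecular graph
#'
#' @param object a [MolecularGraph-class] object.
#' @return Named integer vector of degrees, one entry per vertex.
#' @seealso [edgeDegreePartition()]
#' @export
setGeneric("vertexDegrees", function(object) standardGeneric("vertexDegrees"))

#' Edge-degree partition of a molecular graph
#'
#' Tallies the edges of a graph by the unordered pair of endpoint degrees
#' \eqn{(a, b)} with \eqn{a \le b}. The partition is a sufficient statistic
#' for every degree-based, edge-additive topological index.
#'
#' @param object a [MolecularGraph-class] object.
#' @return A [DegreePartition-class] object.
#' @examples
#' g <- buildGraph(rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5)))
#' edgeDegreePartition(g)
#' @export
setGeneric("edgeDegreePartition",
           function(object) standardGeneric("edgeDegreePartition"))

#' Total number of edges summarised by a degree partition
#'
#' @param object a [DegreePartition-class] object.
#' @return Integer edge count.
#' @export
setGeneric("edgeTotal", function(object) standardGeneric("edgeTotal"))

#' Per-pair edge counts of a degree partition
#'
#' @param object a [DegreePartition-class] object.
#' @return Named integer vector; names are `"a,b"` degree-pair labels with
#'   \eqn{a \le b}.
#' @export
setGeneric("pairCounts", function(object) standardGeneric("pairCounts"))

#' Compute one topological index
#'
#' Evaluates a degree-based topological index either on a
#' [DegreePartition-class] (the sum of per-pair contributions weighted by edge
#' counts) or on a [MolecularGraph-class] (via its edge-degree partition).
#'
#' @param indexId one of `indexIds()`: `"M1"`, `"M2"`, `"H"`, `"F"`, `"SS"`,
#'   `"ABC"`, `"RI"`, `"SC"`, `"GA"`, `"HZ"`.
#' @param object a [DegreePartition-class] or [MolecularGraph-class].
#' @param ssVariant variant of the Schultz second index, see
#'   [edgeContribution()]. Default `"sqrtRatio"`.
#' @return A single numeric value.
#' @examples
#' p <- partitionFromCounts(c("1,2" = 1, "1,3" = 2, "2,2" = 15, "2,3" = 1))
#' computeIndex("M1", p)   # 76
#' @export
setGeneric("computeIndex",
           function(indexId, object, ssVariant = c("sqrtRatio", "inverseSquare"))
             standardGeneric("computeIndex"),
           signature = "object")

#' Compute all ten topological indices
#'
#' @param object a [DegreePartition-class] or [MolecularGraph-class].
#' @param ssVariant Schultz second index variant, see [edgeContribution()].
#' @return Named numeric vector over `indexIds()`.
#' @examples
#' computeAllIndices(drugPartition("glycine"))
#' @export
setGeneric("computeAllIndices",
           function(object, ssVariant = c("sqrtRatio", "inverseSquare"))
             standardGeneric("computeAllIndices"))

#' Bond list of a molecular graph
#'
#' @param object a [MolecularGraph-class] object.
#' @return Two-column character matrix, one bond per row.
#' @export
setGeneric("bondMatrix", function(object) standardGeneric("bondMatrix"))
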