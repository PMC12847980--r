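#' Build a validated molecular graph from an edge list
#'
#' Constructs a [MolecularGraph-class] from bond pairs. The vertex set is the
#' union of the endpoints; identifiers are opaque and coerced to character.
#' Self-loops, duplicate bonds and disconnected inputs are rejected — the
#' connectivity error names the components so mis-assembled inputs are easy
#' to debug. Degrees above 4 are legal but draw a warning, since organic
#' heavy atoms rarely exceed four bonds.
#'
#' @param edgeList a two-column matrix or data.frame (one bond per row), or a
#'   list of length-2 vectors.
#' @param elements optional named character vector of atomic symbols per
#'   vertex id; annotation only.
#' @return A [MolecularGraph-class] object.
#' @examples
#' # glycine backbone: 5 heavy atoms, 4 bonds
#' g <- buildGraph(rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5)))
#' vertexDegrees(g)
#' @export
buildGraph <- function(edgeList, elements = NULL) {
  if (length(edgeList) == 0L)
    stop("edge list is empty")
  if (is.list(edgeList) && !is.data.frame(edgeList))
    edgeList <- do.call(rbind, lapply(edgeList, function(p) {
      if (length(p) != 2L) stop("each edge must have exactly two endpoints")
      as.character(p)
    }))
  edgeList <- as.matrix(edgeList)
  if (length(edgeList) == 0L || nrow(edgeList) == 0L)
    stop("edge list is empty")
  if (ncol(edgeList) != 2L)
    stop("edge list must have two columns")
  mode(edgeList) <- "character"
  if (any(is.na(edgeList)) || any(!nzchar(edgeList)))
    stop("missing or empty vertex identifier in edge list")
  if (any(edgeList[, 1L] == edgeList[, 2L]))
    stop("self-loop found: edge (", edgeList[which(edgeList[, 1L] ==
         edgeList[, 2L])[1L], 1L], ") — molecular graphs are simple")
  key <- paste(pmin(edgeList[, 1L], edgeList[, 2L]),
               pmax(edgeList[, 1L], edgeList[, 2L]), sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate edge (", sub("\r", ", ", d),
         "): molecular graphs are simple")
  }
  verts <- sort(unique(as.vector(edgeList)))
  ig <- igraph::graph_from_edgelist(edgeList, directed = FALSE)
  comp <- igraph::components(ig)
  if (comp$no > 1L) {
    parts <- split(names(comp$membership), comp$membership)
    stop("graph is disconnected (", comp$no, " components): ",
         paste(vapply(parts, function(p)
           paste0("{", paste(sort(p), collapse = ","), "}"), ""),
           collapse = " "))
  }
  elements <- if (is.null(elements)) character() else {
    stopifnot(is.character(elements), !is.null(names(elements)))
    elements
  }
  g <- new("MolecularGraph", vertices = verts,
           edges = unname(edgeList), elements = elements)
  validObject(g)
  if (max(vertexDegrees(g)) > 4L)
    warning("vertex degree above 4; unusual for a hydrogen-suppressed ",
            "organic molecule")
  g
}

#' Read a molecular graph from an edge-list text file
#'
#' Format: one bond per line, two whitespace-separated vertex tokens;
#' `#` starts a comment; blank lines are skipped.
#'
#' @param path file path.
#' @return A [MolecularGraph-class] object.
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("no edges in ", path)
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad))
    stop("line ", bad[1L], " of ", path,
         ": expected two vertex tokens, got ", length(toks[[bad[1L]]]))
  buildGraph(do.call(rbind, toks))
}

#' @describeIn vertexDegrees number of incident edges per vertex; degrees
#'   sum to twice the edge count (handshake identity).
#' @export
setMethod("vertexDegrees", "MolecularGraph", function(object) {
  d <- table(factor(as.vector(object@edges), levels = object@vertices))
  stats::setNames(as.integer(d), object@vertices)
})

#' @describeIn edgeDegreePartition tally each edge as the unordered pair of
#'   its endpoint degrees.
#' @export
setMethod("edgeDegreePartition", "MolecularGraph", function(object) {
  deg <- vertexDegrees(object)
  du <- deg[object@edges[, 1L]]
  dv <- deg[object@edges[, 2L]]
  a <- pmin(du, dv)
  b <- pmax(du, dv)
  tab <- table(paste(a, b, sep = ","))
  partitionFromCounts(stats::setNames(as.integer(tab), names(tab)))
})

#' Build a degree partition from raw pair counts
#'
#' Ingests edge tallies given directly as counts per degree pair, e.g. when
#' the realizing structure is not available. Keys are canonicalized to
#' \eqn{a \le b} (counts of equivalent orientations are merged), zero counts
#' are dropped, and the result is validated.
#'
#' @param raw either a named numeric vector with names `"a,b"` (separators
#'   `,`, `-`, `:` or whitespace are accepted), or a data.frame/matrix with
#'   columns `a`, `b`, `count`.
#' @return A [DegreePartition-class] object.
#' @examples
#' partitionFromCounts(c("3,1" = 2))          # canonicalized to (1,3): 2
#' partitionFromCounts(data.frame(a = 2, b = 2, count = 6))
#' @export
partitionFromCounts <- function(raw) {
  if (is.data.frame(raw) || is.matrix(raw)) {
    raw <- as.data.frame(raw)
    stopifnot(all(c("a", "b", "count") %in% names(raw)))
    a <- as.numeric(raw$a); b <- as.numeric(raw$b)
    n <- as.numeric(raw$count)
  } else {
    if (is.null(names(raw)) || !length(raw))
      stop("counts must be a non-empty named vector or an a/b/count table")
    ab <- strsplit(names(raw), "[,:[:space:]-]+")
    if (any(lengths(ab) != 2L))
      stop("pair labels must contain exactly two degrees, e.g. \"2,3\"")
    ab <- vapply(ab, as.numeric, numeric(2))
    a <- ab[1L, ]; b <- ab[2L, ]
    n <- as.numeric(raw)
  }
  if (any(is.na(a)) || any(is.na(b)) || any(a < 1) || any(b < 1) ||
      any(a != round(a)) || any(b != round(b)))
    stop("degrees must be integers >= 1")
  if (any(is.na(n)) || any(n < 0) || any(n != round(n)))
    stop("counts must be nonnegative integers")
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- n > 0
  if (!any(keep))
    stop("empty partition: all counts are zero")
  key <- paste(lo[keep], hi[keep])
  agg <- rowsum(n[keep], key)
  ord <- order(as.numeric(sub(" .*", "", rownames(agg))),
               as.numeric(sub(".* ", "", rownames(agg))))
  pairs <- do.call(rbind, strsplit(rownames(agg)[ord], " "))
  mode(pairs) <- "integer"
  p <- new("DegreePartition", pairs = unname(pairs),
           counts = as.integer(agg[ord, 1L]))
  validObject(p)
  p
}

#' @describeIn edgeTotal sum of all pair counts.
#' @export
setMethod("edgeTotal", "DegreePartition",
          function(object) sum(object@counts))

#' @describeIn pairCounts counts named by canonical `"a,b"` labels.
#' @export
setMethod("pairCounts", "DegreePartition", function(object)
  stats::setNames(object@counts, pairLabels(object@pairs)))

setMethod("show", "MolecularGraph", function(object) {
  deg <- vertexDegrees(object)
  cat("MolecularGraph with", length(object@vertices), "heavy atoms and",
      nrow(object@edges), "bonds\n")
  cat("  degree sequence:", paste(sort(deg, decreasing = TRUE),
                                  collapse = " "), "\n")
  if (length(object@elements))
    cat("  elements:", paste0(names(object@elements), ":",
                              object@elements, collapse = " "), "\n")
})

setMethod("show", "DegreePartition", function(object) {
  cat("DegreePartition over", edgeTotal(object), "edges\n")
  pc <- pairCounts(object)
  cat(" ", paste0("(", names(pc), ")=", pc, collapse = "  "), "\n")
})

#' @describeIn bondMatrix the graph's edges.
#' @export
setMethod("bondMatrix", "MolecularGraph", function(object) object@edges)
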