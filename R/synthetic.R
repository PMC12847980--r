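#' Generate a chemistry-like random graph
#'
#' Builds a connected simple graph the way small drug-like skeletons look: a
#' random tree grown by uniform attachment to vertices with spare degree
#' capacity, plus `ringEdges` chords between non-adjacent vertices that
#' still have capacity. All degrees respect `maxDegree` (default 4, the
#' valence ceiling of organic heavy atoms). Trees and unicyclic/bicyclic
#' graphs produced this way cover the structural class of the bundled
#' nine-drug study.
#'
#' @param nVertices number of heavy atoms, \eqn{\ge 2}.
#' @param maxDegree degree cap, \eqn{\ge 1}.
#' @param ringEdges number of extra (cycle-closing) edges to add.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return A [MolecularGraph-class] object with `nVertices + ringEdges - 1`
#'   edges.
#' @examples
#' g <- randomChemlikeGraph(8, ringEdges = 1, seed = 1)
#' max(vertexDegrees(g)) <= 4
#' @export
randomChemlikeGraph <- function(nVertices, maxDegree = 4, ringEdges = 0,
                                seed = NULL) {
  stopifnot(nVertices >= 2, maxDegree >= 1, ringEdges >= 0)
  if (maxDegree == 1 && nVertices > 2)
    stop("cannot grow a connected graph on ", nVertices,
         " vertices with degree cap 1")
  withSeed(seed, {
    deg <- integer(nVertices)
    edges <- matrix(integer(), 0, 2)
    for (i in seq_len(nVertices)[-1L]) {
      open <- which(deg[seq_len(i - 1L)] < maxDegree)
      # a growing tree always has a vertex under any cap >= 2
      parent <- if (length(open) == 1L) open else sample(open, 1L)
      edges <- rbind(edges, c(parent, i))
      deg[parent] <- deg[parent] + 1L
      deg[i] <- deg[i] + 1L
    }
    for (r in seq_len(ringEdges)) {
      adj <- paste(edges[, 1L], edges[, 2L])  # rows already have u < v
      open <- which(deg < maxDegree)
      cand <- if (length(open) >= 2L) utils::combn(open, 2L) else
        matrix(integer(), 2, 0)
      if (ncol(cand))
        cand <- cand[, !(paste(cand[1L, ], cand[2L, ]) %in% adj),
                     drop = FALSE]
      if (!ncol(cand))
        stop("cannot place ring edge ", r, ": no non-adjacent vertex ",
             "pair with spare degree capacity")
      pick <- cand[, sample.int(ncol(cand), 1L)]
      edges <- rbind(edges, pick)
      deg[pick] <- deg[pick] + 1L
    }
    em <- matrix(paste0("v", edges), ncol = 2)
    suppressWarnings(buildGraph(em))
  })
}

#' Simulate a property response from index values
#'
#' Draws \eqn{y_i = \alpha + \beta g(T_i) [+ \gamma T_i^2] + \varepsilon_i}
#' with \eqn{g} the identity (linear, quadratic) or natural log
#' (logarithmic) and \eqn{\varepsilon \sim N(0, \sigma^2)} — the generating
#' model mirroring the fitted model forms.
#'
#' @param indexValues numeric predictor values \eqn{T_i}.
#' @param form generating form, see [fitModel()].
#' @param alpha,beta,gamma generating coefficients (`gamma` is used only by
#'   the quadratic form).
#' @param sigma noise standard deviation, \eqn{\ge 0}.
#' @param seed optional integer seed.
#' @return Numeric response vector.
#' @examples
#' simulateProperty(2, "quadratic", 1, 2, 0.5, sigma = 0)  # exactly 7
#' @export
simulateProperty <- function(indexValues,
                             form = c("linear", "quadratic", "logarithmic"),
                             alpha, beta, gamma = 0, sigma = 0,
                             seed = NULL) {
  form <- match.arg(form)
  stopifnot(sigma >= 0)
  if (form == "logarithmic" && any(indexValues <= 0))
    stop("logarithmic form requires strictly positive index values")
  mu <- switch(form,
               linear      = alpha + beta * indexValues,
               quadratic   = alpha + beta * indexValues +
                             gamma * indexValues^2,
               logarithmic = alpha + beta * log(indexValues))
  withSeed(seed, mu + stats::rnorm(length(mu), 0, sigma))
}

#' Specification of a synthetic QSPR study
#'
#' Bundles the generator settings for [generateStudy()]. Defaults mirror the
#' bundled nine-drug study: nine molecules of 5-20 heavy atoms, degree cap
#' 4, zero to two rings, and a quadratic index-property relation on the
#' Randic index with coefficients and noise on the scale of the study's
#' molar-volume fit.
#'
#' @param nMolecules number of molecules.
#' @param sizeRange integer range of heavy-atom counts, min \eqn{\ge 2}.
#' @param maxDegree degree cap, \eqn{\ge 2}.
#' @param ringEdges integer vector of allowed extra-edge counts; each
#'   molecule draws one uniformly.
#' @param responseForm generating model form.
#' @param predictorId index driving the response, one of [indexIds()].
#' @param alpha,beta,gamma,sigma generating coefficients and noise SD.
#' @param seed integer seed driving the whole study generation.
#' @return A list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nMolecules = 9, sizeRange = c(5, 20),
                          maxDegree = 4, ringEdges = 0:2,
                          responseForm = c("quadratic", "linear",
                                           "logarithmic"),
                          predictorId = "RI",
                          alpha = -9.117, beta = 32.180, gamma = -0.448,
                          sigma = 13, seed = 1) {
  responseForm <- match.arg(responseForm)
  stopifnot(nMolecules >= 1, length(sizeRange) == 2, sizeRange[1] >= 2,
            sizeRange[1] <= sizeRange[2], maxDegree >= 2, sigma >= 0,
            all(ringEdges >= 0), predictorId %in% indexIds())
  structure(list(nMolecules = nMolecules, sizeRange = sizeRange,
                 maxDegree = maxDegree, ringEdges = ringEdges,
                 responseForm = responseForm, predictorId = predictorId,
                 alpha = alpha, beta = beta, gamma = gamma, sigma = sigma,
                 seed = seed),
            class = "SyntheticSpec")
}

#' Generate a full synthetic study
#'
#' End-to-end synthetic dataset shaped like the bundled study: one graph,
#' one partition, one index vector and one simulated property response per
#' molecule. Deterministic given `spec$seed`.
#'
#' @param spec a [syntheticSpec()] object.
#' @return List with elements `graphs`, `partitions`, `indices` (matrix,
#'   molecules by [indexIds()]), `response` (numeric vector) and `spec`.
#' @examples
#' st <- generateStudy(syntheticSpec(nMolecules = 5, seed = 7))
#' dim(st$indices)  # 5 x 10
#' @export
generateStudy <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$seed, {
    sizes <- sample(seq(spec$sizeRange[1], spec$sizeRange[2]),
                    spec$nMolecules, replace = TRUE)
    rings <- if (length(spec$ringEdges) == 1L)
      rep(spec$ringEdges, spec$nMolecules)
    else sample(spec$ringEdges, spec$nMolecules, replace = TRUE)
    graphs <- lapply(seq_len(spec$nMolecules), function(i)
      randomChemlikeGraph(sizes[i], spec$maxDegree, rings[i]))
    names(graphs) <- paste0("mol", seq_along(graphs))
    partitions <- lapply(graphs, edgeDegreePartition)
    indices <- indexTable(partitions)
    response <- simulateProperty(indices[, spec$predictorId],
                                 spec$responseForm, spec$alpha, spec$beta,
                                 spec$gamma, spec$sigma)
    list(graphs = graphs, partitions = partitions, indices = indices,
         response = response, spec = spec)
  })
}
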