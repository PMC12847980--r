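#' Fit a single-predictor model form by ordinary least squares
#'
#' Fits one of the three model forms used throughout the package (see
#' [RegressionFit-class]) with [stats::lm()] and extracts the statistics of
#' interest: coefficients, \eqn{R}, \eqn{R^2}, the overall F statistic with
#' its exact p-value from the F distribution, and the residual standard
#' error. For a perfect fit (zero residual sum of squares) `Fstat` is
#' `Inf` and `pValue` is 0.
#'
#' @param x predictor values (a topological index); must be strictly
#'   positive for the logarithmic form.
#' @param y response values (a physicochemical property).
#' @param form `"linear"`, `"quadratic"` or `"logarithmic"`.
#' @param xName,yName optional names recorded for equation rendering.
#' @return A [RegressionFit-class] object.
#' @examples
#' idx <- indexTable(drugPartitions())
#' pr  <- drugProperties()
#' fitModel(idx[, "RI"], pr$MV, "linear", xName = "RI", yName = "MV")
#' @export
fitModel <- function(x, y, form = c("linear", "quadratic", "logarithmic"),
                     xName = "T", yName = "P") {
  form <- match.arg(form)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  k <- if (form == "quadratic") 2L else 1L
  if (length(y) != n) stop("x and y lengths differ")
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y")
  if (n < k + 2L)
    stop("need at least ", k + 2L, " observations for the ", form, " form")
  if (form == "logarithmic" && any(x <= 0))
    stop("logarithmic form requires strictly positive predictor values")
  if (diff(range(x)) == 0)
    stop("constant predictor: design matrix is rank deficient")
  fit <- switch(form,
                linear      = stats::lm(y ~ x),
                quadratic   = stats::lm(y ~ x + I(x^2)),
                logarithmic = stats::lm(y ~ log(x)))
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design for the ", form, " form")
  cf <- unname(stats::coef(fit))
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant response: R2 undefined")
  r2 <- 1 - sse / sst
  df2 <- n - k - 1L
  perfect <- sse <= 1e-12 * sst
  fstat <- if (perfect) Inf else (r2 / k) / ((1 - r2) / df2)
  pval <- if (perfect) 0 else stats::pf(fstat, k, df2, lower.tail = FALSE)
  rmul <- sqrt(max(r2, 0))
  new("RegressionFit",
      form = form, alpha = cf[1L], beta = cf[2L],
      gamma = if (form == "quadratic") cf[3L] else NA_real_,
      n = n,
      R = if (form == "quadratic") rmul else sign(cf[2L]) * rmul,
      R2 = r2, Fstat = fstat, pValue = pval,
      residSE = sqrt(sse / df2), residuals = unname(res),
      xName = xName, yName = yName)
}

#' Standardized residuals of a fit
#'
#' Raw residuals divided by the residual standard error, the diagnostic the
#' study design uses to screen for outliers. A perfect fit returns all
#' zeros with attribute `perfectFit = TRUE`.
#'
#' @param fit a [RegressionFit-class] object.
#' @return Numeric vector, with attribute `perfectFit` when `residSE` is 0.
#' @export
standardizedResiduals <- function(fit) {
  stopifnot(is(fit, "RegressionFit"))
  if (fit@residSE == 0 || !is.finite(fit@Fstat))
    return(structure(rep(0, fit@n), perfectFit = TRUE))
  fit@residuals / fit@residSE
}

#' R-squared grid: every property against every index
#'
#' @param properties data.frame of responses, molecules as rows (e.g.
#'   [drugProperties()]).
#' @param indices numeric matrix of predictors, molecules as rows and
#'   indices as columns (e.g. [indexTable()] or [referenceIndices()]); rows
#'   must align with `properties`.
#' @param form model form, see [fitModel()].
#' @return Numeric matrix of \eqn{R^2}, properties by indices.
#' @examples
#' g <- r2Grid(drugProperties(), indexTable(drugPartitions()), "linear")
#' roundHalfAway(g["MV", "RI"], 3)  # 0.967
#' @export
r2Grid <- function(properties, indices,
                   form = c("linear", "quadratic", "logarithmic")) {
  form <- match.arg(form)
  if (nrow(properties) != nrow(indices))
    stop("properties and indices must cover the same molecules")
  if (!is.null(rownames(properties)) && !is.null(rownames(indices)) &&
      !identical(rownames(properties), rownames(indices)))
    stop("row names of properties and indices disagree: ",
         paste(setdiff(rownames(properties), rownames(indices)),
               collapse = ", "))
  out <- matrix(NA_real_, ncol(properties), ncol(indices),
                dimnames = list(colnames(properties), colnames(indices)))
  for (p in colnames(properties))
    for (i in colnames(indices))
      out[p, i] <- fitModel(indices[, i], properties[[p]], form)@R2
  out
}

#' Best predictor of a property in an R-squared grid
#'
#' Selects the index with maximal \eqn{R^2}, comparing at `digits` decimal
#' places (default three, half away from zero) so near-equal predictors are
#' reported as ties rather than broken by floating-point noise.
#'
#' @param grid matrix from [r2Grid()].
#' @param property row name to examine.
#' @param candidates index ids to consider; defaults to all grid columns.
#' @param digits decimal places at which \eqn{R^2} values are compared.
#' @return List with `indexIds` (all argmax ids) and `R2` (the maximal
#'   unrounded value among them).
#' @export
bestPredictor <- function(grid, property, candidates = colnames(grid),
                          digits = 3) {
  if (!property %in% rownames(grid)) stop("unknown property ", property)
  if (!length(candidates)) stop("empty candidate set")
  if (!all(candidates %in% colnames(grid)))
    stop("candidates not in grid: ",
         paste(setdiff(candidates, colnames(grid)), collapse = ", "))
  v <- grid[property, candidates]
  r <- roundHalfAway(v, digits)
  ids <- candidates[r == max(r)]
  list(indexIds = ids, R2 = max(v[ids]))
}

#' Compare model forms across properties
#'
#' Builds a [ComparisonReport-class]: per property, the best predictor under
#' each form and the winning form (argmax of the best \eqn{R^2}, again at
#' three-decimal comparison so exact ties — e.g. a noiseless linear
#' relation, where the quadratic fit adds nothing — are reported as ties).
#'
#' @param grids named list of \eqn{R^2} matrices with identical dimnames,
#'   e.g. `list(linear = ..., quadratic = ..., logarithmic = ...)`.
#' @param candidates restricts which indices compete per form: `NULL` (all
#'   grid columns), a character vector applied to every form, or a named
#'   list by form whose elements are character vectors or data.frames with
#'   columns `property`/`index` (per-property candidate sets, as needed when
#'   only some cells of a grid were reported). A property with no candidates
#'   under a form gets an `NA` row and does not compete for the winner.
#' @param digits decimal places for comparison.
#' @return A [ComparisonReport-class] object.
#' @examples
#' idx <- indexTable(drugPartitions())
#' pr  <- drugProperties()
#' grids <- sapply(c("linear", "quadratic", "logarithmic"),
#'                 function(f) r2Grid(pr, idx, f), simplify = FALSE)
#' compareForms(grids)
#' @export
compareForms <- function(grids, candidates = NULL, digits = 3) {
  stopifnot(is.list(grids), length(grids) >= 2L, !is.null(names(grids)))
  props <- rownames(grids[[1L]])
  best <- do.call(rbind, lapply(names(grids), function(f) {
    cand <- if (is.null(candidates)) colnames(grids[[f]])
            else if (is.list(candidates) && !is.data.frame(candidates))
              candidates[[f]]
            else candidates
    do.call(rbind, lapply(props, function(p) {
      cc <- if (is.data.frame(cand)) cand$index[cand$property == p]
            else cand
      if (!length(cc))
        return(data.frame(property = p, form = f, predictors = NA_character_,
                          R2 = NA_real_))
      b <- bestPredictor(grids[[f]], p, cc, digits)
      data.frame(property = p, form = f,
                 predictors = paste(b$indexIds, collapse = ","), R2 = b$R2)
    }))
  }))
  winner <- do.call(rbind, lapply(props, function(p) {
    sub <- best[best$property == p & !is.na(best$R2), ]
    r <- roundHalfAway(sub$R2, digits)
    w <- sub[r == max(r), ]
    data.frame(property = p, form = paste(w$form, collapse = ","),
               predictors = paste(unique(w$predictors), collapse = ";"),
               R2 = max(w$R2))
  }))
  new("ComparisonReport", best = best, winner = winner, grids = grids)
}

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("RegressionFit (%s): %s = %s\n", object@form, object@yName,
              renderFitEquation(object)))
  cat(sprintf("  n = %d, R = %.3f, R2 = %.3f, F = %s, p = %.3g, resid SE = %.3f\n",
              object@n, object@R, object@R2,
              if (is.finite(object@Fstat)) sprintf("%.3f", object@Fstat)
              else "Inf", object@pValue, object@residSE))
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport over", nrow(object@winner), "properties\n")
  for (i in seq_len(nrow(object@winner)))
    cat(sprintf("  %-4s best form %-22s predictor %-8s R2 %.3f\n",
                object@winner$property[i], object@winner$form[i],
                object@winner$predictors[i], object@winner$R2[i]))
})
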