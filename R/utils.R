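#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' all table reproduction in this package), unlike [base::round()] which
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' roundHalfAway(0.5, 0)    # 1
#' roundHalfAway(-2.345, 2) # -2.35
#' @export
roundHalfAway <- function(x, digits = 0) {
  s <- 10^digits
  # nudge by one ulp so values stored just under a .5 boundary round up
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

# evaluate a block with a deterministic RNG stream, restoring the caller's
# RNG state afterwards; seed = NULL leaves the global stream untouched
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

pairLabels <- function(pairs) paste(pairs[, 1L], pairs[, 2L], sep = ",")
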