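test_that("fitModel matches the hand-solved normal equations", {
  # 3-point oracle worked out before implementation: beta = 1.5, alpha = -2/3
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  o <- olsOracle(x, y)
  expect_equal(o$beta, 1.5)
  expect_equal(o$alpha, -2 / 3)
  f <- fitModel(x, y, "linear")
  expect_equal(f@beta, o$beta)
  expect_equal(f@alpha, o$alpha)
  # a larger random dataset against the same closed form
  set.seed(21)
  x2 <- runif(40, 1, 10); y2 <- 3 - 2 * x2 + rnorm(40)
  o2 <- olsOracle(x2, y2)
  f2 <- fitModel(x2, y2, "linear")
  expect_equal(f2@beta, o2$beta)
  expect_equal(f2@alpha, o2$alpha)
  expect_equal(f2@R, -sqrt(f2@R2))   # negative slope, signed R
})

test_that("perfect fits are reported with the sentinel statistics", {
  x <- 1:6; y <- 2 * x + 1
  f <- fitModel(x, y, "linear")
  expect_equal(f@R2, 1)
  expect_identical(f@Fstat, Inf)
  expect_identical(f@pValue, 0)
  expect_equal(max(abs(f@residuals)), 0, tolerance = 1e-10)
  sr <- standardizedResiduals(f)
  expect_true(all(sr == 0))
  expect_true(isTRUE(attr(sr, "perfectFit")))
})

test_that("fitModel rejects degenerate inputs", {
  expect_error(fitModel(c(1, 1, 1, 1), 1:4, "linear"), "constant predictor")
  expect_error(fitModel(c(-1, 2, 3, 4), 1:4, "logarithmic"), "positive")
  expect_error(fitModel(1:3, 1:3, "quadratic"), "at least 4")
  expect_error(fitModel(1:4, rep(2, 4), "linear"), "constant response")
})

test_that("logarithmic fit is the linear fit on log-transformed x", {
  set.seed(22)
  x <- runif(15, 0.5, 9); y <- 2 + 3 * log(x) + rnorm(15, 0, 0.3)
  flog <- fitModel(x, y, "logarithmic")
  flin <- fitModel(log(x), y, "linear")
  expect_equal(flog@alpha, flin@alpha)
  expect_equal(flog@beta, flin@beta)
  expect_equal(flog@R2, flin@R2)
  expect_equal(flog@Fstat, flin@Fstat)
})

test_that("F, R2 and residual SE are mutually consistent", {
  idx <- studyIndexMatrix()
  pr <- drugProperties()
  for (form in c("linear", "quadratic", "logarithmic")) {
    k <- if (form == "quadratic") 2 else 1
    f <- fitModel(idx[, "H"], pr$BP, form)
    expect_equal(f@Fstat, (f@R2 / k) / ((1 - f@R2) / (f@n - k - 1)))
    expect_equal(f@residSE,
                 sqrt(sum(f@residuals^2) / (f@n - k - 1)))
    expect_equal(mean(f@residuals), 0, tolerance = 1e-10)
  }
})

test_that("standardized residuals flag the largest misfit drug", {
  idx <- studyIndexMatrix()
  f <- fitModel(idx[, "RI"], drugProperties()$MV, "linear")
  sr <- standardizedResiduals(f)
  expect_equal(sr, f@residuals / f@residSE)
  expect_identical(rownames(idx)[which.max(abs(sr))], "N-acetylglucosamine")
})

test_that("r2Grid covers the full property-by-index grid", {
  idx <- studyIndexMatrix()
  pr <- drugProperties()
  g <- r2Grid(pr, idx, "linear")
  expect_identical(dim(g), c(8L, 10L))
  expect_true(all(g >= 0 & g <= 1))
  expect_equal(roundHalfAway(g["EV", "M2"], 3), 0.955)
  gq <- r2Grid(pr, idx, "quadratic")
  expect_equal(roundHalfAway(gq["MV", "RI"], 3), 0.968)
  expect_error(r2Grid(pr[1:5, ], idx, "linear"), "same molecules")
})

test_that("bestPredictor reports argmax and ties at three decimals", {
  idx <- studyIndexMatrix()
  pr <- drugProperties()
  lin <- r2Grid(pr, idx, "linear")
  expect_identical(bestPredictor(lin, "MV")$indexIds, "RI")
  expect_equal(bestPredictor(lin, "MV")$R2, 0.967, tolerance = 1e-3)
  log_ <- r2Grid(pr, idx, "logarithmic")
  expect_identical(sort(bestPredictor(log_, "EV")$indexIds), c("M1", "M2"))
  expect_identical(bestPredictor(lin, "MV", candidates = "H")$indexIds, "H")
  expect_error(bestPredictor(lin, "MV", candidates = character()), "empty")
})

test_that("compareForms finds the winning form and keeps ties", {
  idx <- studyIndexMatrix()
  pr <- drugProperties()
  grids <- sapply(c("linear", "quadratic", "logarithmic"),
                  function(f) r2Grid(pr, idx, f), simplify = FALSE)
  rep <- compareForms(grids)
  expect_s4_class(rep, "ComparisonReport")
  expect_true(all(rep@winner$form == "quadratic"))
  # identical grids tie rather than silently breaking
  tied <- compareForms(list(a = grids$linear, b = grids$linear))
  expect_true(all(tied@winner$form == "a,b"))
})

test_that("quadratic R2 is never below linear R2 (nested models)", {
  idx <- studyIndexMatrix()
  pr <- drugProperties()
  lin <- r2Grid(pr, idx, "linear")
  quad <- r2Grid(pr, idx, "quadratic")
  expect_true(all(quad - lin >= -1e-12))
})
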