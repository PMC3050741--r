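test_that("chi-square tail probability matches closed forms", {
  expect_equal(chi2TailProbability(0, 5), 0)
  expect_equal(chi2TailProbability(1e8, 3), 1, tolerance = 1e-12)
  # with 2 dof the distribution is exponential: P = 1 - exp(-x/2),
  # so the median is 2 log 2
  expect_equal(chi2TailProbability(2 * log(2), 2), 0.5, tolerance = 1e-12)
  x <- c(0.3, 1.7, 6.2)
  expect_equal(chi2TailProbability(x, 2), 1 - exp(-x / 2), tolerance = 1e-12)
  expect_error(chi2TailProbability(1, 0), "positive")
  expect_error(chi2TailProbability(-1, 2), "nonnegative")
})

test_that("acceptance filter keeps near-perfect fits and drops bad ones", {
  mkFit <- function(chi2, conv = TRUE)
    new("FitResult", startLog10 = c(0, 0),
        estimate = c(a = 1, b = 2), chi2 = chi2, converged = conv,
        firstOrderNorm = 0, nEvals = 1L, message = "")
  mkMs <- function(fits)
    new("MultiStartResult", fits = fits, bestIndex = 1L,
        boundsLog10 = cbind(c(-2, -2), c(2, 2)),
        parameterNames = c("a", "b"), seed = 1L)

  dof <- 28L
  good <- mkFit(1e-8)
  high <- mkFit(qchisq(0.9999, dof))    # far above the acceptance quantile
  notConv <- mkFit(1e-8, conv = FALSE)

  Q <- acceptEstimates(mkMs(list(good, high, notConv)), dof, 0.001)
  expect_equal(ncol(Q), 1L)             # only the converged near-zero fit
  expect_equal(Q[, 1], c(a = 1, b = 2))

  # vacuous filter keeps every converged fit
  Qall <- acceptEstimates(mkMs(list(good, high)), dof, significance = 1)
  expect_equal(ncol(Qall), 2L)

  # nothing converged, nothing acceptable -> explicit errors
  expect_error(acceptEstimates(mkMs(list(notConv)), dof), "no converged")
  expect_error(acceptEstimates(mkMs(list(high)), dof, 0.001), "no estimate accepted")
})

test_that("variance report reproduces the textbook estimator arithmetic", {
  # row (9, 11): mean 10, variance ((9-10)^2 + (11-10)^2)/(2-1) = 2,
  # v = sqrt(2)/10
  Q <- matrix(c(9, 11), 1, 2, dimnames = list("k", NULL))
  b <- matrix(c(1 - 12, 1 + 12), 1, 2)
  rep <- varianceReport(Q, b, vBar = 0.01, nTotal = 5)
  expect_equal(unname(rep@means), 10)
  expect_equal(unname(rep@variances), 2)
  expect_equal(unname(rep@cv), sqrt(2) / 10)
  expect_identical(rep@verdict, "not_identifiable")
  expect_identical(rep@limitingParameter, "k")

  # identical columns well inside the box: identifiable, v = 0
  Q2 <- matrix(c(10, 10, 10), 1, 3, dimnames = list("k", NULL))
  rep2 <- varianceReport(Q2, b, vBar = 0.01, nTotal = 3)
  expect_equal(unname(rep2@cv), 0)
  expect_identical(rep2@verdict, "identifiable")
  expect_false(any(rep2@boundLimited))

  # v above the bound names the limiting parameter in check order
  Q3 <- rbind(p1 = c(5, 15), p2 = c(10, 10.0001))
  b3 <- cbind(log10(c(10, 10)) - 12, log10(c(10, 10)) + 12)
  rep3 <- varianceReport(Q3, b3, vBar = 0.01, nTotal = 2)
  expect_identical(rep3@verdict, "not_identifiable")
  expect_identical(rep3@limitingParameter, "p1")

  expect_error(varianceReport(matrix(1, 1, 1), b), "at least 2")
})

test_that("estimates crowding the sampling box raise the bound-limited flag", {
  # spread over nearly the full 4-decade box around 1
  Q <- matrix(10^c(-1.99, 0, 1.99), 1, 3, dimnames = list("k", NULL))
  b <- matrix(c(-2, 2), 1, 2)
  rep <- varianceReport(Q, b, vBar = 0.01, nTotal = 3)
  expect_true(rep@boundLimited[1])
  expect_identical(rep@verdict, "not_identifiable")

  # contact with a single edge is enough (v is then only a lower bound)
  Qlo <- matrix(10^c(-1.95, -1, 0), 1, 3, dimnames = list("k", NULL))
  expect_true(varianceReport(Qlo, b, vBar = 0.01, nTotal = 3)@boundLimited[1])
  # comfortably interior estimates are not flagged
  Qin <- matrix(10^c(-0.5, 0, 0.5), 1, 3, dimnames = list("k", NULL))
  expect_false(varianceReport(Qin, b, vBar = 2, nTotal = 3)@boundLimited[1])
})

test_that("coefficients of variation are scale invariant", {
  Q <- rbind(a = c(2, 3, 4), b = c(0.1, 0.2, 0.3))
  b1 <- cbind(log10(c(3, 0.2)) - 6, log10(c(3, 0.2)) + 6)
  r1 <- varianceReport(Q, b1, vBar = 1e6, nTotal = 3)
  # rescale parameter units by 1000: v unchanged
  r2 <- varianceReport(Q * 1000, b1 + 3, vBar = 1e6, nTotal = 3)
  expect_equal(r1@cv, r2@cv, tolerance = 1e-12)
})

test_that("full variance analysis verdicts identifiable vs redundant toys", {
  des <- toyDesign()

  net <- toyChain()
  ds <- generateDataset(net, design = des, noiseMode = "noise_free")
  ms <- multiStartFit(net, des, ds, referenceParams(net), nStarts = 15,
                      seed = 2)
  va <- runVarianceAnalysis(net, des, ds, bestFit(ms)@estimate,
                            nStarts = 60, seed = 3)
  expect_identical(verdict(va), "identifiable")
  expect_true(all(coefficientsOfVariation(va) <= 0.01))
  expect_gte(va@nAccept, 2L)

  dup <- toyChainDuplicated()
  dsD <- generateDataset(dup, design = des, noiseMode = "noise_free")
  vaD <- runVarianceAnalysis(dup, des, dsD, referenceParams(dup),
                             nStarts = 60, seed = 4)
  expect_identical(verdict(vaD), "not_identifiable")
  expect_gt(max(coefficientsOfVariation(vaD)[c("k1a", "k1b")]), 0.01)
  expect_true(any(vaD@boundLimited[c("k1a", "k1b")]))
  expect_false(vaD@boundLimited[["k2"]])
})

test_that("enlarging the sampling box cannot shrink the spread", {
  des <- toyDesign()
  dup <- toyChainDuplicated()
  ds <- generateDataset(dup, design = des, noiseMode = "noise_free")
  vNarrow <- runVarianceAnalysis(dup, des, ds, referenceParams(dup),
                                 nStarts = 40, halfWidthDecades = 2,
                                 seed = 6)
  vWide <- runVarianceAnalysis(dup, des, ds, referenceParams(dup),
                               nStarts = 40, halfWidthDecades = 8,
                               seed = 6)
  expect_gte(max(coefficientsOfVariation(vWide)),
             0.5 * max(coefficientsOfVariation(vNarrow)))
})

test_that("variance report file carries the verdict", {
  Q <- matrix(c(10, 10.0001, 9.9999), 1, 3, dimnames = list("k", NULL))
  b <- matrix(c(-11, 13), 1, 2)
  rep <- varianceReport(Q, b, vBar = 0.01, nTotal = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeVarianceReport(rep, path)
  txt <- readLines(path)
  expect_true(any(grepl("verdict=identifiable", txt)))
  df <- read.csv(path, comment.char = "#")
  expect_identical(names(df),
                   c("parameter", "mean", "variance", "v", "bound_limited"))
})
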