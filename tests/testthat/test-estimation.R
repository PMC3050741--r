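test_that("chi-square matches hand-computed residual sums", {
  net <- toyDecay(k = 0.3, A0 = 10)
  des <- experimentDesign(samplingTimes = c(0, 1), fitMask = c(FALSE, TRUE))
  truth <- simulateNetwork(net, design = des)@outputs
  # single fitted point, residual of exactly 2 sigma
  sig <- matrix(0.5, 2, 1)
  obs <- truth; obs[2, 1] <- truth[2, 1] + 2 * 0.5
  ds <- makeDataset(c(0, 1), obs, sig, "yA")
  expect_equal(chiSquared(c(k = 0.3), net, des, ds), 4, tolerance = 1e-8)

  # two fitted points with residuals (1 sigma, 3 sigma): 1 + 9 = 10
  des2 <- experimentDesign(samplingTimes = c(0, 1, 2),
                           fitMask = c(FALSE, TRUE, TRUE))
  truth2 <- simulateNetwork(net, design = des2)@outputs
  sig2 <- matrix(0.5, 3, 1)
  obs2 <- truth2 + c(0, 1, 3) * 0.5
  ds2 <- makeDataset(c(0, 1, 2), obs2, sig2, "yA")
  expect_equal(chiSquared(c(k = 0.3), net, des2, ds2), 10, tolerance = 1e-8)

  # perfect agreement is exactly zero
  ds0 <- makeDataset(c(0, 1, 2), truth2, sig2, "yA")
  expect_lt(chiSquared(c(k = 0.3), net, des2, ds0), 1e-16)
})

test_that("chi-square is invariant under reordering of outputs", {
  net <- toyChain()
  des <- toyDesign()
  ds <- generateDataset(net, design = des, noiseMode = "gaussian", seed = 9)
  p <- c(k1 = 0.25, k2 = 0.2)
  v1 <- chiSquared(p, net, des, ds)

  # swap the two outputs in both the model and the data
  swapped <- buildNetwork(
    species = c(A = 10, B = 0, C = 0),
    reactions = reactionList(net),
    parameters = referenceParams(net),
    outputMap = outputMap(net)[2:1, ], name = "swapped")
  dsSwap <- makeDataset(ds@times, ds@observations[, 2:1], ds@sigmas[, 2:1],
                        ds@outputNames[2:1])
  expect_equal(chiSquared(p, swapped, des, dsSwap), v1, tolerance = 1e-10)
})

test_that("gradient vanishes at a perfect fit and matches finite differences", {
  net <- toyChain()
  des <- toyDesign()
  ds <- generateDataset(net, design = des, noiseMode = "noise_free")
  g0 <- chiSquaredGradient(referenceParams(net), net, des, ds)
  expect_lt(max(abs(g0)), 1e-6)

  # at a random point, compare to central FD of chi-square in log10 space
  p <- c(k1 = 0.21, k2 = 0.33)
  gan <- chiSquaredGradient(p, net, des, ds, space = "log10")
  h <- 1e-6
  lp <- log10(p)
  gfd <- vapply(1:2, function(i) {
    e <- c(0, 0); e[i] <- h
    (chiSquared(10^(lp + e), net, des, ds, rtol = 1e-12, atol = 1e-14) -
     chiSquared(10^(lp - e), net, des, ds, rtol = 1e-12, atol = 1e-14)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(gan - gfd)) / max(abs(gfd)), 1e-4)
})

test_that("gradient has a closed form for an output linear in the parameter", {
  # A' = k u(t) with u = 1 throughout: y(t) = k t, linear in k, so
  # dchi2/dk = -2 sum_j t_j (obs_j - k t_j) / sigma_j^2
  net <- buildNetwork(c(S = 1, A = 0),
                      list(reaction(c(S = 1), c(S = 1, A = 1), "k",
                                    inputModulated = TRUE)),
                      c(k = 2),
                      matrix(c(0, 1), 1, 2, dimnames = list("y", NULL)))
  des <- experimentDesign(input = inputSignal(1, 100),
                          samplingTimes = 0:5, fitMask = c(FALSE, rep(TRUE, 5)))
  tj <- 1:5
  obs <- matrix(c(0, 3 * tj), 6, 1)       # data generated by k = 3
  sig <- matrix(2, 6, 1)
  ds <- makeDataset(0:5, obs, sig, "y")
  k <- 2
  expected <- -2 * sum(tj * (3 * tj - k * tj) / 4)
  g <- chiSquaredGradient(c(k = k), net, des, ds, space = "linear")
  expect_equal(unname(g), expected, tolerance = 1e-6)
})

test_that("LHS sampling stratifies every dimension exactly", {
  b <- cbind(c(-2, 0), c(2, 4))
  for (n in c(1L, 7L, 10L)) {
    pts <- lhsSample(n, b, seed = 5)
    expect_equal(dim(pts), c(n, 2L))
    for (d in 1:2) {
      expect_true(all(pts[, d] > b[d, 1] & pts[, d] < b[d, 2]))
      strata <- floor((pts[, d] - b[d, 1]) / (b[d, 2] - b[d, 1]) * n)
      expect_setequal(strata, 0:(n - 1))   # one point per stratum
    }
  }
  expect_identical(lhsSample(10, b, seed = 5), lhsSample(10, b, seed = 5))
  expect_false(identical(lhsSample(10, b, seed = 5), lhsSample(10, b, seed = 6)))
  expect_error(lhsSample(5, cbind(c(1, 0), c(0, 1))), "bounds")
  expect_error(lhsSample(0, b), "nPoints")
})

test_that("a single fit recovers a one-parameter decay from a bad start", {
  net <- toyDecay(k = 0.3, A0 = 10)
  des <- experimentDesign(samplingTimes = 0:15,
                          fitMask = c(FALSE, rep(TRUE, 15)))
  ds <- generateDataset(net, design = des, noiseMode = "noise_free")
  bounds <- matrix(log10(0.3) + c(-2, 2), 1, 2)
  fit <- fitSingle(log10(0.3) + 1.4, net, des, ds, bounds)
  expect_true(fit@converged)
  expect_lt(abs(fit@estimate[["k"]] - 0.3) / 0.3, 1e-6)

  # starting exactly at the optimum stays there
  fit0 <- fitSingle(log10(0.3), net, des, ds, bounds)
  expect_true(fit0@converged)
  expect_lt(fit0@chi2, 1e-10)
})

test_that("integration failure inside a fit is recorded, not raised", {
  # autocatalysis A -> 2A explodes for large k; data come from a tame k
  net <- buildNetwork(c(A = 1, B = 0),
                      list(reaction(c(A = 1), c(A = 2), "k"),
                           reaction(c(A = 1), c(B = 1), "kout")),
                      c(k = 0.01, kout = 0.5),
                      matrix(c(0, 1), 1, 2, dimnames = list("y", NULL)))
  des <- experimentDesign(samplingTimes = 0:15,
                          fitMask = c(FALSE, rep(TRUE, 15)))
  ds <- generateDataset(net, design = des, noiseMode = "noise_free")
  bounds <- cbind(log10(c(0.01, 0.5)) - 12, log10(c(0.01, 0.5)) + 12)
  fit <- fitSingle(c(10, 0), net, des, ds, bounds)   # k = 1e10: blows up
  expect_s4_class(fit, "FitResult")
  expect_false(fit@converged)
})

test_that("multi-start estimation uses the documented box and finds the truth", {
  net <- toyChain(k1 = 0.3, k2 = 0.15)
  des <- toyDesign()
  ds <- generateDataset(net, design = des, noiseMode = "noise_free")
  ms <- multiStartFit(net, des, ds, referenceParams(net), nStarts = 20,
                      seed = 7)
  # default half width: two decades either side of the reference
  expect_equal(ms@boundsLog10[, 1], log10(c(0.3, 0.15)) - 2,
               ignore_attr = TRUE)
  expect_equal(ms@boundsLog10[, 2], log10(c(0.3, 0.15)) + 2,
               ignore_attr = TRUE)
  best <- bestFit(ms)
  expect_true(best@converged)
  expect_lt(max(abs(best@estimate - c(0.3, 0.15)) / c(0.3, 0.15)), 1e-6)

  # the running best over the first m starts is non-increasing in m
  chis <- vapply(ms@fits, function(f)
    if (f@converged && is.finite(f@chi2)) f@chi2 else Inf, numeric(1))
  expect_true(all(diff(cummin(chis)) <= 0))

  # determinism: same seed, same fits
  ms2 <- multiStartFit(net, des, ds, referenceParams(net), nStarts = 20,
                       seed = 7)
  expect_equal(vapply(ms2@fits, function(f) f@chi2, numeric(1)),
               vapply(ms@fits, function(f) f@chi2, numeric(1)))
})

test_that("fit report file has one row per start", {
  net <- toyDecay()
  des <- experimentDesign(samplingTimes = 0:10,
                          fitMask = c(FALSE, rep(TRUE, 10)))
  ds <- generateDataset(net, design = des, noiseMode = "noise_free")
  ms <- multiStartFit(net, des, ds, referenceParams(net), nStarts = 5, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFitReport(ms, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 5L)
  expect_true(all(c("start", "chi2", "converged", "estimate_k") %in% names(df)))
})
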