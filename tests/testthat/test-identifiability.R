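test_that("Gauss-Newton Hessian reduces to s^2/sigma^2 in the scalar case", {
  # linear-in-parameter model: y(t) = k t under constant input, so the
  # sensitivity at t is exactly t
  net <- buildNetwork(c(S = 1, A = 0),
                      list(reaction(c(S = 1), c(S = 1, A = 1), "k",
                                    inputModulated = TRUE)),
                      c(k = 2),
                      matrix(c(0, 1), 1, 2, dimnames = list("y", NULL)))
  des <- experimentDesign(input = inputSignal(1, 100), samplingTimes = c(0, 3),
                          fitMask = c(FALSE, TRUE))
  sig <- matrix(0.5, 2, 1)
  H <- gaussNewtonHessian(net, c(k = 2), des, sig, space = "linear")
  expect_equal(H@matrix[1, 1], 3^2 / 0.5^2, tolerance = 1e-6)
  expect_equal(H@eigenvalues, 36, tolerance = 1e-6)
})

test_that("Gauss-Newton equals the chi-square curvature at zero residual", {
  # at a zero-residual optimum the neglected second-order residual terms
  # vanish, so S^T W S equals the Hessian of chi^2 / 2 exactly
  net <- toyChain()
  des <- toyDesign()
  ds <- generateDataset(net, design = des, noiseMode = "noise_free")
  p <- referenceParams(net)
  H <- gaussNewtonHessian(net, p, des, ds, space = "log10")@matrix
  lp <- log10(p); h <- 1e-4; n <- length(p)
  f <- function(l) chiSquared(10^l, net, des, ds, rtol = 1e-12, atol = 1e-14)
  Hfd <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    e1 <- e2 <- rep(0, n); e1[i] <- h; e2[j] <- h
    Hfd[i, j] <- (f(lp + e1 + e2) - f(lp + e1 - e2) -
                  f(lp - e1 + e2) + f(lp - e1 - e2)) / (4 * h^2)
  }
  expect_lt(max(abs(H - Hfd / 2)) / max(abs(Hfd / 2)), 1e-3)
})

test_that("a duplicated rate constant produces an exact rank deficiency", {
  net <- toyChainDuplicated()
  des <- toyDesign()
  ds <- generateDataset(net, design = des, noiseMode = "noise_free")
  H <- gaussNewtonHessian(net, referenceParams(net), des, ds)
  expect_lt(abs(H@eigenvalues[1]), 1e-10 * sum(diag(H@matrix)))
  # eigenvalues come back ascending, matrix symmetric
  expect_true(all(diff(H@eigenvalues) >= 0))
  expect_equal(H@matrix, t(H@matrix))
})

test_that("ranking a diagonal Hessian is ascending in the diagonal", {
  d <- c(b = 5, a = 0.1, c = 100, d = 2)
  builder <- function(free) diag(d[free], nrow = length(free))
  rk <- identifiabilityRanking(builder, names(d))
  expect_identical(rk@order, names(sort(d)))
  expect_equal(rk@lambdaMin, unname(sort(d)))
  expect_setequal(rk@order, names(d))   # always a permutation
})

test_that("ranking follows the dominant component of the null eigenvector", {
  # constructed 3x3 with a known null direction dominated by parameter p2
  u <- c(0.2, 0.9, -0.37); u <- u / sqrt(sum(u^2))
  v1 <- c(1, 0, 0); v1 <- v1 - sum(v1 * u) * u; v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(u[2] * v1[3] - u[3] * v1[2],
          u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  V <- cbind(u, v1, v2)
  H <- V %*% diag(c(1e-12, 3, 7)) %*% t(V)
  dimnames(H) <- list(c("p1", "p2", "p3"), c("p1", "p2", "p3"))
  builder <- function(free) H[free, free, drop = FALSE]
  rk <- identifiabilityRanking(builder, rownames(H))
  expect_identical(rk@order[1], "p2")
  expect_equal(rk@dominantComponent[1], max(abs(u)), tolerance = 1e-8)
})

test_that("redundant parameters occupy the top ranking positions", {
  # two independent duplicated pairs -> two null directions; the first two
  # fixes must come from the union of the duplicates
  net <- buildNetwork(
    species = c(A = 10, B = 0, C = 0),
    reactions = list(reaction(c(A = 1), c(B = 1), "k1a"),
                     reaction(c(A = 1), c(B = 1), "k1b"),
                     reaction(c(B = 1), c(C = 1), "k2a"),
                     reaction(c(B = 1), c(C = 1), "k2b")),
    parameters = c(k1a = 0.15, k1b = 0.15, k2a = 0.07, k2b = 0.08),
    outputMap = matrix(c(0, 1, 0, 0, 0, 1), 2, 3, byrow = TRUE,
                       dimnames = list(c("yB", "yC"), NULL)),
    name = "double-dup")
  des <- toyDesign()
  ds <- generateDataset(net, design = des, noiseMode = "noise_free")
  rk <- rankParameters(net, referenceParams(net), des, ds)
  expect_true(all(rk@order[1:2] %in% c("k1a", "k1b", "k2a", "k2b")))
  # one from each pair, since fixing one duplicate resolves that pair
  expect_length(unique(substr(rk@order[1:2], 1, 2)), 2L)
})

test_that("ranking is invariant to declaration order up to the tie-break", {
  net <- toyChainDuplicated(k1a = 0.1, k1b = 0.2, k2 = 0.15)
  des <- toyDesign()
  ds <- generateDataset(net, design = des, noiseMode = "noise_free")
  rk <- rankParameters(net, referenceParams(net), des, ds)

  perm <- buildNetwork(
    species = c(A = 10, B = 0, C = 0),
    reactions = list(reaction(c(B = 1), c(C = 1), "k2"),
                     reaction(c(A = 1), c(B = 1), "k1b"),
                     reaction(c(A = 1), c(B = 1), "k1a")),
    parameters = c(k2 = 0.15, k1b = 0.2, k1a = 0.1),
    outputMap = matrix(c(0, 1, 0, 0, 0, 1), 2, 3, byrow = TRUE,
                       dimnames = list(c("yB", "yC"), NULL)),
    name = "permuted")
  dsP <- makeDataset(ds@times, ds@observations, ds@sigmas, ds@outputNames)
  rkP <- rankParameters(perm, referenceParams(perm), des, dsP)
  expect_identical(rk@order, rkP@order)
})

test_that("eigenvalue interlacing holds for principal submatrices", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    A <- matrix(rnorm(n * n), n)
    H <- crossprod(A)                     # random PSD
    dimnames(H) <- list(paste0("p", 1:n), paste0("p", 1:n))
    lmin <- min(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
    for (drop in 1:n) {
      sub <- H[-drop, -drop, drop = FALSE]
      lsub <- min(eigen(sub, symmetric = TRUE, only.values = TRUE)$values)
      expect_gte(lsub, lmin - 1e-10 * max(abs(H)))
    }
  }
})

test_that("ranking reports write the per-step eigen-diagnostics", {
  rk <- identifiabilityRanking(function(free)
    diag(setNames(seq_along(free), free), nrow = length(free)), c("a", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeRankingReport(rk, path)
  df <- read.csv(path)
  expect_identical(names(df),
                   c("step", "parameter", "lambda_min", "dominant_component"))
  expect_equal(nrow(df), 2L)
})
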