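# Workflow tests run with deliberately small multi-start counts; the
# statistical behaviour under study (termination, targeting, carry-over) is
# insensitive to the count for these well-conditioned toys.
smallConfig <- function(seed = 1L)
  workflowConfig(nStartsFit = 12, nStartsVariance = 40, masterSeed = seed)

test_that("an identifiable model terminates the iteration", {
  net <- toyChain()
  des <- toyDesign()
  ds <- generateDataset(net, design = des, noiseMode = "noise_free")
  rep <- runIteration(net, des, ds, config = smallConfig())
  expect_identical(rep@decision, "terminate")
  expect_identical(verdict(rep@variance), "identifiable")
  expect_lt(rep@best@chi2, 1e-4)
  expect_true(is.na(rep@target))
  expect_equal(rep@score$nData, 30)      # 2 outputs x 15 fitted times
})

test_that("a duplicated rate triggers a simplify decision against a duplicate", {
  dup <- toyChainDuplicated()
  des <- toyDesign()
  ds <- generateDataset(dup, design = des, noiseMode = "noise_free")
  rep <- runIteration(dup, des, ds, config = smallConfig())
  expect_identical(rep@decision, "simplify")
  expect_true(rep@target %in% c("k1a", "k1b"))
  # the target is the first ranking entry that violates the bound
  expect_identical(rep@target, rep@ranking@order[1])
})

test_that("a redundant-to-reduced model sequence runs to identifiability", {
  des <- toyDesign()
  dup <- toyChainDuplicated(k1a = 0.15, k1b = 0.15, k2 = 0.15)
  # the reduced model declares how the surviving rate maps onto its name
  red <- buildNetwork(
    species = c(A = 10, B = 0, C = 0),
    reactions = list(reaction(c(A = 1), c(B = 1), "k1"),
                     reaction(c(B = 1), c(C = 1), "k2")),
    parameters = c(k1 = 0.2, k2 = 0.1),   # deliberately off the truth
    outputMap = matrix(c(0, 1, 0, 0, 0, 1), 2, 3, byrow = TRUE,
                       dimnames = list(c("yB", "yC"), NULL)),
    name = "reduced", renames = c(k1a = "k1"))
  ds <- generateDataset(dup, design = des, noiseMode = "noise_free")
  res <- runWorkflow(list(dup, red), des, ds, config = smallConfig())

  expect_length(res$iterations, 2L)
  expect_identical(res$iterations[[1]]@decision, "simplify")
  expect_identical(res$iterations[[2]]@decision, "terminate")
  expect_true(res$identifiable)
  # the reduced model recovers the lumped rate k1 = k1a + k1b = 0.3
  est <- res$iterations[[2]]@best@estimate
  expect_lt(abs(est[["k1"]] - 0.3) / 0.3, 1e-4)
  # the identifiable model wins the information-criterion comparison
  sel <- res$selection
  expect_lt(sel$aicc[sel$model == "reduced"],
            sel$aicc[sel$model == "toy-chain-dup"])
  expect_gt(sel$weight[sel$model == "reduced"], 0.5)
  # smallest eigenvalue rises from the degenerate model to the reduced one
  expect_gt(res$iterations[[2]]@ranking@lambdaMin[1],
            res$iterations[[1]]@ranking@lambdaMin[1])
})

test_that("a single identifiable model ends the workflow in one iteration", {
  des <- toyDesign()
  net <- toyChain()
  res <- runWorkflow(list(net), des, config = smallConfig())
  expect_length(res$iterations, 1L)
  expect_true(res$identifiable)
})

test_that("workflow results are deterministic in config and master seed", {
  des <- toyDesign()
  net <- toyChain()
  ds <- generateDataset(net, design = des, noiseMode = "noise_free")
  r1 <- runWorkflow(list(net), des, ds, config = smallConfig(seed = 5L))
  r2 <- runWorkflow(list(net), des, ds, config = smallConfig(seed = 5L))
  expect_identical(r1$iterations[[1]]@best@estimate,
                   r2$iterations[[1]]@best@estimate)
  expect_identical(r1$selection, r2$selection)
  expect_identical(coefficientsOfVariation(r1$iterations[[1]]@variance),
                   coefficientsOfVariation(r2$iterations[[1]]@variance))
})

test_that("cli dispatches subcommands and signals usage errors", {
  expect_equal(cliMain(character()), 2L)
  expect_equal(suppressMessages(cliMain("frobnicate")), 2L)
  expect_equal(suppressMessages(cliMain(c("fit", "--model"))), 2L)
  expect_equal(suppressMessages(cliMain(c("fit", "--out", "x.csv"))), 1L)

  dir <- withr::local_tempdir()
  model <- file.path(dir, "decay.model")
  writeNetworkModel(toyDecay(), model)

  traj <- file.path(dir, "traj.csv")
  expect_equal(cliMain(c("simulate", "--model", model, "--out", traj)), 0L)
  expect_true(file.exists(traj))

  data <- file.path(dir, "data.csv")
  expect_equal(cliMain(c("generate-data", "--model", model, "--out", data,
                         "--noise", "gaussian", "--seed", "4")), 0L)
  ds <- readDataset(data)
  expect_length(ds@times, 16L)

  scores <- file.path(dir, "scores.csv")
  write.csv(data.frame(model = c("M5", "M6"), chi2 = c(7.6e-1, 7.6e-1),
                       nParams = c(11, 10)),
            scores, row.names = FALSE)
  sel <- file.path(dir, "sel.csv")
  expect_equal(cliMain(c("select", "--scores", scores, "--n-data", "60",
                         "--out", sel)), 0L)
  tab <- read.csv(sel)
  expect_equal(round(tab$aicc), c(28, 25))
})

test_that("cli workflow runs from a YAML config and writes reports", {
  dir <- withr::local_tempdir()
  dupPath <- file.path(dir, "dup.model")
  redPath <- file.path(dir, "red.model")
  writeNetworkModel(toyChainDuplicated(), dupPath)
  red <- buildNetwork(
    species = c(A = 10, B = 0, C = 0),
    reactions = list(reaction(c(A = 1), c(B = 1), "k1"),
                     reaction(c(B = 1), c(C = 1), "k2")),
    parameters = c(k1 = 0.3, k2 = 0.15),
    outputMap = matrix(c(0, 1, 0, 0, 0, 1), 2, 3, byrow = TRUE,
                       dimnames = list(c("yB", "yC"), NULL)),
    name = "reduced", renames = c(k1a = "k1"))
  writeNetworkModel(red, redPath)
  cfg <- file.path(dir, "wf.yml")
  writeLines(c("models:", "  - dup.model", "  - red.model",
               paste0("out_dir: ", file.path(dir, "reports")),
               "master_seed: 3", "n_starts_fit: 10", "n_starts_variance: 30"),
             cfg)
  expect_equal(cliMain(c("workflow", "--config", cfg)), 0L)
  out <- file.path(dir, "reports")
  expect_true(file.exists(file.path(out, "selection.csv")))
  expect_true(file.exists(file.path(out, "manifest.txt")))
  expect_true(file.exists(file.path(out, "toy-chain-dup_ranking.csv")))
  manifest <- readLines(file.path(out, "manifest.txt"))
  expect_true(any(grepl("master_seed 3", manifest)))
  expect_true(any(grepl("identifiable TRUE", manifest)))
})
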