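#' @include selection.R
NULL

#' Workflow configuration with the study defaults
#'
#' Collects the tunable parameters of the iterative reduction workflow. The
#' defaults are the study conditions of the JAK-STAT case: identifiability
#' bound vBar = 0.01 (estimates must agree to 1 percent), chi-square
#' acceptance significance 0.1 percent, 1000 starts for both the estimation
#' and the variance analysis, start boxes of +/- 2 decades around the
#' carried-over estimate for fitting and +/- 12 decades for the variance
#' analysis.
#'
#' @param vBar bound on the coefficients of variation
#' @param significance acceptance level for P(chi2 | dof)
#' @param nStartsFit multi-start count for parameter estimation
#' @param nStartsVariance multi-start count for the variance analysis
#' @param fitHalfWidthDecades half-width of the estimation start box (decades)
#' @param varianceHalfWidthDecades half-width of the variance-analysis box
#' @param masterSeed master seed; every stage derives its own substream
#' @param coverageFraction box-contact threshold for bound-limited flags
#' @param firstOrderTol,maxit,rtol,atol numerical controls for the fits
#' @return a named list
#' @export
workflowConfig <- function(vBar = 0.01, significance = 0.001,
                           nStartsFit = 1000, nStartsVariance = 1000,
                           fitHalfWidthDecades = 2,
                           varianceHalfWidthDecades = 12,
                           masterSeed = 1L, coverageFraction = 0.95,
                           firstOrderTol = 1e-4, maxit = 400,
                           rtol = 1e-10, atol = 1e-12) {
  stopifnot(vBar > 0, significance > 0, significance < 1,
            nStartsFit >= 1, nStartsVariance >= 1)
  list(vBar = vBar, significance = significance, nStartsFit = nStartsFit,
       nStartsVariance = nStartsVariance,
       fitHalfWidthDecades = fitHalfWidthDecades,
       varianceHalfWidthDecades = varianceHalfWidthDecades,
       masterSeed = as.integer(masterSeed),
       coverageFraction = coverageFraction,
       firstOrderTol = firstOrderTol, maxit = maxit,
       rtol = rtol, atol = atol)
}

#' One iteration of the model-reduction workflow
#'
#' Steps 1-3 for a single candidate model: multi-start estimation around the
#' reference parameters, identifiability ranking of the parameters at the
#' best estimate, and the variance analysis. The coefficients of variation
#' are examined in ranking order (least identifiable first); the first
#' parameter violating the bound - by v > vBar or by a bound-limited flag -
#' becomes the simplification target. The decision is "terminate" exactly
#' when the variance verdict is identifiable.
#'
#' @param network the candidate \linkS4class{ReactionNetwork}
#' @param design an \linkS4class{ExperimentDesign}
#' @param dataset the (shared) \linkS4class{Dataset}
#' @param referenceParams center of the estimation start box (typically the
#'   previous model's mapped estimate); defaults to the network's reference
#'   values
#' @param config list from \code{\link{workflowConfig}}
#' @return an \linkS4class{IterationReport}
#' @export
runIteration <- function(network, design, dataset,
                         referenceParams = NULL,
                         config = workflowConfig()) {
  if (is.null(referenceParams)) referenceParams <- network@parameters
  tag <- network@name
  ms <- multiStartFit(network, design, dataset,
                      referenceParams = referenceParams,
                      nStarts = config$nStartsFit,
                      halfWidthDecades = config$fitHalfWidthDecades,
                      seed = .subSeed(config$masterSeed, paste0("fit:", tag)),
                      firstOrderTol = config$firstOrderTol,
                      maxit = config$maxit,
                      rtol = config$rtol, atol = config$atol)
  if (is.na(ms@bestIndex))
    stop("iteration aborted for ", tag, ": no converged fit")
  best <- bestFit(ms)
  ranking <- rankParameters(network, best@estimate, design, dataset,
                            space = "log10",
                            rtol = config$rtol, atol = config$atol)
  variance <- runVarianceAnalysis(
    network, design, dataset, pHat = best@estimate,
    nStarts = config$nStartsVariance,
    halfWidthDecades = config$varianceHalfWidthDecades,
    significance = config$significance, vBar = config$vBar,
    seed = .subSeed(config$masterSeed, paste0("variance:", tag)),
    checkOrder = ranking@order,
    coverageFraction = config$coverageFraction,
    firstOrderTol = config$firstOrderTol, maxit = config$maxit,
    rtol = config$rtol, atol = config$atol)
  nData <- sum(design@fitMask) * nOutputs(network)
  score <- data.frame(model = tag, chi2 = best@chi2,
                      nParams = nParameters(network), nData = nData,
                      aic = aicScore(best@chi2, nParameters(network)),
                      aicc = aiccScore(best@chi2, nParameters(network), nData))
  terminate <- verdict(variance) == "identifiable"
  new("IterationReport", modelName = tag, best = best, ranking = ranking,
      variance = variance, score = score,
      decision = if (terminate) "terminate" else "simplify",
      target = if (terminate) NA_character_ else variance@limitingParameter)
}

setMethod("show", "IterationReport", function(object) {
  cat(sprintf("IterationReport '%s': chi2 = %.4g, verdict = %s, decision = %s",
              object@modelName, object@best@chi2, object@variance@verdict,
              object@decision))
  if (object@decision == "simplify")
    cat(sprintf(" (target %s)", object@target))
  cat("\n")
})

#' Run the iterative model-reduction workflow over a model sequence
#'
#' Applies \code{\link{runIteration}} to a user-supplied sequence of
#' candidate models (model simplification itself is human-in-the-loop: the
#' ranking only points at the part of the model to simplify, it does not
#' rewrite the model). Each iteration centers its estimation box on the
#' previous model's best estimate, mapped by name with the model's declared
#' renames; parameters new to a model start from its own reference values.
#' The loop stops early at the first identifiable model. A cross-model
#' selection table (AIC, AICc, differences, Akaike weights) over the visited
#' models is returned alongside the iteration reports.
#'
#' @param models list of \linkS4class{ReactionNetwork} (the candidate
#'   sequence) or character paths to model files
#' @param design an \linkS4class{ExperimentDesign}
#' @param dataset a \linkS4class{Dataset}; by default generated once,
#'   noise-free, from the first model's reference parameters
#' @param config list from \code{\link{workflowConfig}}
#' @return list with elements \code{iterations} (list of
#'   \linkS4class{IterationReport}), \code{selection} (data.frame), and
#'   \code{identifiable} (logical: did the sequence reach an identifiable
#'   model?)
#' @export
runWorkflow <- function(models, design, dataset = NULL,
                        config = workflowConfig()) {
  if (!length(models)) stop("runWorkflow: empty model sequence")
  models <- lapply(models, function(m)
    if (is.character(m)) readNetworkModel(m) else m)
  if (is.null(dataset))
    dataset <- generateDataset(models[[1L]], design = design,
                               noiseMode = "noise_free",
                               rtol = config$rtol, atol = config$atol)
  reports <- list()
  carried <- NULL
  for (k in seq_along(models)) {
    net <- models[[k]]
    ref <- referenceParams(net)
    if (!is.null(carried)) {
      mapped <- names(carried)
      ren <- net@renames
      if (length(ren)) mapped[match(names(ren), mapped)] <- ren
      hit <- match(names(ref), mapped)
      ref[!is.na(hit)] <- carried[hit[!is.na(hit)]]
    }
    rep <- runIteration(net, design, dataset, referenceParams = ref,
                        config = config)
    reports[[net@name]] <- rep
    carried <- rep@best@estimate
    if (rep@decision == "terminate") break
  }
  scores <- do.call(rbind, lapply(reports, function(r)
    r@score[, c("model", "chi2", "nParams")]))
  nData <- sum(design@fitMask) * nOutputs(models[[1L]])
  sel <- selectionTable(scores, nData = nData)
  identifiable <- reports[[length(reports)]]@decision == "terminate"
  if (!identifiable)
    message("model sequence exhausted without reaching an identifiable model")
  list(iterations = reports, selection = sel, identifiable = identifiable)
}
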