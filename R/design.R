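#' @include simulate.R
NULL

#' Construct an experiment design
#'
#' Bundles the stimulus, the sampling grid and the measurement-error model.
#' Standard deviations of synthetic observations are
#' \code{max(noiseFraction * y, sigmaFloor)} per point. \code{fitMask} marks
#' the sampling times that enter the chi-square objective; by default every
#' point is fitted.
#'
#' @param input an \linkS4class{InputSignal}
#' @param samplingTimes strictly increasing nonnegative times (min)
#' @param noiseFraction relative standard deviation (0.2 = 20 percent)
#' @param sigmaFloor absolute standard-deviation floor (nM)
#' @param fitMask logical over samplingTimes (default: all TRUE)
#' @return an \linkS4class{ExperimentDesign}
#' @export
experimentDesign <- function(input = inputSignal(1, 7), samplingTimes,
                             noiseFraction = 0.2, sigmaFloor = 1e-6,
                             fitMask = NULL) {
  if (is.null(fitMask)) fitMask <- rep(TRUE, length(samplingTimes))
  new("ExperimentDesign", input = input,
      samplingTimes = as.numeric(samplingTimes),
      noiseFraction = as.numeric(noiseFraction),
      sigmaFloor = as.numeric(sigmaFloor),
      fitMask = as.logical(fitMask))
}

#' The default early-JAK-STAT experiment design
#'
#' A unit pulse of interferon removed from the medium at t = 7 min, outputs
#' recorded every minute from t = 0 to 15 min, and 20 percent relative
#' standard deviation (typical of Western-blot quantification). The t = 0
#' point is recorded but excluded from fitting: every observable is zero
#' before stimulation (no phosphorylated or dimeric species exist), so its
#' relative standard deviation is undefined; with four outputs this leaves
#' n = 4 x 15 = 60 fitted data points.
#'
#' @return an \linkS4class{ExperimentDesign}
#' @examples
#' des <- defaultJakstatDesign()
#' length(des@samplingTimes); sum(des@fitMask)
#' @export
defaultJakstatDesign <- function() {
  experimentDesign(input = inputSignal(1, 7), samplingTimes = 0:15,
                   noiseFraction = 0.2, sigmaFloor = 1e-6,
                   fitMask = c(FALSE, rep(TRUE, 15)))
}

#' Generate a synthetic dataset from a model
#'
#' Simulates the network at the given parameters, records the outputs at the
#' design's sampling times, and attaches standard deviations
#' \code{sigma = max(noiseFraction * y, sigmaFloor)}. In \code{"noise_free"}
#' mode the observations are the exact simulated values and the sigmas act as
#' weights only (the replication mode for in-silico identifiability studies:
#' the generating parameters then have chi-square exactly zero). In
#' \code{"gaussian"} mode independent normal noise with the per-point sigma
#' is added, seeded and reproducible.
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @param params generating parameters (defaults to the network's reference
#'   values)
#' @param design an \linkS4class{ExperimentDesign}
#' @param noiseMode "noise_free" or "gaussian"
#' @param seed integer seed used in gaussian mode
#' @param rtol,atol integrator tolerances
#' @return a \linkS4class{Dataset}
#' @export
generateDataset <- function(network, params = referenceParams(network),
                            design, noiseMode = c("noise_free", "gaussian"),
                            seed = 1L, rtol = 1e-10, atol = 1e-12) {
  noiseMode <- match.arg(noiseMode)
  sim <- simulateNetwork(network, params, design, sensitivities = FALSE,
                         rtol = rtol, atol = atol)
  y <- sim@outputs
  sig <- pmax(design@noiseFraction * y, design@sigmaFloor)
  obs <- y
  if (noiseMode == "gaussian") {
    obs <- .withSeed(seed, {
      y + matrix(stats::rnorm(length(y), sd = as.numeric(sig)),
                 nrow(y), ncol(y))
    })
  }
  new("Dataset", times = design@samplingTimes, observations = obs,
      sigmas = sig, outputNames = colnames(y))
}

setMethod("show", "Dataset", function(object) {
  cat(sprintf("Dataset: %d time points x %d outputs (%s)\n",
              length(object@times), length(object@outputNames),
              paste(object@outputNames, collapse = ", ")))
})

#' Read / write datasets as CSV
#'
#' The file format is a comma-separated table with a \code{time} column, one
#' column per output and one \code{sigma_<output>} column per output; lines
#' starting with \code{#} are comments. \code{readDataset} validates that
#' times are strictly increasing and that no fitted use of the file can
#' divide by a zero sigma unless the caller masks those rows.
#'
#' @param dataset a \linkS4class{Dataset}
#' @param path file path
#' @return \code{readDataset}: a \linkS4class{Dataset};
#'   \code{writeDataset}: the path, invisibly
#' @rdname datasetIO
#' @export
writeDataset <- function(dataset, path) {
  sig <- dataset@sigmas
  colnames(sig) <- paste0("sigma_", dataset@outputNames)
  df <- data.frame(time = dataset@times, dataset@observations, sig,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname datasetIO
#' @export
readDataset <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time" %in% names(df)) stop("dataset file lacks a 'time' column")
  sigCols <- grep("^sigma_", names(df), value = TRUE)
  outNames <- sub("^sigma_", "", sigCols)
  if (!length(outNames) || !all(outNames %in% names(df)))
    stop("dataset file must pair every output column with a sigma_ column")
  t <- df$time
  if (anyDuplicated(t)) stop("duplicate time rows in dataset file")
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing")
  obs <- as.matrix(df[, outNames, drop = FALSE])
  sig <- as.matrix(df[, sigCols, drop = FALSE])
  if (any(sig < 0)) stop("negative sigma in dataset file")
  if (any(sig == 0 & t > 0))
    stop("zero sigma at a nonzero (fitted) time in dataset file")
  colnames(sig) <- outNames
  new("Dataset", times = t, observations = obs, sigmas = sig,
      outputNames = outNames)
}
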