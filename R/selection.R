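#' @include variance.R
NULL

#' Akaike information criterion for chi-square fits
#'
#' For weighted least-squares (chi-square) estimation the log-likelihood is
#' \eqn{\ln L = C - \chi^2/2} with a model-independent constant C, so up to
#' that constant \eqn{AIC = \chi^2 + 2 n_p}.
#'
#' @param chi2 chi-square value of the best fit
#' @param nParams number of estimated parameters
#' @return the AIC value (constant C dropped)
#' @examples
#' aicScore(7.6e-1, 10)   # 20.76
#' @export
aicScore <- function(chi2, nParams) {
  if (any(chi2 < 0)) stop("chi2 must be nonnegative")
  if (any(nParams < 0)) stop("nParams must be nonnegative")
  chi2 + 2 * nParams
}

#' Small-sample corrected AIC (AICc)
#'
#' The Hurvich-Tsai correction for small data sets:
#' \deqn{AICc = AIC + \frac{2 n_p (n_p + 1)}{n - n_p - 1},}
#' which penalizes complexity more strongly when the number of data points n
#' is not large relative to the number of parameters.
#'
#' @param chi2 chi-square value of the best fit
#' @param nParams number of estimated parameters
#' @param nData number of fitted data points; must exceed nParams + 1
#' @return the AICc value
#' @examples
#' aiccScore(8.7e-6, 23, 60)   # 76.67, rounds to 77
#' @export
aiccScore <- function(chi2, nParams, nData) {
  if (any(nData - nParams - 1 <= 0))
    stop("AICc requires nData > nParams + 1")
  aicScore(chi2, nParams) + 2 * nParams * (nParams + 1) / (nData - nParams - 1)
}

#' Model-selection table: AIC, AICc, differences and Akaike weights
#'
#' For a set of candidate models with best-fit chi-square values and
#' parameter counts, computes AIC, AICc, the AICc differences
#' \eqn{\Delta_k = AICc_k - \min_j AICc_j} and the Akaike weights
#' \eqn{w_k = \exp(-\Delta_k/2) / \sum_j \exp(-\Delta_j/2)}, interpretable
#' as the probability that model k is the best of the set. Differences and
#' weights are computed on unrounded AICc values.
#'
#' @param entries data.frame with columns \code{model}, \code{chi2},
#'   \code{nParams} (one row per candidate model)
#' @param nData number of fitted data points, common to all candidates
#' @return data.frame with columns model, chi2, nParams, aic, aicc, delta,
#'   weight
#' @examples
#' tab <- selectionTable(data.frame(
#'   model = c("M5", "M6"), chi2 = c(7.6e-1, 7.6e-1), nParams = c(11, 10)),
#'   nData = 60)
#' round(tab$aicc)
#' @export
selectionTable <- function(entries, nData) {
  req <- c("model", "chi2", "nParams")
  if (!all(req %in% names(entries)))
    stop("entries must have columns model, chi2, nParams")
  if (nrow(entries) < 1L) stop("need at least one model")
  aic <- aicScore(entries$chi2, entries$nParams)
  aicc <- aiccScore(entries$chi2, entries$nParams, nData)
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  data.frame(model = entries$model, chi2 = entries$chi2,
             nParams = entries$nParams, aic = aic, aicc = aicc,
             delta = delta, weight = w)
}

#' Write a model-selection table to CSV
#'
#' @param table a data.frame from \code{\link{selectionTable}}
#' @param path output file
#' @return the path, invisibly
#' @export
writeSelectionTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
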