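#' @include identifiability.R
NULL

#' Lower-tail chi-square probability P(chi2 | dof)
#'
#' The probability that a chi-square variable with \code{dof} degrees of
#' freedom is less than the observed value - the acceptance statistic for
#' multi-start estimates: a fit is acceptable when this probability is small
#' (the observed chi-square sits far into the lower tail expected of a
#' correct model).
#'
#' @param chi2 observed chi-square value(s), nonnegative
#' @param dof degrees of freedom, positive integer (number of fitted data
#'   points minus number of parameters)
#' @return lower-tail probability in [0, 1]
#' @examples
#' chi2TailProbability(2 * log(2), 2)  # the median of chi-square with 2 dof
#' @export
chi2TailProbability <- function(chi2, dof) {
  if (dof <= 0)
    stop("dof must be positive (model has at least as many parameters as fitted points?)")
  if (any(chi2 < 0)) stop("chi2 must be nonnegative")
  stats::pchisq(chi2, df = dof)
}

#' Filter multi-start estimates by the chi-square acceptance test
#'
#' Keeps the converged fits whose chi-square has lower-tail probability at
#' most \code{significance} (default 0.1 percent) and returns their
#' estimates as the columns of the matrix Q used by the variance analysis.
#'
#' @param multistart a \linkS4class{MultiStartResult}
#' @param dof degrees of freedom of the chi-square reference distribution
#' @param significance acceptance level for P(chi2 | dof)
#' @return matrix (n_p x n_accept) of accepted estimates, linear space;
#'   an error is raised when no estimate is accepted
#' @export
acceptEstimates <- function(multistart, dof, significance = 0.001) {
  conv <- Filter(function(f) f@converged && is.finite(f@chi2),
                 multistart@fits)
  if (!length(conv)) stop("acceptEstimates: no converged fits to filter")
  keep <- Filter(function(f)
    chi2TailProbability(f@chi2, dof) <= significance, conv)
  if (!length(keep))
    stop(sprintf(
      "acceptEstimates: no estimate accepted at significance %g (best P = %.3g)",
      significance,
      min(vapply(conv, function(f) chi2TailProbability(f@chi2, dof),
                 numeric(1)))))
  Q <- vapply(keep, function(f) f@estimate,
              numeric(length(multistart@parameterNames)))
  Q <- matrix(Q, nrow = length(multistart@parameterNames),
              dimnames = list(multistart@parameterNames, NULL))
  Q
}

#' Variance analysis of accepted estimates
#'
#' Computes per-parameter means \eqn{\bar p_i}, sample variances
#' \eqn{\sigma^2(p_i) = \sum_j (Q_{ij} - \bar p_i)^2 / (n_{accept} - 1)} and
#' scale-invariant coefficients of variation \eqn{v(p_i) = \sigma(p_i)/\bar
#' p_i} on the linear-scale estimates. A parameter is flagged
#' \code{boundLimited} when its accepted estimates approach the sampling-box
#' boundary (within \code{1 - coverageFraction} of the log10 box width of
#' either edge): the box then truncated the estimate spread, so v is only a
#' lower bound on the true coefficient of variation - enough to conclude
#' non-identifiability, never identifiability. Verdict: identifiable iff all
#' v are at most vBar and no parameter is bound-limited.
#'
#' @param Q matrix (n_p x n_accept) of accepted estimates, linear space
#' @param boundsLog10 matrix (n_p x 2) log10 sampling box the estimates came
#'   from
#' @param vBar upper bound on acceptable coefficients of variation
#' @param nTotal number of multi-start fits the estimates were selected from
#' @param checkOrder order in which parameters are examined for the limiting
#'   parameter (default: row order of Q); pass the identifiability ranking
#'   order to mirror the workflow's step 3
#' @param coverageFraction box-contact threshold for the boundLimited flag
#' @return a \linkS4class{VarianceReport}
#' @examples
#' Q <- matrix(c(9, 11), 1, 2, dimnames = list("k", NULL))
#' b <- matrix(c(log10(10) - 12, log10(10) + 12), 1, 2)
#' rep <- varianceReport(Q, b, vBar = 0.01, nTotal = 2)
#' rep@means; rep@variances; rep@cv   # 10, 2, sqrt(2)/10
#' @export
varianceReport <- function(Q, boundsLog10, vBar = 0.01, nTotal = ncol(Q),
                           checkOrder = NULL, coverageFraction = 0.95) {
  Q <- as.matrix(Q)
  if (ncol(Q) < 2L)
    stop("varianceReport: need at least 2 accepted estimates")
  pn <- rownames(Q)
  if (is.null(pn)) pn <- paste0("p", seq_len(nrow(Q)))
  rownames(Q) <- pn
  means <- rowMeans(Q)
  variances <- apply(Q, 1L, stats::var)        # n - 1 denominator
  cv <- sqrt(variances) / means
  lo <- boundsLog10[, 1L]; hi <- boundsLog10[, 2L]
  margin <- (1 - coverageFraction) * (hi - lo)
  lq <- log10(Q)
  boundLimited <- structure(
    (apply(lq, 1L, min) <= lo + margin) |
    (apply(lq, 1L, max) >= hi - margin),
    names = pn)
  if (is.null(checkOrder)) checkOrder <- pn
  bad <- checkOrder[cv[checkOrder] > vBar | boundLimited[checkOrder]]
  verdict <- if (length(bad)) "not_identifiable" else "identifiable"
  new("VarianceReport", Q = Q, nTotal = as.integer(nTotal),
      nAccept = ncol(Q), means = means, variances = variances, cv = cv,
      boundLimited = boundLimited, verdict = verdict,
      limitingParameter = if (length(bad)) bad[1L] else NA_character_,
      parameterNames = pn, vBar = vBar)
}

#' Run the full variance-based identifiability analysis
#'
#' Step 3 of the reduction workflow: a delocalized multi-start estimation
#' inside the wide box \code{pHat * 10^(+/- halfWidthDecades)} (default 12
#' decades), acceptance of the converged estimates by the chi-square tail
#' test at the given significance, and the variance report with verdict. The
#' degrees of freedom are the number of fitted data points minus the number
#' of parameters.
#'
#' @param network,design,dataset the estimation problem
#' @param pHat the estimate from a prior multi-start fit (box center)
#' @param nStarts number of starting points
#' @param halfWidthDecades half-width of the sampling box, decades
#' @param significance acceptance level for P(chi2 | dof)
#' @param vBar identifiability bound on the coefficients of variation
#' @param seed seed for the start sample
#' @param checkOrder parameter order for reporting the limiting parameter
#'   (e.g. the identifiability ranking)
#' @param coverageFraction see \code{\link{varianceReport}}
#' @param firstOrderTol,maxit,rtol,atol passed to the fits
#' @return a \linkS4class{VarianceReport}
#' @export
runVarianceAnalysis <- function(network, design, dataset, pHat,
                                nStarts = 1000, halfWidthDecades = 12,
                                significance = 0.001, vBar = 0.01,
                                seed = 1L, checkOrder = NULL,
                                coverageFraction = 0.95,
                                firstOrderTol = 1e-4, maxit = 400,
                                rtol = 1e-10, atol = 1e-12) {
  dof <- sum(design@fitMask) * nOutputs(network) - nParameters(network)
  if (dof <= 0)
    stop("nonpositive degrees of freedom: more parameters than fitted points")
  ms <- multiStartFit(network, design, dataset, referenceParams = pHat,
                      nStarts = nStarts, halfWidthDecades = halfWidthDecades,
                      seed = seed, firstOrderTol = firstOrderTol,
                      maxit = maxit, rtol = rtol, atol = atol)
  Q <- acceptEstimates(ms, dof = dof, significance = significance)
  varianceReport(Q, ms@boundsLog10, vBar = vBar, nTotal = length(ms@fits),
                 checkOrder = checkOrder, coverageFraction = coverageFraction)
}

#' @rdname accessors
#' @export
setMethod("verdict", "VarianceReport", function(x) x@verdict)

#' @rdname accessors
#' @export
setMethod("coefficientsOfVariation", "VarianceReport", function(x) x@cv)

#' @rdname accessors
#' @export
setMethod("acceptedEstimates", "VarianceReport", function(x) x@Q)

setMethod("show", "VarianceReport", function(object) {
  cat(sprintf("VarianceReport: %d/%d estimates accepted, verdict = %s\n",
              object@nAccept, object@nTotal, object@verdict))
  if (!is.na(object@limitingParameter))
    cat(sprintf("  limiting parameter: %s (v = %.3g%s)\n",
                object@limitingParameter,
                object@cv[object@limitingParameter],
                if (object@boundLimited[match(object@limitingParameter,
                                              object@parameterNames)])
                  ", bound-limited: v is a lower bound" else ""))
  cat(sprintf("  max v = %.3g (bound vBar = %g)\n",
              max(object@cv), object@vBar))
})

#' Write a variance report to CSV
#'
#' One row per parameter (mean, variance, v, bound-limited flag) plus a
#' trailing comment line with the verdict and acceptance counts.
#'
#' @param report a \linkS4class{VarianceReport}
#' @param path output file
#' @return the path, invisibly
#' @export
writeVarianceReport <- function(report, path) {
  df <- data.frame(parameter = report@parameterNames,
                   mean = report@means, variance = report@variances,
                   v = report@cv, bound_limited = as.integer(report@boundLimited))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  cat(sprintf("# verdict=%s n_accept=%d n_total=%d vBar=%g\n",
              report@verdict, report@nAccept, report@nTotal, report@vBar),
      file = path, append = TRUE)
  invisible(path)
}
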