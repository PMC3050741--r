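#' @include design.R
NULL

# Objective factory: builds chi-square and gradient evaluators over log10
# parameters on a compiled network, with a one-slot cache so optim's fn/gr
# pairs reuse a single sensitivity integration.
.makeObjective <- function(network, design, dataset, rtol = 1e-10,
                           atol = 1e-12) {
  .checkDesignData(design, dataset)
  cn <- .compileNetwork(network)
  x0 <- network@initialState
  mask <- design@fitMask
  obs <- dataset@observations[mask, , drop = FALSE]
  sig <- dataset@sigmas[mask, , drop = FALSE]
  np <- cn$np
  ln10 <- log(10)
  cache <- new.env(parent = emptyenv())
  cache$key <- NULL
  cache$nEvals <- 0L

  evalAt <- function(lp, needGrad) {
    key <- paste(c(needGrad, sprintf("%.17g", lp)), collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    # a gradient evaluation also serves later plain evaluations at the point
    if (!needGrad && !is.null(cache$key) &&
        identical(sub("^TRUE", "FALSE", cache$key), key))
      return(cache$val)
    p <- 10^lp
    val <- tryCatch({
      sim <- .simulateCompiled(cn, x0, p, design, sensitivities = needGrad,
                               rtol = rtol, atol = atol, maxsteps = 5000,
                               quiet = TRUE)
      y <- sim@outputs[mask, , drop = FALSE]
      res <- (obs - y) / sig
      chi2 <- sum(res * res)
      grad <- NULL
      if (needGrad) {
        grad <- numeric(np)
        sens <- sim@sensitivities
        for (k in seq_len(np)) {
          dy <- sens[mask, , k, drop = FALSE]
          dim(dy) <- dim(res)
          grad[k] <- -2 * sum(res / sig * dy)
        }
        grad <- grad * ln10 * p          # chain rule into log10 space
      }
      list(chi2 = chi2, grad = grad, ok = TRUE)
    }, error = function(e) list(chi2 = NA_real_, grad = NULL, ok = FALSE,
                                message = conditionMessage(e)))
    cache$key <- key
    cache$val <- val
    cache$nEvals <- cache$nEvals + 1L
    val
  }

  list(
    chi2 = function(lp) evalAt(lp, FALSE),
    chi2grad = function(lp) evalAt(lp, TRUE),
    evals = function() cache$nEvals
  )
}

#' Chi-square objective of a parameter vector
#'
#' The weighted least-squares objective
#' \deqn{\chi^2(p) = \sum_i \sum_j \left(\frac{\tilde y_i(t_j) - y_i(t_j, p)}
#' {\sigma_{ij}}\right)^2,}
#' summed over the design's fitted points only. Under independent Gaussian
#' noise its minimizer is the maximum-likelihood estimate.
#'
#' @param params rate parameters, linear space
#' @param network a \linkS4class{ReactionNetwork}
#' @param design an \linkS4class{ExperimentDesign}
#' @param dataset a \linkS4class{Dataset} on the design's time grid
#' @param rtol,atol integrator tolerances
#' @return the chi-square value (nonnegative); integration failures raise an
#'   error identifying the failing evaluation
#' @export
chiSquared <- function(params, network, design, dataset,
                       rtol = 1e-10, atol = 1e-12) {
  params <- .checkParams(network, params)
  obj <- .makeObjective(network, design, dataset, rtol, atol)
  v <- obj$chi2(log10(params))
  if (!v$ok) stop("chi-square evaluation failed: ", v$message)
  v$chi2
}

#' Gradient of the chi-square objective
#'
#' Computed from forward sensitivities:
#' \eqn{\partial\chi^2/\partial p_k = -2 \sum_{ij} (r_{ij}/\sigma_{ij})
#' \partial y_i(t_j)/\partial p_k / \sigma_{ij}} with residuals
#' \eqn{r_{ij} = \tilde y_i(t_j) - y_i(t_j,p)}. With \code{space = "log10"}
#' the chain rule \eqn{\partial/\partial \log_{10} p_k = \ln(10) p_k
#' \partial/\partial p_k} is applied (the space the estimation runs in).
#'
#' @inheritParams chiSquared
#' @param space "linear" or "log10"
#' @return named gradient vector over the parameters
#' @export
chiSquaredGradient <- function(params, network, design, dataset,
                               space = c("linear", "log10"),
                               rtol = 1e-10, atol = 1e-12) {
  space <- match.arg(space)
  params <- .checkParams(network, params)
  obj <- .makeObjective(network, design, dataset, rtol, atol)
  v <- obj$chi2grad(log10(params))
  if (!v$ok) stop("chi-square gradient evaluation failed: ", v$message)
  g <- v$grad
  if (space == "linear") g <- g / (log(10) * params)
  names(g) <- parameterNames(network)
  g
}

#' Latin Hypercube sample in log10-parameter space
#'
#' Stratified sampling: in every dimension the n points occupy the n
#' equal-width strata of [lo, hi] exactly once, giving delocalized coverage
#' of a box spanning several orders of magnitude.
#'
#' @param nPoints number of sample points (>= 1)
#' @param boundsLog10 matrix (n_p x 2) of per-dimension (lo, hi) in log10
#'   units; rownames, if any, name the parameters
#' @param seed integer seed; the same seed reproduces the same design
#' @return matrix (nPoints x n_p) of log10-space sample points
#' @export
lhsSample <- function(nPoints, boundsLog10, seed = 1L) {
  boundsLog10 <- as.matrix(boundsLog10)
  if (ncol(boundsLog10) != 2L) stop("boundsLog10 must be an n_p x 2 matrix")
  lo <- boundsLog10[, 1L]; hi <- boundsLog10[, 2L]
  if (any(!(lo < hi))) stop("invalid bounds: need lo < hi in every dimension")
  if (nPoints < 1L) stop("nPoints must be >= 1")
  unit <- .withSeed(seed, lhs::randomLHS(as.integer(nPoints), nrow(boundsLog10)))
  pts <- sweep(sweep(unit, 2L, hi - lo, "*"), 2L, lo, "+")
  colnames(pts) <- rownames(boundsLog10)
  pts
}

#' One local gradient-based fit in log10-parameter space
#'
#' Runs a bounded quasi-Newton minimization (L-BFGS-B) of the chi-square
#' objective over log10 parameters, using the analytic sensitivity-based
#' gradient. The fit is marked converged only when the optimizer terminated
#' normally and the projected gradient (gradient components pointing into the
#' active box bounds are zeroed) satisfies the first-order tolerance. Failed
#' integrations during the search are treated as rejected steps via a large
#' finite penalty; a failure at the returned point yields
#' \code{converged = FALSE} with the diagnostic recorded. Errors never
#' propagate out of the fit.
#'
#' @param startLog10 start point, log10 units, inside the bounds
#' @param network,design,dataset the estimation problem
#' @param boundsLog10 matrix (n_p x 2) box bounds in log10 units
#' @param firstOrderTol max-norm bound on the projected log10-space gradient
#'   for declaring convergence
#' @param maxit iteration cap for the optimizer
#' @param rtol,atol integrator tolerances
#' @return a \linkS4class{FitResult} (estimate in linear space)
#' @export
fitSingle <- function(startLog10, network, design, dataset, boundsLog10,
                      firstOrderTol = 1e-4, maxit = 400,
                      rtol = 1e-10, atol = 1e-12) {
  obj <- .makeObjective(network, design, dataset, rtol, atol)
  penalty <- 1e12
  fn <- function(lp) {
    v <- obj$chi2(lp)
    if (!v$ok || !is.finite(v$chi2)) penalty else v$chi2
  }
  gr <- function(lp) {
    v <- obj$chi2grad(lp)
    if (!v$ok || is.null(v$grad) || any(!is.finite(v$grad)))
      rep(0, length(lp)) else v$grad
  }
  lo <- boundsLog10[, 1L]; hi <- boundsLog10[, 2L]
  res <- tryCatch(
    stats::optim(par = pmin(pmax(startLog10, lo), hi), fn = fn, gr = gr,
                 method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = maxit, factr = 10, pgtol = 0)),
    error = function(e) NULL)
  pn <- parameterNames(network)
  if (is.null(res)) {
    return(new("FitResult", startLog10 = startLog10,
               estimate = structure(10^startLog10, names = pn),
               chi2 = NA_real_, converged = FALSE,
               firstOrderNorm = NA_real_, nEvals = obj$evals(),
               message = "optimizer error"))
  }
  lp <- res$par
  v <- obj$chi2grad(lp)
  if (!v$ok) {
    return(new("FitResult", startLog10 = startLog10,
               estimate = structure(10^lp, names = pn), chi2 = NA_real_,
               converged = FALSE, firstOrderNorm = NA_real_,
               nEvals = obj$evals(),
               message = paste("evaluation failed at solution:",
                               v$message %||% "")))
  }
  g <- v$grad
  eps <- 1e-10 * pmax(1, abs(hi - lo))
  atLo <- lp <= lo + eps; atHi <- lp >= hi - eps
  g[atLo & g > 0] <- 0
  g[atHi & g < 0] <- 0
  fon <- max(abs(g))
  new("FitResult", startLog10 = startLog10,
      estimate = structure(10^lp, names = pn), chi2 = v$chi2,
      converged = (res$convergence == 0L) && fon <= firstOrderTol,
      firstOrderNorm = fon, nEvals = obj$evals(),
      message = if (is.null(res$message)) "" else res$message)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Delocalized multi-start maximum-likelihood estimation
#'
#' Samples \code{nStarts} starting points by Latin Hypercube sampling inside
#' the log10 box \code{reference * 10^(+/- halfWidthDecades)} (the default of
#' two decades spans four orders of magnitude around the reference values)
#' and runs an independent local fit from each. The best fit is the converged
#' one with minimal chi-square. Results are deterministic given the seed and
#' independent of evaluation order (fits are indexed by start).
#'
#' @param network,design,dataset the estimation problem
#' @param referenceParams positive reference values the sampling box is
#'   centered on (log10 scale)
#' @param nStarts number of starting points (>= 1)
#' @param halfWidthDecades half-width of the sampling box in decades
#' @param seed master seed for the start sample
#' @param firstOrderTol,maxit,rtol,atol passed to \code{\link{fitSingle}}
#' @return a \linkS4class{MultiStartResult}; if no start converged the result
#'   carries \code{bestIndex = NA} and a warning is raised
#' @export
multiStartFit <- function(network, design, dataset, referenceParams,
                          nStarts = 1000, halfWidthDecades = 2, seed = 1L,
                          firstOrderTol = 1e-4, maxit = 400,
                          rtol = 1e-10, atol = 1e-12) {
  referenceParams <- .checkParams(network, referenceParams)
  pn <- parameterNames(network)
  bounds <- cbind(log10(referenceParams) - halfWidthDecades,
                  log10(referenceParams) + halfWidthDecades)
  rownames(bounds) <- pn
  colnames(bounds) <- c("lo", "hi")
  starts <- lhsSample(nStarts, bounds, seed = .subSeed(seed, "lhs-starts"))
  fits <- vector("list", nStarts)
  for (i in seq_len(nStarts)) {
    fits[[i]] <- fitSingle(starts[i, ], network, design, dataset, bounds,
                           firstOrderTol = firstOrderTol, maxit = maxit,
                           rtol = rtol, atol = atol)
  }
  conv <- vapply(fits, function(f) f@converged && is.finite(f@chi2), logical(1))
  bestIndex <- if (any(conv)) {
    ci <- which(conv)
    ci[which.min(vapply(fits[ci], function(f) f@chi2, numeric(1)))]
  } else {
    warning("multiStartFit: no start converged")
    NA_integer_
  }
  new("MultiStartResult", fits = fits, bestIndex = as.integer(bestIndex),
      boundsLog10 = bounds, parameterNames = pn, seed = as.integer(seed))
}

#' @rdname accessors
#' @export
setMethod("bestFit", "MultiStartResult", function(x) {
  if (is.na(x@bestIndex))
    stop("no converged fit in this MultiStartResult")
  x@fits[[x@bestIndex]]
})

setMethod("show", "MultiStartResult", function(object) {
  conv <- sum(vapply(object@fits, function(f) f@converged, logical(1)))
  cat(sprintf("MultiStartResult: %d starts, %d converged", length(object@fits), conv))
  if (!is.na(object@bestIndex))
    cat(sprintf(", best chi2 = %.4g", object@fits[[object@bestIndex]]@chi2))
  cat("\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: chi2 = %.6g, converged = %s, |proj grad| = %.3g\n",
              object@chi2, object@converged, object@firstOrderNorm))
})

#' Write a multi-start fit report to CSV
#'
#' One row per start: the start point (log10), the estimate (linear), the
#' chi-square value and the convergence flag.
#'
#' @param multistart a \linkS4class{MultiStartResult}
#' @param path output file
#' @return the path, invisibly
#' @export
writeFitReport <- function(multistart, path) {
  pn <- multistart@parameterNames
  rows <- lapply(seq_along(multistart@fits), function(i) {
    f <- multistart@fits[[i]]
    c(start = i, setNames(f@startLog10, paste0("start_log10_", pn)),
      setNames(f@estimate, paste0("estimate_", pn)),
      chi2 = f@chi2, converged = as.integer(f@converged))
  })
  df <- as.data.frame(do.call(rbind, rows))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
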