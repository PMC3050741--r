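#' @import methods
NULL

#' Reaction: a single mass-action reaction
#'
#' A reaction converts a multiset of reactant species into a multiset of
#' product species with a rate constant named by \code{rate}. The rate follows
#' mass-action kinetics, \eqn{r = k \prod_s x_s^{\nu_s}}, optionally multiplied
#' by the time-varying input \eqn{u(t)} when \code{inputModulated} is set
#' (used to model a stimulus, e.g. a ligand pulse, without carrying the ligand
#' as a state variable). Total reactant order is restricted to 1 or 2
#' (at most bimolecular).
#'
#' @slot reactants named integer vector, species name -> stoichiometry
#' @slot products named integer vector, species name -> stoichiometry
#' @slot rate single character, the name of the rate parameter
#' @slot inputModulated logical, multiply the rate by the input signal u(t)?
#' @exportClass Reaction
setClass("Reaction",
  representation(
    reactants      = "integer",
    products       = "integer",
    rate           = "character",
    inputModulated = "logical"
  ),
  prototype(inputModulated = FALSE)
)

setValidity("Reaction", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || !nzchar(object@rate))
    msg <- c(msg, "rate must be a single non-empty parameter name")
  if (length(object@reactants) &&
      (is.null(names(object@reactants)) || any(!nzchar(names(object@reactants)))))
    msg <- c(msg, "reactants must be a named integer vector")
  if (length(object@products) &&
      (is.null(names(object@products)) || any(!nzchar(names(object@products)))))
    msg <- c(msg, "products must be a named integer vector")
  if (any(object@reactants <= 0L) || any(object@products <= 0L))
    msg <- c(msg, "stoichiometric coefficients must be positive integers")
  ord <- sum(object@reactants)
  if (ord < 1L || ord > 2L)
    msg <- c(msg, sprintf(
      "total reactant order must be 1 or 2 (mass action, at most bimolecular), got %d", ord))
  if (length(object@inputModulated) != 1L)
    msg <- c(msg, "inputModulated must be a single logical")
  if (length(msg)) msg else TRUE
})

#' ReactionNetwork: a mass-action ODE reaction network with linear outputs
#'
#' Represents a kinetic model \eqn{\dot x = f(x, p, u)}, \eqn{y = C x}: an
#' ordered species list with initial concentrations (nM), mass-action
#' reactions referencing named rate parameters, and a linear output map
#' \eqn{C} (one row per observable, one column per species). Species and
#' parameter order is declaration order and is preserved in every vector and
#' matrix derived from the network, so that eigenvector components, sampling
#' designs and reports are reproducibly indexed.
#'
#' @slot name model name
#' @slot species ordered character vector of species names
#' @slot initialState named numeric, initial concentrations (nM), in species order
#' @slot reactions list of \linkS4class{Reaction}
#' @slot parameters named numeric, reference values of the rate parameters
#'   (min^-1 for first order, nM^-1 min^-1 for second order), in declaration
#'   order
#' @slot outputMap numeric matrix (n_y x n_x) of nonnegative coefficients;
#'   rownames are output names, columns follow species order
#' @slot renames named character; maps parameter names of a predecessor model
#'   onto this model's names (old -> new), used when carrying estimates across
#'   a model-reduction step
#' @exportClass ReactionNetwork
setClass("ReactionNetwork",
  representation(
    name         = "character",
    species      = "character",
    initialState = "numeric",
    reactions    = "list",
    parameters   = "numeric",
    outputMap    = "matrix",
    renames      = "character"
  ),
  prototype(name = "network", renames = character())
)

setValidity("ReactionNetwork", function(object) {
  msg <- character()
  sp <- object@species
  if (anyDuplicated(sp))
    msg <- c(msg, sprintf("duplicate species name: %s",
                          paste(unique(sp[duplicated(sp)]), collapse = ", ")))
  if (length(object@initialState) != length(sp) ||
      !identical(names(object@initialState), sp))
    msg <- c(msg, "initialState must be named exactly like (and ordered as) species")
  if (any(object@initialState < 0))
    msg <- c(msg, "initial concentrations must be nonnegative")
  pn <- names(object@parameters)
  if (anyDuplicated(pn))
    msg <- c(msg, sprintf("duplicate parameter name: %s",
                          paste(unique(pn[duplicated(pn)]), collapse = ", ")))
  if (any(object@parameters <= 0))
    msg <- c(msg, "rate parameters must be positive")
  used <- character()
  for (i in seq_along(object@reactions)) {
    rx <- object@reactions[[i]]
    if (!is(rx, "Reaction")) {
      msg <- c(msg, sprintf("reactions[[%d]] is not a Reaction", i))
      next
    }
    v <- validObject(rx, test = TRUE)
    if (!isTRUE(v)) msg <- c(msg, sprintf("reactions[[%d]]: %s", i, paste(v, collapse = "; ")))
    bad <- setdiff(c(names(rx@reactants), names(rx@products)), sp)
    if (length(bad))
      msg <- c(msg, sprintf("reactions[[%d]] references undeclared species: %s",
                            i, paste(bad, collapse = ", ")))
    if (!(rx@rate %in% pn))
      msg <- c(msg, sprintf("reactions[[%d]] references undeclared parameter: %s",
                            i, rx@rate))
    used <- c(used, rx@rate)
  }
  dangling <- setdiff(pn, used)
  if (length(dangling))
    msg <- c(msg, sprintf("parameters never referenced by any reaction: %s",
                          paste(dangling, collapse = ", ")))
  if (!is.numeric(object@outputMap) ||
      ncol(object@outputMap) != length(sp))
    msg <- c(msg, "outputMap must be a numeric matrix with one column per species")
  else {
    if (any(object@outputMap < 0))
      msg <- c(msg, "outputMap coefficients must be nonnegative")
    if (is.null(rownames(object@outputMap)))
      msg <- c(msg, "outputMap must have rownames (output names)")
  }
  if (length(object@renames) &&
      (is.null(names(object@renames)) || any(!(object@renames %in% pn))))
    msg <- c(msg, "renames must be a named character vector mapping old -> declared parameter names")
  if (length(msg)) msg else TRUE
})

#' InputSignal: a rectangular pulse stimulus
#'
#' \eqn{u(t) = amplitude} for \eqn{0 \le t \le pulseEnd}, 0 afterwards
#' (boundary inclusive). Models e.g. ligand present in the medium until a
#' washing step.
#'
#' @slot amplitude stimulus level while the pulse is on (dimensionless)
#' @slot pulseEnd time at which the stimulus is removed (min), > 0
#' @exportClass InputSignal
setClass("InputSignal",
  representation(amplitude = "numeric", pulseEnd = "numeric"))

setValidity("InputSignal", function(object) {
  msg <- character()
  if (length(object@amplitude) != 1L || !is.finite(object@amplitude))
    msg <- c(msg, "amplitude must be a single finite number")
  if (length(object@pulseEnd) != 1L || !is.finite(object@pulseEnd) ||
      object@pulseEnd <= 0)
    msg <- c(msg, "pulseEnd must be a single positive time (min)")
  if (length(msg)) msg else TRUE
})

#' ExperimentDesign: stimulus, sampling grid and error model of an experiment
#'
#' @slot input the \linkS4class{InputSignal}
#' @slot samplingTimes strictly increasing nonnegative times (min) at which
#'   outputs are recorded
#' @slot noiseFraction relative standard deviation of the measurements
#'   (e.g. 0.2 for 20\%)
#' @slot sigmaFloor absolute lower bound on the standard deviation (nM),
#'   guarding against zero weights where a simulated output vanishes
#' @slot fitMask logical over samplingTimes; points entering the chi-square
#'   objective (recorded-but-unfitted points, e.g. t = 0 where all outputs are
#'   zero, carry FALSE)
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
  representation(
    input         = "InputSignal",
    samplingTimes = "numeric",
    noiseFraction = "numeric",
    sigmaFloor    = "numeric",
    fitMask       = "logical"
  ))

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  st <- object@samplingTimes
  if (length(st) < 1L || any(st < 0))
    msg <- c(msg, "samplingTimes must be nonnegative")
  if (length(st) > 1L && any(diff(st) <= 0))
    msg <- c(msg, "samplingTimes must be strictly increasing")
  if (length(object@noiseFraction) != 1L || object@noiseFraction < 0)
    msg <- c(msg, "noiseFraction must be a single nonnegative number")
  if (length(object@sigmaFloor) != 1L || object@sigmaFloor < 0)
    msg <- c(msg, "sigmaFloor must be a single nonnegative number")
  if (length(object@fitMask) != length(st))
    msg <- c(msg, "fitMask must have one entry per sampling time")
  if (length(msg)) msg else TRUE
})

#' Dataset: observed outputs with per-point standard deviations
#'
#' @slot times observation times (min)
#' @slot observations numeric matrix (n_t x n_y), observed output values (nM)
#' @slot sigmas numeric matrix (n_t x n_y), standard deviations (nM)
#' @slot outputNames character, column names of the outputs
#' @exportClass Dataset
setClass("Dataset",
  representation(
    times        = "numeric",
    observations = "matrix",
    sigmas       = "matrix",
    outputNames  = "character"
  ))

setValidity("Dataset", function(object) {
  msg <- character()
  nt <- length(object@times)
  ny <- length(object@outputNames)
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (!identical(dim(object@observations), c(nt, ny)))
    msg <- c(msg, "observations must be an n_t x n_y matrix")
  if (!identical(dim(object@sigmas), c(nt, ny)))
    msg <- c(msg, "sigmas must be an n_t x n_y matrix")
  if (any(object@sigmas < 0, na.rm = TRUE))
    msg <- c(msg, "sigmas must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' SimulationResult: trajectories, outputs and optional sensitivities
#'
#' @slot times sampling times (min)
#' @slot states matrix (n_t x n_x), species concentrations (nM)
#' @slot outputs matrix (n_t x n_y), observables (nM)
#' @slot sensitivities either NULL or an array (n_t x n_y x n_p) of output
#'   sensitivities dy_i(t_j)/dp_k in linear parameter space
#' @exportClass SimulationResult
setClass("SimulationResult",
  representation(
    times         = "numeric",
    states        = "matrix",
    outputs       = "matrix",
    sensitivities = "ANY"
  ),
  prototype(sensitivities = NULL))

#' FitResult: outcome of one local gradient-based fit
#'
#' @slot startLog10 the start point, log10 units
#' @slot estimate named numeric, the estimate in linear space
#' @slot chi2 chi-square objective at the estimate
#' @slot converged TRUE iff the optimizer terminated normally and the
#'   projected-gradient first-order condition is met
#' @slot firstOrderNorm max-norm of the projected gradient (log10 space)
#' @slot nEvals number of objective evaluations
#' @slot message optimizer diagnostic
#' @exportClass FitResult
setClass("FitResult",
  representation(
    startLog10     = "numeric",
    estimate       = "numeric",
    chi2           = "numeric",
    converged      = "logical",
    firstOrderNorm = "numeric",
    nEvals         = "integer",
    message        = "character"
  ))

#' MultiStartResult: a family of local fits from LHS-sampled starts
#'
#' @slot fits list of \linkS4class{FitResult}, ordered by start index
#' @slot bestIndex index of the converged fit with minimal chi-square
#'   (NA_integer_ if no fit converged)
#' @slot boundsLog10 matrix (n_p x 2) of per-parameter (lo, hi) bounds, log10
#' @slot parameterNames parameter names, declaration order
#' @slot seed the seed the start sample and fit sequence derive from
#' @exportClass MultiStartResult
setClass("MultiStartResult",
  representation(
    fits           = "list",
    bestIndex      = "integer",
    boundsLog10    = "matrix",
    parameterNames = "character",
    seed           = "integer"
  ))

#' HessianResult: Gauss-Newton Hessian with its eigendecomposition
#'
#' H = S^T W S where S is the output-sensitivity matrix over fitted points and
#' W the inverse measurement-variance matrix; positive semidefinite by
#' construction and equal to the exact Hessian of the chi-square objective at
#' a zero-residual optimum.
#'
#' @slot matrix symmetric (n_p x n_p)
#' @slot eigenvalues ascending
#' @slot eigenvectors columns matched to eigenvalues
#' @slot parameterNames ordered names of the (free) parameters
#' @slot space "linear" or "log10": the parameter space the derivatives refer to
#' @exportClass HessianResult
setClass("HessianResult",
  representation(
    matrix         = "matrix",
    eigenvalues    = "numeric",
    eigenvectors   = "matrix",
    parameterNames = "character",
    space          = "character"
  ))

#' IdentifiabilityRanking: fixing order of the eigenvalue method
#'
#' Parameters ordered least-identifiable first: at each step the eigenvector
#' of the smallest eigenvalue of the reduced Hessian is examined and the
#' parameter carrying its largest-magnitude component is fixed.
#'
#' @slot order parameter names, least identifiable first
#' @slot lambdaMin smallest eigenvalue of the reduced Hessian at each step
#' @slot dominantComponent magnitude of the selected eigenvector entry per step
#' @exportClass IdentifiabilityRanking
setClass("IdentifiabilityRanking",
  representation(
    order             = "character",
    lambdaMin         = "numeric",
    dominantComponent = "numeric"
  ))

setValidity("IdentifiabilityRanking", function(object) {
  n <- length(object@order)
  if (anyDuplicated(object@order))
    return("order must not contain duplicates")
  if (length(object@lambdaMin) != n || length(object@dominantComponent) != n)
    return("lambdaMin and dominantComponent must have one entry per ranked parameter")
  TRUE
})

#' VarianceReport: variance-based identifiability verdict
#'
#' Holds the accepted-estimate matrix Q (parameters in rows, accepted
#' multi-start estimates in columns), per-parameter means, variances and
#' coefficients of variation v = sd/mean, the box-limitation flags, and the
#' verdict: a model is identifiable iff every v is at most vBar and no
#' parameter's accepted estimates were limited by the sampling box.
#'
#' @slot Q matrix (n_p x n_accept) of accepted estimates, linear space
#' @slot nTotal number of multi-start fits run
#' @slot nAccept number of accepted estimates (columns of Q)
#' @slot means per-parameter mean of accepted estimates
#' @slot variances per-parameter sample variance (n_accept - 1 denominator)
#' @slot cv coefficients of variation v = sd/mean
#' @slot boundLimited logical per parameter; TRUE when accepted estimates
#'   approach the sampling-box boundary, making v a lower bound only
#' @slot verdict "identifiable" or "not_identifiable"
#' @slot limitingParameter first parameter violating the criterion (in the
#'   order the report was asked to examine), or NA
#' @slot parameterNames parameter names, row order of Q
#' @slot vBar the bound the coefficients of variation are compared against
#' @exportClass VarianceReport
setClass("VarianceReport",
  representation(
    Q                 = "matrix",
    nTotal            = "integer",
    nAccept           = "integer",
    means             = "numeric",
    variances         = "numeric",
    cv                = "numeric",
    boundLimited      = "logical",
    verdict           = "character",
    limitingParameter = "character",
    parameterNames    = "character",
    vBar              = "numeric"
  ))

setValidity("VarianceReport", function(object) {
  msg <- character()
  if (object@nAccept > object@nTotal)
    msg <- c(msg, "nAccept cannot exceed nTotal")
  if (any(object@cv < 0, na.rm = TRUE))
    msg <- c(msg, "coefficients of variation must be nonnegative")
  if (!object@verdict %in% c("identifiable", "not_identifiable"))
    msg <- c(msg, "verdict must be 'identifiable' or 'not_identifiable'")
  ok <- all(object@cv <= object@vBar, na.rm = TRUE) && !any(object@boundLimited)
  if ((object@verdict == "identifiable") != ok)
    msg <- c(msg, "verdict inconsistent with cv/vBar/boundLimited invariant")
  if (length(msg)) msg else TRUE
})

#' IterationReport: one pass of the model-reduction workflow
#'
#' @slot modelName name of the model examined in this iteration
#' @slot best best \linkS4class{FitResult} of the multi-start estimation
#' @slot ranking the \linkS4class{IdentifiabilityRanking} at the estimate
#' @slot variance the \linkS4class{VarianceReport}
#' @slot score one-row data.frame: chi2, nParams, nData, aic, aicc
#' @slot decision "terminate" or "simplify"
#' @slot target the parameter to target next when decision == "simplify"
#' @exportClass IterationReport
setClass("IterationReport",
  representation(
    modelName = "character",
    best      = "FitResult",
    ranking   = "IdentifiabilityRanking",
    variance  = "VarianceReport",
    score     = "data.frame",
    decision  = "character",
    target    = "character"
  ))
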