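#' @include network.R
NULL

#' Construct a pulse input signal
#'
#' @param amplitude stimulus level while the pulse is on
#' @param pulseEnd time (min) at which the stimulus is removed
#' @return an \linkS4class{InputSignal}
#' @examples
#' sig <- inputSignal(1, 7)
#' pulseInput(c(0, 7, 7.0001, 10), sig)
#' @export
inputSignal <- function(amplitude = 1, pulseEnd = 7) {
  new("InputSignal", amplitude = as.numeric(amplitude),
      pulseEnd = as.numeric(pulseEnd))
}

#' Evaluate a pulse input signal
#'
#' u(t) equals the amplitude for t <= pulseEnd (boundary inclusive) and 0
#' afterwards, modeling a stimulus washed out of the medium at pulseEnd.
#'
#' @param t time(s), min, nonnegative
#' @param signal an \linkS4class{InputSignal}
#' @return numeric vector of input values, same length as t
#' @export
pulseInput <- function(t, signal) {
  if (any(t < 0)) stop("pulseInput: t must be nonnegative")
  ifelse(t <= signal@pulseEnd, signal@amplitude, 0)
}

#' Map states to outputs
#'
#' Applies the linear output map row-wise: \code{outputs = states \%*\% t(C)}.
#'
#' @param states matrix (n_t x n_x) of species concentrations
#' @param outputMap matrix (n_y x n_x) of output coefficients
#' @return matrix (n_t x n_y), columns named after outputMap rows
#' @export
observeOutputs <- function(states, outputMap) {
  states <- as.matrix(states)
  if (ncol(states) != ncol(outputMap))
    stop(sprintf("observeOutputs: states have %d columns, outputMap %d",
                 ncol(states), ncol(outputMap)))
  out <- states %*% t(outputMap)
  colnames(out) <- rownames(outputMap)
  out
}

# Integrate one constant-input segment with deSolve::lsoda.
# y0 is the (possibly sensitivity-extended) state; returns the deSolve matrix.
# quiet = TRUE swallows the solver's diagnostics (used inside optimization,
# where failing evaluations at extreme parameter corners are expected and
# handled as rejected steps).
.integrateSegment <- function(cn, y0, times, params, u, withSens, rtol, atol,
                              maxsteps = 50000, quiet = FALSE) {
  .Call("ma_set_run", as.numeric(params), as.numeric(u), PACKAGE = "kinetred")
  fname <- if (withSens) "ma_derivs_sens" else "ma_derivs"
  run <- function()
    deSolve::lsoda(y = y0, times = times, func = fname, parms = numeric(1),
                   dllname = "kinetred", initfunc = "ma_init",
                   rtol = rtol, atol = atol, maxsteps = maxsteps)
  if (quiet) {
    con <- file(nullfile(), open = "wt")
    sink(con)
    sink(con, type = "message")
    on.exit({
      sink(type = "message")
      sink()
      close(con)
    })
    sol <- suppressWarnings(run())
  } else {
    sol <- run()
  }
  if (attr(sol, "istate")[1L] < 0)
    stop(sprintf("integration failed near t = %.4g", sol[nrow(sol), 1L]))
  sol
}

# Stage a compiled network's topology into the C module before integrating.
.stageNetwork <- function(cn) {
  i2 <- ifelse(cn$i2 > cn$nx, 0L, cn$i2)    # sentinel -> -1 (0-based)
  .Call("ma_set_network",
        as.integer(cn$nx), as.integer(cn$nr), as.integer(cn$np),
        as.numeric(cn$N), as.integer(cn$i1 - 1L), as.integer(i2 - 1L),
        as.integer(cn$rateIdx - 1L), as.integer(cn$mod),
        PACKAGE = "kinetred")
  invisible(NULL)
}

#' Simulate a reaction network under an experiment design
#'
#' Integrates the mass-action ODE system with a stiff variable-order code
#' (deSolve's lsoda) and records states and outputs at the design's sampling
#' times. The discontinuous pulse input is handled exactly by splitting the
#' integration at the pulse end and restarting, so no integration step
#' straddles the discontinuity. When \code{sensitivities = TRUE} the forward
#' sensitivity system \eqn{\dot S = (\partial f/\partial x) S + \partial
#' f/\partial p} is co-integrated from \eqn{S(0) = 0} (initial conditions are
#' known, not estimated) and output sensitivities \eqn{C S} are returned.
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @param params rate parameters (linear space, declaration order); defaults
#'   to the network's reference values
#' @param design an \linkS4class{ExperimentDesign}
#' @param sensitivities also integrate the forward sensitivity equations?
#' @param rtol,atol integrator tolerances (relative; absolute in nM)
#' @return a \linkS4class{SimulationResult}
#' @examples
#' net <- buildNetwork(c(A = 10, B = 0),
#'                     list(reaction(c(A = 1), c(B = 1), "k")),
#'                     c(k = 0.3),
#'                     matrix(c(1, 0), 1, 2, dimnames = list("yA", NULL)))
#' des <- experimentDesign(samplingTimes = 0:10)
#' sim <- simulateNetwork(net, design = des)
#' max(abs(sim@outputs[, 1] - 10 * exp(-0.3 * (0:10))))
#' @export
simulateNetwork <- function(network, params = referenceParams(network),
                            design, sensitivities = FALSE,
                            rtol = 1e-10, atol = 1e-12) {
  params <- .checkParams(network, params)
  cn <- .compileNetwork(network)
  .simulateCompiled(cn, network@initialState, params, design,
                    sensitivities, rtol, atol)
}

.checkParams <- function(network, params) {
  pn <- names(network@parameters)
  if (!is.null(names(params))) {
    missing <- setdiff(pn, names(params))
    if (length(missing))
      stop("missing parameters: ", paste(missing, collapse = ", "))
    params <- params[pn]
  } else if (length(params) != length(pn)) {
    stop(sprintf("params has length %d, network has %d parameters",
                 length(params), length(pn)))
  }
  if (any(!is.finite(params)) || any(params <= 0))
    stop("all rate parameters must be positive and finite")
  structure(as.numeric(params), names = pn)
}

# Core simulator on a compiled network; x0 a named numeric in species order.
.simulateCompiled <- function(cn, x0, params, design, sensitivities,
                              rtol, atol, maxsteps = 50000, quiet = FALSE) {
  st <- design@samplingTimes
  sig <- design@input
  tEnd <- max(st)
  nx <- cn$nx; np <- cn$np; ny <- cn$ny
  y0 <- as.numeric(x0)
  if (sensitivities) y0 <- c(y0, rep(0, nx * np))
  if (tEnd == 0) {
    states <- matrix(y0[seq_len(nx)], 1, nx, dimnames = list(NULL, cn$species))
    outputs <- states %*% t(cn$C)
    colnames(outputs) <- rownames(cn$C)
    sens <- if (sensitivities)
      array(0, dim = c(1, ny, np),
            dimnames = list(NULL, rownames(cn$C), cn$params)) else NULL
    return(new("SimulationResult", times = st, states = states,
               outputs = outputs, sensitivities = sens))
  }

  .stageNetwork(cn)
  # segment boundaries: pulse end splits the horizon when interior
  cut <- sig@pulseEnd
  segs <- if (cut > 0 && cut < tEnd) list(c(0, cut), c(cut, tEnd))
          else list(c(0, tEnd))
  rows <- matrix(NA_real_, length(st), length(y0))
  filled <- logical(length(st))
  cur <- y0
  for (si in seq_along(segs)) {
    a <- segs[[si]][1]; b <- segs[[si]][2]
    u <- pulseInput((a + b) / 2, sig)     # constant within the segment
    inside <- which(st >= a & st <= b)
    times <- sort(unique(c(a, st[inside], b)))
    if (length(times) == 1L) times <- c(times, times)  # degenerate horizon
    sol <- .integrateSegment(cn, cur, times, params, u, sensitivities,
                             rtol, atol, maxsteps = maxsteps, quiet = quiet)
    solT <- sol[, 1L]
    for (i in inside) {
      if (!filled[i]) {
        k <- which.min(abs(solT - st[i]))
        rows[i, ] <- sol[k, -1L]
        filled[i] <- TRUE
      }
    }
    cur <- as.numeric(sol[nrow(sol), -1L])
  }
  # t = 0 row when tEnd == 0 handled by degenerate horizon above
  states <- rows[, seq_len(nx), drop = FALSE]
  colnames(states) <- cn$species
  outputs <- states %*% t(cn$C)
  colnames(outputs) <- rownames(cn$C)
  sens <- NULL
  if (sensitivities) {
    sens <- array(0, dim = c(length(st), ny, np),
                  dimnames = list(NULL, rownames(cn$C), cn$params))
    for (i in seq_along(st)) {
      S <- matrix(rows[i, -seq_len(nx)], nx, np)
      sens[i, , ] <- cn$C %*% S
    }
  }
  new("SimulationResult", times = st, states = states, outputs = outputs,
      sensitivities = sens)
}

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d time points, %d species, %d outputs%s\n",
              length(object@times), ncol(object@states), ncol(object@outputs),
              if (!is.null(object@sensitivities)) ", with sensitivities" else ""))
})

#' Write a simulated trajectory to CSV
#'
#' Columns: time, one per species, one per output.
#'
#' @param result a \linkS4class{SimulationResult}
#' @param path output file
#' @return the path, invisibly
#' @export
writeTrajectory <- function(result, path) {
  df <- data.frame(time = result@times,
                   result@states, result@outputs, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
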