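#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a single mass-action reaction
#'
#' @param reactants named numeric/integer vector of reactant stoichiometries
#'   (e.g. \code{c(A = 1, B = 1)} or \code{c(A = 2)}); total order must be 1
#'   or 2
#' @param products named numeric/integer vector of product stoichiometries;
#'   may be empty for a degradation reaction
#' @param rate name of the rate parameter
#' @param inputModulated multiply the rate by the input u(t)?
#' @return a \linkS4class{Reaction}
#' @examples
#' reaction(c(A = 1), c(B = 1), "k1")
#' reaction(c(A = 2), c(A2 = 1), "kf3")
#' @export
reaction <- function(reactants, products = numeric(), rate,
                     inputModulated = FALSE) {
  toStoich <- function(v) {
    if (length(v) == 0L) return(integer())
    iv <- as.integer(round(v))
    if (any(abs(v - iv) > 1e-8))
      stop("stoichiometric coefficients must be integers")
    names(iv) <- names(v)
    iv
  }
  new("Reaction", reactants = toStoich(reactants),
      products = toStoich(products), rate = as.character(rate),
      inputModulated = isTRUE(inputModulated))
}

#' Build and validate a reaction network
#'
#' Assembles species, reactions, parameters and the output map into a
#' validated \linkS4class{ReactionNetwork}. Species and parameter ordering is
#' the declaration order passed here; all vectors and matrices produced from
#' the network follow it.
#'
#' @param species named numeric vector: species names with their initial
#'   concentrations (nM, nonnegative)
#' @param reactions list of \linkS4class{Reaction} (see \code{\link{reaction}})
#' @param parameters named numeric vector of positive rate parameters; every
#'   declared parameter must be used by at least one reaction
#' @param outputMap numeric matrix, one row per output (rownames = output
#'   names), one column per species (in declaration order); nonnegative
#'   coefficients
#' @param name model name
#' @param renames optional named character vector mapping a predecessor
#'   model's parameter names onto this model's (old name -> new name), used to
#'   carry estimates across a reduction step
#' @return a validated \linkS4class{ReactionNetwork}
#' @examples
#' net <- buildNetwork(
#'   species    = c(A = 10, B = 0),
#'   reactions  = list(reaction(c(A = 1), c(B = 1), "k1")),
#'   parameters = c(k1 = 0.2),
#'   outputMap  = matrix(c(0, 1), 1, 2, dimnames = list("y1", NULL)))
#' nSpecies(net); nParameters(net)
#' @export
buildNetwork <- function(species, reactions, parameters, outputMap,
                         name = "network", renames = character()) {
  if (is.null(names(species)) || any(!nzchar(names(species))))
    stop("species must be a named numeric vector (name = initial concentration)")
  if (is.null(names(parameters)) || any(!nzchar(names(parameters))))
    stop("parameters must be a named numeric vector")
  outputMap <- as.matrix(outputMap)
  if (is.null(rownames(outputMap)))
    rownames(outputMap) <- paste0("y", seq_len(nrow(outputMap)))
  colnames(outputMap) <- names(species)
  new("ReactionNetwork",
      name = name,
      species = names(species),
      initialState = structure(as.numeric(species), names = names(species)),
      reactions = reactions,
      parameters = structure(as.numeric(parameters), names = names(parameters)),
      outputMap = outputMap,
      renames = renames)
}

## ---- accessors -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("speciesNames", "ReactionNetwork", function(x) x@species)

#' @rdname accessors
#' @export
setMethod("parameterNames", "ReactionNetwork", function(x) names(x@parameters))

#' @rdname accessors
#' @export
setMethod("initialState", "ReactionNetwork", function(x) x@initialState)

#' @rdname accessors
#' @export
setMethod("outputMap", "ReactionNetwork", function(x) x@outputMap)

#' @rdname accessors
#' @export
setMethod("reactionList", "ReactionNetwork", function(x) x@reactions)

#' @rdname accessors
#' @export
setMethod("nSpecies", "ReactionNetwork", function(x) length(x@species))

#' @rdname accessors
#' @export
setMethod("nParameters", "ReactionNetwork", function(x) length(x@parameters))

#' @rdname accessors
#' @export
setMethod("nOutputs", "ReactionNetwork", function(x) nrow(x@outputMap))

#' @rdname accessors
#' @export
setMethod("referenceParams", "ReactionNetwork", function(x) x@parameters)

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork '%s': %d species, %d reactions, %d parameters, %d outputs\n",
              object@name, length(object@species), length(object@reactions),
              length(object@parameters), nrow(object@outputMap)))
  cat("  species:   ", paste(utils::head(object@species, 8), collapse = ", "),
      if (length(object@species) > 8) ", ..." else "", "\n", sep = "")
  cat("  parameters:", paste(utils::head(names(object@parameters), 8), collapse = ", "),
      if (length(object@parameters) > 8) ", ..." else "", "\n", sep = "")
  cat("  outputs:   ", paste(rownames(object@outputMap), collapse = ", "), "\n", sep = "")
})

setMethod("show", "Reaction", function(object) {
  side <- function(st) {
    if (!length(st)) return("0")
    paste(ifelse(st > 1L, paste(st, names(st)), names(st)), collapse = " + ")
  }
  cat(sprintf("%s -> %s : %s%s\n", side(object@reactants), side(object@products),
              object@rate, if (object@inputModulated) " [input]" else ""))
})

## ---- internal compiled representation ------------------------------------

# Precompute index structures for fast rate-law evaluation:
#   N       n_x x n_r net stoichiometric matrix
#   i1, i2  reactant indices per reaction (i2 = n_x + 1 points at a padded 1
#           for first-order reactions)
#   rateIdx index of the rate parameter per reaction
#   mod     logical, input-modulated?
# Rates are r_j = k_j * u^[mod_j] * x[i1_j] * xpad[i2_j].
.compileNetwork <- function(network) {
  sp <- network@species
  nx <- length(sp)
  rx <- network@reactions
  nr <- length(rx)
  N <- matrix(0, nx, nr, dimnames = list(sp, NULL))
  i1 <- integer(nr); i2 <- integer(nr)
  rateIdx <- integer(nr); mod <- logical(nr)
  pn <- names(network@parameters)
  for (j in seq_len(nr)) {
    r <- rx[[j]]
    for (s in names(r@reactants)) N[s, j] <- N[s, j] - r@reactants[[s]]
    for (s in names(r@products))  N[s, j] <- N[s, j] + r@products[[s]]
    ridx <- match(names(r@reactants), sp)
    st <- as.integer(r@reactants)
    if (sum(st) == 1L) {
      i1[j] <- ridx[1L]; i2[j] <- nx + 1L
    } else if (length(ridx) == 1L) {       # 2A -> ...
      i1[j] <- ridx[1L]; i2[j] <- ridx[1L]
    } else {                               # A + B -> ...
      i1[j] <- ridx[1L]; i2[j] <- ridx[2L]
    }
    rateIdx[j] <- match(r@rate, pn)
    mod[j] <- r@inputModulated
  }
  list(N = N, i1 = i1, i2 = i2, rateIdx = rateIdx, mod = mod,
       nx = nx, nr = nr, np = length(pn), ny = nrow(network@outputMap),
       C = network@outputMap, species = sp, params = pn)
}

.rates <- function(cn, x, k, u) {
  xpad <- c(x, 1)
  kk <- k[cn$rateIdx]
  r <- kk * xpad[cn$i1] * xpad[cn$i2]
  if (any(cn$mod)) r[cn$mod] <- r[cn$mod] * u
  r
}

# Jacobian of the rate vector w.r.t. the state: n_r x n_x
.ratesJacX <- function(cn, x, k, u) {
  xpad <- c(x, 1)
  kk <- k[cn$rateIdx]
  kk[cn$mod] <- kk[cn$mod] * u
  D <- matrix(0, cn$nr, cn$nx)
  j <- seq_len(cn$nr)
  # dr/dx[i1] += k * xpad[i2];  dr/dx[i2] += k * xpad[i1] (when i2 is a species)
  D[cbind(j, cn$i1)] <- D[cbind(j, cn$i1)] + kk * xpad[cn$i2]
  real2 <- which(cn$i2 <= cn$nx)
  if (length(real2))
    D[cbind(real2, cn$i2[real2])] <- D[cbind(real2, cn$i2[real2])] +
      kk[real2] * xpad[cn$i1[real2]]
  D
}

# Jacobian of the rate vector w.r.t. the parameters: n_r x n_p.
# r_j is linear in its own rate constant, so dr_j/dk = r_j / k.
.ratesJacP <- function(cn, x, k, u) {
  r <- .rates(cn, x, k, u)
  E <- matrix(0, cn$nr, cn$np)
  E[cbind(seq_len(cn$nr), cn$rateIdx)] <- r / k[cn$rateIdx]
  E
}

#' Right-hand side of the mass-action ODE system
#'
#' Evaluates \eqn{dx/dt = N r(x, p, u)} where N is the net stoichiometric
#' matrix and \eqn{r_j = k_j u^{[mod_j]} \prod x^{\nu}} the mass-action rate
#' of reaction j (multiplied by the input value where the reaction is
#' input-modulated).
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @param state numeric vector of species concentrations (nM), species order
#' @param params numeric vector of rate parameters, declaration order
#'   (defaults to the network's reference values)
#' @param inputValue current value of the input signal u(t)
#' @return named numeric vector dx/dt (nM/min)
#' @examples
#' net <- buildNetwork(c(A = 3, B = 0),
#'                     list(reaction(c(A = 1), c(B = 1), "k")),
#'                     c(k = 2),
#'                     matrix(c(0, 1), 1, 2, dimnames = list("y", NULL)))
#' massActionRHS(net, c(3, 0))   # dA/dt = -6, dB/dt = +6
#' @export
massActionRHS <- function(network, state, params = referenceParams(network),
                          inputValue = 0) {
  cn <- .compileNetwork(network)
  if (length(state) != cn$nx)
    stop(sprintf("state has length %d, network has %d species",
                 length(state), cn$nx))
  if (length(params) != cn$np)
    stop(sprintf("params has length %d, network has %d parameters",
                 length(params), cn$np))
  dx <- as.numeric(cn$N %*% .rates(cn, as.numeric(state), as.numeric(params),
                                   inputValue))
  names(dx) <- cn$species
  dx
}

#' Conservation laws of a reaction network
#'
#' Computes a basis of the left null space of the net stoichiometric matrix:
#' weight vectors w with \eqn{w^T N = 0}, so that \eqn{w^T x(t)} is constant
#' along every trajectory (the input only rescales reaction rates and cannot
#' break these invariants). Each basis vector is rescaled so its smallest
#' nonzero magnitude is 1 and its first nonzero entry is positive.
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @param tol singular values below \code{tol} times the largest are treated
#'   as zero
#' @return a list with one element per conservation law; each element is a
#'   list with \code{coefficients} (named numeric over species) and
#'   \code{total} (the conserved value at the initial state). Empty list if
#'   the network has no conservation law.
#' @examples
#' net <- buildNetwork(c(A = 2, A2 = 1),
#'                     list(reaction(c(A = 2), c(A2 = 1), "kf"),
#'                          reaction(c(A2 = 1), c(A = 2), "kd")),
#'                     c(kf = 1, kd = 1),
#'                     matrix(c(1, 0), 1, 2, dimnames = list("y", NULL)))
#' conservationLaws(net)[[1]]$coefficients   # A + 2 A2
#' @export
conservationLaws <- function(network, tol = 1e-10) {
  cn <- .compileNetwork(network)
  s <- svd(cn$N, nu = cn$nx, nv = 0)
  d <- c(s$d, rep(0, cn$nx - length(s$d)))
  null <- which(d <= tol * max(d, 1e-300))
  laws <- list()
  for (i in null) {
    w <- s$u[, i]
    w[abs(w) < 1e-9] <- 0
    if (all(w == 0)) next
    w <- w / min(abs(w[w != 0]))
    if (w[which(w != 0)[1L]] < 0) w <- -w
    names(w) <- cn$species
    laws[[length(laws) + 1L]] <- list(
      coefficients = w,
      total = sum(w * network@initialState))
  }
  laws
}
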