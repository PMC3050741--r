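# Shared toy fixtures: small mass-action networks with known closed forms,
# built in code so every test constructs its inputs from scratch.

# Irreversible chain A -> B -> C with both downstream species observed;
# both rate constants are identifiable from noise-free data.
toyChain <- function(k1 = 0.3, k2 = 0.15) {
  buildNetwork(
    species    = c(A = 10, B = 0, C = 0),
    reactions  = list(reaction(c(A = 1), c(B = 1), "k1"),
                      reaction(c(B = 1), c(C = 1), "k2")),
    parameters = c(k1 = k1, k2 = k2),
    outputMap  = matrix(c(0, 1, 0,
                          0, 0, 1), 2, 3, byrow = TRUE,
                        dimnames = list(c("yB", "yC"), NULL)),
    name = "toy-chain")
}

# The same chain with the first step split into two identical reactions:
# only k1a + k1b enters the dynamics, a structural redundancy.
toyChainDuplicated <- function(k1a = 0.15, k1b = 0.15, k2 = 0.15) {
  buildNetwork(
    species    = c(A = 10, B = 0, C = 0),
    reactions  = list(reaction(c(A = 1), c(B = 1), "k1a"),
                      reaction(c(A = 1), c(B = 1), "k1b"),
                      reaction(c(B = 1), c(C = 1), "k2")),
    parameters = c(k1a = k1a, k1b = k1b, k2 = k2),
    outputMap  = matrix(c(0, 1, 0,
                          0, 0, 1), 2, 3, byrow = TRUE,
                        dimnames = list(c("yB", "yC"), NULL)),
    name = "toy-chain-dup")
}

# Single exponential decay A -> B observing A: A(t) = A0 exp(-k t).
toyDecay <- function(k = 0.3, A0 = 10) {
  buildNetwork(
    species    = c(A = A0, B = 0),
    reactions  = list(reaction(c(A = 1), c(B = 1), "k")),
    parameters = c(k = k),
    outputMap  = matrix(c(1, 0), 1, 2, dimnames = list("yA", NULL)),
    name = "toy-decay")
}

# Minute grid over the first 15 minutes, t = 0 recorded but not fitted
# (all observables vanish there for stimulus-driven models).
toyDesign <- function(tEnd = 15) {
  experimentDesign(input = inputSignal(1, 7), samplingTimes = 0:tEnd,
                   noiseFraction = 0.2, sigmaFloor = 1e-6,
                   fitMask = c(FALSE, rep(TRUE, tEnd)))
}

# Build a Dataset directly from matrices (for hand-constructed examples).
makeDataset <- function(times, observations, sigmas,
                        outputNames = colnames(observations)) {
  new("Dataset", times = as.numeric(times),
      observations = as.matrix(observations), sigmas = as.matrix(sigmas),
      outputNames = outputNames)
}

# Central-difference output sensitivities in log10-parameter space, used as
# the independent oracle for the forward-sensitivity integration. Step in
# decades; integrations at tight tolerance so the quotient is not
# noise-limited.
fdLogSensitivities <- function(network, params, design, hDecades = 1e-3,
                               rtol = 1e-12, atol = 1e-14) {
  np <- length(params)
  out <- vector("list", np)
  for (k in seq_len(np)) {
    up <- params; up[k] <- params[k] * 10^hDecades
    dn <- params; dn[k] <- params[k] * 10^-hDecades
    out[[k]] <- (simulateNetwork(network, up, design, rtol = rtol, atol = atol)@outputs -
                 simulateNetwork(network, dn, design, rtol = rtol, atol = atol)@outputs) /
                (2 * hDecades)
  }
  out
}
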