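#' @include AllClasses.R
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All randomness in the package flows through
# this helper so that a master seed makes every stage reproducible.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stage-specific sub-seed from a master seed. Distinct stage labels
# give distinct, deterministic streams; results stay below 2^31 - 1.
.subSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 69621) %% 2147483647)
}

# Internal consistency checks between a design and a dataset.
.checkDesignData <- function(design, dataset) {
  if (length(design@samplingTimes) != length(dataset@times) ||
      max(abs(design@samplingTimes - dataset@times)) > 1e-9)
    stop("dataset time grid does not match the design's sampling times")
  if (any(dataset@sigmas[design@fitMask, ] <= 0))
    stop("nonpositive sigma at a fitted point")
  invisible(TRUE)
}
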