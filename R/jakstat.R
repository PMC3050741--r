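#' @include network.R
NULL

# Reference initial concentrations (nM). R, JAK, PPX and the pre-associated
# R_JAK of the later variants follow the published values of the Yamada et
# al. (2003) IFN-gamma JAK-STAT model this family truncates; STAT1c and SHP2
# likewise. All complexes start at zero (unstimulated cell).
.jakstatX0 <- c(
  R = 12, JAK = 12, R_JAK = 0,
  IFN_R_JAK = 0, IFN_R_JAK_2 = 0, IFN_R_JAKPhos_2 = 0,
  STAT1c = 1000, IFN_R_JAKPhos_2_STAT1c = 0, STAT1cPhos = 0,
  IFN_R_JAKPhos_2_STAT1cPhos = 0, STAT1cPhos_2 = 0, STAT1c_STAT1cPhos = 0,
  SHP2 = 100, IFN_R_JAKPhos_2_SHP2 = 0,
  PPX = 50, PPX_STAT1cPhos = 0, PPX_STAT1cPhos_2 = 0)

# Synthetic order-of-magnitude reference rate constants (min^-1, or
# nM^-1 min^-1 for second order). The exact published calibration lives in
# supplementary material not reproduced here; these placeholders have
# realistic magnitudes for receptor/kinase/phosphatase kinetics and are meant
# to be overridden by a user calibration. Topology, not these values, is the
# fixture's contract.
.jakstatP0 <- c(
  kf1 = 0.1,    kd1 = 0.05,
  kf2 = 0.02,   kd2 = 0.02,
  kf3 = 0.04,   kd3 = 0.2,
  kf4 = 0.005,
  kf5 = 0.008,  kd5 = 0.8,
  kf6 = 0.4,
  kf7 = 0.005,  kd7 = 0.5,
  kf8 = 0.02,   kd8 = 0.1,
  kf9 = 0.001,  kd9 = 0.2,
  kf10 = 0.003,
  kf11 = 0.001, kd11 = 0.2,
  kf12 = 0.003,
  kf13 = 0.0001, kd13 = 0.2,
  kf24 = 0.0001, kd24 = 0.2,
  kf25 = 0.0005,
  k11new = 0.05, k5new = 0.0001)

#' The truncated early-JAK-STAT model family M0 ... M6
#'
#' Reconstructed topologies of the seven-stage reduction of a truncated
#' (first 15 minutes, no transcriptional feedback) IFN-gamma JAK-STAT
#' signalling model after Yamada et al. (2003). IFN is not a state variable:
#' the receptor-complex formation rate kf2 is multiplied by the pulse input
#' u(t). The reduction stages are:
#' \describe{
#'   \item{M0}{full truncated model: 17 species, 25 parameters. Receptor
#'     assembly (kf1/kd1, kf2/kd2, kf3/kd3, kf4), STAT1c recruitment and
#'     phosphorylation (kf5/kd5 binding, kf6 catalysis+release),
#'     re-association of phosphorylated STAT1c (kf7/kd7), SHP2-mediated
#'     receptor deactivation (kf9/kd9 binding, kf8/kd8 catalysis),
#'     STAT1cPhos homodimerization (kf10), PPX dephosphorylation of the
#'     monomer (kf11/kd11, kf12) and the dimer (kf24/kd24, kf25), and
#'     STAT1c heterodimerization (kf13/kd13).}
#'   \item{M1}{drops the STAT1cPhos re-association: kf7, kd7 and the complex
#'     IFN_R_JAKPhos_2_STAT1cPhos are removed (16 species, 23 parameters).}
#'   \item{M2}{drops the dissociation of high-affinity complexes before
#'     catalysis: kd5, kd9, kd11, kd24 removed; the surviving binding rates
#'     are renamed kf5 -> k5, kf9 -> k9, kf11 -> k11, kf24 -> k24 (16
#'     species, 19 parameters).}
#'   \item{M3}{assumes JAK and the receptor are pre-associated: R, JAK,
#'     kf1, kd1 removed and R_JAK(0) set to 12 nM (14 species, 17
#'     parameters).}
#'   \item{M4}{removes PPX, all PPX complexes and the STAT1c heterodimer
#'     (with k11, kf12, k24, kf25, kf13, kd13) and adds the first-order
#'     dimer dissociation-and-dephosphorylation k11new:
#'     STAT1cPhos_2 -> 2 STAT1c (10 species, 12 parameters).}
#'   \item{M5}{lumps STAT1c binding, phosphorylation and release into the
#'     single second-order step k5new in which the activated receptor is
#'     not consumed; k5, kf6 and the complex IFN_R_JAKPhos_2_STAT1c are
#'     removed (9 species, 11 parameters).}
#'   \item{M6}{removes the k11new dephosphorylation route entirely -
#'     cytoplasmic dephosphorylation is negligible within the first 15
#'     minutes (9 species, 10 parameters).}
#' }
#'
#' Outputs are sums of species concentrations: y1 all phosphorylated STAT1,
#' y2 all activated JAK, y3 all STAT1 dimers, y4 all STAT1 monomers. With
#' \code{multiplicityWeighted = TRUE} (default) a phospho-STAT1 homodimer
#' contributes 2 to y1 and a doubly phosphorylated receptor dimer
#' contributes 2 to y2 (molecule counting); y3 and y4 always count
#' complexes, not monomer equivalents.
#'
#' @param variant one of "M0" ... "M6"
#' @param params optional named numeric vector overriding (part of) the
#'   synthetic reference rate constants
#' @param multiplicityWeighted count phospho-STAT1 and phospho-JAK copies in
#'   y1/y2 with their multiplicity inside dimers?
#' @return a validated \linkS4class{ReactionNetwork}
#' @examples
#' m6 <- jakstatFamily("M6")
#' nSpecies(m6); nParameters(m6)
#' @export
jakstatFamily <- function(variant = c("M0", "M1", "M2", "M3", "M4", "M5", "M6"),
                          params = NULL, multiplicityWeighted = TRUE) {
  variant <- match.arg(variant)
  lvl <- as.integer(substring(variant, 2L))

  b5 <- if (lvl >= 2) "k5" else "kf5"     # renamed binding rates from M2 on
  b9 <- if (lvl >= 2) "k9" else "kf9"
  b11 <- if (lvl >= 2) "k11" else "kf11"
  b24 <- if (lvl >= 2) "k24" else "kf24"

  rx <- list()
  add <- function(re, pr, rate, mod = FALSE)
    rx[[length(rx) + 1L]] <<- reaction(re, pr, rate, mod)

  if (lvl < 3) {
    add(c(R = 1, JAK = 1), c(R_JAK = 1), "kf1")
    add(c(R_JAK = 1), c(R = 1, JAK = 1), "kd1")
  }
  add(c(R_JAK = 1), c(IFN_R_JAK = 1), "kf2", mod = TRUE)
  add(c(IFN_R_JAK = 1), c(R_JAK = 1), "kd2")
  add(c(IFN_R_JAK = 2), c(IFN_R_JAK_2 = 1), "kf3")
  add(c(IFN_R_JAK_2 = 1), c(IFN_R_JAK = 2), "kd3")
  add(c(IFN_R_JAK_2 = 1), c(IFN_R_JAKPhos_2 = 1), "kf4")

  if (lvl < 5) {
    add(c(IFN_R_JAKPhos_2 = 1, STAT1c = 1), c(IFN_R_JAKPhos_2_STAT1c = 1), b5)
    if (lvl < 2)
      add(c(IFN_R_JAKPhos_2_STAT1c = 1), c(IFN_R_JAKPhos_2 = 1, STAT1c = 1), "kd5")
    add(c(IFN_R_JAKPhos_2_STAT1c = 1), c(IFN_R_JAKPhos_2 = 1, STAT1cPhos = 1), "kf6")
  } else {
    add(c(IFN_R_JAKPhos_2 = 1, STAT1c = 1),
        c(IFN_R_JAKPhos_2 = 1, STAT1cPhos = 1), "k5new")
  }
  if (lvl < 1) {
    add(c(IFN_R_JAKPhos_2 = 1, STAT1cPhos = 1), c(IFN_R_JAKPhos_2_STAT1cPhos = 1), "kf7")
    add(c(IFN_R_JAKPhos_2_STAT1cPhos = 1), c(IFN_R_JAKPhos_2 = 1, STAT1cPhos = 1), "kd7")
  }

  add(c(IFN_R_JAKPhos_2 = 1, SHP2 = 1), c(IFN_R_JAKPhos_2_SHP2 = 1), b9)
  if (lvl < 2)
    add(c(IFN_R_JAKPhos_2_SHP2 = 1), c(IFN_R_JAKPhos_2 = 1, SHP2 = 1), "kd9")
  add(c(IFN_R_JAKPhos_2_SHP2 = 1), c(IFN_R_JAK_2 = 1, SHP2 = 1), "kf8")
  add(c(IFN_R_JAK_2 = 1, SHP2 = 1), c(IFN_R_JAKPhos_2_SHP2 = 1), "kd8")

  add(c(STAT1cPhos = 2), c(STAT1cPhos_2 = 1), "kf10")

  if (lvl < 4) {
    add(c(PPX = 1, STAT1cPhos = 1), c(PPX_STAT1cPhos = 1), b11)
    if (lvl < 2)
      add(c(PPX_STAT1cPhos = 1), c(PPX = 1, STAT1cPhos = 1), "kd11")
    add(c(PPX_STAT1cPhos = 1), c(PPX = 1, STAT1c = 1), "kf12")
    add(c(PPX = 1, STAT1cPhos_2 = 1), c(PPX_STAT1cPhos_2 = 1), b24)
    if (lvl < 2)
      add(c(PPX_STAT1cPhos_2 = 1), c(PPX = 1, STAT1cPhos_2 = 1), "kd24")
    add(c(PPX_STAT1cPhos_2 = 1), c(PPX = 1, STAT1c_STAT1cPhos = 1), "kf25")
    add(c(STAT1c = 1, STAT1cPhos = 1), c(STAT1c_STAT1cPhos = 1), "kf13")
    add(c(STAT1c_STAT1cPhos = 1), c(STAT1c = 1, STAT1cPhos = 1), "kd13")
  } else if (lvl < 6) {
    add(c(STAT1cPhos_2 = 1), c(STAT1c = 2), "k11new")
  }

  # species present in this variant, declaration order of the full family
  x0 <- .jakstatX0
  drop <- character()
  if (lvl >= 1) drop <- c(drop, "IFN_R_JAKPhos_2_STAT1cPhos")
  if (lvl >= 3) drop <- c(drop, "R", "JAK")
  if (lvl >= 4) drop <- c(drop, "PPX", "PPX_STAT1cPhos", "PPX_STAT1cPhos_2",
                          "STAT1c_STAT1cPhos")
  if (lvl >= 5) drop <- c(drop, "IFN_R_JAKPhos_2_STAT1c")
  x0 <- x0[setdiff(names(x0), drop)]
  if (lvl >= 3) x0[["R_JAK"]] <- 12   # pre-associated receptor-kinase pool

  # reference parameter values: rename-aware, restricted to used rates
  p0 <- .jakstatP0
  ren <- c(kf5 = "k5", kf9 = "k9", kf11 = "k11", kf24 = "k24")
  if (lvl >= 2) names(p0)[match(names(ren), names(p0))] <- ren
  used <- unique(vapply(rx, function(r) r@rate, character(1)))
  p0 <- p0[used]
  if (!is.null(params)) {
    unknown <- setdiff(names(params), used)
    if (length(unknown))
      stop("unknown parameter(s) for ", variant, ": ",
           paste(unknown, collapse = ", "))
    p0[names(params)] <- params
  }

  w <- if (multiplicityWeighted) 2 else 1
  sp <- names(x0)
  coef <- function(weights) {
    v <- numeric(length(sp)); names(v) <- sp
    keep <- intersect(names(weights), sp)
    v[keep] <- weights[keep]
    v
  }
  C <- rbind(
    y1 = coef(c(STAT1cPhos = 1, IFN_R_JAKPhos_2_STAT1cPhos = 1,
                STAT1cPhos_2 = w, STAT1c_STAT1cPhos = 1,
                PPX_STAT1cPhos = 1, PPX_STAT1cPhos_2 = w)),
    y2 = coef(c(IFN_R_JAKPhos_2 = w, IFN_R_JAKPhos_2_STAT1c = w,
                IFN_R_JAKPhos_2_STAT1cPhos = w, IFN_R_JAKPhos_2_SHP2 = w)),
    y3 = coef(c(STAT1cPhos_2 = 1, STAT1c_STAT1cPhos = 1,
                PPX_STAT1cPhos_2 = 1)),
    y4 = coef(c(STAT1c = 1, STAT1cPhos = 1, IFN_R_JAKPhos_2_STAT1c = 1,
                IFN_R_JAKPhos_2_STAT1cPhos = 1, PPX_STAT1cPhos = 1)))

  renames <- if (lvl == 2) ren else character()
  buildNetwork(species = x0, reactions = rx, parameters = p0,
               outputMap = C, name = variant, renames = renames)
}

#' STAT1 moiety weights of a JAK-STAT family member
#'
#' Returns, per species, the number of STAT1 molecules it contains (monomers
#' 1, dimers 2, receptor- or phosphatase-bound monomers 1). The weighted sum
#' over any trajectory of the family is constant: no reaction creates or
#' destroys STAT1 within the first 15 minutes (no synthesis or degradation is
#' modeled).
#'
#' @param network a network from \code{\link{jakstatFamily}}
#' @return named numeric vector over the network's species
#' @export
jakstatStat1Moiety <- function(network) {
  full <- c(R = 0, JAK = 0, R_JAK = 0, IFN_R_JAK = 0, IFN_R_JAK_2 = 0,
            IFN_R_JAKPhos_2 = 0, STAT1c = 1, IFN_R_JAKPhos_2_STAT1c = 1,
            STAT1cPhos = 1, IFN_R_JAKPhos_2_STAT1cPhos = 1,
            STAT1cPhos_2 = 2, STAT1c_STAT1cPhos = 2, SHP2 = 0,
            IFN_R_JAKPhos_2_SHP2 = 0, PPX = 0, PPX_STAT1cPhos = 1,
            PPX_STAT1cPhos_2 = 2)
  sp <- speciesNames(network)
  if (!all(sp %in% names(full)))
    stop("network does not look like a jakstatFamily member")
  full[sp]
}
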