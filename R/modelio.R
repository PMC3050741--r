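#' @include network.R
NULL

#' Read / write reaction networks as declarative model files
#'
#' The model file is a flat text document with four mandatory sections and
#' two optional ones; lines starting with \code{#} are comments. The grammar:
#' \preformatted{
#' name: M3
#' species:
#'   R_JAK = 12
#'   STAT1c = 1000
#' parameters:
#'   kf2 = 0.02
#' reactions:
#'   R_JAK -> IFN_R_JAK : kf2 [input]
#'   2 STAT1cPhos -> STAT1cPhos_2 : kf10
#' outputs:
#'   y1 = STAT1cPhos + 2 STAT1cPhos_2
#' renames:
#'   kf5 -> k5
#' }
#' Reactant/product sides are \code{+}-separated terms, each an optional
#' integer multiplier followed by a species name; \code{0} denotes an empty
#' side. \code{[input]} marks a rate multiplied by the input signal u(t).
#' The \code{renames} section maps a predecessor model's parameter names
#' onto this model's, for estimate carry-over across a reduction step.
#' \code{writeNetworkModel} and \code{readNetworkModel} round-trip
#' losslessly.
#'
#' @param path file path
#' @param network a \linkS4class{ReactionNetwork}
#' @return \code{readNetworkModel}: a validated
#'   \linkS4class{ReactionNetwork}; \code{writeNetworkModel}: the path,
#'   invisibly
#' @rdname modelIO
#' @export
readNetworkModel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  name <- "network"
  section <- NULL
  species <- numeric(); params <- numeric()
  rx <- list(); outputs <- list(); renames <- character()
  for (ln in lines) {
    if (grepl("^name\\s*:", ln)) {
      name <- trimws(sub("^name\\s*:", "", ln)); next
    }
    if (grepl("^(species|parameters|reactions|outputs|renames)\\s*:\\s*$", ln)) {
      section <- sub("\\s*:\\s*$", "", ln); next
    }
    if (is.null(section)) stop("model file: content before any section: ", ln)
    switch(section,
      species = {
        kv <- .parseAssign(ln)
        if (kv$key %in% names(species)) stop("duplicate species: ", kv$key)
        species[kv$key] <- kv$value
      },
      parameters = {
        kv <- .parseAssign(ln)
        if (kv$key %in% names(params)) stop("duplicate parameter: ", kv$key)
        params[kv$key] <- kv$value
      },
      reactions = rx[[length(rx) + 1L]] <- .parseReaction(ln),
      outputs = {
        m <- regmatches(ln, regexec("^(\\S+)\\s*=\\s*(.+)$", ln))[[1]]
        if (length(m) != 3L) stop("malformed output line: ", ln)
        outputs[[m[2]]] <- .parseLinearCombo(m[3])
      },
      renames = {
        m <- regmatches(ln, regexec("^(\\S+)\\s*->\\s*(\\S+)$", ln))[[1]]
        if (length(m) != 3L) stop("malformed rename line: ", ln)
        renames[m[2]] <- m[3]
      })
  }
  if (!length(species)) stop("model file: no species section")
  if (!length(outputs)) stop("model file: no outputs section")
  C <- matrix(0, length(outputs), length(species),
              dimnames = list(names(outputs), names(species)))
  for (oy in names(outputs)) {
    combo <- outputs[[oy]]
    bad <- setdiff(names(combo), names(species))
    if (length(bad))
      stop("output ", oy, " references undeclared species: ",
           paste(bad, collapse = ", "))
    C[oy, names(combo)] <- combo
  }
  buildNetwork(species = species, reactions = rx, parameters = params,
               outputMap = C, name = name, renames = renames)
}

.parseAssign <- function(ln) {
  m <- regmatches(ln, regexec("^(\\S+)\\s*=\\s*(\\S+)$", ln))[[1]]
  if (length(m) != 3L) stop("malformed assignment line: ", ln)
  v <- suppressWarnings(as.numeric(m[3]))
  if (is.na(v)) stop("non-numeric value in line: ", ln)
  list(key = m[2], value = v)
}

.parseSide <- function(txt) {
  txt <- trimws(txt)
  if (txt == "0" || txt == "") return(numeric())
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  st <- numeric()
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9]+\\s+)?(\\S+)$", tm))[[1]]
    if (length(m) != 3L || !nzchar(m[3])) stop("malformed reaction term: ", tm)
    mult <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
    st[m[3]] <- (if (m[3] %in% names(st)) st[[m[3]]] else 0) + mult
  }
  st
}

.parseReaction <- function(ln) {
  mod <- grepl("\\[input\\]\\s*$", ln)
  ln <- sub("\\s*\\[input\\]\\s*$", "", ln)
  m <- regmatches(ln, regexec("^(.*)->(.*):(.*)$", ln))[[1]]
  if (length(m) != 4L) stop("malformed reaction line: ", ln)
  reaction(.parseSide(m[2]), .parseSide(m[3]), trimws(m[4]),
           inputModulated = mod)
}

.parseLinearCombo <- function(txt) {
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  combo <- numeric()
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9.]+\\s+)?(\\S+)$", tm))[[1]]
    if (length(m) != 3L) stop("malformed output term: ", tm)
    mult <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
    combo[m[3]] <- mult
  }
  combo
}

.formatSide <- function(st) {
  if (!length(st)) return("0")
  paste(ifelse(st > 1, paste(st, names(st)), names(st)), collapse = " + ")
}

#' @rdname modelIO
#' @export
writeNetworkModel <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("name: %s", network@name)
  w("species:")
  for (s in network@species)
    w("  %s = %.17g", s, network@initialState[[s]])
  w("parameters:")
  for (p in names(network@parameters))
    w("  %s = %.17g", p, network@parameters[[p]])
  w("reactions:")
  for (r in network@reactions)
    w("  %s -> %s : %s%s", .formatSide(r@reactants), .formatSide(r@products),
      r@rate, if (r@inputModulated) " [input]" else "")
  w("outputs:")
  C <- network@outputMap
  for (oy in rownames(C)) {
    nz <- which(C[oy, ] != 0)
    terms <- ifelse(C[oy, nz] != 1,
                    paste(C[oy, nz], colnames(C)[nz]), colnames(C)[nz])
    w("  %s = %s", oy, paste(terms, collapse = " + "))
  }
  if (length(network@renames)) {
    w("renames:")
    for (old in names(network@renames))
      w("  %s -> %s", old, network@renames[[old]])
  }
  invisible(path)
}

#' Export a reaction network to SBML (export only)
#'
#' Writes an SBML Level 2 Version 4 document with one compartment, the
#' species with their initial concentrations, the rate parameters, and one
#' reaction per mass-action step with an explicit MathML kinetic law
#' \eqn{k \cdot u^{[mod]} \cdot \prod reactants}. The input signal is
#' exported as a global parameter \code{u} holding the pulse amplitude
#' (SBML has no native pulse primitive; consumers should attach their own
#' event or piecewise definition for the washout). Import of arbitrary SBML
#' is intentionally not supported.
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @param path output file
#' @param inputValue value assigned to the exported input parameter u
#' @return the path, invisibly
#' @export
exportSBML <- function(network, path, inputValue = 1) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level2/version4",
    level = "2", version = "4")
  model <- xml2::xml_add_child(doc, "model", id = network@name)
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1")
  spl <- xml2::xml_add_child(model, "listOfSpecies")
  for (s in network@species)
    xml2::xml_add_child(spl, "species", id = s, compartment = "cell",
                        initialConcentration =
                          format(network@initialState[[s]], digits = 17))
  pl <- xml2::xml_add_child(model, "listOfParameters")
  for (p in names(network@parameters))
    xml2::xml_add_child(pl, "parameter", id = p,
                        value = format(network@parameters[[p]], digits = 17))
  xml2::xml_add_child(pl, "parameter", id = "u",
                      value = format(inputValue, digits = 17))
  rl <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_along(network@reactions)) {
    r <- network@reactions[[i]]
    rn <- xml2::xml_add_child(rl, "reaction", id = sprintf("r%d", i),
                              reversible = "false")
    lor <- xml2::xml_add_child(rn, "listOfReactants")
    for (s in names(r@reactants))
      xml2::xml_add_child(lor, "speciesReference", species = s,
                          stoichiometry = as.character(r@reactants[[s]]))
    if (length(r@products)) {
      lop <- xml2::xml_add_child(rn, "listOfProducts")
      for (s in names(r@products))
        xml2::xml_add_child(lop, "speciesReference", species = s,
                            stoichiometry = as.character(r@products[[s]]))
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    factors <- c(r@rate, if (r@inputModulated) "u",
                 rep(names(r@reactants), r@reactants))
    if (length(factors) == 1L) {
      xml2::xml_add_child(math, "ci", factors)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (f in factors) xml2::xml_add_child(ap, "ci", f)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
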