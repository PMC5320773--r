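# SBML input/output. Writes SBML Level 3 (core + a subset of the fbc-v2
# package: flux-bound parameters and geneProductAssociation trees) and
# reads both that dialect and the legacy Level-2 COBRA dialect (kineticLaw
# LOWER_BOUND/UPPER_BOUND parameters, GENE_ASSOCIATION notes). Role
# designations (biomass, maintenance, tracked exchanges, molecular
# weights) travel in the model notes and can be overridden via `roles`;
# when absent, name-pattern defaults are applied.

.sbmlEsc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.num17 <- function(x) sprintf("%.17g", x)

# ---- GPR expression <-> tree ------------------------------------------------

# Recursive-descent parse of "a and (b or c)" into nested lists:
# list(op = "or"/"and", args = ...) or list(op = "ref", gene = id).
.gprParse <- function(expr) {
  toks <- .gprTokens(expr)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[pos - 1L] }
  parseAtom <- function() {
    tk <- peek()
    if (is.na(tk)) stop("malformed GPR: '", expr, "'")
    if (tk == "(") {
      advance()
      node <- parseOr()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in GPR")
      advance()
      node
    } else {
      list(op = "ref", gene = advance())
    }
  }
  parseAnd <- function() {
    args <- list(parseAtom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parseAtom()))
    }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parseOr <- function() {
    args <- list(parseAnd())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parseAnd()))
    }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  out <- parseOr()
  if (pos <= length(toks)) stop("trailing tokens in GPR: '", expr, "'")
  out
}

# Canonical string form: `and` binds tighter than `or`; and-nodes nested in
# an or are parenthesized.
.gprDeparse <- function(node, parenAnd = FALSE) {
  if (node$op == "ref") return(node$gene)
  if (node$op == "and") {
    s <- paste(vapply(node$args, .gprDeparse, "", parenAnd = FALSE),
               collapse = " and ")
    return(if (parenAnd) paste0("(", s, ")") else s)
  }
  paste(vapply(node$args, .gprDeparse, "", parenAnd = TRUE),
        collapse = " or ")
}

.gprTreeToFbc <- function(node, indent) {
  pad <- strrep(" ", indent)
  if (node$op == "ref")
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                   pad, .sbmlEsc(node$gene)))
  tag <- if (node$op == "and") "fbc:and" else "fbc:or"
  inner <- vapply(node$args, .gprTreeToFbc, "", indent = indent + 2)
  paste0(pad, "<", tag, ">\n", paste(inner, collapse = "\n"),
         "\n", pad, "</", tag, ">")
}

.fbcToGprTree <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    attrs <- xml2::xml_attrs(node)
    ref <- attrs[grepl("geneProduct$", names(attrs))][1]
    return(list(op = "ref", gene = sub("^G_", "", unname(ref))))
  }
  kids <- xml2::xml_children(node)
  args <- lapply(kids, .fbcToGprTree)
  if (nm %in% c("and", "or")) list(op = nm, args = args)
  else if (length(args) == 1) args[[1]]
  else stop("unsupported geneProductAssociation node: ", nm)
}

# ---- Writer -----------------------------------------------------------------

#' Write a network as SBML
#'
#' Emits SBML Level 3 Version 1 with fbc-v2 flux bounds and gene-product
#' associations. Role designations (biomass/maintenance reactions, the
#' tracked-species exchange map, molecular weights and the carbon table)
#' are stored in the model notes so that [readSBML()] round-trips them.
#'
#' @param network a [MetabolicNetwork-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSBML <- function(network, path) {
  S <- as.matrix(network@S)
  n <- length(network@rxns)
  pid <- function(kind, i, side) sprintf("%s_%s_%s", kind, i, side)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="true">',
    "    <notes>",
    '      <body xmlns="http://www.w3.org/1999/xhtml">',
    sprintf("        <p>BIOMASS_REACTION: %s</p>", network@biomassRxn),
    sprintf("        <p>MAINTENANCE_REACTION: %s</p>", network@maintenanceRxn),
    if (length(network@exchangeMap))
      sprintf("        <p>EXCHANGE_MAP: %s</p>",
              paste(names(network@exchangeMap), network@exchangeMap,
                    sep = "=", collapse = ";")),
    if (length(network@mw))
      sprintf("        <p>MOLECULAR_WEIGHTS: %s</p>",
              paste(names(network@mw), .num17(network@mw),
                    sep = "=", collapse = ";")),
    if (length(network@carbon))
      sprintf("        <p>CARBON: %s</p>",
              paste(names(network@carbon), .num17(network@carbon),
                    sep = "=", collapse = ";")),
    "      </body>",
    "    </notes>",
    "    <listOfCompartments>",
    '      <compartment id="c" constant="true"/>',
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    sprintf(paste0('      <species id="M_%s" compartment="c" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"/>'), .sbmlEsc(network@mets)),
    "    </listOfSpecies>",
    "    <listOfParameters>",
    unlist(lapply(seq_len(n), function(j) c(
      sprintf('      <parameter id="%s" value="%s" constant="true"/>',
              pid("bnd", j, "lb"), .num17(network@lb[j])),
      sprintf('      <parameter id="%s" value="%s" constant="true"/>',
              pid("bnd", j, "ub"), .num17(network@ub[j]))))),
    "    </listOfParameters>",
    if (length(network@genes)) c(
      "    <fbc:listOfGeneProducts>",
      sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
              .sbmlEsc(network@genes), .sbmlEsc(network@genes)),
      "    </fbc:listOfGeneProducts>"),
    "    <listOfReactions>")
  for (j in seq_len(n)) {
    sj <- S[, j]
    react <- which(sj < 0)
    prod <- which(sj > 0)
    lines <- c(lines, sprintf(
      paste0('      <reaction id="R_%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      .sbmlEsc(network@rxns[j]),
      if (network@lb[j] < 0) "true" else "false",
      pid("bnd", j, "lb"), pid("bnd", j, "ub")))
    if (length(react)) lines <- c(lines,
      "        <listOfReactants>",
      sprintf(paste0('          <speciesReference species="M_%s" ',
                     'stoichiometry="%s" constant="true"/>'),
              .sbmlEsc(network@mets[react]), .num17(-sj[react])),
      "        </listOfReactants>")
    if (length(prod)) lines <- c(lines,
      "        <listOfProducts>",
      sprintf(paste0('          <speciesReference species="M_%s" ',
                     'stoichiometry="%s" constant="true"/>'),
              .sbmlEsc(network@mets[prod]), .num17(sj[prod])),
      "        </listOfProducts>")
    if (nzchar(network@gpr[j])) lines <- c(lines,
      "        <fbc:geneProductAssociation>",
      .gprTreeToFbc(.gprParse(network@gpr[j]), 10),
      "        </fbc:geneProductAssociation>")
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

# ---- Reader -----------------------------------------------------------------

.xmlLocal <- function(node, name)
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))

.attrAny <- function(node, name) {
  attrs <- xml2::xml_attrs(node)
  hit <- attrs[names(attrs) == name |
                 grepl(paste0(":", name, "$"), names(attrs))]
  if (length(hit)) unname(hit[1]) else NA_character_
}

.parseNotesMap <- function(txt) {
  out <- list()
  for (key in c("BIOMASS_REACTION", "MAINTENANCE_REACTION", "EXCHANGE_MAP",
                "MOLECULAR_WEIGHTS", "CARBON")) {
    m <- regmatches(txt, regexec(paste0(key, ":\\s*([^<\n]+)"), txt))[[1]]
    if (length(m) == 2) out[[key]] <- trimws(m[2])
  }
  out
}

.parsePairs <- function(s, numeric = FALSE) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- vapply(kv, function(x) trimws(x[2]), "")
  if (numeric) vals <- as.numeric(vals)
  stats::setNames(vals, vapply(kv, function(x) trimws(x[1]), ""))
}

#' Read a metabolic model from SBML
#'
#' Supports SBML Levels 2 and 3. Flux bounds are taken from fbc-v2
#' attributes, kineticLaw LOWER_BOUND/UPPER_BOUND parameters, or the
#' \code{reversible} flag (in that order of preference); GPRs from fbc
#' geneProductAssociation trees or GENE_ASSOCIATION notes. COBRA-style
#' \code{M_}/\code{R_}/\code{G_} id prefixes are stripped, and boundary
#' species are dropped.
#'
#' Role designations are resolved from (highest priority first) the
#' \code{roles} argument, the model notes written by [writeSBML()], then
#' name-pattern defaults (\code{biomass}/\code{growth} for the biomass
#' reaction, \code{ATPM}/\code{maintenance} for maintenance, standard
#' species-name patterns for the tracked exchanges).
#'
#' @param path SBML file.
#' @param roles optional list overriding role resolution: entries
#'   \code{biomass}, \code{maintenance}, \code{exchangeMap} (named
#'   character), \code{mw}, \code{carbon} (named numeric).
#' @param defaultBound magnitude used when a file specifies no bounds.
#' @return a [MetabolicNetwork-class].
#' @export
readSBML <- function(path, roles = NULL, defaultBound = 1000) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse error in '", path, "': ", conditionMessage(e)))
  model <- .xmlLocal(doc, "model")
  if (!length(model)) stop("SBML parse error: no <model> element")
  model <- model[[1]]

  spNodes <- .xmlLocal(model, "species")
  spIds <- xml2::xml_attr(spNodes, "id")
  boundary <- xml2::xml_attr(spNodes, "boundaryCondition") %in% "true"
  spKeep <- spIds[!boundary]
  mets <- sub("^M_", "", spKeep)

  parNodes <- xml2::xml_find_all(model, paste0(
    "./*[local-name()='listOfParameters']/*[local-name()='parameter']"))
  parVal <- stats::setNames(as.numeric(xml2::xml_attr(parNodes, "value")),
                            xml2::xml_attr(parNodes, "id"))

  geneNodes <- .xmlLocal(model, "geneProduct")
  genes <- character(0)
  if (length(geneNodes)) {
    lab <- vapply(geneNodes, function(g) {
      l <- .attrAny(g, "label")
      if (is.na(l)) sub("^G_", "", .attrAny(g, "id")) else l
    }, "")
    genes <- unique(lab)
  }

  rxNodes <- xml2::xml_find_all(model, paste0(
    "./*[local-name()='listOfReactions']/*[local-name()='reaction']"))
  if (!length(rxNodes)) stop("SBML parse error: model has no reactions")
  nr <- length(rxNodes)
  rxns <- sub("^R_", "", xml2::xml_attr(rxNodes, "id"))
  S <- matrix(0, length(mets), nr, dimnames = list(mets, rxns))
  lb <- numeric(nr); ub <- numeric(nr); gpr <- character(nr)

  for (j in seq_len(nr)) {
    node <- rxNodes[[j]]
    addSide <- function(listName, sign) {
      refs <- xml2::xml_find_all(node, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']",
        listName))
      for (r in refs) {
        sp <- xml2::xml_attr(r, "species")
        if (sp %in% spIds[boundary]) next
        st <- xml2::xml_attr(r, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        S[sub("^M_", "", sp), j] <<- S[sub("^M_", "", sp), j] + sign * st
      }
    }
    addSide("listOfReactants", -1)
    addSide("listOfProducts", 1)

    rev <- xml2::xml_attr(node, "reversible") %in% c("true", NA)
    lbj <- if (rev) -defaultBound else 0
    ubj <- defaultBound
    lbRef <- .attrAny(node, "lowerFluxBound")
    ubRef <- .attrAny(node, "upperFluxBound")
    if (!is.na(lbRef) && lbRef %in% names(parVal)) lbj <- parVal[[lbRef]]
    if (!is.na(ubRef) && ubRef %in% names(parVal)) ubj <- parVal[[ubRef]]
    if (is.na(lbRef) && is.na(ubRef)) {
      klPars <- xml2::xml_find_all(node, paste0(
        ".//*[local-name()='kineticLaw']//*[local-name()='parameter' or ",
        "local-name()='localParameter']"))
      if (length(klPars)) {
        kid <- xml2::xml_attr(klPars, "id")
        kval <- as.numeric(xml2::xml_attr(klPars, "value"))
        if ("LOWER_BOUND" %in% kid) lbj <- kval[match("LOWER_BOUND", kid)]
        if ("UPPER_BOUND" %in% kid) ubj <- kval[match("UPPER_BOUND", kid)]
      }
    }
    lb[j] <- lbj; ub[j] <- ubj

    gpa <- xml2::xml_find_first(node, paste0(
      "./*[local-name()='geneProductAssociation']"))
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids))
        gpr[j] <- .gprDeparse(.fbcToGprTree(kids[[1]]))
    } else {
      notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        m <- regmatches(txt, regexec("GENE[ _]ASSOCIATION:\\s*([^<\n]+)",
                                     txt))[[1]]
        if (length(m) == 2 && nzchar(trimws(m[2])))
          gpr[j] <- .gprDeparse(.gprParse(trimws(m[2])))
      }
    }
  }
  if (!length(genes)) genes <- .gprGenes(gpr)

  notesNode <- xml2::xml_find_first(model, "./*[local-name()='notes']")
  noteMap <- if (!inherits(notesNode, "xml_missing"))
    .parseNotesMap(as.character(notesNode)) else list()

  biomass <- roles$biomass %||% noteMap$BIOMASS_REACTION %||%
    grep("biomass|growth", rxns, ignore.case = TRUE, value = TRUE)[1]
  if (is.na(biomass) || is.null(biomass) || !biomass %in% rxns)
    stop("configuration error: biomass reaction could not be resolved; ",
         "provide roles$biomass")
  maintenance <- roles$maintenance %||% noteMap$MAINTENANCE_REACTION %||%
    grep("^ATPM$|maintenance|atp.?hydrolysis", rxns, ignore.case = TRUE,
         value = TRUE)[1]
  if (is.na(maintenance) || is.null(maintenance) || !maintenance %in% rxns)
    stop("configuration error: maintenance reaction could not be resolved; ",
         "provide roles$maintenance")

  exMap <- roles$exchangeMap
  if (is.null(exMap) && !is.null(noteMap$EXCHANGE_MAP))
    exMap <- .parsePairs(noteMap$EXCHANGE_MAP)
  if (is.null(exMap)) {
    exRxns <- rxns[colSums(S != 0) == 1]
    pat <- c(glucose = "glc|glucose", ethanol = "etoh|ethanol",
             arabitol = "arab", citrate = "cit", pyruvate = "pyr",
             oxygen = "o2(?!.*co2)|oxygen", co2 = "co2")
    exMap <- character(0)
    for (sp in names(pat)) {
      hit <- grep(pat[[sp]], exRxns, ignore.case = TRUE, perl = TRUE,
                  value = TRUE)
      if (length(hit)) exMap[sp] <- hit[1]
    }
  }
  mw <- roles$mw
  if (is.null(mw) && !is.null(noteMap$MOLECULAR_WEIGHTS))
    mw <- .parsePairs(noteMap$MOLECULAR_WEIGHTS, numeric = TRUE)
  if (is.null(mw)) mw <- .SPECIES_MW[intersect(names(exMap),
                                               names(.SPECIES_MW))]
  carbon <- roles$carbon
  if (is.null(carbon) && !is.null(noteMap$CARBON))
    carbon <- .parsePairs(noteMap$CARBON, numeric = TRUE)
  if (is.null(carbon)) carbon <- numeric(0)

  metabolicNetwork(S, mets = mets, rxns = rxns, lb = lb, ub = ub, gpr = gpr,
                   genes = genes, exchangeMap = exMap, biomassRxn = biomass,
                   maintenanceRxn = maintenance, mw = mw, carbon = carbon)
}

#' Read role overrides / curation rules from YAML or JSON
#'
#' Convenience loader for the configuration files consumed by
#' [readSBML()] (\code{roles}) and [applyReversibilityCuration()]
#' (\code{curation}: a table with reaction/lb/ub columns).
#'
#' @param path YAML or JSON file.
#' @return a list.
#' @export
readModelConfig <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}
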