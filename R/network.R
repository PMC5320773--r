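# Network manipulation: reversibility curation, recombinant-protein drains,
# gene knockouts and GPR evaluation.

# Tokenize a GPR expression into gene ids (anything that is not and/or/parens).
.gprTokens <- function(expr) {
  toks <- regmatches(expr, gregexpr("\\(|\\)|[^\\s()]+", expr, perl = TRUE))[[1]]
  toks
}

.gprGenes <- function(gpr) {
  toks <- as.character(unlist(lapply(gpr[nzchar(gpr)], .gprTokens)))
  sort(unique(toks[!toks %in% c("(", ")") &
                   !tolower(toks) %in% c("and", "or")]))
}

# Evaluate a boolean GPR expression given a character vector of absent
# (deleted) genes. Empty expression means "no gene association" -> TRUE.
.gprEval <- function(expr, absent) {
  if (!nzchar(expr)) return(TRUE)
  toks <- .gprTokens(expr)
  mapped <- vapply(toks, function(tk) {
    lt <- tolower(tk)
    if (tk %in% c("(", ")")) tk
    else if (lt == "and") "&"
    else if (lt == "or") "|"
    else if (tk %in% absent) "FALSE" else "TRUE"
  }, character(1))
  out <- try(eval(parse(text = paste(mapped, collapse = " "))), silent = TRUE)
  if (inherits(out, "try-error") || !is.logical(out) || length(out) != 1)
    stop("malformed GPR expression: '", expr, "'")
  out
}

#' Apply reversibility curation rules to a network
#'
#' Replaces the flux bounds of the listed reactions, leaving the
#' stoichiometry and every other reaction untouched. Typical use is closing
#' the wrong direction of cytosolic redox-cofactor reactions and
#' mitochondrial symporters whose unconstrained reversibility lets
#' thermodynamically infeasible cycles carry flux. Every change is appended
#' to the network's curation log (see [curationLog()]).
#'
#' @param network a [MetabolicNetwork-class].
#' @param rules data.frame with columns \code{reaction}, \code{lb},
#'   \code{ub} (one row per reaction to curate).
#' @return the curated network.
#' @export
applyReversibilityCuration <- function(network, rules) {
  stopifnot(is(network, "MetabolicNetwork"))
  if (is.null(rules) || nrow(rules) == 0) return(network)
  if (!all(c("reaction", "lb", "ub") %in% names(rules)))
    stop("rules must have columns reaction, lb, ub")
  j <- match(rules$reaction, network@rxns)
  if (anyNA(j))
    stop("unknown reaction id(s) in curation rules: ",
         paste(rules$reaction[is.na(j)], collapse = ", "))
  log <- data.frame(reaction = rules$reaction,
                    old_lb = network@lb[j], old_ub = network@ub[j],
                    new_lb = as.numeric(rules$lb),
                    new_ub = as.numeric(rules$ub),
                    stringsAsFactors = FALSE)
  network@lb[j] <- as.numeric(rules$lb)
  network@ub[j] <- as.numeric(rules$ub)
  network@curationLog <- rbind(network@curationLog, log)
  validObject(network)
  network
}

#' Write a curation log as TSV
#'
#' @param network a curated [MetabolicNetwork-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCurationLog <- function(network, path) {
  utils::write.table(curationLog(network), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Add a recombinant-protein drain to a network
#'
#' Appends a protein synthesis (drain) reaction consuming the listed
#' precursor metabolites plus ATP/GTP energy costs and producing one unit of
#' a new extracellular protein species, together with its exchange reaction.
#' The new species is registered in the exchange map and its molecular
#' weight derived from the composition (sum of precursor weights), unless
#' given explicitly.
#'
#' @param network a [MetabolicNetwork-class].
#' @param composition named numeric: precursor metabolite id -> mmol per
#'   mmol protein (coefficients must be positive).
#' @param costs named numeric of energy costs, e.g. \code{c(atp = 60)},
#'   naming metabolites consumed per mmol protein (may be empty).
#' @param name identifier of the protein species (also names the tracked
#'   species in the exchange map).
#' @param mw molecular weight of the protein (g/mmol); computed from the
#'   composition via \code{weights} when omitted.
#' @param weights named numeric of precursor molecular weights (g/mmol per
#'   metabolite id), used to derive \code{mw} from the composition.
#' @return the extended network; reaction count grows by two (drain +
#'   exchange).
#' @export
addProteinReaction <- function(network, composition, costs = numeric(),
                               name = "protein", mw = NULL, weights = NULL) {
  stopifnot(is(network, "MetabolicNetwork"))
  if (any(composition <= 0)) stop("composition coefficients must be positive")
  unknown <- setdiff(c(names(composition), names(costs)), network@mets)
  if (length(unknown))
    stop("unknown metabolite id(s): ", paste(unknown, collapse = ", "))
  if (name %in% names(network@exchangeMap))
    stop("species '", name, "' already tracked")
  protMet <- paste0(name, "_e")
  drainId <- paste0("PROT_", name)
  exId <- paste0("EX_", name)

  S <- as.matrix(network@S)
  S <- rbind(S, matrix(0, 1, ncol(S), dimnames = list(protMet, NULL)))
  newCols <- matrix(0, nrow(S), 2, dimnames = list(rownames(S), c(drainId, exId)))
  newCols[names(composition), drainId] <- -composition
  if (length(costs)) newCols[names(costs), drainId] <-
      newCols[names(costs), drainId] - costs
  newCols[protMet, drainId] <- 1
  newCols[protMet, exId] <- -1
  S <- cbind(S, newCols)

  if (is.null(mw)) {
    if (!is.null(weights)) {
      have <- intersect(names(composition), names(weights))
      if (length(have) < length(composition))
        stop("no molecular weight for precursor(s): ",
             paste(setdiff(names(composition), have), collapse = ", "))
      mw <- sum(composition[have] * weights[have])
    } else {
      warning("no molecular weight given for '", name,
              "'; set it before coupling to a productivity relation")
      mw <- NA_real_
    }
  }

  net <- network
  net@S <- Matrix::Matrix(S, sparse = TRUE)
  net@mets <- c(network@mets, protMet)
  net@rxns <- c(network@rxns, drainId, exId)
  net@lb <- c(network@lb, 0, 0)
  net@ub <- c(network@ub, 1000, 1000)
  net@gpr <- c(network@gpr, "", "")
  net@exchangeMap <- c(network@exchangeMap, stats::setNames(exId, name))
  net@mw <- c(network@mw, stats::setNames(mw, name))
  if (length(net@carbon))
    net@carbon <- c(net@carbon, stats::setNames(
      sum(composition * net@carbon[names(composition)]), protMet))
  validObject(net)
  net
}

#' Knock out one or more genes
#'
#' Marks the genes as deleted and blocks (lb = ub = 0) every reaction whose
#' GPR expression evaluates to FALSE with the accumulated deleted-gene set
#' absent. Standard boolean semantics: isoenzymes (\code{or}) survive single
#' deletions, complexes (\code{and}) do not. The operation is idempotent and
#' commutes across distinct genes.
#'
#' @param network a [MetabolicNetwork-class].
#' @param genes gene identifier(s) to delete.
#' @return the knockout network.
#' @export
geneKnockout <- function(network, genes) {
  stopifnot(is(network, "MetabolicNetwork"))
  unknown <- setdiff(genes, network@genes)
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  absent <- union(network@deletedGenes, genes)
  blocked <- !vapply(network@gpr, .gprEval, logical(1), absent = absent)
  net <- network
  net@deletedGenes <- absent
  net@lb[blocked] <- 0
  net@ub[blocked] <- 0
  validObject(net)
  net
}

#' Reactions affected by deleting a gene
#'
#' @param network a [MetabolicNetwork-class].
#' @param gene a single gene id.
#' @return character vector of reaction ids blocked by the deletion (on top
#'   of any genes already deleted in \code{network}).
#' @export
geneReactions <- function(network, gene) {
  stopifnot(is(network, "MetabolicNetwork"))
  if (!gene %in% network@genes) stop("unknown gene: ", gene)
  absent <- union(network@deletedGenes, gene)
  before <- vapply(network@gpr, .gprEval, logical(1),
                   absent = network@deletedGenes)
  after <- vapply(network@gpr, .gprEval, logical(1), absent = absent)
  network@rxns[before & !after]
}
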