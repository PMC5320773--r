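#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
NULL

#' Stoichiometric metabolic network
#'
#' Container for a (genome-scale or toy) constraint-based metabolic model:
#' the sparse stoichiometric matrix \code{S} (metabolites x reactions),
#' per-reaction flux bounds in mmol/gDCW/h, boolean gene-protein-reaction
#' (GPR) rules, and the role designations the dynamic framework needs --
#' which reaction is the biomass (growth) flux, which one the cytosolic ATP
#' hydrolysis used for non-growth-associated maintenance, and which exchange
#' reaction corresponds to each extracellular species tracked in the
#' bioreactor mass balances.
#'
#' The sign convention follows COBRA practice: exchange reactions are written
#' as pure drains (one nonzero stoichiometric coefficient, -1 on the drained
#' species), so uptake is a negative exchange flux and secretion a positive
#' one.
#'
#' @slot S sparse stoichiometric matrix, metabolites x reactions.
#' @slot mets,rxns metabolite / reaction identifiers.
#' @slot lb,ub lower / upper flux bounds (mmol/gDCW/h; growth entry 1/h).
#' @slot gpr per-reaction GPR expression (\code{""} when none), using
#'   \code{and}/\code{or} and parentheses over gene identifiers.
#' @slot genes gene identifiers.
#' @slot deletedGenes genes knocked out so far (see [geneKnockout()]).
#' @slot exchangeMap named character: tracked species name -> exchange
#'   reaction id.
#' @slot biomassRxn,maintenanceRxn reaction ids of the growth flux and the
#'   cytosolic ATP hydrolysis (maintenance) flux.
#' @slot mw named numeric: tracked species -> molecular weight (g/mmol).
#' @slot carbon named numeric: metabolite -> carbon content (mmol C per
#'   mmol; may be empty for models without an element table).
#' @slot curationLog data.frame recording bound changes made by
#'   [applyReversibilityCuration()].
#'
#' @export
setClass("MetabolicNetwork",
  slots = c(
    S = "Matrix",
    mets = "character",
    rxns = "character",
    lb = "numeric",
    ub = "numeric",
    gpr = "character",
    genes = "character",
    deletedGenes = "character",
    exchangeMap = "character",
    biomassRxn = "character",
    maintenanceRxn = "character",
    mw = "numeric",
    carbon = "numeric",
    curationLog = "data.frame"
  )
)

setValidity("MetabolicNetwork", function(object) {
  msg <- character()
  m <- length(object@mets); n <- length(object@rxns)
  if (!all(dim(object@S) == c(m, n)))
    msg <- c(msg, sprintf("S is %dx%d but there are %d metabolites and %d reactions",
                          nrow(object@S), ncol(object@S), m, n))
  if (length(object@lb) != n || length(object@ub) != n)
    msg <- c(msg, "lb/ub length must equal the number of reactions")
  if (length(object@gpr) != n)
    msg <- c(msg, "gpr length must equal the number of reactions")
  if (any(object@lb > object@ub + 1e-12))
    msg <- c(msg, "lb > ub for at least one reaction")
  if (anyDuplicated(object@rxns)) msg <- c(msg, "duplicated reaction ids")
  if (anyDuplicated(object@mets)) msg <- c(msg, "duplicated metabolite ids")
  if (length(object@exchangeMap)) {
    missing <- setdiff(object@exchangeMap, object@rxns)
    if (length(missing))
      msg <- c(msg, paste("exchangeMap targets not in the network:",
                          paste(missing, collapse = ", ")))
    for (rid in intersect(object@exchangeMap, object@rxns)) {
      j <- match(rid, object@rxns)
      if (sum(object@S[, j] != 0) != 1)
        msg <- c(msg, sprintf(
          "exchange reaction '%s' must have exactly one nonzero coefficient", rid))
    }
  }
  if (!length(object@biomassRxn) || !object@biomassRxn %in% object@rxns)
    msg <- c(msg, "biomassRxn missing from the network")
  if (!length(object@maintenanceRxn) || !object@maintenanceRxn %in% object@rxns)
    msg <- c(msg, "maintenanceRxn missing from the network")
  if (length(object@biomassRxn) && length(object@maintenanceRxn) &&
      identical(object@biomassRxn, object@maintenanceRxn))
    msg <- c(msg, "biomassRxn and maintenanceRxn must be distinct")
  if (length(msg)) msg else TRUE
})

#' Construct a MetabolicNetwork
#'
#' @param S stoichiometric matrix (coerced to sparse), metabolites x reactions.
#' @param mets,rxns metabolite and reaction identifiers.
#' @param lb,ub flux bounds; defaults are -1000/1000 for reactions flagged
#'   reversible and 0/1000 otherwise when omitted.
#' @param gpr per-reaction GPR strings (\code{""} = no gene association).
#' @param genes gene identifiers (inferred from GPRs when omitted).
#' @param exchangeMap named character, species name -> exchange reaction id.
#' @param biomassRxn,maintenanceRxn role designations (reaction ids).
#' @param mw named numeric of molecular weights (g/mmol) for tracked species.
#' @param carbon named numeric of per-metabolite carbon contents.
#' @return a validated [MetabolicNetwork-class] object.
#' @export
metabolicNetwork <- function(S, mets, rxns, lb = NULL, ub = NULL,
                             gpr = rep("", length(rxns)), genes = NULL,
                             exchangeMap = character(),
                             biomassRxn, maintenanceRxn,
                             mw = numeric(), carbon = numeric()) {
  S <- Matrix::Matrix(as.matrix(S), sparse = TRUE)
  dimnames(S) <- list(mets, rxns)
  n <- length(rxns)
  if (is.null(lb)) lb <- rep(-1000, n)
  if (is.null(ub)) ub <- rep(1000, n)
  if (is.null(genes)) genes <- .gprGenes(gpr)
  new("MetabolicNetwork", S = S, mets = mets, rxns = rxns,
      lb = as.numeric(lb), ub = as.numeric(ub), gpr = gpr,
      genes = genes, deletedGenes = character(),
      exchangeMap = exchangeMap, biomassRxn = biomassRxn,
      maintenanceRxn = maintenanceRxn, mw = mw, carbon = carbon,
      curationLog = .emptyCurationLog())
}

.emptyCurationLog <- function() {
  data.frame(reaction = character(), old_lb = numeric(), old_ub = numeric(),
             new_lb = numeric(), new_ub = numeric(), stringsAsFactors = FALSE)
}

#' Flux distribution from the metabolic block
#'
#' @slot v named per-reaction fluxes (mmol/gDCW/h; growth entry in 1/h).
#' @slot mu growth rate (1/h), equal to the biomass-reaction entry of
#'   \code{v}.
#' @slot alpha the suboptimal growth coefficient used (NA for MOMA solves).
#' @slot objectiveValue value of the solved objective on its literal scale.
#' @slot status \code{"optimal"}, \code{"infeasible"} or
#'   \code{"numeric-failure"}.
#' @export
setClass("FluxDistribution",
  slots = c(v = "numeric", mu = "numeric", alpha = "numeric",
            objectiveValue = "numeric", status = "character"))

#' Kinetic-block parameters
#'
#' The fourteen parameters of the kinetic block: Michaelis-Menten glucose
#' uptake (\code{v_G_max}, \code{K_G}), batch-phase minimum secretion rates
#' and fed/starvation-phase minimum consumption rates for ethanol, pyruvate,
#' arabitol and citrate, the suboptimal growth coefficients of both phases,
#' the non-growth-associated maintenance ATP flux \code{m_ATP} and the time
#' \code{T_Fed} at which by-product consumption starts. Each parameter
#' carries a calibration box \code{[lb, ub]} and an adjustable/fixed flag.
#'
#' @slot values named numeric of current parameter values.
#' @slot adjustable named logical; \code{FALSE} marks a fixed parameter.
#' @slot lb,ub named numeric calibration bounds.
#' @export
setClass("KineticParameters",
  slots = c(values = "numeric", adjustable = "logical",
            lb = "numeric", ub = "numeric"))

setValidity("KineticParameters", function(object) {
  nm <- names(object@values)
  if (is.null(nm) || anyDuplicated(nm)) return("values must be uniquely named")
  if (!identical(nm, names(object@adjustable)) ||
      !identical(nm, names(object@lb)) || !identical(nm, names(object@ub)))
    return("values, adjustable, lb and ub must share the same names")
  bad <- object@adjustable &
    (object@values < object@lb - 1e-12 | object@values > object@ub + 1e-12)
  if (any(bad))
    return(paste("adjustable parameter(s) outside bounds:",
                 paste(nm[bad], collapse = ", ")))
  neg <- grepl("^(v_|m_ATP|T_Fed|K_G)", nm) & object@values < -1e-12
  if (any(neg))
    return(paste("negative rate/threshold parameter(s):",
                 paste(nm[neg], collapse = ", ")))
  TRUE
})

#' Exponential feeding policy
#'
#' Defines the exponential feed \eqn{F(t)} designed to track a prescribed
#' specific growth rate schedule
#' \eqn{\mu_{set}(t) = (\mu_{max}-\mu_{min}) e^{-C t} + \mu_{min}} from feed
#' start \code{ti} onwards (\code{t} in the schedule measured from feed
#' start), together with the constant sampling outflow \code{SR}.
#'
#' @slot GF feed glucose concentration (g/L).
#' @slot YSX glucose-to-biomass yield (gDCW/g) used in the feed design.
#' @slot ti feed start time (h).
#' @slot Vi,Xi volume (L) and biomass (g/L) at feed start.
#' @slot muMax,muMin initial and asymptotic set growth rates (1/h).
#' @slot Cdecay exponential decay constant of the schedule (1/h).
#' @slot SR constant sampling rate (L/h).
#' @slot feedEnd end of feeding (h; Inf = until stopped).
#' @slot id policy identifier used in screening reports.
#' @export
setClass("FeedPolicy",
  slots = c(GF = "numeric", YSX = "numeric", ti = "numeric", Vi = "numeric",
            Xi = "numeric", muMax = "numeric", muMin = "numeric",
            Cdecay = "numeric", SR = "numeric", feedEnd = "numeric",
            id = "character"))

setValidity("FeedPolicy", function(object) {
  if (object@GF <= 0) return("GF must be positive")
  if (object@muMin > object@muMax) return("muMin must not exceed muMax")
  if (object@SR < 0) return("SR must be non-negative")
  TRUE
})

#' Simulated cultivation trajectory
#'
#' @slot times output times (h), strictly increasing.
#' @slot states data.frame with one row per output time: volume \code{V}
#'   (L), biomass \code{X} (g/L), glucose \code{G} (g/L), one column per
#'   tracked by-product (g/L), oxygen uptake rate \code{OUR} (g/L/h) and
#'   cumulative CO2 / O2 exchange (mmol).
#' @slot fluxes matrix (time x reaction) of the instantaneous flux
#'   distributions used at each output time.
#' @slot events data.frame (time, kind) of fired events: glucose depletion,
#'   consumption switch, feed start, volume/OTR limit, constraint
#'   relaxations.
#' @export
setClass("Trajectory",
  slots = c(times = "numeric", states = "data.frame", fluxes = "matrix",
            events = "data.frame"))

setValidity("Trajectory", function(object) {
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (nrow(object@states) != length(object@times))
    return("one state row per time required")
  if (nrow(object@fluxes) != length(object@times))
    return("one flux record per time required")
  TRUE
})

#' Cultivation dataset
#'
#' Time-series measurements of a batch or fed-batch culture in long format,
#' as produced by [generateCultivationData()] or read from delimited text.
#'
#' @slot data data.frame with columns \code{variable} (one of X, G, EtOH,
#'   Arab, Cit, Pyr, V), \code{time_h}, \code{value} (native units) and
#'   \code{sd} (replicate SD, may be NA).
#' @slot meta list of metadata: sampling rate \code{SR}, feed composition,
#'   policy, initial state, and (for synthetic data) the generating
#'   parameters \code{theta_true}.
#' @export
setClass("CultivationData", slots = c(data = "data.frame", meta = "list"))

setValidity("CultivationData", function(object) {
  need <- c("variable", "time_h", "value")
  if (!all(need %in% names(object@data)))
    return("data must have columns variable, time_h, value")
  if (any(object@data$time_h < 0)) return("times must be non-negative")
  cnt <- table(object@data$variable)
  if (!any(cnt >= 3)) return("at least one variable needs >= 3 points")
  TRUE
})

#' Calibration result
#'
#' @slot theta named numeric of all parameter values at the optimum (fixed
#'   parameters included at their fixation values).
#' @slot parameters the full [KineticParameters-class] object at the optimum.
#' @slot J objective value (dimensionless max-normalised sum of squares).
#' @slot residuals per-dataset list of per-variable residual series.
#' @slot trace data.frame (iteration, bestJ) of the optimizer's best-so-far.
#' @slot seed integer seed used.
#' @export
setClass("CalibrationResult",
  slots = c(theta = "numeric", parameters = "KineticParameters",
            J = "numeric", residuals = "list", trace = "data.frame",
            seed = "integer"))
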