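# Accessor generics and show methods. Slot access from user code is
# discouraged; these are the supported surface.

#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))
#' @export
setGeneric("bounds", function(object) standardGeneric("bounds"))
#' @export
setGeneric("setBounds", function(object, rxn, lb, ub) standardGeneric("setBounds"))
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))
#' @export
setGeneric("exchangeMap", function(object) standardGeneric("exchangeMap"))
#' @export
setGeneric("biomassReaction", function(object) standardGeneric("biomassReaction"))
#' @export
setGeneric("maintenanceReaction", function(object) standardGeneric("maintenanceReaction"))
#' @export
setGeneric("molecularWeights", function(object) standardGeneric("molecularWeights"))
#' @export
setGeneric("curationLog", function(object) standardGeneric("curationLog"))
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))
#' @export
setGeneric("paramValues", function(object) standardGeneric("paramValues"))
#' @export
setGeneric("paramBounds", function(object) standardGeneric("paramBounds"))
#' @export
setGeneric("adjustableParams", function(object) standardGeneric("adjustableParams"))
#' @export
setGeneric("states", function(object) standardGeneric("states"))
#' @export
setGeneric("eventLog", function(object) standardGeneric("eventLog"))
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))
#' @export
setGeneric("datasetMeta", function(object) standardGeneric("datasetMeta"))

#' @describeIn MetabolicNetwork-class reaction identifiers
#' @param object an object of the documented class
#' @export
setMethod("reactions", "MetabolicNetwork", function(object) object@rxns)
#' @describeIn MetabolicNetwork-class metabolite identifiers
#' @export
setMethod("metabolites", "MetabolicNetwork", function(object) object@mets)
#' @describeIn MetabolicNetwork-class sparse stoichiometric matrix
#' @export
setMethod("stoichiometry", "MetabolicNetwork", function(object) object@S)
#' @describeIn MetabolicNetwork-class data.frame of per-reaction bounds
#' @export
setMethod("bounds", "MetabolicNetwork", function(object)
  data.frame(reaction = object@rxns, lb = object@lb, ub = object@ub,
             stringsAsFactors = FALSE))
#' @describeIn MetabolicNetwork-class replace bounds of one or more reactions
#' @param rxn reaction id(s)
#' @param lb,ub new bounds (recycled)
#' @export
setMethod("setBounds", "MetabolicNetwork", function(object, rxn, lb, ub) {
  j <- match(rxn, object@rxns)
  if (anyNA(j)) stop("unknown reaction id(s): ",
                     paste(rxn[is.na(j)], collapse = ", "))
  object@lb[j] <- rep_len(as.numeric(lb), length(j))
  object@ub[j] <- rep_len(as.numeric(ub), length(j))
  validObject(object)
  object
})
#' @describeIn MetabolicNetwork-class gene identifiers
#' @export
setMethod("geneIds", "MetabolicNetwork", function(object) object@genes)
#' @describeIn MetabolicNetwork-class per-reaction GPR expressions
#' @export
setMethod("gprRules", "MetabolicNetwork", function(object)
  stats::setNames(object@gpr, object@rxns))
#' @describeIn MetabolicNetwork-class species -> exchange reaction map
#' @export
setMethod("exchangeMap", "MetabolicNetwork", function(object) object@exchangeMap)
#' @describeIn MetabolicNetwork-class biomass (growth) reaction id
#' @export
setMethod("biomassReaction", "MetabolicNetwork", function(object) object@biomassRxn)
#' @describeIn MetabolicNetwork-class maintenance ATP hydrolysis reaction id
#' @export
setMethod("maintenanceReaction", "MetabolicNetwork",
          function(object) object@maintenanceRxn)
#' @describeIn MetabolicNetwork-class molecular weights of tracked species
#' @export
setMethod("molecularWeights", "MetabolicNetwork", function(object) object@mw)
#' @describeIn MetabolicNetwork-class log of curation bound changes
#' @export
setMethod("curationLog", "MetabolicNetwork", function(object) object@curationLog)

setMethod("show", "MetabolicNetwork", function(object) {
  cat("MetabolicNetwork:", length(object@mets), "metabolites x",
      length(object@rxns), "reactions,", length(object@genes), "genes\n")
  cat("  biomass:", object@biomassRxn,
      " maintenance:", object@maintenanceRxn, "\n")
  if (length(object@exchangeMap))
    cat("  tracked exchanges:",
        paste(names(object@exchangeMap), collapse = ", "), "\n")
  if (length(object@deletedGenes))
    cat("  deleted genes:", paste(object@deletedGenes, collapse = ", "), "\n")
})

#' @describeIn FluxDistribution-class named flux vector
#' @param object an object of the documented class
#' @export
setMethod("fluxes", "FluxDistribution", function(object) object@v)
#' @describeIn FluxDistribution-class growth rate (1/h)
#' @export
setMethod("growthRate", "FluxDistribution", function(object) object@mu)
#' @describeIn FluxDistribution-class solver status string
#' @export
setMethod("solverStatus", "FluxDistribution", function(object) object@status)

setMethod("show", "FluxDistribution", function(object) {
  cat("FluxDistribution (", object@status, "): mu =",
      format(object@mu, digits = 6), "1/h, alpha =", object@alpha, "\n")
})

#' @describeIn KineticParameters-class named parameter values
#' @param object an object of the documented class
#' @export
setMethod("paramValues", "KineticParameters", function(object) object@values)
#' @describeIn KineticParameters-class data.frame of calibration bounds
#' @export
setMethod("paramBounds", "KineticParameters", function(object)
  data.frame(parameter = names(object@values), lb = object@lb, ub = object@ub,
             adjustable = object@adjustable, row.names = NULL,
             stringsAsFactors = FALSE))
#' @describeIn KineticParameters-class names of adjustable parameters
#' @export
setMethod("adjustableParams", "KineticParameters",
          function(object) names(object@values)[object@adjustable])

setMethod("show", "KineticParameters", function(object) {
  df <- paramBounds(object)
  df$value <- object@values
  print(df[, c("parameter", "value", "lb", "ub", "adjustable")])
})

setMethod("show", "FeedPolicy", function(object) {
  cat("FeedPolicy", object@id, ": mu_set", object@muMax, "->", object@muMin,
      "1/h (C =", object@Cdecay, "), GF =", object@GF,
      "g/L, feed start", object@ti, "h\n")
})

#' @describeIn Trajectory-class data.frame of culture states over time
#' @param object an object of the documented class
#' @export
setMethod("states", "Trajectory", function(object) object@states)
#' @describeIn Trajectory-class time x reaction flux matrix
#' @export
setMethod("fluxes", "Trajectory", function(object) object@fluxes)
#' @describeIn Trajectory-class fired events
#' @export
setMethod("eventLog", "Trajectory", function(object) object@events)

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "time points over",
      format(max(object@times) - min(object@times), digits = 4), "h\n")
  if (nrow(object@events))
    cat("  events:", paste(unique(object@events$kind), collapse = ", "), "\n")
})

#' @describeIn CultivationData-class long-format measurement table
#' @param object an object of the documented class
#' @export
setMethod("measurements", "CultivationData", function(object) object@data)
#' @describeIn CultivationData-class metadata list
#' @export
setMethod("datasetMeta", "CultivationData", function(object) object@meta)

setMethod("show", "CultivationData", function(object) {
  cat("CultivationData:", nrow(object@data), "measurements of",
      length(unique(object@data$variable)), "variables\n")
})

setMethod("show", "CalibrationResult", function(object) {
  cat("CalibrationResult: J =", format(object@J, digits = 6),
      "(seed", object@seed, ")\n")
  print(object@theta)
})
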