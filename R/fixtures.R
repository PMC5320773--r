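# Toy stoichiometric networks and synthetic cultivation datasets. These
# stand in, at desk scale, for a curated genome-scale yeast model and for
# experimental batch/fed-batch HPLC/OD time series, so that every other
# module is testable without downloads.

.SPECIES_VAR <- c(ethanol = "EtOH", arabitol = "Arab",
                  citrate = "Cit", pyruvate = "Pyr")

.SPECIES_MW <- c(glucose = 0.18015, ethanol = 0.04607, pyruvate = 0.08806,
                 arabitol = 0.15215, citrate = 0.19212, oxygen = 0.032,
                 co2 = 0.04401)

#' Build a toy glucose-limited metabolic network
#'
#' Constructs a small (roughly 20-reaction) network with the architecture
#' the dynamic framework expects from a genome-scale yeast model: glucose
#' uptake and transport, a lumped glycolysis producing pyruvate and ATP,
#' lumped respiration consuming oxygen and producing CO2 and ATP, secretion
#' and catabolic (consumption) routes for the requested by-products
#' (ethanol, arabitol, citrate, pyruvate), a carbon- and ATP-consuming
#' biomass reaction, and a cytosolic ATP hydrolysis reaction for
#' non-growth-associated maintenance. Every internal reaction balances
#' carbon exactly (ATP and O2 are treated as carbon-free energy carriers).
#'
#' Optional structural features used by the test fixtures:
#' \itemize{
#'   \item \code{futileCycle}: a three-reaction reversible cycle detached
#'     from all exchanges (a type III pathway); it can carry arbitrary
#'     circulation in a degenerate LP solution but is suppressed by the
#'     quadratic flux-norm term.
#'   \item \code{parallelRoutes}: a four-reaction bypass of glycolysis with
#'     identical net stoichiometry, so the QP must decide a flux split.
#'   \item \code{atpCycle}: a two-reaction loop that generates ATP from
#'     nothing while its second reaction is (wrongly) reversible --
#'     emulating the misbehaving redox-cofactor reactions that reversibility
#'     curation is meant to close.
#' }
#'
#' @param byProducts subset of \code{c("ethanol","arabitol","citrate",
#'   "pyruvate")} to include.
#' @param futileCycle,parallelRoutes,atpCycle include the optional
#'   structures described above.
#' @param biomassGlc mmol glucose consumed per unit growth flux.
#' @param biomassATP mmol ATP consumed per unit growth flux (growth
#'   associated maintenance).
#' @return a [MetabolicNetwork-class].
#' @export
makeToyNetwork <- function(byProducts = c("ethanol", "arabitol", "citrate",
                                          "pyruvate"),
                           futileCycle = FALSE, parallelRoutes = FALSE,
                           atpCycle = FALSE,
                           biomassGlc = 10, biomassATP = 60) {
  byProducts <- match.arg(byProducts, several.ok = TRUE)
  bioCO2 <- 6 * biomassGlc - 40   # biomass carries 40 mmol C per gDCW
  if (bioCO2 < 0) stop("biomassGlc too small to supply biomass carbon")

  rxn <- list(
    EX_glc = list(s = c(glc_e = -1), lb = -10, ub = 0),
    GLCt   = list(s = c(glc_e = -1, glc_c = 1), lb = 0, gpr = "g_glt"),
    GLYC   = list(s = c(glc_c = -1, pyr_c = 2, atp = 2), lb = 0,
                  gpr = "g_gly1 or g_gly2"),
    RESP   = list(s = c(pyr_c = -1, o2 = -2.5, co2 = 3, atp = 12.5), lb = 0,
                  gpr = "g_resp1 and g_resp2"),
    BIOMASS = list(s = c(glc_c = -biomassGlc, atp = -biomassATP,
                         biomass = 1, co2 = bioCO2), lb = 0),
    DM_biomass = list(s = c(biomass = -1), lb = 0),
    ATPM   = list(s = c(atp = -1), lb = 0),
    EX_o2  = list(s = c(o2 = -1), lb = -1000, ub = 0),
    EX_co2 = list(s = c(co2 = -1), lb = 0)
  )
  if ("ethanol" %in% byProducts) {
    rxn$FERM <- list(s = c(pyr_c = -1, etoh_e = 1, co2 = 1), lb = 0,
                     gpr = "g_ferm")
    rxn$ETOHCAT <- list(s = c(etoh_e = -1.5, pyr_c = 1), lb = 0,
                        gpr = "g_ecat")
    rxn$EX_etoh <- list(s = c(etoh_e = -1), lb = 0)
  }
  if ("arabitol" %in% byProducts) {
    rxn$ARABS <- list(s = c(glc_c = -1, arab_e = 1, co2 = 1), lb = 0,
                      gpr = "g_arab")
    rxn$ARABCAT <- list(s = c(arab_e = -3, pyr_c = 5), lb = 0,
                        gpr = "g_acat")
    rxn$EX_arab <- list(s = c(arab_e = -1), lb = 0)
  }
  if ("citrate" %in% byProducts) {
    rxn$CITS <- list(s = c(pyr_c = -2, cit_e = 1), lb = 0, gpr = "g_cit")
    rxn$CITCAT <- list(s = c(cit_e = -1, pyr_c = 2), lb = 0, gpr = "g_ccat")
    rxn$EX_cit <- list(s = c(cit_e = -1), lb = 0)
  }
  if ("pyruvate" %in% byProducts) {
    rxn$PYRt <- list(s = c(pyr_c = -1, pyr_e = 1), lb = -1000, gpr = "g_pyrt")
    rxn$EX_pyr <- list(s = c(pyr_e = -1), lb = 0)
  }
  if (parallelRoutes) {
    rxn$PR1 <- list(s = c(glc_c = -1, i1 = 1), lb = 0)
    rxn$PR2 <- list(s = c(i1 = -1, i2 = 1), lb = 0)
    rxn$PR3 <- list(s = c(i2 = -1, i3 = 1), lb = 0)
    rxn$PR4 <- list(s = c(i3 = -1, pyr_c = 2, atp = 2), lb = 0)
  }
  if (futileCycle) {
    rxn$FC1 <- list(s = c(fm1 = -1, fm2 = 1), lb = -1000)
    rxn$FC2 <- list(s = c(fm2 = -1, fm3 = 1), lb = -1000)
    rxn$FC3 <- list(s = c(fm3 = -1, fm1 = 1), lb = -1000)
  }
  if (atpCycle) {
    rxn$RC1 <- list(s = c(rm1 = -1, rm2 = 1, atp = 1), lb = 0)
    rxn$RC2 <- list(s = c(rm1 = -1, rm2 = 1), lb = -1000)
  }

  mets <- unique(unlist(lapply(rxn, function(r) names(r$s))))
  S <- matrix(0, length(mets), length(rxn), dimnames = list(mets, names(rxn)))
  for (j in seq_along(rxn)) S[names(rxn[[j]]$s), j] <- rxn[[j]]$s
  lb <- vapply(rxn, function(r) if (is.null(r$lb)) -1000 else r$lb, 0)
  ub <- vapply(rxn, function(r) if (is.null(r$ub)) 1000 else r$ub, 0)
  gpr <- vapply(rxn, function(r) if (is.null(r$gpr)) "" else r$gpr, "")

  carbon <- c(glc_e = 6, glc_c = 6, pyr_c = 3, atp = 0, o2 = 0, co2 = 1,
              biomass = 40, etoh_e = 2, arab_e = 5, cit_e = 6, pyr_e = 3,
              i1 = 6, i2 = 6, i3 = 6, fm1 = 1, fm2 = 1, fm3 = 1,
              rm1 = 1, rm2 = 1)[mets]

  exMap <- c(glucose = "EX_glc", oxygen = "EX_o2", co2 = "EX_co2")
  if ("ethanol" %in% byProducts) exMap["ethanol"] <- "EX_etoh"
  if ("arabitol" %in% byProducts) exMap["arabitol"] <- "EX_arab"
  if ("citrate" %in% byProducts) exMap["citrate"] <- "EX_cit"
  if ("pyruvate" %in% byProducts) exMap["pyruvate"] <- "EX_pyr"

  genes <- union(.gprGenes(gpr), "g_orphan")
  metabolicNetwork(S, mets = mets, rxns = names(rxn), lb = lb, ub = ub,
                   gpr = unname(gpr), genes = genes, exchangeMap = exMap,
                   biomassRxn = "BIOMASS", maintenanceRxn = "ATPM",
                   mw = .SPECIES_MW[names(exMap)], carbon = carbon)
}

#' Check the carbon balance of every internal reaction
#'
#' Exchange reactions and single-metabolite drains are exempt (they
#' represent transfer across the system boundary).
#'
#' @param network a [MetabolicNetwork-class] with a carbon table.
#' @return named numeric of carbon imbalances (mmol C per unit flux) for all
#'   internal reactions; all zero for an elementally consistent network.
#' @export
carbonImbalance <- function(network) {
  if (!length(network@carbon)) stop("network has no carbon table")
  S <- as.matrix(network@S)
  internal <- colSums(S != 0) > 1
  drop(network@carbon[network@mets] %*% S[, internal, drop = FALSE])
}

#' Generate a noisy synthetic cultivation dataset
#'
#' Simulates a batch or fed-batch culture at known kinetic parameters,
#' samples the trajectory on a realistic schedule (one sample every
#' \code{sampleEvery} hours, emulating manual sampling), and adds
#' heteroscedastic Gaussian noise with standard deviation
#' \code{cv * value}, floored at \code{floorSD}, clipping at zero. The
#' generating parameters are stored in the dataset metadata so parameter
#' recovery can be scored.
#'
#' @param network a [MetabolicNetwork-class].
#' @param theta_true a [KineticParameters-class] used as ground truth.
#' @param initial initial culture state, see [simulateCultivation()].
#' @param tEnd simulation horizon (h).
#' @param policy a [FeedPolicy-class] or NULL for batch.
#' @param noise list with elements \code{cv} (proportional CV, default
#'   0.05), \code{floorSD} (absolute SD floor, default 0) and optional
#'   \code{seed}.
#' @param sampleEvery sampling interval (h).
#' @param variables which variables to report.
#' @param options simulation options passed to [simulateCultivation()].
#' @return a [CultivationData-class].
#' @export
generateCultivationData <- function(network, theta_true, initial, tEnd,
                                    policy = NULL,
                                    noise = list(cv = 0.05, floorSD = 0),
                                    sampleEvery = 2.5,
                                    variables = NULL, options = list()) {
  cv <- if (is.null(noise$cv)) 0.05 else noise$cv
  floorSD <- if (is.null(noise$floorSD)) 0 else noise$floorSD
  stopifnot(cv >= 0, floorSD >= 0)
  if (!is.null(noise$seed)) set.seed(noise$seed)

  tSamp <- seq(0, tEnd, by = sampleEvery)
  options$outTimes <- tSamp
  traj <- simulateCultivation(network, theta_true, initial, tEnd,
                              policy = policy, options = options)
  st <- states(traj)
  if (is.null(variables))
    variables <- intersect(c("X", "G", "EtOH", "Arab", "Cit", "Pyr", "V"),
                           names(st))
  rows <- lapply(variables, function(vn) {
    val <- st[[vn]]
    sd <- pmax(cv * abs(val), floorSD)
    noisy <- pmax(val + stats::rnorm(length(val), 0, sd), 0)
    data.frame(variable = vn, time_h = st$t, value = noisy, sd = sd,
               stringsAsFactors = FALSE)
  })
  new("CultivationData", data = do.call(rbind, rows),
      meta = list(SR = options$SR, policy = policy, initial = initial,
                  tEnd = tEnd, theta_true = theta_true, cv = cv,
                  floorSD = floorSD))
}

#' Read / write a cultivation dataset as CSV
#'
#' Long format with columns \code{variable}, \code{time_h}, \code{value},
#' \code{sd}.
#'
#' @param path CSV file path.
#' @param meta optional metadata list attached on read.
#' @return a [CultivationData-class] (read) or the path (write).
#' @export
readCultivationData <- function(path, meta = list()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sd" %in% names(df)) df$sd <- NA_real_
  new("CultivationData", data = df, meta = meta)
}

#' @rdname readCultivationData
#' @param dataset a [CultivationData-class].
#' @export
writeCultivationData <- function(dataset, path) {
  utils::write.csv(measurements(dataset), path, row.names = FALSE)
  invisible(path)
}
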