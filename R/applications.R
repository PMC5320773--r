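# Case-study pipelines: growth-rate-dependent specific productivity,
# MOMA single-knockout screening, and feeding-policy evaluation under
# reactor limits.

#' Growth-rate-dependent specific productivity relation
#'
#' Fits a third-degree polynomial to support points of specific product
#' (e.g. recombinant protein) formation rate \eqn{q_P} versus growth rate
#' \eqn{\mu}, as measured in chemostat cultures. The relation is used to
#' impose a growth-dependent *minimum* protein-drain flux during dynamic
#' simulations.
#'
#' @param support data.frame with columns \code{mu} (1/h) and \code{qP}
#'   (mg/gDCW/h); at least 4 points.
#' @return an object of class \code{QpRelation}: list with
#'   \code{coefficients} (degree 0..3), \code{range} (valid mu range) and
#'   \code{support}.
#' @export
qpRelation <- function(support) {
  stopifnot(is.data.frame(support), all(c("mu", "qP") %in% names(support)))
  if (nrow(support) < 4)
    stop("cannot fit a degree-3 polynomial with fewer than 4 support points")
  fit <- stats::lm(qP ~ poly(mu, 3, raw = TRUE), data = support)
  cf <- unname(stats::coef(fit))
  rel <- structure(list(coefficients = cf, range = range(support$mu),
                        support = support), class = "QpRelation")
  grid <- seq(rel$range[1], rel$range[2], length.out = 50)
  if (any(vapply(grid, function(m) qpOfMu(m, rel, warn = FALSE), 0) < -1e-8))
    warning("fitted q_P(mu) goes negative inside the valid range")
  rel
}

#' @export
print.QpRelation <- function(x, ...) {
  cat("QpRelation: qP(mu) =",
      paste(signif(x$coefficients, 4), c("", "mu", "mu^2", "mu^3"),
            collapse = " + "),
      "\n  valid mu range:", paste(signif(x$range, 4), collapse = " .. "),
      "1/h\n")
  invisible(x)
}

#' Synthetic default productivity relation
#'
#' A clearly synthetic stand-in for a measured \eqn{q_P(\mu)} curve (the
#' coefficients of published curves are typically digitized from figures
#' and strain-specific): monotonically saturating from ~1 to ~2.9 mg/gDCW/h
#' over mu in [0.01, 0.2] 1/h, in the range reported for glucose-grown
#' recombinant yeasts. Replace with a measured table for real use.
#'
#' @return a \code{QpRelation}.
#' @export
defaultQpRelation <- function() {
  qpRelation(data.frame(mu = c(0.01, 0.05, 0.10, 0.15, 0.20),
                        qP = c(1.0, 2.0, 2.6, 2.9, 2.95)))
}

#' Evaluate a productivity relation
#'
#' Horner evaluation of the fitted cubic; \code{mu} outside the valid range
#' is clamped to the nearest edge (with a warning by default). Negative
#' evaluations are floored at zero, since the relation acts as a minimum
#' secretion bound.
#'
#' @param mu growth rate (1/h).
#' @param rel a \code{QpRelation}.
#' @param warn warn when clamping.
#' @return specific productivity (mg/gDCW/h).
#' @export
qpOfMu <- function(mu, rel, warn = TRUE) {
  stopifnot(inherits(rel, "QpRelation"))
  if (mu < rel$range[1] || mu > rel$range[2]) {
    if (warn) warning("mu = ", signif(mu, 4), " outside the valid range; clamped")
    mu <- min(max(mu, rel$range[1]), rel$range[2])
  }
  cf <- rel$coefficients
  max(cf[1] + mu * (cf[2] + mu * (cf[3] + mu * cf[4])), 0)
}

#' Screen single-gene knockouts for product overproduction
#'
#' Runs one batch simulation per gene. At every metabolic-block step of a
#' knockout simulation the parental QP is solved first (same kinetic
#' constraints), the gene's reactions are blocked, and the MOMA projection
#' of the parental fluxes onto the knockout network supplies the realized
#' growth and exchange rates. Final protein and biomass concentrations are
#' compared against the parental run.
#'
#' @param network the parental [MetabolicNetwork-class] (with the protein
#'   drain already added, see [addProteinReaction()]).
#' @param params a [KineticParameters-class].
#' @param rel a \code{QpRelation} coupling growth to minimum protein
#'   production.
#' @param genes gene ids to knock out (default: all genes).
#' @param initial,tEnd,options as in [simulateCultivation()].
#' @return data.frame with one row per gene: final biomass \code{X} (g/L)
#'   and protein \code{P} (mg/L), \code{fold_change} of
#'   final protein vs parent, \code{status}
#'   (improved/neutral/impaired/lethal) and \code{cluster}
#'   (growth-impaired when final biomass < 50% of parental, trade-off
#'   otherwise). The parental trajectory and per-gene trajectories are
#'   attached as attributes \code{parent} and \code{trajectories}.
#' @export
knockoutScan <- function(network, params, rel, genes = geneIds(network),
                         initial, tEnd, options = list()) {
  options$qpRel <- rel
  parent <- simulateCultivation(network, params, initial, tEnd,
                                options = options)
  protVar <- .protVarName(network)
  pst <- states(parent)
  parentX <- pst$X[nrow(pst)]
  parentP <- 1000 * pst[[protVar]][nrow(pst)]   # g/L -> mg/L

  trajs <- list()
  rows <- lapply(genes, function(g) {
    blocked <- geneReactions(network, g)
    if (!length(blocked))
      return(data.frame(gene = g, X = parentX, P = parentP, fold_change = 1,
                        status = "neutral", cluster = "trade-off",
                        stringsAsFactors = FALSE))
    ko <- geneKnockout(network, g)
    opts <- options
    opts$parentNetwork <- network
    tr <- tryCatch(
      simulateCultivation(ko, params, initial, tEnd, options = opts),
      error = function(e) e)
    if (inherits(tr, "error"))
      return(data.frame(gene = g, X = NA_real_, P = NA_real_,
                        fold_change = NA_real_, status = "lethal",
                        cluster = NA_character_, stringsAsFactors = FALSE))
    trajs[[g]] <<- tr
    st <- states(tr)
    X <- st$X[nrow(st)]; P <- 1000 * st[[protVar]][nrow(st)]
    fc <- if (parentP > 0) P / parentP else NA_real_
    status <- if (!is.na(fc) && fc > 1 + 1e-6) "improved"
              else if (!is.na(fc) && fc < 1 - 1e-6) "impaired" else "neutral"
    cluster <- if (X < 0.5 * parentX) "growth-impaired" else "trade-off"
    data.frame(gene = g, X = X, P = P, fold_change = fc, status = status,
               cluster = cluster, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "parent") <- parent
  attr(out, "parent_final") <- c(X = parentX, P = parentP)
  attr(out, "trajectories") <- trajs
  out
}

.protVarName <- function(network) {
  protein <- setdiff(names(network@exchangeMap),
                     c("glucose", "oxygen", "co2", names(.SPECIES_VAR)))
  if (!length(protein)) stop("network tracks no protein species")
  protein[1]
}

#' Time-integrated synthesis turnover of species, knockout vs parent
#'
#' For each listed metabolite, integrates its total synthesis flux (the sum
#' of positive stoichiometric contributions across reactions, weighted by
#' biomass) over both trajectories and reports the knockout-to-parent
#' ratio. Used to ask how precursor (e.g. amino-acid) production
#' redistributes in knockout strains.
#'
#' @param ko_traj,parent_traj [Trajectory-class] objects over comparable
#'   spans.
#' @param network the [MetabolicNetwork-class] the fluxes refer to.
#' @param species metabolite ids.
#' @return named numeric of ratios; NA (with a message in the names'
#'   attribute) where the parental integral is zero.
#' @export
relativeTurnover <- function(ko_traj, parent_traj, network, species) {
  S <- as.matrix(network@S)
  miss <- setdiff(species, rownames(S))
  if (length(miss)) stop("unknown metabolite(s): ", paste(miss, collapse = ", "))
  integrate1 <- function(traj, met) {
    fx <- fluxes(traj)
    st <- states(traj)
    contrib <- sweep(fx, 2, S[met, colnames(fx)], "*")
    synth <- rowSums(pmax(contrib, 0)) * st$X * st$V   # mmol/h
    sum(diff(st$t) * (synth[-1] + synth[-length(synth)]) / 2)
  }
  vapply(species, function(m) {
    p <- integrate1(parent_traj, m)
    if (abs(p) < 1e-12) NA_real_ else integrate1(ko_traj, m) / p
  }, 0)
}

#' Screen exponential feeding policies under reactor limits
#'
#' Simulates each policy until its volume or oxygen-transfer limit fires
#' (or the horizon ends) and ranks the policies by volumetric productivity
#' (final protein concentration over stop time).
#'
#' @param policies list of [FeedPolicy-class] objects.
#' @param network,params,rel,initial,tEnd,options as in [knockoutScan()].
#' @param Vmax maximum reactor volume (L).
#' @param OTRmax maximum oxygen transfer rate (g/L/h).
#' @return data.frame ranked by decreasing volumetric productivity
#'   \code{qPvol} (mg/L/h), with final biomass/protein, stop time and the
#'   limitation that terminated each run (\code{volume}, \code{oxygen} or
#'   \code{horizon}); infeasible policies are reported with status
#'   \code{failed} and excluded from the ranking order.
#' @export
feedPolicyScreen <- function(policies, network, params, rel, initial, tEnd,
                             Vmax = 1, OTRmax = 10.9, options = list()) {
  options$qpRel <- rel
  options$Vmax <- Vmax
  options$OTRmax <- OTRmax
  protVar <- .protVarName(network)
  rows <- lapply(policies, function(pol) {
    tr <- tryCatch(
      simulateCultivation(network, params, initial, tEnd, policy = pol,
                          options = options),
      error = function(e) e)
    if (inherits(tr, "error"))
      return(data.frame(policy = pol@id, mu_max = pol@muMax,
                        mu_min = pol@muMin, rate = pol@Cdecay,
                        X_final = NA_real_, P_final = NA_real_,
                        qPvol = NA_real_, stop_time = NA_real_,
                        limitation = "failed", stringsAsFactors = FALSE))
    st <- states(tr)
    ev <- eventLog(tr)
    lim <- if ("volume_limit" %in% ev$kind) "volume"
           else if ("otr_limit" %in% ev$kind) "oxygen" else "horizon"
    tStop <- st$t[nrow(st)]
    P <- 1000 * st[[protVar]][nrow(st)]   # g/L -> mg/L
    data.frame(policy = pol@id, mu_max = pol@muMax, mu_min = pol@muMin,
               rate = pol@Cdecay, X_final = st$X[nrow(st)], P_final = P,
               qPvol = P / tStop, stop_time = tStop, limitation = lim,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$qPvol)
  out <- rbind(out[ok, ][order(-out$qPvol[ok]), ], out[!ok, ])
  rownames(out) <- NULL
  out
}
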