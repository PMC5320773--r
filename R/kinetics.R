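# Kinetic block: parameter container, glucose uptake kinetics, feed
# profiles, and the translation of culture state into network constraints.

.PARAM_NAMES <- c("v_G_max", "K_G",
                  "v_EtOH_B", "v_Pyr_B", "v_Arab_B", "v_Cit_B",
                  "v_EtOH_FB", "v_Pyr_FB", "v_Arab_FB", "v_Cit_FB",
                  "alpha_B", "alpha_FB", "m_ATP", "T_Fed")

#' Kinetic parameters with their calibration box
#'
#' Creates the fourteen-parameter set of the kinetic block at its standard
#' initial values and bounds. \code{v_G_max} and \code{K_G} parameterize
#' Michaelis-Menten glucose uptake; the \code{*_B} rates are minimum
#' secretion rates active during the batch phase; the \code{*_FB} rates are
#' minimum consumption rates active once by-product consumption starts at
#' \code{T_Fed}; \code{alpha_B}/\code{alpha_FB} weight the flux-norm term of
#' the metabolic block in each phase; \code{m_ATP} is the non-growth
#' associated maintenance flux.
#'
#' @param ... named parameter values overriding the defaults.
#' @param adjustable character vector naming the adjustable (calibrated)
#'   parameters; all others are treated as fixed.
#' @param lb,ub named numeric overrides of individual bounds.
#' @return a [KineticParameters-class].
#' @export
kineticParameters <- function(..., adjustable = .PARAM_NAMES,
                              lb = NULL, ub = NULL) {
  values <- c(v_G_max = 2.5, K_G = 1e-4,
              v_EtOH_B = 0.5, v_Pyr_B = 0.1, v_Arab_B = 0.2, v_Cit_B = 0,
              v_EtOH_FB = 0, v_Pyr_FB = 0, v_Arab_FB = 0, v_Cit_FB = 0,
              alpha_B = 0, alpha_FB = 0, m_ATP = 2, T_Fed = 25)
  lower <- c(v_G_max = 0, K_G = 0,
             v_EtOH_B = 0, v_Pyr_B = 0, v_Arab_B = 0, v_Cit_B = 0,
             v_EtOH_FB = 0, v_Pyr_FB = 0, v_Arab_FB = 0, v_Cit_FB = 0,
             alpha_B = 0, alpha_FB = 0, m_ATP = 0, T_Fed = 20)
  upper <- c(v_G_max = 10, K_G = 1e-3,
             v_EtOH_B = 3, v_Pyr_B = 2, v_Arab_B = 2, v_Cit_B = 2,
             v_EtOH_FB = 2, v_Pyr_FB = 2, v_Arab_FB = 2, v_Cit_FB = 2,
             alpha_B = 1e-3, alpha_FB = 1e-3, m_ATP = 10, T_Fed = 32)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), .PARAM_NAMES)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    values[names(ov)] <- unlist(ov)
  }
  if (!is.null(lb)) lower[names(lb)] <- lb
  if (!is.null(ub)) upper[names(ub)] <- ub
  adj <- stats::setNames(.PARAM_NAMES %in% adjustable, .PARAM_NAMES)
  # fixed parameters may sit outside the search box (e.g. a literature K_G)
  new("KineticParameters", values = values[.PARAM_NAMES], adjustable = adj,
      lb = lower[.PARAM_NAMES], ub = upper[.PARAM_NAMES])
}

#' Standard fixation values for parameters removed from the adjustable set
#'
#' Literature or consensus values at which problematic parameters are fixed
#' during reparametrization and cross-calibration: glucose kinetics at their
#' reported chemostat values, batch minimum secretion rates at zero (no
#' a-priori forced secretion), feed-phase consumption rates at typical
#' calibrated means, flux-norm weights at zero, and maintenance at its
#' genome-scale reconstruction value.
#'
#' @return named numeric of fixation values.
#' @export
fixationDefaults <- function() {
  c(v_G_max = 6, K_G = 0.0027,
    v_EtOH_B = 0, v_Pyr_B = 0, v_Arab_B = 0, v_Cit_B = 0,
    v_EtOH_FB = 1.21, v_Pyr_FB = 0.14, v_Arab_FB = 0.15, v_Cit_FB = 0.008,
    alpha_B = 0, alpha_FB = 0, m_ATP = 2.18, T_Fed = 22)
}

#' Update parameter values
#'
#' @param params a [KineticParameters-class].
#' @param theta named numeric of new values (subset of the parameters).
#' @return the updated object.
#' @export
setParamValues <- function(params, theta) {
  bad <- setdiff(names(theta), names(params@values))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params@values[names(theta)] <- theta
  validObject(params)
  params
}

#' Fix parameters at given values
#'
#' Removes parameters from the adjustable set, pinning them at \code{at}
#' (default: the standard fixation values).
#'
#' @param params a [KineticParameters-class].
#' @param which parameter names to fix.
#' @param at named numeric of fixation values.
#' @return the updated object.
#' @export
fixParams <- function(params, which, at = fixationDefaults()[which]) {
  params@values[which] <- at
  params@adjustable[which] <- FALSE
  validObject(params)
  params
}

#' Michaelis-Menten glucose uptake
#'
#' \eqn{v_G = v_{G,max} G / (K_G + G)} in mmol/gDCW/h. Glucose
#' concentrations below zero (beyond a -1e-9 numerical floor) are clipped
#' to zero with a warning.
#'
#' @param G glucose concentration (g/L).
#' @param v_G_max maximum uptake rate (mmol/gDCW/h).
#' @param K_G half-saturation constant (g/L), positive.
#' @return uptake rate (mmol/gDCW/h), vectorized over \code{G}.
#' @export
glucoseUptake <- function(G, v_G_max, K_G) {
  stopifnot(K_G > 0, v_G_max >= 0)
  if (any(G < -1e-9)) warning("negative glucose concentration clipped to 0")
  G <- pmax(G, 0)
  v_G_max * G / (K_G + G)
}

#' Feed-policy constructor
#'
#' @param GF feed glucose concentration (g/L).
#' @param YSX design glucose-to-biomass yield (gDCW/g).
#' @param ti feed start time (h).
#' @param Vi,Xi volume (L) and biomass (g/L) at feed start.
#' @param muMax,muMin initial and asymptotic set growth rates (1/h).
#' @param Cdecay decay constant of the growth-rate schedule (1/h); 0 gives
#'   a constant schedule at \code{muMax} (set \code{muMin = muMax}).
#' @param SR constant sampling rate (L/h).
#' @param feedEnd end of feeding (h).
#' @param id policy label.
#' @return a [FeedPolicy-class].
#' @export
feedPolicy <- function(GF = 500, YSX = 0.5, ti = 0, Vi = 0.5, Xi = 10,
                       muMax = 0.1, muMin = 0.07, Cdecay = 0.07, SR = 0,
                       feedEnd = Inf, id = "policy") {
  new("FeedPolicy", GF = GF, YSX = YSX, ti = ti, Vi = Vi, Xi = Xi,
      muMax = muMax, muMin = muMin, Cdecay = Cdecay, SR = SR,
      feedEnd = feedEnd, id = id)
}

#' Set growth-rate schedule of a feeding policy
#'
#' \eqn{\mu_{set}(t) = (\mu_{max}-\mu_{min}) e^{-C t} + \mu_{min}}, with
#' \code{t} measured from feed start; monotone non-increasing from
#' \code{muMax} to \code{muMin}.
#'
#' @param t time since feed start (h), non-negative.
#' @param policy a [FeedPolicy-class].
#' @return set growth rate (1/h), vectorized over \code{t}.
#' @export
muSet <- function(t, policy) {
  stopifnot(all(t >= 0))
  (policy@muMax - policy@muMin) * exp(-policy@Cdecay * t) + policy@muMin
}

#' Closed-form integral of the set growth-rate schedule
#'
#' \eqn{\int_0^\tau \mu_{set}(s) ds = (\mu_{max}-\mu_{min})
#' (1 - e^{-C\tau})/C + \mu_{min}\tau} (limit \eqn{\mu_{max}\tau} as
#' \eqn{C \to 0}).
#'
#' @inheritParams muSet
#' @param tau upper limit, time since feed start (h).
#' @return integrated specific growth (dimensionless).
#' @export
muSetIntegral <- function(tau, policy) {
  stopifnot(all(tau >= 0))
  if (policy@Cdecay == 0) return(policy@muMax * tau)
  (policy@muMax - policy@muMin) * (1 - exp(-policy@Cdecay * tau)) /
    policy@Cdecay + policy@muMin * tau
}

#' Exponential feed profile
#'
#' \eqn{F(t) = \mu_{set}(t-t_i) / (G_F Y_{SX}) \cdot V_i X_i \cdot
#' \exp(\int_{t_i}^{t} \mu_{set})}, using the closed-form integral of the
#' schedule. Zero before feed start and after \code{feedEnd}.
#'
#' @param t absolute culture time (h).
#' @param policy a [FeedPolicy-class].
#' @return feed rate (L/h), vectorized over \code{t}.
#' @export
feedRate <- function(t, policy) {
  if (policy@YSX <= 0) stop("configuration error: YSX must be positive")
  tau <- pmax(t - policy@ti, 0)
  F <- muSet(tau, policy) / (policy@GF * policy@YSX) * policy@Vi *
    policy@Xi * exp(muSetIntegral(tau, policy))
  F[t < policy@ti | t > policy@feedEnd] <- 0
  F
}

#' Translate culture state into network flux bounds
#'
#' The kinetic block of the framework: sets the glucose exchange lower
#' bound to \eqn{-v_G(G)}, pins the maintenance reaction at \code{m_ATP}
#' (lb = ub), and imposes the phase-dependent by-product constraints. In
#' the batch phase each tracked by-product exchange gets a minimum
#' secretion rate (positive lower bound \code{v_*_B}); from \code{T_Fed}
#' onwards (\code{phase = "post_TFed"}) each gets a minimum consumption
#' rate: upper bound \eqn{-v_{*,FB}\, s(P_k)}, where the depletion switch
#' \eqn{s(P) = \min(1, P/\epsilon_P)} smoothly releases forced consumption
#' as the extracellular pool empties, and the lower bound opens to
#' \code{-consumptionCap}.
#'
#' @param network a [MetabolicNetwork-class].
#' @param state culture state: list with \code{G} (g/L) and \code{P}
#'   (named numeric of by-product concentrations, g/L).
#' @param params a [KineticParameters-class].
#' @param phase \code{"batch"} or \code{"post_TFed"}.
#' @param epsP depletion-switch threshold (g/L).
#' @param consumptionCap largest allowed consumption rate magnitude
#'   (mmol/gDCW/h).
#' @return the constrained network.
#' @export
constrainNetwork <- function(network, state, params,
                             phase = c("batch", "post_TFed"),
                             epsP = 0.05, consumptionCap = 10) {
  phase <- match.arg(phase)
  th <- paramValues(params)
  bnd <- .kineticBounds(.simContext(network), state$G,
                        state$P, th, phase, epsP, consumptionCap)
  network@lb <- bnd$lb
  network@ub <- bnd$ub
  validObject(network)
  network
}

# Internal fast path shared with the simulator: returns full lb/ub vectors.
.kineticBounds <- function(ctx, G, P, th, phase, epsP, consumptionCap,
                           protLb = NULL) {
  lb <- ctx$baseLb
  ub <- ctx$baseUb
  lb[ctx$glcIdx] <- -glucoseUptake(G, th[["v_G_max"]], th[["K_G"]])
  lb[ctx$maintIdx] <- ub[ctx$maintIdx] <- th[["m_ATP"]]
  for (sp in names(ctx$byIdx)) {
    j <- ctx$byIdx[[sp]]
    suffix <- .SPECIES_VAR[[sp]]
    if (phase == "batch") {
      lb[j] <- th[[paste0("v_", suffix, "_B")]]
    } else {
      # the depletion switch scales both the forced minimum and the cap,
      # so nothing can be consumed from an empty extracellular pool
      s <- min(1, max(P[[sp]], 0) / epsP)
      ub[j] <- -th[[paste0("v_", suffix, "_FB")]] * s
      lb[j] <- -consumptionCap * s
    }
  }
  if (!is.null(protLb)) lb[ctx$protIdx] <- protLb
  list(lb = lb, ub = ub)
}
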