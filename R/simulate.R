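# Dynamic block: bioreactor ODEs with the metabolic block embedded in the
# right-hand side ("direct" dynamic FBA). The state vector integrates the
# extensive masses (V, V*X, V*G, V*P_k) exactly as the mass balances are
# written, so the continuous sampling outflow SR needs no product-rule
# manipulation; concentrations are derived by division.

#' @importFrom deSolve lsodar ode
NULL

# Precomputed solver context for one network.
.simContext <- function(network, fluxCap = .FLUX_CAP) {
  exMap <- network@exchangeMap
  rxns <- network@rxns
  products <- setdiff(names(exMap), c("glucose", "oxygen", "co2"))
  byProducts <- intersect(products, names(.SPECIES_VAR))
  protein <- setdiff(products, byProducts)
  if (length(protein) > 1)
    stop("at most one non-standard (protein) tracked species is supported")
  bb <- .cappedBounds(network, fluxCap)
  list(
    S = as.matrix(network@S), rxns = rxns,
    bioIdx = match(network@biomassRxn, rxns),
    maintIdx = match(network@maintenanceRxn, rxns),
    glcIdx = match(exMap[["glucose"]], rxns),
    o2Idx = if ("oxygen" %in% names(exMap)) match(exMap[["oxygen"]], rxns) else NA,
    co2Idx = if ("co2" %in% names(exMap)) match(exMap[["co2"]], rxns) else NA,
    byIdx = stats::setNames(
      lapply(byProducts, function(sp) match(exMap[[sp]], rxns)), byProducts),
    protIdx = if (length(protein)) match(exMap[[protein]], rxns) else NA,
    protein = if (length(protein)) protein else NULL,
    products = products,
    prodIdx = vapply(products, function(sp) match(exMap[[sp]], rxns), 0L),
    mw = network@mw,
    baseLb = bb$lb, baseUb = bb$ub,
    cache = new.env(parent = emptyenv())
  )
}

# One metabolic-block solve at given kinetic bounds, with the infeasibility
# relaxation ladder: (1) release forced by-product/protein bounds,
# (2) release the maintenance lower bound, (3) give up.
.solveLadder <- function(ctx, bnd, alpha, feasTol) {
  solveOnce <- function(lb, ub) {
    if (alpha > 0) {
      d <- numeric(length(lb)); d[ctx$bioIdx] <- (1 - alpha) / alpha
      .qpSolveFull(ctx$S, lb, ub, d, feasTol, ctx$cache)
    } else {
      .lpMaxGrowth(ctx$S, lb, ub, ctx$bioIdx, feasTol, cache = ctx$cache)
    }
  }
  res <- solveOnce(bnd$lb, bnd$ub)
  relax <- 0L
  if (res$status != "optimal") {
    relax <- 1L
    lb <- bnd$lb; ub <- bnd$ub
    forced <- c(unlist(ctx$byIdx), if (!is.na(ctx$protIdx)) ctx$protIdx)
    lb[forced] <- pmin(lb[forced], 0)
    ub[forced] <- pmax(ub[forced], 0)
    res <- solveOnce(lb, ub)
    if (res$status != "optimal") {
      relax <- 2L
      lb[ctx$maintIdx] <- 0
      res <- solveOnce(lb, ub)
      if (res$status != "optimal") relax <- 3L
    }
  }
  list(v = res$v, status = res$status, relax = relax)
}

# Full kinetic + metabolic block evaluation at one culture state. With a
# parent context (`ctxParent`), the knockout workflow is used: parental QP
# first, then MOMA projection onto the knockout network. With a q_P(mu)
# relation, the protein drain minimum is set from a first growth-only pass.
.metabolicStep <- function(ctx, ctxParent, G, P, th, alpha, phase, opts) {
  kb <- function(cc, protLb = NULL)
    .kineticBounds(cc, G, P, th, phase, opts$epsP, opts$consumptionCap, protLb)
  solveCtx <- ctxParent %||% ctx
  protLb <- NULL
  if (!is.null(opts$qpRel)) {
    pre <- .solveLadder(solveCtx, kb(solveCtx), alpha, opts$feasTol)
    if (pre$status != "optimal")
      return(list(status = pre$status, relax = pre$relax))
    mu1 <- max(pre$v[solveCtx$bioIdx], 0)
    qp <- qpOfMu(mu1, opts$qpRel, warn = FALSE)      # mg/gDCW/h
    protLb <- qp / 1000 / ctx$mw[[ctx$protein]]      # -> mmol/gDCW/h
  }
  base <- .solveLadder(solveCtx, kb(solveCtx, protLb), alpha, opts$feasTol)
  if (base$status != "optimal")
    return(list(status = base$status, relax = base$relax))
  if (is.null(ctxParent))
    return(list(v = base$v, mu = base$v[ctx$bioIdx], status = "optimal",
                relax = base$relax))
  # MOMA projection of the parental fluxes onto the knockout feasible set
  bnd <- kb(ctx, protLb)
  moma <- .solveLadder2(ctx, bnd, base$v, opts$feasTol)
  if (moma$status != "optimal")
    return(list(status = moma$status, relax = moma$relax))
  list(v = moma$v, mu = moma$v[ctx$bioIdx], status = "optimal",
       relax = max(base$relax, moma$relax), v0 = base$v)
}

# MOMA variant of the relaxation ladder.
.solveLadder2 <- function(ctx, bnd, v0, feasTol) {
  res <- .qpSolveFull(ctx$S, bnd$lb, bnd$ub, 2 * v0, feasTol, ctx$cache)
  relax <- 0L
  if (res$status != "optimal") {
    relax <- 1L
    lb <- bnd$lb; ub <- bnd$ub
    forced <- c(unlist(ctx$byIdx), if (!is.na(ctx$protIdx)) ctx$protIdx)
    lb[forced] <- pmin(lb[forced], 0)
    ub[forced] <- pmax(ub[forced], 0)
    res <- .qpSolveFull(ctx$S, lb, ub, 2 * v0, feasTol, ctx$cache)
    if (res$status != "optimal") {
      relax <- 2L
      lb[ctx$maintIdx] <- 0
      res <- .qpSolveFull(ctx$S, lb, ub, 2 * v0, feasTol, ctx$cache)
      if (res$status != "optimal") relax <- 3L
    }
  }
  list(v = res$v, status = res$status, relax = relax)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.simOptions <- function(options) {
  defaults <- list(dt = 0.25, method = "lsoda", rtol = 1e-6, atol = 1e-8,
                   epsP = 0.05, epsG = 1e-6, consumptionCap = 10,
                   feasTol = 1e-6, fluxCap = .FLUX_CAP, SR = 0,
                   Vmax = Inf, OTRmax = Inf, qpRel = NULL,
                   parentNetwork = NULL, outTimes = NULL)
  defaults[names(options)] <- options
  defaults
}

#' Simulate a batch or fed-batch cultivation
#'
#' Integrates the bioreactor mass balances
#' \deqn{dV/dt = F(t) - SR,\quad d(VX)/dt = \mu VX - SR\,X,}
#' \deqn{d(VG)/dt = F G_F - v_G\,MW_G\,VX - SR\,G,\quad
#'       d(VP_k)/dt = v_{P_k} MW_{P_k} VX - SR\,P_k,}
#' where \eqn{\mu} and the exchange fluxes are read from the metabolic
#' block (bi-objective QP, or parental QP + MOMA when
#' \code{options$parentNetwork} is given for knockout simulation) at every
#' integrator step. Cumulative CO2 and O2 exchange are carried as auxiliary
#' states for elemental audits and the oxygen uptake rate.
#'
#' Events fired and recorded: glucose depletion (root of
#' \eqn{G - \epsilon_G}), the by-product consumption switch at
#' \code{T_Fed}, feed start, volume and oxygen-transfer limit violations
#' (which terminate the run when \code{Vmax}/\code{OTRmax} are finite),
#' and any constraint relaxations the infeasibility ladder had to apply.
#'
#' @param network a [MetabolicNetwork-class].
#' @param params a [KineticParameters-class].
#' @param initial list with \code{V} (L), \code{X} (g/L), \code{G} (g/L)
#'   and optionally \code{P}, a named numeric of initial by-product
#'   concentrations (g/L, default 0).
#' @param tEnd simulation horizon (h).
#' @param policy a [FeedPolicy-class], or NULL for a batch culture
#'   (\eqn{F \equiv 0}).
#' @param options list of solver options: output step \code{dt} (h),
#'   integrator \code{method}, tolerances \code{rtol}/\code{atol},
#'   depletion-switch threshold \code{epsP} (g/L), glucose-depletion
#'   threshold \code{epsG} (g/L), \code{consumptionCap} (mmol/gDCW/h),
#'   batch sampling rate \code{SR} (L/h; fed-batch runs take SR from the
#'   policy), reactor limits \code{Vmax} (L) and \code{OTRmax} (g/L/h), a
#'   \code{qpRel} growth-to-productivity relation (see [qpRelation()]),
#'   \code{parentNetwork} for MOMA knockout runs, and \code{outTimes}
#'   overriding the output grid.
#' @return a [Trajectory-class].
#' @export
simulateCultivation <- function(network, params, initial, tEnd,
                                policy = NULL, options = list()) {
  opts <- .simOptions(options)
  ctx <- .simContext(network, opts$fluxCap)
  ctxParent <- if (!is.null(opts$parentNetwork))
    .simContext(opts$parentNetwork, opts$fluxCap) else NULL
  if (!is.null(opts$qpRel) && is.null(ctx$protein))
    stop("qpRel given but the network tracks no protein species")
  th <- paramValues(params)
  SR <- if (!is.null(policy)) policy@SR else opts$SR

  products <- ctx$products
  P0 <- stats::setNames(numeric(length(products)), products)
  if (!is.null(initial$P)) P0[names(initial$P)] <- initial$P
  if (is.null(initial$V) || initial$V <= 0) stop("initial V must be positive")
  y0 <- c(V = initial$V, MX = initial$V * initial$X,
          MG = initial$V * initial$G,
          stats::setNames(initial$V * P0, paste0("M_", products)),
          cumCO2 = 0, cumO2 = 0)
  nP <- length(products)
  iV <- 1L; iMX <- 2L; iMG <- 3L
  iMP <- if (nP) seq.int(4L, 3L + nP) else integer(0)
  iCO2 <- 4L + nP; iO2 <- 5L + nP

  memo <- new.env(parent = emptyenv())
  memo$relax <- 0L
  relaxEvents <- list()

  evalStep <- function(t, y) {
    key <- c(t, y)
    if (!is.null(memo$key) && identical(memo$key, key)) return(memo$sol)
    V <- max(y[iV], 1e-12)
    X <- max(y[iMX] / V, 0)
    G <- max(y[iMG] / V, 0)
    P <- stats::setNames(pmax(y[iMP] / V, 0), products)
    phase <- if (t >= th[["T_Fed"]]) "post_TFed" else "batch"
    alpha <- if (!is.null(policy) && t >= policy@ti)
      th[["alpha_FB"]] else th[["alpha_B"]]
    sol <- .metabolicStep(ctx, ctxParent, G, P, th, alpha, phase, opts)
    if (sol$status != "optimal")
      stop("metabolic block infeasible at t = ", signif(t, 6),
           " h after the relaxation ladder; forced bounds: ",
           .forcedBoundsMsg(network))
    if (sol$relax != memo$relax) {
      if (sol$relax > 0)
        relaxEvents[[length(relaxEvents) + 1L]] <<- data.frame(
          time = t, kind = if (sol$relax == 1) "relax_byproducts"
                           else "relax_maintenance")
      memo$relax <- sol$relax
    }
    sol <- c(sol, list(V = V, X = X, G = G, P = P,
                       F = if (!is.null(policy)) feedRate(t, policy) else 0))
    memo$key <- key
    memo$sol <- sol
    sol
  }

  rhs <- function(t, y, parms) {
    s <- evalStep(t, y)
    v <- s$v
    dV <- s$F - SR
    dMX <- s$mu * y[iMX] - SR * s$X
    dMG <- s$F * (if (!is.null(policy)) policy@GF else 0) +
      v[ctx$glcIdx] * ctx$mw[["glucose"]] * y[iMX] - SR * s$G
    dMP <- if (nP) v[ctx$prodIdx] * ctx$mw[products] * y[iMX] - SR * s$P
           else numeric(0)
    dCO2 <- if (!is.na(ctx$co2Idx)) v[ctx$co2Idx] * y[iMX] else 0
    dO2 <- if (!is.na(ctx$o2Idx)) -v[ctx$o2Idx] * y[iMX] else 0
    list(c(dV, dMX, dMG, dMP, dCO2, dO2))
  }

  glcArmed <- initial$G > opts$epsG
  rootfun <- function(t, y, parms) {
    r <- numeric(0)
    if (glcArmed) r <- c(r, max(y[iMG] / y[iV], 0) - opts$epsG)
    if (is.finite(opts$Vmax)) r <- c(r, y[iV] - opts$Vmax)
    if (is.finite(opts$OTRmax)) {
      s <- evalStep(t, y)
      our <- if (!is.na(ctx$o2Idx))
        -s$v[ctx$o2Idx] * ctx$mw[["oxygen"]] * s$X else 0
      r <- c(r, our - opts$OTRmax)
    }
    r
  }
  useRoots <- function() glcArmed || is.finite(opts$Vmax) ||
    is.finite(opts$OTRmax)

  outTimes <- opts$outTimes %||% seq(0, tEnd, by = opts$dt)
  outTimes <- sort(unique(c(outTimes, tEnd)))
  breaks <- c(0, tEnd)
  if (th[["T_Fed"]] > 0 && th[["T_Fed"]] < tEnd)
    breaks <- c(breaks, th[["T_Fed"]])
  if (!is.null(policy)) {
    if (policy@ti > 0 && policy@ti < tEnd) breaks <- c(breaks, policy@ti)
    if (is.finite(policy@feedEnd) && policy@feedEnd < tEnd)
      breaks <- c(breaks, policy@feedEnd)
  }
  breaks <- sort(unique(breaks))

  events <- list()
  if (!is.null(policy) && policy@ti <= tEnd)
    events[[length(events) + 1L]] <- data.frame(time = policy@ti,
                                                kind = "feed_start")
  if (th[["T_Fed"]] <= tEnd)
    events[[length(events) + 1L]] <- data.frame(time = th[["T_Fed"]],
                                                kind = "consumption_switch")

  rows <- list()
  tcur <- 0; ycur <- y0
  terminated <- FALSE
  # limits already violated by the initial state terminate immediately
  if (is.finite(opts$Vmax) && y0[iV] >= opts$Vmax) {
    events[[length(events) + 1L]] <- data.frame(time = 0,
                                                kind = "volume_limit")
    terminated <- TRUE
  } else if (is.finite(opts$OTRmax)) {
    s0 <- evalStep(0, y0)
    our0 <- if (!is.na(ctx$o2Idx))
      -s0$v[ctx$o2Idx] * ctx$mw[["oxygen"]] * s0$X else 0
    if (our0 >= opts$OTRmax) {
      events[[length(events) + 1L]] <- data.frame(time = 0,
                                                  kind = "otr_limit")
      terminated <- TRUE
    }
  }
  if (!terminated) for (si in seq_len(length(breaks) - 1)) {
    segEnd <- breaks[si + 1]
    repeat {
      tt <- sort(unique(c(tcur, outTimes[outTimes > tcur & outTimes < segEnd],
                          segEnd)))
      memo$key <- NULL
      out <- if (useRoots())
        deSolve::lsodar(ycur, tt, rhs, parms = NULL, rtol = opts$rtol,
                        atol = opts$atol, rootfunc = rootfun)
      else
        deSolve::ode(ycur, tt, rhs, parms = NULL, method = opts$method,
                     rtol = opts$rtol, atol = opts$atol)
      rows[[length(rows) + 1L]] <- out[-1, , drop = FALSE]
      last <- out[nrow(out), ]
      tcur <- last[[1]]
      ycur <- last[-1]
      if (tcur >= segEnd - 1e-10) break
      # a root fired before the segment end; identify and handle it
      memo$key <- NULL
      rvals <- rootfun(tcur, ycur, NULL)
      labs <- c(if (glcArmed) "glucose_depleted",
                if (is.finite(opts$Vmax)) "volume_limit",
                if (is.finite(opts$OTRmax)) "otr_limit")
      kind <- labs[which.min(abs(rvals))]
      events[[length(events) + 1L]] <- data.frame(time = tcur, kind = kind)
      if (kind == "glucose_depleted") {
        glcArmed <- FALSE
      } else {
        terminated <- TRUE
        break
      }
    }
    if (terminated) break
  }

  allOut <- do.call(rbind, rows)
  allOut <- rbind(matrix(c(0, y0), 1, dimnames = list(NULL, colnames(allOut))),
                  allOut)
  keep <- vapply(allOut[, 1], function(t)
    any(abs(t - outTimes) < 1e-9), TRUE)
  keep[nrow(allOut)] <- TRUE
  allOut <- allOut[keep & !duplicated(round(allOut[, 1], 9)), , drop = FALSE]

  tOut <- allOut[, 1]
  V <- allOut[, iV + 1]
  X <- allOut[, iMX + 1] / V
  G <- allOut[, iMG + 1] / V
  st <- data.frame(t = tOut, V = V, X = X, G = G)
  for (k in seq_len(nP)) {
    sp <- products[k]
    vn <- if (sp %in% names(.SPECIES_VAR)) .SPECIES_VAR[[sp]] else sp
    st[[vn]] <- allOut[, iMP[k] + 1] / V
  }
  st$cumCO2 <- allOut[, iCO2 + 1]
  st$cumO2 <- allOut[, iO2 + 1]

  fx <- matrix(NA_real_, nrow(st), length(ctx$rxns),
               dimnames = list(NULL, ctx$rxns))
  our <- numeric(nrow(st))
  for (i in seq_len(nrow(st))) {
    memo$key <- NULL
    s <- evalStep(tOut[i], allOut[i, -1])
    fx[i, ] <- s$v
    our[i] <- if (!is.na(ctx$o2Idx))
      -s$v[ctx$o2Idx] * ctx$mw[["oxygen"]] * s$X else NA_real_
  }
  st$OUR <- our

  ev <- do.call(rbind, c(events, relaxEvents))
  if (is.null(ev)) ev <- data.frame(time = numeric(), kind = character())
  ev <- ev[ev$time <= tOut[length(tOut)] + 1e-9, , drop = FALSE]
  ev <- ev[order(ev$time), , drop = FALSE]
  new("Trajectory", times = tOut, states = st, fluxes = fx, events = ev)
}

#' Scan a trajectory for reactor-limit violations
#'
#' @param traj a [Trajectory-class].
#' @param Vmax maximum reactor volume (L).
#' @param OTRmax maximum oxygen transfer rate (g/L/h), compared against the
#'   oxygen uptake rate computed from the oxygen exchange flux.
#' @return list with \code{terminate} (logical), \code{kind}
#'   (\code{"volume"}, \code{"oxygen"} or NA) and \code{time} of the first
#'   violation.
#' @export
checkLimits <- function(traj, Vmax = Inf, OTRmax = Inf) {
  st <- states(traj)
  tol <- 1e-6   # runs stopped by root-finding sit exactly on the limit
  iv <- which(st$V >= Vmax - tol)
  io <- which(!is.na(st$OUR) & st$OUR >= OTRmax - tol)
  tv <- if (length(iv)) st$t[iv[1]] else Inf
  to <- if (length(io)) st$t[io[1]] else Inf
  if (!is.finite(tv) && !is.finite(to))
    return(list(terminate = FALSE, kind = NA_character_, time = NA_real_))
  if (tv <= to) list(terminate = TRUE, kind = "volume", time = tv)
  else list(terminate = TRUE, kind = "oxygen", time = to)
}

#' Effective glucose-to-biomass yield of a network
#'
#' Finds the glucose uptake rate at which the metabolic block grows at
#' \code{mu} (given maintenance and phase constraints with empty by-product
#' pools) and returns the differential yield \eqn{Y_{SX} = \mu / (v_G\,
#' MW_G)} in gDCW/g. Useful for designing a self-consistent exponential
#' feed.
#'
#' @param network a [MetabolicNetwork-class].
#' @param params a [KineticParameters-class] (maintenance and alpha are
#'   honoured; secretion minima are ignored by evaluating the
#'   post-consumption phase with empty pools).
#' @param mu target growth rate (1/h).
#' @return list with \code{YSX} (gDCW/g) and \code{vG} (mmol/gDCW/h).
#' @export
designYield <- function(network, params, mu) {
  ctx <- .simContext(network)
  th <- paramValues(params)
  P0 <- stats::setNames(rep(0, length(ctx$products)), ctx$products)
  muAt <- function(vG) {
    bnd <- .kineticBounds(ctx, G = 0, P = P0, th = th, phase = "post_TFed",
                          epsP = 0.05, consumptionCap = 10)
    bnd$lb[ctx$glcIdx] <- -vG
    alpha <- max(th[["alpha_B"]], 1e-6)
    d <- numeric(length(bnd$lb)); d[ctx$bioIdx] <- (1 - alpha) / alpha
    res <- .qpSolveFull(ctx$S, bnd$lb, bnd$ub, d, cache = ctx$cache)
    if (res$status != "optimal") return(0)   # below maintenance demand
    res$v[ctx$bioIdx]
  }
  f <- function(vG) muAt(vG) - mu
  vG <- stats::uniroot(f, c(1e-6, th[["v_G_max"]]), tol = 1e-10)$root
  list(YSX = mu / (vG * network@mw[["glucose"]]), vG = vG)
}
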