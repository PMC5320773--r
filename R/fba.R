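# Metabolic block: bi-objective growth/flux-norm QP and MOMA.
#
# All problems share the feasible set {v : S v = 0, lb <= v <= ub} and a
# strictly convex quadratic objective, solved with quadprog after
# eliminating the equality constraints through a null-space (SVD)
# parametrization. The SVD route is robust to the linearly dependent rows
# that stoichiometric matrices routinely contain (conserved moieties), which
# break naive equality handling in active-set solvers.

#' @importFrom quadprog solve.QP
NULL

.FLUX_CAP <- 1000          # COBRA convention for "unbounded" internal fluxes
.FIX_TOL <- 1e-10          # ub - lb below this treats a variable as fixed

# Solve min v'v - d'v  s.t.  S v = rhs, lb <= v <= ub  (free variables only;
# fixed ones must already be removed). Returns list(v, status). `sv` may
# carry a precomputed svd(S, nu = nrow(S), nv = ncol(S)).
.qpNullspace <- function(S, rhs, d, lb, ub, feasTol = 1e-6, sv = NULL) {
  n <- length(lb)
  if (n == 0) return(list(v = numeric(0), status = "optimal"))
  if (is.null(sv)) sv <- svd(S, nu = nrow(S), nv = n)
  tolS <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps
  r <- sum(sv$d > tolS)
  # particular (minimum-norm) solution of S v = rhs
  if (r > 0) {
    p <- sv$v[, seq_len(r), drop = FALSE] %*%
      ((crossprod(sv$u[, seq_len(r), drop = FALSE], rhs)) / sv$d[seq_len(r)])
    p <- drop(p)
  } else p <- numeric(n)
  if (max(abs(S %*% p - rhs)) > feasTol * max(1, max(abs(rhs))))
    return(list(v = NULL, status = "infeasible"))
  N <- sv$v[, seq.int(r + 1, length.out = n - r), drop = FALSE]
  if (ncol(N) == 0) {
    ok <- all(p >= lb - feasTol) && all(p <= ub + feasTol)
    return(list(v = if (ok) pmin(pmax(p, lb), ub) else NULL,
                status = if (ok) "optimal" else "infeasible"))
  }
  # variables (near-)fully determined by the equalities have tiny rows in
  # N; their box constraints degenerate to feasibility checks and must not
  # reach the active-set solver, whose pivoting breaks on vanishing
  # constraint normals. The remaining constraint rows are normalized to
  # unit normals for numerical robustness.
  norms <- sqrt(rowSums(N^2))
  det <- norms < 1e-9
  if (any(det)) {
    if (any(p[det] < lb[det] - feasTol) || any(p[det] > ub[det] + feasTol))
      return(list(v = NULL, status = "infeasible"))
  }
  Dmat <- 2 * crossprod(N)
  dvec <- drop(crossprod(N, d - 2 * p))
  Nc <- N[!det, , drop = FALSE] / norms[!det]
  Amat <- cbind(t(Nc), -t(Nc))
  bvec <- c((lb[!det] - p[!det]) / norms[!det],
            (p[!det] - ub[!det]) / norms[!det])
  trySolve <- function(bv) tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bv, meq = 0),
    error = function(e) e)
  sol <- trySolve(bvec)
  if (inherits(sol, "error") &&
      grepl("inconsistent", conditionMessage(sol))) {
    # the active-set method reports degenerate (duplicate-normal)
    # constraint sets as inconsistent; a deterministic sub-feasTol
    # relaxation breaks the ties without materially moving the optimum
    m <- length(bvec)
    sol <- trySolve(bvec - 1e-9 * seq_len(m) / m)
  }
  if (inherits(sol, "error")) {
    status <- if (grepl("inconsistent", conditionMessage(sol)))
      "infeasible" else "numeric-failure"
    return(list(v = NULL, status = status))
  }
  v <- drop(p + N %*% sol$solution)
  list(v = pmin(pmax(v, lb), ub), status = "optimal")
}

# Full-network quadratic solve with fixed-variable elimination.
# Objective (over all variables): sum v_i^2 - sum d_i v_i. `cache` (an
# environment) memoizes the SVD of the free-column submatrix keyed by the
# fixed-variable pattern, which is constant across the many solves of a
# dynamic simulation.
.qpSolveFull <- function(S, lb, ub, d, feasTol = 1e-6, cache = NULL) {
  n <- length(lb)
  fixed <- (ub - lb) < .FIX_TOL
  vfix <- (lb + ub) / 2
  v <- numeric(n)
  v[fixed] <- vfix[fixed]
  if (all(fixed)) {
    ok <- max(abs(S %*% v)) <= feasTol
    return(list(v = if (ok) v else NULL,
                status = if (ok) "optimal" else "infeasible"))
  }
  rhs <- if (any(fixed))
    drop(-S[, fixed, drop = FALSE] %*% vfix[fixed]) else numeric(nrow(S))
  Sf <- S[, !fixed, drop = FALSE]
  sv <- NULL
  if (!is.null(cache)) {
    key <- paste(which(fixed), collapse = ",")
    sv <- cache[[paste0("k", key)]]
    if (is.null(sv)) {
      sv <- svd(Sf, nu = nrow(Sf), nv = ncol(Sf))
      cache[[paste0("k", key)]] <- sv
    }
  }
  res <- .qpNullspace(Sf, rhs, d[!fixed], lb[!fixed], ub[!fixed], feasTol, sv)
  if (is.null(res$v)) return(res)
  v[!fixed] <- res$v
  list(v = v, status = "optimal")
}

.forcedBoundsMsg <- function(network) {
  forced <- which(network@lb > 0 | network@ub < 0)
  if (!length(forced)) return("none")
  paste(sprintf("%s[%g,%g]", network@rxns[forced],
                network@lb[forced], network@ub[forced]), collapse = ", ")
}

.cappedBounds <- function(network, fluxCap) {
  lb <- pmax(network@lb, -fluxCap)
  ub <- pmin(network@ub, fluxCap)
  list(lb = lb, ub = ub)
}

.mkFlux <- function(network, v, alpha, obj, status) {
  if (is.null(v)) v <- rep(NA_real_, length(network@rxns))
  names(v) <- network@rxns
  mu <- if (status == "optimal") v[[network@biomassRxn]] else NA_real_
  new("FluxDistribution", v = v, mu = mu, alpha = alpha,
      objectiveValue = obj, status = status)
}

#' Solve the bi-objective growth / flux-norm problem
#'
#' Solves \deqn{\min\; \alpha \sum_i v_i^2 - (1-\alpha)\,\mu \quad
#' \mathrm{s.t.}\; S v = 0,\; lb \le v \le ub,} where \eqn{\mu} is the flux
#' of the biomass reaction. For \eqn{\alpha > 0} the problem is strictly
#' convex and the optimum unique; the quadratic term suppresses
#' thermodynamically infeasible internal cycles (type III pathways). For
#' \eqn{\alpha = 0} the growth-maximisation linear program is solved by
#' bisection on \eqn{\mu} over feasibility QPs, and the returned flux vector
#' is the minimum-norm distribution at the optimal growth rate (the LP
#' optimum is degenerate in \eqn{v}; the minimum-norm representative makes
#' the result deterministic).
#'
#' @param network a [MetabolicNetwork-class] with the kinetic constraints
#'   already applied.
#' @param alpha suboptimal growth coefficient in \eqn{[0, 1)}.
#' @param fluxCap magnitude at which unbounded fluxes are capped
#'   (mmol/gDCW/h).
#' @param feasTol feasibility tolerance on \eqn{S v = 0} and bounds.
#' @return a [FluxDistribution-class]; \code{solverStatus()} is
#'   \code{"infeasible"} when the constraint set is empty, in which case the
#'   message records the forced (sign-constrained) bounds.
#' @export
solveBiObjective <- function(network, alpha = 0, fluxCap = .FLUX_CAP,
                             feasTol = 1e-6) {
  stopifnot(is(network, "MetabolicNetwork"), alpha >= 0, alpha < 1)
  bb <- .cappedBounds(network, fluxCap)
  S <- as.matrix(network@S)
  bio <- match(network@biomassRxn, network@rxns)
  n <- length(network@rxns)
  if (alpha > 0) {
    d <- numeric(n); d[bio] <- (1 - alpha) / alpha
    res <- .qpSolveFull(S, bb$lb, bb$ub, d, feasTol)
    obj <- if (res$status == "optimal")
      alpha * sum(res$v^2) - (1 - alpha) * res$v[bio] else NA_real_
    fd <- .mkFlux(network, res$v, alpha, obj, res$status)
  } else {
    res <- .lpMaxGrowth(S, bb$lb, bb$ub, bio, feasTol)
    obj <- if (res$status == "optimal") -res$v[bio] else NA_real_
    fd <- .mkFlux(network, res$v, 0, obj, res$status)
  }
  if (fd@status == "infeasible")
    attr(fd, "forcedBounds") <- .forcedBoundsMsg(network)
  fd
}

# Growth-maximisation LP by bisection on mu, with a minimum-norm QP as the
# feasibility oracle; final flux vector is the minimum-norm solution at the
# optimal growth rate.
.lpMaxGrowth <- function(S, lb, ub, bio, feasTol = 1e-6, muTol = 1e-9,
                         cache = NULL) {
  zero <- numeric(length(lb))
  feasAt <- function(mu) {
    l <- lb; l[bio] <- mu
    u <- ub; u[bio] <- max(ub[bio], mu)
    .qpSolveFull(S, l, u, zero, feasTol, cache)
  }
  base <- .qpSolveFull(S, lb, ub, zero, feasTol, cache)
  if (base$status != "optimal") return(base)
  lo <- base$v[bio]
  hi <- ub[bio]
  if (feasAt(hi)$status == "optimal") {
    lo <- hi
  } else {
    while (hi - lo > muTol * max(1, abs(hi))) {
      mid <- (lo + hi) / 2
      if (feasAt(mid)$status == "optimal") lo <- mid else hi <- mid
    }
  }
  feasAt(lo)
}

#' Minimisation of metabolic adjustment (MOMA)
#'
#' Projects a parental flux distribution onto the feasible set of a
#' (typically knockout) network: \deqn{\min\; \|v_0 - v\|^2 \quad
#' \mathrm{s.t.}\; S v = 0,\; lb \le v \le ub.} The distance is zero exactly
#' when the parental fluxes remain feasible in the perturbed network.
#'
#' @param network_ko the perturbed [MetabolicNetwork-class].
#' @param v0 parental fluxes: a [FluxDistribution-class] or a named numeric
#'   vector matching the network's reactions.
#' @param fluxCap,feasTol as in [solveBiObjective()].
#' @return a [FluxDistribution-class]; \code{objectiveValue} holds the
#'   squared Euclidean distance, \code{alpha} is NA. Infeasible networks
#'   (lethal deletions at these constraints) return status
#'   \code{"infeasible"}.
#' @export
solveMOMA <- function(network_ko, v0, fluxCap = .FLUX_CAP, feasTol = 1e-6) {
  stopifnot(is(network_ko, "MetabolicNetwork"))
  if (is(v0, "FluxDistribution")) v0 <- fluxes(v0)
  if (length(v0) != length(network_ko@rxns))
    stop("v0 dimension (", length(v0), ") does not match the network (",
         length(network_ko@rxns), " reactions)")
  if (!is.null(names(v0))) v0 <- v0[network_ko@rxns]
  bb <- .cappedBounds(network_ko, fluxCap)
  res <- .qpSolveFull(as.matrix(network_ko@S), bb$lb, bb$ub, 2 * v0, feasTol)
  obj <- if (res$status == "optimal") sum((v0 - res$v)^2) else NA_real_
  fd <- .mkFlux(network_ko, res$v, NA_real_, obj, res$status)
  if (fd@status == "infeasible")
    attr(fd, "forcedBounds") <- .forcedBoundsMsg(network_ko)
  fd
}

#' Export a flux distribution as TSV
#'
#' @param fd a [FluxDistribution-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeFluxes <- function(fd, path) {
  utils::write.table(
    data.frame(reaction = names(fluxes(fd)), flux = unname(fluxes(fd))),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
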