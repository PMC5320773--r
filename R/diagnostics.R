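# Pre/post-regression diagnostics: relative sensitivities, identifiability
# (sensitivity-column correlations), FIM-based significance, the iterative
# reparametrization loop, structure scoring and goodness of fit.
#
# All operations work on a generic "model function": a function of a named
# parameter vector returning a numeric matrix of state variables at the
# measurement times (rows = times, named columns = variables). For
# cultivation models, makeModelFn() builds one from a network + dataset.

#' @importFrom nortest ad.test
NULL

#' Build a model function for diagnostics from a cultivation setup
#'
#' @param network a [MetabolicNetwork-class].
#' @param params a [KineticParameters-class] (supplies fixed values).
#' @param initial initial state, see [simulateCultivation()].
#' @param times output times (h).
#' @param variables state columns to report.
#' @param policy a [FeedPolicy-class] or NULL.
#' @param options simulation options.
#' @return a function \code{theta -> matrix} suitable for
#'   [relativeSensitivity()]; \code{theta} is a named numeric overriding
#'   the corresponding entries of \code{params}.
#' @export
makeModelFn <- function(network, params, initial, times, variables,
                        policy = NULL, options = list()) {
  options$outTimes <- times
  tEnd <- max(times)
  function(theta) {
    p <- setParamValues(params, theta)
    traj <- simulateCultivation(network, p, initial, tEnd, policy = policy,
                                options = options)
    st <- states(traj)
    out <- vapply(variables, function(vn)
      stats::approx(st$t, st[[vn]], xout = times, rule = 2)$y,
      numeric(length(times)))
    matrix(out, nrow = length(times), dimnames = list(NULL, variables))
  }
}

#' Time-resolved relative parameter sensitivities
#'
#' Computes \eqn{g_{ik}(t) = \theta_k / X_i(t) \cdot dX_i(t)/d\theta_k} by
#' central finite differences with relative step \code{h_rel} (one-sided at
#' bound edges or when a perturbed simulation fails, with a warning). Times
#' where \eqn{|X_i| < \epsilon_X} are skipped. The per-(variable,
#' parameter) score is the mean of \eqn{|g_{ik}|} over the remaining
#' times; a parameter whose score is below \code{threshold} for every
#' variable is flagged insensitive.
#'
#' @param modelFn function of a named parameter vector returning a matrix
#'   (times x variables), e.g. from [makeModelFn()].
#' @param theta named numeric of parameter values at which to evaluate.
#' @param h_rel relative finite-difference step.
#' @param epsX guard floor on \eqn{|X_i(t)|}.
#' @param lower,upper optional named bounds; steps crossing them fall back
#'   to one-sided differences.
#' @param threshold insensitivity threshold on the averaged score.
#' @return an object of class \code{SensitivityResult}: arrays \code{g}
#'   (relative) and \code{jac} (absolute, \eqn{dX/d\theta}) of dimension
#'   time x variable x parameter, the score matrix \code{avg}, and the
#'   \code{insensitive} parameter set.
#' @export
relativeSensitivity <- function(modelFn, theta, h_rel = 1e-3, epsX = 1e-8,
                                lower = NULL, upper = NULL,
                                threshold = 0.01) {
  Y0 <- modelFn(theta)
  vars <- colnames(Y0)
  nt <- nrow(Y0); nv <- ncol(Y0); np <- length(theta)
  g <- jac <- array(NA_real_, c(nt, nv, np),
                    dimnames = list(NULL, vars, names(theta)))
  evalAt <- function(th) tryCatch(modelFn(th), error = function(e) NULL)
  for (k in seq_len(np)) {
    nm <- names(theta)[k]
    step <- h_rel * max(abs(theta[k]), h_rel)
    up <- theta; up[k] <- theta[k] + step
    dn <- theta; dn[k] <- theta[k] - step
    okUp <- is.null(upper) || is.na(upper[nm]) || up[k] <= upper[nm]
    okDn <- is.null(lower) || is.na(lower[nm]) || dn[k] >= lower[nm]
    Yup <- if (okUp) evalAt(up) else NULL
    Ydn <- if (okDn) evalAt(dn) else NULL
    if (!is.null(Yup) && !is.null(Ydn)) {
      J <- (Yup - Ydn) / (2 * step)
    } else if (!is.null(Yup)) {
      warning("one-sided (forward) difference for ", nm)
      J <- (Yup - Y0) / step
    } else if (!is.null(Ydn)) {
      warning("one-sided (backward) difference for ", nm)
      J <- (Y0 - Ydn) / step
    } else {
      warning("both perturbed evaluations failed for ", nm,
              "; sensitivities set to NA")
      next
    }
    jac[, , k] <- J
    gk <- theta[k] / Y0 * J
    gk[abs(Y0) < epsX] <- NA
    g[, , k] <- gk
  }
  avg <- apply(abs(g), c(2, 3), function(x)
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  score <- apply(avg, 2, function(x)
    if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
  structure(list(g = g, jac = jac, avg = avg,
                 insensitive = names(theta)[score < threshold],
                 theta = theta, threshold = threshold, Y0 = Y0),
            class = "SensitivityResult")
}

#' @export
print.SensitivityResult <- function(x, ...) {
  cat("SensitivityResult over", dim(x$g)[1], "times,", dim(x$g)[2],
      "variables,", dim(x$g)[3], "parameters\n")
  print(round(x$avg, 4))
  cat("insensitive (all scores <", x$threshold, "):",
      if (length(x$insensitive)) paste(x$insensitive, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Practical identifiability from sensitivity-column correlations
#'
#' Stacks the relative sensitivities over (time x variable) and computes
#' Pearson correlations between parameter columns; pairs with
#' \eqn{|C_{jk}|} at or above the threshold are flagged as not separately
#' identifiable. Zero-variance columns have undefined correlations and are
#' reported as insensitive instead of flagged.
#'
#' @param sens a \code{SensitivityResult}.
#' @param threshold flagging threshold (inclusive).
#' @return an object of class \code{IdentifiabilityResult}: the correlation
#'   matrix \code{Cmat}, the \code{flagged} pair table, and
#'   \code{zeroVariance} parameters.
#' @export
identifiability <- function(sens, threshold = 0.95) {
  np <- dim(sens$g)[3]
  pn <- dimnames(sens$g)[[3]]
  stacked <- matrix(sens$g, ncol = np, dimnames = list(NULL, pn))
  keepRows <- rowSums(is.na(stacked)) == 0
  stacked <- stacked[keepRows, , drop = FALSE]
  if (nrow(stacked) < 3)
    stop("need at least 3 complete stacked sensitivity rows")
  sdv <- apply(stacked, 2, stats::sd)
  zero <- pn[sdv < 1e-12]
  ok <- setdiff(pn, zero)
  Cmat <- matrix(NA_real_, np, np, dimnames = list(pn, pn))
  diag(Cmat) <- 1
  if (length(ok) >= 2)
    Cmat[ok, ok] <- stats::cor(stacked[, ok, drop = FALSE])
  flagged <- data.frame(p1 = character(), p2 = character(), C = numeric())
  if (length(ok) >= 2) {
    idx <- which(upper.tri(Cmat[ok, ok, drop = FALSE]) &
                   abs(Cmat[ok, ok, drop = FALSE]) >= threshold,
                 arr.ind = TRUE)
    if (nrow(idx))
      flagged <- data.frame(p1 = ok[idx[, 1]], p2 = ok[idx[, 2]],
                            C = Cmat[ok, ok][idx],
                            stringsAsFactors = FALSE)
  }
  structure(list(Cmat = Cmat, flagged = flagged, zeroVariance = zero,
                 threshold = threshold),
            class = "IdentifiabilityResult")
}

#' @export
print.IdentifiabilityResult <- function(x, ...) {
  cat("IdentifiabilityResult (threshold", x$threshold, "):",
      nrow(x$flagged), "flagged pair(s)\n")
  if (nrow(x$flagged)) print(x$flagged)
  if (length(x$zeroVariance))
    cat("zero-variance columns:", paste(x$zeroVariance, collapse = ", "), "\n")
  invisible(x)
}

#' Parameter significance from the Fisher Information Matrix
#'
#' \deqn{FIM = \sum_j g_j^T Q_j g_j,} summed over measurement times, with
#' \eqn{g_j} the absolute sensitivity matrix \eqn{dX/d\theta} at time j and
#' \eqn{Q_j} the inverse measurement-error covariance (diagonal, white
#' uncorrelated noise). Parameter variances are the diagonal of
#' \eqn{FIM^{-1}}; 95% confidence intervals are
#' \eqn{\hat\theta_k \pm 1.96\sigma_k} and the coefficient of confidence is
#' \eqn{CC_k = 2\cdot 1.96 \sigma_k/\hat\theta_k}. A parameter is
#' non-significant when \eqn{|CC_k| \ge 2}, equivalently when its CI
#' contains zero.
#'
#' @param sens a \code{SensitivityResult} evaluated at \code{theta_hat}.
#' @param theta_hat named estimates (default: the sensitivity expansion
#'   point).
#' @param noise measurement-noise model: either \code{list(sd = ...)} with
#'   a named per-variable SD, or \code{list(cv = 0.05, max = ...)} for
#'   proportional error \code{sd_i = cv * max_i} relative to each
#'   variable's maximum measurement (the default mirrors the 5%
#'   proportional error assumed elsewhere).
#' @param ccThreshold non-significance threshold on |CC| (inclusive).
#' @return an object of class \code{SignificanceResult}: \code{FIM},
#'   \code{sigma2}, the \code{CI} matrix, \code{CC}, and the
#'   \code{nonsignificant} set.
#' @export
significance <- function(sens, theta_hat = sens$theta,
                         noise = list(cv = 0.05), ccThreshold = 2) {
  vars <- dimnames(sens$jac)[[2]]
  pn <- dimnames(sens$jac)[[3]]
  np <- length(pn)
  if (!is.null(noise$sd)) {
    sdv <- noise$sd[vars]
  } else {
    cv <- noise$cv %||% 0.05
    mx <- if (!is.null(noise$max)) noise$max[vars]
          else apply(abs(sens$Y0), 2, max)
    sdv <- cv * mx
  }
  if (any(!is.finite(sdv)) || any(sdv <= 0))
    stop("noise model yields non-positive SD for some variable")
  w <- 1 / sdv^2
  FIM <- matrix(0, np, np, dimnames = list(pn, pn))
  for (j in seq_len(dim(sens$jac)[1])) {
    Jj <- matrix(sens$jac[j, , ], nrow = length(vars))
    if (anyNA(Jj)) next
    FIM <- FIM + t(Jj) %*% (w * Jj)
  }
  ev <- eigen(FIM, symmetric = TRUE)
  tol <- max(ev$values) * 1e-10
  rankDef <- sum(ev$values <= tol)
  if (rankDef > 0) {
    warning("FIM is singular (rank deficiency ", rankDef,
            "); using a pseudo-inverse. Null-space directions involve: ",
            paste(unique(unlist(lapply(which(ev$values <= tol), function(i)
              pn[abs(ev$vectors[, i]) > 0.3]))), collapse = ", "))
    inv <- ev$vectors %*% diag(ifelse(ev$values > tol, 1 / ev$values, 0),
                               np) %*% t(ev$vectors)
  } else {
    inv <- ev$vectors %*% diag(1 / ev$values, np) %*% t(ev$vectors)
  }
  sigma2 <- stats::setNames(pmax(diag(inv), 0), pn)
  sigma <- sqrt(sigma2)
  th <- theta_hat[pn]
  CI <- cbind(lower = th - 1.96 * sigma, upper = th + 1.96 * sigma)
  CC <- stats::setNames(2 * 1.96 * sigma / th, pn)
  structure(list(FIM = FIM, sigma2 = sigma2, CI = CI, CC = CC,
                 nonsignificant = pn[!is.finite(CC) | abs(CC) >= ccThreshold],
                 ccThreshold = ccThreshold, rankDeficiency = rankDef),
            class = "SignificanceResult")
}

#' @export
print.SignificanceResult <- function(x, ...) {
  df <- data.frame(sigma = sqrt(x$sigma2), CI_lower = x$CI[, 1],
                   CI_upper = x$CI[, 2], CC = x$CC)
  print(round(df, 5))
  cat("non-significant (|CC| >=", x$ccThreshold, "):",
      if (length(x$nonsignificant)) paste(x$nonsignificant, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Iterative reparametrization: fix problematic parameters one by one
#'
#' Runs the sensitivity and identifiability diagnostics at the current
#' estimate and, while problems remain, fixes one parameter per round at
#' its fixation value: first any insensitive parameter (lowest score
#' first), otherwise the member of the most-correlated flagged pair with
#' the lower sensitivity score. After each fixation the model is
#' recalibrated. When no sensitivity/identifiability issue remains,
#' significance is determined once for the surviving adjustable set.
#'
#' @param problem a calibration problem as for [calibrate()], additionally
#'   providing \code{modelFn} (a function of the full named parameter
#'   vector returning the times x variables matrix used by the
#'   diagnostics) and optionally \code{noise} for [significance()] and
#'   \code{fixation} (named fixation values; defaults to
#'   [fixationDefaults()] entries, else the current value).
#' @param seed,budget passed to [calibrate()] (the seed is advanced each
#'   round to keep rounds independent but reproducible).
#' @param sensThreshold,corThreshold diagnostic thresholds.
#' @param maxRounds safety cap (default: number of adjustable parameters).
#' @return an object of class \code{ReparametrizationResult}: the reduced
#'   \code{params}, final \code{result}, the fixation \code{trail}
#'   (round, parameter, trigger, value), the final \code{significance}, and
#'   an \code{irreducible} flag set when one adjustable parameter remains
#'   with unresolved issues.
#' @export
reparametrize <- function(problem, seed = 1L, budget = 400L,
                          sensThreshold = 0.01, corThreshold = 0.95,
                          maxRounds = NULL) {
  params <- problem$params
  if (is.null(problem$modelFn))
    stop("problem$modelFn is required for the diagnostics loop")
  fixation <- problem$fixation
  if (is.null(fixation)) {
    fixation <- fixationDefaults()
  }
  maxRounds <- maxRounds %||% sum(params@adjustable)
  trail <- data.frame(round = integer(), parameter = character(),
                      trigger = character(), value = numeric(),
                      stringsAsFactors = FALSE)
  result <- NULL
  irreducible <- FALSE
  round <- 0L
  repeat {
    round <- round + 1L
    prob <- problem
    prob$params <- params
    result <- calibrate(prob, seed = seed + round - 1L, budget = budget)
    adj <- adjustableParams(result@parameters)
    if (!length(adj)) break
    thetaAdj <- result@theta[adj]
    wrapFn <- function(th) {
      full <- result@theta
      full[names(th)] <- th
      problem$modelFn(full)
    }
    sens <- relativeSensitivity(wrapFn, thetaAdj,
                                lower = params@lb[adj], upper = params@ub[adj],
                                threshold = sensThreshold)
    ident <- identifiability(sens, threshold = corThreshold)
    insens <- union(sens$insensitive, ident$zeroVariance)
    score <- apply(sens$avg, 2, function(x)
      if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
    if (length(insens)) {
      fix <- insens[which.min(score[insens])]
      trigger <- "insensitive"
    } else if (nrow(ident$flagged)) {
      top <- ident$flagged[which.max(abs(ident$flagged$C)), ]
      pair <- c(top$p1, top$p2)
      fix <- pair[which.min(score[pair])]
      trigger <- sprintf("correlated with %s (C = %.3f)",
                         setdiff(pair, fix), top$C)
    } else break
    if (length(adj) <= 1) { irreducible <- TRUE; break }
    at <- if (fix %in% names(fixation)) fixation[[fix]] else result@theta[[fix]]
    params <- fixParams(result@parameters, fix, at = at)
    trail <- rbind(trail, data.frame(round = round, parameter = fix,
                                     trigger = trigger, value = at,
                                     stringsAsFactors = FALSE))
    if (round >= maxRounds) break
  }
  sig <- NULL
  adj <- adjustableParams(result@parameters)
  if (length(adj) && !irreducible) {
    thetaAdj <- result@theta[adj]
    wrapFn <- function(th) {
      full <- result@theta
      full[names(th)] <- th
      problem$modelFn(full)
    }
    sens <- relativeSensitivity(wrapFn, thetaAdj,
                                lower = params@lb[adj],
                                upper = params@ub[adj])
    sig <- significance(sens, thetaAdj, noise = problem$noise %||%
                          list(cv = 0.05))
  }
  structure(list(params = result@parameters, result = result, trail = trail,
                 significance = sig, irreducible = irreducible),
            class = "ReparametrizationResult")
}

#' @export
print.ReparametrizationResult <- function(x, ...) {
  cat("ReparametrizationResult:", nrow(x$trail), "parameter(s) fixed",
      if (x$irreducible) "(irreducible structure)" else "", "\n")
  if (nrow(x$trail)) print(x$trail)
  invisible(x)
}

#' Compare an original and a reduced model structure
#'
#' \deqn{J_{DIFF} = \frac{1}{n}\sum_i
#' \frac{J_{i,Reduced} - J_{i,Original}}{J_{i,Original}}} over n datasets
#' (negative = the reduced structure fits better), plus the bookkeeping of
#' diagnostic determinations: a structure with p parameters calibrated on n
#' datasets undergoes \eqn{p\cdot n} significance (and sensitivity)
#' determinations and \eqn{p(p-1)/2 \cdot n} identifiability pair
#' determinations.
#'
#' @param J_original,J_reduced per-dataset objective values (equal length).
#' @param p number of parameters of the reduced structure.
#' @param n number of datasets.
#' @param significanceIssues,sensitivityIssues,identifiabilityIssues issue
#'   counts over all determinations.
#' @return an object of class \code{StructureSummary} with \code{J_DIFF},
#'   the determination counts and issue percentages.
#' @export
structureSummary <- function(J_original, J_reduced, p, n,
                             significanceIssues = 0, sensitivityIssues = 0,
                             identifiabilityIssues = 0) {
  stopifnot(length(J_original) == length(J_reduced))
  ok <- J_original != 0
  if (any(!ok)) warning(sum(!ok), " dataset(s) with J_original = 0 excluded")
  J_DIFF <- mean((J_reduced[ok] - J_original[ok]) / J_original[ok])
  determinations <- p * n
  totalPairs <- p * (p - 1) / 2 * n
  structure(list(
    J_DIFF = J_DIFF,
    determinations = determinations,
    total_pairs = totalPairs,
    pct_significance_issues = 100 * significanceIssues / determinations,
    pct_sensitivity_issues = 100 * sensitivityIssues / determinations,
    pct_identifiability_issues =
      if (totalPairs > 0) 100 * identifiabilityIssues / totalPairs else NA,
    p = p, n = n), class = "StructureSummary")
}

#' @export
print.StructureSummary <- function(x, ...) {
  cat(sprintf(
    "StructureSummary (p = %d, n = %d): J_DIFF = %.4f\n  %d significance determinations (%.1f%% issues), %d pairs (%.1f%% issues)\n",
    x$p, x$n, x$J_DIFF, x$determinations, x$pct_significance_issues,
    x$total_pairs, x$pct_identifiability_issues))
  invisible(x)
}

#' Goodness of fit: mean normalized error and residual normality
#'
#' Per variable, \deqn{MNE_i = \frac{\sum_j (X^{mod}_{ij} - X^{exp}_{ij})}
#' {n \cdot \max_j X^{exp}_{ij}}} (signed: positive = the model
#' overestimates), plus an Anderson-Darling composite-normality test on the
#' raw residuals; a variable passes when p >= 0.05. Residual series that
#' are constant or shorter than the test's minimum are reported as not
#' testable.
#'
#' @param traj a [Trajectory-class] (dense output; interpolated at the
#'   measurement times).
#' @param dataset a [CultivationData-class].
#' @return an object of class \code{FitReport}: data.frame with one row
#'   per variable (n, MNE, AD p-value, testable, pass).
#' @export
goodnessOfFit <- function(traj, dataset) {
  df <- measurements(dataset)
  rows <- lapply(unique(df$variable), function(vn) {
    d <- df[df$variable == vn, ]
    mod <- .trajValues(traj, vn, d$time_h)
    res <- mod - d$value
    n <- length(res)
    mne <- sum(res) / (n * max(d$value))
    testable <- n >= 8 && stats::sd(res) > 1e-12
    p <- if (testable) nortest::ad.test(res)$p.value else NA_real_
    data.frame(variable = vn, n = n, MNE = mne, ad_p = p,
               testable = testable,
               pass = if (testable) p >= 0.05 else NA,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("FitReport", "data.frame"))
}
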