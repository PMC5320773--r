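# diagnostics: sensitivities vs analytic oracles, identifiability,
# FIM significance, the reparametrization loop, structure scoring, fit
# quality.

# closed-form exponential growth model: X(t) = X0 exp(mu t)
expModelFn <- function(times, X0 = 0.5) {
  function(theta) {
    out <- cbind(X = X0 * exp(theta[["mu"]] * times))
    if ("inert" %in% names(theta)) out <- cbind(out, Z = times * 0 + 1)
    out
  }
}

test_that("FD sensitivities match the analytic g = mu*t on exponential growth", {
  times <- seq(0.5, 10, by = 0.5)
  sens <- relativeSensitivity(expModelFn(times), c(mu = 0.2))
  g <- sens$g[, "X", "mu"]
  expect_equal(g, 0.2 * times, tolerance = 1e-3)
  # halving the step changes the averaged score by far less than 5%
  sens2 <- relativeSensitivity(expModelFn(times), c(mu = 0.2), h_rel = 5e-4)
  expect_lt(abs(sens2$avg["X", "mu"] - sens$avg["X", "mu"]) /
              sens$avg["X", "mu"], 0.05)
})

test_that("parameters not entering the model are flagged insensitive", {
  times <- seq(1, 10)
  sens <- relativeSensitivity(expModelFn(times), c(mu = 0.2, inert = 3))
  expect_true(all(abs(sens$g[, , "inert"]) < 1e-12, na.rm = TRUE))
  expect_identical(sens$insensitive, "inert")
})

test_that("duplicated parameters give identical sensitivity columns", {
  times <- seq(1, 10)
  fn <- function(theta)
    cbind(X = 0.5 * exp((theta[["a"]] + theta[["b"]]) * times))
  sens <- relativeSensitivity(fn, c(a = 0.1, b = 0.1))
  expect_equal(sens$g[, "X", "a"], sens$g[, "X", "b"], tolerance = 1e-6)
  ident <- identifiability(sens)
  expect_equal(nrow(ident$flagged), 1)
  expect_equal(abs(ident$flagged$C), 1, tolerance = 1e-9)
})

test_that("orthogonal sensitivity columns are not flagged", {
  times <- seq(0, 2 * pi, length.out = 41)[-41]
  sens <- list(g = array(c(sin(times), cos(times)),
                         c(length(times), 1, 2),
                         dimnames = list(NULL, "X", c("p1", "p2"))))
  class(sens) <- "SensitivityResult"
  ident <- identifiability(sens)
  expect_lt(abs(ident$Cmat["p1", "p2"]), 0.05)
  expect_equal(nrow(ident$flagged), 0)
})

test_that("the correlation threshold is inclusive at 0.95", {
  # construct two columns with correlation exactly 0.95
  n <- 1000
  set.seed(1)
  x <- stats::rnorm(n)
  e <- stats::rnorm(n)
  e <- stats::residuals(stats::lm(e ~ x))
  y <- 0.95 * x / stats::sd(x) + sqrt(1 - 0.95^2) * e / stats::sd(e)
  x <- x / stats::sd(x)
  expect_equal(stats::cor(x, y), 0.95, tolerance = 1e-12)
  sens <- list(g = array(c(x, y), c(n, 1, 2),
                         dimnames = list(NULL, "X", c("p1", "p2"))))
  class(sens) <- "SensitivityResult"
  ident <- identifiability(sens)
  expect_equal(nrow(ident$flagged), 1)
})

test_that("scalar significance matches the closed form", {
  # constant absolute sensitivity s over n points, measurement SD sigma_m:
  # sigma_k = sigma_m / (s sqrt(n)), CC = 2*1.96*sigma_m/(s sqrt(n) theta)
  n <- 25; s <- 2; sigma_m <- 0.4; theta <- 1.5
  sens <- list(jac = array(s, c(n, 1, 1),
                           dimnames = list(NULL, "X", "p")),
               Y0 = cbind(X = rep(1, n)), theta = c(p = theta))
  class(sens) <- "SensitivityResult"
  sig <- significance(sens, c(p = theta), noise = list(sd = c(X = sigma_m)))
  expect_equal(sqrt(sig$sigma2[["p"]]), sigma_m / (s * sqrt(n)),
               tolerance = 1e-12)
  expect_equal(sig$CC[["p"]], 2 * 1.96 * sigma_m / (s * sqrt(n) * theta),
               tolerance = 1e-12)
  expect_equal(length(sig$nonsignificant), 0)
})

test_that("non-significance (|CC| >= 2) coincides with CI containing zero", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    s <- stats::runif(1, 0.01, 2)
    sigma_m <- stats::runif(1, 0.05, 1)
    theta <- stats::runif(1, 0.01, 1)
    sens <- list(jac = array(s, c(n, 1, 1),
                             dimnames = list(NULL, "X", "p")),
                 Y0 = cbind(X = rep(1, n)), theta = c(p = theta))
    class(sens) <- "SensitivityResult"
    sig <- significance(sens, c(p = theta),
                        noise = list(sd = c(X = sigma_m)))
    containsZero <- sig$CI[1, "lower"] <= 0 && sig$CI[1, "upper"] >= 0
    expect_equal("p" %in% sig$nonsignificant, containsZero)
  }
  # |CC| exactly 2 is non-significant (inclusive)
  n <- 16; s <- 1; theta <- 1
  sigma_m <- 2 * sqrt(n) * theta / (2 * 1.96)   # engineered so CC = 2
  sens <- list(jac = array(s, c(n, 1, 1),
                           dimnames = list(NULL, "X", "p")),
               Y0 = cbind(X = rep(1, n)), theta = c(p = theta))
  class(sens) <- "SensitivityResult"
  sig <- significance(sens, c(p = theta), noise = list(sd = c(X = sigma_m)))
  expect_equal(sig$CC[["p"]], 2, tolerance = 1e-12)
  expect_identical(sig$nonsignificant, "p")
})

test_that("FIM confidence intervals achieve ~95% coverage on a linear model", {
  # y(t) = th1 t + th2 t^2 with known Gaussian noise; the FIM CI is exact
  # for linear models, so empirical coverage over 200 replicates must sit
  # in the 90-98% band
  times <- 1:10
  thTrue <- c(th1 = 0.7, th2 = -0.03)
  Xmat <- cbind(times, times^2)
  sigma_m <- 0.5
  modelFn <- function(theta) cbind(y = drop(Xmat %*% theta))
  set.seed(2024)
  covered <- logical(200)
  for (r in 1:200) {
    yobs <- drop(Xmat %*% thTrue) + stats::rnorm(10, 0, sigma_m)
    est <- stats::coef(stats::lm(yobs ~ Xmat - 1))
    names(est) <- names(thTrue)
    sens <- relativeSensitivity(modelFn, est)
    sig <- significance(sens, est, noise = list(sd = c(y = sigma_m)))
    covered[r] <- sig$CI["th1", "lower"] <= thTrue[["th1"]] &&
      thTrue[["th1"]] <= sig$CI["th1", "upper"]
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.98)
})

test_that("reparametrization fixes an inert parameter in one round", {
  times <- seq(1, 10)
  data <- 0.5 * exp(0.2 * times)
  prob <- list(
    params = parameterSet(c(mu = 0.1, inert = 3),
                          lb = c(mu = 0, inert = 0),
                          ub = c(mu = 1, inert = 10)),
    objective = function(params) {
      th <- paramValues(params)
      sum((0.5 * exp(th[["mu"]] * times) - data)^2)
    },
    modelFn = function(theta)
      cbind(X = 0.5 * exp(theta[["mu"]] * times)),
    fixation = c(inert = 0),
    noise = list(sd = c(X = 0.05)))
  rep <- reparametrize(prob, seed = 1, budget = 200)
  expect_equal(rep$trail$parameter, "inert")
  expect_equal(rep$trail$trigger, "insensitive")
  expect_equal(nrow(rep$trail), 1)
  expect_identical(adjustableParams(rep$params), "mu")
  expect_equal(rep$result@theta[["mu"]], 0.2, tolerance = 1e-3)
  expect_false("mu" %in% rep$significance$nonsignificant)
})

test_that("a confounded product pair is reduced by the correlation rule", {
  times <- seq(0.2, 2, by = 0.2)
  data <- exp(0.06 * times)   # identified combination: a*b = 0.06
  prob <- list(
    params = parameterSet(c(a = 0.5, b = 0.5), lb = c(a = 0.01, b = 0.01),
                          ub = c(a = 1, b = 1)),
    objective = function(params) {
      th <- paramValues(params)
      sum((exp(th[["a"]] * th[["b"]] * times) - data)^2)
    },
    modelFn = function(theta)
      cbind(X = exp(theta[["a"]] * theta[["b"]] * times)),
    fixation = c(a = 0.3, b = 0.3),
    noise = list(sd = c(X = 0.01)))
  rep <- reparametrize(prob, seed = 2, budget = 300)
  expect_equal(nrow(rep$trail), 1)
  expect_match(rep$trail$trigger, "correlated")
  fixed <- rep$trail$parameter
  survivor <- setdiff(c("a", "b"), fixed)
  expect_identical(adjustableParams(rep$params), survivor)
  # the survivor compensates so that the product is recovered
  expect_equal(rep$result@theta[[survivor]] * 0.3, 0.06, tolerance = 0.01)
  expect_false(survivor %in% rep$significance$nonsignificant)
})

test_that("a clean structure is returned unchanged", {
  times <- seq(1, 10)
  data <- 0.5 * exp(0.2 * times)
  prob <- list(
    params = parameterSet(c(mu = 0.15), lb = c(mu = 0), ub = c(mu = 1)),
    objective = function(params)
      sum((0.5 * exp(paramValues(params)[["mu"]] * times) - data)^2),
    modelFn = function(theta) cbind(X = 0.5 * exp(theta[["mu"]] * times)),
    noise = list(sd = c(X = 0.05)))
  rep <- reparametrize(prob, seed = 3, budget = 150)
  expect_equal(nrow(rep$trail), 0)
  expect_false(rep$irreducible)
})

test_that("structure scoring bookkeeping follows the p,n arithmetic", {
  ss <- structureSummary(J_original = rep(1, 8), J_reduced = rep(1, 8),
                         p = 6, n = 8, significanceIssues = 12,
                         identifiabilityIssues = 6)
  expect_equal(ss$determinations, 48)
  expect_equal(ss$total_pairs, 120)
  expect_equal(ss$J_DIFF, 0)
  expect_equal(ss$pct_significance_issues, 25)
  expect_equal(ss$pct_identifiability_issues, 5)
  ss2 <- structureSummary(c(2, 2), c(1, 3), p = 3, n = 2)
  expect_equal(ss2$J_DIFF, 0)          # -0.5 and +0.5 average out
  expect_warning(structureSummary(c(0, 1), c(1, 1), p = 2, n = 2),
                 "excluded")
})

test_that("goodness of fit reports signed MNE and residual normality", {
  p <- batchParams()
  times <- seq(0, 10, by = 1)
  tr <- simulateCultivation(toyNet, p, batchInit, tEnd = 10,
                            options = list(outTimes = times))
  st <- states(tr)
  mk <- function(values) new("CultivationData",
    data = data.frame(variable = "X", time_h = times, value = values,
                      sd = NA),
    meta = list(initial = batchInit))
  # model == data -> MNE 0
  fit0 <- goodnessOfFit(tr, mk(st$X))
  expect_equal(fit0$MNE, 0, tolerance = 1e-12)
  # constant residuals of +1: MNE = +1/max(exp) (signed overestimation)
  tiny <- new("CultivationData",
    data = data.frame(variable = "X", time_h = times[9:11],
                      value = st$X[9:11] - 1, sd = NA),
    meta = list(initial = batchInit))
  fit1 <- goodnessOfFit(tr, tiny)
  expect_equal(fit1$MNE, 1 / max(tiny@data$value), tolerance = 1e-12)
  expect_gt(fit1$MNE, 0)
  # normal residuals pass the AD test; heavily skewed ones fail
  set.seed(11)
  eps <- stats::rnorm(length(times), 0, 0.1)
  fitN <- goodnessOfFit(tr, mk(st$X + eps))
  expect_true(fitN$pass)
  big <- seq(0, 10, length.out = 100)
  trB <- simulateCultivation(toyNet, p, batchInit, tEnd = 10,
                             options = list(outTimes = big))
  stB <- states(trB)
  set.seed(12)
  e2 <- stats::rnorm(100)
  mkB <- function(values) new("CultivationData",
    data = data.frame(variable = "X", time_h = big, value = values, sd = NA),
    meta = list(initial = batchInit))
  fitG <- goodnessOfFit(trB, mkB(stB$X + 0.05 * e2))
  expect_gte(fitG$ad_p, 0.05)
  fitBad <- goodnessOfFit(trB, mkB(stB$X + 0.05 * e2^3))
  expect_lt(fitBad$ad_p, 0.05)
  # constant residuals are not testable
  fitC <- goodnessOfFit(tr, mk(st$X + 1))
  expect_false(fitC$testable)
})
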