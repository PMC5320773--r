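# Dynamic block: conservation, closed-form growth, phase handling, limits.

test_that("batch with SR = 0 conserves volume exactly", {
  tr <- simulateCultivation(toyNet, batchParams(), batchInit, tEnd = 8)
  expect_true(all(states(tr)$V == batchInit$V))
})

test_that("exponential growth matches the closed form when nothing is forced", {
  # all secretion minima zero, glucose far above K_G: mu is the constant QP
  # growth at full uptake and X(t) = X0 exp(mu t)
  p <- batchParams(v_EtOH_B = 0, v_Pyr_B = 0, v_Arab_B = 0, v_Cit_B = 0)
  con <- constrainNetwork(toyNet, list(G = 50, P = NULL), p, "batch")
  muStar <- growthRate(solveBiObjective(con, alpha = 4.1e-4))
  tr <- simulateCultivation(toyNet, p, list(V = 0.5, X = 0.1, G = 50),
                            tEnd = 5)
  st <- states(tr)
  expect_equal(st$X, 0.1 * exp(muStar * st$t), tolerance = 1e-3)
})

test_that("carbon is conserved along a batch trajectory within 0.5%", {
  tr <- simulateCultivation(toyNet, batchParams(), batchInit, tEnd = 14)
  st <- states(tr)
  mw <- molecularWeights(toyNet)
  carbonPool <- function(i) {
    glc <- st$V[i] * st$G[i] / mw[["glucose"]] * 6
    bio <- st$V[i] * st$X[i] * 40          # 40 mmol C per gDCW
    prods <- st$V[i] * (st$EtOH[i] / mw[["ethanol"]] * 2 +
                          st$Arab[i] / mw[["arabitol"]] * 5 +
                          st$Cit[i] / mw[["citrate"]] * 6 +
                          st$Pyr[i] / mw[["pyruvate"]] * 3)
    glc + bio + prods + st$cumCO2[i]
  }
  c0 <- carbonPool(1)
  cAll <- vapply(seq_len(nrow(st)), carbonPool, 0)
  expect_lt(max(abs(cAll - c0)) / c0, 0.005)
})

test_that("concentrations never drop below the numerical floor", {
  # spans glucose depletion, forced consumption after T_Fed, and feeding
  p <- kineticParameters(v_G_max = 6, K_G = 0.0027, m_ATP = 2.18, T_Fed = 20,
                         alpha_B = 4.1e-4, alpha_FB = 2.5e-5,
                         v_EtOH_B = 1.47, v_Pyr_B = 0.13, v_Arab_B = 0.14,
                         v_Cit_B = 0.09, v_EtOH_FB = 1.21, v_Pyr_FB = 0.14,
                         v_Arab_FB = 0.15, v_Cit_FB = 0.008,
                         adjustable = character(0))
  pol <- feedPolicy(GF = 500, YSX = 0.42, ti = 26, Vi = 0.5, Xi = 19,
                    muMax = 0.1, muMin = 0.07, Cdecay = 0.07, SR = 0.002)
  tr <- simulateCultivation(toyNet, p, batchInit, tEnd = 34, policy = pol)
  st <- states(tr)
  conc <- as.matrix(st[, c("X", "G", "EtOH", "Arab", "Cit", "Pyr")])
  expect_gt(min(conc), -1e-6)
  expect_true(all(c("glucose_depleted", "consumption_switch", "feed_start")
                  %in% eventLog(tr)$kind))
  # the feed replenishes glucose and growth resumes
  expect_gt(st$X[nrow(st)], st$X[st$t == 26][1] + 0.5)
})

test_that("a fed-batch run with zero feed reproduces the batch run", {
  p <- batchParams()
  nullPol <- feedPolicy(GF = 500, YSX = 0.5, ti = 0, Vi = 0.5, Xi = 0,
                        muMax = 0.1, muMin = 0.07, Cdecay = 0.07, SR = 0)
  trB <- simulateCultivation(toyNet, p, batchInit, tEnd = 8)
  trF <- simulateCultivation(toyNet, p, batchInit, tEnd = 8,
                             policy = nullPol)
  expect_equal(states(trF), states(trB), tolerance = 1e-12)
})

test_that("halving integrator tolerances barely changes the final state", {
  p <- batchParams()
  tr1 <- simulateCultivation(toyNet, p, batchInit, tEnd = 9,
                             options = list(rtol = 1e-6, atol = 1e-8))
  tr2 <- simulateCultivation(toyNet, p, batchInit, tEnd = 9,
                             options = list(rtol = 5e-7, atol = 5e-9))
  f1 <- states(tr1)[nrow(states(tr1)), c("X", "G", "EtOH", "Arab")]
  f2 <- states(tr2)[nrow(states(tr2)), c("X", "G", "EtOH", "Arab")]
  expect_lt(max(abs(unlist(f1) - unlist(f2)) / pmax(abs(unlist(f1)), 1e-6)),
            1e-3)
})

test_that("reactor limits terminate the integration and are classified", {
  tr <- simulateCultivation(toyNet, batchParams(), batchInit, tEnd = 8)
  expect_false(checkLimits(tr, Vmax = 1)$terminate)     # batch: V constant
  lim <- checkLimits(tr, OTRmax = 0.5)                  # OUR passes 0.5 late
  expect_true(lim$terminate)
  expect_equal(lim$kind, "oxygen")
  expect_gt(lim$time, 0)

  # immediate volume termination when Vmax is below the initial volume
  trV <- simulateCultivation(toyNet, batchParams(),
                             list(V = 0.5, X = 0.25, G = 50), tEnd = 8,
                             policy = feedPolicy(GF = 500, YSX = 0.42,
                                                 ti = 0, Vi = 0.5, Xi = 0.25,
                                                 muMax = 0.1, muMin = 0.1,
                                                 Cdecay = 0),
                             options = list(Vmax = 0.4999))
  expect_true("volume_limit" %in% eventLog(trV)$kind)
  expect_lt(max(states(trV)$t), 0.01)
})

test_that("aggressive feeding hits the oxygen limit before the volume limit", {
  p <- batchParams(v_EtOH_B = 0, v_Pyr_B = 0, v_Arab_B = 0, v_Cit_B = 0)
  dy <- designYield(toyNet, p, 0.2)
  fast <- feedPolicy(GF = 500, YSX = dy$YSX, ti = 0, Vi = 0.5, Xi = 10,
                     muMax = 0.25, muMin = 0.25, Cdecay = 0, id = "fast")
  slow <- feedPolicy(GF = 500, YSX = dy$YSX, ti = 0, Vi = 0.5, Xi = 10,
                     muMax = 0.05, muMin = 0.05, Cdecay = 0, id = "slow")
  init <- list(V = 0.5, X = 10, G = 0.1)
  opts <- list(Vmax = 1, OTRmax = 8)
  trF <- simulateCultivation(toyNet, p, init, tEnd = 80, policy = fast,
                             options = opts)
  trS <- simulateCultivation(toyNet, p, init, tEnd = 80, policy = slow,
                             options = opts)
  expect_true("otr_limit" %in% eventLog(trF)$kind)
  expect_false("otr_limit" %in% eventLog(trS)$kind)
  expect_true("volume_limit" %in% eventLog(trS)$kind)
  # cross-check against the post-hoc limit scan
  expect_equal(checkLimits(trF, 1, 8)$kind, "oxygen")
  expect_equal(checkLimits(trS, 1, 8)$kind, "volume")
})

test_that("fed-batch tracks the set growth-rate schedule", {
  p <- batchParams(v_EtOH_B = 0, v_Pyr_B = 0, v_Arab_B = 0, v_Cit_B = 0)
  dy <- designYield(toyNet, p, 0.085)
  pol <- feedPolicy(GF = 500, YSX = dy$YSX, ti = 0, Vi = 0.5, Xi = 5,
                    muMax = 0.1, muMin = 0.07, Cdecay = 0.07)
  tr <- simulateCultivation(toyNet, p, list(V = 0.5, X = 5, G = 0.5),
                            tEnd = 15, policy = pol)
  st <- states(tr)
  mu <- fluxes(tr)[, biomassReaction(toyNet)]
  sel <- st$t >= 1
  expect_lt(max(abs(mu[sel] - muSet(st$t[sel], pol)) /
                  muSet(st$t[sel], pol)), 0.05)
  # glucose stays near its quasi-steady (low) value during the feed
  expect_lt(max(st$G[sel]), 0.1)
})
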