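# applications: productivity relation, knockout screen, turnover, policy
# screen.

proteinNet <- addProteinReaction(toyNet, composition = c(pyr_c = 30),
                                 costs = c(atp = 60), name = "HSA",
                                 mw = 2.64)
screenParams <- batchParams(v_EtOH_B = 0.3, v_Pyr_B = 0.05, v_Arab_B = 0.14,
                            v_Cit_B = 0.04)

test_that("the cubic productivity relation is recovered exactly and Horner-evaluated", {
  cf <- c(0.5, 10, -20, 8)
  mus <- c(0.02, 0.06, 0.1, 0.14, 0.18)
  qps <- cf[1] + cf[2] * mus + cf[3] * mus^2 + cf[4] * mus^3
  rel <- qpRelation(data.frame(mu = mus, qP = qps))
  expect_equal(rel$coefficients, cf, tolerance = 1e-8)
  mu0 <- mean(range(mus))
  horner <- cf[1] + mu0 * (cf[2] + mu0 * (cf[3] + mu0 * cf[4]))
  expect_equal(qpOfMu(mu0, rel), horner, tolerance = 1e-10)
  expect_warning(qpOfMu(1, rel), "clamped")
  expect_error(qpRelation(data.frame(mu = c(0.1, 0.2), qP = c(1, 2))),
               "fewer than 4")
  # all-zero support closes the drain
  rel0 <- qpRelation(data.frame(mu = mus, qP = 0))
  expect_equal(qpOfMu(0.1, rel0), 0)
})

test_that("knockout screening classifies genes against the parent", {
  rel <- defaultQpRelation()
  ks <- knockoutScan(proteinNet, screenParams, rel,
                     genes = c("g_orphan", "g_arab", "g_glt"),
                     initial = batchInit, tEnd = 15)
  parent <- attr(ks, "parent_final")
  # gene with no reaction mapping: outcome identical to parent, fold 1
  orphan <- ks[ks$gene == "g_orphan", ]
  expect_equal(orphan$fold_change, 1)
  expect_equal(orphan$status, "neutral")
  expect_equal(orphan$P, parent[["P"]])
  # knocking out the drain competing for the protein precursor frees
  # carbon: final protein rises above the parent
  arab <- ks[ks$gene == "g_arab", ]
  expect_equal(arab$status, "improved")
  expect_gt(arab$fold_change, 1)
  # blocking glucose transport abolishes growth
  glt <- ks[ks$gene == "g_glt", ]
  expect_equal(glt$cluster, "growth-impaired")
  expect_lt(glt$X, 0.5 * parent[["X"]])
})

test_that("MOMA steps inside a knockout simulation are projection-optimal", {
  rel <- defaultQpRelation()
  ks <- knockoutScan(proteinNet, screenParams, rel, genes = "g_arab",
                     initial = batchInit, tEnd = 6)
  tr <- attr(ks, "trajectories")[["g_arab"]]
  parentTr <- attr(ks, "parent")
  i <- which(states(tr)$t == 4)
  st <- states(tr)[i, ]
  ko <- geneKnockout(proteinNet, "g_arab")
  # re-derive the parental instant fluxes and check the stored knockout
  # fluxes are the MOMA projection (independent solve at the stored state)
  p <- screenParams
  state <- list(G = st$G, P = c(ethanol = st$EtOH, arabitol = st$Arab,
                                citrate = st$Cit, pyruvate = st$Pyr))
  # reproduce the two-pass protein coupling: growth-only parental solve
  # fixes the minimum drain, then parental QP, then MOMA on the knockout
  pre <- solveBiObjective(constrainNetwork(proteinNet, state, p, "batch"),
                          alpha = 4.1e-4)
  protLb <- qpOfMu(growthRate(pre), defaultQpRelation(), warn = FALSE) /
    1000 / molecularWeights(proteinNet)[["HSA"]]
  conParent <- constrainNetwork(proteinNet, state, p, "batch")
  conParent <- setBounds(conParent, "EX_HSA", protLb, 1000)
  v0 <- solveBiObjective(conParent, alpha = 4.1e-4)
  conKo <- constrainNetwork(ko, state, p, "batch")
  conKo <- setBounds(conKo, "EX_HSA", protLb, 1000)
  conKo <- setBounds(conKo, "EX_arab", 0, 0)   # ladder released this bound
  ref <- solveMOMA(conKo, v0)
  expect_equal(unname(fluxes(ref)), unname(fluxes(tr)[i, ]),
               tolerance = 1e-4)
})

test_that("relative turnover integrates synthesis fluxes against the parent", {
  rel <- defaultQpRelation()
  ks <- knockoutScan(proteinNet, screenParams, rel, genes = "g_arab",
                     initial = batchInit, tEnd = 12)
  parentTr <- attr(ks, "parent")
  koTr <- attr(ks, "trajectories")[["g_arab"]]
  # identical trajectories give ratios of exactly 1
  same <- relativeTurnover(parentTr, parentTr, proteinNet,
                           c("pyr_c", "atp"))
  expect_equal(unname(same), c(1, 1), tolerance = 1e-12)
  # the knockout re-routes precursor supply into the product: protein
  # turnover rises well above the parent while the blocked by-product
  # route drops to zero
  ratio <- relativeTurnover(koTr, parentTr, proteinNet,
                            c("HSA_e", "arab_e"))
  expect_gt(ratio[["HSA_e"]], 1)
  expect_equal(ratio[["arab_e"]], 0)
  expect_error(relativeTurnover(koTr, parentTr, proteinNet, "nope"),
               "unknown metabolite")
})

test_that("policy screening ranks by volumetric productivity with stable ties", {
  p <- batchParams(v_EtOH_B = 0, v_Pyr_B = 0, v_Arab_B = 0, v_Cit_B = 0)
  dy <- designYield(proteinNet, p, 0.1)
  mk <- function(mu, id) feedPolicy(GF = 500, YSX = dy$YSX, ti = 0,
                                    Vi = 0.5, Xi = 8, muMax = mu,
                                    muMin = mu, Cdecay = 0, id = id)
  rel <- defaultQpRelation()
  init <- list(V = 0.5, X = 8, G = 0.1)
  one <- feedPolicyScreen(list(mk(0.1, "only")), proteinNet, p, rel, init,
                          tEnd = 40, Vmax = 1, OTRmax = 6)
  expect_equal(nrow(one), 1)
  twins <- feedPolicyScreen(list(mk(0.1, "a"), mk(0.1, "b")), proteinNet,
                            p, rel, init, tEnd = 40, Vmax = 1, OTRmax = 6)
  expect_equal(twins$qPvol[1], twins$qPvol[2], tolerance = 1e-12)
  expect_equal(twins$policy, c("a", "b"))   # stable tie order by id

  # constant-mu policies: the aggressive one terminates on oxygen, the
  # conservative one on volume, when the thresholds sit between their peaks
  sc <- feedPolicyScreen(list(mk(0.14, "fast"), mk(0.06, "slow")),
                         proteinNet, p, rel, init, tEnd = 60,
                         Vmax = 1, OTRmax = 6)
  expect_equal(sc$limitation[sc$policy == "fast"], "oxygen")
  expect_equal(sc$limitation[sc$policy == "slow"], "volume")
  expect_true(all(diff(sc$qPvol) <= 0))
})
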