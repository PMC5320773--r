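# gsm_io: SBML round trips, curation, protein drains, knockouts, GPRs.

test_that("SBML writer/reader round-trips the generator exactly", {
  net <- makeToyNetwork(futileCycle = TRUE, parallelRoutes = TRUE)
  path <- withr::local_tempfile(fileext = ".xml")
  writeSBML(net, path)
  net2 <- readSBML(path)
  expect_identical(metabolites(net2), metabolites(net))
  expect_identical(reactions(net2), reactions(net))
  expect_true(all(as.matrix(stoichiometry(net2)) ==
                    as.matrix(stoichiometry(net))))
  expect_identical(bounds(net2), bounds(net))
  expect_identical(gprRules(net2), gprRules(net))
  expect_identical(exchangeMap(net2), exchangeMap(net))
  expect_identical(biomassReaction(net2), biomassReaction(net))
  expect_identical(maintenanceReaction(net2), maintenanceReaction(net))
  expect_identical(molecularWeights(net2), molecularWeights(net))
})

test_that("truncated SBML gives a parse error, not a partial network", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeSBML(toyNet, path)
  txt <- readLines(path)
  writeLines(txt[seq_len(floor(length(txt) / 2))], path)
  expect_error(readSBML(path), "parse error")
})

test_that("the reference libSBML-written dialect is readable", {
  # toy_network_cobra.xml is this generator's network re-exported through
  # cobrapy/libSBML (fbc v2), pinning the reader to the canonical dialect
  path <- system.file("extdata", "toy_network_cobra.xml", package = "dynFBA")
  net <- readSBML(path, roles = list(biomass = "BIOMASS",
                                     maintenance = "ATPM"))
  ref <- makeToyNetwork(futileCycle = TRUE, parallelRoutes = TRUE)
  expect_setequal(reactions(net), reactions(ref))
  j <- match(reactions(ref), reactions(net))
  expect_equal(net@lb[j], ref@lb, tolerance = 1e-12)
  expect_equal(net@ub[j], ref@ub, tolerance = 1e-12)
  expect_identical(unname(gprRules(net)[reactions(ref)]),
                   unname(gprRules(ref)))
  expect_equal(growthRate(solveBiObjective(net, alpha = 1e-4)),
               growthRate(solveBiObjective(ref, alpha = 1e-4)),
               tolerance = 1e-8)
})

test_that("missing role designations are configuration errors", {
  net <- makeToyNetwork()
  path <- withr::local_tempfile(fileext = ".xml")
  writeSBML(net, path)
  txt <- readLines(path)
  txt <- txt[!grepl("MAINTENANCE_REACTION", txt)]
  txt <- sub('id="R_ATPM"', 'id="R_xyz"', txt)
  writeLines(txt, path)
  expect_error(readSBML(path), "maintenance")
})

test_that("reversibility curation changes only the listed bounds, logged", {
  expect_identical(applyReversibilityCuration(toyNet, NULL), toyNet)
  rules <- data.frame(reaction = "PYRt", lb = 0, ub = 1000)
  cur <- applyReversibilityCuration(toyNet, rules)
  expect_equal(bounds(cur)$lb[reactions(cur) == "PYRt"], 0)
  others <- reactions(toyNet) != "PYRt"
  expect_identical(bounds(cur)[others, ], bounds(toyNet)[others, ])
  expect_identical(stoichiometry(cur), stoichiometry(toyNet))
  log <- curationLog(cur)
  expect_equal(nrow(log), 1)
  expect_equal(log$old_lb, -1000)
  expect_equal(log$new_lb, 0)
  expect_error(
    applyReversibilityCuration(toyNet,
                               data.frame(reaction = "nope", lb = 0, ub = 1)),
    "nope")
})

test_that("curation closes an ATP-generating cycle opened by wrong reversibility", {
  open <- makeToyNetwork(atpCycle = TRUE)
  fdOpen <- solveBiObjective(open, alpha = 1e-4)
  closed <- applyReversibilityCuration(
    open, data.frame(reaction = "RC2", lb = 0, ub = 1000))
  fdClosed <- solveBiObjective(closed, alpha = 1e-4)
  # open: the reversed second step lets the loop generate ATP from nothing,
  # and the QP exploits it; curation kills the loop and the growth benefit
  expect_gt(fluxes(fdOpen)[["RC1"]], 1)
  expect_lt(fluxes(fdOpen)[["RC2"]], -1)
  expect_lt(abs(fluxes(fdClosed)[["RC1"]]), 1e-6)
  expect_lt(abs(fluxes(fdClosed)[["RC2"]]), 1e-6)
  expect_gt(growthRate(fdOpen), growthRate(fdClosed) + 0.01)
})

test_that("protein drain bookkeeping: two reactions, closed drain is inert", {
  net <- addProteinReaction(toyNet, composition = c(pyr_c = 1),
                            name = "prot", mw = 0.088)
  expect_equal(length(reactions(net)), length(reactions(toyNet)) + 2)
  expect_true("prot" %in% names(exchangeMap(net)))
  base <- solveBiObjective(toyNet, alpha = 1e-4)
  closed <- setBounds(net, "EX_prot", 0, 0)
  fd <- solveBiObjective(closed, alpha = 1e-4)
  expect_equal(fluxes(fd)[reactions(toyNet)], fluxes(base),
               tolerance = 1e-6)
  expect_error(addProteinReaction(toyNet, c(nothere = 1), name = "p2"),
               "unknown metabolite")
  expect_error(addProteinReaction(toyNet, c(pyr_c = -1), name = "p3"),
               "positive")
})

test_that("forced protein flux competes with growth for resources", {
  net <- addProteinReaction(toyNet, composition = c(pyr_c = 30),
                            costs = c(atp = 60), name = "HSA", mw = 2.64)
  net <- setBounds(net, "EX_glc", -6, -6)   # fixed glucose uptake
  mu0 <- growthRate(solveBiObjective(net, alpha = 1e-4))
  forced <- setBounds(net, "EX_HSA", 0.05, 1000)
  mu1 <- growthRate(solveBiObjective(forced, alpha = 1e-4))
  expect_lt(mu1, mu0 - 1e-4)
})

test_that("knockouts follow boolean GPR semantics", {
  # gene in no GPR: nothing blocked
  expect_equal(geneReactions(toyNet, "g_orphan"), character(0))
  ko <- geneKnockout(toyNet, "g_orphan")
  expect_identical(bounds(ko), bounds(toyNet))
  # single-gene reaction: blocked
  ko <- geneKnockout(toyNet, "g_ferm")
  expect_equal(bounds(ko)$lb[reactions(ko) == "FERM"], 0)
  expect_equal(bounds(ko)$ub[reactions(ko) == "FERM"], 0)
  # isoenzymes (or): survives one deletion, dies with both
  ko1 <- geneKnockout(toyNet, "g_gly1")
  expect_equal(bounds(ko1)$ub[reactions(ko1) == "GLYC"], 1000)
  ko12 <- geneKnockout(ko1, "g_gly2")
  expect_equal(bounds(ko12)$ub[reactions(ko12) == "GLYC"], 0)
  # complex (and): dies with either subunit
  koc <- geneKnockout(toyNet, "g_resp1")
  expect_equal(bounds(koc)$ub[reactions(koc) == "RESP"], 0)
  expect_error(geneKnockout(toyNet, "not_a_gene"), "unknown gene")
})

test_that("GPR evaluation matches a truth-table oracle", {
  exprs <- c("gA", "gA or gB", "gA and gB", "gA and (gB or gC)",
             "(gA and gB) or gC")
  genes <- c("gA", "gB", "gC")
  evalRef <- function(expr, present) {
    # independent oracle: substitute+eval via R's own boolean parser
    e <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", expr))
    for (g in genes) e <- gsub(paste0("\\b", g, "\\b"),
                               as.character(g %in% present), e)
    eval(parse(text = e))
  }
  for (expr in exprs) {
    for (mask in 0:7) {
      present <- genes[bitwAnd(mask, c(1L, 2L, 4L)) > 0]
      absent <- setdiff(genes, present)
      expect_equal(dynFBA:::.gprEval(expr, absent), evalRef(expr, present),
                   info = paste(expr, "|", paste(present, collapse = ",")))
    }
  }
})

test_that("knockout is idempotent and commutes across genes", {
  k1 <- geneKnockout(geneKnockout(toyNet, "g_ferm"), "g_ferm")
  expect_identical(bounds(k1), bounds(geneKnockout(toyNet, "g_ferm")))
  ab <- geneKnockout(geneKnockout(toyNet, "g_gly1"), "g_resp1")
  ba <- geneKnockout(geneKnockout(toyNet, "g_resp1"), "g_gly1")
  expect_identical(bounds(ab), bounds(ba))
})
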