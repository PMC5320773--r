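# Shared fixtures, built in code once per test run.

toyNet <- makeToyNetwork()
toyNetLoops <- makeToyNetwork(futileCycle = TRUE)
toyNetRoutes <- makeToyNetwork(parallelRoutes = TRUE)

# Strain-characteristic batch parameters (all fixed) used across simulator
# and application tests; T_Fed beyond the batch horizon.
batchParams <- function(...) {
  kineticParameters(v_G_max = 6, K_G = 0.0027, m_ATP = 2.18, T_Fed = 32,
                    alpha_B = 4.1e-4, alpha_FB = 4.1e-4,
                    v_EtOH_B = 1.47, v_Pyr_B = 0.13, v_Arab_B = 0.14,
                    v_Cit_B = 0.09, adjustable = character(0), ...)
}

batchInit <- list(V = 0.5, X = 0.25, G = 50)

# Minimal two-route network for MOMA projection oracles: forced uptake of A,
# two parallel conversions A -> B, biomass drain on B, inert maintenance.
twoRouteNet <- local({
  mets <- c("A", "B", "Xd")
  rxns <- c("EX_A", "RA", "RB", "BIO", "ATPM")
  S <- matrix(0, 3, 5, dimnames = list(mets, rxns))
  S["A", "EX_A"] <- -1
  S["A", "RA"] <- -1; S["B", "RA"] <- 1
  S["A", "RB"] <- -1; S["B", "RB"] <- 1
  S["B", "BIO"] <- -1
  S["Xd", "ATPM"] <- -1
  metabolicNetwork(S, mets, rxns,
                   lb = c(-10, 0, 0, 0, 0), ub = c(-10, 1000, 1000, 1000, 0),
                   biomassRxn = "BIO", maintenanceRxn = "ATPM")
})

# Unbranched chain with forced uptake: flux vector fully determined.
chainNet <- local({
  mets <- c("A", "B", "Xd")
  rxns <- c("EX_A", "R1", "BIO", "ATPM")
  S <- matrix(0, 3, 4, dimnames = list(mets, rxns))
  S["A", "EX_A"] <- -1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "BIO"] <- -1
  S["Xd", "ATPM"] <- -1
  metabolicNetwork(S, mets, rxns,
                   lb = c(-10, 0, 0, 0), ub = c(-10, 1000, 1000, 0),
                   biomassRxn = "BIO", maintenanceRxn = "ATPM")
})

# LP-optimal growth of the standard toy network at full glucose uptake
# (lb = -10) and free maintenance, computed independently with a simplex
# solver (cobrapy/GLPK) on the SBML export of this generator.
TOY_LP_MU <- 0.8181818181818186
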