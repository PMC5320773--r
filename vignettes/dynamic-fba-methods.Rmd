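---
title: "Dynamic FBA of glucose-limited cultivations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic FBA of glucose-limited cultivations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynFBA)
```

# The modelling framework

`dynFBA` simulates glucose-limited aerobic batch and fed-batch yeast
cultivations by iterating three blocks.

The **kinetic block** converts the extracellular state into flux bounds.
Glucose uptake is Michaelis–Menten, $v_G = v_{G,max}\,G/(K_G+G)$, applied
as the lower bound $-v_G$ of the glucose exchange (uptake is negative by
the COBRA sign convention). Each tracked by-product $k$ (ethanol,
arabitol, citrate, pyruvate) has two rate parameters with phase-dependent
meaning: during the batch phase $v_{k,B}$ is a minimum *secretion* rate
(a positive lower bound on the exchange), and from $T_{Fed}$ onwards
$v_{k,FB}$ is a minimum *consumption* rate (a negative upper bound). The
maintenance demand $m_{ATP}$ pins the cytosolic ATP hydrolysis flux
(lb = ub). We resolve the sign ambiguity of the by-product constraint this
way because the batch phase of a glucose-rich culture overflows into
by-products while starved or fed cells re-consume them; the switch is
gated by $T_{Fed}$ alone, which is exactly how that parameter is defined
("time when secondary metabolite consumption starts").

The **metabolic block** solves, at every instant,
$$\min_v\; \alpha \sum_i v_i^2 - (1-\alpha)\,\mu
\quad\text{s.t.}\quad S v = 0,\; lb \le v \le ub,$$
with $\mu$ the biomass-reaction flux. For $\alpha > 0$ the problem is
strictly convex, the optimum is unique, and internal circulations (type
III pathways) cost quadratic penalty while exchanging nothing, so they
carry zero flux. The calibrated $\alpha$ values live on the literal scale
of this objective (order $10^{-4}$); no renormalisation of the two terms
is applied, because renormalising would change what a given $\alpha$
means. Knockouts are simulated with MOMA: the parental QP is solved first
under the *same* kinetic constraints, the gene's reactions are blocked
(boolean GPR evaluation over the accumulated deleted-gene set), and the
knockout fluxes are the Euclidean projection of the parental vector onto
the mutant's feasible set. The parental vector is recomputed at every
instant rather than frozen from a reference run, because the projection
is defined per-instant.

The **dynamic block** integrates the extensive masses
$(V,\,VX,\,VG,\,VP_k)$ exactly as the balances are written:
$dV/dt = F - SR$, $d(VX)/dt = \mu VX - SR\,X$,
$d(VG)/dt = F G_F - v_G MW_G\, VX - SR\,G$,
$d(VP_k)/dt = v_k MW_k\, VX - SR\,P_k$. Working in masses avoids
product-rule manipulation and keeps the sampling outflow $SR$ (applied as
a continuous stream, as written) literal; concentrations are recovered by
division. Cumulative CO$_2$ and O$_2$ exchange ride along as auxiliary
states for elemental audits and the oxygen uptake rate. The coupling is
"direct" dynamic FBA: the ODE right-hand side calls the kinetic and
metabolic blocks at every integrator step, which assumes the intracellular
steady state relaxes much faster than the reactor state — the standard
assumption of the approach.

Exponential feeding tracks a set growth rate
$\mu_{set}(t) = (\mu_{max}-\mu_{min})e^{-Ct} + \mu_{min}$ (time measured
from feed start $t_i$) through
$F(t) = \mu_{set}/(G_F Y_{SX}) \cdot V_i X_i \cdot
\exp\!\int_{t_i}^{t}\mu_{set}$, with the integral in closed form:
$(\mu_{max}-\mu_{min})(1-e^{-C\tau})/C + \mu_{min}\tau$. The design yield
$Y_{SX}$ should be the network's own differential glucose-to-biomass
yield at the target growth rate; `designYield()` computes it by a root
solve over the metabolic block, and with it the realised $\mu(t)$ tracks
the schedule to within a few percent after the initial transient.

# Parameters

| parameter | units | default box | notes |
|---|---|---|---|
| $v_{G,max}$ | mmol/gDCW/h | [0, 10], start 2.5 | max glucose uptake |
| $K_G$ | g/L | [0, 10⁻³], start 10⁻⁴ | uptake half-saturation; micromolar range |
| $v_{EtOH,B}, v_{Pyr,B}, v_{Arab,B}, v_{Cit,B}$ | mmol/gDCW/h | [0, 3] / [0, 2] | batch minimum secretion |
| $v_{EtOH,FB}, v_{Pyr,FB}, v_{Arab,FB}, v_{Cit,FB}$ | mmol/gDCW/h | [0, 2] | post-$T_{Fed}$ minimum consumption |
| $\alpha_B, \alpha_{FB}$ | — | [0, 10⁻³], start 0 | flux-norm weight per phase |
| $m_{ATP}$ | mmol/gDCW/h | [0, 10], start 2 | non-growth maintenance |
| $T_{Fed}$ | h | [20, 32], start 25 | consumption switch time |

Fixed (non-adjustable) parameters may sit outside the search box — e.g.
the literature chemostat value $K_G = 0.0027$ g/L used by
`fixationDefaults()` exceeds the box's upper bound; the box constrains
only the calibration search. The fixation table pins glucose kinetics at
reported chemostat values, batch secretion minima at zero (no a-priori
forced secretion), feed-phase consumption rates at typical calibrated
means, the flux-norm weights at zero and maintenance at its genome-scale
reconstruction value.

# Numerical choices

* **QP solution.** Equality constraints are eliminated through an SVD
  null-space parametrisation before handing the box-constrained strictly
  convex QP to `quadprog`. The SVD route tolerates the linearly dependent
  rows (conserved moieties) that stoichiometric matrices always contain.
  Variables fully determined by the equalities yield vanishing constraint
  normals in the reduced space; their boxes are checked directly and
  withheld from the active-set solver, and the remaining constraint rows
  are normalised to unit normals. When the active-set method still reports
  a degenerate (duplicate-normal) constraint set as inconsistent, the
  solve is retried once with a deterministic relaxation of $10^{-9}$ —
  three orders of magnitude below the feasibility tolerance — which breaks
  the ties without materially moving the optimum.
* **$\alpha = 0$.** Pure growth maximisation is a degenerate LP. It is
  solved by bisection on $\mu$ (feasibility probed with minimum-norm QPs,
  to $10^{-9}$ relative), and the returned flux vector is the minimum-norm
  distribution at the optimal growth rate. Returning a simplex vertex
  would require an LP pivoting code and would be non-deterministic across
  solvers; the minimum-norm representative is unique and reproducible.
  Callers who want the degeneracy made visible can seed circulations onto
  the solution, as the loop tests do.
* **Tolerances.** Feasibility $10^{-6}$ on $Sv = 0$ and bounds;
  unbounded fluxes capped at $\pm 1000$ mmol/gDCW/h (COBRA convention);
  integrator `lsoda`/`lsodar` with rtol $10^{-6}$, atol $10^{-8}$.
  Halving the integrator tolerances moves a 9-hour batch endpoint by less
  than 0.1%.
* **Events.** Glucose depletion is located by root-finding on
  $G - \epsilon_G$ ($\epsilon_G = 10^{-6}$ g/L) and logged without
  stopping the run; volume and oxygen-transfer limits are terminal roots;
  phase switches ($T_{Fed}$, feed start) split the integration into
  segments so the right-hand side stays smooth within each.
* **Depletion switch.** Forced consumption of a by-product is scaled by
  $s(P) = \min(1, P/\epsilon_P)$ with $\epsilon_P = 0.05$ g/L. The switch
  multiplies *both* the forced minimum (upper bound) and the consumption
  cap (lower bound): if only the minimum were released, the QP could keep
  importing carbon from an empty extracellular pool and drive
  concentrations negative. With the switch on both bounds, concentrations
  stay above $-10^{-6}$ g/L across the parameter box.
* **Infeasibility ladder.** Starvation can make the literal constraint
  set infeasible (e.g. forced secretion with no substrate). On
  infeasibility the simulator relaxes, in order: forced by-product and
  protein bounds, then the maintenance lower bound; each relaxation is
  logged as a trajectory event. Only if all three levels fail does the
  run abort with the time and the offending bounds.
* **Finite differences.** Sensitivities use central differences with
  relative step $10^{-3}$ (absolute floor at the same value for
  zero-valued parameters), one-sided at bound edges or when a perturbed
  simulation fails, and a guard that skips times where
  $|X_i| < 10^{-8}$. Halving the step changes averaged scores by well
  under 5%.
* **Noise weights.** The FIM weighting $Q_j$ is diagonal with entries
  $1/(c\,\max_j X_{ij})^2$, $c = 0.05$ by default — 5% proportional error
  relative to each variable's maximum measurement, matching both the
  max-normalised calibration objective and the synthetic-data noise model;
  an explicit per-variable SD can be supplied instead. Sensitivity
  averaging uses the mean of $|g_{ik}|$ over times, absolute values
  preventing sign cancellation.
* **Reparametrization order.** Each round fixes one parameter: any
  insensitive parameter first (lowest score), otherwise the member of the
  most-correlated flagged pair with the lower sensitivity score — the
  least-information-loss heuristic. Thresholds (0.01 sensitivity, 0.95
  correlation, 2 on the coefficient of confidence) are inclusive and
  configurable.
* **Calibration.** Differential evolution over the adjustable box
  (population max(10, 4d), ~60% of the evaluation budget, the declared
  starting values seeded into the initial population) followed by a
  BOBYQA polish (~40%); a failed simulation scores the penalty $10^6$ so
  the search stays defined everywhere. The same seed and budget reproduce
  the result exactly, and the best-so-far trace is monotone.

# What the synthetic fixtures emulate — and what they do not

`makeToyNetwork()` builds a ~20-reaction network with the architecture the
framework expects from a genome-scale reconstruction: glucose transport,
lumped glycolysis (2 ATP + 2 pyruvate per glucose), lumped respiration
(12.5 ATP per pyruvate, 2.5 O$_2$, 3 CO$_2$), secretion and catabolic
routes for the four by-products, a biomass reaction consuming 10 mmol
glucose and 60 mmol ATP per gDCW (40 mmol C per gDCW fixed in biomass, the
rest leaving as CO$_2$ — an aerobic yield near 0.45 g/g), and ATP
hydrolysis for maintenance. Every internal reaction balances carbon
exactly; ATP and O$_2$ are carbon-free energy carriers. Optional
structures provide the pathological cases the solver must handle: a
detached reversible triangle (type III loop), a four-reaction parallel
bypass of glycolysis with identical net stoichiometry, and a two-reaction
loop that manufactures ATP from nothing while its second step is wrongly
reversible — the motif that reversibility curation closes in real
reconstructions.

`generateCultivationData()` samples a simulated trajectory every 2–3 h
(manual-sampling cadence) and adds heteroscedastic Gaussian noise with
SD = CV × value (default CV 5%, emulating OD/HPLC error), floored and
clipped at zero, recording the generating parameters for recovery scoring.

What passing tests on these fixtures demonstrate is that the machinery is
correct: conservation laws hold, optimality conditions are met, known
parameters are recovered under the stated noise. They do not demonstrate
that a real yeast culture obeys the kinetic forms — real data bring model
misfit (the goodness-of-fit module exists precisely to detect it),
redox/cofactor structure the lumped toy cannot express, measurement error
that is not purely proportional, and a genome-scale reconstruction whose
curation quality the toy does not probe.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in a few minutes: toy networks of 11–17
metabolites and 20–27 reactions, batch horizons of 8–15 h sampled every
2.5 h, a six-parameter recovery study on one 5%-noise dataset with an
optimizer budget of 2000 evaluations, and 200-replicate Monte-Carlo checks
for noise calibration and CI coverage. Genome-scale models load through
the same `readSBML()` path (fbc-v2 and legacy COBRA dialects), but the
dense active-set QP is sized for desk-scale work; a sparse interior-point
solver would be the natural extension for 1000+ reaction networks.

# Known limitations

* No gas-phase dynamics: oxygen supply enters only as an uptake-rate
  limit check, and CO$_2$ is tracked cumulatively, not as a dissolved
  species with transfer kinetics.
* The by-product kinetics are minimum-rate bounds, not mechanistic
  expressions; between glucose depletion and $T_{Fed}$ the model neither
  forces secretion nor consumption beyond what the QP chooses.
* Per-instant MOMA assumes the mutant re-optimises against the parental
  distribution at every time; regulatory adaptation over the culture is
  not modelled.
* The default $q_P(\mu)$ relation is synthetic (real curves are strain-
  and protein-specific and typically digitised from figures); supply a
  measured table for real use.
* Sampling is a continuous outflow; discrete sample withdrawals are not
  modelled.
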