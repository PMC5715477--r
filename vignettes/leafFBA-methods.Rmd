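---
title: "Methods: constraint-based analysis of a compartmentalized leaf network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based analysis of a compartmentalized leaf network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafFBA)
```

## The model and its assumptions

leafFBA analyzes compartmentalized leaf metabolic models at steady
state. A model is a stoichiometric matrix $S$ (metabolites $\times$
reactions) with flux bounds $LB \le v \le UB$, and the core solver
finds the flux distribution that synthesizes a fixed biomass
composition at minimal total enzyme commitment:

$$\min_v \sum_i w_i\,|v_i| \quad \text{s.t.} \quad S v = 0,\;
LB \le v \le UB,$$

with the biomass transporters fixed at experimentally defined
proportions, nutrient and photon uptakes left free, and a maintenance
ATPase fixed at 0.1 flux units. Minimizing the (weighted) sum of
absolute fluxes is the standard proxy for minimal total protein cost;
it is linearized exactly by splitting each flux into nonnegative
forward and backward parts ($v = v^+ - v^-$). All quantities are in
the model's dimensionless "flux unit"; the package attaches no
physical unit to them.

The assumptions are those of every flux-balance analysis: the network
is at steady state, internal metabolite pools neither accumulate nor
deplete, and regulation and kinetics are invisible except insofar as
they are mimicked by objective weights.

### Alternative optima

Flux-minimizing LPs over metabolic networks are systematically
degenerate. The solver returns one optimal vertex deterministically
(fixed variable order, deterministic pivoting), so repeated runs are
reproducible — but a single reported flux distribution is one point on
the optimal face. Every scientific claim the package's tests make is
therefore either certified by flux variability analysis (FVA) or is a
property that holds across all optima (for instance, the objective
value or a flux forced by FVA to a single value). `runFVA()` maximizes
and minimizes each flux subject to the original constraints plus
$\sum_i w_i |v_i| \le Z^*(1+\texttt{tol}) + \varepsilon$; the default
is strict optimality (`tol = 0`) with an absolute slack
$\varepsilon = 10^{-7}$ that keeps the optimal face numerically
nonempty. Whether any slack should be used is not prescribed by the
method itself; strictness is the conservative default and the slack is
configurable.

## The linear-programming kernel

No LP library is part of the package's dependency footprint: the
solver in `R/lp.R` is a bounded-variable two-phase primal simplex with
the classical variable-complement treatment of finite upper bounds,
Dantzig pricing, and a permanent switch to Bland's rule after a stall
to rule out cycling on degenerate bases. The test suite cross-checks
it against an independent simplex implementation and against
hand-enumerated optima. Numerical conventions:

* feasibility and reduced-cost tolerance $10^{-9}$;
* "unconstrained" bounds are encoded as $\pm 10^6$ so every split LP
  stays bounded;
* reported fluxes below $10^{-9}$ in magnitude are snapped to zero,
  three orders below the $10^{-6}$ mode-classification tolerance, so
  transporter direction signatures never flicker on solver noise;
* after termination the basic system is re-solved in the original
  coordinates (`.lpPolish`) to remove accumulated tableau round-off.

## Scenario machinery

**Vc/Vo lumping.** `lumpRubisco()` replaces the separate RuBisCO
carboxylation and oxygenation reactions by one irreversible reaction
with stoichiometry $a\cdot\text{carb} + b\cdot\text{oxy}$ for the
ratio $a\!:\!b$. Coefficients are the raw sum, not normalized by
$a+b$: one unit of lumped flux performs exactly $a$ carboxylations and
$b$ oxygenations, so $V_c = a v$ and $V_o = b v$ hold exactly. Ratios
are small integers and coefficients small rationals, so the arithmetic
is exact in double precision; a dedicated rational type would add
machinery without changing any digit at these magnitudes.

**Light scan.** `lightScan()` fixes the photon influx at each grid
value (an equality, not a cap), enforces
$v_\text{cyclic} \le v_\text{non-cyclic}$ for the two lumped
photophosphorylation reactions, and solves each point independently —
no warm starts, so results are grid-order invariant. Grid points below
the feasibility limit are recorded as infeasible rather than dropped.
`minFeasiblePhotonFlux()` bisects for that limit to a default
half-width of $10^{-4}$.

**Photophosphorylation yields.** The lumped non-cyclic reaction yields
3 ATP + 2 NADPH per unit (8 photons), the cyclic reaction 2 ATP per
unit (4 photons). These are configuration
(`photophosphorylationYields()`), not hard-coded chemistry: lumped
light reactions inherit their stoichiometry from elementary-mode
condensations of thylakoid electron transport, and other conventions
are legitimate. Quantum demand is photons per net CO2 fixed and is
undefined (NA) when CO2 uptake is not positive, as is the ATP:NADPH
ratio when no NADPH is produced.

**Enzymatic-cost ensembles.** `runEnsemble()` mimics varying enzyme
expression by drawing an independent uniform weight on $[0, 1000]$ for
every *metabolic* reaction; transporters of all categories, exchanges,
the maintenance demand and the two photophosphorylation reactions keep
a baseline weight of exactly 1. Two deliberate choices:

* the distribution is continuous uniform — the source method is
  stated only as "random weights from 0 to 1000", and continuity makes
  weight ties measure-zero, so the optimal mode is almost surely
  unique per draw;
* the baseline is 1, not 0 — weight-0 transporters would carry flux at
  no objective cost and admit unbounded futile shuttling.

Per-iteration seeds derive from the master seed by a counter scheme
(`masterSeed * 1000003 + i mod 2^31 - 1`), so a run is reproducible
and any prefix of it is identical regardless of the total $n$. A mode
is the vector of flux signs of a tracked reaction set with a
$10^{-6}$ dead zone; solver failures count as infeasible and never
abort a run.

## Consistency checks

The package operationalizes "no stoichiometric inconsistencies" as
three closed-system tests: `findLeaks()` closes every exchange and
biomass transporter, releases the maintenance demand (a fixed drain
would mask capacity), and maximizes a temporary drain for each
internal metabolite — any optimum above $10^{-6}$ is a leak.
`detectEnergyCycle()` maximizes the flux of a currency discharge
reaction (by default the maintenance ATPase) in the same closed
system; a positive optimum means some internal loop recharges ATP for
free. `elementalBalanceAudit()` checks
$\sum_i c_i \cdot \text{composition}_i = 0$ per element for every
reaction whose species all carry a formula, skipping boundary
reactions that move mass by design. The concrete procedure behind the
published consistency claim is not spelled out in the literature the
package follows; these closed-system LPs are this package's
operationalization of it.

## What the synthetic core model emulates

`buildCoreLeafModel()` is a *curated* (not random) four-compartment
network of about 74 reactions, because the full published
leaf reconstruction cannot be rebuilt from text. It is engineered so
that the qualitative behaviors expected of a photorespiring C3 leaf
are consequences of its structure:

* **Malate valve.** Chloroplastic NADP-MDH is irreversible toward
  malate (the enzyme is light-activated and operates in the reduction
  direction), so the Mal/OAA antiporter can export but not import
  reducing equivalents; its activity falls monotonically as Vc/Vo
  rises from 1:1 to 5:1.
* **GAPDH/PGK switch.** Mitochondrial NADH from glycine
  decarboxylation is abundant at Vc/Vo = 1:1 and covers the cytosolic
  ATP demand; at 3:1 it no longer does, and the cytosolic GAPDH+PGK
  pair activates to deliver ATP and NADH from exported triose
  phosphate. The biomass scale (GAP drain 0.11, lipid drain 0.01,
  maintenance 0.1) was chosen once so the crossover falls between the
  two ratios.
* **Ammonia refixation.** Biomass drains are carbon-only, GS2/GOGAT is
  the only nitrogen assimilation route in the default model, and the
  NH3 exchange is import-only — so photorespiratory ammonia must be
  refixed, and GDC production, chloroplast NH3 import and GS2 flux
  coincide exactly at every ratio.
* **GAPN.** The lipid drain consumes 10 NADPH per unit and cytosolic
  NADPH comes only from GAPN, pinning GAPN at 10x the lipid flux
  across all scenarios — the constant-flux control.
* **Light response.** With the photon influx fixed above the minimum,
  excess photons must be dissipated through real chemistry:
  oxygenation (hence HPR1) rises with light, the AOX branch displaces
  COX, and the triose-phosphate shuttle hands over to the malate
  valve at high light.
* **Alternative H2O2 routes.** The glutathione-ascorbate pair
  (APX/MDAR) can replace catalase, but its NADH supply chain crosses
  several randomly weighted enzymes, so under cost ensembles it
  appears only rarely — catalase dominates, and the substitution is
  asserted deterministically by closing catalase and re-solving.
* **Glu-Gln transporter modes.** With the optional cytosolic GS1
  present, ensembles show distinct transporter modes; whenever GS1 is
  active the transporter imports glutamine into the chloroplast, and
  the GS2-only mode dominates (cytosolic ATP is dearer than
  chloroplastic ATP), matching the strong asymmetry expected for a C3
  leaf.

Elemental formulas are simplified (C,H,N,O,P,S; NAD(P)H = NAD(P) +
H2; ATP = ADP + HPO3; photons and the proton-motive quantum are
massless), which is sufficient for exact balance auditing but is not
real chemistry. Nitrate and sulfate exchanges exist for completeness
of the nutrient boundary but are inert — the core network contains no
nitrate or sulfur assimilation pathway. What passing tests on this
network show is that the *pipeline* reproduces the structural logic of
leaf photorespiration; they say nothing about parameter values of any
real reconstruction, and genome-scale models will stress the LP kernel
(~1000+ reactions) harder than this network does.

Transporter sign convention: transporter equations are written with
the cytosolic species on the left, so a negative flux of an
intracellular transporter means export toward the cytosol.

## Problem sizes and defaults used by the automated runs

The packaged tests and the acceptance script run the Vc/Vo scan at the
five integer ratios 1:1..5:1, the light scan on an 11-point grid over
photon flux 5–10 (the core model's feasibility limit is near 4.15, so
the grid sits safely in the feasible region), ensembles of 3000
iterations on the symmetric fixtures and 1500 on the core model, and
bisection brackets of [0.33, 6] flux units. These sizes were chosen as
the smallest at which the binomial standard errors of the ensemble
frequencies are well below the effects being asserted (3-sigma bands)
while keeping each automated run in the tens of seconds.

## Known limitations

* One optimal vertex is reported; enumeration of alternate optima
  beyond FVA min/max (e.g. flux sampling) is out of scope.
* Loops that cost objective weight are suppressed but not forbidden;
  there is no loopless-FVA or thermodynamic (free-energy) filtering.
* The dense-tableau simplex is sized for networks of a few hundred
  reactions; genome-scale models will solve, but slowly.
* Correlations are plain Pearson coefficients on scan series, as in
  the source analysis — no p-values or multiple-testing control are
  attached, and nonlinear (hyperbolic) flux responses legitimately
  yield $|r|$ well below 1.
* The SBML reader/writer covers the package's own round-trip contract
  (stoichiometry, bounds, categories, formulas), not the full FBC
  specification.
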