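---
title: "A gridded partial-equilibrium model of agriculture, land use, carbon and biodiversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A gridded partial-equilibrium model of agriculture, land use, carbon and biodiversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agland)
```

# The question the model answers

Adoption of improved crop varieties raises total factor productivity (TFP)
where it happens. Locally, higher productivity raises the return to
cropland and can *expand* cultivated area (the Jevons direction); globally,
the extra supply lowers crop prices, which slows cropland expansion
everywhere else (the Borlaug, land-sparing direction). Which force wins,
where, and what that means for land-use-change (LUC) carbon emissions and
biodiversity, is an equilibrium question: it depends on demand elasticities,
trade, and how tightly physical land availability constrains each location.

`agland` implements a spatially explicit partial-equilibrium simulator for
exactly this comparison: a multi-period historical *baseline* is run against
a *counterfactual* in which the productivity gains from improved varieties
are removed, and the per-cell cropland differences are passed through
linear carbon and biodiversity accounting.

# Model structure

## Commodities, agents, markets

Three composite commodities: **crops** (measured in corn-equivalent tons —
heterogeneous crop outputs are aggregated by their price relative to corn,
and the regional nonland-input price is the numeraire, fixed at 1),
**livestock** and **processed food**. Regions hold the demand side; crop
*production* is resolved on grid cells within each region. Market clearing:

* one domestic crop market per region (domestic sales = domestically
  sourced requirement),
* one livestock and one processed-food market per region (these sectors
  clear regionally only),
* one world crop pool (global exports = global imports).

This gives a price vector of dimension 3R+1, solved by damped Newton
iteration on log prices with a finite-difference Jacobian. Grid-cell rents
are solved analytically inside every residual evaluation, so the outer
system stays small no matter how many cells the grid has.

## Grid-cell production

Each cell produces crops from land and a nonland composite with
constant-returns CES technology in calibrated share form. With land cost
share $\theta_L$, substitution elasticity $\sigma$ and Hicks-neutral TFP
$a$, the unit cost at rent $r$ and nonland price 1 is

$$c(r) = \frac{c_0}{a}\left[\theta_L (r/r_0)^{1-\sigma} +
  (1-\theta_L)\right]^{1/(1-\sigma)},$$

with the Cobb-Douglas case $\sigma = 1$ evaluated as its analytic limit.
Free entry under constant returns pins the rent down through zero profit,
$c(r) = P$, which has a closed form; land follows from the supply curve,
and nonland input and output from Shephard's lemma. For $\sigma < 1$ land
is essential: a price below the minimum attainable unit cost puts the cell
at a *corner* (zero land, flagged diagnostically). Output rises in both the
producer price and TFP.

## Saturating land supply

Cropland supplied in a cell responds to the rental rate but saturates at
the cell's cultivable-land asymptote $\Lambda$:

$$L(r) = \frac{\Lambda\, r^{\gamma}}{r^{\gamma} + \kappa}, \qquad
  \gamma = \frac{\eta_0}{1 - L_0/\Lambda}, \qquad
  \kappa = r_0^{\gamma}\,\frac{\Lambda - L_0}{L_0}.$$

The curve passes through the calibration anchor $(r_0, L_0)$ with point
elasticity $\eta_0$ there, and the implied elasticity declines *linearly*
in land use, $\eta(L) = \gamma\,(1 - L/\Lambda)$, reaching zero at the
asymptote: physical land limits bind progressively. This particular
saturating form was chosen because it satisfies all three contract points
(anchor, asymptote, linearly decaying elasticity) at once; it is isolated
behind the `land_supply_curve` object so an alternative form can be
swapped without touching the solver.

## Demand

Final demand per region and commodity is constant-elasticity,
$$D = N\,d_0\,(Y/Y_0)^{\varepsilon_y}\,(P/P_0)^{\varepsilon_p},$$
driven by exogenous population $N$ and per-capita income $Y$. The
elasticities are looked up once per period from a monotone
income-elasticity table (richer regions respond less to both income and
price — the Engel/Bennett pattern), so dietary change with affluence is
captured without making the within-period system income-path-dependent.
Biofuel feedstock demand enters as an exogenous quantity of the crop
composite. Livestock and processed food use a crop/noncrop CES with
calibrated cost shares; being constant-returns with elastically supplied
inputs, they supply perfectly elastically at unit cost, and their market
residual is expressed in tons as $D(c) - D(P)$, which vanishes exactly
where price equals unit cost.

## Trade

Domestically produced and world-pool crops are imperfect substitutes
(Armington). We use a tons-conserving formulation: the sourcing shares are
CES in relative prices,
$$\omega_d \propto b_d\,(P_d/P_{d0})^{-\sigma_A}, \qquad
  \omega_w \propto b_w\,(P_w/P_{w0})^{-\sigma_A},$$
normalized to sum to one and applied to the physical composite requirement,
so sourced quantities always add up exactly to the requirement (the
$\sigma_A \to 0$ limit is fixed-share Leontief sourcing). The sales side is
a mirrored constant-elasticity-of-transformation split of output between
the domestic market and the world pool. The CES/CET dual price indices
(equal to 1 at the calibration anchor) drive demand and cell supply.
Quantity conservation is what makes the adding-up identity exact: regional
net-export residuals sum to minus the world import residual by
construction. A word on Walras' law: this is a *partial* equilibrium model
without budget closure, so clearing all regional markets does not by
itself imply world clearing — the solver therefore solves the full
(3R+1)-dimensional system rather than dropping a redundant equation.

A transformation elasticity separate from $\sigma_A$ is needed because with
perfect transformation the domestic and world prices collapse into one and
the Armington structure degenerates; the synthetic worlds draw both from
the same range.

## Calibration and re-basing

`calibrate()` turns base-year share and level tables into an exact
equilibrium: all base prices are 1, quantities are backed out from shares,
and the raw tables must satisfy the base market-clearing identities (they
are validated, then stored in reconciled form so residuals at base are
zero to machine precision).

Multi-period runs are sequential comparative statics: each period's solved
state becomes the next period's calibration point. Two details matter:

* **Anchored price levels.** Re-basing does *not* renormalize prices to 1.
  Renormalizing each market's price separately while keeping quantities in
  tons would rescale each market's "currency" differently and silently
  change the economy (the re-based world would no longer be a fixed point
  of the zero-shock solve). Instead every behavioral form carries explicit
  base-price anchors, and re-basing moves the anchors to the solved levels.
  World price levels then remain directly comparable across periods.
* **Share updates.** Cell cost shares become realized value shares (under
  which the CES cost function is unchanged *as a function*); trade
  allocation shares become realized quantity shares and the price-index
  weights realized value weights (under which both trade rules are also
  invariant); the land-supply anchor moves along the same curve, leaving
  $\kappa$ unchanged.

Because every re-based form reproduces the same behavioral curves, solving
a period in $n$ equal multiplicative sub-shocks (`solve_multistep`) ends at
the same point as one full solve — a path-independence property the test
suite checks to 1e-6 and which would break if any re-basing rule were
inconsistent.

The land-cover shifter scales the whole supply curve proportionally
($\Lambda$ scaled, $\kappa$, $\gamma$ kept), applied identically in
baseline and counterfactual. A per-period proportional shift composes
path-independently across sub-steps, which an anchor-re-fitting rule would
not.

## Scenarios and comparison

The baseline applies each period's regional crop TFP growth to all cells.
The `no_iv` counterfactual subtracts the cell's improved-variety gain
$\tau_g$ (itself the crop-mix-weighted downscaling of regional per-crop
gain estimates) from the period's TFP growth; `no_cgiar_iv` subtracts only
the CGIAR-attributed fraction. Differences are reported counterfactual
minus baseline, so positive cropland differences are land *savings*
attributable to the removed technology. Cropland is a stock: per-period
values are increments of the difference and sum exactly to the
end-of-horizon difference. Output is a flow (per-period flow differences);
the price comparison uses the world price level, comparable across periods
thanks to the anchored re-basing.

# Environmental accounting

Both operators are linear in the cropland change and signed:

* **Carbon**: converting a hectare releases its vegetation carbon stock
  plus a fraction $f_s$ of its soil stock, once:
  $E_g = \Delta L_g\,(C_{veg,g} + f_s\,C_{soil,g}) \times 44/12$ tCO2e.
  No discounting and no foregone future sequestration. The soil fraction
  default is $f_s = 0.25$, configurable — a conventional value for the
  share of topsoil carbon lost on conversion to cropland.
* **Biodiversity**: potential species committed to extinction per taxon,
  $S_t = \sum_g CF_{t,e(g)}\,\Delta L_g$, using per-ecoregion occupation
  characterization factors from a countryside species-area relationship
  for plants, amphibians, birds, mammals and reptiles. Occupation factors
  only — transformation/regeneration factors are deliberately excluded
  (they would substantially enlarge the estimates), as are fertilizer and
  pesticide pressures.

Aggregation (taxa to total, periods to cumulative, cells to countries,
regions and hotspots) is exact summation; the test suite asserts the
partitions to machine precision.

# Uncertainty propagation

`run_uncertainty` re-solves the full baseline/counterfactual pair under
Latin-hypercube draws of multiplicative scale factors on selected
parameters (substitution elasticities, land supply elasticities, Armington
elasticities, demand elasticities, carbon stocks, characterization
factors). Stratification is exact — each parameter's $n$ draws occupy each
of $n$ equal-probability strata once — and grouped entries share a draw.
Reported intervals are the 2.5th and 97.5th percentiles with linear
interpolation between order statistics (R's default type-7 rule; the
method is a package choice since percentile conventions differ).
Environmental-factor draws cannot perturb the economic solution — the
pipeline factorizes — and the tests assert this structure. Default ranges
are ±50% uniform scale factors, clearly a synthetic placeholder: real runs
should supply measured parameter uncertainty. The default sample size
mirrors the study convention of n = 375; the test suite and the analysis
scripts use n = 25 to keep desk-scale runtimes.

# The synthetic world generator

`make_world()` draws a seeded toy economy with the statistical structure
the analysis assumes, so every stage is exercised without any external
data:

* **Cells** on a lon/lat lattice: lognormal base cropland and yields; land
  cost shares U(0.2, 0.4); land/nonland substitution U(0.2, 0.5) (land and
  other inputs are poor substitutes in crop production); land-supply point
  elasticity $\eta_0 = U(0.25, 0.7)\times(1 - L_0/\Lambda)$ — moderate
  curvature, consistent with the saturating curve itself, so
  land-constrained cells respond little in either direction.
* **Headroom**: $\Lambda/L_0 = 1 + \text{lognormal}$, median ratio around
  2.5 — the scale of cultivable-land estimates relative to current
  cropland — with the first (developing) region land-constrained and the
  last (rich) region land-abundant.
* **Adoption**: improved varieties diffuse only in the developing regions,
  in contiguous blocks covering half the cells by default, placed on
  higher-yield (1.4×) land, mirroring diffusion that favored irrigated,
  better-connected cropland. Per-crop regional gains are drawn per period
  (first period 0.20–0.40, echoing initial yield gains of 30–40 percent;
  later periods smaller) and downscaled through each cell's crop-mix value
  shares, so $\tau_g$ is a convex combination of crop-level gains. A
  per-cell CGIAR attribution fraction U(0.3, 0.7) supports the CGIAR-only
  variant.
* **Growth paths**: population, income, biofuel and sectoral TFP growth
  per period, with demand growth slightly ahead of TFP-driven supply
  growth, so baseline cropland expands and real crop prices drift gently
  downward — the stylized 1961–2015 record.
* **Environment**: lognormal vegetation and soil carbon; per-taxon
  lognormal characterization factors with plants far above the animal
  taxa; ecoregions in latitude bands; two countries per region; hotspots
  on the most plant-rich ecoregions present on the grid.

## Why these defaults sit in the land-sparing regime

Linearizing the one-market version of the model shows the global saving
from removing gains $\tau$ on an adopter set with output share $\phi$ and
land share $\lambda$ is proportional to
$$\phi\,\frac{1+k}{k - \varepsilon_p} - \lambda,$$
where $k$ is the supply elasticity implied by $\eta_0$, $\sigma$ and
$\theta_L$ and $\varepsilon_p < 0$ the crop demand elasticity. With
$|\varepsilon_p| < 1$ and $\phi = \lambda$ this is always positive — the
homogeneous-economy land-sparing result — but the margin is thin, and
second-order curvature of the saturating supply curve (contraction is
amplified, expansion damped) can flip small margins. The defaults above
keep the margin robustly positive the way the real economy does: adopters
farm high-yield land ($\phi > \lambda$), demand is price-inelastic, land
supply elasticities are well below 1, and the land-abundant non-adopting
region absorbs the counterfactual expansion. Under these conditions the
full sign pattern — baseline expansion in adopting cells, contraction
elsewhere, net global saving, counterfactual price above baseline — holds
across every generator seed we tested.

## What the generator does *not* emulate

Magnitudes are not calibrated to any country: cropland, outputs, carbon
stocks and characterization factors are realistic in scale but synthetic
in pattern. Passing tests therefore demonstrate the *mechanics and sign
structure* of the method — calibration identities, oracle agreement,
conservation, the equilibrium sign pattern, linear accounting, stratified
uncertainty — not the reproduction of real-world magnitudes, which depend
on the proprietary/large input datasets of a real run.

# Numerical choices and degenerate inputs

* Solver: Newton on log relative prices (positivity for free), tolerance
  1e-8 on residuals scaled by base market size, step-halving damping, step
  cap of 2 log units, at most 200 iterations; deterministic throughout.
  The tolerance and stepping are engineering defaults.
* Markets with zero base quantity (an absent sector, or the world pool in
  an autarky world) are pinned at their anchor price and excluded from the
  system, so toy worlds with a single active market are solved exactly.
* $\sigma = 1$ and $\sigma_A = 0$ are analytic limits, not numerical
  approaches.
* Ties and degenerate cases: zero-width uncertainty bounds are allowed
  (degenerate distributions collapse the intervals to a point); a zero
  global species impact makes the hotspot share undefined (flagged NA with
  a warning); corner cells make a state non-re-basable and raise an error
  if a later period needs them.
* The nonland input is supplied perfectly elastically at the numeraire
  price within each region. A finite nonland supply elasticity would make
  the nonland price endogenous and conflict with the numeraire convention,
  so it is out of scope here.
* The income-elasticity table shipped with the generator is synthetic and
  labeled as such; real runs should supply their own mapping.

# Problem sizes

The study world used by the tests and the acceptance script is 3 regions ×
100 cells (300 grid cells, 10 market prices), which a zero-shock solve
completes in well under a second and a full three-period scenario pair in
about two seconds; the n = 25 uncertainty run takes under a minute. These
sizes were chosen so the whole suite runs comfortably on a laptop; the
solver's outer system is independent of cell count, so grids several
orders of magnitude larger change only the vectorized per-cell work.

# Known limitations

Partial equilibrium without budget closure (no income feedback from factor
earnings); no bilateral trade matrix (single world pool); crops are one
corn-equivalent composite inside the equilibrium; no within-region demand
heterogeneity; one-time carbon accounting without flux dynamics; occupation
characterization factors only. The regional demand system and the
grid-cell supply side are the places a real-data application would extend
first.
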