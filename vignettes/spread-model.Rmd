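---
title: "A process-based spread model for the spotted lanternfly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A process-based spread model for the spotted lanternfly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slfspread)
```

## The model

`slfspread` simulates the invasion of the spotted lanternfly (*Lycorma
delicatula*, SLF) over a raster landscape at the level of pest *groups* per
grid cell rather than individuals — the unit at which survey programmes
actually observe this species. Each yearly (or monthly) step has three
stages.

**Reproduction.** A cell holding $g$ groups produces dispersing offspring
groups as the sum of $g$ independent Poisson draws with rate
$$\lambda = \beta \, T_{i,t} \, X_t,$$
where $\beta$ is the baseline reproductive rate under optimal conditions,
$T_{i,t} \in [0,1]$ is the cell's monthly temperature coefficient and
$X_t \in \{0,1\}$ a seasonality mask (April–October active by default).
For instance, $\beta = 2.2$ under $T = 0.7$ in season gives a modified rate
of $1.54$; five groups then disperse $7.7$ offspring groups on average.
Because a sum of $g$ Poisson($\lambda$) draws is Poisson($g\lambda$), the
engine draws once per cell.

**Dispersal.** Each dispersing group chooses a route: if its cell contains a
rail line, it disperses naturally with probability $\gamma$ and otherwise
rides the rail network; without rail it always disperses naturally.

* The *natural kernel* draws a distance $|{\rm Cauchy}(0, \alpha_1)|$ (a
  half-Cauchy whose median equals the scale $\alpha_1$) and a bearing
  uniform on $[0^\circ, 360^\circ)$, $0^\circ$ = North, clockwise.
* The *network kernel* boards the group at the point of the within-cell rail
  nearest the cell centre, draws a travel distance from
  ${\rm Uniform}(d_{\min}, d_{\max})$, and walks the graph: the initial
  direction is uniform over the two arc directions (or over all incident
  edges when boarding exactly at a node); at each node passed, a continuing
  edge is chosen uniformly among incident edges excluding the arrival edge;
  a dead end stops the ride. The group disembarks exactly at the residual
  arc-length — anywhere along an edge, not only at nodes, which is the
  point of modelling rail transport with full edge geometry.

**Establishment.** A group landing in cell $i$ establishes with probability
$$p = \frac{S_i}{N_i} \, T_{i,t} \, X_t,$$
where $N_i$ is the cell's total potential host units (tree of heaven) and
$S_i$ its still-susceptible units; $p = 0$ where no hosts occur. On success
the cell gains one group and one host unit moves from susceptible to
infested ($\psi$ counts these per step). Infested cells never revert:
mortality, treatment and quarantine are out of scope.

### Parameters

| parameter | meaning | units | prior bounds (default) |
|---|---|---|---|
| $\beta$ | offspring groups per group per step | 1/step | 0.2 – 5 |
| $\alpha_1$ | natural kernel scale | m | 500 – 8000 |
| $\gamma$ | probability of natural dispersal | – | 0.5 – 1 |
| $d_{\min}$ | minimum rail travel | m | 5,000 – 50,000 |
| $d_{\max}$ | maximum rail travel | m | 50,000 – 300,000 |

The prior bounds are working assumptions: at a 5-km grid a natural-kernel
scale beyond a cell width or two is already long-range, most dispersal of
this species is local, and documented rail-associated jumps span tens to
hundreds of kilometres.

## Calibration: ABC with sequential Monte Carlo

`slf_calibrate()` fits the five parameters to presence/absence surveys.
Each candidate parameter set is simulated and compared with the surveys
pooled over the calibration period: a positive record in a simulated-
infested cell is a true positive, a negative record in an infested cell a
false positive, and so on, giving accuracy, precision, recall and
specificity. Ratios with zero denominators are flagged as undefined and
never pass a gate.

Generation 1 draws from independent uniforms over the prior bounds and
keeps sets whose four statistics all *strictly* exceed the initial
thresholds (0.65 by default) until the quota (10,000 by default) is kept.
Each later generation draws from a multivariate normal fitted to the
previous generation's kept sets (rejecting draws outside the bounds or with
$d_{\min} > d_{\max}$) and gates on the componentwise means of the previous
kept statistics, so thresholds tighten in expectation and never loosen. The
final generation's kept sets are the posterior sample; seven generations is
the reference design.

Two numerical choices deserve note. The proposal is a single multivariate
normal fitted to all kept sets, not a per-particle perturbation kernel —
the simpler scheme matches the generation-wise description the design
follows and mixes adequately at the scales tested. And when a generation's
acceptance rate falls below `1/max_draw_factor` the chain aborts with a
diagnostic rather than running forever; the joint four-statistic gate makes
late-generation acceptance rates of a few percent normal, so desk
configurations raise `max_draw_factor` rather than loosening gates.

## Forecasting

`predict()` on a fitted model (or `run_ensemble()` directly) re-runs the
stochastic model many times — 10,000 in the reference design — drawing one
posterior parameter set per run so calibration uncertainty propagates, and
resampling whole historical weather years with replacement so within-year
month correlation is preserved. The probability of occurrence of a cell in
a year is exactly the fraction of runs in which it was infested; with no
recovery in the model it is non-decreasing in time.

Downstream utilities: `mask_and_downscale()` replicates coarse cells onto a
finer grid and zeroes fine cells without hosts; `county_probability()`
aggregates a probability raster over a zone raster by mean or maximum
(empty zones are reported missing, never zero — the county mean saturates
at the county's suitable-pixel fraction once every suitable pixel is
predicted infested); `categorize()` applies the published risk boundaries
8.359%, 26.89% and 51.99%, with boundary values assigned to the higher
category ("below" being strict); `compare_maps()` cross-tabulates two
category maps as pixel fractions whose margins reproduce each map's
category totals exactly.

## The synthetic study system

Real SLF survey data are confidential, so the package ships a generator
(`gen_scenario()`) whose defaults define the study conditions used
throughout the tests:

* a 50 × 50 grid of 5-km cells; host suitability from a Gaussian random
  field smoothed over 3 cells, thresholded to 70% host cover and converted
  to integer host capacities (100 units at full suitability);
* a Y-shaped rail network through the grid centre (line and lattice
  topologies are available);
* smooth seasonal temperature coefficients peaking in July, scaled per cell
  in [0.8, 1], April–October active;
* an introduction of 30 groups in 2014 in a host-rich rail cell near the
  centre, spread simulated for 6 years under the true parameters
  $\beta = 1.5$, $\alpha_1 = 2500$ m, $\gamma = 0.9$,
  $d_{\min} = 20$ km, $d_{\max} = 120$ km;
* 1,000 surveys per year, 30% clustered around infested cells (Gaussian
  jitter, 3-cell standard deviation) and the rest uniform background, with
  a 10% false-negative rate on truly infested cells.

These values were chosen once as a plausible desk-scale analogue of a
regional invasion: a several-year-old founder population by first
detection, mostly-natural dispersal with occasional long rail jumps, and a
survey programme that concentrates near known infestations but retains
background coverage. The generator emulates the *structure* of real
surveillance data — clustered effort, imperfect detection, positives and
negatives — but not real geography, real climate statistics, or
observation processes such as reporting bias; passing tests therefore
demonstrate internal consistency and recoverability, not predictive skill
on real landscapes.

## Desk-scale experiment sizes

The test suite runs everything at sizes a laptop handles comfortably: the
parameter-recovery experiment uses 20 independent scenarios, each
calibrated with 3 generations of 200 kept sets, initial thresholds of 0.35,
and yearly stepping (`sub_steps = 1`, which folds the season into the mean
active-month coefficient; $\beta$ is then a per-year rate). Yearly stepping
at this scale keeps each of the roughly $10^4$–$10^5$ simulations per
experiment in the low milliseconds without changing the structure of the
inference problem. Initial thresholds sit below the reference 0.65 because
a single stochastic run against a single survey realisation has an
achievable recall around 0.5 at the true parameters; gates above that level
would reject the truth itself. Forecast property checks use ensembles of a
few hundred to a few thousand runs.

## Numerical conventions and edge cases

* Coordinates are projected metres; the grid origin is the upper-left
  corner, y decreases southward; cells are half-open so boundary points
  belong to the next cell east/south; out-of-bounds lookups error rather
  than clamp. Dispersers crossing the landscape boundary are lost
  (absorbing boundary).
* Establishment is implemented by an exact vectorised equivalence: each
  arrival passes the $T$ gate, then picks a uniform host slot in its cell;
  it establishes iff the slot is susceptible and it is the slot's first
  claimant. This reproduces the sequential Bernoulli$(S/N \cdot T)$ process
  with $S$ depleting per success, without per-arrival loops.
* Group counts are uncapped; saturation emerges as $S \to 0$. Dispersing
  groups are propagules — the source population persists.
* A disperser cannot chain a second network hop in the same step, and rail
  traffic volume/directionality is not modelled.
* Host rasters are suitability surfaces in [0, 1]; integer capacity is
  `round(suitability * carrying_units)` with host-positive cells floored at
  one unit.
* All randomness flows from R's global RNG; a single `set.seed()` makes
  scenario generation, calibration and forecasting reproducible
  end-to-end, and the command-line interface threads `--seed` through
  every subcommand.

## Limitations

The model inherits the scope of its design: no mortality or management, a
single static host layer, weather as a monthly 0–1 coefficient rather than
mechanistic phenology, and rail dispersal without traffic weighting. The
legacy long-distance Cauchy kernel (historically `alpha2`) that the network
kernel replaces is not part of the calibrated model. Calibration quality
degrades gracefully with survey sparsity — at desk scale the posterior for
$\gamma$ is noticeably wider than for $\beta$ and $\alpha_1$, because only
the minority of dispersal events in rail cells inform it.
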