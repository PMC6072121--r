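---
title: "A hybrid Potts/reaction-diffusion model of endothelial sprouting in fibrin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid Potts/reaction-diffusion model of endothelial sprouting in fibrin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiosprout)
```

## The system being modeled

In the classic in-vitro sprouting assay a confluent monolayer of human
microvascular endothelial cells is seeded on a polymerized fibrin gel.
Under pro-angiogenic stimulation, a few cells in the monolayer locally
proteolyse the fibrin and invade it, forming capillary-like sprouts over
about ten days.  Cell-associated fibrinolysis is carried out by plasmin,
activated from fibrin-bound plasminogen by uPA bound to its receptor uPAR
on the cell membrane; cells secrete PAI-1, which inactivates uPAR-bound
uPA and is internalized with it.  Fibrin also stores latent TGF$\beta$1;
plasmin releases and activates it, and active TGF$\beta$1 induces uPAR
expression.  Together these reactions close a positive feedback loop —
uPAR $\to$ plasmin $\to$ TGF$\beta$1 $\to$ uPAR — whose local, stochastic
ignition is this model's explanation for where sprouts start and why
high-molecular-weight fibrin (with more binding sites for latent
TGF$\beta$1) supports more ingrowth than low-molecular-weight fibrin.

`angiosprout` implements this hypothesis as a hybrid model: a cellular
Potts model (CPM) for cell shape and movement on a 2-D cross-section of
the culture, a ten-species reaction-diffusion system for the plasmin
chemistry, and one ordinary differential equation per cell for its
membrane uPAR level, coupled by operator splitting.

## Cell movement: the cellular Potts model

The domain is a `width` $\times$ `height` lattice (default $500 \times
150$ sites at $\Delta x = 2\,\mu m$, i.e. $1000 \times 300\,\mu m$).
Every site carries the identifier $\sigma(\vec x)$ of a *generalized
cell*: an endothelial cell, the fibrin block (one identifier), the
medium, the border frame, or a static "cell patch" embedded in each side
wall at monolayer height that glues the monolayer to the boundary.  The
Hamiltonian is

$$H = \sum_{(\vec x,\vec x')} J\!\left(\tau(\sigma(\vec x)),
\tau(\sigma(\vec x'))\right)\bigl(1-\delta_{\sigma(\vec x),\sigma(\vec x')}\bigr)
  + \sum_{s\,\in\,\text{cells}} \lambda_A \bigl(A(s) - a(s)\bigr)^2,$$

with contact energies over all 8-adjacent site pairs and a quadratic
area constraint for cells only.  One Monte Carlo step (MCS $\approx$ 2.5
minutes) performs as many copy attempts as there are lattice sites: a
random site's identifier is proposed to copy into a random 8-neighbor,
and the move is accepted with probability $\min\{1, e^{-(\Delta H +
H_0)/\mu}\}$.  $H_0$ collects dissipative penalties: a connectivity
penalty of $10^9$ if the retracting cell would fragment (cheap ring test
around the retracted site; a full BFS audit runs in the test suite), and
the fibrin obstruction term

$$\Delta H_{0,\text{invasion}} = \frac{p}{1 + e^{-E(f(\vec x') - m)}}
\quad\text{for } f(\vec x') > \theta_{\text{fibrin}},$$

with $p = 1000$, $E = 10$, $m = 0.5$, $\theta_{\text{fibrin}} = 0.3$ and
$f$ the total fibrin concentration, so that intact fibrin ($f = 1$)
resists invasion while degraded fibrin ($f < 0.3$) is freely entered.
Only cells and medium may move; fibrin can only be displaced (both by
cells and by medium, so that fully degraded regions can fill with
medium); the border and the side patches never change.  Default contact
energies: $J_{\text{cell,cell}} = 15$, $J_{\text{cell,medium}} = 30$,
$J_{\text{cell,fibrin}} = 75$, $J_{\text{fibrin,medium}} = 120$,
$J_{\text{cell,border}} = 10^6$, with $\lambda_A = 100$, $\mu = 100$ and
a cell target area of 200 sites ($800\,\mu m^2$).

Every 10 MCS each cell whose membrane fraction in contact with other
cells, $R_\sigma$, is below $R_{\text{mitosis}} = 0.35$ divides with
probability $P_{\text{mitosis}} = 0.6$ over its short principal axis
(second-moment tensor; sites with positive projection on the long axis
go to the new identifier, ties stay with the parent).  Both daughters
keep the parent's target area and uPAR level.  Contact with the static
side patches counts as cell-cell contact: the patches stand in for the
continuing monolayer, and treating them as foreign would leave the two
edge cells permanently below the contact threshold and make them divide
without bound.

## The plasmin chemistry

Ten concentration fields live on the same lattice, in relative units
(RU) anchored to the initial fibrin-bound complex concentration of 1:
free fibrin $F$, free plasminogen $PLG$, free latent TGF$\beta$1
$LTGF$, active TGF$\beta$1 $TGF$, PAI-1 $PAI$, and the fibrin-bound
complexes $F_{PLG}$, $F_{LTGF}$, $F_{PLG,LTGF}$, $F_{PLS}$,
$F_{PLS,LTGF}$.  Binding of plasminogen ($k_{f1}, k_{r1}$) and latent
TGF$\beta$1 ($k_{f2}, k_{r2}$) to fibrin is reversible and
non-competitive (the same constants apply whether or not the other
ligand is bound).  uPAR converts fibrin-bound plasminogen to
fibrin-bound plasmin with Michaelis-Menten kinetics ($k_{u1}, k_{m1}$)
in the local uPAR level $U$, taken as the 9-site neighborhood mean of
the projected per-cell uPAR field.  Total bound plasmin releases and
activates latent TGF$\beta$1 ($k_{u2}, k_{m2}$).  Fibrinolysis removes
the two plasmin complexes through a Hill term $h\,X^2/(d + X^2)$, the
doubly-loaded form also returning free latent TGF$\beta$1 to solution.
Cells secrete PAI-1 at rate $\alpha$ on every occupied site, and PAI-1
is consumed by uPAR binding at rate $k_{f3}$.  The four free species
diffuse; bound species are structurally immobile.  Free fibrin does not
decay; every other species has a first-order decay.

Because plasmin never unbinds, each unit of activated plasmin is
eventually removed together with its fibrin (by the Hill term or by
complex decay): the site-wise total fibrin never increases, and the
baseline fibrin loss rate equals the baseline plasmin activation rate.
This identity drives the calibration below.

The per-cell uPAR equation combines first-order decay
$\epsilon_{\text{uPAR}}$, internalization $k_{f3}\,[\text{uPAR}]
\sum_{\vec x \in C(s)} PAI(\vec x)$ over the cell's occupied sites,
basal production $c$, and TGF-induced production $k_{u3}
T^2/(k_{m3}+T^2)$ with $T$ the *sum* of TGF$\beta$1 over the cell's
boundary sites.  Both sums are implemented exactly as stated (occupied
sites for PAI, boundary sites for TGF), which makes $k_{m3}$
perimeter-scale dependent; the defaults are calibrated for the 200-site
cell used throughout.

## Numerics and operator splitting

One simulation step is: (1) one MCS of the CPM at frozen chemistry,
with the invasion penalty read from the current total fibrin; (2) one
forward-Euler step ($\Delta t = 1$ MCS $= 150$ s) of all per-cell uPAR
equations at the frozen field state, then re-projection of uPAR onto
the new cell footprints; (3) ten forward-Euler reaction-diffusion
substeps ($\Delta t = 0.1$ MCS $= 15$ s); (4) the division check every
10 MCS; (5) scheduled TGF$\beta$1 re-dosing, if configured.  Diffusion
uses the 5-point Laplacian with zero-flux boundaries — the culture well
is closed, and this choice conserves mass to machine precision (a test
asserts it).  The lattice diffusion number $D\,\Delta t/\Delta x^2$ of
every mobile species must stay below 0.25; the configuration
constructor refuses settings that violate the bound.  No clipping or
caps are applied to the fields; a concentration below $-10^{-9}$ raises
a diagnostic warning, signalling a too-large time step.  Within one
reaction substep all transfer terms are evaluated at the same old
state, so the network's conserved moieties (total plasminogen with
fibrinolysis and decays off; total latent TGF$\beta$1 including the
activated form with decays off) are conserved exactly, not just to
$O(\Delta t)$; tests assert this too.

Degenerate Michaelis-Menten and Hill denominators (substrate and
half-saturation constant both zero) are defined as zero flux, so
switched-off reaction channels are exactly inert.

## Initial condition and what it emulates

`initialize_simulation()` builds a cross-section of the assay: a
one-site border frame; fibrin filling the lower two thirds of the
interior (the exact fraction is configurable — the assay's gel depth is
not critical as long as there is headroom for sprouts); `n_cells`
equal-sized cells in one row on top, each starting at exactly its
target area so no pressure transient pushes the monolayer into the
fibrin; medium above; and the static side patches at monolayer height.
Every fibrin site starts with $F_{PLG,LTGF} = 1$ (both plasminogen and
latent TGF$\beta$1 fully bound).  The depletion experiments lower one
moiety while keeping totals at 1: $F_{PLG,LTGF} = q,\ F_{LTGF} = 1-q$
(plasminogen depletion) or $F_{PLG,LTGF} = q,\ F_{PLG} = 1-q$ (latent
TGF$\beta$1 depletion, the low-molecular-weight fibrin analogue).
Cells start at the basal uPAR steady state $c/\epsilon_{\text{uPAR}}$,
and the PAI-1 field starts at its domain-wide mass-balance steady state
$\alpha\,n_{\text{cell sites}}/(\epsilon_{PAI}\,n_{\text{sites}})$:
the assay seeds the monolayer a day before stimulation, during which
PAI-1 accumulates, and starting it at zero would give every run a
brake-free window in which the feedback ignites regardless of the PAI-1
parameters (`pai_equilibrium = FALSE` restores the bare start).  TGF$\beta$1 dosing sets the TGF field
uniformly to the dose at $t = 0$ and again every `redose_period` MCS
(default 1152 MCS = two days at 2.5 min/MCS), mimicking medium
refreshment.

The generator reproduces the geometry, stoichiometry and stimulation
protocol of the assay, not its biological variability: real monolayers
have heterogeneous cell sizes and donor-dependent responsiveness, fibrin
gels have fiber-scale structure far below the 2 µm lattice, and the
third dimension is collapsed to a cross-section.  Passing tests
therefore demonstrate the claimed mechanism inside this idealization,
not quantitative agreement with any particular culture.

## Calibrated kinetic defaults

Printed anchors fix $c$ (swept over 0.001-0.005 RU/MCS; the validation
set uses 0.005), $\epsilon_{PAI} = 0.01$, $\epsilon_{\text{uPAR}} =
0.0095$ MCS$^{-1}$, the initial bound concentrations, and the CPM and
invasion parameters.  The remaining constants are the package's own
qualitative calibration, chosen once against four requirements and then
frozen:

1. **Quiet baseline.**  With the feedback silent, fibrin loss equals
   plasmin activation, so baseline activation must stay near
   $5\times10^{-4}$ RU/MCS: over a 10-day run the monolayer then sinks
   at most a few sites, inside the top-10% band that the angiogenesis
   quantifier deliberately ignores.  This sets $k_{u1}$ given the basal
   uPAR level.
2. **Fast fronts.**  An ignited cell (uPAR tens of times basal) must
   clear a site of fibrin in $\sim$100 MCS so sprouts reach a useful
   depth within 6000 MCS; the Hill constants $h$ and $d$ are set so the
   tip's plasmin level sits near the Hill's saturating knee while the
   baseline level sits deep in its quadratic foot, which is what
   separates tip fibrinolysis from baseline fibrinolysis by orders of
   magnitude despite only a $\sim$40-fold uPAR ratio.
3. **Local ignition.**  Active TGF$\beta$1 is short-ranged
   ($D_{TGF} = 0.5$, $\epsilon_{TGF} = 0.1$: a decay length of
   $\sim$2 sites), so the plume of a degradation front feeds the cell
   at the front and barely its neighbors; PAI-1, with a 14-site range,
   holds the rest of the monolayer down.  With long-ranged TGF$\beta$1
   the whole monolayer ignites in a chain reaction and lowers uniformly
   — the opposite of sprouting.
4. **Thresholded induction.**  $k_{m3}$ and $k_{u2}$ place the basal
   perimeter TGF$\beta$1 sum well below the induction Hill's
   half-saturation, so ignition is a rare fluctuation-driven event
   whose rate rises steeply with basal uPAR expression $c$ — a handful
   of ignitions per monolayer at $c = 0.005$, essentially none at
   $c = 0.001$.

Decay of the bound complexes is kept at $10^{-5}$ MCS$^{-1}$, except
the plasmin complexes at $3\times10^{-2}$: inactivation there keeps
the baseline plasmin level decay-dominated and hence *linear* in uPAR,
which preserves the quadratic foot of the induction Hill and with it
the ignition barrier (with consumption-dominated plasmin the level
grows only as the square root of uPAR and bistability is lost).  Free
plasminogen and latent TGF$\beta$1 decay slowly ($10^{-3}$); PLG,
LTGF and PAI-1 diffuse at 2 sites$^2$/MCS (lattice diffusion number
0.2, under the 0.25 stability bound).

## Quantification

The *angiogenesis level* scans one horizontal line per vertical site
through the lower 90% of the initial fibrin region and counts, per
line, runs of cell-or-medium sites longer than one cell diameter
(strictly more than 20 sites) but narrower than the full line; the
level is the mean count over lines.  Full-width runs are uniform
monolayer lowering, not sprouting, and the excluded top 10% absorbs the
slow baseline sinking.  Scan lines live in the *initial* fibrin
region, measured at set-up, because the current fibrin recedes as it is
degraded; this also excludes the occasional stacks of cells left
hovering above the monolayer after heavy dosing, which are a lattice
artifact.  A run is *sprouted* if its level exceeds zero;
*fibrinolysis* is the percentage of initial fibrin sites now occupied
by cells (medium does not count).  Cell-cycle duration is the mean
MCS between consecutive divisions of a lineage, converted at 2.5
min/MCS.

On narrow lattices the level cannot signal uniform monolayer lowering
the way it does on the full domain: residual fibrin septa — in
particular next to the side patches, which carry no uPAR — prevent
full-width components from ever forming, so heavily degrading runs keep
a positive level.  `monolayer_descent()` (the median, over columns, of
how far the fibrin surface has receded) is therefore the package's
lowering indicator: sprouting runs have near-zero median descent with
deep local minima, lowered monolayers have a large median descent.  The
dosing and PAI-1-decay experiments use it to separate the two regimes.

## Problem sizes

The defaults reproduce the full study conditions ($500\times150$, 50
cells, 6000 MCS).  The package's test suite and the acceptance script
run the same model at half linear scale ($250\times75$, 25 cells,
3000 MCS) for the cell-cycle statistic, and the sweep tests on a
$150\times64$-site lattice (15 cells, fibrin filling 60% of the
interior, 1350-2400 MCS) with 3-12 replicates per condition; these
sizes were chosen as the smallest at which the monolayer, sprout
widths (>20 sites) and the quantifier's scan band remain
well-separated scales.  The dosing experiment uses a basal expression
of $c = 0.0015$ RU/MCS, below the spontaneous-sprouting regime, so
that dose-driven enhancement is visible over the undosed baseline.  Trend checks compare replicate statistics
under common random numbers (the same seeds across parameter values),
which makes paired sign tests sensitive at modest replication.

## Known limitations

* Chemical fields do not advect with displaced fibrin; the model
  operates in the low-Péclet regime where diffusion and degradation
  dominate transport.
* PAI-1 secretion is uniform over all cells, so the brake is global;
  the model selects sprouts by rare local ignition rather than by
  activator-inhibitor pattern formation.
* All cell-bound uPAR is treated as active uPA-uPAR complex; pro-uPA
  kinetics, tPA, MT1-MMP proteolysis and Delta-Notch signalling are out
  of scope.
* The division rule replenishes sprouts; with division disabled the
  invasion mechanism still operates but sprouts are thinner and
  shallower.
* Quantities are in relative units; only cell size, lattice spacing and
  the MCS-to-minutes conversion are anchored to physical units.
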