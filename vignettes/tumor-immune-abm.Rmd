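---
title: "A hybrid agent-based model of FGFR3-driven bladder tumor-immune dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid agent-based model of FGFR3-driven bladder tumor-immune dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgfr3tme)
```

## The model

`fgfr3tme` simulates a bladder tumor microenvironment (TME) as a 3D on-lattice
agent-based model coupled to continuum fields. Two agent types live on a cubic
lattice with at most one agent per site:

* **Tumor cells** carry two heritable binary traits, assigned independently at
  initialization: antigenicity (high, HA, or low, LA) and FGFR3 mutation
  status (Mut or WT). Both traits pass unchanged to daughters; there is no
  mutation process, so the subtype set can only shrink over a simulation.
* **CD8+ T cells (CTLs)** enter at the boundary vasculature and cycle through
  three behavioral states: *active* (free to move, divide, conjugate),
  *engaged* (locked onto a tumor cell), and *exhausted* (irreversibly inert,
  occupying space until death).

The simulation is initialized with 100 tumor cells packed breadth-first around
the lattice center and no immune cells. Each iteration advances the clock by
one tumor step (15 min) in a fixed order: FGFR3 kinetics update, tumor events,
PD-1/PD-L1 kinetics update, CTL recruitment followed by two immune sub-steps
(7.5 min each), removal of apoptotic tumor cells, and scheduled drug dosing.

### Stochastic events

Each cell receives at most one event per step. With a menu of competing rates
$r_i$ and total $R = \sum_i r_i$, nothing happens with probability
$e^{-R\,\Delta t}$ and otherwise event $i$ fires with probability $r_i / R$ —
the exact law for competing exponential clocks with rates held constant over
the step. Agent update order is randomized each step to avoid lattice-scan
bias.

Tumor cells proliferate at $\alpha_T + \alpha_F\,\phi_D$ and die at
$\delta_T\,(1 - \epsilon_F \min(\phi_D, 1))$, where $\phi_D$ is the
active-dimer fractional occupancy of the FGFR3 pathway (zero for WT cells).
Division requires at most `crowd_threshold` occupied Moore neighbors *and* an
empty neighbor site for the daughter. Both FGFR3 effects are linear in
$\phi_D$; these two coefficients, $(\alpha_F, \epsilon_F)$, are exactly the
axes swept by `run_fitness_sweep()`.

Active CTLs choose among six events: proliferation (base rate $\alpha_I$
multiplied by a saturating function of the local immune stimulatory factor,
ISF), apoptosis ($\delta_I$), movement ($m$, taking `n_move` single-site
steps), conjugation with a neighboring non-apoptotic tumor cell ($\beta$),
exhaustion (a Hill function of the regional PD-1–PD-L1 complex), and
activation-induced cell death (AICD), which switches on only after the cell
has gone longer than `tau_idle` without conjugating. Engaged CTLs can only die
or exhaust; either event releases the target unharmed. Kills complete after
exactly 30 min of uninterrupted engagement for HA targets (perforin/granzyme)
and 2 h for LA targets (Fas/FasL) — the 4-fold exposure difference is the core
fitness advantage of low antigenicity, because exhaustion can interrupt a
2-hour Fas engagement far more often than a 30-minute perforin one.

### Fields and region-averaged kinetics

The ISF field lives at lattice resolution: live tumor cells deposit
$\sigma \Delta t$ at their own site (HA cells four times more than LA at the
defaults), and the field diffuses (explicit 6-point stencil, sub-cycled to the
stability bound, reflecting boundaries) and decays each step. CTL chemotaxis
samples an empty Moore neighbor with weight
$\exp(\lambda\,(c_{nbr} - c_{here})/d_{nbr})$, discounting diagonal moves by
their lattice distance.

Receptor and drug kinetics use a *global method*: the lattice is partitioned
into cubic regions (default $5^3$), each split into mutant-occupied,
WT-occupied and tumor-free subregions by occupant census every tumor step.
FGFR3 species (free monomer $M$, active dimer $D$, inhibitor-bound monomer
$B$) are per-cell-average concentrations on the mutant subregion obeying
mass-action dimerization ($k_{dim} M^2 \leftrightarrow k_{undim} D$) and
inhibitor binding, with the conservation law $M + 2D + B = R_{total}$
maintained to integrator precision. The free small-molecule inhibitor (SMI)
diffuses on the region graph and enters at boundary regions from its
pharmacokinetic (PK) model. On a lattice whose regions are internally
homogeneous, the region-averaged trajectories coincide with per-cell
integration — this is verified in the test suite.

$\phi_D$ normalizes the dimer concentration by the mutant-cell average total
FGFR3. Because two monomers make one dimer, the literal ratio $D / R_{total}$
caps at 0.5; the package therefore offers a `phi_normalization` switch and
defaults to `"half"` ($D / (R_{total}/2)$), so that full dimerization gives
$\phi_D = 1$ and the swept proliferation axis reaches
$\alpha_T + \alpha_F$ — e.g. $1.75\,d^{-1}$ at the default
$\alpha_T = 0.5$, $\alpha_F = 1.25$. The `"total"` option preserves the
literal ratio.

PD-1/PD-L1 follows the same regional pattern with a quasi-equilibrium
shortcut: anti-PD-1 antibody binding to PD-1 is integrated dynamically per
region (PD-1 totals come from the resident CTL census, PD-L1 from the tumor
census), and the PD-1–PD-L1 complex is then taken at binding equilibrium —
the unique root of $(P - C)(L - C) = K_d\,C$. That complex drives the
exhaustion Hill rate. FGFR3 signaling additionally suppresses CTL
recruitment by the factor $1 - s_{max}\,\overline{\phi_D}$ (mean over mutant
cells), the mechanism by which mutant tumors starve themselves of immune
pressure.

### Therapy

Each drug has a two-compartment PK model advanced in closed form (exact 2×2
matrix exponential), with first-order elimination and a central-to-TME
transfer that feeds boundary regions. The SMI has a ~6 h half-life and is
dosed daily; the antibody has a ~10 d half-life and is dosed every 3 days.
Five arms are built by `build_schedule()`: control, the two monotherapies
(default window days 14–21), and the two staggered combinations (first drug
days 14–21, second days 21–28).

## Parameter defaults

Structural constants of the model: 100 initial tumor cells, 15/7.5 min
tumor/immune steps, 30 min and 2 h kill durations, ten replicates per
parameter set, and the three-bin response classification at 30%/90% Day-25
burden reduction. Every remaining rate was chosen once, as a biologically
reasonable value on the literature scale for that process, and is exposed in
`default_config()` with its unit in the key name:

* **Tumor**: $\alpha_T = 0.5\,d^{-1}$, $\delta_T = 0.1\,d^{-1}$ (cell cycle
  ~1–2 d, baseline apoptosis ~10 d); $\alpha_F = 1.25\,d^{-1}$,
  $\epsilon_F = 0.9$ so that a fully active pathway anchors the landscape's
  printed proliferation scale; crowding threshold 24 of 26 neighbors.
* **CTLs**: movement ~4 µm/min at the 20 µm site length ($m = 0.05$/min,
  `n_move` = 4); conjugation attempts every ~5 min next to a target;
  lifespan ~3 d ($\delta_I = 0.35\,d^{-1}$); recruitment 0.25 CTLs per tumor
  cell per day; exhaustion saturating at 24 d$^{-1}$ with a Hill midpoint at
  complex concentration 0.3 and coefficient 2. These joint choices place the
  model in the regime where fast perforin killing outruns exhaustion but slow
  Fas killing does not — HA-only WT tumors are cleared by the
  recruited response, while tumors with an LA or mutant subpopulation escape.
* **Kinetics**: $k_{dim}/k_{undim} = 100$ per concentration unit gives a
  drug-free equilibrium occupancy $\phi_D^\ast \approx 0.93$; the SMI binds
  monomers fast ($k_{on} = 10$/conc/min) and releases slowly, so a daily-dosed
  window drives $\phi_D$ below 0.02 within ~2 days. Antibody binding
  similarly collapses free PD-1 within a dosing interval.

Concentration and dose units are model units (the PK central amount is in
TME-concentration equivalents); only ratios against $K_d$s, Hill midpoints
and saturation constants matter.

## What the synthetic generators emulate

Two generators produce test data. `initialize_simulation()` *is* the study
condition generator: compositions are Bernoulli-independent across the two
traits at configured fractions, matching the factorial design of the
composition experiments (0/50/100% mutant × 0/50/100% HA).
`synthetic_agent_cloud()` produces position clouds with analytically known
geometry (a square hull of area 100, a uniformly occupied lattice, a thin
spherical shell) so the spatial metrics are tested independently of the
simulator. Neither generator emulates real histology: there is no stroma,
vascular tree, nutrient limitation, or continuous antigen variation, so
passing tests demonstrate internal consistency of the model mechanisms, not
fidelity to patient tissue.

## Numerical choices

* Kinetic ODEs use `deSolve::lsoda` at `rtol 1e-10 / atol 1e-12`; receptor
  conservation holds to $10^{-8}$ through drug exposure. Tiny negative
  round-off concentrations are clipped to zero.
* The ISF explicit diffusion sub-cycles at $D\,\Delta t_{sub}/\Delta x^2 \le
  1/6$; with reflecting boundaries the scheme conserves mass to machine
  precision and spreads a point release by exactly $2Dt$ per axis.
* PK advances by an exact 2×2 matrix exponential (trace/traceless
  decomposition); the TME influx uses the central amount at the start of each
  15-min step (piecewise-constant source), a negligible approximation at both
  drug half-lives.
* A region that newly gains mutant cells inherits the volume-weighted mean
  receptor state of existing mutant subregions (receptors travel with cells);
  a region losing its last mutant resets to fresh monomer. Receptors are
  carried by mutant cells only — WT FGFR3 is not modeled as a drug sink.
* Division placement and immune event execution run sequentially in a
  randomized order so that two agents never claim the same site; occupancy
  exclusivity is asserted after every iteration in the test suite.
* Ties and degeneracies in metrics are *flagged*, not silently zeroed:
  hulls need three non-collinear tumor positions, reductions need a nonzero
  control burden, and KDE needs nonzero variance.

## Problem sizes used by the test and acceptance suites

Replicate-level checks run on a compact domain chosen so the full suite
completes on a single CPU: a $16^3$ lattice with $4^3$ kinetics regions,
25 simulated days, three replicates per condition, and (for the mixed
composition arms) a 30-cell seed so that the therapy window opens while the
control arm is still below carrying capacity. The mechanistic and oracle
checks (equilibria, conservation, samplers, PK) are size-independent.
On this domain the calibrated defaults reproduce the qualitative study
behaviors: HA-WT tumors regress without treatment; LA and mutant fractions
take over under control and ICI; anti-FGFR3 monotherapy reduces Day-25
burden when mutants are present; and increasing antibody exposure
monotonically lowers the regional complex and with it the exhaustion rate.

## Known limitations

* Supplementary-level quantitative details of the original study (exact
  parameter table, lattice size, dosing regimens) are not encoded; the
  defaults reproduce the mechanism structure and qualitative orderings, so
  quantitative figure-level agreement is out of scope.
* The global method averages receptor state within subregions; strong
  intra-region heterogeneity (e.g. a single mutant cell at a region corner)
  is smoothed by construction.
* Exhausted CTLs keep expressing PD-1 and contribute to regional totals; the
  alternative bookkeeping would slightly lower complex concentrations in
  heavily exhausted regions.
* Recruitment suppression follows the mean mutant $\phi_D$ regardless of the
  mutant *fraction*; a 1%-mutant tumor with a fully active pathway therefore
  suppresses recruitment as strongly as a pure-mutant one. This mirrors the
  stated dependence; scaling by mutant fraction is a plausible alternative.

## A worked example

```{r, eval = FALSE}
cfg <- tme_config(
  lattice = list(dims = c(16L, 16L, 16L), regions_per_axis = 4L),
  init = list(n_tumor = 30L, frac_mutant = 0.5, frac_ha = 0.5),
  measure = list(log_every_steps = 16L)
)
ctrl <- run_replicates(cfg, n_reps = 3, base_seed = 11)
cfg$therapy$arm <- "aFGFR3"
trt <- run_replicates(cfg, n_reps = 3, base_seed = 11)
percent_reduction(trt, ctrl, day = 25)
classify_response(percent_reduction(trt, ctrl, day = 25))
```
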