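# fgfr3tme

An R package simulating the bladder tumor microenvironment (TME) as a 3D
on-lattice, hybrid discrete-continuum agent-based model, built for asking how
FGFR3-activating mutations reshape the immune landscape and how anti-PD-1
(ICI) and anti-FGFR3 small-molecule (SMI) therapy should be combined. It is
aimed at computational oncology and systems-biology users who want a seeded,
testable simulator with a virtual-trial harness rather than a one-off script.

## The model in brief

Tumor cells differ along two heritable binary traits, assigned independently
at initialization: antigenicity (HA/LA) and FGFR3 mutation (Mut/WT). Mutant
cells dimerize FGFR3 ligand-independently; the active-dimer fractional
occupancy φ_D (from region-averaged mass-action kinetics) sets their fitness:

- proliferation rate: α_T + α_F · φ_D
- apoptosis rate: δ_T · (1 − ε_F · min(φ_D, 1))
- CTL recruitment is suppressed by 1 − s_max · mean(φ_D over mutant cells)

CD8+ T cells are recruited at the boundary vasculature in proportion to tumor
size, chemotax up a tumor-secreted immune stimulatory factor (ISF) gradient,
and kill by two lytic pathways: perforin/granzyme clears an HA target in
30 min; Fas/FasL needs 2 h for an LA target. Exhaustion is driven by the
PD-1–PD-L1 complex C through a Hill rate ρ_max · C^h / (C50^h + C^h), with C
at quasi-equilibrium, the root of (P − C)(L − C) = Kd·C. Each drug has a
two-compartment PK model (exact matrix-exponential advance) feeding boundary
regions of the lattice; five therapy arms (control, ICI, aFGFR3, and the two
staggered combinations) follow configurable dosing windows.

Events are competing exponentials per cell per step (tumor step 15 min,
immune step 7.5 min); identical configuration + seed reproduces bit-identical
trajectories.

## A worked example

```r
library(fgfr3tme)

cfg <- tme_config(
  lattice = list(dims = c(16L, 16L, 16L), regions_per_axis = 4L),
  init = list(n_tumor = 30L, frac_mutant = 0.5, frac_ha = 0.5),
  measure = list(log_every_steps = 16L)
)
ctrl <- run_replicates(cfg, n_reps = 3, base_seed = 11)
cfg$therapy$arm <- "aFGFR3"
trt <- run_replicates(cfg, n_reps = 3, base_seed = 11)

burden_at_day(ctrl, 25)                 # 3684.333
burden_at_day(trt, 25)                  # 2278.667
percent_reduction(trt, ctrl, day = 25)  # 38.15254
classify_response(38.15)                # effective
```

Here a mixed-composition tumor (half FGFR3-mutant, half high-antigen) grows
to ~3700 cells by Day 25 untreated; a daily anti-FGFR3 window on days 14–21
drives the mutant dimer occupancy from ~0.93 to ~0.02 within two days of the
first dose and cuts the Day-25 burden by more than a third — an "effective" (30–90%
reduction) response in the three-bin classification. A purely high-antigen,
wild-type tumor regresses with no treatment at all, cleared by the recruited
CTL response.

The therapy-landscape harness sweeps the two FGFR3 fitness parameters over a
50-point grid, classifies each arm's Day-25 reduction, and reports the
minimal therapy achieving the best response per grid point:

```r
# full study harness: grid = sweep_grid() (50 points) x 5 arms x n_reps;
# a 2-point grid over two arms runs in minutes on a laptop-scale lattice
grid <- data.frame(alpha_F = c(0, 1.5), eps_F = c(0, 0.9))
land <- run_fitness_sweep(cfg, grid, arms = c("ICI", "aFGFR3"),
                          n_reps = 1, base_seed = 1)
land[, c("prolif_per_day", "t_apop_days", "red_ICI", "red_aFGFR3")]
```

A thin command-line wrapper is installed at `inst/cli/fgfr3tme`
(`run`, `sweep`, `analyze`, `fixtures` subcommands) for shell-driven use;
it writes census CSVs, agent snapshots, and a run manifest with the config
hash and seed.

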