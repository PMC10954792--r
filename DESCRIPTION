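Package: fgfr3tme
Title: Agent-Based Simulation of FGFR3-Driven Bladder Tumor-Immune Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Hybrid discrete-continuum, three-dimensional on-lattice
    agent-based model of the bladder tumor microenvironment. Tumor cells are
    heterogeneous in antigenicity and FGFR3 mutation status; FGFR3 signaling
    is resolved through region-averaged monomer-dimer-inhibitor kinetics and
    modulates proliferation, apoptosis, and CD8+ T cell recruitment. CD8+ T
    cells are recruited from a static boundary vasculature, migrate up an
    immune stimulatory factor gradient, kill high-antigen targets via the
    fast perforin/granzyme pathway and low-antigen targets via the slow
    Fas/FasL pathway, and exhaust under PD-1/PD-L1 signaling. Includes
    two-compartment pharmacokinetics and staggered schedules for anti-PD-1
    and anti-FGFR3 therapy, seeded replicate runs, spatial infiltration
    metrics (convex-hull densities, shell-normalized radial profiles), and a
    fitness-landscape sweep with a minimal-therapy response classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
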