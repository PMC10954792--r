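# Shared test scaffolding: compact lattice configurations and an empty-state
# builder for hand-placed agent arrangements.

small_cfg <- function(...) {
  over <- list(...)
  base <- list(
    lattice = list(dims = c(8L, 8L, 8L), regions_per_axis = 2L),
    time = list(t_end_days = 1),
    init = list(n_tumor = 0L),
    measure = list(log_every_steps = 8L)
  )
  validate_config(modifyList(base, over))
}

# Empty TME on a small lattice; agents are added with place_tumor_cell() /
# place_immune_cell().
empty_state <- function(dims = c(8L, 8L, 8L), rpa = 2L, seed = 1L, ...) {
  cfg <- small_cfg(lattice = list(dims = dims, regions_per_axis = rpa), ...)
  initialize_simulation(cfg, seed = seed)
}

# Trial-level config used by the qualitative reproduction suite: the default
# biology on a compact 16^3 domain (problem size documented in the methods
# vignette) with a 30-cell seed so therapy starts well before carrying
# capacity.
qual_cfg <- function(arm, frac_mutant = 0.5, frac_ha = 0.5, n_tumor = 30L) {
  validate_config(list(
    lattice = list(dims = c(16L, 16L, 16L), regions_per_axis = 4L),
    time = list(t_end_days = 25),
    init = list(n_tumor = n_tumor, frac_mutant = frac_mutant, frac_ha = frac_ha),
    measure = list(log_every_steps = 16L),
    therapy = list(arm = arm)
  ))
}

# Lazily computed, cached replicate bundles shared across acceptance blocks.
.qual_cache <- new.env(parent = emptyenv())

qual_runs <- function(name) {
  if (!is.null(.qual_cache[[name]])) return(.qual_cache[[name]])
  res <- switch(name,
    hawt_control = run_replicates(
      qual_cfg("control", frac_mutant = 0, frac_ha = 1, n_tumor = 100L),
      n_reps = 3, base_seed = 101L),
    mixed_control = run_replicates(qual_cfg("control"), n_reps = 3,
                                   base_seed = 201L),
    mixed_afgfr3 = run_replicates(qual_cfg("aFGFR3"), n_reps = 3,
                                  base_seed = 201L),
    mixed_ici = run_replicates(qual_cfg("ICI"), n_reps = 3,
                               base_seed = 201L),
    stop("unknown bundle: ", name))
  .qual_cache[[name]] <- res
  res
}

# Mean subtype-fraction trajectory across replicates (columns of the
# composition matrix divided by burden; extinct time points dropped).
mean_fraction <- function(trials, cols) {
  mats <- lapply(trials, function(tr) {
    ok <- tr$burden > 0
    rowSums(tr$composition[ok, cols, drop = FALSE]) / tr$burden[ok]
  })
  n <- min(lengths(mats))
  rowMeans(do.call(cbind, lapply(mats, function(v) v[seq_len(n)])))
}
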