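# Scheduler: competing-event sampling, the per-iteration phase order, full
# runs and seeded replicates.

#' Sample one event from a competing-risk menu
#'
#' With total rate `R = sum(rates)` over an interval `dt`, no event occurs
#' with probability `exp(-R dt)`; otherwise event `i` is chosen with
#' probability proportional to its rate. This is the exact law for competing
#' exponential clocks with rates held constant within the step.
#'
#' @param rates named nonnegative rate vector (min^-1).
#' @param dt interval (min), > 0.
#' @return the chosen event's name, or `"none"`.
#' @export
sample_event <- function(rates, dt) {
  stopifnot(dt > 0)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("event rates must be finite and nonnegative")
  R <- sum(rates)
  if (R == 0) return("none")
  if (runif(1) >= -expm1(-R * dt)) return("none")
  lab <- names(rates) %||% as.character(seq_along(rates))
  lab[sample.int(length(rates), 1L, prob = rates)]
}

# Vectorized competing-risk sampling over a rate matrix (rows = agents,
# columns = events). Returns 0 for "none" or the winning column index.
#' @keywords internal
sample_events <- function(rates, dt) {
  n <- nrow(rates)
  if (n == 0L) return(integer(0))
  R <- rowSums(rates)
  out <- integer(n)
  u <- runif(n)
  idx <- which(R > 0 & u < -expm1(-R * dt))
  if (length(idx)) {
    u2 <- runif(length(idx)) * R[idx]
    acc <- numeric(length(idx))
    res <- integer(length(idx))
    for (k in seq_len(ncol(rates))) {
      nxt <- acc + rates[idx, k]
      hit <- res == 0L & u2 < nxt
      res[hit] <- k
      acc <- nxt
    }
    res[res == 0L] <- ncol(rates)   # guard against rounding at the top end
    out[idx] <- res
  }
  out
}

#' Advance the simulation by one tumor step
#'
#' Executes the iteration in fixed order: (1) FGFR3 state variables are
#' updated (SMI PK, receptor/inhibitor kinetics); (2) tumor events for every
#' tumor cell in randomized order; (3) PD-1/PD-L1 state variables are
#' updated (antibody PK, binding, quasi-equilibrium complex); (4) immune
#' recruitment, then immune events repeated `dt_tumor / dt_immune` times;
#' (5) apoptotic tumor cells are removed from the lattice; (6) scheduled
#' doses are administered into the matching PK central compartment. The
#' clock advances by `dt_tumor`. Call [enable_trace()] first to record the
#' phase order in `state$trace`.
#'
#' @param state simulation state.
#' @return the state, invisibly (modified in place).
#' @export
step_iteration <- function(state) {
  cfg <- state$cfg
  dtT <- cfg$time$dt_tumor_min
  dtI <- cfg$time$dt_immune_min
  n_tumor_start <- state$tum$n
  trace_phase(state, "fgfr3_update")
  fgfr3_phase(state, dtT)
  trace_phase(state, "tumor_events")
  tumor_phase(state, dtT)
  trace_phase(state, "checkpoint_update")
  checkpoint_phase(state, dtT)
  trace_phase(state, "immune_recruitment")
  recruit_immune_cells(state, n_tumor = n_tumor_start)
  nsub <- as.integer(round(dtT / dtI))
  for (s in seq_len(nsub)) {
    trace_phase(state, "immune_events")
    immune_substep(state, dtI)
  }
  trace_phase(state, "remove_apoptotic")
  compact_agents(state)
  trace_phase(state, "dosing")
  apply_doses(state, dtT)
  state$clock <- state$clock + dtT
  invisible(state)
}

# Census row: tumor counts by (antigenicity x mutation) subtype and CTL
# counts by behavioral state.
#' @keywords internal
census <- function(state) {
  tu <- state$tum; im <- state$imm
  i <- seq_len(tu$n)
  i <- i[!tu$apop[i]]
  ha <- tu$ha[i]; mu <- tu$mut[i]
  j <- seq_len(im$n)
  stv <- im$st[j]
  c(LA_WT = sum(!ha & !mu), LA_Mut = sum(!ha & mu),
    HA_WT = sum(ha & !mu), HA_Mut = sum(ha & mu),
    ctl_active = sum(stv == IMM_ACTIVE), ctl_engaged = sum(stv == IMM_ENGAGED),
    ctl_exhausted = sum(stv == IMM_EXHAUSTED))
}

#' Run one full simulation
#'
#' Initializes the TME from `config` (therapy arm included) and iterates to
#' the configured horizon, recording a census time series and agent
#' snapshots at the configured measurement days.
#'
#' @param config configuration list (raw overrides accepted).
#' @param seed integer seed; identical `(config, seed)` pairs reproduce
#'   bit-identical trajectories.
#' @return a `tme_trial` object: list with `times` (days), `burden` (live
#'   tumor count), `composition` (matrix, LA_WT/LA_Mut/HA_WT/HA_Mut),
#'   `ctl` (matrix, active/engaged/exhausted), `snapshots` (named list of
#'   agent tables), `arm`, `seed`, `config`.
#' @export
run_simulation <- function(config = default_config(), seed = 1L) {
  state <- initialize_simulation(config, seed = seed)
  cfg <- state$cfg
  dtT <- cfg$time$dt_tumor_min
  nsteps <- ceiling(cfg$time$t_end_days * MIN_PER_DAY / dtT)
  every <- max(1L, as.integer(cfg$measure$log_every_steps))
  nrow_log <- 1L + nsteps %/% every
  times <- numeric(nrow_log)
  counts <- matrix(0L, nrow_log, 7,
                   dimnames = list(NULL, names(census(state))))
  times[1] <- 0
  counts[1, ] <- census(state)
  snap_days <- sort(unique(cfg$measure$snapshot_days))
  snapshots <- list()
  r <- 1L
  for (s in seq_len(nsteps)) {
    step_iteration(state)
    if (s %% every == 0L) {
      r <- r + 1L
      times[r] <- state$clock / MIN_PER_DAY
      counts[r, ] <- census(state)
    }
    while (length(snap_days) && state$clock >= snap_days[1] * MIN_PER_DAY) {
      snapshots[[paste0("day", snap_days[1])]] <- snapshot_agents(state)
      snap_days <- snap_days[-1]
    }
  }
  keep <- seq_len(r)
  structure(list(times = times[keep],
                 burden = unname(rowSums(counts[keep, 1:4, drop = FALSE])),
                 composition = counts[keep, 1:4, drop = FALSE],
                 ctl = counts[keep, 5:7, drop = FALSE],
                 snapshots = snapshots,
                 arm = cfg$therapy$arm, seed = seed, config = cfg),
            class = "tme_trial")
}

#' Run seeded replicate simulations
#'
#' Runs `n_reps` independent simulations with seeds
#' `base_seed, ..., base_seed + n_reps - 1` (stochasticity is assessed over
#' ten replicates per parameter set by default).
#'
#' @param config configuration list.
#' @param n_reps number of replicates (default `config$run$n_reps`).
#' @param base_seed first replicate seed.
#' @return list of `tme_trial` objects.
#' @export
run_replicates <- function(config = default_config(), n_reps = NULL,
                           base_seed = 1L) {
  cfg <- validate_config(config)
  n_reps <- as.integer(n_reps %||% cfg$run$n_reps)
  stopifnot(n_reps >= 1)
  base_seed <- as.integer(base_seed)
  lapply(seq_len(n_reps) - 1L,
         function(k) run_simulation(cfg, seed = base_seed + k))
}

#' @export
print.tme_trial <- function(x, ...) {
  cat("<tme_trial>", x$arm, "arm, seed", x$seed, "\n")
  cat("  ", length(x$times), "time points over", round(max(x$times), 2),
      "days\n")
  cat("  burden:", x$burden[1], "->", tail(x$burden, 1), "\n")
  cat("  snapshots:", paste(names(x$snapshots), collapse = ", "), "\n")
  invisible(x)
}

#' Plot tumor burden of one or more trials
#'
#' @param x `tme_trial` object.
#' @param ... further `tme_trial` objects to overlay.
#' @export
plot.tme_trial <- function(x, ...) {
  extra <- Filter(function(o) inherits(o, "tme_trial"), list(...))
  ylim <- range(0, x$burden, unlist(lapply(extra, `[[`, "burden")))
  plot(x$times, x$burden, type = "l", xlab = "time (days)",
       ylab = "tumor cells", ylim = ylim)
  for (k in seq_along(extra))
    lines(extra[[k]]$times, extra[[k]]$burden, col = k + 1)
  invisible(x)
}

#' Mean tumor burden at a given day
#'
#' @param trials list of `tme_trial` objects (or a single trial).
#' @param day simulated day (nearest sampled time point is used).
#' @return mean burden across trials.
#' @export
burden_at_day <- function(trials, day) {
  if (inherits(trials, "tme_trial")) trials <- list(trials)
  mean(vapply(trials, function(tr) {
    tr$burden[which.min(abs(tr$times - day))]
  }, numeric(1)))
}
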