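# Simulation state: agent registries (preallocated parallel vectors with
# amortized growth), the single-occupancy lattice map, continuum fields,
# region-averaged kinetic state, PK compartments and the dose schedule.
# The state is an environment so engine phases mutate it in place.

IMM_DEAD <- 0L; IMM_ACTIVE <- 1L; IMM_ENGAGED <- 2L; IMM_EXHAUSTED <- 3L

new_tumor_registry <- function(cap = 256L) {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$site <- integer(cap)
  e$ha <- logical(cap)
  e$mut <- logical(cap)
  e$apop <- logical(cap)
  e
}

new_immune_registry <- function(cap = 256L) {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$site <- integer(cap)
  e$st <- integer(cap)        # 0 dead, 1 active, 2 engaged, 3 exhausted
  e$target <- integer(cap)    # tumor slot while engaged, NA otherwise
  e$kill <- numeric(cap)      # min engaged with current target
  e$idle <- numeric(cap)      # min since last conjugation ended / arrival
  e
}

grow_registry <- function(reg, need, fields) {
  cap <- length(reg$site)
  if (reg$n + need <= cap) return(invisible())
  newcap <- max(cap * 2L, reg$n + need)
  for (f in fields) {
    v <- reg[[f]]
    length(v) <- newcap
    reg[[f]] <- v
  }
  invisible()
}

TUM_FIELDS <- c("site", "ha", "mut", "apop")
IMM_FIELDS <- c("site", "st", "target", "kill", "idle")

#' @keywords internal
add_tumor_cells <- function(state, sites, ha, mut) {
  k <- length(sites)
  if (k == 0L) return(invisible(integer(0)))
  if (any(state$occ[sites] != 0L)) stop("site already occupied")
  tu <- state$tum
  grow_registry(tu, k, TUM_FIELDS)
  idx <- tu$n + seq_len(k)
  tu$site[idx] <- sites
  tu$ha[idx] <- ha
  tu$mut[idx] <- mut
  tu$apop[idx] <- FALSE
  tu$n <- tu$n + k
  state$occ[sites] <- idx
  invisible(idx)
}

#' @keywords internal
add_immune_cells <- function(state, sites) {
  k <- length(sites)
  if (k == 0L) return(invisible(integer(0)))
  if (any(state$occ[sites] != 0L)) stop("site already occupied")
  im <- state$imm
  grow_registry(im, k, IMM_FIELDS)
  idx <- im$n + seq_len(k)
  im$site[idx] <- sites
  im$st[idx] <- IMM_ACTIVE
  im$target[idx] <- NA_integer_
  im$kill[idx] <- 0
  im$idle[idx] <- 0
  im$n <- im$n + k
  state$occ[sites] <- -idx
  invisible(idx)
}

#' Place a single tumor cell (state construction helper)
#'
#' Adds one tumor cell at lattice coordinates `(x, y, z)`. Used to build
#' bespoke configurations for tests and metric fixtures; the daughter
#' inherits nothing here -- traits are given explicitly.
#'
#' @param state simulation state from [initialize_simulation()].
#' @param x,y,z 1-based lattice coordinates.
#' @param antigenicity `"HA"` or `"LA"`.
#' @param mutant logical, FGFR3 mutation flag.
#' @return tumor slot index, invisibly.
#' @export
place_tumor_cell <- function(state, x, y, z, antigenicity = "HA", mutant = FALSE) {
  s <- site_index(state$lat$dims, x, y, z)
  add_tumor_cells(state, s, ha = antigenicity == "HA", mut = isTRUE(mutant))
}

#' Place a single CTL (state construction helper)
#'
#' @inheritParams place_tumor_cell
#' @param exhausted logical; place the cell already exhausted.
#' @return immune slot index, invisibly.
#' @export
place_immune_cell <- function(state, x, y, z, exhausted = FALSE) {
  s <- site_index(state$lat$dims, x, y, z)
  i <- add_immune_cells(state, s)
  if (isTRUE(exhausted)) state$imm$st[i] <- IMM_EXHAUSTED
  invisible(i)
}

#' Initialize a simulation state
#'
#' Seeds the TME: `init$n_tumor` tumor cells fill the sites nearest the
#' lattice center (breadth-first by Euclidean distance), each independently
#' assigned high antigenicity with probability `init$frac_ha` and the FGFR3
#' mutation with probability `init$frac_mutant`. No immune cells are present
#' initially; the ISF field, region kinetics and PK compartments start at
#' zero (FGFR3 receptors start fully monomeric at `R_total`).
#'
#' @param config validated configuration (see [validate_config()]); a raw
#'   override list is accepted and validated.
#' @param seed optional integer; if given, seeds the RNG for the whole run.
#' @return simulation state (an environment).
#' @export
initialize_simulation <- function(config = default_config(), seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lat <- make_lattice(cfg$lattice$dims)
  reg <- make_regions(lat, cfg$lattice$regions_per_axis)
  state <- new.env(parent = emptyenv())
  state$cfg <- cfg
  state$lat <- lat
  state$reg <- reg
  state$clock <- 0
  state$occ <- integer(lat$nsite)
  state$tum <- new_tumor_registry(max(256L, 2L * cfg$init$n_tumor))
  state$imm <- new_immune_registry()
  state$isf <- numeric(lat$nsite)
  nreg <- reg$nreg
  state$fg <- list(M = rep(cfg$fgfr3$R_total, nreg), D = numeric(nreg),
                   B = numeric(nreg), I = numeric(nreg),
                   act = logical(nreg))
  state$chk <- list(fb = numeric(nreg), P_free = numeric(nreg),
                    A = numeric(nreg), C = numeric(nreg))
  state$pk <- list(smi = make_pk(cfg$pk$smi), antibody = make_pk(cfg$pk$antibody))
  state$sched <- build_schedule(cfg$therapy$arm, cfg)
  state$dose_ptr <- 1L
  state$trace <- NULL
  # initial tumor seeding: nearest-to-center breadth-first fill
  n0 <- cfg$init$n_tumor
  if (n0 > 0L) {
    ctr <- (lat$dims + 1) / 2
    d2 <- (lat$x - ctr[1])^2 + (lat$y - ctr[2])^2 + (lat$z - ctr[3])^2
    sites <- order(d2)[seq_len(n0)]
    ha <- runif(n0) < cfg$init$frac_ha
    mut <- runif(n0) < cfg$init$frac_mutant
    add_tumor_cells(state, sites, ha, mut)
  }
  refresh_subregions(state)
  state
}

#' Turn on scheduler-phase tracing
#'
#' After calling this, every [step_iteration()] appends the phase labels it
#' executes (in order) to `state$trace`.
#' @param state simulation state.
#' @export
enable_trace <- function(state) {
  state$trace <- character(0)
  invisible(state)
}

#' @keywords internal
trace_phase <- function(state, label) {
  if (!is.null(state$trace)) state$trace <- c(state$trace, label)
  invisible()
}

# Remove apoptotic tumor cells and dead CTLs; reindex slots and the
# occupancy map; remap engagement targets.
#' @keywords internal
compact_agents <- function(state) {
  tu <- state$tum
  n <- tu$n
  map <- NULL
  if (n > 0L) {
    i <- seq_len(n)
    keep <- !tu$apop[i]
    if (!all(keep)) {
      state$occ[tu$site[i][!keep]] <- 0L
      nk <- sum(keep)
      map <- integer(n)
      map[keep] <- seq_len(nk)
      for (f in TUM_FIELDS) tu[[f]][seq_len(nk)] <- tu[[f]][i][keep]
      tu$n <- nk
      if (nk > 0L) state$occ[tu$site[seq_len(nk)]] <- seq_len(nk)
    }
  }
  im <- state$imm
  m <- im$n
  if (m > 0L) {
    j <- seq_len(m)
    keepI <- im$st[j] != IMM_DEAD
    if (!all(keepI)) {
      mk <- sum(keepI)
      for (f in IMM_FIELDS) im[[f]][seq_len(mk)] <- im[[f]][j][keepI]
      im$n <- mk
      if (mk > 0L) state$occ[im$site[seq_len(mk)]] <- -seq_len(mk)
    }
    if (!is.null(map) && im$n > 0L) {
      jj <- seq_len(im$n)
      eng <- which(im$st[jj] == IMM_ENGAGED)
      if (length(eng)) {
        newt <- map[im$target[eng]]
        if (any(newt == 0L)) stop("internal: CTL engaged to a removed tumor cell")
        im$target[eng] <- newt
      }
    }
  }
  invisible(state)
}

#' Check structural state invariants
#'
#' Verifies single occupancy (no two live agents share a site), agent
#' positions inside the lattice, occupancy-map consistency, and the
#' engagement contract (a CTL has a target iff it is engaged, and the target
#' is a live tumor cell). Errors on the first violation.
#'
#' @param state simulation state.
#' @return `TRUE` invisibly.
#' @export
validate_state <- function(state) {
  tu <- state$tum; im <- state$imm
  ti <- seq_len(tu$n); ji <- seq_len(im$n)
  live_imm <- ji[im$st[ji] != IMM_DEAD]
  sites <- c(tu$site[ti], im$site[live_imm])
  if (anyDuplicated(sites)) stop("occupancy violation: two agents share a site")
  if (length(sites) && (any(sites < 1L) || any(sites > state$lat$nsite)))
    stop("agent position outside lattice")
  occ_ref <- integer(state$lat$nsite)
  occ_ref[tu$site[ti]] <- ti
  occ_ref[im$site[live_imm]] <- -live_imm
  if (!identical(occ_ref, state$occ)) stop("occupancy map out of sync")
  eng <- ji[im$st[ji] == IMM_ENGAGED]
  if (any(is.na(im$target[eng]))) stop("engaged CTL without target")
  non_eng <- live_imm[im$st[live_imm] != IMM_ENGAGED]
  if (any(!is.na(im$target[non_eng]))) stop("unengaged CTL holds a target")
  if (length(eng)) {
    tg <- im$target[eng]
    if (any(tg < 1L | tg > tu$n)) stop("engagement target out of range")
  }
  invisible(TRUE)
}

#' Agent snapshot table
#'
#' One row per live agent: `id`, `type` (`"tumor"`/`"ctl"`), lattice
#' coordinates, `antigenicity` (`"HA"`/`"LA"`, `NA` for CTLs), `mutation`
#' (`"Mut"`/`"WT"`, `NA` for CTLs) and `state` (`"alive"` for tumor;
#' `"active"`, `"engaged"` or `"exhausted"` for CTLs). This is the on-disk
#' snapshot format written by the CLI and consumed by the spatial metrics.
#'
#' @param state simulation state.
#' @return data.frame of agents.
#' @export
snapshot_agents <- function(state) {
  lat <- state$lat
  tu <- state$tum; im <- state$imm
  ti <- seq_len(tu$n)
  ji <- which(im$st[seq_len(im$n)] != IMM_DEAD)
  st_lab <- c("active", "engaged", "exhausted")
  ts <- tu$site[ti]; is_ <- im$site[ji]
  data.frame(
    id = c(ti, if (length(ji)) ji + tu$n else integer(0)),
    type = c(rep("tumor", length(ti)), rep("ctl", length(ji))),
    x = c(lat$x[ts], lat$x[is_]),
    y = c(lat$y[ts], lat$y[is_]),
    z = c(lat$z[ts], lat$z[is_]),
    antigenicity = c(ifelse(tu$ha[ti], "HA", "LA"), rep(NA_character_, length(ji))),
    mutation = c(ifelse(tu$mut[ti], "Mut", "WT"), rep(NA_character_, length(ji))),
    state = c(rep("alive", length(ti)), st_lab[im$st[ji]]),
    stringsAsFactors = FALSE
  )
}
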