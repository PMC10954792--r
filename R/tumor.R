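# Tumor cell events: FGFR3-modulated proliferation and apoptosis,
# density-dependent division with heritable traits, and ISF secretion.

#' FGFR3-modulated proliferation rate
#'
#' The tumor proliferation rate is the base rate `alpha_T` plus an increment
#' directly proportional to the active-dimer fractional occupancy `phi_D`:
#' `alpha_T + alpha_F * phi_D` (per day). Wild-type cells have `phi_D = 0`
#' and proliferate at exactly `alpha_T`.
#'
#' @param phi_D dimensionless fractional occupancy (>= 0), vectorized.
#' @param params tumor parameter list (uses `alpha_T_per_day`,
#'   `alpha_F_per_day`); defaults to the package defaults.
#' @return rate(s) in per day.
#' @export
proliferation_rate <- function(phi_D, params = default_config()$tumor) {
  if (any(phi_D < 0)) stop("phi_D must be nonnegative")
  params$alpha_T_per_day + params$alpha_F_per_day * phi_D
}

#' FGFR3-modulated apoptosis rate
#'
#' FGFR3 signaling protects tumor cells from apoptosis: the base rate
#' `delta_T` is reduced by the factor `1 - eps_F * min(phi_D, 1)`. The rate
#' is strictly decreasing in `phi_D` for `eps_F > 0` and never negative
#' (`eps_F < 1`).
#'
#' @inheritParams proliferation_rate
#' @param params tumor parameter list (uses `delta_T_per_day`, `eps_F`).
#' @return rate(s) in per day.
#' @export
apoptosis_rate <- function(phi_D, params = default_config()$tumor) {
  if (any(phi_D < 0)) stop("phi_D must be nonnegative")
  params$delta_T_per_day * (1 - params$eps_F * pmin(phi_D, 1))
}

#' Attempt a tumor cell division
#'
#' Division is density-dependent: it succeeds only if the number of occupied
#' Moore neighbors is at most `crowd_threshold` and at least one Moore
#' neighbor site is empty. The daughter is placed on a uniformly chosen empty
#' neighbor and inherits the parent's antigenicity and mutation status
#' exactly (no mutation process).
#'
#' @param state simulation state.
#' @param i tumor slot index of the (non-apoptotic) parent.
#' @return `"divided"` or `"blocked"`.
#' @export
attempt_division <- function(state, i) {
  tu <- state$tum
  if (tu$apop[i]) stop("apoptotic cells cannot divide")
  nbs <- state$lat$nb[tu$site[i], ]
  nbs <- nbs[!is.na(nbs)]
  occv <- state$occ[nbs]
  n_occ <- sum(occv != 0L)
  if (n_occ > state$cfg$tumor$crowd_threshold) return("blocked")
  empty <- nbs[occv == 0L]
  if (!length(empty)) return("blocked")
  dest <- empty[sample.int(length(empty), 1L)]
  add_tumor_cells(state, dest, ha = tu$ha[i], mut = tu$mut[i])
  "divided"
}

#' Deposit ISF from live tumor cells
#'
#' Each non-apoptotic tumor cell deposits `sigma * dt` of immune stimulatory
#' factor at its own lattice site, with `sigma = sigma_HA` for high-antigen
#' and `sigma_LA` for low-antigen cells (HA > LA). Apoptotic cells stop
#' secreting immediately. The spatial spread of the deposit is handled by
#' field diffusion in [update_isf()].
#'
#' @param state simulation state.
#' @param dt deposition interval (min).
#' @return total mass deposited, invisibly.
#' @export
secrete_isf <- function(state, dt) {
  stopifnot(dt >= 0)
  tu <- state$tum
  i <- seq_len(tu$n)
  i <- i[!tu$apop[i]]
  if (!length(i) || dt == 0) return(invisible(0))
  p <- state$cfg$tumor
  sig <- ifelse(tu$ha[i], p$sigma_HA, p$sigma_LA)
  state$isf[tu$site[i]] <- state$isf[tu$site[i]] + sig * dt
  invisible(sum(sig) * dt)
}

# Per-cell active-dimer fractional occupancy (vector over tumor slots).
# Mutant cells read the dimer concentration of their region's mutant
# subregion, normalized per cfg$fgfr3$phi_normalization; WT cells are 0.
#' @keywords internal
phi_of_cells <- function(state) {
  tu <- state$tum
  n <- tu$n
  phi <- numeric(n)
  if (n == 0L) return(phi)
  i <- seq_len(n)
  mu <- which(tu$mut[i])
  if (length(mu)) {
    p <- state$cfg$fgfr3
    rnorm_ <- if (p$phi_normalization == "half") p$R_total / 2 else p$R_total
    rid <- state$reg$id[tu$site[mu]]
    phi[mu] <- state$fg$D[rid] / rnorm_
  }
  phi
}

#' Active-dimer fractional occupancy of tumor cells
#'
#' Returns `phi_D` for the requested tumor cells: the active FGFR3 dimer
#' concentration of the cell's region (mutant subregion), normalized by the
#' mutant-cell average total FGFR3 (`R_total/2` under the default `"half"`
#' normalization, so full dimerization gives 1; `R_total` under `"total"`,
#' which caps at 0.5 by receptor conservation). WT cells always have 0.
#'
#' @param state simulation state.
#' @param cells tumor slot indices (default: all live cells).
#' @return numeric vector of occupancies.
#' @export
phi_D <- function(state, cells = NULL) {
  phi <- phi_of_cells(state)
  if (is.null(cells)) phi else phi[cells]
}

# One tumor phase: sample a competing-risk event (proliferate vs apoptose)
# for every tumor cell, mark apoptotic cells (releasing any engaged CTLs),
# then execute divisions sequentially in randomized order.
#' @keywords internal
tumor_phase <- function(state, dt) {
  tu <- state$tum
  n <- tu$n
  if (n > 0L) {
    i <- seq_len(n)
    phi <- phi_of_cells(state)
    p <- state$cfg$tumor
    pr <- per_day_to_per_min(proliferation_rate(phi, p))
    ap <- per_day_to_per_min(apoptosis_rate(phi, p))
    ev <- sample_events(cbind(pr, ap), dt)
    died <- i[ev == 2L]
    if (length(died)) {
      tu$apop[died] <- TRUE
      release_ctls_on(state, died)
    }
    div <- i[ev == 1L]
    if (length(div)) {
      div <- div[sample.int(length(div))]
      for (j in div) attempt_division(state, j)
    }
  }
  secrete_isf(state, dt)
  cfgI <- state$cfg$isf
  f <- array(state$isf, dim = state$lat$dims)
  f <- update_isf(f, D = cfgI$diffusion_site2_per_min,
                  decay = cfgI$decay_per_min, dt = dt)
  state$isf <- as.vector(f)
  invisible(state)
}

# Conjugation ends when the tumor cell becomes apoptotic: CTLs engaged with
# any of the given tumor slots return to the active state.
#' @keywords internal
release_ctls_on <- function(state, tumor_slots) {
  im <- state$imm
  m <- im$n
  if (m == 0L) return(invisible())
  j <- seq_len(m)
  hit <- j[im$st[j] == IMM_ENGAGED & im$target[j] %in% tumor_slots]
  if (length(hit)) {
    im$st[hit] <- IMM_ACTIVE
    im$target[hit] <- NA_integer_
    im$kill[hit] <- 0
    im$idle[hit] <- 0
  }
  invisible()
}
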