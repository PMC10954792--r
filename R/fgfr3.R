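# Region-averaged ("global method") FGFR3 kinetics: mass-action
# monomer-dimer-inhibitor reactions per mutant subregion, inter-region
# inhibitor diffusion on the region graph, vascular influx from the SMI PK
# model, per-cell fractional occupancy, and the equilibrium fitness summaries
# used as sweep axes.

#' Subregion volumes of every kinetics region
#'
#' Each region of the uniform partition is split into three subregions by
#' occupant type: mutant-occupied (FGFR3-mutant tumor cells), non-mutant
#' occupied (wild-type tumor cells) and tumor-free (everything else,
#' including CTL-occupied sites). Volumes are site counts and sum to the
#' region volume.
#'
#' @param state simulation state.
#' @return data.frame with columns `region`, `vol_mut`, `vol_wt`, `vol_free`.
#' @export
classify_subregions <- function(state) {
  tu <- state$tum
  nreg <- state$reg$nreg
  i <- seq_len(tu$n)
  rid <- state$reg$id[tu$site[i]]
  vol_mut <- tabulate(rid[tu$mut[i]], nreg)
  vol_wt <- tabulate(rid[!tu$mut[i]], nreg)
  data.frame(region = seq_len(nreg), vol_mut = vol_mut, vol_wt = vol_wt,
             vol_free = state$reg$vol - vol_mut - vol_wt)
}

# Recompute subregion volumes and (de)activate mutant subregions. A region
# that newly acquires mutant cells inherits the volume-weighted mean
# receptor state of the currently active subregions (cells spilled over from
# a neighboring region carry their receptors); if none exist it starts fully
# monomeric. A region that loses all mutants resets to the fresh state.
#' @keywords internal
refresh_subregions <- function(state) {
  grid <- classify_subregions(state)
  state$subvol <- grid
  fg <- state$fg
  act_new <- grid$vol_mut > 0L
  newly <- act_new & !fg$act
  if (any(newly)) {
    if (any(fg$act)) {
      w <- grid$vol_mut[fg$act]
      w <- if (sum(w) > 0) w else rep(1, sum(fg$act))
      fg$M[newly] <- weighted.mean(fg$M[fg$act], w)
      fg$D[newly] <- weighted.mean(fg$D[fg$act], w)
      fg$B[newly] <- weighted.mean(fg$B[fg$act], w)
    } else {
      fg$M[newly] <- state$cfg$fgfr3$R_total
      fg$D[newly] <- 0
      fg$B[newly] <- 0
    }
  }
  lost <- !act_new & fg$act
  if (any(lost)) {
    fg$M[lost] <- state$cfg$fgfr3$R_total
    fg$D[lost] <- 0
    fg$B[lost] <- 0
  }
  fg$act <- act_new
  state$fg <- fg
  invisible(grid)
}

#' Advance the FGFR3 monomer/dimer/inhibitor system
#'
#' Integrates, per region, the mass-action system
#' \deqn{dM/dt = -2 k_{dim} M^2 + 2 k_{undim} D - k_{on} M I + k_{off} B}
#' \deqn{dD/dt = k_{dim} M^2 - k_{undim} D}
#' \deqn{dI/dt = k_{diff} \nabla^2 I + influx - f_{mut}(k_{on} M I - k_{off} B)}
#' with `B` the inhibitor-bound monomer. Receptor species live on the mutant
#' subregion (per-cell-average concentrations, conserving
#' `M + 2D + B = R_total`); the free inhibitor `I` lives on the region and
#' diffuses on the region graph (reflecting boundaries), with net binding
#' scaled by the mutant volume fraction `f_mut`. Regions without mutant
#' cells (`act = FALSE`) have frozen receptor state and no binding sink.
#' Uses a stiff-safe integrator (`deSolve::lsoda`) at tight tolerance;
#' integration failure raises an error carrying the offending state.
#'
#' @param fstate list with numeric vectors `M`, `D`, `B`, `I` (equal length,
#'   one entry per region) and optionally `act` (logical; default all TRUE).
#' @param params FGFR3 parameter list (see `default_config()$fgfr3`).
#' @param dt integration interval (min), > 0.
#' @param fmut mutant volume fraction per region (recycled; default 1).
#' @param influx inhibitor source per region (conc/min; recycled, default 0).
#' @param region_nb optional region adjacency matrix (rows = regions,
#'   columns = up-to-6 neighbor ids, `NA` for missing) for diffusion; `NULL`
#'   disables inter-region diffusion.
#' @return updated `fstate` (same shape).
#' @export
advance_fgfr3 <- function(fstate, params, dt, fmut = 1, influx = 0,
                          region_nb = NULL) {
  stopifnot(dt > 0)
  nreg <- length(fstate$M)
  act <- fstate$act %||% rep(TRUE, nreg)
  fmut <- rep_len(fmut, nreg)
  influx <- rep_len(influx, nreg)
  if (!any(act) && all(fstate$I == 0) && all(influx == 0)) return(fstate)
  a <- as.numeric(act)
  y0 <- c(fstate$M, fstate$D, fstate$B, fstate$I)
  iM <- seq_len(nreg); iD <- iM + nreg; iB <- iD + nreg; iI <- iB + nreg
  deriv <- function(t, y, parms) {
    M <- y[iM]; D2 <- y[iD]; B <- y[iB]; I <- y[iI]
    dim_on <- params$k_dim_per_min * M^2
    dim_off <- params$k_undim_per_min * D2
    bind <- params$k_on_I_per_min * M * I
    unb <- params$k_off_I_per_min * B
    dM <- a * (-2 * dim_on + 2 * dim_off - bind + unb)
    dD <- a * (dim_on - dim_off)
    dB <- a * (bind - unb)
    dI <- influx - fmut * a * (bind - unb)
    if (!is.null(region_nb))
      dI <- dI + params$drug_diff_per_min * region_laplacian(I, region_nb)
    list(c(dM, dD, dB, dI))
  }
  sol <- try(deSolve::lsoda(y0, times = c(0, dt), func = deriv, parms = NULL,
                            rtol = 1e-10, atol = 1e-12), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < 2)
    stop("FGFR3 kinetics integration failed; state: ",
         paste(signif(y0, 4), collapse = ","))
  y <- unname(sol[nrow(sol), -1])
  y[y < 0 & y > -1e-12] <- 0
  fstate$M <- y[iM]; fstate$D <- y[iD]; fstate$B <- y[iB]; fstate$I <- y[iI]
  fstate$act <- act
  fstate
}

#' FGFR3-mediated recruitment suppression factor
#'
#' `1 - s_max * mean(phi_D over mutant tumor cells)` (cell-weighted mean);
#' exactly 1 when no mutant cells are present or when the pathway is fully
#' inhibited (`phi_D = 0` everywhere).
#'
#' @param state simulation state.
#' @return factor in `[1 - s_max, 1]`.
#' @export
recruitment_suppression <- function(state) {
  tu <- state$tum
  i <- seq_len(tu$n)
  mu <- i[tu$mut[i]]
  if (!length(mu)) return(1)
  phi <- phi_of_cells(state)[mu]
  1 - state$cfg$immune$s_max * min(mean(phi), 1)
}

#' Drug-free equilibrium fitness of FGFR3-mutant cells
#'
#' Solves the dimerization equilibrium analytically
#' (`k_dim M^2 = k_undim D` with `M + 2D = R_total`, a quadratic in `M`),
#' converts the equilibrium occupancy `phi_D*` to the two fitness summaries
#' used as sweep axes: the proliferation rate
#' `alpha_T + alpha_F * phi_D*` (per day) and the expected time to
#' apoptosis `1 / (delta_T * (1 - eps_F * phi_D*))` (days; `Inf` when the
#' protected rate vanishes).
#'
#' @param alpha_F,eps_F FGFR3 effect parameters (vectorized, recycled).
#' @param config full configuration supplying `tumor` base rates and
#'   `fgfr3` kinetic constants.
#' @return data.frame with columns `alpha_F`, `eps_F`, `phi_eq`,
#'   `prolif_per_day`, `t_apop_days`.
#' @export
equilibrium_fitness <- function(alpha_F, eps_F, config = default_config()) {
  cfg <- validate_config(config)
  n <- max(length(alpha_F), length(eps_F))
  alpha_F <- rep_len(alpha_F, n); eps_F <- rep_len(eps_F, n)
  p <- cfg$fgfr3
  kd <- p$k_dim_per_min; ku <- p$k_undim_per_min; R <- p$R_total
  if (kd == 0) {
    Ds <- 0
  } else {
    Ms <- (-ku + sqrt(ku^2 + 8 * kd * ku * R)) / (4 * kd)
    Ds <- (R - Ms) / 2
  }
  rnorm_ <- if (p$phi_normalization == "half") R / 2 else R
  phi <- Ds / rnorm_
  tu <- cfg$tumor
  prolif <- tu$alpha_T_per_day + alpha_F * phi
  denom <- tu$delta_T_per_day * (1 - eps_F * pmin(phi, 1))
  t_apop <- ifelse(denom <= 0, Inf, 1 / denom)
  data.frame(alpha_F = alpha_F, eps_F = eps_F, phi_eq = phi,
             prolif_per_day = prolif, t_apop_days = t_apop)
}

# One FGFR3 phase of the iteration: re-classify subregions, advance the SMI
# PK model, and integrate receptor/inhibitor kinetics over the tumor step.
# The vascular influx uses the central amount at the start of the step
# (constant over 15 min), spread uniformly over boundary regions.
#' @keywords internal
fgfr3_phase <- function(state, dt) {
  grid <- refresh_subregions(state)
  pk <- state$pk$smi
  influx_amt <- pk$k_tme * pk$central       # amount/min drained to the TME
  state$pk$smi <- advance_pk(pk, dt)
  reg <- state$reg
  nb <- sum(reg$boundary)
  influx <- ifelse(reg$boundary, influx_amt / nb, 0)
  state$fg <- advance_fgfr3(state$fg, state$cfg$fgfr3, dt,
                            fmut = grid$vol_mut / reg$vol,
                            influx = influx, region_nb = reg$nbreg)
  invisible(state)
}
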