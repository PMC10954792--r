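# PD-1/PD-L1/anti-PD-1: region-averaged antibody binding kinetics, a
# quasi-equilibrium PD-1--PD-L1 complex, and the regional complex
# concentrations that drive CTL exhaustion.

#' Quasi-equilibrium PD-1--PD-L1 complex concentration
#'
#' Unique nonnegative root of the equilibrium binding relation with
#' conservation: `C = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / 2`,
#' computed in a numerically stable form. Always `0 <= C <= min(P, L)`.
#'
#' @param P_free free (antibody-unbound) PD-1 concentration(s).
#' @param L_total local PD-L1 concentration(s).
#' @param Kd_PL dissociation constant.
#' @return complex concentration(s).
#' @export
quasi_equilibrium_complex <- function(P_free, L_total, Kd_PL) {
  if (any(P_free < 0) || any(L_total < 0) || any(Kd_PL < 0))
    stop("concentrations and Kd must be nonnegative")
  b <- P_free + L_total + Kd_PL
  disc <- pmax(b^2 - 4 * P_free * L_total, 0)
  C <- 2 * P_free * L_total / (b + sqrt(disc))
  pmin(C, pmin(P_free, L_total))
}

#' Regional PD-L1 concentration
#'
#' PD-L1 is carried by tumor cells, uniformly per cell:
#' `L_total = n_tumor * L_per_cell / region_volume`.
#'
#' @param state simulation state.
#' @return numeric vector, one concentration per region.
#' @export
region_pdl1 <- function(state) {
  tu <- state$tum
  i <- seq_len(tu$n)
  i <- i[!tu$apop[i]]
  nt <- tabulate(state$reg$id[tu$site[i]], state$reg$nreg)
  nt * state$cfg$checkpoint$L_per_cell / state$reg$vol
}

#' Advance anti-PD-1 binding and transport
#'
#' Per region: `dP_free/dt = -k_on P_free A + k_off (P_total - P_free)` and
#' `dA/dt = k_diff Laplacian(A) + influx - (k_on P_free A - k_off PA)`,
#' where `P_total` is fixed over the step by the resident CTL count. The
#' free-PD-1 output feeds [quasi_equilibrium_complex()].
#'
#' @param cstate list with per-region vectors `P_total`, `P_free`, `A`.
#' @param params checkpoint parameter list (see
#'   `default_config()$checkpoint`).
#' @param dt interval (min), > 0.
#' @param influx antibody source per region (conc/min; recycled, default 0).
#' @param region_nb optional region adjacency matrix for diffusion.
#' @return list with `P_total`, `P_free`, `PA`, `A`.
#' @export
advance_anti_pd1 <- function(cstate, params, dt, influx = 0, region_nb = NULL) {
  stopifnot(dt > 0)
  nreg <- length(cstate$P_total)
  influx <- rep_len(influx, nreg)
  Pt <- cstate$P_total
  if (all(cstate$A == 0) && all(influx == 0)) {
    return(list(P_total = Pt, P_free = pmin(cstate$P_free, Pt), PA = Pt - pmin(cstate$P_free, Pt),
                A = cstate$A))
  }
  y0 <- c(cstate$P_free, cstate$A)
  iP <- seq_len(nreg); iA <- iP + nreg
  deriv <- function(t, y, parms) {
    Pf <- y[iP]; A <- y[iA]
    bind <- params$k_on_A_per_min * Pf * A
    unb <- params$k_off_A_per_min * (Pt - Pf)
    dP <- -bind + unb
    dA <- influx - bind + unb
    if (!is.null(region_nb))
      dA <- dA + params$drug_diff_per_min * region_laplacian(A, region_nb)
    list(c(dP, dA))
  }
  sol <- try(deSolve::lsoda(y0, times = c(0, dt), func = deriv, parms = NULL,
                            rtol = 1e-10, atol = 1e-12), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < 2)
    stop("anti-PD-1 kinetics integration failed")
  y <- unname(sol[nrow(sol), -1])
  y[y < 0 & y > -1e-12] <- 0
  Pf <- pmin(y[iP], Pt)
  list(P_total = Pt, P_free = Pf, PA = Pt - Pf, A = y[iA])
}

# One checkpoint phase: rebuild regional PD-1 totals from the resident CTL
# census (all non-dead CTLs express PD-1, exhausted included), advance the
# antibody PK and binding, then set the quasi-equilibrium complex that the
# exhaustion Hill function reads. The antibody-bound fraction per region is
# carried between steps so PD-1 totals can change with CTL traffic.
#' @keywords internal
checkpoint_phase <- function(state, dt) {
  cp <- state$cfg$checkpoint
  reg <- state$reg
  im <- state$imm
  j <- seq_len(im$n)
  j <- j[im$st[j] != IMM_DEAD]
  nctl <- tabulate(reg$id[im$site[j]], reg$nreg)
  Pt <- nctl * cp$P_per_cell / reg$vol
  Pf0 <- (1 - state$chk$fb) * Pt
  pk <- state$pk$antibody
  influx_amt <- pk$k_tme * pk$central
  state$pk$antibody <- advance_pk(pk, dt)
  nb <- sum(reg$boundary)
  influx <- ifelse(reg$boundary, influx_amt / nb, 0)
  res <- advance_anti_pd1(list(P_total = Pt, P_free = Pf0, A = state$chk$A),
                          cp, dt, influx = influx, region_nb = reg$nbreg)
  fb <- ifelse(Pt > 0, 1 - res$P_free / Pt, 0)
  L <- region_pdl1(state)
  state$chk <- list(fb = fb, P_free = res$P_free, A = res$A,
                    C = quasi_equilibrium_complex(res$P_free, L, cp$Kd_PL))
  invisible(state)
}
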