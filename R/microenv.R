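# Microenvironment: explicit diffusion-decay of the ISF scalar field,
# closed-form two-compartment pharmacokinetics, and therapy dose schedules.

#' Diffuse and decay the ISF field
#'
#' Explicit 6-point finite-difference diffusion with reflecting boundaries,
#' sub-cycled to respect the 3D stability bound (`D dt_sub / dx^2 <= 1/6`),
#' followed by exponential decay each sub-step. With reflecting boundaries
#' and no decay, total mass is conserved to machine precision and the
#' variance of a point release grows by `2 D t` per axis.
#'
#' @param field 3D numeric array of concentrations.
#' @param D diffusivity (site^2/min).
#' @param decay first-order decay rate (min^-1).
#' @param dt interval (min), > 0.
#' @param dx site length (default 1 site).
#' @return updated 3D array (never negative).
#' @export
update_isf <- function(field, D, decay, dt, dx = 1) {
  stopifnot(dt > 0, D >= 0, decay >= 0)
  d <- dim(field)
  if (is.null(d) || length(d) != 3) stop("field must be a 3D array")
  if (D == 0 && decay == 0) return(field)
  nsub <- max(1L, ceiling(6 * D * dt / dx^2))
  dts <- dt / nsub
  a <- D * dts / dx^2
  dec <- exp(-decay * dts)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  ixp <- c(2:nx, nx); ixm <- c(1, 1:(nx - 1))
  iyp <- c(2:ny, ny); iym <- c(1, 1:(ny - 1))
  izp <- c(2:nz, nz); izm <- c(1, 1:(nz - 1))
  for (s in seq_len(nsub)) {
    if (a > 0) {
      lap <- field[ixp, , ] + field[ixm, , ] +
        field[, iyp, ] + field[, iym, ] +
        field[, , izp] + field[, , izm] - 6 * field
      field <- field + a * lap
    }
    if (decay > 0) field <- field * dec
  }
  field[field < 0] <- 0
  field
}

# PK state constructor: two-compartment model with first-order elimination
# from the central compartment plus a central -> TME transfer (k_tme) that
# feeds the boundary-region drug pools.
#' @keywords internal
make_pk <- function(p) {
  list(central = 0, peripheral = 0,
       k_el = log(2) / p$half_life_min,
       k12 = p$k12_per_min, k21 = p$k21_per_min,
       k_tme = p$k_tme_per_min)
}

# Exact 2x2 matrix exponential (trace/traceless decomposition).
#' @keywords internal
expm2 <- function(M) {
  tr2 <- (M[1, 1] + M[2, 2]) / 2
  B <- M
  B[1, 1] <- B[1, 1] - tr2
  B[2, 2] <- B[2, 2] - tr2
  q2 <- B[1, 1]^2 + B[1, 2] * B[2, 1]
  if (q2 > 0) {
    q <- sqrt(q2); ch <- cosh(q); sh <- sinh(q) / q
  } else if (q2 < 0) {
    q <- sqrt(-q2); ch <- cos(q); sh <- sin(q) / q
  } else {
    ch <- 1; sh <- 1
  }
  exp(tr2) * (ch * diag(2) + sh * B)
}

#' Advance a two-compartment PK model in closed form
#'
#' Linear central/peripheral kinetics advanced exactly by the matrix
#' exponential: the central compartment loses drug by first-order
#' elimination (`k_el`), transfer to the periphery (`k12`, returned at
#' `k21`) and vascular transfer into the TME (`k_tme`).
#'
#' @param pk PK state list (`central`, `peripheral`, `k_el`, `k12`, `k21`,
#'   `k_tme`), e.g. from a running simulation.
#' @param dt interval (min), > 0.
#' @return updated PK state.
#' @export
advance_pk <- function(pk, dt) {
  stopifnot(dt > 0)
  if (pk$central == 0 && pk$peripheral == 0) return(pk)
  A <- matrix(c(-(pk$k_el + pk$k_tme + pk$k12), pk$k21,
                pk$k12, -pk$k21), 2, 2, byrow = TRUE)
  v <- expm2(A * dt) %*% c(pk$central, pk$peripheral)
  pk$central <- max(v[1], 0)
  pk$peripheral <- max(v[2], 0)
  pk
}

#' Build a dose schedule for a therapy arm
#'
#' Arms: `control` (no doses); `ICI` (anti-PD-1 antibody only) and `aFGFR3`
#' (small molecule inhibitor only), dosed during the monotherapy window
#' (default simulated days 14--21); `FGFR3_first` and `ICI_first`, the two
#' staggered combinations in which the first drug is given in weeks 2--3
#' (days 14--21) and the second in weeks 3--4 (days 21--28). Within a
#' window, the antibody is dosed every `dose_interval_days` (default 3) and
#' the SMI daily.
#'
#' @param arm one of `"control"`, `"ICI"`, `"aFGFR3"`, `"FGFR3_first"`,
#'   `"ICI_first"`.
#' @param config full configuration (therapy windows, dose amounts and
#'   intervals).
#' @return data.frame with columns `time_min`, `drug`
#'   (`"smi"`/`"antibody"`), `amount`, sorted by time.
#' @export
build_schedule <- function(arm, config = default_config()) {
  cfg <- validate_config(config)
  if (!arm %in% THERAPY_ARMS) stop("unknown therapy arm: ", arm)
  th <- cfg$therapy
  window_doses <- function(drug, start_day, end_day) {
    p <- cfg$pk[[drug]]
    if (end_day <= start_day) return(NULL)
    times <- seq(start_day, end_day - 1e-9, by = p$dose_interval_days)
    data.frame(time_min = times * MIN_PER_DAY, drug = drug,
               amount = p$dose_amount, stringsAsFactors = FALSE)
  }
  ev <- switch(arm,
    control = NULL,
    ICI = window_doses("antibody", th$mono_start_day, th$mono_end_day),
    aFGFR3 = window_doses("smi", th$mono_start_day, th$mono_end_day),
    FGFR3_first = rbind(
      window_doses("smi", th$combo_first_start_day, th$combo_switch_day),
      window_doses("antibody", th$combo_switch_day, th$combo_end_day)),
    ICI_first = rbind(
      window_doses("antibody", th$combo_first_start_day, th$combo_switch_day),
      window_doses("smi", th$combo_switch_day, th$combo_end_day))
  )
  if (is.null(ev))
    ev <- data.frame(time_min = numeric(0), drug = character(0),
                     amount = numeric(0), stringsAsFactors = FALSE)
  ev[order(ev$time_min), , drop = FALSE]
}

# Administer every scheduled dose that falls inside the iteration ending at
# clock + dt: bolus into the central compartment of the matching PK model.
#' @keywords internal
apply_doses <- function(state, dt) {
  sc <- state$sched
  while (state$dose_ptr <= nrow(sc) &&
         sc$time_min[state$dose_ptr] <= state$clock + dt) {
    row <- sc[state$dose_ptr, ]
    state$pk[[row$drug]]$central <- state$pk[[row$drug]]$central + row$amount
    state$dose_ptr <- state$dose_ptr + 1L
  }
  invisible(state)
}
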