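# CTL events: vascular recruitment, competing-risk event menus, chemotactic
# migration, conjugation with dual-pathway killing, PD-1-driven exhaustion,
# and activation-induced cell death (AICD).

#' PD-1/PD-L1-driven exhaustion rate
#'
#' Hill function of the local PD-1--PD-L1 complex concentration:
#' `rho_max * C^h / (C50^h + C^h)`. Zero at `C = 0`, half-maximal at
#' `C = C50`, saturating at `rho_max`.
#'
#' @param C_complex complex concentration(s), >= 0.
#' @param params immune parameter list (uses `rho_max_per_day`, `C50`,
#'   `hill_h`).
#' @return exhaustion rate(s), per day.
#' @export
exhaustion_rate <- function(C_complex, params = default_config()$immune) {
  if (any(C_complex < 0)) stop("C_complex must be nonnegative")
  h <- params$hill_h
  params$rho_max_per_day * C_complex^h / (params$C50^h + C_complex^h)
}

#' Recruit CTLs at the boundary vasculature
#'
#' The arrival count is Poisson with mean
#' `r_rec * N_tumor * f_sup`, where `r_rec` is the per-tumor-cell
#' recruitment coefficient (converted to the tumor step) and
#' `f_sup = 1 - s_max * mean(phi_D over mutant cells)` is the
#' FGFR3-mediated suppression factor ([recruitment_suppression()]).
#' Arrivals are placed at uniformly chosen empty perivascular sites; surplus
#' arrivals beyond the available sites are discarded. New CTLs are active
#' with `idle_time = 0`.
#'
#' @param state simulation state.
#' @param n_tumor tumor size driving recruitment (default: current count,
#'   in-engine the count at the start of the iteration).
#' @return number of CTLs placed, invisibly.
#' @export
recruit_immune_cells <- function(state, n_tumor = NULL) {
  cfg <- state$cfg
  n_tumor <- n_tumor %||% state$tum$n
  if (n_tumor == 0L) return(invisible(0L))
  r_step <- cfg$immune$r_rec_per_day * cfg$time$dt_tumor_min / MIN_PER_DAY
  lambda <- r_step * n_tumor * recruitment_suppression(state)
  k <- rpois(1L, lambda)
  if (k == 0L) return(invisible(0L))
  avail <- state$lat$peri[state$occ[state$lat$peri] == 0L]
  k <- min(k, length(avail))
  if (k == 0L) return(invisible(0L))
  sites <- avail[sample.int(length(avail), k)]
  add_immune_cells(state, sites)
  invisible(k)
}

#' Event menu for a CTL
#'
#' Competing-risk rates (per min) for the six immune events, by behavioral
#' state. Active, unengaged cells can proliferate (base rate boosted by
#' local ISF through a saturating multiplier), die, move, conjugate (only if
#' a non-apoptotic tumor neighbor exists), exhaust (Hill in the regional
#' PD-1--PD-L1 complex) or undergo AICD (only once idle longer than
#' `tau_idle`). Engaged cells can only die or exhaust; exhausted cells only
#' die.
#'
#' @param state simulation state.
#' @param i immune slot index.
#' @return named rate vector (min^-1) with entries `proliferation`,
#'   `apoptosis`, `movement`, `conjugation`, `exhaustion`, `aicd`.
#' @export
immune_event_menu <- function(state, i) {
  im <- state$imm
  if (im$st[i] == IMM_DEAD) stop("dead immune cell has no events")
  p <- state$cfg$immune
  r <- c(proliferation = 0, apoptosis = per_day_to_per_min(p$delta_I_per_day),
         movement = 0, conjugation = 0, exhaustion = 0, aicd = 0)
  if (im$st[i] == IMM_EXHAUSTED) return(r)
  Cc <- state$chk$C[state$reg$id[im$site[i]]]
  r["exhaustion"] <- per_day_to_per_min(exhaustion_rate(Cc, p))
  if (im$st[i] == IMM_ENGAGED) return(r)
  cisf <- state$isf[im$site[i]]
  r["proliferation"] <- per_day_to_per_min(
    p$alpha_I_per_day * (1 + p$boost_max * cisf / (p$k_isf + cisf)))
  r["movement"] <- p$m_per_min
  if (length(eligible_tumor_neighbors(state, im$site[i])))
    r["conjugation"] <- p$beta_per_min
  if (im$idle[i] > p$tau_idle_min) r["aicd"] <- per_day_to_per_min(p$d_a_per_day)
  r
}

# Non-apoptotic tumor cells in the Moore neighborhood of a site (tumor slots).
#' @keywords internal
eligible_tumor_neighbors <- function(state, site) {
  nbs <- state$lat$nb[site, ]
  nbs <- nbs[!is.na(nbs)]
  v <- state$occ[nbs]
  tslot <- v[v > 0L]
  tslot[!state$tum$apop[tslot]]
}

#' Chemotactic migration of a CTL
#'
#' Performs `n_move` single-site sub-steps. At each sub-step an empty Moore
#' neighbor is sampled with probability proportional to
#' `exp(lambda * (c_nbr - c_here) / d_nbr)`, where `c` is the local ISF
#' concentration and `d_nbr` the lattice distance to the neighbor (so an
#' axial neighbor is preferred over a body-diagonal one at equal
#' concentration excess). With a uniform field the choice is uniform over
#' empty neighbors. If no empty neighbor exists the cell stays put.
#'
#' @param state simulation state.
#' @param i immune slot index (active, unengaged).
#' @return the new lattice site index, invisibly.
#' @export
migrate <- function(state, i) {
  im <- state$imm
  if (im$st[i] != IMM_ACTIVE) stop("only active, unengaged CTLs migrate")
  p <- state$cfg$immune
  cur <- im$site[i]
  for (s in seq_len(p$n_move)) {
    nbs <- state$lat$nb[cur, ]
    ok <- !is.na(nbs)
    nbs2 <- nbs[ok]
    empty <- state$occ[nbs2] == 0L
    if (!any(empty)) break
    cand <- nbs2[empty]
    dd <- state$lat$nb_dist[ok][empty]
    w <- exp(p$lambda_chemo * (state$isf[cand] - state$isf[cur]) / dd)
    dest <- cand[sample.int(length(cand), 1L, prob = w)]
    state$occ[cur] <- 0L
    state$occ[dest] <- -i
    im$site[i] <- dest
    cur <- dest
  }
  invisible(cur)
}

#' Attempt conjugation with a neighboring tumor cell
#'
#' An active, unengaged CTL picks a uniformly random non-apoptotic tumor
#' cell in its Moore neighborhood and engages it: the CTL becomes `engaged`
#' with `kill_elapsed = 0` and `idle_time = 0`. Fails (no state change) if
#' no eligible neighbor exists. The lytic pathway is decided by the target:
#' perforin/granzyme (30 min) for HA, Fas/FasL (2 h) for LA.
#'
#' @param state simulation state.
#' @param i immune slot index.
#' @return `"engaged"` or `"failed"`.
#' @export
attempt_conjugation <- function(state, i) {
  im <- state$imm
  if (im$st[i] != IMM_ACTIVE) stop("only active, unengaged CTLs conjugate")
  tg <- eligible_tumor_neighbors(state, im$site[i])
  if (!length(tg)) return("failed")
  pick <- tg[sample.int(length(tg), 1L)]
  im$st[i] <- IMM_ENGAGED
  im$target[i] <- pick
  im$kill[i] <- 0
  im$idle[i] <- 0
  "engaged"
}

#' Progress an engagement by one interval
#'
#' Advances the kill clock of an engaged CTL by `dt`. When the elapsed
#' engagement reaches the pathway duration (`T_perforin` for HA targets,
#' `T_fas` for LA), the target is marked apoptotic, and every CTL engaged
#' with it (including this one) returns to the active state with
#' `idle_time = 0`. If the target already became apoptotic the engagement is
#' released without a kill. Engaging a removed target is a contract
#' violation.
#'
#' @param state simulation state.
#' @param i immune slot index (engaged).
#' @param dt elapsed interval (min).
#' @return `"continuing"`, `"target_killed"` or `"released"`.
#' @export
progress_engagement <- function(state, i, dt) {
  im <- state$imm
  tu <- state$tum
  if (im$st[i] != IMM_ENGAGED) stop("CTL is not engaged")
  tg <- im$target[i]
  if (is.na(tg) || tg < 1L || tg > tu$n)
    stop("engagement with a removed tumor cell")
  if (tu$apop[tg]) {
    release_ctls_on(state, tg)
    return("released")
  }
  im$kill[i] <- im$kill[i] + dt
  p <- state$cfg$immune
  dur <- if (tu$ha[tg]) p$T_perforin_min else p$T_fas_min
  if (im$kill[i] >= dur) {
    tu$apop[tg] <- TRUE
    release_ctls_on(state, tg)
    return("target_killed")
  }
  "continuing"
}

# One immune sub-step of duration dt: build the per-cell rate matrix from a
# consistent snapshot of the fields, sample competing-risk events, execute
# them in randomized order, then progress engagements that predate this
# sub-step and advance idle clocks.
#' @keywords internal
immune_substep <- function(state, dt) {
  im <- state$imm
  n <- im$n
  if (n == 0L) return(invisible())
  j <- seq_len(n)
  live <- j[im$st[j] != IMM_DEAD]
  if (!length(live)) return(invisible())
  p <- state$cfg$immune
  stv <- im$st[live]
  engaged_before <- live[stv == IMM_ENGAGED]
  sitev <- im$site[live]
  Cc <- state$chk$C[state$reg$id[sitev]]
  exh <- per_day_to_per_min(exhaustion_rate(Cc, p))
  cisf <- state$isf[sitev]
  prolif <- per_day_to_per_min(
    p$alpha_I_per_day * (1 + p$boost_max * cisf / (p$k_isf + cisf)))
  # tumor-neighbor eligibility, vectorized over live cells
  NB <- state$lat$nb[sitev, , drop = FALSE]
  OV <- matrix(0L, nrow(NB), ncol(NB))
  okn <- !is.na(NB)
  OV[okn] <- state$occ[NB[okn]]
  TN <- OV > 0L
  TN[TN] <- !state$tum$apop[OV[TN]]
  has_tgt <- rowSums(TN) > 0L
  active <- stv == IMM_ACTIVE
  rates <- cbind(
    proliferation = ifelse(active, prolif, 0),
    apoptosis = per_day_to_per_min(p$delta_I_per_day),
    movement = ifelse(active, p$m_per_min, 0),
    conjugation = ifelse(active & has_tgt, p$beta_per_min, 0),
    exhaustion = ifelse(stv == IMM_EXHAUSTED, 0, exh),
    aicd = ifelse(active & im$idle[live] > p$tau_idle_min,
                  per_day_to_per_min(p$d_a_per_day), 0)
  )
  ev <- sample_events(rates, dt)
  todo <- which(ev > 0L)
  if (length(todo)) {
    todo <- todo[sample.int(length(todo))]
    for (k in todo) {
      i <- live[k]
      if (im$st[i] == IMM_DEAD) next
      switch(ev[k],
        { # proliferation: needs room, mirrors the tumor crowding rule
          if (im$st[i] == IMM_ACTIVE) {
            nbs <- state$lat$nb[im$site[i], ]
            nbs <- nbs[!is.na(nbs)]
            occv <- state$occ[nbs]
            if (sum(occv != 0L) <= state$cfg$tumor$crowd_threshold) {
              empty <- nbs[occv == 0L]
              if (length(empty))
                add_immune_cells(state, empty[sample.int(length(empty), 1L)])
            }
          }
        },
        { # apoptosis: if engaged, the target survives
          state$occ[im$site[i]] <- 0L
          im$st[i] <- IMM_DEAD
          im$target[i] <- NA_integer_
        },
        { if (im$st[i] == IMM_ACTIVE) migrate(state, i) },
        { if (im$st[i] == IMM_ACTIVE) attempt_conjugation(state, i) },
        { # exhaustion: irreversible; releases any engagement, target survives
          im$st[i] <- IMM_EXHAUSTED
          im$target[i] <- NA_integer_
          im$kill[i] <- 0
        },
        { # AICD
          state$occ[im$site[i]] <- 0L
          im$st[i] <- IMM_DEAD
          im$target[i] <- NA_integer_
        })
    }
  }
  # kill-clock progression for engagements that predate this sub-step
  still <- engaged_before[im$st[engaged_before] == IMM_ENGAGED]
  for (i in still) {
    if (im$st[i] == IMM_ENGAGED) progress_engagement(state, i, dt)
  }
  # idle clocks advance for active, unengaged cells
  j2 <- seq_len(im$n)
  act2 <- j2[im$st[j2] == IMM_ACTIVE]
  im$idle[act2] <- im$idle[act2] + dt
  invisible()
}
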