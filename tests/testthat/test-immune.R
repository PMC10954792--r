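test_that("exhaustion rate is a Hill function of the complex", {
  p <- list(rho_max_per_day = 2, C50 = 0.2, hill_h = 2)
  expect_equal(exhaustion_rate(0, p), 0)
  expect_equal(exhaustion_rate(0.2, p), 1)               # half-max at C50
  expect_lt(abs(exhaustion_rate(200, p) - 2) / 2, 0.01)  # saturation
  expect_true(all(diff(exhaustion_rate(seq(0, 5, 0.1), p)) >= 0))
  expect_error(exhaustion_rate(-1, p), "nonnegative")
})

test_that("event menus honor the behavioral state", {
  st <- empty_state()
  a <- place_immune_cell(st, 4, 4, 4)
  m <- immune_event_menu(st, a)
  expect_gt(m[["proliferation"]], 0)
  expect_gt(m[["movement"]], 0)
  expect_equal(m[["conjugation"]], 0)        # no tumor neighbor
  expect_equal(m[["aicd"]], 0)               # idle below threshold
  expect_equal(m[["exhaustion"]], 0)         # no complex anywhere
  place_tumor_cell(st, 4, 5, 4)
  m2 <- immune_event_menu(st, a)
  expect_equal(m2[["conjugation"]], st$cfg$immune$beta_per_min)
  # engaged: only death and exhaustion can fire
  expect_equal(attempt_conjugation(st, a), "engaged")
  m3 <- immune_event_menu(st, a)
  expect_equal(unname(m3[c("proliferation", "movement", "conjugation",
                           "aicd")]), rep(0, 4))
  expect_gt(m3[["apoptosis"]], 0)
  # exhausted: apoptosis only
  e <- place_immune_cell(st, 6, 6, 6, exhausted = TRUE)
  m4 <- immune_event_menu(st, e)
  expect_equal(sum(m4 > 0), 1L)
  expect_gt(m4[["apoptosis"]], 0)
  # AICD switches on only past the idle threshold
  st$imm$idle[a] <- st$cfg$immune$tau_idle_min + 1
  st$imm$st[a] <- fgfr3tme:::IMM_ACTIVE
  st$imm$target[a] <- NA_integer_
  m5 <- immune_event_menu(st, a)
  expect_equal(m5[["aicd"]],
               st$cfg$immune$d_a_per_day / 1440)
})

test_that("perforin and Fas kills complete at exactly 30 and 120 minutes", {
  for (anti in c("HA", "LA")) {
    st <- empty_state()
    tg <- place_tumor_cell(st, 4, 5, 4, antigenicity = anti)
    i <- place_immune_cell(st, 4, 4, 4)
    expect_equal(attempt_conjugation(st, i), "engaged")
    dur <- if (anti == "HA") 30 else 120
    n_sub <- dur / 7.5
    for (k in seq_len(n_sub - 1))
      expect_equal(progress_engagement(st, i, 7.5), "continuing")
    expect_equal(progress_engagement(st, i, 7.5), "target_killed")
    expect_true(st$tum$apop[tg])
    expect_equal(st$imm$st[i], fgfr3tme:::IMM_ACTIVE)
    expect_equal(st$imm$idle[i], 0)
  }
})

test_that("engagement ends without a kill if the target dies first", {
  st <- empty_state()
  tg <- place_tumor_cell(st, 4, 5, 4, antigenicity = "LA")
  i <- place_immune_cell(st, 4, 4, 4)
  attempt_conjugation(st, i)
  progress_engagement(st, i, 7.5)
  st$tum$apop[tg] <- TRUE                 # spontaneous apoptosis
  expect_equal(progress_engagement(st, i, 7.5), "released")
  expect_equal(st$imm$st[i], fgfr3tme:::IMM_ACTIVE)
  expect_true(is.na(st$imm$target[i]))
})

test_that("conjugation picks uniformly among eligible neighbors", {
  st <- empty_state()
  t1 <- place_tumor_cell(st, 4, 5, 4)
  t2 <- place_tumor_cell(st, 4, 3, 4)
  ta <- place_tumor_cell(st, 5, 5, 4)
  st$tum$apop[ta] <- TRUE                 # apoptotic: never engaged
  i <- place_immune_cell(st, 4, 4, 4)
  set.seed(21)
  picks <- replicate(2000, {
    st$imm$st[i] <- fgfr3tme:::IMM_ACTIVE
    st$imm$target[i] <- NA_integer_
    attempt_conjugation(st, i)
    st$imm$target[i]
  })
  expect_setequal(unique(picks), c(t1, t2))
  expect_lt(abs(mean(picks == t1) - 0.5), 3 * sqrt(0.25 / 2000))
  # no eligible neighbor: failed
  st2 <- empty_state()
  j <- place_immune_cell(st2, 4, 4, 4)
  expect_equal(attempt_conjugation(st2, j), "failed")
})

test_that("migration is uniform on a flat field and climbs ISF gradients", {
  st <- empty_state(immune = list(n_move = 1L))
  i <- place_immune_cell(st, 4, 4, 4)
  home <- st$imm$site[i]
  set.seed(31)
  dest <- replicate(10000, {
    s <- migrate(st, i)
    st$occ[s] <- 0L
    st$imm$site[i] <- home
    st$occ[home] <- -i
    s
  })
  tab <- table(dest)
  expect_equal(length(tab), 26L)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 1e-4)
  # single higher-ISF neighbor attracts the most traffic
  up <- fgfr3tme:::site_index(c(8, 8, 8), 5, 4, 4)
  st$isf[up] <- 1
  dest2 <- replicate(4000, {
    s <- migrate(st, i)
    st$occ[s] <- 0L
    st$imm$site[i] <- home
    st$occ[home] <- -i
    s
  })
  tab2 <- table(dest2)
  expect_equal(as.integer(names(tab2)[which.max(tab2)]), up)
})

test_that("gradients are distance-discounted: axial beats body-diagonal", {
  st <- empty_state(immune = list(n_move = 1L, lambda_chemo = 1))
  i <- place_immune_cell(st, 4, 4, 4)
  home <- st$imm$site[i]
  nb <- moore_neighbors(c(4, 4, 4), c(8, 8, 8))
  axial <- fgfr3tme:::site_index(c(8, 8, 8), 5, 4, 4)
  diag3 <- fgfr3tme:::site_index(c(8, 8, 8), 5, 5, 5)
  # block every neighbor except one axial and one body-diagonal site
  for (k in seq_len(nrow(nb))) {
    s <- fgfr3tme:::site_index(c(8, 8, 8), nb$x[k], nb$y[k], nb$z[k])
    if (!s %in% c(axial, diag3)) place_tumor_cell(st, nb$x[k], nb$y[k], nb$z[k])
  }
  st$isf[c(axial, diag3)] <- 1
  set.seed(41)
  dest <- replicate(4000, {
    s <- migrate(st, i)
    st$occ[s] <- 0L
    st$imm$site[i] <- home
    st$occ[home] <- -i
    s
  })
  p_ax <- mean(dest == axial)
  ratio_expected <- exp(1) / exp(1 / sqrt(3))   # weight ratio at unit excess
  p_expected <- ratio_expected / (1 + ratio_expected)
  expect_lt(abs(p_ax - p_expected), 3 * sqrt(p_expected * (1 - p_expected) / 4000))
})

test_that("recruitment is Poisson with tumor-size-proportional mean", {
  st <- empty_state(immune = list(r_rec_per_day = 4.8))
  for (x in 3:6) for (y in 3:6) place_tumor_cell(st, x, y, 4)  # 16 WT cells
  expect_equal(recruitment_suppression(st), 1)
  r_step <- 4.8 * 15 / 1440
  lambda <- r_step * 16
  set.seed(51)
  draws <- replicate(2000, {
    k <- recruit_immune_cells(st)
    j <- seq_len(st$imm$n)
    st$occ[st$imm$site[j]] <- 0L
    st$imm$n <- 0L
    k
  })
  expect_lt(abs(mean(draws) - lambda), 3 * sqrt(lambda / 2000))
  # no tumor: no arrivals
  st0 <- empty_state()
  expect_equal(recruit_immune_cells(st0), 0L)
})

test_that("FGFR3 signaling suppresses recruitment by the mean occupancy", {
  st <- empty_state(immune = list(r_rec_per_day = 4.8, s_max = 0.8))
  for (x in 3:6) for (y in 3:6) place_tumor_cell(st, x, y, 4, mutant = TRUE)
  st$fg$D <- rep(0.5, st$reg$nreg)       # fully dimerized: phi = 1 ("half")
  st$fg$act <- rep(TRUE, st$reg$nreg)
  expect_equal(recruitment_suppression(st), 0.2)  # 5-fold reduction
  st$fg$D <- rep(0.25, st$reg$nreg)
  expect_equal(recruitment_suppression(st), 0.6)  # phi 0.5, s_max 0.8
  st$fg$D <- rep(0, st$reg$nreg)
  expect_equal(recruitment_suppression(st), 1)    # fully inhibited
  set.seed(61)
  st$fg$D <- rep(0.5, st$reg$nreg)
  lambda <- 4.8 * 15 / 1440 * 16 * 0.2
  draws <- replicate(3000, {
    k <- recruit_immune_cells(st)
    j <- seq_len(st$imm$n)
    st$occ[st$imm$site[j]] <- 0L
    st$imm$n <- 0L
    k
  })
  expect_lt(abs(mean(draws) - lambda), 3 * sqrt(lambda / 3000))
})

test_that("without conjugation no tumor cell ever dies by CTL action", {
  cfg <- small_cfg(init = list(n_tumor = 25L, frac_ha = 1),
                   tumor = list(delta_T_per_day = 0),
                   immune = list(beta_per_min = 0, r_rec_per_day = 2),
                   time = list(t_end_days = 2))
  tr <- run_simulation(cfg, seed = 6)
  expect_true(all(diff(tr$burden) >= 0))
})

test_that("exhausted CTLs never move, proliferate or conjugate", {
  st <- empty_state(immune = list(r_rec_per_day = 0))
  place_tumor_cell(st, 4, 5, 4)
  e <- place_immune_cell(st, 4, 4, 4, exhausted = TRUE)
  home <- st$imm$site[e]
  set.seed(71)
  for (k in 1:30) step_iteration(st)
  expect_lte(st$imm$n, 1L)   # no proliferation happened
  if (st$imm$n == 1L) {      # still alive: exhausted and exactly where placed
    expect_equal(st$imm$st[e], fgfr3tme:::IMM_EXHAUSTED)
    expect_equal(st$imm$site[e], home)
    expect_error(migrate(st, e), "active")
    expect_error(attempt_conjugation(st, e), "active")
  }
})
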