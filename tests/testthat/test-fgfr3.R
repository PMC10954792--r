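test_that("subregion volumes are exact occupant counts", {
  st <- empty_state()          # 8^3 lattice, 2^3 regions of 64 sites
  expect_true(all(classify_subregions(st)$vol_free == 64))
  # region 1 spans x,y,z in 1..4: put 10 mutant and 30 WT cells there
  k <- 0
  for (x in 1:4) for (y in 1:4) for (z in 1:4) {
    k <- k + 1
    if (k <= 10) place_tumor_cell(st, x, y, z, mutant = TRUE)
    else if (k <= 40) place_tumor_cell(st, x, y, z, mutant = FALSE)
  }
  g <- classify_subregions(st)
  expect_equal(g$vol_mut[1], 10)
  expect_equal(g$vol_wt[1], 30)
  expect_equal(g$vol_free[1], 24)
  expect_true(all(g$vol_mut + g$vol_wt + g$vol_free == 64))
})

test_that("drug-free dimerization reaches the closed-form equilibrium", {
  p <- default_config()$fgfr3
  fs <- list(M = p$R_total, D = 0, B = 0, I = 0)
  out <- advance_fgfr3(fs, p, dt = 2e4)
  # quadratic equilibrium: k_dim M^2 = k_undim D, M + 2D = R_total
  ku <- p$k_undim_per_min; kd <- p$k_dim_per_min; R <- p$R_total
  M_star <- (-ku + sqrt(ku^2 + 8 * kd * ku * R)) / (4 * kd)
  D_star <- (R - M_star) / 2
  expect_lt(abs(out$M - M_star), 1e-6)
  expect_lt(abs(out$D - D_star), 1e-6)
  expect_lt(abs(out$M + 2 * out$D + out$B - R), 1e-8)  # conservation
  # no dimerization: D stays zero
  p0 <- modifyList(p, list(k_dim_per_min = 0))
  out0 <- advance_fgfr3(list(M = 1, D = 0, B = 0, I = 0), p0, dt = 1e3)
  expect_equal(out0$D, 0)
})

test_that("receptor conservation holds through drug exposure", {
  p <- default_config()$fgfr3
  fs <- list(M = rep(1, 8), D = rep(0, 8), B = rep(0, 8),
             I = c(2, 0, 0, 0, 1, 0, 0, 0))
  lat <- make_lattice(c(8L, 8L, 8L))
  reg <- fgfr3tme:::make_regions(lat, 2L)
  for (k in 1:40) {
    fs <- advance_fgfr3(fs, p, dt = 30, fmut = 0.5, region_nb = reg$nbreg)
    expect_true(all(abs(fs$M + 2 * fs$D + fs$B - 1) < 1e-8))
    expect_true(all(c(fs$M, fs$D, fs$B, fs$I) >= 0))
  }
})

test_that("saturating inhibitor suppresses dimers far below drug-free level", {
  p <- default_config()$fgfr3
  drug_free <- advance_fgfr3(list(M = 1, D = 0, B = 0, I = 0), p, dt = 2e4)
  # hold a large inhibitor reservoir via constant influx
  dosed <- advance_fgfr3(list(M = 1, D = 0, B = 0, I = 50), p, dt = 2e4,
                         fmut = 0)
  expect_lt(dosed$D, 0.01 * drug_free$D)
})

test_that("steady-state dimer level is monotone in inhibitor dose", {
  p <- default_config()$fgfr3
  D_at <- vapply(c(0, 0.2, 1, 5, 25), function(I0) {
    advance_fgfr3(list(M = 1, D = 0, B = 0, I = I0), p, dt = 2e4, fmut = 0)$D
  }, numeric(1))
  expect_true(all(diff(D_at) < 0))
})

test_that("region-averaged kinetics equal the per-cell ODE on a homogeneous lattice", {
  # 8^3 lattice fully mutant-occupied: every cell sees identical kinetics, so
  # the region-averaged trajectory must match a single-cell integration.
  p <- default_config()$fgfr3
  lat <- make_lattice(c(8L, 8L, 8L))
  reg <- fgfr3tme:::make_regions(lat, 2L)
  fs <- list(M = rep(1, 8), D = rep(0, 8), B = rep(0, 8), I = rep(0.5, 8))
  out <- advance_fgfr3(fs, p, dt = 500, fmut = 1, region_nb = reg$nbreg)
  one_cell <- deSolve::lsoda(
    c(M = 1, D = 0, B = 0, I = 0.5), times = c(0, 500),
    func = function(t, y, parms) {
      dim_on <- p$k_dim_per_min * y[1]^2
      dim_off <- p$k_undim_per_min * y[2]
      bind <- p$k_on_I_per_min * y[1] * y[4]
      unb <- p$k_off_I_per_min * y[3]
      list(c(-2 * dim_on + 2 * dim_off - bind + unb,
             dim_on - dim_off, bind - unb, -(bind - unb)))
    }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  ref <- one_cell[2, -1]
  expect_true(all(abs(out$M - ref[1]) < 1e-7))
  expect_true(all(abs(out$D - ref[2]) < 1e-7))
  expect_true(all(abs(out$B - ref[3]) < 1e-7))
  expect_true(all(abs(out$I - ref[4]) < 1e-7))
})

test_that("phi_D is zero for WT cells and reads the regional dimer level", {
  st <- empty_state()
  w <- place_tumor_cell(st, 2, 2, 2, mutant = FALSE)
  m <- place_tumor_cell(st, 6, 6, 6, mutant = TRUE)
  fgfr3tme:::refresh_subregions(st)
  st$fg$D <- rep(0.5, st$reg$nreg)
  phi <- phi_D(st)
  expect_equal(phi[w], 0)
  expect_equal(phi[m], 1)        # "half" normalization: D = R/2 -> phi = 1
  st$cfg$fgfr3$phi_normalization <- "total"
  expect_equal(phi_D(st)[m], 0.5)
  st$fg$D <- rep(0, st$reg$nreg)
  st$cfg$fgfr3$phi_normalization <- "half"
  expect_true(all(phi_D(st) == 0))
})

test_that("equilibrium fitness summaries match the analytic forms", {
  cfg <- default_config()
  eq0 <- equilibrium_fitness(0, 0, cfg)
  expect_equal(eq0$prolif_per_day, cfg$tumor$alpha_T_per_day)
  expect_equal(eq0$t_apop_days, 1 / cfg$tumor$delta_T_per_day)
  eq <- equilibrium_fitness(1.25, 0.9, cfg)
  expect_equal(eq$prolif_per_day, 0.5 + 1.25 * eq$phi_eq)
  expect_equal(eq$t_apop_days, 1 / (0.1 * (1 - 0.9 * eq$phi_eq)))
  expect_gt(eq$phi_eq, 0.9)      # strong default dimerization
  # full protection at eps -> 1, phi -> 1 would diverge; at the default
  # kinetics the expected time is finite but long
  grid <- sweep_grid(cfg)
  expect_equal(nrow(grid), 50)
  expect_equal(nrow(unique(grid[, c("alpha_F", "eps_F")])), 50)
  expect_gte(max(grid$prolif_per_day), 1.75)
})

test_that("a fully suppressed or absent pathway leaves recruitment intact", {
  st <- empty_state()
  place_tumor_cell(st, 4, 4, 4, mutant = FALSE)
  expect_equal(recruitment_suppression(st), 1)
})
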