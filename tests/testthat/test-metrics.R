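test_that("infiltrate percentage is the CTL share of all cells", {
  snap <- synthetic_agent_cloud("hull_square")
  expect_equal(ctl_infiltrate_pct(snap), 100 * 4 / 8)
  tum_only <- snap[snap$type == "tumor", ]
  expect_equal(ctl_infiltrate_pct(tum_only), 0)
  expect_warning(v <- ctl_infiltrate_pct(snap[0, ]), "empty")
  expect_true(is.na(v))
})

test_that("hull density counts active CTLs over the known hull area", {
  snap <- synthetic_agent_cloud("hull_square")
  # 10x10 square hull (area 100), 2 active CTLs inside; the outside CTL and
  # the exhausted CTL inside must not count
  expect_equal(hull_ctl_density(snap), 2 / 100)
  # boundary inclusivity: move one inside CTL onto a hull vertex
  snap2 <- snap
  tum <- snap2[snap2$type == "tumor", ]
  ctl_in <- which(snap2$type == "ctl" & snap2$state == "active")[1]
  snap2$x[ctl_in] <- tum$x[1]; snap2$y[ctl_in] <- tum$y[1]
  expect_equal(hull_ctl_density(snap2), 2 / 100)
  # no active CTLs in slice -> zero density
  snap3 <- snap[!(snap$type == "ctl" & snap$state == "active"), ]
  expect_equal(hull_ctl_density(snap3), 0)
  # degenerate hull flagged, not zero
  degen <- snap[snap$type == "tumor", ][1:2, ]
  expect_warning(v <- hull_ctl_density(degen), "hull")
  expect_true(is.na(v))
})

test_that("radial PDFs are shell-normalized and integrate to one", {
  dims <- c(13L, 13L, 13L)
  ctr <- c(7, 7, 7)
  uni <- synthetic_agent_cloud("uniform", dims = dims)
  rp <- radial_pdf(as.matrix(uni[, c("x", "y", "z")]), ctr, 1, dims)
  expect_lt(abs(sum(rp$density) * 1 - 1), 1e-6)
  occ_bins <- rp$n_sites > 0
  expect_lt(diff(range(rp$density[occ_bins])), 1e-12)  # exactly flat
  sh <- synthetic_agent_cloud("shell", dims = dims)
  rs <- radial_pdf(as.matrix(sh[, c("x", "y", "z")]), ctr, 2, dims)
  expect_equal(sum(rs$count > 0), 1L)                  # one occupied shell
  expect_lt(abs(sum(rs$density) * 2 - 1), 1e-6)
  mx <- synthetic_agent_cloud("mixed", dims = dims, n = 40, seed = 3)
  tum <- mx[mx$type == "tumor", ]
  rm_ <- radial_pdf(as.matrix(tum[, c("x", "y", "z")]),
                    c(mean(tum$x), mean(tum$y), mean(tum$z)), 0.75, dims)
  expect_lt(abs(sum(rm_$density) * 0.75 - 1), 1e-6)
})

test_that("percent reduction and response bins follow the decision rules", {
  mk <- function(b) structure(list(times = c(0, 25), burden = c(100, b)),
                              class = "tme_trial")
  expect_equal(percent_reduction(list(mk(70)), list(mk(100)), 25), 30)
  expect_equal(percent_reduction(list(mk(100)), list(mk(100)), 25), 0)
  expect_equal(percent_reduction(list(mk(0)), list(mk(100)), 25), 100)
  expect_warning(v <- percent_reduction(list(mk(10)), list(mk(0)), 25), "zero")
  expect_true(is.na(v))
  expect_equal(as.character(classify_response(c(10, 29.999, 30, 89.9, 90, 99))),
               c("not_effective", "not_effective", "effective", "effective",
                 "highly_effective", "highly_effective"))
  expect_error(classify_response(NA_real_), "finite")
  # invariance under common rescaling of both arms
  r1 <- percent_reduction(list(mk(55)), list(mk(100)), 25)
  r2 <- percent_reduction(list(mk(550)), list(mk(1000)),
                          25)
  expect_equal(classify_response(r1), classify_response(r2))
})

test_that("minimal best therapy prefers monotherapy and reports ties", {
  base <- c(ICI = 95, aFGFR3 = 40, FGFR3_first = 92, ICI_first = 50)
  expect_equal(minimal_best_therapy(base), "ICI")
  both_mono <- c(ICI = 45, aFGFR3 = 60, FGFR3_first = 70, ICI_first = 35)
  expect_setequal(minimal_best_therapy(both_mono), c("ICI", "aFGFR3"))
  combos_only <- c(ICI = 10, aFGFR3 = 5, FGFR3_first = 95, ICI_first = 91)
  expect_setequal(minimal_best_therapy(combos_only),
                  c("FGFR3_first", "ICI_first"))
  none <- c(ICI = 5, aFGFR3 = 12, FGFR3_first = 0, ICI_first = 29)
  expect_length(minimal_best_therapy(none), 0)
  expect_error(minimal_best_therapy(c(ICI = 50)), "arms")
})

test_that("kernel-smoothed histograms integrate to one", {
  set.seed(15)
  for (vals in list(rnorm(40, 100, 12), rexp(25, 0.1), runif(30, 0, 5))) {
    kd <- kde_histogram(vals)
    dx <- diff(kd$x[1:2])
    expect_lt(abs(sum(kd$density) * dx - 1), 1e-6)
  }
  # symmetry about the mean for symmetric input
  sym <- c(-3, -1, 0, 1, 3)
  kd <- kde_histogram(sym, bandwidth = 0.8)
  left <- kd$density[kd$x < 0]
  right <- rev(kd$density[kd$x > 0])
  n <- min(length(left), length(right))
  expect_lt(max(abs(left[seq_len(n)] - right[seq_len(n)])), 1e-6)
  # single tight cluster: mode within one bandwidth of the mean
  vals <- rnorm(50, 10, 0.3)
  kd2 <- kde_histogram(vals, bandwidth = 0.5)
  expect_lt(abs(kd2$x[which.max(kd2$density)] - mean(vals)), 0.5)
  expect_error(kde_histogram(1), "at least 2")
  expect_error(kde_histogram(rep(3, 10)), "variance")
})

test_that("a tiny landscape sweep produces classified rows", {
  cfg <- small_cfg(
    init = list(n_tumor = 15L, frac_mutant = 1, frac_ha = 0),
    time = list(t_end_days = 4),
    measure = list(log_every_steps = 24L))
  grid <- data.frame(alpha_F = c(0, 1.5), eps_F = c(0, 0.9))
  land <- run_fitness_sweep(cfg, grid, arms = c("ICI", "aFGFR3"),
                            n_reps = 1, base_seed = 3, day = 4)
  expect_equal(nrow(land), 2)
  expect_true(all(c("prolif_per_day", "t_apop_days", "red_ICI",
                    "bin_aFGFR3", "best") %in% names(land)))
  # the degenerate point has WT fitness on the axes
  expect_equal(land$prolif_per_day[1], cfg$tumor$alpha_T_per_day)
  expect_true(all(land$bin_ICI %in% c("not_effective", "effective",
                                      "highly_effective")))
})
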